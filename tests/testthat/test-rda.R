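test_that("constrained inertia hits its structural anchors", {
  set.seed(41)
  y <- rnorm(20)
  # single response explained by itself
  f <- fit_rda(matrix(y, dimnames = list(sprintf("s%d", 1:20), "y")),
               cbind(x = y))
  expect_equal(f$R2, 1, tolerance = 1e-10)

  # X orthogonal to the centered response by construction
  Y <- matrix(rnorm(30), 15, 2, dimnames = list(sprintf("s%d", 1:15), c("a", "b")))
  Yc <- scale(Y, scale = FALSE)
  x <- rnorm(15)
  x_orth <- resid(lm(x ~ Yc[, 1] + Yc[, 2]))
  f2 <- fit_rda(Yc[, 1, drop = FALSE], cbind(x = x_orth))
  expect_lt(f2$constrained_inertia, 1e-20)

  expect_true(abs(f2$total_inertia -
                  (f2$conditioned_inertia + f2$constrained_inertia +
                   f2$residual_inertia)) < 1e-8 * f2$total_inertia)
})

test_that("RDA equals the brute-force least-squares decomposition", {
  set.seed(42)
  Y <- matrix(rnorm(48), 12, 4,
              dimnames = list(sprintf("s%d", 1:12), sprintf("t%d", 1:4)))
  g <- rep(c(0, 1), each = 6)
  f <- fit_rda(Y, cbind(group = g))
  # oracle: SS of group-mean-fitted centered Y over total SS
  Yc <- scale(Y, scale = FALSE)
  fitted <- apply(Yc, 2L, function(col) ave(col, g))
  expect_equal(f$R2, sum(fitted^2) / sum(Yc^2), tolerance = 1e-10)
  expect_equal(f$F, (sum(fitted^2) / 1) / (sum((Yc - fitted)^2) / 10),
               tolerance = 1e-10)

  # one response column: reduces to ordinary regression R^2
  x1 <- rnorm(12); x2 <- rnorm(12)
  y1 <- matrix(rnorm(12), dimnames = list(sprintf("s%d", 1:12), "y"))
  fr <- fit_rda(y1, cbind(x1, x2))
  expect_equal(fr$R2, summary(lm(y1[, 1] ~ x1 + x2))$r.squared,
               tolerance = 1e-10)
})

test_that("RDA agrees with vegan on inertia, R2, F and eigenvalues", {
  skip_if_not_installed("vegan")
  set.seed(43)
  Y <- matrix(rnorm(100), 20, 5,
              dimnames = list(sprintf("s%d", 1:20), sprintf("t%d", 1:5)))
  X <- data.frame(a = rnorm(20), b = rep(c(0, 1), 10))
  f <- fit_rda(Y, as.matrix(X))
  v <- vegan::rda(Y ~ a + b, data = X)
  expect_equal(f$constrained_inertia, unname(v$CCA$tot.chi), tolerance = 1e-8)
  expect_equal(f$total_inertia, unname(v$tot.chi), tolerance = 1e-8)
  expect_equal(unname(f$eig), unname(v$CCA$eig), tolerance = 1e-8)
  av <- vegan::anova.cca(v, permutations = 99)
  expect_equal(f$F, av$F[1], tolerance = 1e-8)
  expect_equal(f$adj_R2,
               vegan::RsquareAdj(v)$adj.r.squared, tolerance = 1e-8)

  # partial RDA conditioned on a covariate
  Z <- matrix(rnorm(20), dimnames = list(NULL, "z"))
  fp <- fit_rda(Y, as.matrix(X), Z)
  vp <- vegan::rda(Y ~ a + b + Condition(z),
                   data = cbind(X, z = Z[, 1]))
  expect_equal(fp$constrained_inertia, unname(vp$CCA$tot.chi), tolerance = 1e-8)
  avp <- vegan::anova.cca(vp, permutations = 99)
  expect_equal(fp$F, avp$F[1], tolerance = 1e-8)
})

test_that("rank-deficient and constant designs error informatively", {
  Y <- matrix(rnorm(30), 10, 3,
              dimnames = list(sprintf("s%d", 1:10), c("a", "b", "c")))
  x <- rnorm(10)
  expect_error(fit_rda(Y, cbind(x1 = x, x2 = 2 * x)), "collinear")
  expect_error(fit_rda(Y, cbind(k = rep(1, 10))), "constant")
})

test_that("permutation p-values are reproducible, floored and calibrated", {
  set.seed(44)
  Y <- matrix(rnorm(60), 20, 3,
              dimnames = list(sprintf("s%d", 1:20), c("a", "b", "c")))
  x <- rnorm(20)
  p1 <- permutation_test(Y, cbind(x), n_perm = 99, seed = 5)
  p2 <- permutation_test(Y, cbind(x), n_perm = 99, seed = 5)
  expect_identical(p1$p, p2$p)
  expect_error(permutation_test(Y, cbind(x), n_perm = 0), "n_perm")

  # deterministic response => minimal attainable p
  Yd <- matrix(x, dimnames = list(sprintf("s%d", 1:20), "y"))
  pd <- permutation_test(Yd, cbind(x), n_perm = 99, seed = 6)
  expect_equal(pd$p, 1 / 100)

  # under independence the test holds its level (Monte-Carlo calibration)
  rej <- 0L
  set.seed(45)
  for (b in seq_len(200)) {
    Yb <- matrix(rnorm(36), 12, 3,
                 dimnames = list(sprintf("s%d", 1:12), c("a", "b", "c")))
    xb <- rnorm(12)
    pb <- permutation_test(Yb, cbind(x = xb), n_perm = 99, seed = b)
    rej <- rej + (pb$p <= 0.05)
  }
  expect_gte(rej / 200, 0.01)
  expect_lte(rej / 200, 0.09)
})

test_that("effects table covers simple and conditional modes coherently", {
  coh <- small_cohort(n_per_group = 12, n_taxa = 8, seed = 51,
                      bf_missing = c(cc = 0, home = 0))
  clr <- clr_transform(coh$abundance, pseudocount = 0)
  blocks <- design_blocks(coh$metadata)
  tab <- effects_table(clr, blocks, n_perm = 49, seed = 1)
  expect_setequal(unique(tab$term), names(blocks))
  expect_true(all(tab$df[tab$term == "Breastfeeding"] == 2))
  expect_true(all(tab$df[tab$term == "CC x Time"] == 3))
  expect_true(all(tab$p >= 1 / 50 & tab$p <= 1))

  # a single block has nothing to condition on: only the simple row exists
  tab1 <- effects_table(clr, blocks["Age"], n_perm = 19, seed = 2)
  expect_equal(tab1$mode, "simple")
})

test_that("variance partitioning obeys inclusion-exclusion exactly", {
  set.seed(52)
  n <- 24
  Y <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(sprintf("s%d", 1:n), sprintf("t%d", 1:5)))
  # three correlated blocks
  b1 <- cbind(x1 = rnorm(n)); b2 <- cbind(x2 = rnorm(n) + 0.5 * b1[, 1])
  b3 <- cbind(x3 = rnorm(n), x4 = rnorm(n))
  vp <- variance_partition(Y, list(A = b1, B = b2, C = b3))
  expect_equal(sum(vp$regions$fraction), vp$full_R2, tolerance = 1e-8)

  # orthogonal *centered* blocks: no shared fraction, uniques = simple R2
  q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 2), n))))
  bo1 <- cbind(o1 = q[, 2]); bo2 <- cbind(o2 = q[, 3])
  vo <- variance_partition(Y, list(A = bo1, B = bo2))
  shared <- vo$regions$fraction[vo$regions$region == "A:B"]
  expect_lt(abs(shared), 1e-8)
  expect_equal(unname(vo$unique), unname(vo$simple), tolerance = 1e-8)

  # a block duplicated under two names is entirely shared
  vd <- variance_partition(Y, list(A = b1, B = cbind(x1b = b1[, 1] * 2)))
  expect_true(all(abs(vd$unique) < 1e-8))
  expect_equal(unname(vd$regions$fraction[vd$regions$region == "A:B"]),
               unname(vd$simple["A"]), tolerance = 1e-8)

  expect_error(variance_partition(Y, list(b1, b2, b3, bo1, bo2)), "2-4")
})

test_that("partitioning matches vegan::varpart on adjusted fractions", {
  skip_if_not_installed("vegan")
  set.seed(53)
  n <- 30
  Y <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(sprintf("s%d", 1:n), sprintf("t%d", 1:4)))
  X1 <- cbind(a = rnorm(n)); X2 <- cbind(b = rnorm(n) + 0.4 * X1[, 1])
  vp <- variance_partition(Y, list(X1 = X1, X2 = X2))
  vv <- vegan::varpart(Y, X1, X2)
  ind <- vv$part$indfract
  expect_equal(unname(vp$regions$fraction_adj[vp$regions$region == "X1"]),
               ind$Adj.R.square[1], tolerance = 1e-8)
  expect_equal(unname(vp$regions$fraction_adj[vp$regions$region == "X2"]),
               ind$Adj.R.square[2], tolerance = 1e-8)
  expect_equal(unname(vp$regions$fraction_adj[vp$regions$region == "X1:X2"]),
               ind$Adj.R.square[3], tolerance = 1e-8)
})
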