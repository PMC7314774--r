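test_that("relative-abundance closure is exact, idempotent and guarded", {
  m <- matrix(c(2, 3, 5), 1, dimnames = list("s1", c("a", "b", "c")))
  rel <- to_relative_abundance(abundance_table(m, "signal"))
  expect_equal(unname(rel$values[1, ]), c(0.2, 0.3, 0.5))
  expect_equal(to_relative_abundance(rel)$values, rel$values)
  m0 <- matrix(c(0, 0, 0, 1, 2, 3), 2, byrow = TRUE,
               dimnames = list(c("sA", "sB"), c("a", "b", "c")))
  expect_error(to_relative_abundance(abundance_table(m0, "signal")), "sA")
})

test_that("clr matches its closed forms and zero-sum property", {
  m <- matrix(c(1, 2, 4) / 7, 1, dimnames = list("s1", c("a", "b", "c")))
  clr <- clr_transform(abundance_table(m, "relative"), pseudocount = 0)
  expect_equal(unname(clr$values[1, ]), c(-log(2), 0, log(2)), tolerance = 1e-12)

  u <- matrix(rep(0.25, 4), 1, dimnames = list("s1", letters[1:4]))
  expect_equal(unname(clr_transform(abundance_table(u, "relative"), 0)$values[1, ]),
               rep(0, 4))

  tab <- rand_abundance(n = 10, k = 6, seed = 7, scale = "relative")
  out <- clr_transform(tab, pseudocount = 0)
  expect_true(all(abs(rowSums(out$values)) < 1e-8))
  # against the direct formula log(x) - mean(log(x))
  direct <- t(apply(tab$values, 1L, function(x) log(x) - mean(log(x))))
  expect_equal(out$values, direct, tolerance = 1e-12)
})

test_that("clr handles zeros through the pseudocount policy", {
  m <- matrix(c(0, 0.4, 0.6), 1, dimnames = list("s1", c("a", "b", "c")))
  tab <- abundance_table(m, "relative")
  expect_error(clr_transform(tab, pseudocount = 0), "pseudocount")
  auto <- clr_transform(tab)           # default: half the smallest positive
  expect_equal(auto$pseudocount, 0.2)
  expect_equal(sum(auto$values), 0, tolerance = 1e-10)
})

test_that("Shannon diversity hits the analytic anchors", {
  m <- rbind(uniform = c(0.25, 0.25, 0.25, 0.25),
             single = c(1, 0, 0, 0),
             two = c(0.5, 0.5, 0, 0))
  colnames(m) <- letters[1:4]
  H <- shannon_diversity(abundance_table(m, "relative"))
  expect_equal(unname(H), c(log(4), 0, log(2)), tolerance = 1e-12)
  # permutation invariance and the uniform maximum
  tab <- rand_abundance(n = 5, k = 6, seed = 13, scale = "relative")
  perm <- tab$values[, sample(6)]
  expect_equal(sort(unname(shannon_diversity(abundance_table(perm, "relative")))),
               sort(unname(shannon_diversity(tab))))
  expect_true(all(shannon_diversity(tab) <= log(6) + 1e-12))
})

test_that("detection-threshold richness follows the per-feature quantile rule", {
  m <- cbind(f1 = c(1, 2, 3, 4, 10), f2 = rep(2, 5))
  rownames(m) <- sprintf("s%d", 1:5)
  r <- richness(abundance_table(m, "signal"), detection_quantile = 0.8)
  # f1 threshold = type-7 quantile(., 0.8) = 5.2 -> only the sample at 10
  # exceeds; constant f2 never exceeds its own quantile
  expect_equal(unname(r), c(0L, 0L, 0L, 0L, 1L))
  expect_equal(unname(stats::quantile(m[, "f1"], 0.8)), 5.2, tolerance = 1e-12)

  tab <- rand_abundance(n = 8, k = 10, seed = 17)
  expect_true(all(richness(tab) <= 10L))
  # monotone non-increasing in the detection quantile
  qs <- c(0.2, 0.5, 0.8, 0.95)
  rr <- sapply(qs, function(q) sum(richness(tab, q)))
  expect_true(all(diff(rr) <= 0))
  one <- abundance_table(m[1, , drop = FALSE], "signal")
  expect_error(richness(one), "two samples")
})

test_that("coefficient of variation uses the sample-SD convention and is scale-free", {
  m <- cbind(const = c(0.5, 0.5), varies = c(0.2, 0.4), rest = c(0.3, 0.1))
  rownames(m) <- c("s1", "s2")
  cv <- coefficient_of_variation(abundance_table(m / rowSums(m), "relative"))
  expect_equal(unname(cv["const"]), 0)
  # values (0.2, 0.4) after closure stay (0.2, 0.4): mean .3, sd sqrt(2)*.1
  expect_equal(unname(cv["varies"]), sqrt(2) / 3, tolerance = 1e-12)

  tab <- rand_abundance(n = 6, k = 4, seed = 23)
  cv1 <- coefficient_of_variation(to_relative_abundance(tab))
  scaled <- abundance_table(tab$values * 37, "signal")
  cv2 <- coefficient_of_variation(to_relative_abundance(scaled))
  expect_equal(cv1, cv2, tolerance = 1e-12)

  mz <- cbind(a = c(1, 1), b = c(0, 0))
  mz <- mz / rowSums(mz)
  rownames(mz) <- c("s1", "s2")
  expect_warning(cvz <- coefficient_of_variation(abundance_table(mz, "relative")),
                 "undefined")
  expect_true(is.na(cvz["b"]))
  expect_false(is.na(cvz["a"]))
})
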