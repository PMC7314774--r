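quick_fit <- function(df, ...) {
  suppressWarnings(robt(y ~ cc * time, df, sigma = ~ cc,
                        subject = "infant_id", chains = 1, iter = 20,
                        warmup = 20, thin = 1, ...))
}

test_that("the implemented log posterior matches a hand-coded evaluation", {
  set.seed(71)
  df <- simulate_study_outcome(J = 8, seed = 71)
  fit <- quick_fit(df)
  dat <- fit$dat
  npar <- 2 + ncol(dat$Xmu) + ncol(dat$Xsg) + 2 + 8
  for (rep in seq_len(20)) {
    par <- rnorm(npar, sd = 0.7)
    expect_equal(robt_log_posterior(fit, par), oracle_logpost(par, dat),
                 tolerance = 1e-6)
  }
})

test_that("posterior recovers a known mean-model effect", {
  set.seed(72)
  n <- 400
  x <- rnorm(n)
  df <- data.frame(y = 0.8 * x + 0.2 * rnorm(n), x = x,
                   sid = sprintf("g%03d", rep(1:(n / 2), 2)))
  f <- suppressWarnings(robt(y ~ x, df, subject = "sid", standardize = FALSE,
                             chains = 2, iter = 500, warmup = 600, thin = 3,
                             seed = 1))
  expect_lt(abs(coef(f)[["b_x"]] - 0.8), 0.15)
})

test_that("sigma regression recovers group heteroscedasticity", {
  set.seed(73)
  n <- 400
  g <- rep(c(0, 1), each = n / 2)
  y <- rnorm(n, 0, ifelse(g == 1, 1.0, 0.5))   # sigma doubled in group 1
  df <- data.frame(y = y, g = g)
  f <- suppressWarnings(robt(y ~ g, df, sigma = ~ g, chains = 2, iter = 500,
                             warmup = 600, thin = 3, seed = 2))
  lr <- coef(f)[["bs_g"]]               # log sigma ratio
  expect_lt(abs(lr - log(2)) / log(2), 0.25)
})

test_that("the t likelihood resists gross outliers where the gaussian does not", {
  set.seed(74)
  n <- 300
  x <- rnorm(n)
  y_clean <- 0.7 * x + 0.4 * rt(n, df = 3)
  y_out <- y_clean
  idx <- sample(n, 15)                          # 5% wild contamination
  y_out[idx] <- y_out[idx] + sample(c(-1, 1), 15, TRUE) * runif(15, 8, 12)
  fit1 <- function(yy, fam) suppressWarnings(
    robt(y ~ x, data.frame(y = yy, x = x), family = fam, standardize = FALSE,
         chains = 2, iter = 400, warmup = 500, thin = 2, seed = 3))
  b_clean <- coef(fit1(y_clean, "student"))[["b_x"]]
  b_robust <- coef(fit1(y_out, "student"))[["b_x"]]
  b_gauss <- coef(fit1(y_out, "gaussian"))[["b_x"]]
  shift_robust <- abs(b_robust - b_clean)
  shift_gauss <- abs(b_gauss - b_clean)
  expect_lt(shift_robust, 0.1)
  expect_gt(shift_gauss, shift_robust)
})

test_that("with light tails the t fit agrees with the gaussian fit", {
  set.seed(75)
  n <- 300
  x <- rnorm(n)
  df <- data.frame(y = 1 + 0.5 * x + 0.3 * rnorm(n), x = x)
  fs <- suppressWarnings(robt(y ~ x, df, chains = 2, iter = 400, warmup = 500,
                              thin = 2, seed = 4))
  fg <- suppressWarnings(robt(y ~ x, df, family = "gaussian", chains = 2,
                              iter = 400, warmup = 500, thin = 2, seed = 4))
  expect_lt(abs(coef(fs)[["b_x"]] - coef(fg)[["b_x"]]), 0.03)
  expect_lt(abs(coef(fs)[["b0"]] - coef(fg)[["b0"]]), 0.03)
})

test_that("posterior summaries match an independent MCMC engine", {
  skip_if_not_installed("rjags")
  set.seed(76)
  J <- 30; n <- 60
  inf <- rep(sprintf("S%02d", 1:J), 2)
  x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.5)
  u <- rnorm(J, 0, 0.4); names(u) <- sprintf("S%02d", 1:J)
  y <- 1 + 0.6 * x1 - 0.4 * x2 + u[inf] + 0.5 * rt(n, 6)
  df <- data.frame(y, x1, x2, infant_id = inf)
  f <- suppressWarnings(robt(y ~ x1 + x2, df, sigma = ~ x2,
                             subject = "infant_id", standardize = FALSE,
                             chains = 2, iter = 3000, warmup = 2000, thin = 4,
                             seed = 5))
  mad_y <- mad(y); sd_y <- sd(y)
  mstr <- "model {
    for (i in 1:N) {
      mu[i] <- b0 + u[subj[i]] + b1*x1[i] + b2*x2[i]
      tau_y[i] <- exp(-2*(g0 + s1*x2[i]))
      y[i] ~ dt(mu[i], tau_y[i], nuv)
    }
    for (j in 1:J) { u[j] ~ dnorm(0, pow(tau_u,-2)) }
    b1 ~ dnorm(0,1); b2 ~ dnorm(0,1); s1 ~ dnorm(0,1)
    b0 ~ dt(b0loc, pow(b0sc,-2), 3)
    g0 ~ dt(g0loc, pow(2.5,-2), 3)
    tau_u ~ dt(0, pow(tausc,-2), 3) T(0,)
    nuv <- 1 + nr
    nr ~ dgamma(2, 0.1)
  }"
  m <- rjags::jags.model(
    textConnection(mstr),
    data = list(y = as.numeric(y), x1 = x1, x2 = x2, N = n, J = J,
                subj = as.integer(factor(inf)), b0loc = median(y),
                b0sc = 2.5 * mad_y, g0loc = log(sd_y), tausc = 2.5 * mad_y),
    inits = list(list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = 1)),
    n.chains = 1, n.adapt = 1000, quiet = TRUE)
  update(m, 1500, progress.bar = "none")
  s <- rjags::coda.samples(m, c("b0", "b1", "b2", "g0", "s1", "tau_u"),
                           n.iter = 12000, progress.bar = "none")
  ref <- summary(s)$statistics
  mine <- summary(f)
  pick <- function(p) mine$mean[mine$parameter == p]
  expect_equal(pick("b0"), unname(ref["b0", "Mean"]), tolerance = 0.05)
  expect_equal(pick("b_x1"), unname(ref["b1", "Mean"]), tolerance = 0.04)
  expect_equal(pick("b_x2"), unname(ref["b2", "Mean"]), tolerance = 0.05)
  expect_equal(pick("g0"), unname(ref["g0", "Mean"]), tolerance = 0.06)
  expect_equal(pick("bs_x2"), unname(ref["s1", "Mean"]), tolerance = 0.07)
  expect_equal(pick("tau"), unname(ref["tau_u", "Mean"]), tolerance = 0.05)
})

test_that("contrast flags are a pure function of the interval", {
  set.seed(77)
  d <- cbind(a = rnorm(4000, 0.5, 0.1), b = rnorm(4000, 0, 1))
  ct <- contrast_summaries(d, list(pos = c(a = 1), null = c(b = 1),
                                   self = c(a = 1, a = -1)))
  expect_true(ct$flagged[ct$contrast == "pos"])
  expect_false(ct$flagged[ct$contrast == "null"])
  expect_equal(ct$median[ct$contrast == "self"], 0)
  expect_false(ct$flagged[ct$contrast == "self"])
  expect_equal(ct$flagged, ct$lower > 0 | ct$upper < 0)
  expect_error(contrast_summaries(d, list(bad = c(zzz = 1))), "zzz")
})

test_that("imputation pooling concatenates draws and checks names", {
  df <- simulate_study_outcome(J = 10, seed = 78)
  f1 <- quick_fit(df, seed = 1)
  f2 <- quick_fit(df, seed = 2)
  pooled <- pool_imputations(list(f1, f2))
  expect_equal(nrow(pooled$draws), nrow(f1$draws) + nrow(f2$draws))
  f3 <- suppressWarnings(robt(y ~ cc, df, subject = "infant_id",
                              chains = 1, iter = 20, warmup = 20, thin = 1))
  expect_error(pool_imputations(list(f1, f3)), "mismatched")
})

test_that("fits are deterministic under a fixed seed and expose diagnostics", {
  df <- simulate_study_outcome(J = 12, seed = 79)
  f1 <- quick_fit(df, seed = 9)
  f2 <- quick_fit(df, seed = 9)
  expect_identical(f1$draws, f2$draws)
  expect_true(all(is.finite(f1$rhat)))
  expect_identical(f1$n_divergent, NA_integer_)
  expect_equal(anyDuplicated(colnames(f1$draws)), 0L)
})

test_that("model methods behave coherently", {
  set.seed(80)
  df <- simulate_study_outcome(J = 20, b = c(cc = 0.3, time = 0, cc_time = 0),
                               seed = 80)
  f <- suppressWarnings(robt(y ~ cc * time + age + bf + sib * csec, df,
                             sigma = ~ cc * time + sib * csec,
                             subject = "infant_id", chains = 2, iter = 300,
                             warmup = 500, thin = 2, seed = 6))
  expect_equal(length(fitted(f)), nrow(df))
  expect_equal(residuals(f), df$y - fitted(f))
  pr <- predict(f, type = "mean")
  expect_equal(nrow(pr), nrow(df))
  expect_true(all(pr$lower <= pr$median & pr$median <= pr$upper))
  sg <- predict(f, type = "sigma")
  expect_true(all(sg$median > 0))
  nd <- df[1:4, ]
  pp <- predict(f, newdata = nd, type = "response", summary = FALSE)
  expect_equal(ncol(pp), 4L)
  sims <- simulate(f, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(nrow(df), 3L))
  out <- capture.output(print(f))
  expect_true(any(grepl("Robust hierarchical", out)))
})

test_that("per-taxon sweep returns one contrast table row block per taxon", {
  coh <- small_cohort(n_per_group = 10, n_taxa = 3, seed = 81,
                      bf_missing = c(cc = 0, home = 0))
  clr <- clr_transform(coh$abundance, pseudocount = 0)
  tab <- suppressWarnings(
    fit_all_taxa(clr, coh$metadata, taxa = 1, chains = 1, iter = 150,
                 warmup = 300, thin = 2, seed = 1))
  expect_equal(unique(tab$taxon), clr$taxon_ids[1])
  expect_equal(nrow(tab), 14L)   # the default contrast set
  expect_true(all(c("median", "lower", "upper", "flagged") %in% names(tab)))
})

test_that("posterior predictive intervals achieve nominal coverage at a profile", {
  sigma_true <- 0.45; tau_true <- 0.3; nu_true <- 20
  df <- simulate_study_outcome(J = 98, b = c(cc = 0, time = 0, cc_time = 0),
                               sigma = sigma_true, tau = tau_true,
                               nu = nu_true, seed = 404)
  f <- suppressWarnings(robt(y ~ cc * time + age + bf + sib * csec, df,
                             sigma = ~ cc * time + sib * csec,
                             subject = "infant_id", chains = 2, iter = 600,
                             warmup = 800, thin = 3, seed = 1))
  prof <- data.frame(cc = 0, time = 0, age = 0, bf = 0, sib = 0, csec = 0)
  pi95 <- predict(f, newdata = prof, type = "response")
  # fresh observations from the true data-generating process at the profile
  set.seed(405)
  fresh <- rnorm(4000, 0, tau_true) + sigma_true * rt(4000, df = nu_true)
  cover <- mean(fresh >= pi95$lower & fresh <= pi95$upper)
  expect_gt(cover, 0.88)
  expect_lt(cover, 0.995)
})
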