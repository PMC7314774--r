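# small cohorts and hand-built tables shared across test files

small_cohort <- function(n_per_group = 8, n_taxa = 12, seed = 1, ...) {
  generate_cohort(cohort_config(n_per_group = n_per_group, n_taxa = n_taxa,
                                seed = seed, ...))
}

# minimal valid two-infant metadata frame
tiny_meta <- function() {
  data.frame(
    sample_id = c("a_PRE", "a_POST", "b_PRE", "b_POST"),
    infant_id = c("a", "a", "b", "b"),
    group = c("CC", "CC", "HOME", "HOME"),
    timepoint = c("PRE", "POST", "PRE", "POST"),
    age_days = c(80, 110, 75, 105),
    bf_rate = c(5, 4, 6, 5),
    bf_rate_prior_period = c(5, 5, 6, 6),
    sibling = c(TRUE, TRUE, FALSE, FALSE),
    csection = c(FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE)
}

rand_abundance <- function(n = 6, k = 4, seed = 99, scale = "signal") {
  set.seed(seed)
  m <- matrix(stats::runif(n * k, 0.1, 10), n, k,
              dimnames = list(sprintf("s%02d", seq_len(n)),
                              sprintf("t%02d", seq_len(k))))
  if (scale == "relative") m <- m / rowSums(m)
  abundance_table(m, scale = scale)
}

# simulate an outcome from the study's data-generating model on a
# cohort-shaped design; returns the data frame ready for robt()
simulate_study_outcome <- function(J = 98, b = c(cc = 0, time = 0, cc_time = -0.22),
                                   sigma = 0.45, tau = 0.3, nu = 20, seed = 1) {
  set.seed(seed)
  inf <- rep(sprintf("I%03d", seq_len(J)), 2)
  cc <- rep(rep(c(1, 0), each = J / 2), 2)
  tm <- rep(c(0, 1), each = J)
  age <- rnorm(2 * J); bf <- rnorm(2 * J)
  sib <- rbinom(2 * J, 1, 0.5); csec <- rbinom(2 * J, 1, 0.1)
  u <- rnorm(J, 0, tau); names(u) <- sprintf("I%03d", seq_len(J))
  y <- b[["cc"]] * cc + b[["time"]] * tm + b[["cc_time"]] * cc * tm +
    u[inf] + sigma * rt(2 * J, df = nu)
  data.frame(y = y, cc = cc, time = tm, age = age, bf = bf,
             sib = sib, csec = csec, infant_id = inf)
}

# hand-coded log posterior used as the independent oracle: Student-t
# likelihood via stats::dt on standardized residuals, priors written out
# term by term with R's density functions
oracle_logpost <- function(par, dat) {
  pm <- ncol(dat$Xmu); ps <- ncol(dat$Xsg)
  k <- 1
  b0 <- par[k]; k <- k + 1
  beta <- par[seq_len(pm) + k - 1]; k <- k + pm
  g0 <- par[k]; k <- k + 1
  betas <- par[seq_len(ps) + k - 1]; k <- k + ps
  log_tau <- par[k]; k <- k + 1
  log_nu_raw <- par[k]; k <- k + 1
  u <- par[k:length(par)]
  tau <- exp(log_tau); nu <- 1 + exp(log_nu_raw)

  mu <- b0 + as.numeric(dat$Xmu %*% beta) + u[dat$subj + 1]
  eta <- g0 + as.numeric(dat$Xsg %*% betas)
  sg <- if (dat$log_link) exp(eta) else eta
  lp <- sum(stats::dt((dat$y - mu) / sg, df = nu, log = TRUE) - log(sg))
  lp <- lp + sum(stats::dnorm(beta, 0, dat$beta_sd, log = TRUE))
  lp <- lp + sum(stats::dnorm(betas, 0, dat$betas_sd, log = TRUE))
  tl <- function(x, loc, sc) stats::dt((x - loc) / sc, df = 3, log = TRUE) - log(sc)
  lp <- lp + tl(b0, dat$b0_loc, dat$b0_scale) + tl(g0, dat$g0_loc, dat$g0_scale)
  if (dat$use_u) {
    lp <- lp + log(2) + tl(tau, 0, dat$tau_scale) + log_tau   # half-t + jacobian
    lp <- lp + sum(stats::dnorm(u, 0, tau, log = TRUE))
  }
  lp + stats::dgamma(exp(log_nu_raw), dat$nu_shape, dat$nu_rate, log = TRUE) +
    log_nu_raw
}

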