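#' Priors for the robust hierarchical model
#'
#' Comparison (slope) coefficients on both the mean and the sigma linear
#' predictor get independent Normal(0, 1) priors, which presumes
#' standardized continuous covariates and 0/1 binaries so that "1" is a
#' large effect on every outcome's scale. Intercepts get wide data-driven
#' Student-t(3) priors, the hierarchical SD a half-t(3), and the
#' normality parameter is `nu = 1 + nu_raw` with `nu_raw ~
#' Gamma(shape, rate)` so the likelihood can approach the gaussian but
#' never loses a defined mean.
#'
#' @param beta_sd prior SD of mean-model coefficients.
#' @param betas_sd prior SD of sigma-model coefficients.
#' @param nu_shape,nu_rate Gamma prior on `nu - 1`.
#' @return List of class `robt_priors`.
#' @export
robt_priors <- function(beta_sd = 1, betas_sd = 1, nu_shape = 2, nu_rate = 0.1) {
  structure(list(beta_sd = beta_sd, betas_sd = betas_sd,
                 nu_shape = nu_shape, nu_rate = nu_rate),
            class = "robt_priors")
}

#' Bayesian hierarchical robust regression with distributional sigma
#'
#' Fits
#' \deqn{y_i \sim T(\nu, \mu_i, \sigma_i)}
#' with \eqn{\mu_i = \beta_0 + u_{j[i]} + x_i'\beta} and
#' \eqn{\log \sigma_i = \beta_{\sigma 0} + z_i'\beta_\sigma} (log link by
#' default; an identity link is available and rejects non-positive
#' sigma). Subjects deviate from the population intercept through
#' partial pooling: \eqn{u_j \sim N(0, \tau)}. The Student-t likelihood
#' downweights outlying observations; the sigma regression lets the
#' residual spread differ between groups instead of assuming
#' homogeneous variance.
#'
#' Sampling uses an adaptive Metropolis-within-Gibbs scheme (see the
#' package vignette); proposal scales and covariances adapt only during
#' warmup. Convergence is screened via split-Rhat across chains; values
#' above 1.05 trigger a warning and are flagged in the result.
#'
#' @param formula model formula for the mean, e.g.
#'   `shannon ~ cc * time + age + bf + sib * csec`.
#' @param data data frame with all variables; no missing values (impute
#'   first, see [pmm_impute()]).
#' @param sigma one-sided formula for the sigma linear predictor
#'   (default `~ 1`, homoscedastic).
#' @param subject name of the grouping column for the per-subject
#'   intercept deviations, or `NULL` for no subject term.
#' @param family `"student"` (default) or `"gaussian"` (fixes the
#'   likelihood to the normal limit; no `nu` parameter).
#' @param sigma_link `"log"` (default) or `"identity"`.
#' @param standardize center/scale continuous covariates to unit SD
#'   (binary 0/1 columns are left alone); default `TRUE` so the
#'   Normal(0,1) coefficient priors are comparable across outcomes.
#' @param chains,iter,warmup,thin MCMC settings: `chains` independent
#'   chains, each run for `warmup` adaptation iterations (discarded) plus
#'   `iter * thin` further iterations saved every `thin`-th.
#' @param priors a [robt_priors()] object.
#' @param seed integer seed; fits are reproducible.
#' @return Object of class `robt` with posterior draws, chain ids,
#'   split-Rhat per parameter, the designs and scaling used, and the
#'   model specification. Methods: `print`, `summary`, `coef`,
#'   `fitted`, `residuals`, `predict`, `simulate`, `plot`.
#' @export
robt <- function(formula, data, sigma = ~ 1, subject = NULL,
                 family = c("student", "gaussian"),
                 sigma_link = c("log", "identity"),
                 standardize = TRUE,
                 chains = 4L, iter = 1000L, warmup = 1000L, thin = 4L,
                 priors = robt_priors(), seed = 1L) {
  family <- match.arg(family)
  sigma_link <- match.arg(sigma_link)
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  if (!is.numeric(y)) stopf("response must be numeric")
  Xmu <- stats::model.matrix(formula, mf)
  Xmu <- Xmu[, colnames(Xmu) != "(Intercept)", drop = FALSE]
  Xsg <- stats::model.matrix(sigma, stats::model.frame(sigma, data,
                                                       na.action = stats::na.fail))
  Xsg <- Xsg[, colnames(Xsg) != "(Intercept)", drop = FALSE]

  scaling <- list(mu = NULL, sg = NULL)
  if (standardize) {
    std <- standardize_columns(Xmu)
    Xmu <- std$X; scaling$mu <- std$info
    std <- standardize_columns(Xsg)
    Xsg <- std$X; scaling$sg <- std$info
  }

  if (!is.null(subject)) {
    if (inherits(subject, "formula")) subject <- all.vars(subject)
    sv <- factor(data[[subject]])
    subj <- as.integer(sv) - 1L
    subjects <- levels(sv)
  } else {
    subj <- rep(0L, length(y))
    subjects <- character(0)
  }

  fit <- robt_run(y, Xmu, Xsg, subj, use_u = !is.null(subject),
                  family = family, sigma_link = sigma_link,
                  chains = chains, iter = iter, warmup = warmup, thin = thin,
                  priors = priors, seed = seed, subjects = subjects)
  fit$call <- match.call()
  fit$formula <- formula
  fit$sigma_formula <- sigma
  fit$subject <- subject
  fit$scaling <- scaling
  fit$data <- data
  fit
}

standardize_columns <- function(X) {
  if (ncol(X) == 0L)
    return(list(X = X, info = data.frame(column = character(0), center = numeric(0),
                                         scale = numeric(0))))
  info <- data.frame(column = colnames(X), center = 0, scale = 1,
                     stringsAsFactors = FALSE)
  for (j in seq_len(ncol(X))) {
    v <- X[, j]
    if (all(v %in% c(0, 1))) next
    info$center[j] <- mean(v)
    info$scale[j] <- stats::sd(v)
    if (info$scale[j] == 0) stopf("constant covariate column '%s'", colnames(X)[j])
    X[, j] <- (v - info$center[j]) / info$scale[j]
  }
  list(X = X, info = info)
}

# core sampler driver shared by robt() and sample_posterior()
robt_run <- function(y, Xmu, Xsg, subj, use_u, family, sigma_link,
                     chains, iter, warmup, thin, priors, seed,
                     subjects = character(0)) {
  n <- length(y)
  J <- if (use_u) max(subj) + 1L else 1L
  mad_y <- stats::mad(y)
  if (mad_y == 0) mad_y <- max(stats::sd(y), 1e-3)
  sd_y <- max(stats::sd(y), 1e-3)
  dat <- list(y = as.numeric(y), Xmu = Xmu, Xsg = Xsg,
              subj = as.integer(if (use_u) subj else rep(0L, n)),
              student = family == "student", log_link = sigma_link == "log",
              b0_loc = stats::median(y), b0_scale = 2.5 * mad_y,
              g0_loc = if (sigma_link == "log") log(sd_y) else sd_y,
              g0_scale = 2.5,
              tau_scale = 2.5 * mad_y,
              nu_shape = priors$nu_shape, nu_rate = priors$nu_rate,
              beta_sd = priors$beta_sd, betas_sd = priors$betas_sd,
              use_u = use_u)
  pm <- ncol(Xmu); ps <- ncol(Xsg)
  init_base <- c(stats::median(y), rep(0, pm),
                 if (sigma_link == "log") log(sd_y) else sd_y, rep(0, ps),
                 log(mad_y / 2), log(20), rep(0, J))
  draws_list <- vector("list", chains)
  n_keep <- iter
  with_seed(seed, {
    for (ch in seq_len(chains)) {
      init <- init_base
      jit <- stats::rnorm(length(init), 0, 0.1)
      jit[length(init) - J + seq_len(J)] <- 0
      init <- init + jit
      res <- robt_sample_cpp(dat, init, as.integer(warmup),
                             as.integer(n_keep * thin))
      d <- res$draws[seq(thin, n_keep * thin, by = thin), , drop = FALSE]
      colnames(d) <- c("b0",
                       if (pm > 0) paste0("b_", colnames(Xmu)),
                       "g0",
                       if (ps > 0) paste0("bs_", colnames(Xsg)),
                       "tau", "nu",
                       paste0("u_", if (length(subjects)) subjects else seq_len(J)))
      draws_list[[ch]] <- d
    }
  })
  draws <- do.call(rbind, draws_list)
  chain_id <- rep(seq_len(chains), each = n_keep)
  fixed <- setdiff(colnames(draws), grep("^u_", colnames(draws), value = TRUE))
  if (family == "gaussian") fixed <- setdiff(fixed, "nu")
  if (!use_u) fixed <- setdiff(fixed, "tau")
  rhat <- vapply(fixed, function(p)
    split_rhat(matrix(draws[, p], ncol = chains)), numeric(1))
  converged <- all(is.finite(rhat) & rhat < 1.05)
  if (!converged)
    warnf("convergence warning: max split-Rhat = %.3f (threshold 1.05)",
          max(rhat, na.rm = TRUE))
  structure(list(draws = draws, chain_id = chain_id, rhat = rhat,
                 converged = converged, n_divergent = NA_integer_,
                 y = y, Xmu = Xmu, Xsg = Xsg, subj = subj, use_u = use_u,
                 subjects = subjects, family = family,
                 sigma_link = sigma_link, priors = priors, dat = dat,
                 chains = chains, iter = iter, warmup = warmup, thin = thin,
                 seed = seed),
            class = "robt")
}

#' Split-Rhat convergence diagnostic
#'
#' Potential scale reduction computed after splitting each chain in half,
#' so within-chain drift also registers as non-convergence.
#'
#' @param x matrix of draws with one column per chain.
#' @return The split-Rhat statistic (1 at perfect convergence).
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  half <- floor(n / 2)
  if (half < 2L) return(NA_real_)
  sp <- cbind(x[seq_len(half), , drop = FALSE],
              x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sp); nn <- nrow(sp)
  means <- colMeans(sp)
  vars <- apply(sp, 2L, stats::var)
  W <- mean(vars)
  B <- nn * stats::var(means)
  if (W == 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' Evaluate the model's log posterior density
#'
#' The unnormalised log posterior (Student-t or gaussian log likelihood
#' plus all log priors, including change-of-variable jacobians for the
#' positive parameters) at a given parameter vector, in the internal
#' parameter layout `b0, beta, g0, beta_sigma, log(tau), log(nu - 1), u`.
#'
#' @param object a fitted `robt` object (supplies data, designs, priors).
#' @param par numeric parameter vector in the layout above.
#' @return Scalar log posterior density (up to the normalising constant).
#' @export
robt_log_posterior <- function(object, par) {
  stopifnot(inherits(object, "robt"))
  robt_logpost_cpp(par, object$dat)
}

#' @export
print.robt <- function(x, ...) {
  cat(sprintf("Robust hierarchical %s model (%s-link sigma)\n",
              x$family, x$sigma_link))
  cat(sprintf("  %d observations, %d subjects; %d chains x %d draws (thin %d)\n",
              length(x$y), if (x$use_u) length(x$subjects) else 0L,
              x$chains, x$iter, x$thin))
  cat(sprintf("  max split-Rhat %.3f%s\n", max(x$rhat),
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(round(coef(x), 3))
  invisible(x)
}

#' @export
coef.robt <- function(object, ...) {
  fixed <- setdiff(colnames(object$draws),
                   grep("^u_", colnames(object$draws), value = TRUE))
  apply(object$draws[, fixed, drop = FALSE], 2L, stats::median)
}

#' @export
summary.robt <- function(object, prob = 0.95, ...) {
  a <- (1 - prob) / 2
  fixed <- setdiff(colnames(object$draws),
                   grep("^u_", colnames(object$draws), value = TRUE))
  d <- object$draws[, fixed, drop = FALSE]
  out <- data.frame(
    parameter = fixed,
    median = apply(d, 2L, stats::median),
    mean = colMeans(d),
    sd = apply(d, 2L, stats::sd),
    lower = apply(d, 2L, stats::quantile, probs = a),
    upper = apply(d, 2L, stats::quantile, probs = 1 - a),
    rhat = object$rhat[fixed],
    row.names = NULL)
  class(out) <- c("summary.robt", "data.frame")
  out
}

#' @export
print.summary.robt <- function(x, ...) {
  y <- x
  class(y) <- "data.frame"
  y[-1] <- lapply(y[-1], round, 3)
  print(y, row.names = FALSE)
  invisible(x)
}

# posterior draws of mu and sigma for given designs
robt_linpred <- function(object, Xmu, Xsg, subj_names = NULL) {
  d <- object$draws
  beta_cols <- paste0("b_", colnames(object$Xmu))
  bs_cols <- paste0("bs_", colnames(object$Xsg))
  mu <- d[, "b0"] + tcrossprod(d[, beta_cols, drop = FALSE], Xmu)
  eta_sg <- d[, "g0"] + tcrossprod(d[, bs_cols, drop = FALSE], Xsg)
  if (!is.null(subj_names)) {
    known <- subj_names %in% object$subjects
    for (i in which(known))
      mu[, i] <- mu[, i] + d[, paste0("u_", subj_names[i])]
  }
  sigma <- if (object$sigma_link == "log") exp(eta_sg) else eta_sg
  list(mu = mu, sigma = sigma)
}

#' @export
fitted.robt <- function(object, ...) {
  subj_names <- if (object$use_u) object$subjects[object$subj + 1L] else NULL
  lp <- robt_linpred(object, object$Xmu, object$Xsg, subj_names)
  apply(lp$mu, 2L, stats::median)
}

#' @export
residuals.robt <- function(object, ...) {
  object$y - fitted.robt(object)
}

#' Posterior predictions from a robust hierarchical fit
#'
#' @param object a fitted `robt`.
#' @param newdata optional data frame; defaults to the training data.
#'   Continuous covariates are standardized with the training centers and
#'   scales. Unknown subjects get the population intercept (`type =
#'   "mean"`, `"sigma"`) or a fresh subject deviation (`type =
#'   "response"`).
#' @param type `"mean"` (posterior draws of mu), `"sigma"` (draws of
#'   sigma), or `"response"` (posterior predictive draws of new
#'   observations).
#' @param summary if `TRUE` (default) return a data frame of medians and
#'   central 95% intervals; otherwise the draws-by-rows matrix.
#' @param ... unused.
#' @return Data frame or matrix, one column/row block per `newdata` row.
#' @export
predict.robt <- function(object, newdata = NULL,
                         type = c("mean", "sigma", "response"),
                         summary = TRUE, ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    Xmu <- object$Xmu; Xsg <- object$Xsg
    subj_names <- if (object$use_u) object$subjects[object$subj + 1L] else NULL
  } else {
    ff <- object$formula
    rhs <- stats::delete.response(stats::terms(ff))
    Xmu <- stats::model.matrix(rhs, newdata)
    Xmu <- Xmu[, colnames(Xmu) != "(Intercept)", drop = FALSE]
    Xsg <- stats::model.matrix(object$sigma_formula, newdata)
    Xsg <- Xsg[, colnames(Xsg) != "(Intercept)", drop = FALSE]
    Xmu <- apply_scaling(Xmu, object$scaling$mu)
    Xsg <- apply_scaling(Xsg, object$scaling$sg)
    subj_names <- if (object$use_u && !is.null(object$subject) &&
                      object$subject %in% names(newdata))
      as.character(newdata[[object$subject]]) else NULL
  }
  lp <- robt_linpred(object, Xmu, Xsg, subj_names)
  out <- switch(type,
    mean = lp$mu,
    sigma = lp$sigma,
    response = {
      nd <- nrow(lp$mu)
      nu <- if (object$family == "student") object$draws[, "nu"] else Inf
      tau <- if (object$use_u) object$draws[, "tau"] else 0
      eps <- matrix(if (is.finite(nu[1]) || object$family == "student")
                      stats::rt(length(lp$mu), df = rep(nu, ncol(lp$mu)))
                    else stats::rnorm(length(lp$mu)),
                    nrow = nd)
      unew <- if (is.null(subj_names))
        matrix(stats::rnorm(length(lp$mu), sd = rep(tau, ncol(lp$mu))), nrow = nd)
      else {
        m <- matrix(0, nd, ncol(lp$mu))
        unknown <- which(!(subj_names %in% object$subjects))
        if (length(unknown))
          m[, unknown] <- stats::rnorm(nd * length(unknown),
                                       sd = rep(tau, length(unknown)))
        m
      }
      lp$mu + unew + eps * lp$sigma
    })
  if (!summary) return(out)
  data.frame(row = seq_len(ncol(out)),
             median = apply(out, 2L, stats::median),
             lower = apply(out, 2L, stats::quantile, probs = 0.025),
             upper = apply(out, 2L, stats::quantile, probs = 0.975))
}

apply_scaling <- function(X, info) {
  if (is.null(info)) return(X)
  for (j in seq_len(nrow(info))) {
    cn <- info$column[j]
    if (cn %in% colnames(X))
      X[, cn] <- (X[, cn] - info$center[j]) / info$scale[j]
  }
  X
}

#' @export
simulate.robt <- function(object, nsim = 1, seed = NULL, newdata = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  reps <- lapply(seq_len(nsim), function(i) {
    m <- predict.robt(object, newdata = newdata, type = "response",
                      summary = FALSE)
    m[sample.int(nrow(m), 1L), ]
  })
  out <- as.data.frame(do.call(cbind, reps))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.robt <- function(x, pars = NULL, ...) {
  fixed <- setdiff(colnames(x$draws), grep("^u_", colnames(x$draws), value = TRUE))
  pars <- pars %||% utils::head(fixed, 6L)
  old <- graphics::par(mfrow = c(length(pars), 2),
                       mar = c(2.5, 4, 1.5, 0.5))
  on.exit(graphics::par(old))
  for (p in pars) {
    for (ch in seq_len(x$chains)) {
      v <- x$draws[x$chain_id == ch, p]
      if (ch == 1L)
        graphics::plot(v, type = "l", col = ch, ylab = p, xlab = "",
                       main = if (p == pars[1]) "trace" else "")
      else graphics::lines(v, col = ch)
    }
    graphics::plot(stats::density(x$draws[, p]), main = if (p == pars[1]) "density" else "",
                   xlab = "")
    graphics::abline(v = 0, lty = 2, col = "grey50")
  }
  invisible(x)
}
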