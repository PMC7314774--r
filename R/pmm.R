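# Bayesian linear-regression draw used by PMM (type-1 matching):
# sigma^2 from a scaled inverse chi-square at the residual sum of squares,
# beta drawn normal around the least-squares fit. Returns both the LS and
# drawn coefficients so observed cases are predicted with the former and
# missing cases with the latter.
blr_draw <- function(X, y) {
  cols <- seq_len(ncol(X))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    # collinear predictors (e.g. a constant chained target, or a binary
    # covariate with no variation among observed cases): keep a basis
    cols <- sort(qx$pivot[seq_len(qx$rank)])
    X <- X[, cols, drop = FALSE]
    qx <- qr(X)
  }
  beta_hat <- qr.coef(qx, y)
  res <- y - X %*% beta_hat
  dfr <- length(y) - ncol(X)
  if (dfr <= 0L) stopf("too few observed cases for the imputation model")
  sigma2 <- sum(res^2) / stats::rchisq(1L, dfr)
  R <- qr.R(qx)
  z <- stats::rnorm(ncol(X))
  beta_star <- beta_hat + backsolve(R, z) * sqrt(sigma2)
  list(beta_hat = beta_hat, beta_star = beta_star, cols = cols)
}

# one PMM pass for a single incomplete vector: returns the completed vector
# and, for each missing position, the index of the observed donor used
pmm_draw <- function(y, X, miss, k_donors) {
  obs <- which(!miss)
  d <- blr_draw(X[obs, , drop = FALSE], y[obs])
  Xk <- X[, d$cols, drop = FALSE]
  pred_obs <- as.numeric(Xk[obs, , drop = FALSE] %*% d$beta_hat)
  pred_mis <- as.numeric(Xk[miss, , drop = FALSE] %*% d$beta_star)
  filled <- y
  donors <- integer(sum(miss))
  mis_idx <- which(miss)
  for (ii in seq_along(mis_idx)) {
    dist <- abs(pred_obs - pred_mis[ii])
    k <- min(k_donors, length(dist))
    pool <- obs[order(dist)[seq_len(k)]]
    pick <- pool[sample.int(k, 1L)]
    filled[mis_idx[ii]] <- y[pick]
    donors[ii] <- pick
  }
  list(y = filled, donors = donors)
}

#' Predictive-mean-matching multiple imputation of breastfeeding
#'
#' The cohort's missingness pattern is all-or-nothing per infant: when the
#' feeding diary is absent, both breastfeeding rates (birth to PRE, and
#' PRE to POST) are missing at both timepoints. Imputation therefore runs
#' on one row per infant with two incomplete variables, which are imputed
#' jointly by chained equations; completed values are then broadcast back
#' to the per-sample layout (`bf_rate` on PRE rows and
#' `bf_rate_prior_period` everywhere carry the birth-to-PRE rate;
#' `bf_rate` on POST rows carries the PRE-to-POST rate).
#'
#' Each sweep uses predictive mean matching: regress the incomplete
#' variable on the predictors over observed infants, draw regression
#' coefficients from their approximate posterior (sigma-squared from a
#' scaled inverse chi-square, beta normal around the least-squares fit),
#' predict observed infants with the least-squares coefficients and
#' missing infants with the drawn ones, and copy the observed value of
#' one of the `k_donors` nearest neighbours in predicted-mean space.
#' Imputed values are therefore always genuinely observed values.
#'
#' @param meta a `sample_metadata` frame.
#' @param predictors complete metadata variables for the imputation model
#'   (default group, sibling, C-section, PRE age).
#' @param m number of imputations (default 10).
#' @param k_donors donor-pool size (default 5).
#' @param iterations chained-equation sweeps per imputation (default 5).
#' @param seed integer seed.
#' @return An object of class `imputation_set`: list with `m`,
#'   `completed` (list of `m` complete metadata frames), `donor_log`
#'   (per imputation and variable, the donor infant for each missing
#'   infant), `seed`.
#' @export
pmm_impute <- function(meta,
                       predictors = c("group", "sibling", "csection", "age_days"),
                       m = 10L, k_donors = 5L, iterations = 5L, seed = 1L) {
  stopifnot(all(predictors %in% names(meta)))
  pre <- meta[meta$timepoint == "PRE", , drop = FALSE]
  post <- meta[meta$timepoint == "POST", , drop = FALSE]
  pre <- pre[order(pre$infant_id), , drop = FALSE]
  post <- post[order(post$infant_id), , drop = FALSE]
  stopifnot(identical(pre$infant_id, post$infant_id))

  # infant-level incomplete variables: the two feeding periods
  ys <- list(bf_p1 = pre$bf_rate, bf_p2 = post$bf_rate)
  miss <- lapply(ys, is.na)
  n_miss_total <- sum(vapply(miss, sum, integer(1)))

  Xp <- stats::model.matrix(~ ., data = pre[, predictors, drop = FALSE])
  # a constant observed target is allowed: the donor pool is then forced
  # and every imputed value equals that constant
  for (tg in names(ys)) {
    yo <- ys[[tg]][!miss[[tg]]]
    if (length(yo) < ncol(Xp) + 2L)
      stopf("too few observed infants to impute '%s'", tg)
  }

  completed <- vector("list", m)
  donor_log <- vector("list", m)
  with_seed(seed, {
    for (im in seq_len(m)) {
      cur <- ys
      for (tg in names(ys)) {          # random observed starts
        mi <- miss[[tg]]
        if (any(mi)) cur[[tg]][mi] <- sample(ys[[tg]][!mi], sum(mi), replace = TRUE)
      }
      dl <- list()
      n_sweeps <- if (n_miss_total == 0L) 0L else iterations
      for (it in seq_len(n_sweeps)) {
        for (tg in names(ys)) {
          mi <- miss[[tg]]
          if (!any(mi)) next
          other <- setdiff(names(ys), tg)
          Xfull <- cbind(Xp, do.call(cbind, cur[other]))
          yt <- ys[[tg]]
          yt[mi] <- NA_real_
          draw <- pmm_draw(yt, Xfull, mi, k_donors)
          cur[[tg]][mi] <- draw$y[mi]
          dl[[tg]] <- stats::setNames(pre$infant_id[draw$donors],
                                      pre$infant_id[mi])
        }
      }
      out <- meta
      p1 <- stats::setNames(cur$bf_p1, pre$infant_id)
      p2 <- stats::setNames(cur$bf_p2, pre$infant_id)
      is_pre <- out$timepoint == "PRE"
      out$bf_rate[is_pre] <- unname(p1[out$infant_id[is_pre]])
      out$bf_rate[!is_pre] <- unname(p2[out$infant_id[!is_pre]])
      out$bf_rate_prior_period <- unname(p1[out$infant_id])
      completed[[im]] <- out
      donor_log[[im]] <- dl
    }
  })
  structure(list(m = as.integer(m), completed = completed,
                 donor_log = donor_log, seed = as.integer(seed)),
            class = "imputation_set")
}

#' @export
print.imputation_set <- function(x, ...) {
  cat(sprintf("<imputation_set> m = %d completed datasets\n", x$m))
  invisible(x)
}
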