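#' Build the study design for the robust hierarchical model
#'
#' Expands cohort metadata into the model frame used for every outcome:
#' binary covariates coded 0/1 (`cc`, `time`, `sib`, `csec`), continuous
#' age and breastfeeding. The mean model is
#' `y ~ cc*time + age + bf + sib*csec` (intercept, eight slopes and the
#' per-infant deviations) and the sigma model `~ cc*time + sib*csec`
#' (intercept plus six slopes). By default breastfeeding enters as the
#' single time-varying rate of the period preceding each sample
#' (`bf = "time_varying"`); `bf = "two_period"` instead includes both
#' period rates as separate fixed columns.
#'
#' @param meta complete `sample_metadata` (no missing breastfeeding; run
#'   [pmm_impute()] first, or use listwise deletion).
#' @param bf `"time_varying"` or `"two_period"`.
#' @return List with `data` (model frame with `cc`, `time`, `age`, `bf`
#'   (or `bf_p1`/`bf_p2`), `sib`, `csec`, `infant_id`, `sample_id`),
#'   `mu_formula`, `sigma_formula`, `subject`.
#' @export
build_design <- function(meta, bf = c("time_varying", "two_period")) {
  bf <- match.arg(bf)
  if (anyNA(meta$bf_rate) || anyNA(meta$bf_rate_prior_period))
    stopf("metadata has missing breastfeeding values; impute first (pmm_impute) or drop incomplete infants")
  df <- data.frame(
    sample_id = meta$sample_id,
    infant_id = meta$infant_id,
    cc = as.numeric(meta$group == "CC"),
    time = as.numeric(meta$timepoint == "POST"),
    age = meta$age_days,
    sib = as.numeric(meta$sibling),
    csec = as.numeric(meta$csection),
    stringsAsFactors = FALSE)
  if (bf == "time_varying") {
    df$bf <- meta$bf_rate
    mu_formula <- y ~ cc * time + age + bf + sib * csec
  } else {
    is_post <- meta$timepoint == "POST"
    p2 <- stats::setNames(meta$bf_rate[is_post], meta$infant_id[is_post])
    df$bf_p1 <- meta$bf_rate_prior_period
    df$bf_p2 <- unname(p2[meta$infant_id])
    mu_formula <- y ~ cc * time + age + bf_p1 + bf_p2 + sib * csec
  }
  list(data = df, mu_formula = mu_formula,
       sigma_formula = ~ cc * time + sib * csec, subject = "infant_id")
}

#' Default contrast set for the childcare analysis
#'
#' Returns the named contrasts summarised for every outcome: the four
#' group-mean comparisons (within-group temporal and between-group at
#' each timepoint), the covariate slopes, and the same group comparisons
#' on the residual-SD scale, computed at the reference covariate profile
#' (no sibling, vaginal birth). With the log sigma link the SD contrasts
#' are nonlinear in the coefficients, so they are defined as functions of
#' the posterior draws.
#'
#' @param sigma_link `"log"` or `"identity"` (must match the fit).
#' @return Named list of contrast definitions for [contrast_summaries()]:
#'   numeric linear-combination vectors (named by parameter) or
#'   functions mapping the draws matrix to a draw vector, each carrying a
#'   `scope` attribute (`mean`, `slope` or `sd`).
#' @export
default_contrasts <- function(sigma_link = c("log", "identity")) {
  sigma_link <- match.arg(sigma_link)
  lin <- function(w, scope) structure(w, scope = scope)
  sg <- function(cc, time) {
    force(cc); force(time)
    function(d) {
      eta <- d[, "g0"] + cc * d[, "bs_cc"] + time * d[, "bs_time"] +
        cc * time * d[, "bs_cc:time"]
      if (sigma_link == "log") exp(eta) else eta
    }
  }
  sgd <- function(a, b) { f1 <- sg(a[1], a[2]); f2 <- sg(b[1], b[2])
    structure(function(d) f1(d) - f2(d), scope = "sd") }
  sg_cov <- function(col) {
    force(col)
    structure(function(d) {
      if (sigma_link == "log") exp(d[, "g0"] + d[, col]) - exp(d[, "g0"])
      else d[, col]
    }, scope = "sd")
  }
  list(
    `CC PRE - HOME PRE` = lin(c(b_cc = 1), "mean"),
    `HOME POST - HOME PRE` = lin(c(b_time = 1), "mean"),
    `CC POST - CC PRE` = lin(c(b_time = 1, `b_cc:time` = 1), "mean"),
    `CC POST - HOME POST` = lin(c(b_cc = 1, `b_cc:time` = 1), "mean"),
    `C-section:yes - C-section:no` = lin(c(b_csec = 1), "slope"),
    `Sibling:yes - Sibling:no` = lin(c(b_sib = 1), "slope"),
    Age = lin(c(b_age = 1), "slope"),
    Breastfeeding = lin(c(b_bf = 1), "slope"),
    `SD: CC PRE - HOME PRE` = sgd(c(1, 0), c(0, 0)),
    `SD: HOME POST - HOME PRE` = sgd(c(0, 1), c(0, 0)),
    `SD: CC POST - CC PRE` = sgd(c(1, 1), c(1, 0)),
    `SD: CC POST - HOME POST` = sgd(c(1, 1), c(0, 1)),
    `SD: C-section:yes - C-section:no` = sg_cov("bs_csec"),
    `SD: Sibling:yes - Sibling:no` = sg_cov("bs_sib"))
}

#' Summarise posterior contrasts with the interval decision rule
#'
#' For each contrast, the draw-wise value is computed (a linear
#' combination of named parameters, or an arbitrary function of the
#' draws), and summarised by its median and central 95% credible
#' interval. A contrast is *flagged* exactly when that interval excludes
#' zero — the study's decision rule; the flag is a pure function of the
#' interval.
#'
#' @param object a fitted `robt`, a pooled fit, or a draws matrix with
#'   named columns.
#' @param contrasts named list as produced by [default_contrasts()];
#'   numeric vectors are interpreted as linear combinations over
#'   parameter names.
#' @param prob interval probability (default 0.95).
#' @return Data frame with columns `contrast`, `scope`, `median`,
#'   `lower`, `upper`, `flagged`.
#' @export
contrast_summaries <- function(object, contrasts = NULL, prob = 0.95) {
  d <- if (is.matrix(object)) object else object$draws
  if (is.null(contrasts)) {
    link <- if (!is.matrix(object)) object$sigma_link else "log"
    contrasts <- default_contrasts(link)
  }
  a <- (1 - prob) / 2
  rows <- lapply(names(contrasts), function(nm) {
    ct <- contrasts[[nm]]
    scope <- attr(ct, "scope") %||% "mean"
    v <- if (is.function(ct)) ct(d)
         else {
           missing <- setdiff(names(ct), colnames(d))
           if (length(missing) > 0L)
             stopf("contrast '%s' refers to unknown parameter(s): %s",
                   nm, paste(missing, collapse = ", "))
           as.numeric(d[, names(ct), drop = FALSE] %*% unname(ct))
         }
    q <- stats::quantile(v, c(a, 1 - a), names = FALSE)
    data.frame(contrast = nm, scope = scope, median = stats::median(v),
               lower = q[1], upper = q[2],
               flagged = q[1] > 0 || q[2] < 0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pool posterior draws across multiple imputations
#'
#' Fitting the model once per completed dataset and concatenating the
#' posterior draws yields the multiple-imputation posterior (a mixture of
#' the per-imputation posteriors). Convergence diagnostics are kept per
#' imputation.
#'
#' @param fits list of `robt` objects with identical parameter sets.
#' @return A `robt_pooled` object (usable by [contrast_summaries()]):
#'   `draws`, `imputation_id`, `rhat` (worst case per parameter),
#'   `per_fit_rhat`, `sigma_link`, `fits`.
#' @export
pool_imputations <- function(fits) {
  stopifnot(length(fits) >= 1L)
  cn <- colnames(fits[[1]]$draws)
  for (f in fits)
    if (!identical(colnames(f$draws), cn))
      stopf("imputation fits have mismatched parameter sets")
  draws <- do.call(rbind, lapply(fits, `[[`, "draws"))
  per_rhat <- lapply(fits, `[[`, "rhat")
  rhat <- do.call(pmax, per_rhat)
  structure(list(draws = draws,
                 imputation_id = rep(seq_along(fits),
                                     vapply(fits, function(f) nrow(f$draws), integer(1))),
                 rhat = rhat, per_fit_rhat = per_rhat,
                 converged = all(vapply(fits, `[[`, logical(1), "converged")),
                 sigma_link = fits[[1]]$sigma_link, fits = fits),
            class = c("robt_pooled", "robt"))
}

# fit the study model for one outcome vector on one completed dataset
fit_outcome_once <- function(y, meta, bf = "time_varying",
                             chains = 2L, iter = 600L, warmup = 800L,
                             thin = 4L, seed = 1L, family = "student",
                             sigma_link = "log") {
  des <- build_design(meta, bf = bf)
  df <- des$data
  df$y <- as.numeric(y[df$sample_id])
  if (anyNA(df$y)) stopf("outcome is missing for some samples")
  robt(des$mu_formula, df, sigma = des$sigma_formula, subject = "infant_id",
       family = family, sigma_link = sigma_link,
       chains = chains, iter = iter, warmup = warmup, thin = thin, seed = seed)
}

#' Group effects on Shannon diversity
#'
#' Fits the robust hierarchical model to the Shannon index once per
#' completed (imputed) dataset, pools the posteriors, summarises the
#' default contrast set under the 95%-interval decision rule, and
#' computes posterior predictive intervals for each group-by-timepoint
#' subgroup at the cohort-median breastfeeding rate and the
#' timepoint-median age (reference profile: no sibling, vaginal birth).
#'
#' @param H named Shannon vector (names = sample ids), e.g. from
#'   [shannon_diversity()].
#' @param imputations an `imputation_set` from [pmm_impute()], or a
#'   single complete metadata frame.
#' @param bf breastfeeding coding, see [build_design()].
#' @param chains,iter,warmup,thin,seed sampler settings per imputation.
#' @return List of class `diversity_fit`: `pooled` (pooled draws),
#'   `contrasts` (decision table), `predictive` (subgroup predictive
#'   intervals), `fits`.
#' @export
fit_diversity <- function(H, imputations, bf = "time_varying",
                          chains = 2L, iter = 600L, warmup = 800L,
                          thin = 4L, seed = 1L) {
  metas <- if (inherits(imputations, "imputation_set")) imputations$completed
           else list(imputations)
  fits <- lapply(seq_along(metas), function(i)
    fit_outcome_once(H, metas[[i]], bf = bf, chains = chains, iter = iter,
                     warmup = warmup, thin = thin,
                     seed = derive_seed(seed, paste0("imp", i))))
  pooled <- pool_imputations(fits)
  ctr <- contrast_summaries(pooled, default_contrasts(fits[[1]]$sigma_link))

  # predictive intervals at the median covariate profile
  meta1 <- metas[[1]]
  prof <- expand.grid(cc = c(0, 1), time = c(0, 1))
  prof$age <- ifelse(prof$time == 1,
                     stats::median(meta1$age_days[meta1$timepoint == "POST"]),
                     stats::median(meta1$age_days[meta1$timepoint == "PRE"]))
  bfmed <- stats::median(meta1$bf_rate)
  if ("bf" %in% all.vars(fits[[1]]$formula)) prof$bf <- bfmed
  if ("bf_p1" %in% all.vars(fits[[1]]$formula)) {
    prof$bf_p1 <- stats::median(meta1$bf_rate_prior_period)
    prof$bf_p2 <- bfmed
  }
  prof$sib <- 0; prof$csec <- 0
  pred <- do.call(rbind, lapply(fits, function(f)
    predict(f, newdata = prof, type = "response", summary = FALSE)))
  predictive <- data.frame(
    group = ifelse(prof$cc == 1, "CC", "HOME"),
    timepoint = ifelse(prof$time == 1, "POST", "PRE"),
    median = apply(pred, 2L, stats::median),
    lower = apply(pred, 2L, stats::quantile, probs = 0.025),
    upper = apply(pred, 2L, stats::quantile, probs = 0.975))
  structure(list(pooled = pooled, contrasts = ctr, predictive = predictive,
                 fits = fits),
            class = "diversity_fit")
}

#' @export
print.diversity_fit <- function(x, ...) {
  cat("Robust hierarchical model for Shannon diversity\n")
  y <- x$contrasts
  y[c("median", "lower", "upper")] <- lapply(y[c("median", "lower", "upper")],
                                             round, 3)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Per-taxon group effects on clr abundances
#'
#' Fits the robust hierarchical model to each taxon's clr-transformed
#' abundance (pooled over imputations) and returns the contrast table
#' with the interval decision flag, one row per taxon and contrast.
#'
#' @param clr a `clr_matrix` from [clr_transform()].
#' @param imputations an `imputation_set` or a complete metadata frame.
#' @param taxa optional character/integer subset of taxa to fit.
#' @param contrast_subset optional character vector restricting which
#'   contrasts are summarised.
#' @inheritParams fit_diversity
#' @return Data frame with `taxon`, `contrast`, `scope`, `median`,
#'   `lower`, `upper`, `flagged`, `max_rhat`.
#' @export
fit_all_taxa <- function(clr, imputations, taxa = NULL, bf = "time_varying",
                         chains = 2L, iter = 600L, warmup = 800L, thin = 4L,
                         seed = 1L, contrast_subset = NULL) {
  stopifnot(inherits(clr, "clr_matrix"))
  metas <- if (inherits(imputations, "imputation_set")) imputations$completed
           else list(imputations)
  sel <- taxa %||% clr$taxon_ids
  if (is.numeric(sel)) sel <- clr$taxon_ids[sel]
  out <- vector("list", length(sel))
  for (ti in seq_along(sel)) {
    tx <- sel[ti]
    y <- stats::setNames(clr$values[, tx], clr$sample_ids)
    fits <- lapply(seq_along(metas), function(i)
      fit_outcome_once(y, metas[[i]], bf = bf, chains = chains, iter = iter,
                       warmup = warmup, thin = thin,
                       seed = derive_seed(seed, paste(tx, i))))
    pooled <- pool_imputations(fits)
    ctr <- contrast_summaries(pooled, default_contrasts(fits[[1]]$sigma_link))
    if (!is.null(contrast_subset))
      ctr <- ctr[ctr$contrast %in% contrast_subset, , drop = FALSE]
    ctr <- cbind(taxon = tx, ctr, max_rhat = max(pooled$rhat))
    out[[ti]] <- ctr
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
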