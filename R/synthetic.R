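#' Configuration for the synthetic infant-cohort generator
#'
#' The generator emulates a two-group (CC = center-based childcare,
#' HOME = home care), two-timepoint (PRE, POST) cohort of infants around
#' three months of age, with a Bifidobacterium-dominated and highly
#' variable gut microbiota. Compositions follow a logistic-normal model:
#' per-taxon logits are the sum of a population mean, a per-infant random
#' intercept, optional covariate effects, and per-sample noise; the
#' softmax closes each sample to relative abundances. The population-mean
#' logits are calibrated internally (by fixed-seed Monte Carlo) so that
#' the realised population means match `taxon_mean_targets` — by default
#' a dominant taxon at 51% mean relative abundance and the five dominant
#' taxa summing to just over 75%, with the remainder decaying
#' geometrically over the other taxa.
#'
#' @param n_per_group infants per group (default 49, i.e. 196 samples).
#' @param n_taxa number of genus-like groups (default 130).
#' @param seed integer seed; the whole cohort is a deterministic function
#'   of the configuration.
#' @param taxon_mean_targets target population-mean relative abundances
#'   (length `n_taxa`, summing to 1), or `NULL` for the default profile.
#' @param subject_sd between-infant SD of taxon logits. Together with
#'   `noise_sd` this controls the inter-individual spread; the defaults
#'   make the dominant taxon range from near-absence to near-total
#'   dominance across a cohort.
#' @param noise_sd within-infant (sample-level) SD of taxon logits.
#' @param effects named list mapping a covariate (`"cc"`, `"time"`,
#'   `"cc_time"`, `"sib"`, `"csec"`, `"age"`, `"bf"`) to a length-`n_taxa`
#'   vector of additive logit-scale effects. Default: none — the
#'   childcare null.
#' @param diversity_effects named list mapping a binary covariate to an
#'   additive shift of the Shannon index (nats) applied to samples where
#'   the covariate is 1, via a sharpening/flattening power transform of
#'   the composition.
#' @param bf_missing integer vector `c(cc = , home = )`: how many infants
#'   per group have breastfeeding blanked entirely (default 4 CC, 1 HOME).
#' @param age_means_sds 4x2 matrix (rows CC_PRE, HOME_PRE, CC_POST,
#'   HOME_POST; columns mean, sd) of age in days.
#' @param halfdays_distribution named numeric vector: probability mass
#'   function of weekly childcare half-days for CC infants (median 4,
#'   interquartile range 3-4 by default).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 49L,
                          n_taxa = 130L,
                          seed = 1L,
                          taxon_mean_targets = NULL,
                          subject_sd = 1.2,
                          noise_sd = 0.8,
                          effects = list(),
                          diversity_effects = list(),
                          bf_missing = c(cc = 4L, home = 1L),
                          age_means_sds = NULL,
                          halfdays_distribution = c(`2` = 0.08, `3` = 0.25,
                                                    `4` = 0.50, `5` = 0.17)) {
  if (is.null(taxon_mean_targets))
    taxon_mean_targets <- default_taxon_means(n_taxa)
  if (length(taxon_mean_targets) != n_taxa)
    stopf("taxon_mean_targets must have length n_taxa (%d)", n_taxa)
  if (abs(sum(taxon_mean_targets) - 1) > 1e-8)
    stopf("taxon_mean_targets must sum to 1")
  if (subject_sd < 0 || noise_sd < 0) stopf("SDs must be nonnegative")
  if (is.null(age_means_sds)) {
    age_means_sds <- matrix(c(87.8, 16.0,   # CC PRE
                              76.7, 6.3,    # HOME PRE
                              118.4, 16.1,  # CC POST
                              106.5, 5.9),  # HOME POST
                            nrow = 4, byrow = TRUE,
                            dimnames = list(c("CC_PRE", "HOME_PRE",
                                              "CC_POST", "HOME_POST"),
                                            c("mean", "sd")))
  }
  bf_missing <- c(cc = as.integer(bf_missing[["cc"]]),
                  home = as.integer(bf_missing[["home"]]))
  if (sum(bf_missing) > 2L * n_per_group)
    stopf("bf_missing exceeds cohort size")
  for (nm in names(effects))
    if (length(effects[[nm]]) != n_taxa)
      stopf("effects[['%s']] must have length n_taxa", nm)
  if (abs(sum(halfdays_distribution) - 1) > 1e-8)
    stopf("halfdays_distribution must sum to 1")
  structure(list(n_per_group = as.integer(n_per_group),
                 n_taxa = as.integer(n_taxa), seed = as.integer(seed),
                 taxon_mean_targets = taxon_mean_targets,
                 subject_sd = subject_sd, noise_sd = noise_sd,
                 effects = effects, diversity_effects = diversity_effects,
                 bf_missing = bf_missing, age_means_sds = age_means_sds,
                 halfdays_distribution = halfdays_distribution),
            class = "cohort_config")
}

# dominant profile: Bifidobacterium-like 51%, then Streptococcus-like 16.8%,
# Enterococcus 3.4%, Lactobacillus 2.9%, Granulicatella 1.0%, cumulatively
# above 75% (values sit within rounding of those percentages so the strict
# inequality holds); the remaining mass decays geometrically over the rest.
default_taxon_means <- function(n_taxa) {
  top <- c(0.5110, 0.1683, 0.0344, 0.0294, 0.0104)
  if (n_taxa <= length(top)) {
    w <- top[seq_len(n_taxa)]
    return(w / sum(w))
  }
  k <- n_taxa - length(top)
  tail_w <- 0.97^seq_len(k)
  tail_w <- tail_w / sum(tail_w) * (1 - sum(top))
  c(top, tail_w)
}

.calib_cache <- new.env(parent = emptyenv())

# Monte-Carlo calibration of population-mean logits: because the mean of a
# softmax of noisy logits is not the softmax of the mean, the logits are
# adjusted iteratively (fixed internal seed, independent of the cohort seed)
# until the simulated population means hit the targets.
calibrate_taxon_logits <- function(targets, total_sd, n_mc = 20000L, iters = 12L) {
  key <- paste(length(targets), signif(total_sd, 10),
               paste(signif(targets, 10), collapse = ","), sep = "|")
  hit <- .calib_cache[[digest_key(key)]]
  if (!is.null(hit)) return(hit)
  logit <- log(targets)
  if (total_sd > 0) {
    with_seed(20260101L, {
      K <- length(targets)
      z <- matrix(stats::rnorm(n_mc * K, sd = total_sd), n_mc, K)
      for (it in seq_len(iters)) {
        p <- row_softmax(sweep(z, 2L, logit, `+`))
        logit <- logit + (log(targets) - log(colMeans(p)))
        logit <- logit - mean(logit)
      }
    })
  }
  logit <- logit - mean(logit)
  .calib_cache[[digest_key(key)]] <- logit
  logit
}

digest_key <- function(s) {
  f <- tempfile(); on.exit(unlink(f))
  writeLines(s, f)
  unname(tools::md5sum(f))
}

#' Generate a synthetic cohort
#'
#' Draws covariates (age, breastfeeding rates, siblings, C-section,
#' weekly childcare half-days) from distributions matched to the
#' demographics of a 49+49 infant childcare cohort, simulates
#' logistic-normal compositions for every sample, and blanks the
#' breastfeeding variables for the configured number of infants
#' (missing completely at random). The realised effect vectors and
#' subject intercepts are returned as ground truth for recovery tests.
#'
#' @param config a [cohort_config()].
#' @return A list with elements `abundance` (an [abundance_table()] on the
#'   relative scale), `metadata` (a validated `sample_metadata` frame with
#'   an extra `halfdays` column, `NA` for HOME infants), and `truth`
#'   (population logits, subject intercepts, effects, diversity effects,
#'   ids of breastfeeding-missing infants).
#' @examples
#' coh <- generate_cohort(cohort_config(n_per_group = 6, n_taxa = 10, seed = 42))
#' dim(coh$abundance)
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  total_sd <- sqrt(cfg$subject_sd^2 + cfg$noise_sd^2)
  logits <- calibrate_taxon_logits(cfg$taxon_mean_targets, total_sd)
  set.seed(cfg$seed)

  n <- cfg$n_per_group
  J <- 2L * n
  infant_id <- sprintf("I%03d", seq_len(J))
  group <- rep(c("CC", "HOME"), each = n)

  sib_p <- c(CC = 25 / 49, HOME = 32 / 49)
  csec_p <- c(CC = 6 / 49, HOME = 3 / 49)
  sibling <- stats::runif(J) < sib_p[group]
  csection <- stats::runif(J) < csec_p[group]

  am <- cfg$age_means_sds
  age_pre <- ifelse(group == "CC",
                    rtruncnorm1(J, am["CC_PRE", "mean"], am["CC_PRE", "sd"], 58, 123),
                    rtruncnorm1(J, am["HOME_PRE", "mean"], am["HOME_PRE", "sd"], 68, 90))
  gap_mean <- ifelse(group == "CC",
                     am["CC_POST", "mean"] - am["CC_PRE", "mean"],
                     am["HOME_POST", "mean"] - am["HOME_PRE", "mean"])
  age_post <- age_pre + rtruncnorm1(J, gap_mean, 2.5, 14, Inf)

  bf_a <- ifelse(group == "CC",
                 rtruncnorm1(J, 5.4, 2.9, 0, 11.4),
                 rtruncnorm1(J, 5.7, 2.3, 0, 8.9))
  bf_b <- pmax(0, 0.72 * bf_a + stats::rnorm(J, 0, 1.2))

  hd_vals <- as.integer(names(cfg$halfdays_distribution))
  halfdays <- ifelse(group == "CC",
                     sample(hd_vals, J, replace = TRUE,
                            prob = cfg$halfdays_distribution),
                     NA_integer_)

  meta <- data.frame(
    sample_id = c(paste0(infant_id, "_PRE"), paste0(infant_id, "_POST")),
    infant_id = rep(infant_id, 2L),
    group = rep(group, 2L),
    timepoint = rep(c("PRE", "POST"), each = J),
    age_days = c(age_pre, age_post),
    bf_rate = c(bf_a, bf_b),
    bf_rate_prior_period = c(bf_a, bf_a),
    sibling = rep(sibling, 2L),
    csection = rep(csection, 2L),
    halfdays = rep(halfdays, 2L),
    stringsAsFactors = FALSE)

  K <- cfg$n_taxa
  subj_int <- matrix(stats::rnorm(J * K, sd = cfg$subject_sd), J, K,
                     dimnames = list(infant_id, NULL))
  N <- nrow(meta)
  eta <- matrix(logits, N, K, byrow = TRUE) +
    subj_int[meta$infant_id, , drop = FALSE] +
    matrix(stats::rnorm(N * K, sd = cfg$noise_sd), N, K)

  if (length(cfg$effects) > 0L) {
    X <- covariate_values(meta)
    for (nm in names(cfg$effects))
      eta <- eta + outer(X[[nm]], cfg$effects[[nm]])
  }
  p <- row_softmax(eta)

  if (length(cfg$diversity_effects) > 0L) {
    X <- covariate_values(meta)
    shift <- rep(0, N)
    for (nm in names(cfg$diversity_effects))
      shift <- shift + X[[nm]] * cfg$diversity_effects[[nm]]
    for (i in which(abs(shift) > 1e-12))
      p[i, ] <- shannon_power_adjust(p[i, ], shift[i])
  }
  p <- p / rowSums(p)
  top_names <- c("Bifidobacterium", "Streptococcus", "Enterococcus",
                 "Lactobacillus", "Granulicatella")
  taxon_names <- if (K <= 5L) top_names[seq_len(K)]
                 else c(top_names, sprintf("taxon_%03d", 6:K))
  dimnames(p) <- list(meta$sample_id, taxon_names)

  abundance <- abundance_table(p, scale = "relative")
  meta <- inject_missingness(meta, n_cc = cfg$bf_missing[["cc"]],
                             n_home = cfg$bf_missing[["home"]],
                             seed = derive_seed(cfg$seed, "bf_missing"))
  missing_inf <- unique(meta$infant_id[is.na(meta$bf_rate)])
  meta <- validate_metadata(meta)
  truth <- list(taxon_logits = logits, subject_intercepts = subj_int,
                effects = cfg$effects, diversity_effects = cfg$diversity_effects,
                missing_infants = missing_inf)
  list(abundance = abundance, metadata = meta, truth = truth)
}

# design covariates on the scale used for logit-level effects
covariate_values <- function(meta) {
  cc <- as.numeric(meta$group == "CC")
  tm <- as.numeric(meta$timepoint == "POST")
  age_z <- as.numeric(scale(meta$age_days))
  bf <- meta$bf_rate
  bf_z <- if (all(is.na(bf))) rep(0, nrow(meta))
          else as.numeric(scale(ifelse(is.na(bf), mean(bf, na.rm = TRUE), bf)))
  list(cc = cc, time = tm, cc_time = cc * tm,
       sib = as.numeric(meta$sibling), csec = as.numeric(meta$csection),
       age = age_z, bf = bf_z)
}

# shift a composition's Shannon index by `shift` nats through the power
# family p^theta / sum(p^theta); theta is found by root-finding (theta > 1
# sharpens and lowers H, theta < 1 flattens and raises it).
shannon_power_adjust <- function(p, shift) {
  H <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  target <- min(max(H(p) + shift, 1e-3), log(length(p)) - 1e-3)
  f <- function(theta) {
    q <- p^theta; q <- q / sum(q); H(q) - target
  }
  theta <- tryCatch(stats::uniroot(f, c(0.01, 50), tol = 1e-10)$root,
                    error = function(e) 1)
  q <- p^theta
  q / sum(q)
}

#' Blank breastfeeding data for randomly chosen infants
#'
#' Marks the breastfeeding variables missing completely at random for
#' `n_cc` childcare-group and `n_home` home-group infants, at both
#' timepoints (the study's missingness pattern: when a feeding diary is
#' absent, everything about that infant's feeding is absent).
#'
#' @param meta sample metadata (data frame).
#' @param n_cc,n_home number of infants to blank per group.
#' @param seed integer seed.
#' @return The metadata with `bf_rate` and `bf_rate_prior_period` set to
#'   `NA` for the selected infants.
#' @export
inject_missingness <- function(meta, n_cc, n_home, seed = 1L) {
  groups <- tapply(as.character(meta$group), meta$infant_id, `[`, 1L)
  cc_inf <- names(groups)[groups == "CC"]
  home_inf <- names(groups)[groups == "HOME"]
  if (n_cc > length(cc_inf))
    stopf("n_cc (%d) exceeds the number of CC infants (%d)", n_cc, length(cc_inf))
  if (n_home > length(home_inf))
    stopf("n_home (%d) exceeds the number of HOME infants (%d)", n_home, length(home_inf))
  if (n_cc + n_home == 0L) return(meta)
  picked <- with_seed(seed, c(sample(cc_inf, n_cc), sample(home_inf, n_home)))
  hit <- meta$infant_id %in% picked
  meta$bf_rate[hit] <- NA_real_
  meta$bf_rate_prior_period[hit] <- NA_real_
  meta
}
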