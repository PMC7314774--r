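test_that("imputation on complete data is the identity", {
  md <- small_cohort(seed = 61, bf_missing = c(cc = 0, home = 0))$metadata
  imp <- pmm_impute(md, m = 3, seed = 1)
  expect_equal(imp$m, 3L)
  for (d in imp$completed) expect_equal(d$bf_rate, md$bf_rate)
})

test_that("defaults give ten complete datasets with donor-borrowed values", {
  coh <- generate_cohort(cohort_config(seed = 62))
  md <- coh$metadata
  imp <- pmm_impute(md, seed = 7)
  expect_equal(imp$m, 10L)
  obs_p1 <- md$bf_rate[md$timepoint == "PRE" & !is.na(md$bf_rate)]
  obs_p2 <- md$bf_rate[md$timepoint == "POST" & !is.na(md$bf_rate)]
  for (d in imp$completed) {
    expect_false(anyNA(d$bf_rate))
    expect_false(anyNA(d$bf_rate_prior_period))
    # PMM's defining property: every imputed value is an observed value
    was_na <- is.na(md$bf_rate)
    imputed_pre <- d$bf_rate[was_na & md$timepoint == "PRE"]
    imputed_post <- d$bf_rate[was_na & md$timepoint == "POST"]
    expect_true(all(imputed_pre %in% obs_p1))
    expect_true(all(imputed_post %in% obs_p2))
    # observed entries untouched
    expect_equal(d$bf_rate[!was_na], md$bf_rate[!was_na])
  }
  # imputations differ (stochastic coefficient draws)
  filled <- sapply(imp$completed, function(d) d$bf_rate[is.na(md$bf_rate)])
  expect_gt(length(unique(as.vector(filled))), 1L)
  # and are reproducible under the same seed
  imp2 <- pmm_impute(md, seed = 7)
  expect_identical(imp$completed, imp2$completed)
})

test_that("a constant observed target forces the donor pool", {
  md <- small_cohort(seed = 63)$metadata
  md$bf_rate[!is.na(md$bf_rate)] <- 4
  md$bf_rate_prior_period[!is.na(md$bf_rate_prior_period)] <- 4
  imp <- pmm_impute(md, m = 2, seed = 2)
  for (d in imp$completed) expect_true(all(d$bf_rate == 4))
})

test_that("too few observed infants is an error", {
  md <- tiny_meta()
  md$bf_rate[1] <- NA; md$bf_rate_prior_period[1] <- NA
  expect_error(pmm_impute(md, m = 2), "too few")
})

test_that("pooled post-imputation means are unbiased under MCAR", {
  # the generator blanks breastfeeding completely at random; over seeds the
  # pooled imputed mean must track the complete-data mean
  diffs <- ses <- numeric(50)
  for (s in seq_len(50)) {
    full <- generate_cohort(cohort_config(n_per_group = 25, n_taxa = 10,
                                          seed = s,
                                          bf_missing = c(cc = 0, home = 0)))
    md_full <- full$metadata
    md_miss <- inject_missingness(md_full, n_cc = 3, n_home = 2, seed = s)
    imp <- pmm_impute(md_miss, m = 5, seed = s)
    pooled <- rowMeans(sapply(imp$completed, function(d) d$bf_rate))
    diffs[s] <- mean(pooled) - mean(md_full$bf_rate)
    ses[s] <- stats::sd(md_full$bf_rate) / sqrt(nrow(md_full))
  }
  mc_se <- stats::sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 2 * mc_se + 1e-12)
})
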