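test_that("default cohort has the study's shape and missingness", {
  coh <- generate_cohort(cohort_config(seed = 2))
  expect_equal(nrow(coh$abundance$values), 196L)
  md <- coh$metadata
  infants <- md[md$timepoint == "PRE", ]
  expect_equal(as.integer(table(infants$group)[c("CC", "HOME")]), c(49L, 49L))
  miss <- unique(md$infant_id[is.na(md$bf_rate)])
  expect_equal(length(miss), 5L)
  grp <- tapply(as.character(md$group), md$infant_id, `[`, 1L)
  expect_equal(sum(grp[miss] == "CC"), 4L)
  expect_equal(sum(grp[miss] == "HOME"), 1L)
  # missing at both timepoints for those infants
  expect_true(all(is.na(md$bf_rate[md$infant_id %in% miss])))
  expect_true(all(is.na(md$bf_rate_prior_period[md$infant_id %in% miss])))
})

test_that("generated compositions close to one and are seed-deterministic", {
  coh1 <- small_cohort(seed = 11)
  coh2 <- small_cohort(seed = 11)
  coh3 <- small_cohort(seed = 12)
  expect_identical(coh1$abundance$values, coh2$abundance$values)
  expect_identical(coh1$metadata, coh2$metadata)
  expect_false(identical(coh1$truth$subject_intercepts,
                         coh3$truth$subject_intercepts))
  expect_true(all(abs(rowSums(coh1$abundance$values) - 1) < 1e-9))
})

test_that("degenerate generator (no variability, no effects) repeats one composition", {
  coh <- small_cohort(seed = 5, subject_sd = 0, noise_sd = 0)
  v <- coh$abundance$values
  expect_true(all(abs(sweep(v, 2L, v[1, ])) < 1e-12))
})

test_that("missingness injection respects counts, identity and bounds", {
  md <- small_cohort(seed = 8, bf_missing = c(cc = 0, home = 0))$metadata
  expect_equal(sum(is.na(md$bf_rate)), 0L)
  md2 <- inject_missingness(md, 0, 0)
  expect_identical(md2, md)
  md3 <- inject_missingness(md, 3, 2, seed = 4)
  expect_equal(length(unique(md3$infant_id[is.na(md3$bf_rate)])), 5L)
  expect_error(inject_missingness(md, 50, 0), "exceeds")
})

test_that("childcare half-days sit at the reported median with IQR 3-4", {
  meds <- lo <- hi <- numeric(10)
  for (s in seq_len(10)) {
    md <- generate_cohort(cohort_config(seed = s))$metadata
    hd <- md$halfdays[md$group == "CC" & md$timepoint == "PRE"]
    meds[s] <- stats::median(hd)
    lo[s] <- stats::quantile(hd, 0.25)
    hi[s] <- stats::quantile(hd, 0.75)
  }
  expect_true(all(meds == 4))
  expect_true(mean(lo == 3) >= 0.8)
  expect_true(all(hi == 4))
})

test_that("diversity effects shift Shannon by the requested amount", {
  base <- small_cohort(n_per_group = 10, n_taxa = 20, seed = 21)
  shifted <- small_cohort(n_per_group = 10, n_taxa = 20, seed = 21,
                          diversity_effects = list(cc_time = -0.3))
  H0 <- shannon_diversity(base$abundance)
  H1 <- shannon_diversity(shifted$abundance)
  md <- base$metadata
  hit <- md$group == "CC" & md$timepoint == "POST"
  expect_equal(unname(H1[hit] - H0[hit]), rep(-0.3, sum(hit)), tolerance = 1e-6)
  expect_equal(H1[!hit], H0[!hit])
})

test_that("taxon-level effects imprint on clr abundances", {
  eff <- rep(0, 15); eff[1] <- 1.5
  coh <- small_cohort(n_per_group = 20, n_taxa = 15, seed = 31,
                      effects = list(cc_time = eff))
  clr <- clr_transform(coh$abundance, pseudocount = 0)
  md <- coh$metadata
  hit <- md$group == "CC" & md$timepoint == "POST"
  gap <- mean(clr$values[hit, 1]) - mean(clr$values[!hit & md$group == "CC", 1])
  expect_gt(gap, 0.7)
})

test_that("cohort config validates its inputs", {
  expect_error(cohort_config(n_taxa = 10, taxon_mean_targets = rep(0.1, 5)),
               "length")
  expect_error(cohort_config(taxon_mean_targets = rep(0.5, 130)), "sum to 1")
  expect_error(cohort_config(subject_sd = -1), "nonnegative")
  expect_error(cohort_config(n_per_group = 2, bf_missing = c(cc = 4, home = 1)),
               "exceeds")
})
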