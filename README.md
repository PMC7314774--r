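# gutshift

Does entry into center-based childcare shift the infant gut microbiota?
`gutshift` is an R package for analysing two-group (childcare **CC** vs
home care **HOME**), two-timepoint (**PRE** / **POST**) infant cohorts
with genus-level microbiota profiles. It implements the full statistical
pipeline such a study needs — compositional preprocessing, constrained
ordination, multiple imputation, a Bayesian hierarchical robust model
with distributional variance regression, and machine-learning group
classification — together with a calibrated synthetic-cohort generator,
so every stage is testable without access to cohort data (which, for
infant studies, is rarely depositable).

It is aimed at microbiome statisticians and developmental researchers
who want a reproducible, seed-deterministic reference implementation of
this analysis style.

## What's inside

* **Compositional metrics** — relative abundance, centered log-ratio
  (clr), Shannon alpha diversity, detection-threshold richness,
  per-taxon coefficient of variation.
* **Redundancy analysis (RDA)** from first principles — simple and
  conditional (partial) effects with permutation F-tests, restricted
  permutations for the repeated-measures structure (whole-infant blocks
  for between-infant factors, within-infant for time), and Venn-style
  variance partitioning by inclusion–exclusion. Cross-checked against
  `vegan` in the test suite.
* **Predictive-mean-matching (PMM) multiple imputation** of the
  breastfeeding covariates (chained over the two feeding periods,
  infant-level, donor-based — imputed values are always observed
  values).
* **The robust hierarchical model** at the core, fit by `robt()`:

  ```
  y_i        ~ T(nu, mu_i, sigma_i)
  mu_i       = beta_0 + u_{j[i]} + beta_1 CC + beta_2 time + beta_3 CC x time
               + beta_4 age + beta_5 bf + beta_6 sib + beta_7 csec
               + beta_8 sib x csec
  log sigma_i = beta_s0 + beta_s1 CC + beta_s2 time + beta_s3 CC x time
               + beta_s4 sib + beta_s5 csec + beta_s6 sib x csec
  u_j        ~ N(0, tau)
  ```

  A Student-t likelihood downweights outliers, each infant *j* deviates
  from the population intercept by partial pooling, and the residual SD
  itself is regressed on the grouping variables instead of assuming
  homogeneous variance. Comparison coefficients carry Normal(0, 1)
  priors; effects are declared when the central 95% credible interval
  excludes zero. Sampling uses a purpose-built Gibbs/adaptive-Metropolis
  sampler in C++ (scale-mixture representation of the t), validated
  against an independent MCMC engine in the tests. Posteriors are fitted
  once per imputed dataset and pooled by concatenation.
* **Random-forest classification** of POST samples (CC vs HOME) under
  repeated stratified 10-fold cross-validation.
* **A synthetic cohort generator** — logistic-normal compositions
  calibrated so the dominant *Bifidobacterium*-like taxon averages ~51%
  relative abundance (ranging from near-absence to near-total dominance)
  and the five dominant taxa together exceed 75%; demographics (ages,
  feeding rates, siblings, C-sections, weekly childcare half-days with
  median 4) match a 49+49-infant cohort; breastfeeding is blanked
  completely for 5 infants (4 CC, 1 HOME).

## Worked example

```r
library(gutshift)

coh <- generate_cohort(cohort_config(seed = 1))
rel <- to_relative_abundance(coh$abundance)
round(sort(colMeans(rel$values), decreasing = TRUE)[1:5], 3)
#> Bifidobacterium   Streptococcus    Enterococcus   Lactobacillus  Granulicatella
#>           0.505           0.151           0.036           0.035           0.013

H <- shannon_diversity(rel)
imp <- pmm_impute(coh$metadata, m = 10, seed = 1)   # 10 completed datasets
div <- fit_diversity(H, imp, seed = 1)
div
#> Robust hierarchical model for Shannon diversity
#>                          contrast scope median  lower upper flagged
#>                 CC PRE - HOME PRE  mean -0.148 -0.515 0.222   FALSE
#>              HOME POST - HOME PRE  mean  0.000 -0.456 0.475   FALSE
#>                  CC POST - CC PRE  mean  0.028 -0.446 0.535   FALSE
#>               CC POST - HOME POST  mean -0.119 -0.483 0.252   FALSE
#>      C-section:yes - C-section:no slope  0.177 -0.613 0.966   FALSE
#>          Sibling:yes - Sibling:no slope  0.072 -0.243 0.386   FALSE
#>                               Age slope  0.025 -0.261 0.292   FALSE
#>                     Breastfeeding slope -0.036 -0.167 0.095   FALSE
#>  ... (the same four group contrasts on the residual-SD scale follow)
```

Every group contrast is unflagged: this cohort was generated under the
childcare null (no CC effect), and the decision rule correctly stays
quiet. The `median`/`lower`/`upper` columns are posterior medians and
central 95% credible intervals of the named difference on the Shannon
scale (nats); `flagged` is `TRUE` exactly when the interval excludes 0.

Ordination with restricted permutations, and classification:

```r
clrm <- clr_transform(rel)
md <- coh$metadata
cmeta <- md[!(md$infant_id %in% unique(md$infant_id[is.na(md$bf_rate)])), ]
eff <- effects_table(clrm$values[cmeta$sample_id, ], design_blocks(cmeta),
                     n_perm = 999, seed = 1, exchange_blocks = cmeta$infant_id)
head(eff[, c("term", "mode", "df", "F", "p", "R2")], 4)
#>   term        mode df     F     p     R2
#> 1 Time      simple  1 0.331 0.264 0.0018
#> 2 Time conditional  1 1.031 0.639 0.0055
#> 3   CC      simple  1 1.541 0.758 0.0083
#> 4   CC conditional  1 1.730 0.482 0.0092

post <- md[md$timepoint == "POST", ]
classify_groups(rel$values[post$sample_id, ], post$group, seed = 1)
#> Repeated 10-fold CV (10 repeats): mean accuracy 51.9% (range 48.0-56.1%)
```

R² is the fraction of total clr-scale microbiota variance a predictor
explains; with no childcare effect in the generator the CC rows are
non-significant and the random forest classifies at chance (~50%).

`run_full_analysis("out_dir", cohort_config(), seed = 1)` runs all
stages end-to-end and writes CSV/TSV outputs plus a JSON manifest; a
command-line wrapper lives in `inst/scripts/run_pipeline.R`.

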