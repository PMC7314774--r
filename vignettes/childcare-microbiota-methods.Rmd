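---
title: "Methods: robust hierarchical modelling of infant microbiota around childcare entry"
author: "gutshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: robust hierarchical modelling of infant microbiota around childcare entry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical machinery: the
models and procedures, the assumptions they make, the parameters that
matter, what the synthetic cohort generator does and does not emulate,
and the numerical and design choices taken where more than one
defensible option existed.

## The scientific setting

A cohort of infants around three months of age is sampled twice — before
(PRE) and roughly four weeks after (POST) a childcare-entry window —
with half the infants entering center-based childcare (CC) and half
staying in home care (HOME). Each fecal sample yields genus-level
relative abundances of ~130 bacterial groups. The questions are whether
childcare entry shifts overall community composition (a multivariate
question), whether it shifts individual taxa or alpha diversity (many
univariate questions), and whether post-entry composition is predictive
of group membership (a classification question). The early-life gut is
dominated by a handful of taxa — *Bifidobacterium* above all — and is
extremely variable between and within infants, which shapes every
methodological choice below.

## Compositional preprocessing

Microbiota profiles are compositions: only relative information is
meaningful. The package closes each sample to relative abundance and
applies the centered log-ratio transform,
$\mathrm{clr}(x)_k = \log x_k - \tfrac1K\sum_j \log x_j$,
mapping each sample to a vector summing to zero on which
covariance-based methods (RDA, linear models) are defensible.

* **Pseudocount.** Hybridization-style signals are strictly positive,
  but synthetic or sequencing-derived tables may contain zeros. The
  default pseudocount is *half the smallest positive relative abundance
  in the table*, applied only when zeros are present; `pseudocount = 0`
  gives the exact clr. This is a data-scale-free convention that leaves
  zero-free tables untouched.
* **Shannon diversity** is reported in nats (natural log), the
  convention of the ecology stack this package sits beside; the log base
  is an argument.
* **Richness** uses a detection threshold per feature: the 0.8 quantile
  of that feature across samples (type-7, R's default linear
  interpolation), with *strict* exceedance. Strictness makes the
  constant-feature case well-defined (a flat feature is detected
  nowhere). The per-feature—rather than global—threshold is a documented
  interpretation choice.
* **Coefficient of variation** uses the sample (n−1) standard deviation,
  the default of the statistical environment the analysis style comes
  from. Zero-mean taxa get `NA` with a warning, never silent `NaN`.

## Redundancy analysis and variance partitioning

RDA is computed from first principles: column-center the clr matrix,
regress it on the (centered) predictors by least squares, and the
"constrained inertia" is the variance of the fitted matrix; partial RDA
first residualizes response and predictors on the conditioning block.
R² is reported against the *total* variance of the centered response, so
simple and conditional effects share a denominator. The pseudo-F is
`(constrained/df_X) / (residual/(n − 1 − df_X − df_Z))`. Inertia is on
the variance scale (SS/(n−1)), matching `vegan`'s convention; the test
suite checks equality with `vegan::rda`/`anova.cca` to 1e−8.

**Permutation inference.** p-values use the add-one convention with a
floor of 1/(n_perm+1); the default n_perm is 999. Two samples from one
infant are correlated, so rows are not freely exchangeable:

* between-infant terms (group, age, siblings, birth mode, breastfeeding)
  permute *whole infants* as units;
* the pure within-infant term (time) permutes *within* infants;
* independent-row data uses free permutation.

For free permutation of conditional effects the package uses
reduced-model (Freedman–Lane) residual permutation. For *restricted*
schemes it permutes the raw response instead: during development the
residual scheme combined with block restrictions proved badly
miscalibrated whenever a conditioning covariate is aligned with the
exchangeability structure (age increases almost deterministically along
the within-infant direction, so reduced-model residuals are not
within-infant exchangeable) — the package's null-calibration tests
rejected essentially always. Raw-response (Manly) permutation under the
restricted schemes holds the nominal level in those same tests. This is
the one place the implementation deliberately departs from the
most common textbook recipe, and it is a calibration-driven choice.

**Variance partitioning** fits an RDA for every nonempty subset of 2–4
predictor blocks and decomposes the full-model R² into unique and shared
Venn fractions by Möbius inversion of the subset R² lattice. Small
negative fractions are legitimate artifacts of non-orthogonal designs
and are reported as-is. Both raw and Ezekiel-adjusted fractions are
emitted (the adjusted ones match `vegan::varpart`); collinear subset
designs (overlapping blocks) are projected via pivoted QR rather than
rejected, so a duplicated block correctly shows zero unique fractions.

## Predictive mean matching

The two breastfeeding variables (average feedings/day from birth to PRE,
and from PRE to POST) are missing together, per infant, when the feeding
diary is absent. Imputation therefore runs on one row per infant with
two incomplete variables, chained (each variable regressed on the
demographic predictors plus the other variable's current values, 5
sweeps), with m = 10 imputations by default and a donor pool of k = 5 —
the conventional PMM donor count. The Bayesian regression draw is the
standard one: σ² from a scaled inverse-χ² at the residual sum of
squares, β normal around the least-squares fit; observed cases are
predicted with the least-squares coefficients and missing cases with the
drawn ones (type-1 matching), and each missing case copies the observed
value of one of its k nearest neighbours in predicted-mean space.
Imputed values are therefore always genuinely observed values, the
property the tests assert. A constant observed target is allowed (the
donor pool is then forced); collinear predictors are reduced to a basis
rather than rejected, since a binary covariate can easily lack variation
among the observed cases of a small cohort.

## The robust hierarchical model

For each outcome $y$ (a taxon's clr abundance, or Shannon diversity):

$$y_i \sim T(\nu, \mu_i, \sigma_i)$$
$$\mu_i = \beta_0 + u_{j[i]} + \beta_1\,\mathrm{CC} + \beta_2\,\mathrm{time}
 + \beta_3\,\mathrm{CC{\times}time} + \beta_4\,\mathrm{age} + \beta_5\,\mathrm{bf}
 + \beta_6\,\mathrm{sib} + \beta_7\,\mathrm{csec} + \beta_8\,\mathrm{sib{\times}csec}$$
$$\log\sigma_i = \beta_{\sigma 0} + \beta_{\sigma 1}\,\mathrm{CC} + \beta_{\sigma 2}\,\mathrm{time}
 + \beta_{\sigma 3}\,\mathrm{CC{\times}time} + \beta_{\sigma 4}\,\mathrm{sib}
 + \beta_{\sigma 5}\,\mathrm{csec} + \beta_{\sigma 6}\,\mathrm{sib{\times}csec},
 \qquad u_j \sim N(0, \tau).$$

The Student-t likelihood accommodates the heavy-tailed, outlier-prone
distributions of clr abundances; the per-infant deviations $u_j$ encode
the repeated measures by partial pooling; and the σ regression lets an
exposure change the *spread* of an outcome, not only its mean — a real
possibility for an environmental intervention that standard
homoscedastic models cannot express.

* **σ link.** A linear σ can go negative, so σ is modelled through a log
  link by default (the convention of the Bayesian regression software
  family this model class comes from). An identity-link variant is
  available (`sigma_link = "identity"`); it rejects non-positive σ
  during sampling.
* **Priors.** Comparison coefficients (both predictors' β and the σ
  model's βσ) get Normal(0, 1); this is meaningful because continuous
  covariates are standardized to unit SD by default and binaries are
  0/1, so "1" is a large effect on any outcome's scale, and the prior
  gently shrinks comparisons toward zero — a conservative choice that
  makes 95% intervals more likely to include zero than their frequentist
  counterparts. Intercepts get wide data-driven Student-t(3) priors
  (location median(y), scale 2.5·MAD); τ gets a half-t(3, 0, 2.5·MAD);
  ν = 1 + ν₀ with ν₀ ~ Gamma(2, 0.1), keeping the mean defined while
  allowing an effectively gaussian fit at large ν.
* **Breastfeeding coding.** The default is time-varying: each row
  carries the feeding rate of the period preceding that sample (birth→PRE
  for PRE rows, PRE→POST for POST rows). The alternative — both period
  rates as two fixed columns — is available (`bf = "two_period"`). The
  underlying study description is ambiguous between the two; the
  time-varying form matches the single-β₅ model statement, the
  two-column form matches the ordination's two-column breastfeeding
  block, so both are exposed and the choice is a config option.
* **Decision rule.** A contrast is *flagged* exactly when its central
  95% credible interval excludes zero; the flag is a pure function of
  the interval. Default contrasts: the four group-mean comparisons
  (within-group temporal, between-group per timepoint), covariate
  slopes, and the same group comparisons on the σ scale evaluated at the
  reference profile (no sibling, vaginal birth) — with the log link, σ
  differences are computed by transforming the draws, not the
  coefficients.
* **Multiple imputation.** The model is fitted once per completed
  dataset and the posterior draws concatenated (the mixture-of-posteriors
  pooling that multiple imputation justifies); diagnostics are kept per
  imputation and the worst case reported.

### Sampling

The sampler (RcppArmadillo) exploits the scale-mixture representation
$y_i \mid w_i \sim N(\mu_i, \sigma_i^2/w_i)$, $w_i \sim
\Gamma(\nu/2, \nu/2)$:

* mean-model coefficients and the intercept draw jointly from their
  exact gaussian conditional (the t(3) intercept prior is expanded with
  a Γ(3/2, 3/2) mixing scalar);
* subject deviations draw from exact gaussian conditionals;
* τ uses the Huang–Wand inverse-gamma expansion of the half-t(3) prior,
  giving exact conjugate updates;
* ν is updated by Metropolis on log(ν−1) against the *marginal* t
  likelihood (weights integrated out; they are refreshed from their full
  conditional at the start of the next sweep before anything else uses
  them, so the collapsed step is valid) — this decouples the strong ν–w
  dependence that slows the naive scheme;
* the σ-regression block, which has no conjugate form, uses
  coordinate-wise adaptive Metropolis walks plus an occasional joint
  move along the adapted covariance; all adaptation targets standard
  acceptance rates and is frozen after warmup, so the saved draws come
  from a valid fixed-kernel chain.

All randomness flows from R's RNG, so a seed fixes the fit bit-for-bit.
Defaults are 4 chains × 1000 saved draws (thin 4) after 1000 warmup
iterations; the study-level helpers (`fit_diversity`, `fit_all_taxa`)
default to 2 chains × 600 draws (thin 4, warmup 800), which keeps a full
per-outcome fit under half a second at the cohort's size (196 samples,
98 infants) while holding split-Rhat comfortably below the 1.05 warning
threshold in calibration runs. Convergence is screened by split-Rhat
across chains; a fit exceeding 1.05 warns and carries
`converged = FALSE`. Divergence counts, a Hamiltonian-specific
diagnostic, are reported as `NA` — the field exists so downstream code
written for gradient-based backends can read the same structure. The
unnormalised log posterior (likelihood, priors, and the jacobians of the
log-scale parameters) is exposed as `robt_log_posterior()` and is pinned
in the tests against an independently hand-coded evaluation; the whole
sampler is additionally cross-validated against an independent MCMC
engine (JAGS) on a fixture, where all posterior means and SDs agree
within Monte-Carlo error.

## Random-forest classification

POST samples' relative abundances predict CC vs HOME via random forests
under repeated stratified 10-fold cross-validation (10 repeats by
default). Folds are stratified because the design is balanced 49/49;
forests use 500 trees and mtry = ⌊√p⌋, the standard defaults. Forests
are trained on training folds only; the no-leakage property is exercised
by a null test (pure-noise features with random labels must score ~0.5,
which any leak of held-out labels would violate). Accuracy is averaged
over repeats.

## The synthetic cohort generator

The generator is the package's study stand-in and the truth source for
recovery tests. Compositions are logistic-normal: per-taxon logits =
population logit + per-infant intercept (SD 1.2) + per-sample noise
(SD 0.8), closed by softmax. Because the mean of a softmax is not the
softmax of the mean, the population logits are *calibrated* by
fixed-seed Monte Carlo (20,000 draws, 12 iterations, cached) so realized
population means hit the target profile: a dominant taxon at 51%, the
five dominant taxa cumulatively above 75% (targets sit within rounding
of 51/16.8/3.4/2.9/1.0 percent so the strict inequality holds), and a
geometrically decaying tail. The logit-scale SDs were chosen once so the
dominant taxon spans near-absence to near-total dominance across a
cohort — the extreme inter-individual variability characteristic of the
early-life gut; they are config fields, not constants.

Demographics: ages truncated-normal per group and timepoint (CC PRE
87.8 ± 16.0 days in [58, 123]; HOME PRE 76.7 ± 6.3 in [68, 90]; POST =
PRE + ~30 days), breastfeeding rates truncated-normal with a realistic
declining second period, sibling and C-section frequencies per group,
and weekly childcare half-days drawn from a pmf with median 4 and
interquartile range 3–4 (CC infants only). Breastfeeding is blanked
completely at random for 4 CC + 1 HOME infants, at both timepoints —
all-or-nothing per infant, as a missing diary implies.

Effects are opt-in: per-taxon logit-scale effect vectors per covariate
(default zero — the childcare null), and Shannon-shift effects applied
by a power transform of the composition (solving
$H(p^\theta/\lVert p^\theta\rVert_1) = H(p) + \delta$ by 1-D
root-finding), which changes diversity without renaming taxa.

**What passing tests do and do not show.** The generator emulates the
cohort's *statistical geometry* — compositional dominance, two-level
variability, covariate distributions, MCAR missingness — not its
biology: no taxon co-occurrence structure, no phylogenetic correlation,
no age-dependent succession, no antibiotic or illness events, no
probe-level measurement artifacts. Calibration results (false-flag
rates, permutation-test level, classifier chance performance,
parameter recovery) therefore certify the *estimators* under the
assumed data-generating geometry; they cannot certify conclusions about
any real cohort whose structure departs from it.

## Numerical choices and degenerate inputs

* Validation errors name the offending sample/taxon/infant.
* clr requires a positive pseudocount when zeros are present; an
  all-zero sample is an error at closure.
* A constant feature is never "detected" (strict exceedance); a
  single-sample table has no defined detection quantile and errors.
* RDA rejects rank-deficient designs by name (except inside variance
  partitioning, where overlap is meaningful and handled by projection);
  permutation p-values are floored at 1/(n_perm+1).
* The imputation model reduces collinear predictors to a basis; a
  constant target forces the donor pool rather than erroring.
* Sampler initialisation: intercept at median(y), coefficients at 0
  with per-chain jitter (SD 0.1), σ intercept at log sd(y), τ at
  MAD/2, ν at 21; the subject vector starts at zero.
* Zero-variance variables in descriptives are flagged `zero variance`
  with `NA` p, never passed to a t-test.
* `run_full_analysis` derives one sub-seed per stage from the master
  seed, so toggling one stage never changes another's stream; outputs
  are cached by configuration hash.

## Problem sizes used by the test suite

The suite runs the full cohort geometry (49+49 infants, 130 taxa) for
counting, calibration and RDA checks; reduced-draw sampler settings
(2 chains × 300 draws) for the 100-replicate coverage study and the
200-fit null-calibration sweep; 999 permutations for single RDA tables
and 99–199 inside calibration loops; and 20-seed averages for generator
calibration. These sizes were chosen so the complete suite documents the
package's statistical claims in a few minutes on one core while keeping
Monte-Carlo error well inside each test's tolerance band.

## Known limitations

* The σ model's identity-link variant can mix poorly when the posterior
  presses against the positivity boundary; the log link is the default
  for good reason.
* Pooled-imputation Rhat is reported per imputation; there is no
  across-imputation convergence statistic (the pooled object is a
  mixture by construction).
* The RDA triplot scores are exported numerically (species scores scaled
  by singular values, correlation-style biplot scores); no figure
  rendering is provided.
* PMM assumes the missingness is ignorable given the predictors (MCAR /
  MAR); there is no sensitivity analysis for informative missingness. A
  listwise-deletion path exists for sensitivity comparison (drop the
  incomplete infants and fit on complete data).
* With ~5 C-section infants per group, σ-scale contrasts involving birth
  mode are prior-dominated; their intervals mostly reflect the
  Normal(0,1) shrinkage.
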