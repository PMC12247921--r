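---
title: "Modeling bundle valuation and normalized neural value codes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling bundle valuation and normalized neural value codes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

When people evaluate a bundle of two consumer items, the bundle's
subjective value is typically *sub-additive*: it falls short of the sum
of the items' individual values, and the shortfall grows with the item
values. `bundleval` implements the full computational workflow for
studying this phenomenon behaviorally and neurally:

1. a generator for willingness-to-pay (WTP) bids elicited with a
   Becker–DeGroot–Marschak (BDM) auction, for single items and all
   pairwise bundles over a multi-day roster;
2. mixed-effects fitting and BIC comparison of four bundle-value model
   families;
3. closed-form theory for a divisively normalized value code and its two
   testable predictions (concavity of bundle value, attenuation of
   neural responsiveness on bundle trials);
4. cross-condition ridge decoding of value from simulated multivoxel
   patterns, with leave-one-run-out cross-validation and group-level
   Wilcoxon/FDR statistics;
5. representational similarity analysis (RSA) comparing absolute and
   normalized value codes, including a context-dependent normalization
   model whose value coefficient differs by trial type.

All stages run on synthetic data whose statistical structure mirrors the
experimental design the methods assume: 40 unique items over 3 days (10
shared across days, 10 fresh per day, 20 per day split evenly between
food and trinkets), 210 bundles per day (190 distinct pairs + 20
same-item pairs), and a choice task of 5 runs x 62 trials per day — 930
trials per participant, with 14 participants as the default cohort.

## Behavioral models

Item bids `vi`, `vj` enter four families for the bundle value `vij`:

* linear: `vij = b0 + b1*vi + b2*vj`
* power: `vij = b0 + b1*vi^b2 + b3*vj^b4`
* logarithmic: `vij = b0 + b1*log(b3 + vi) + b4*log(b5 + vj)`
* divisive normalization: `vij = b0 + b1*(vi + vj) / (sigma + vi + vj)`

Sub-additivity appears as slopes below one (linear family) or concavity
(the nonlinear families). Mixed-effects fits place subject random
effects on the intercept and the leading scale coefficient, mirroring
the linear model's intercept-and-slope structure while keeping
nonlinear estimation stable; the linear family uses `lme4::lmer`
(REML), nonlinear families `nlme::nlme` (ML) warm-started from pooled
fixed-effects fits. Fixed-effects nonlinear fits use multi-start
Levenberg–Marquardt with exponents box-constrained to (0, 5] and the
normalization constant bounded below at 1e-6.

Two numerical choices matter here:

* **Profile fitting for the divisive-normalization family.** Conditional
  on `sigma` the family is linear in `(b0, b1)`, so the fixed-effects
  fit profiles the residual sum of squares over `log(sigma)` with 1-D
  optimization. On (near-)linear data the optimum runs along the
  `sigma -> Inf` ridge where the family degenerates to a linear model;
  full Gauss–Newton iterations develop singular gradients there, while
  the profile remains well defined and returns the boundary solution
  gracefully.
* **Two BIC aggregations.** `compare_bundle_models()` reports both the
  BIC of the single mixed-effects fit and the sum of per-subject
  fixed-effects BICs, clearly labelled; ranking (`delta_bic`) uses the
  summed per-subject column, which is fast, robust, and treats all
  families identically.

Fitted curves are evaluated with both item values set equal, on a grid
from $0 to $10 in $0.01 steps (1001 points), plotted against the summed
item value — the natural axis for comparison with the additive
benchmark.

## Normalization theory

The divisive normalization transform `z = v / (sigma + sum(v))` with
contrast parameter `sigma > 0` makes two predictions, both available in
closed form:

* the implied bundle value `vbar / (sigma + vbar)` is strictly concave
  in the summed item value `vbar` (second derivative
  `-2*sigma / (sigma + vbar)^3 < 0`), so bundles are discounted more as
  their parts grow in value;
* the responsiveness `sigma / (sigma + v1 + v2)^2` is maximal when the
  context contains a single item and strictly smaller whenever a second
  item is present — a neural measure linear in normalized value will
  respond less strongly to value on bundle trials.

The implementation generalizes to N items; tests cover N in {1, 2, 3,
5}. Range normalization shares the attenuation prediction but has no
closed form here; the pattern generator exposes attenuation directly
through an `attenuation_ratio`, so the package, like the design it
emulates, does not attempt to distinguish divisive from range
normalization.

## Synthetic data: what is and is not emulated

**Latent item values** are drawn from an exponential distribution with
mean $3.30 truncated to the $0–20 budget, matching the right-skewed,
low-value-dominated bid distributions typical of consumer-item
auctions; the mean is configurable. Each subject's latent item values
are drawn once and re-elicited each day as item bids with additive
Gaussian noise. Bundle bids apply the chosen family to the *latent*
item values, add subject random effects (s.d. 0.30 on the intercept,
0.08 on the scale coefficient) and Gaussian noise (s.d. $1), and are
censored to [0, 20]. Censored bids are included as-is in fitting — the
simplest convention, and a documented limitation: heavy censoring
biases naïve fits, which is why parameter-recovery analyses fit against
the retained latent covariates (`with_latent_covariates()`), targeting
the generative model directly rather than the error-in-variables
regression on noisy item bids.

**Trial schedules** partition each day's 210 bundles evenly at random
across the 5 runs (42 per run; the allocation rule is not dictated by
the design, so a random even partition per seed is used), present each
roster item once per run, interleave item and bundle trials at random,
and attach per-category reference amounts equal to the subject's
median same-day bid for that category (midpoint convention for even
counts; references are computed per day). Choices follow a logistic
rule in (bid − reference), with a configurable temperature and an
optional money bias on item trials; this choice model is plumbing — the
analyses only require that the stimulus is chosen about half the time,
which the median reference guarantees.

**Multivoxel patterns** are a low-rank linear code plus i.i.d. Gaussian
noise: fixed unit-norm direction vectors carry the coded value, a
trial-type signal, and a button-side signal. Coding schemes select the
value transform (raw bid; bid minus the trial-type mean; z-score within
trial type; context-normalized value with bundle responsiveness equal
to `attenuation_ratio` times item responsiveness; or no value signal),
and an `orthogonal` geometry places item and bundle value on orthogonal
directions to realize a condition-specific code. What is *not*
emulated: BOLD time series, HRF convolution, spatially correlated
noise, motion artifacts, or trial-wise GLM estimation — passing tests
show that the analysis chain recovers what was encoded under the
assumed low-rank-plus-noise structure, not that real fMRI preprocessing
is handled.

## Cross-condition decoding

Targets are bids z-scored within trial type (population s.d.), putting
item and bundle values on one scale. The decoder is closed-form ridge
regression with an unpenalized intercept at `alpha = 1e3`; voxels are
not standardized (patterns stand in for beta maps, fed in raw). For
each held-out run the decoder is trained on one trial type from the
other 14 runs and scored by Pearson correlation separately per test
trial type; per-split accuracy is the plain mean of r across folds (no
Fisher transform). Group inference uses two-sided one-sample Wilcoxon
signed-rank tests against r = 0, Benjamini–Hochberg corrected across
ROIs within each split at q = 0.05; condition differences use paired
signed-rank tests on per-subject split differences (samples are paired
within subject). Folds with fewer than two test trials of a condition
are skipped with a warning; all-zero samples return p = 1.

## RSA and the full normalization model

Neural dissimilarity matrices are pairwise Euclidean distances between
trial patterns, with every within-day pair hard-masked out (the
stricter of the plausible conventions) to avoid run- and day-level
confounds. The predicted DSM is

```
PredictedDSM = a0 + a1*ButtonPressDSM + a2*TrialTypeDSM + ValueDSM
```

with the nuisance DSMs defined as binary disagreement (0 same, 1
different) and `ValueDSM` the pairwise absolute differences of the
family's per-trial values, entering with a unit coefficient as printed
— the value scale is carried inside the value computation. For the
absolute, subtractive and z-score families the per-trial value is `b1`
times the transformed bid, which makes the model linear in its
parameters and exactly solvable by least squares. "Category" in the
subtractive transform is read as trial type (item vs bundle) for
consistency with the rest of the analysis; centering by stimulus
category (food/trinket) is exposed as an option. The full normalization
family computes per-trial values as

```
(b1*AbsValue + b2*AbsValue*TrialCategory) /
  (sigma + w_avg*AvgValue + w_1*TrialCategory + w_v*AbsValue)
```

with `AvgValue` the mean value within the trial's type. Three
identifiability choices are built in:

* `sigma` is fixed at 1 during optimization — joint scaling of all six
  parameters leaves the values unchanged, so one scale must be pinned;
* `b1 >= 0` fixes the sign convention (absolute differences only
  identify the coefficients up to a joint sign flip);
* when `w_v = 0` the value is linear in the bid within each trial type,
  leaving `(b1, b2, w_avg, w_1)` identified only up to a per-type
  rescaling; a tiny ridge penalty on the denominator weights
  (1e-4 times the summed squared dissimilarities) breaks the tie toward
  the parsimonious representation. The penalty affects only the
  optimizer's path; reported RSS and BIC are unpenalized.

Optimization is multi-start (5 starts by default) bounded L-BFGS-B with
|b| <= 10 and non-negative denominator weights, followed by a polishing
pass. BIC is `n*log(RSS/n) + k*log(n)` with k counting all free mean
parameters plus the residual variance, identically across families, so
one extra parameter at equal RSS costs exactly `log(n)`. Model
comparison reports delta-BIC against the nuisance-only null model; the
attenuation test is a paired two-sided t test of the bundle coefficient
`b1 + b2` against the item coefficient `b1` across subject (x ROI)
cells, with p = 1 by convention when all differences are zero.

## Validation suites and problem sizes

The package's validation suites generate data at the study's design
size — 14 subjects, 3 days x 5 runs x 62 trials — with these scaled
analysis choices, stated here as the package's own problem sizes:
decoding simulations use 60-voxel regions; RSA fits subsample 25 trials
per day (75 trials, ~1 875 cross-day pairs) before building DSMs;
replicate suites use 20 seeded replicates. The model-selection suite
generates linear data with mildly asymmetric slopes (0.74/0.63, in the
range of the stratified per-type estimates); with exactly symmetric
slopes the linear family is observationally nested in the
divisive-normalization family's `sigma -> Inf` limit and selection
between them is undefined by construction. The type-I decoding check
counts a replicate as clean when no split survives Benjamini–Hochberg
correction over the full family of split tests. All replicate suites
derive their seeds deterministically from a single base seed.

## Known limitations

* Censoring at the budget boundary is not modeled in the likelihood;
  fits treat censored bids as exact.
* The pattern generator's noise is i.i.d. Gaussian; real multivoxel
  noise is spatially and temporally structured, so decoding accuracies
  here are not calibrated to empirical effect sizes.
* The RSA model's parameters beyond the per-type value slopes are
  weakly identified when the generating code is linear in value; only
  the derived item/bundle coefficients (and their contrast) should be
  interpreted.
* The full normalization and range accounts of attenuation are not
  distinguishable within this design, by construction.
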