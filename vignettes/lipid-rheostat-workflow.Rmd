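---
title: "From feature tables to the sphingolipid rheostat: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From feature tables to the sphingolipid rheostat: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(LipidRheostat)
```

## The problem

Untargeted lipidomics assigns identities to thousands of MS1 ions by mass
alone, so its conclusions stand or fall on a handful of quality decisions:
how observed m/z is recalibrated, where the noise floor sits, how tight the
mass tolerance is, and (for LC-MS) whether a lipid's retention time is
stable enough to trust the annotation. Downstream, the biology of interest
here is a single number per sample: the balance of pro-survival
sphingosine-1-phosphate (S1P) against pro-apoptotic C16 ceramide — the
*sphingolipid rheostat* — read either from total-normalized AUC fractions
or from absolute pmol obtained by single-point internal-standard
quantitation. This vignette records how each stage is modeled, which
parameters matter, and which design decisions were genuinely open.

## Mass recalibration

`fitMassCalibration()` maps observed standard m/z to theoretical m/z with a
straight line, `corrected = slope * observed + intercept`.

* With one standard the slope is pinned at 1 and only the offset is
  estimated: a one-point fit of both parameters would be degenerate.
* With two or more standards, ordinary least squares. A global linear model
  absorbs both a constant Da offset and a proportional (ppm-scale) stretch,
  which covers the dominant error modes of a calibrated Orbitrap/QTOF over
  a single acquisition; per-window calibration was considered and left out
  because three spiked standards cannot support five window-level fits.

The model object carries per-standard residuals in ppm; applying a model
never touches intensities, retention times or row order.

## Noise floor and the 2x rule

The instrumental noise baseline is estimated as the **median of the lowest
intensity decile** across all features of a run
(`estimateNoiseBaseline()`). "Baseline detection level" is not a precisely
defined quantity; the decile median is robust to the bulk of genuine peaks,
insensitive to a few zero or saturated readings, and exposed via the
`decile` argument. The filter then keeps exactly the features with
intensity at or above `noiseFactor * baseline` — the boundary is
*inclusive*, because inclusion is phrased as "at least twice" the noise
level. Raising the factor can only remove features (a tested monotonicity
property).

## ppm matching and its tie-breaks

`matchFeatures()` scans every (record, adduct) pair for each feature and
applies the tolerance to the signed relative error
`1e6 * (observed - theoretical) / theoretical` with the default
`tolPpm = 50`. Numerical choices:

* the tolerance is applied **after** calibration (correct first, then
  filter);
* the best assignment is the smallest |ppm error|; exact ties (possible
  when two records share a mass) resolve by lexicographic lipid id, and
  every in-tolerance candidate is retained in an audit column;
* both one-best-match and all-matches behaviour are exposed via
  `mode = c("best", "all")`, since either convention is defensible for a
  50-ppm database scan;
* the default adduct list (protonated and ammoniated positive, deprotonated
  negative) is configuration, not assertion — ammonium acetate in the
  extraction buffer makes the ammoniated series worth searching, but any
  adduct table built with `adductSpec()` can be supplied.

The implementation is required (and tested on randomized instances up to
200 features x 200 records) to agree exactly with a brute-force all-pairs
scan; there is no indexing shortcut that could silently change results.

MS2 information is reduced to a boolean `fragment_support` flag (the
feature was selected for fragmentation and its database record lists
diagnostic fragments). Spectral scoring is out of scope.

## Retention-time CV verification

For LC-MS cohorts, `rtCvFilter()` computes per lipid the coefficient of
variation of retention time across samples and keeps lipids with
CV <= `rtCvMax` (default 0.25). Two conventions needed fixing:

* **Population sd** (n denominator). The CV here is a descriptive summary
  of alignment quality, not an inferential variance estimate; the
  population form is used consistently (also in
  `coefficientOfVariation()`), and the threshold is configurable, so the
  n vs n-1 choice never changes a conclusion by itself.
* Lipids observed in fewer than `minSampleFraction` (default 80%) of the
  samples are **excluded and reported**, not imputed: an RT CV over a
  handful of detections says little, and imputation would manufacture
  stability.

## Normalization and targeted quantitation

`normalizeTotal()` divides each sample by its total AUC over the
*quantified* lipids — annotated, quality-passing species — so unannotated
noise never inflates the denominator. Rows (samples) sum to 1 within 1e-9
and the operation is idempotent.

`quantifyByIS()` implements the proportional single-point rule
`pmol = pmol_IS * AUC_analyte / AUC_IS`. It is exactly linear in the
analyte AUC and inverse in the standard AUC; a zero analyte AUC returns 0
pmol, and the rheostat instead flags such samples as undefined (`NA` with a
warning) because a log ratio cannot absorb a zero. When two standards can
normalize C16 ceramide (the deuterated C16 Cer-d7 or the odd-chain C17
Cer), `selectInternalStandard()` picks the one with the higher
signal-to-noise in that run, ties broken by name. Spike amounts come from
`spikeAmount(volume_uL, conc_uM)`: 20 uL of 2.5 uM = 50 pmol for both
ceramide standards, 20 uL of 5 uM = 100 pmol for S1P-d7.

The rheostat itself, `sphingolipidRatio()`, is the linear or natural-log
ratio of S1P to C16 ceramide *on the same normalization* — either both as
total-normalized fractions (in which case the totals cancel) or both in
pmol. The log form is antisymmetric under swapping the two lipids.

## Group statistics

Standard machinery is delegated to base R (`t.test`, `p.adjust`, `ptukey`,
`hclust`, `svd`); the package adds the conventions and the one procedure
base R lacks:

* **Dunnett many-to-one comparisons** use the pooled error variance and
  adjust by the distribution of `max |T_i|` under the equicorrelated
  multivariate t with correlations
  `sqrt(n_i n_j / ((n_i + n0)(n_j + n0)))`. The tail probability is
  estimated by seeded Monte Carlo (default 50,000 draws) rather than
  numerical integration: the estimate is deterministic given the seed,
  its resolution (~1/nDraws, standard error about 0.001 at p = 0.05) is
  far below any decision threshold used here, and the reduction k = 1 to
  the pooled t-test is exact up to that error. Adjusted p-values are
  floored at the raw p so Monte Carlo noise can never make an adjusted
  value undercut its unadjusted counterpart.
* **Tukey-Kramer** uses the studentized range with Kramer's harmonic
  correction for unbalanced groups.
* Degenerate t-test inputs follow explicit conventions: zero variance with
  zero difference gives p = 1, zero variance with a real difference p = 0.
* **Fold change exactly 1** is classified "unchanged"; the up/down
  dichotomy leaves the boundary undefined and silently assigning it to
  either side would be arbitrary.
* **SNP density** is emitted both per kb and as a percentage (x100),
  because both conventions circulate and the denominator of the percentage
  form is ambiguous; neither is asserted as canonical.
* **PCA "with imputation"** fills missing entries with variable means
  before the SVD — the simplest defensible reading — with an iterative
  low-rank refinement behind `impute = "iterative"` for users who want
  missingness re-estimated under the model.
* **Serum-batch stability** is tested by batch-pair t-tests *paired by
  lipid* on the log scale, BH-adjusted over the pairs. With one
  concentration per lipid per batch, a within-lipid test across batches
  does not exist; pairing by lipid asks the answerable question — do two
  batches differ systematically? — and leaves large, direction-free
  per-lipid scatter (the ~70% CV structure) correctly non-significant.

## Phenotype fits

* `fitGrowthRate()` scans all contiguous windows covering at least 30% of
  the time points and returns the least-squares slope of the window with
  maximal R^2 (ties towards longer, then earlier windows). On a logistic
  curve this selects the most linear stretch around the inflection; with
  hourly sampling over ~110 h and growth rates in the 0.7-1.1 %/h range
  the window slope sits within a few percent of the analytic maximum
  r K / 4 — the residual bias is the price of reading a "linear-like
  phase" off a curve that is never exactly linear. A constant curve is a
  perfect fit to its own mean and returns slope 0.
* `fitEc50()` fits the four-parameter log-logistic
  `y = lower + (upper - lower) d^h / (d^h + e^h)` by bounded
  Levenberg-Marquardt least squares from three deterministic starting
  points, keeping the best converged fit. Asymptotes are constrained to
  [0, 1] (responses are fractions dead), the hill slope to be positive.
  Unfittable data return `converged = FALSE` rather than an extrapolated
  number, and an EC50 outside the tested dose range is flagged. The
  reported `tol` is the standard error of the EC50 from the fit's
  covariance; it is *a* tolerance, with no claim to match any particular
  historical error-bar convention.
* `percentIncreaseDeath()` defaults to the percentage-point difference
  `combo - single` — the natural reading when both arms are percent-dead
  values on the same scale — with the relative convention
  `100 (combo - single) / single` behind a flag.

## What the generators emulate — and what they do not

The generators in `simConfig()` / `simulate*()` define the package's study
conditions:

* a healthy control (hT) and four cancer subclones (pA-pD), six replicates
  per arm, paired vehicle / SKI-II treatment reusing the same noise draws
  so the treatment effect is the only difference between arms;
* lognormal intensity noise at 10% CV (multiplicative, strictly positive —
  the natural model when only CV summaries are known);
* a planted rheostat shift of +1.1 on the log scale in every cancer group
  (S1P x e^0.55, C16 Cer x e^-0.55), S1P halved under treatment; the
  magnitudes are synthetic choices in the qualitatively observed direction
  (S1P up, C16 Cer down, inhibitor reduces S1P), not measured values;
* retention-time jitter of 2% CV for genuine lipids against 40% for
  decoys, straddling the 25% filter threshold;
* serum batches whose lognormal per-lipid batch effects are *calibrated*
  (numerically, on a fixed internal draw) so the median empirical
  across-batch CV matches the 0.7 target — the sample CV of three
  lognormal draws is biased well below the distribution CV, and the
  observable being emulated is the median of sample CVs;
* logistic growth at the measured per-group rates (hT 0.72 up to pB 1.12
  %confluence/h), sampled hourly over 0-110 h from 15% starting
  confluence, with 0.3 percentage points of additive measurement noise;
* binomial cell-death counts (10,000 events per dose) from a 4PL curve
  with hill 2 and per-group EC50s of 8-14 uM.

Each generator is a pure function of its config; per-sample substreams are
derived deterministically from the master seed, so extending a cohort never
perturbs existing samples.

What passing tests do **not** show: the generators emit feature-level data
only. There are no chromatographic peak shapes, no isotope envelopes, no
adduct cross-talk, no in-source fragmentation, no missing-not-at-random
dropout, and noise is homoscedastic on the log scale. Recovery of planted
parameters therefore validates the *computations*, not the behaviour of
the pipeline on pathological instrument data.

## Problem sizes and determinism in the test suite

The suite exercises: oracle equivalence on 100 randomized instances up to
200 features x 200 records; error-rate calibration of BH, Monte Carlo
Dunnett and Tukey-Kramer on 1,000 simulated null datasets each (nominal
level 0.05, acceptance band +-2 Monte Carlo standard errors); EC50 recovery
over 100 seeded replicates at 10,000 events per dose; and serum-batch
stability over 20 seeded cohorts. These sizes keep each property estimate's
Monte Carlo error well inside its acceptance band while the whole suite
runs in about two minutes. All stochastic tests are pre-seeded; an
exact-level test at FDR 0.05 is *expected* to flag some batch pair in about
5% of null runs, which is the calibration being verified, not a defect.

## Known limitations

* The annotation stage trusts the database: isomers and isobars within
  50 ppm are distinguished only by the id tie-break and the audit column.
* Single-point internal-standard quantitation assumes equal response
  factors between analyte and standard; no response curve is fitted.
* The Dunnett adjustment's Monte Carlo resolution bounds reportable
  adjusted p-values below by ~1/nDraws; raw p-values remain exact.
* Standard PCA applied to binary presence/absence matrices is supported
  but the linear model is a rough approximation for binary data; treat
  such score plots as exploratory.
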