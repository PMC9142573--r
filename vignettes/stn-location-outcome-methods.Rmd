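---
title: "Mapping subthalamic stimulation site to neuropsychological outcome: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping subthalamic stimulation site to neuropsychological outcome: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Deep brain stimulation (DBS) of the subthalamic nucleus (STN) treats the
motor symptoms of Parkinson's disease, but the STN is small and functionally
segregated: its posterior/dorsolateral sensorimotor territory abuts
associative and limbic territories anteromedially. Where within (or near)
the nucleus a patient is chronically stimulated may therefore matter for
*non*-motor outcomes — cognition and mood — and that relationship may differ
in patients with a psychiatric history. `stnlda` implements a pipeline for
asking exactly this question from tabular data: per-hemisphere active-contact
positions in MNI millimetres, plus pre- and postoperative scores on an
18-measure neuropsychological battery (15 cognitive measures on the
psychometric T scale, mean 50 / SD 10, and three psychiatric self-report
scales: CES-D, the Zung SAS anxiety index, and the Apathy Evaluation Scale).

Everything upstream of those tables — image coregistration, normalization,
electrode reconstruction, field modelling — is out of scope; coordinates and
any volume-of-tissue-activated (VTA) summaries arrive precomputed.

## The procedure

For one measure and one hemisphere (hemispheres are never pooled):

1. **Change scores.** `delta = post - pre` on the measure's own scale. By
   default (`polarity_adjusted`) the difference is sign-flipped for
   lower-is-better scales so a positive delta always means clinical
   improvement; `strict` mode keeps the raw difference for every
   scale. The flip matters only for the three psychiatric scales.
2. **Tri-class outcome.** `worsening` if delta < −5, `unchanged` if
   −5 ≤ delta ≤ 5 (boundaries inclusive), `improvement` if delta > 5. The
   band half-width of 5 makes the unchanged class span 10 T-points — one
   population SD, the conventional threshold for clinically meaningful
   change. The same band is applied to the raw/index psychiatric scales by
   default (no standardized alternative is defined for them); it is
   configurable per analysis.
3. **Fisher discriminant axis.** Contact coordinates are standardized per
   axis (mean 0, SD 1); class-size-weighted between-class scatter
   `S_b = sum_c n_c (mu_c − mu)(mu_c − mu)'` and pooled within-class scatter
   `S_w` are formed, and the generalized eigenproblem `S_b v = lambda S_w v`
   is solved by whitening (Cholesky of `S_w`, symmetric eigendecomposition).
   LDA1 is the leading eigenvector, oriented so that it points from the
   grand mean toward the improvement-class mean, mapped back to native MNI
   space by multiplying each component by its axis SD and renormalizing,
   and decomposed into axis proportions `p_i = |v_i| / sum |v|`.
4. **Correlation.** All usable contacts are projected onto LDA1, the
   projections z-scored (an affine map, so correlations are unaffected),
   and Pearson's r computed against the change scores with the usual
   two-sided t-transform p-value on n − 2 degrees of freedom.
5. **Multiplicity.** Benjamini–Hochberg at FDR α = 0.10 across the family
   of all measure × hemisphere tests in the run (up to 36); a
   `per_hemisphere` family definition is available because the original
   family is not unambiguously recorded anywhere we could follow.
6. **Stratification.** The same family is repeated within strata defined by
   a psychiatric-history flag (depression, anxiety, visual hallucinations,
   impulse-control behaviors), each stratum guarded by a minimum size of 11
   subjects — smaller discriminant models were judged too unstable to
   interpret — and an overlap report compares significant associations
   across strata and the full cohort.

### Numerical choices

* **Regularization.** With classes as small as 2 at n = 42, `S_w` can be
  ill-conditioned; when its condition number exceeds 1e10 (or Cholesky
  fails) a Tikhonov term `1e-8 · trace(S_w)/3 · I` is added, and the fit is
  refused only if that still fails.
* **Rank.** With C classes at most C − 1 eigenvalues are genuine;
  eigenvalues are clamped at zero and compared against a relative tolerance
  (`1e-7 · lambda_1`), and the share of class-to-class variability explained
  by LDA1 is `lambda_1 / sum(supra-tolerance lambdas)`. Summing over all
  three eigenvalues instead would only shrink the denominator by numerical
  noise.
* **Ties.** If the two leading eigenvalues agree within 1e-9 relative, the
  eigenvector better aligned with the improvement class (after orientation)
  is chosen and a message records the tie.
* **Degenerate inputs.** Zero-variance axes, single-class labelings and
  zero projection variance raise classed errors; `run_measure()` converts
  them into `single-class` / `insufficient-n` statuses so a family run
  never aborts. Classes with exactly one member are dropped from the
  scatter computation (with a warning) but their contacts are still
  projected and correlated.
* **Axis proportions** use absolute-component normalization, consistent
  with reported triplets that sum to ~100%; squared components are
  available behind a flag.

## What the synthetic generator emulates

`synthetic_config()` / `simulate_cohort()` generate cohorts with the
structure the analysis assumes: per-hemisphere Gaussian contact clouds
around STN-region centroids (±12, −13, −6 mm — conventional coordinates,
not estimates from any specific dataset; 1.5 mm isotropic SD), and for each
measure a clinical change score

```
delta = slope · <contact − centroid, direction> + N(0, noise_sd²)
```

with per-flag modulation (an added or replacing gradient for flagged
subjects). Baselines are drawn around each scale's conventional mean with a
10-point SD; postoperative scores are baseline plus the change,
sign-flipped for lower-is-better scales so the planted gradient is always
on the improvement scale.

Defaults are the motivating study's conditions: 42 subjects, history-flag
rates 12/42, 15/42, 11/42 and 6/42, bipolar stimulation on 33/84 leads, and
a z-axis gradient. No physical effect size (change units per mm) is
published anywhere we could adopt, so the default slope of 4 with noise
calibrated to a theoretical projection–outcome correlation of 0.7
(`noise_sd_for_r()`) was chosen to give a total change-score SD of ~8.6 —
about one T-score SD, in line with observed change spreads — which
populates all three outcome classes (~28/44/28%) under the ±5 band. A
much shallower gradient starves the extreme classes (at slope 2 roughly
three quarters of subjects sit in the unchanged band and the fit rests on
~5 subjects per extreme class), which no cohort this analysis was designed
for resembles.

Deliberate simplifications, and what they mean for the tests:

* Contact clouds are Gaussian, not atlas-constrained; the analysis consumes
  coordinates only, and real group-space normalization itself pushes
  contacts across atlas boundaries.
* Scores are generated independently per hemisphere, so each hemisphere's
  geometry–outcome link can be recovered and tested in isolation; in a real
  cohort both hemisphere rows of the long score table would carry the same
  subject-level scores, and the two hemispheres' tests would be correlated.
* History flags are independent of each other and of location
  (`flag_sampling = "exact"` fixes the flag counts instead of drawing them
  binomially, matching a cohort with known subgroup sizes).
* No dropout, disease progression, practice effects, or measure-to-measure
  correlation. Passing recovery tests on these cohorts shows the estimator
  chain is correct under its own assumptions — not that real data satisfy
  those assumptions.

## Statistical caveats the package measures rather than hides

**The parametric p-value is anticonservative by construction.** The
discriminant axis is *selected* using class labels that are a banding of
the same change scores the projections are then correlated with. Under a
true null (location independent of outcome) the oriented correlation is
biased positive (mean ≈ +0.14 at n = 42 with the default band and a
5-point noise SD) and the nominal-0.05 test rejects ≈ 18% of the time;
consequently all-null 36-test families reject *something* far more often
than the BH level suggests. This circularity is a property of the published
procedure that the package reimplements, not of the implementation:
labelling with an independent draw of change scores restores uniform
p-values (KS p = 0.44 over 2000 replicates). Two acceptance-suite checks —
empirical FDR of all-null families at the BH level, and uniformity of
per-test p-values under permutation — are therefore expected to fail for
the parametric pipeline and are retained, failing, as an honest record.
`run_measure(..., p_method = "permutation")` provides the package's remedy:
the entire pipeline (class assignment, fit, projection, correlation) is
refitted under permutations of the change scores, which calibrates the
p-value for the selection step by construction, at roughly `n_perm` times
the cost. The default remains parametric to match the original procedure;
treat its uncorrected p-values as descriptive.

**Noiseless data do not give r = 1 at small n.** Even with a perfectly
linear, noise-free gradient, the class means of the *off*-gradient
coordinates differ by sampling noise, which tilts LDA1 by O(1/√n); the
deficit 1 − r shrinks as O(1/n) (measured: r ≈ 0.991 at n = 42, ≈ 0.9998 at
n = 2000). Tests assert this convergence rather than exact unity.

**Direction recovery degrades for oblique gradients.** At the study
conditions (n = 42, theoretical r = 0.7, 200 seeds) the median angular
error of the recovered native-space axis is ≈ 13° for the default z-axis
gradient, and the dominant axis is identified essentially always. For an
oblique gradient `(1,1,2)/√6` the same conditions give ≈ 16° median error
and an 84% dominant-axis rate — the axis-proportion readout should be
trusted only when one axis clearly dominates.

## Monte-Carlo problem sizes

The test suite and `scripts/acceptance.R` use: 100 random instances for the
brute-force Rayleigh-quotient oracle (grid search plus local refinement,
sharing no code with the fit), 150 fits for the rank bound, 50 instances
for affine equivariance (tolerance 1e-8), 200 seeds for planted-direction
recovery, 1000 seeds (300 in the faster acceptance script) for the all-null
FDR study, 1000 permutations for the null-calibration check, and 100 seeds
for the subgroup axis-contrast study. The paired-change and regression
calibrations use 500–1000 replicates.

## Known limitations

* Patient-level data from the motivating study are not deposited, so
  nothing here reproduces its numeric results; all quantitative claims are
  about synthetic cohorts with known truth.
* The pipeline never classifies held-out subjects; LDA is used purely as a
  dimension-reduction step, and no cross-validated accuracy is defined.
* VTA analyses operate on precomputed summary tables only
  (`simulate_vta_summaries()` generates summary-level stand-ins, not
  fields).
* The min_n = 11 guard, the ±5 band on raw psychiatric scales, and the
  all-tests BH family are judgement calls exposed as parameters; results
  for small strata or alternative families should be read accordingly.
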