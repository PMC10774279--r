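---
title: "Methods: seed-connectivity screening of bipolar versus unipolar depression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seed-connectivity screening of bipolar versus unipolar depression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Bipolar disorder typically begins with depressive episodes and is therefore
often diagnosed — and treated — as unipolar major depression until a manic or
hypomanic episode reveals the true diagnosis. `limbicscreen` implements an
individual-level screening analysis built on resting-state fMRI: the
functional connectivity (FC) of a bilateral amygdala seed with the rest of
the brain is used to train a classifier that separates known bipolar
patients from unipolar patients, and that classifier is then applied to an
independent sample of patients who *converted* to bipolar disorder during
follow-up. The scientific claim being operationalized is that amygdala-based
connectivity in the cortico-limbic circuit carries *trait* information about
bipolarity that is present before the first manic episode.

The analysis chain is:

1. **Seed FC maps.** For each subject, the preprocessed BOLD run is reduced
   to one map: the Pearson correlation \(r_v\) between the mean time series
   of the seed region and every other voxel \(v\), variance-stabilized by
   the Fisher transform \(z_v = \operatorname{atanh}(r_v)\).
2. **Region-based feature selection.** A random-forest ensemble scores each
   voxel by mean decrease in impurity (MDI); scores are summed within atlas
   regions; regions are ranked by that sum; walking down the ranking, each
   region's subject-wise mean FC is compared between groups with a
   two-sided Mann–Whitney U test, and regions are admitted while
   \(p < 0.05\). The final feature set is every voxel with non-zero MDI in
   an admitted region.
3. **Classification.** A linear soft-margin classifier (hinge loss, penalty
   \(C\) chosen by cross-validated grid search) is evaluated by stratified
   eightfold cross-validation, with the entire selection re-run inside each
   training split, and then frozen and applied without refitting to the
   independent test sample. Significance of the cross-validated accuracy is
   assessed by label-permutation (1000 iterations in the source design;
   configurable here).
4. **Group statistics.** Demographics are compared with ANOVA /
   Kruskal–Wallis / chi-square / exact tests; the top-ranked regions'
   mean FC is compared across the three groups (unipolar, converted
   bipolar, bipolar) by ANOVA with Levene-routed post-hocs (pooled-variance
   Bonferroni when variances are homogeneous, Tamhane T2 otherwise); FC is
   correlated with symptom scales under Benjamini–Hochberg FDR control.

## What the synthetic generator emulates

No patient data accompany the analysis, so the package ships a generator
(`cohort_spec()`, `simulate_cohort()`) that reproduces the *statistical
structure* the method assumes. A small 3-D grid is partitioned into
contiguous axis-aligned regions by recursive bisection (a miniature
anatomical parcellation with a designated seed region). Each subject has a
latent seed series \(s_t \sim N(0,1)\); a voxel in a region with coupling
\(c\) carries

\[ x_t = c\, s_t + \sqrt{1-c^2}\,\varepsilon_t, \qquad
   \varepsilon_t \sim N(0, \sigma^2), \]

independently over voxels and timepoints. With \(\sigma = 1\) the expected
seed correlation of that voxel is exactly \(c\) (generally it is
\(c/\sqrt{c^2 + (1-c^2)\sigma^2}\)); this closed-form identity is what makes
the generator testable. A *planted* subset of regions receives a higher
coupling in the bipolar-like groups, reproducing the published direction of
effect (unipolar < bipolar ≈ converted-bipolar); all other regions share a
baseline coupling common to all groups. Clinician scales (HAMD-17, HAMA,
YMRS), age and sex are drawn per group from truncated normals/Bernoullis
whose parameters approximate the published cohort description, and the
published contingency tables themselves are shipped verbatim as a plain-text
fixture (`load_table1_fixtures()`).

Default study conditions, chosen once: 200 frames at TR 2 s (a 400 s
acquisition), baseline coupling 0.2, planted coupling 0.6 for the
bipolar-like groups versus 0.2 for unipolar (a coupling gap of 0.4 — the
source reports only F statistics, not effect sizes, so the gap is a
calibration choice of this package), unit noise, 30 subjects per group for
calibration cohorts. The generator deliberately omits hemodynamic
autocorrelation, spatial smoothness, scanner drift and motion: passing tests
demonstrate that the *pipeline machinery* is correct under the assumed
generative model, not that the published patient-level performance numbers
are reproducible — those require the unavailable cohort.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `trim` | 10 frames | equilibration frames dropped before anything else |
| `bandpass` | 0.01–0.08 Hz | ideal (brick-wall) DFT filter; DC always removed |
| `alpha` | 0.05 | sequential U-test admission threshold |
| `n_trees` | 100 | ensemble size; Gini impurity, bootstrap, \(\sqrt{p}\) features per split |
| `penalty_grid` | \(10^{-3} \ldots 10^{3}\) | grid-search candidates for \(C\); ties go to the smallest |
| `n_folds` | 8 | stratified CV folds (98 subjects split as six folds of 12 and two of 13) |
| `positive_class` | BD / tBD | sensitivity is the true-positive rate on the bipolar-like class |

Processing order is fixed: trim → linear detrend → nuisance regression
(intercept + tissue/global/motion regressors, sequential OLS) → bandpass →
seed extraction → correlation → Fisher z. The frequency-domain ideal filter
is the convention of the resting-state toolboxes this analysis models;
nuisance regression is sequential rather than joint because the source
pipeline lists the steps in sequence without further detail.

## Numerical choices and degenerate inputs

* \(|r|\) is clamped at \(1-10^{-7}\) before `atanh`, bounding \(z\) at
  about 8.1; zero-variance voxels get \(r = 0\) with a warning.
* Feature vectorization uses ascending column-major linear order (first
  axis fastest); the registry mapping positions to coordinates and region
  labels round-trips bit-exactly. Seed-region voxels are excluded from the
  feature space — the map is the seed's correlation with the *remaining*
  voxels.
* Region ranks break importance ties by ascending region id; the admission
  rule stops at the first region with \(p \ge \alpha\) (the boundary region
  is excluded), so the selected set is always a prefix of the ranking. If
  the top-ranked region already fails, the selection is empty: at the top
  level this is an error, while inside a CV fold or permutation iteration
  the fold falls back to predicting the training majority class with score
  0, which keeps resampling well defined.
* The Mann–Whitney test uses the exact distribution when the combined
  sample is at most 12 without ties, otherwise a normal approximation with
  tie and continuity corrections.
* The exact r×c test enumerates the conditional distribution up to 200
  observations and falls back to Monte Carlo beyond that.
* The decision function is oriented so positive scores always mean the
  positive (bipolar-like) class, independent of the order in which classes
  appear in the data.
* Manifests contain versions, seeds and content hashes but no timestamps,
  so a rerun of the same configuration is bit-identical.

## Design choices where the design was open

* **Leakage policy.** The source trains selection "on the training set"
  without stating per-fold behavior. The default here re-runs the full
  selection inside every CV training split and every permutation
  iteration (the leakage-free reading); `refit_selection_per_fold = FALSE`
  reproduces the optimistic variant. The penalty \(C\) is chosen once by
  grid search on the full training sample (selection precedes evaluation in
  the source's step order) and reused across folds.
* **Permutation null.** "Randomly selected data … 1000 times" is read as
  label permutation, the standard classifier null; a subject-resampling
  variant is available behind `permutation_scheme = "resample"`.
* **U test as "correlation".** The source describes testing "the
  correlation between the mean FC and the group label … using the U test";
  this is implemented as the two-sample Mann–Whitney test on mean regional
  FC, which is the operational content of that sentence.
* **Homogeneity gate.** The Bonferroni/Tamhane switch is gated on Levene's
  test (mean-centered) at 0.05; the source names the switch but not the
  gate. Tamhane is implemented as T2 (Welch t with Šidák-style correction).
* **Normality routing** for demographics (ANOVA versus Kruskal–Wallis) is
  caller-specified per variable, mirroring the published table's footnotes,
  rather than auto-detected.

## Problem sizes used by the tests

The packaged checks run on deliberately small instances chosen as a
package design decision: unit tests use a 6×6×4 grid with 6 regions and
10–20 subjects per group; calibration checks use a 12×12×8 grid (1152
voxels, 12 regions, 4 planted) with 30 subjects per group and 20 seeded
replicates; permutation-uniformity checks use an 8×8×4 grid with 12
subjects per group, 99 permutations and 20 replicates. The acceptance
script reports the same quantities at 10 replicates.

## Known limitations

* **Discrete permutation p under the null.** On a class-balanced cohort
  with no signal, the mean-CV-accuracy statistic of a max-margin classifier
  has a large point mass at exactly 0.5: the hinge-loss optimum collapses
  to its bias term and predicts a single class, and stratified folds are
  class-balanced. The permutation p value remains valid (ties are counted
  in the exceedance), but it is markedly non-uniform — bimodal in practice —
  so calibration diagnostics that assume a continuous statistic (e.g. a KS
  test against the uniform) will reject. This is a property of the method,
  not an implementation defect; the corresponding check is kept in the
  suite as a faithful record of that behavior.
* **Selection bias in the ranking.** Region ranking (by importance) and
  region testing (by U test) use the same training data, so under the null
  the top-ranked region's p value is not uniform. The sequential rule is
  implemented exactly as specified; its selective-inference character is
  inherited from the source design.
* The generator's independence assumptions (white noise in time and space)
  make the planted effects easier to detect than real FC effects of equal
  nominal size; published patient-level accuracies are out of reach by
  construction and are not targets of the test suite.

## Reproducing the headline quantities

`scripts/acceptance.R --seed 1 --out results/acceptance.json` recomputes,
from scratch: the published demographic statistics from the packaged
tables (sex chi-square 0.019, medication chi-square 16.452, HAMD-17
summary-ANOVA F ≈ 21.65), planted-region recovery and cross-validated
accuracy on the calibration cohort, frozen-classifier holdout performance
on a converted-bipolar test sample sized like the published one (19 + 23),
the permutation p of the cross-validated accuracy, and the null-cohort
accuracy. All numbers in this vignette and the README are produced by that
script or the test suite; none are transcribed from elsewhere.
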