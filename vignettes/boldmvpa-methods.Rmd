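---
title: "Decoding stimulus category and goal relevance from BOLD patterns: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding stimulus category and goal relevance from BOLD patterns: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boldmvpa)
```

## The scientific problem

In a face/scene one-back matching experiment, two binary neural codes can be
read out from trial-wise multivoxel BOLD patterns: the *stimulus category*
code (was a face or a scene on screen?) and the *goal relevance* code (was
the stimulus relevant to the current task set — a face during "Remember
Faces" or a scene during "Remember Scenes"?). When a cortical region is
transiently disrupted (for example with continuous theta-burst magnetic
stimulation before scanning), the fidelity of these codes — indexed by
cross-validated decoding accuracy — may drop in the disrupted region and in
regions that depend on it. `boldmvpa` implements the full analysis chain for
this question: a synthetic cohort generator that plants the two codes into
simulated BOLD runs, nuisance-GLM preprocessing, ROI and searchlight
decoding, and three tiers of nonparametric inference. Because no real data
ship with the package, the generator is a first-class, tested component: it
defines the conditions under which every statistical guarantee of the
pipeline is verified.

## The forward model (synthetic cohorts)

Each run follows the modeled experiment: 20 trials (10 face, 10 scene) of 600 ms
stimuli, onset-to-onset gaps drawn from {3, 5, 7} s, four one-back matches
per run within the relevant category, relevant stimuli separated by 0–3
irrelevant ones, TR = 1 s, onsets on the TR grid. Each subject contributes
one control and one disrupted session of five "Remember Faces" plus five
"Remember Scenes" runs.

The BOLD signal of voxel $v$ at time $t$ is

$$
y_v(t) = \sum_{i} h(t) * \text{box}_i(t)\,
\big[ a^{cat}_v\, s^{cat}_i + a^{rel}_v\, d\, s^{rel}_i \big]
\; + \; \text{drift}_v(t) + \mathbf{m}(t)^\top \mathbf{b}_v + \varepsilon_v(t),
$$

where $h$ is the canonical double-gamma HRF (response delay 6 s, undershoot
delay 16 s, unit dispersions, undershoot ratio 1/6, peak-normalized),
$s^{cat}_i = \pm 1$ for face/scene and $s^{rel}_i = \pm 1$ for
relevant/irrelevant trials, $a^{cat}_v, a^{rel}_v$ are the planted per-voxel
signed amplitudes (an amplitude times a random ±1 sign per voxel, fixed per
cohort), and $d \in [0,1]$ is the disruption factor applied to the relevance
code in designated regions during the disrupted session only ($d = 1$
elsewhere and in control sessions). Nuisance terms are low-order polynomial
drift, six random-walk motion traces coupled per voxel, and i.i.d. Gaussian
noise. Disruption is modeled purely as code attenuation — the operational
readout of stimulation in this analysis — not as a biophysical model;
a config switch (`disrupt_codes`) can extend the attenuation to the category
code.

Behavioral accuracy per subject and session is `baseline + gain ×
(subject amplitude scale) × d + noise`, clipped to [0, 1]. Subjects carry a
log-normal amplitude scale (σ = 0.25), so behavior correlates positively
with the subject's undisrupted relevance-code strength — the brain–behavior
relationship the correlation analyses probe. The defaults (baseline 0.873,
gain 0.056, d = 0.5) put mean accuracy near 93% in the control and 90% in
the disrupted session. Correctness labels are generated per trial but never
used to filter: both correct and incorrect trials enter every analysis.

What the generator deliberately omits: scanner artifacts, slice timing,
registration error, spatial noise correlations, and any anatomical
structure. Passing tests therefore demonstrate the statistical correctness
of the pipeline under its own assumptions, not robustness to real-data
pathologies.

## Preprocessing

Per run and voxel, an ordinary least-squares GLM with one HRF-convolved
boxcar regressor per stimulus-category × task-condition combination present
in the run, six motion regressors, and six orthogonal polynomial baseline
columns (orders 0–5). Two numerical choices matter:

* A quintic baseline is represented by all orders 0–5 (6 columns), because a
  lone fifth-order term cannot absorb an intercept or slow drift.
* Stimulus regressors are orthogonalized against the nuisance block, so
  shared variance (their mean and slow-drift components) is attributed to
  the baseline. The baseline-subtracted series is then exactly orthogonal to
  every nuisance regressor while a pure stimulus-shaped series passes
  through unchanged — both contracts are enforced in the test suite.

The fitted motion + polynomial component is subtracted (stimulus-explained
signal retained), each run is z-scored temporally per voxel (SD floor
1e-12; constant voxels are zeroed and flagged), and single-volume trial
patterns are extracted at code-specific lags: the volume whose acquisition
start time falls in [onset + 5, onset + 6) s for the category code and
[onset + 6, onset + 7) s for the relevance code. With TR = 1 s and integer
onsets this volume is unique; any window covering zero or several volumes is
an error, never a silent choice. The GLM is fitted per run independently,
matching the per-run z-scoring and the across-run CV structure.

## Decoding

*ROI decoding* uses binary logistic regression with an L2 penalty λ on the
weights (intercept unpenalized), fitted by Newton iterations with step
halving to a gradient-norm tolerance of 1e-8. λ defaults to 1 and is fixed —
no nested tuning — so permutation nulls remain exchangeable and cheap.
Cross-validation is leave-one-run-pair-out: each fold holds out one
"Remember Faces" and one "Remember Scenes" run (5 folds at the default run
count), pairing fixed by sorted run order; the reported accuracy is the
unweighted mean over folds.

*Searchlight decoding* moves a cubic neighborhood (edge 3 = 27 voxels for
ROI definition, edge 5 = 125 voxels for condition differences) across every
in-mask center under the same CV scheme, with a Gaussian Naive Bayes
classifier: per-voxel class means, pooled within-class variance (floor
1e-6), priors from training frequencies, exact ties resolved to the
lexicographically smaller label. Cubes are clipped at volume borders;
centers whose clipped cube holds fewer than half the nominal cube volume are
invalid (`NaN`), preventing one-voxel "searchlights" at edges. Because the
two-class pooled-variance GNB decision rule is linear in the voxel values,
the per-center score is a box sum that the compiled kernel evaluates with 3D
prefix sums — algebraically identical to fitting GNB independently per
center, which the test suite verifies against a brute-force per-center
oracle at 1e-10.

## Inference

**Above-chance decoding (per ROI × session).** `n_perm` label permutations
are pre-generated by shuffling labels *within run* — runs are the
exchangeability blocks given per-run z-scoring — with the identity
permutation excluded, and the same sets are reused across ROIs and sessions.
Each permutation is decoded exactly like the true labels; subject accuracies
are averaged into a group-mean null. The empirical p is the fraction of null
values strictly exceeding the observed group mean (the `(k+1)/(n+1)` variant
is available as a config switch), Bonferroni-corrected by the number of
ROI × session tests in the invocation.

**Condition differences (matched permutations).** The null difference for
permutation k subtracts, within subject, the disrupted-session accuracy
under permutation k from the control-session accuracy under the *same* k,
then averages across subjects; p is again the fraction of null differences
exceeding the observed one. All tests are one-sided (above chance; control >
disrupted), matching the directional hypotheses.

**Whole-volume cluster inference.** Per subject, control-minus-disrupted
searchlight difference maps are computed for the true labels and for
`n_null` permutations, and all are smoothed identically (masked Gaussian,
FWHM 8 mm, invalid centers excluded by normalized convolution — unequal
smoothness between true and null maps would bias the null). `n_boot`
bootstrap group maps are formed by drawing one null map per subject with
replacement and averaging. A voxel passes if its true group value exceeds
its own per-voxel 99.5% bootstrap quantile (the per-voxel reading of the
threshold rule); face-connected clusters (6-connectivity) of passing voxels
are then compared against the maximum cluster size of each null group map
thresholded by the *same* per-voxel quantiles, and survive if larger than
the 99.5% quantile of those maxima. Study-scale defaults are n_perm = 1000,
n_null = 100, n_boot = 100 000; all counts are config-scalable, and the
bootstrap is chunked so memory stays bounded at large n_boot.

**Functional ROI definition.** Across-subject mean searchlight accuracy is
tested against 50% chance per voxel with a one-sample, one-sided t-test and
Benjamini–Hochberg FDR control at q = 1e-4; zero-variance voxels are
excluded with a warning. At q = 1 the BH rule admits every testable voxel
(every p ≤ 1) — the mathematically correct limit.

**Brain–behavior statistics.** Spearman rank correlation with average ranks
for ties; for n ≤ 9 the two-sided p comes from the exact permutation
distribution (all n! rank assignments), otherwise from the t approximation.
The median-split comparison orders subjects by behavioral accuracy decrement
(control minus disrupted), assigns the larger half to the "most impaired"
group (median subject excluded at odd n, ties at the median going to the
impaired side), and applies Welch's unequal-variance t-test with fractional
degrees of freedom.

## Design choices where the design was open

* **Permutation scheme.** Within-run shuffling preserves the run structure
  the CV follows and the per-run label balance; it is the exchangeability
  assumption consistent with per-run z-scoring.
* **Empirical p rule.** The strict fraction-greater rule is the default and
  can return 0; the add-one variant is provided but not default.
* **Face/scene ratio.** 10/10 per run, fixed, because balanced training and
  test sets are what make 50% the chance level without bias corrections.
* **GNB variance pooling.** Variances are pooled across classes with a
  per-voxel floor; with at most ~100 training trials per class, per-class
  variance estimates are unstable and pooling keeps the decision rule
  well-conditioned.
* **λ in the infinite-penalty limit.** The optimum weight vector is
  O(1/λ) but signed, so predictions never collapse to an exact tie for
  finite λ; the chance-level property of an uninformative classifier is
  therefore validated on structureless data rather than via λ → ∞.
* **Cluster-null thresholding.** Null group maps are thresholded by the same
  per-voxel quantiles as the true map (the symmetric choice); an
  alternative, per-null-map thresholds, is not implemented.
* **Bonferroni family.** The family size is the number of ROI × session
  tests actually run in an invocation and is recorded in every report.

## Validation protocol and problem sizes

The test suite validates the pipeline at desk scale, with every size chosen
as the package's validation protocol:

* **Oracle equivalence** — GNB predictions, searchlight per-center
  accuracies, empirical p, Spearman rho with exhaustive n = 5 enumeration,
  Welch t/df, and cluster sizes match independent brute-force
  implementations at 1e-10 or exactly.
* **Type-I error** — 200 null cohorts (8 subjects, no planted codes,
  n_perm = 99): both the above-chance and the condition-difference test
  reject at α = 0.05 within the exact binomial 95% interval.
* **Family-wise error** — 50 null cohorts on a 12×12×8 grid with n_null =
  20 and n_boot = 2000: at most one cohort may show any surviving cluster
  (the smallest nonzero proportion at 50 cohorts containing twice the
  nominal 0.005 level).
* **Recovery** — a planted category code calibrated to ≈70% single-subject
  decoding yields an FDR-defined ROI ≥90% inside the dilated planted region
  (24 subjects); relevance-code attenuation 0.5 is detected by the matched
  difference test in ≥80% of 25 cohorts and localized by the cluster
  analysis with Dice > 0.5 in ≥80% of 25 cohorts.
* **Monotonicity** — decoding accuracy is nondecreasing over planted
  amplitudes {0, a, 2a} and difference-test power over attenuations
  {1.0, 0.7, 0.4} (20 seeds per point).

The calibrated operating points were fixed once by simulation and frozen:
per-voxel amplitude 0.028 at the BOLD level (≈70% searchlight decoding at
unit noise), 0.12 on a 27-voxel pattern-level ROI (0.15 on 12 voxels), and
0.06 for the 6×6×5-voxel region used in the difference-map analysis — the
last chosen so that interior voxels pass the voxelwise threshold decisively
while the searchlight-plus-smoothing halo does not, which is what makes
cluster-level localization meaningful. The planted region exceeds the
125-voxel searchlight support so interior centers see pure signal.

## A worked example

```{r example, eval = FALSE}
sim <- sim_config(n_subjects = 8, grid_dims = c(12, 12, 8),
                  regions = list(visual = cuboid_region(3:5, 3:5, 3:5),
                                 frontal = cuboid_region(8:10, 8:10, 4:6)),
                  category_code = list(visual = 0.028),
                  relevance_code = list(frontal = 0.028),
                  disruption_factors = list(frontal = 0.5), seed = 1)
config <- pipeline_config(sim, n_perm = 199, n_null = 20, n_boot = 2000,
                          seed = 1)
report <- run_experiment(config, out_dir = "report")
tidy(report)
autoplot(report$diff_results$relevance.frontal$test)
```

## Known limitations

* The generator's noise is white in space and time; real BOLD noise is
  autocorrelated, so the permutation exchangeability argument is cleaner
  here than it would be on real runs.
* No spatial registration or anatomical atlas back-projection is provided;
  masks are taken as given on a shared grid.
* Decoding is restricted to the single lag-window volume per code; no
  temporal decoding, alternative classifiers, or feature selection.
* The cluster-inference memory footprint grows with `n_boot × grid size`;
  the implementation chunks the bootstrap, but very large grids with
  n_boot = 100 000 are still compute-heavy by design.
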