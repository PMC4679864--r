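# boldmvpa

Multivoxel pattern analysis (MVPA) of event-related fMRI with nonparametric
group inference, for experiments that decode two binary neural codes from
trial-wise BOLD activity patterns:

* the **stimulus category** code — was a face or a scene presented on each
  trial of a face/scene one-back matching task; and
* the **goal relevance** code — was the stimulus relevant to the current
  task set (a face during "Remember Faces", a scene during "Remember
  Scenes"),

and ask whether transient disruption of a cortical region (e.g. continuous
theta-burst stimulation before scanning) reduces the fidelity of these
codes, indexed by cross-validated decoding accuracy.

The package is aimed at methodologists who want the full analysis chain as
tested, reusable functions, exercised end-to-end on synthetic cohorts with
known ground truth.

## What it implements

* **Synthetic BOLD cohorts** (`sim_config()`, `simulate_cohort()`): jittered
  event-related runs (20 trials, 10 face / 10 scene, onset gaps from
  {3, 5, 7} s, four one-back matches per run, TR 1 s), with multivoxel
  category and relevance codes planted in designated voxel regions and the
  relevance code attenuated by a disruption factor in one of two sessions;
  NIfTI + TSV dataset layout with a JSON manifest of all seeds.
* **Preprocessing** (`build_design_matrix()`, `residualize_baseline()`,
  `zscore_run()`, `extract_trial_patterns()`): per-run OLS GLM with
  HRF-convolved stimulus regressors, six motion regressors, and an
  orthogonal polynomial baseline (orders 0–5); baseline subtraction;
  run-wise temporal z-scoring; single-volume trial patterns at
  code-specific lags (5–6 s for category, 6–7 s for relevance).
* **Decoding** (`l2_logreg_cv_accuracy()`, `searchlight_accuracy_map()`):
  L2-regularized logistic ROI decoding and a Gaussian Naive Bayes cubic
  searchlight (27- or 125-voxel cubes), both under leave-one-run-pair-out
  cross-validation. Accuracy is the unweighted mean over folds:
  `acc = mean_f [ #correct_f / #test_f ]`, chance = 50% by balanced design.
* **Inference** (`generate_label_permutations()`, `roi_group_null()`,
  `above_chance_test()`, `tms_difference_test()`,
  `searchlight_group_difference()`, `define_functional_rois()`,
  `spearman_corr()`, `median_split_welch()`): within-run permutation nulls
  averaged to group level with empirical p = #(null > observed)/n and
  Bonferroni correction; matched-permutation condition-difference tests;
  bootstrap group searchlight inference with per-voxel 99.5% thresholds and
  empirical max-cluster-size correction over face-connected clusters;
  one-sample-t + FDR (q = 1e-4) functional ROI definition; exact-permutation
  Spearman correlation and median-split Welch t-tests for brain–behavior
  relationships.
* **Orchestration** (`pipeline_config()`, `run_experiment()`, plus a thin
  CLI at `inst/cli/boldmvpa.R`): one config, per-stage seeds, a JSON stats
  report, cluster tables, and tidy/ggplot accessors (`tidy()`, `glance()`,
  `autoplot()`).

Hot loops (batched penalized logistic fits, the searchlight, component
labelling) are compiled C++ (Rcpp/RcppArmadillo); the searchlight evaluates
the linear GNB decision rule with 3D prefix sums and is verified against a
brute-force per-center oracle.

## A worked example

```r
library(boldmvpa)

sim <- sim_config(n_subjects = 8, grid_dims = c(12, 12, 8),
                  regions = list(visual = cuboid_region(3:5, 3:5, 3:5),
                                 frontal = cuboid_region(8:10, 8:10, 4:6)),
                  category_code = list(visual = 0.028),
                  relevance_code = list(frontal = 0.028),
                  disruption_factors = list(frontal = 0.5), seed = 1)
config <- pipeline_config(sim, n_perm = 199, n_null = 20, n_boot = 2000,
                          seed = 1)
report <- run_experiment(config)
print(report)
```

prints, for seed 1:

```
<mvpa_report>
# A tibble: 12 x 9
   kind                 observed p_value p_bonferroni n_perm n_tests code      roi     tms_condition
 1 group-mean-accuracy   0.659    0             0        199       8 category  visual  control
 2 group-mean-accuracy   0.615    0             0        199       8 category  visual  disrupted
 3 group-mean-accuracy   0.506    0.291         1        199       8 category  frontal control
 4 group-mean-accuracy   0.51     0.226         1        199       8 category  frontal disrupted
 5 group-mean-accuracy   0.504    0.322         1        199       8 relevance visual  control
 6 group-mean-accuracy   0.494    0.638         1        199       8 relevance visual  disrupted
 7 group-mean-accuracy   0.657    0             0        199       8 relevance frontal control
 8 group-mean-accuracy   0.535    0.0151        0.121    199       8 relevance frontal disrupted
 9 condition-difference  0.0438   0.0503        0.201    199       4 category  visual  <NA>
10 condition-difference -0.00375  0.523         1        199       4 category  frontal <NA>
11 condition-difference  0.0106   0.276         1        199       4 relevance visual  <NA>
12 condition-difference  0.122    0             0        199       4 relevance frontal <NA>
searchlight: 1 surviving cluster(s)
```

Reading: each code decodes above chance only in its planted region (rows
1–2 and 7–8; the cross-region tests, rows 3–6, sit at chance as they
should). Disruption attenuates only the relevance code, which drops from
65.7% to 53.5% in the frontal region; the matched-permutation test puts
that 12.2-point drop outside all 199 null differences (p = 0, Bonferroni
corrected over the 4 difference tests), while the category code's 4.4-point
fluctuation is not significant (p = 0.05, corrected 0.20). The
cluster-corrected whole-volume searchlight localizes one surviving cluster
at the planted frontal region. With the default behavior model, mean
behavioral accuracy is 92.0% (control) vs 89.8% (disrupted), and
`report$behavior_stats` holds the Spearman correlation between
disrupted-session behavior and relevance decoding (rho = 0.51, exact
p = 0.20 at n = 8) plus the median-split Welch test (t(4.09) = 0.92).

The methods vignette (`vignettes/boldmvpa-methods.Rmd`) documents the
forward model, every tunable parameter with its default and rationale, the
inference tiers, and the validation protocol.

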