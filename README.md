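# repgeom

Representational geometry analysis for condition-rich neuroimaging
experiments.

`repgeom` is for researchers who want to ask *which candidate models
explain the geometry of neural responses* in a condition-rich design --
and to validate the entire analysis chain on synthetic data with planted
ground truth before touching real measurements. It implements, end to end:

- **Design generation** -- serially counterbalanced trial sequences
  (every ordered pair of trial types exactly once among the n² cyclic
  adjacencies, with run-wise block balance), probe-adjacency repair,
  exemplar assignment, and jittered onsets selected for estimation
  efficiency *e* = 1 / tr(C (XᵀX)⁻¹ Cᵀ).
- **Model RDMs** -- behavioral multiple-arrangement designs and
  sparse-distance aggregation; gaze-trajectory preprocessing (blink
  interpolation, 84 ms rolling median, decimation to 60 samples) and gaze
  RDMs with inter-block reliability screening; semantic embedding RDMs
  (average word vectors, cosine distance); generic feature RDMs.
- **Neural RDMs** -- split-data RDMs: 1 − the symmetrized matrix of
  cross-session Pearson correlations between z-scored condition patterns,
  per searchlight neighborhood or ROI.
- **Model comparison** -- per-model Spearman fits, rank-standardized joint
  regression R², variance partitioning (unique R² = full R² − nested R²),
  and the leave-one-out intersubject-correlation noise ceiling, wrapped in
  a classed `rsa_fit` object with `print`/`summary`/`coef` methods.
- **Inference** -- sign-flip permutation tests on Fisher-z scale,
  re-centered bootstrap tests for positively biased R², condition-label
  permutation nulls, subject and subject+stimulus bootstrap intervals, and
  Benjamini-Hochberg FDR, all with add-one p-values and seeded
  reproducibility.
- **Synthetic data** -- every input above can be generated from a planted
  ground truth (mixtures of model geometries plus session noise), so the
  whole pipeline is testable offline.

## Worked example

Simulate a small cohort whose local geometry is a noisy mixture of three
candidate models (weights 0.6 / 0.25 / 0.15, session noise σ = 0.5), build
each subject's split-data RDM, and fit all models:

```r
library(repgeom)

stimuli <- make_stimulus_set(n_categories = 18, n_exemplars = 5)   # 90 conditions
models  <- simulate_model_rdms(stimuli, n_models = 3, seed = 1)
truth   <- ground_truth(models, mixture_weights = c(0.6, 0.25, 0.15),
                        noise_sd = 0.5, n_subjects = 8, n_units = 200,
                        stimuli = stimuli, seed = 7)
patterns <- simulate_subject_patterns(truth)
neural   <- lapply(patterns, function(p) splitdata_rdm(p$session1, p$session2))

fit <- rsa_fit(neural, models)
summary(fit)
#> Model fits (group):
#>      model rho_group rho_min rho_max
#>  category1    0.5924  0.5848  0.6032
#>    random1    0.2557  0.2383  0.2664
#>    random2    0.1419  0.1306  0.1509
#>
#> joint R^2: 0.4382  |  noise ceiling r: 0.7129  |  % of ceiling: 86.2
#> unique R^2 by partition:
#> category1   random1   random2
#>    0.3537    0.0668    0.0191

signflip_permutation_test(fit$spearman[, "category1"], n_perms = 10000, seed = 7)
#> sign-flip permutation: observed = 0.5924, p = 0.005299 (10000 resamples)
```

Reading the output: the planted dominant model (`category1`) attains the
largest group Spearman fit (Fisher-z averaged, ρ = 0.59) and by far the
largest unique R² (0.35) -- the variance no other model can claim. The
joint model explains R² = 0.44, which is 86% of the meaningful variance
indexed by the noise ceiling (leave-one-out intersubject correlation
r = 0.71). The sign-flip permutation p of 0.0053 reflects 8 subjects'
uniformly positive correlations (the attainable floor at n = 8 is
1/2⁸ ≈ 0.004 before Monte-Carlo ties).

`run_pipeline(analysis_config(...), patterns, models, map)` orchestrates
the same fits over every searchlight neighborhood in a `neighborhood_map`,
adds permutation/bootstrap p-values and map-wise FDR, and
`write_results()` exports TSV tables plus a JSON provenance sidecar. A thin
command-line wrapper with `simulate` / `design` / `rdm` / `fit` / `stats` /
`run` subcommands lives at `inst/scripts/repgeom-cli.R`.

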