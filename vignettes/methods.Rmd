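---
title: "Methods: representational geometry analysis with repgeom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: representational geometry analysis with repgeom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repgeom)
```

## The analysis model

`repgeom` implements representational similarity analysis (RSA) for
condition-rich event-related experiments. The unit of analysis is the
**representational dissimilarity matrix (RDM)**: for a set of $n$
experimental conditions, an $n \times n$ symmetric, zero-diagonal matrix of
pairwise dissimilarities. RDMs abstract away the measurement space, so
behavioral arrangements, gaze trajectories, semantic embeddings, arbitrary
feature spaces and neural response patterns all become comparable objects.

**Neural RDMs** are *split-data* RDMs: response patterns (one value per
measurement unit per condition, z-scored per unit across conditions) are
estimated twice, in two independent scanning sessions, and the entry
$(i, j)$ of the cross-session correlation matrix $M$ is the Pearson
correlation between condition $i$'s session-1 pattern and condition $j$'s
session-2 pattern. Because session noise is independent across sessions,
cross-session correlations isolate the stable representational geometry.
The RDM is $1 - (M + M^\top)/2$ with the diagonal forced to zero; the raw
diagonal of $M$ (split-half pattern reliability) is kept in metadata and
excluded from all model comparisons.

**Model fits.** For each subject and each candidate model RDM we compute
the Spearman correlation $\rho$ between the two lower-triangle
vectorizations (one shared routine, so ordering can never silently
diverge). To quantify *joint* model performance, all model vectors and the
neural vector are rank-transformed (average ranks) and standardized, and
the neural vector is predicted by ordinary least squares with an intercept;
performance is the in-sample $R^2$. Rank-standardizing the response as well
as the predictors keeps the single-model case consistent with the Spearman
analysis ($R^2 = \rho^2$ to numerical precision, an invariant the test
suite asserts); a switch (`rank_response = FALSE`) regresses raw
dissimilarities instead.

**Variance partitioning.** The unique contribution of a model (or set of
models) is `unique R^2 = full R^2 - nested R^2`, where the nested
regression drops the models of interest. In-sample OLS monotonicity makes
every unique $R^2$ nonnegative up to floating point; values are stored
unclamped. A duplicated (perfectly collinear) predictor contributes exactly
zero unique variance: the partition fits use pivoted least squares, while
`joint_fit()` itself treats perfect collinearity as an error, since a
user-assembled model set with aliased members is almost certainly a
mistake.

**Noise ceiling.** The leave-one-out intersubject correlation (ISC): each
subject's RDM is correlated (Spearman) with the mean RDM of the remaining
subjects; per-subject values are Fisher-z averaged and back-transformed.
A model family's `ceiling_fraction(R2, r)` expresses its group $R^2$ as a
percentage of the meaningful variance, $100 \, R^2 / r^2$.

**Group inference.** Correlations are tested with a sign-flip permutation
test on the Fisher-z scale: under the null of a symmetric zero-centered
subject distribution, each subject's sign is flipped independently per
permutation. In-sample $R^2$ values are positively biased, so they are
tested with a re-centered bootstrap: subject values are resampled with
replacement, and the bootstrap distribution of means is shifted by the
observed mean to form the null. Both use the add-one convention
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(B + 1)$ with ties counting
against rejection; $p$ is never 0 and never below $1/(B+1)$. ROI-style
analyses can instead build condition-label permutation nulls (one random
relabeling applied to rows and columns of the model RDM per iteration).
Confidence intervals bootstrap either subjects alone or subjects and
stimuli jointly; in the stimulus scheme, conditions are drawn with
replacement, and pairs formed by a condition with its own duplicate
(degenerately zero dissimilarity) are excluded from the vectorization.
Searchlight-style maps are corrected by Benjamini-Hochberg FDR across
centers within each model's map.

## Behavioral, gaze and semantic models

**Multiple arrangements.** Participants drag stimuli inside an arena;
screen distance encodes dissimilarity. A session consists of one full-set
arrangement (guaranteeing every pair is observed at least once) plus
pseudo-random subsets; `design_subsets()` draws each subset from a fresh
permutation and, over `n_candidates` candidate designs (default 1,000),
keeps the one covering the most distinct pairs. Aggregation is the plain
per-pair mean of Euclidean screen distances over all observations, equally
weighted; coordinates stay in native pixels. Whether arrangements made at
different zoom levels should be rescaled before averaging is genuinely
open; plain averaging is the default, and a per-record RMS normalization
is available behind an explicit flag (`normalize = TRUE`), documented
rather than silently applied.

**Gaze.** Raw 1000 Hz trajectories (2500 samples per 2.5 s trial) are
preprocessed in three steps: blink spans are censored and linearly
interpolated from flanking valid samples (edge spans extended from the
nearest valid sample); x and y are independently smoothed with an 84 ms
rolling median (the window shrinks at the boundaries); and the trajectory
is decimated to 60 samples by nearest-sample selection, one per video
frame at 24 Hz. Trials with no valid samples raise a typed
`trial_excluded` condition. The gaze dissimilarity between two stimuli is
the per-frame Euclidean distance summed over the presentation. Participants
whose block RDMs correlate below $r = .1$ on average are excluded before
averaging (within, then across participants).

**Semantics and features.** Word annotations carry embedding vectors; the
per-stimulus verb (or nonverb) vectors are averaged and compared by cosine
distance. Inter-annotator agreement is the per-stimulus Pearson correlation
between the two annotators' mean vectors. Generic feature spaces (e.g.
motion energy, computed upstream) enter through `feature_rdm()` under a
correlation, cosine or Euclidean metric.

## Serially counterbalanced design generation

A condition-rich rapid design needs first-order counterbalancing: a
sequence of $n^2$ trials over $n$ trial types in which every ordered pair
of types, self-pairs included, occurs exactly once among the cyclic
adjacencies. `generate_type1_sequence()` realizes this as a random
Eulerian circuit on the complete directed graph with self-loops
(Hierholzer's algorithm), which exists for every $n \ge 2$.

The experimental sessions additionally need *block balance*: the sequence
must split into $n$ consecutive blocks each containing every type once, so
that 100-trial runs contain every exemplar of every category exactly once
and probes exactly five times. Block balance forces every block junction to
be a self-pair, which makes the object equivalent to a decomposition of
the complete digraph on $n + 1$ vertices into $n$ directed Hamiltonian
cycles chained into a single circuit at a virtual junction vertex. A parity
argument shows that all translate-based (terrace/Williams-style)
constructions chain in 2-cycles and can never satisfy this, and exhaustive
search shows no block-balanced sequence exists for $n \in \{3, 4, 5\}$;
for the relevant even sizes (including $n = 20$) `blocked = TRUE` finds
one by randomized backtracking with fewest-onward-options ordering
(implemented in C++; milliseconds at $n = 20$). Sequences with a probe
immediately after a fixation or another probe are repaired by replacing
the trailing probe with fixation, a left-to-right idempotent scan.

Runs prepend the last three trials of the previous run (drawn from a
separate preparatory exemplar pool) to reinstate temporal context, and add
5 s lead-in and 15 s trailing fixation: 103 trials of 2.5 s stimulus plus
jittered ISIs averaging 2.5 s gives the 535 s run the design targets.
ISIs are `min_isi_s` (2 s floor) plus truncated-exponential draws rescaled
to a fixed total, so the run duration is exact while the decay shape is
approximately preserved; among `n_candidates` schedules the one maximizing
estimation efficiency $e = 1/\mathrm{tr}(C (X^\top X)^{-1} C^\top)$ is
kept, with $X$ built from boxcars convolved with the canonical
double-gamma HRF sampled at 1 s (the acquisition TR; the exact grid shifts
scores but not rankings at these durations).

## The synthetic cohort and what it does (not) show

Every pipeline input can be generated from a planted ground truth, making
the full analysis testable without any acquisition. Candidate model RDMs
are simulated as category-structured (smaller within- than between-category
distances) or unstructured geometries, regenerated until all pairs are
distinguishable (|Spearman| at most 0.8 by default). For a neighborhood
with nonnegative mixture weights $w_k$, the blend
$B = \sum_k w_k (1 - \hat D_k)$ (each model min-max rescaled to $[0,1]$
off-diagonal) defines the planted similarity.

One subtlety is deliberate: because response profiles are z-scored per
unit across conditions, each unit's profile mean is removed, and only the
**double-centered** component of a similarity structure is identifiable.
The planted target is therefore the double-centered blend, projected to
the nearest valid correlation matrix (negative eigenvalues clipped to
zero, unit diagonal restored). Unit profiles are independent draws from a
zero-mean multivariate normal with that covariance; independent session
noise of standard deviation $\sigma$ is added, and profiles are z-scored.
Cross-session correlations then converge, as the unit count grows, to
$S_{ij}/(1 + \sigma^2)$ -- up to a small residual that the z-scoring's
per-unit sample-SD division leaves on spectrally concentrated targets
(empirically about $\pm 0.02$ elementwise at 50,000 units for a
category-structured target at $\sigma = 0$, and smaller at $\sigma = 1$;
the acceptance suite measures exactly this). With all weights zero the
target is the identity geometry, whose z-scoring-induced off-diagonal
value $-1/(n-1)$ the generator reproduces rather than hides.

Simulated arrangements embed the planted (sub-)RDM by classical 2D metric
MDS and add isotropic Gaussian jitter in the embedded coordinates; with
zero jitter and an exactly 2D-embeddable RDM the aggregation round-trips
the planted geometry perfectly, and agreement degrades monotonically with
jitter. Simulated gaze follows an attractor-pulled random walk whose
attractors are stimulus-specific and shared across blocks, so same-stimulus
trajectories correlate across blocks more than different-stimulus ones;
blinks are the only artifact modeled. Simulated annotations draw 2-5 verb
and 3-6 nonverb vectors per stimulus from category-level Gaussians, with
annotator 2 a noisy copy of annotator 1.

What passing tests show: the estimators agree with independent brute-force
oracles; the pipeline recovers planted dominant models (largest group
Spearman fit and largest unique $R^2$) across hundreds of simulated
neighborhoods at realistic noise ($\sigma = 0.5$, 20 subjects, 500 units);
and the sign-flip test is calibrated on null cohorts. What they do not
show: robustness to the structured noise of real measurements --
hemodynamic autocorrelation, motion, inter-subject misalignment,
arrangement strategies that violate the Gaussian-jitter stand-in, or gaze
artifacts beyond blinks. The Gaussian-jitter arrangement noise model in
particular is a stand-in, not a claim about behavior.

## Numerical choices

- Spearman ties use average ranks everywhere.
- Group means of correlations are computed on the Fisher-z scale and
  back-transformed; $R^2$ values are averaged on their native scale.
- RDM vectorization is a single shared lower-triangle routine.
- PSD repair clips negative eigenvalues to zero and renormalizes the
  diagonal -- the simplest repair preserving rank structure.
- Add-one p-values with ties counted as exceedances: conservative, never
  zero, reproducible from `(seed, n_resamples)` alone.
- All generator randomness flows from one root seed through named
  substreams, so adding a stage never perturbs another stage's draws.
- Degenerate inputs fail loudly and specifically: constant units are
  dropped with a warning before z-scoring, zero-variance patterns and
  constant RDM vectors raise errors naming the condition, empty
  neighborhoods are skipped with a logged warning, and fully-blinked gaze
  trials raise a typed condition.

## Problem sizes used by the test suite

The tests exercise the study-scale objects where the contract depends on
them (20 trial types, 90 conditions, 50,000 units for the generative-law
check, 200 neighborhoods of 20 subjects x 500 units for recovery, 2,000
cohorts x 1,000 permutations for calibration) and deliberately small
instances (4-8 conditions, 2-6 subjects) where exhaustive enumeration --
all $2^5$ sign patterns, all $4!$ relabelings, all $4^4$ bootstrap
resamples -- serves as the oracle.

## Known limitations

Searchlight geometry is consumed, not computed: a `neighborhood_map` must
be supplied (or defaults to one whole-pattern ROI). GLM estimation,
preprocessing and alignment are upstream. The arrangement simulator cannot
express systematic strategy differences between participants, and the
inference module offers no parametric random-effects maps, cluster-extent
or TFCE-style spatial inference by design.
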