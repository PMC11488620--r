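---
title: "Transient network dynamics, reliable change, and brain–behaviour coupling with icapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transient network dynamics with icapr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(icapr)
```

`icapr` implements a complete innovation-driven coactivation pattern (iCAP)
analysis for paired-session resting-state fMRI, together with the
statistical machinery to relate reliable pre/post change in network
dynamics to reliable change in clinical scores. This vignette is the
package's account of the model, its assumptions, the parameters that
matter, and the choices made where the method family leaves the design
open.

## 1. The model

### Hemodynamic forward model and deconvolution

Each voxel's BOLD series is modelled as the causal convolution of a
piecewise-constant *activity-inducing signal* `s` with a canonical
double-gamma HRF plus Gaussian noise. `hrf_kernel()` samples the kernel at
the TR with the response gamma peaking at 6 s, the undershoot at 16 s, and
an undershoot ratio of 1/6, scaled so the peak equals 1 (activity amplitude
and BOLD amplitude then share a scale). The first kernel sample (t = 0) is
zero, so the convolution operator is singular on its own; the
total-variation penalty makes the solution unique in practice.

Deconvolution solves, per voxel,

    minimise  0.5 * ||y - H s||^2 + lambda * ||D s||_1

with `D` the first-difference operator. This is the analysis-form,
voxel-independent core of total-activation methods; we deliberately omit
the spatial (structured-sparsity) term and any subject-specific HRF, which
keeps the stage testable voxel by voxel and embarrassingly parallel. The
solver is FISTA with an exact 1-D total-variation proximal step (a direct
single-sweep algorithm) and a monotonicity safeguard: an accelerated step
that would raise the objective is replaced by a plain proximal-gradient
step from the previous iterate, so the objective trace is non-increasing —
a property the test suite asserts on random problems. Step size is
`1/||h||_1^2`, an upper bound on the Lipschitz constant of the smooth part.
Defaults: `max_iter = 500` (300 in the pipeline config, where problems are
small and converge in tens of iterations), `tol = 1e-5` relative objective
change.

The regularisation weight is noise-calibrated per voxel:
`lambda_v = c * sigma_v * sqrt(T)` with `sigma_v` the MAD of the
first-differenced series divided by `0.6745 * sqrt(2)` and `c = 1` by
default. This mirrors the spirit of noise-scaled regularisation without
wavelet machinery; `c` (`lambda_factor`) is the single knob that trades
detection sensitivity against spurious transients.

The *innovation* signal is the first difference of the recovered activity:
sparse spikes at activation onsets (+) and offsets (−).

### Transient selection and clustering

A volume is a *transient frame* if, for its subject, at least
`min_active_voxels` voxels (default 1% of the mask) exceed the subject's
pooled percentile threshold (default 95th) on `|innovation|`. Whether
thresholds should pool within subject or across the whole sample is not
settled in the method family; per-subject pooling is the default, global
pooling is available (`pooling = "global"`).

Frames are clustered with **sign-invariant cosine k-means**: distance
`1 − |cos(frame, centroid)|`, so onset and offset transients of the same
network (which differ only in sign) share a cluster; the flip applied to
each frame is recorded in the label's sign. Initialisation is k-means++ on
the same distance; exact ties in assignment go to the lowest cluster
index; an emptied cluster is re-seeded with the worst-fitted frame. The
default is the best of 20 random restarts; the pipeline configuration uses
50 because, on concatenated multi-subject frame sets where several networks
occasionally transition in the same volume, 20 restarts can stop in a
visibly poorer optimum (the package's tests compare objectives). The
clustering objective on tiny instances is verified against exhaustive
enumeration of all partitions and sign assignments.

The number of clusters K is chosen by **consensus clustering**: for each
candidate K the frames are repeatedly subsampled (default 30 resamples of
80%) and clustered; the consensus matrix entry (i, j) is the fraction of
co-samplings in which i and j co-clustered; the selected K maximises the
mean over full-data clusters of the within-cluster mean consensus. Pairs
never co-sampled are flagged missing and excluded.

Cluster maps are means of sign-aligned member frames, z-scored over the
mask. When an atlas labelling is available, a region is reported for an
iCAP if more than 20% of its voxels have `|z| > 2`.

### Time courses and temporal properties

Per session, iCAP time courses are recovered by back-projecting the maps
into the session's activity-inducing signals: at each time point, ordinary
least squares of the activity map on the K mean-centred z-maps. The full
transient-informed regression of the original framework imposes
innovation-consistency constraints; the per-timepoint OLS used here is a
deliberate simplification (recorded as such), exact when the maps equal the
generating maps up to affine scaling — a property the tests exploit.

Time courses are z-normalised per iCAP over non-scrubbed volumes and
thresholded at `|z| > z_thresh` (default 1) into signed activation trains.
From the trains:

- **total duration**: percent of non-scrubbed volumes active;
- **occurrences**: maximal runs of same-signed nonzero values (a sign flip
  without a zero gap starts a new block);
- **coupling / anticoupling** per pair: Jaccard fractions — time jointly
  active with equal / opposite sign over time at least one is active;
- **static correlations**: plain Pearson correlations of raw courses, as a
  supplementary static view.

A caveat of z-score thresholding worth knowing: for a course active a
fraction `d` of the time, the active state's z-value is
`sqrt((1 − d)/d)`, which crosses 1 at `d = 0.5` — durations near or above
50% are not measurable at `z_thresh = 1`. Realistic transient-network duty
cycles (10–20%) are far from this regime, and the synthetic generator's
defaults live there too.

### Motion

Framewise displacement is the sum of absolute translation increments plus
`head_radius` (default 50 mm) times the absolute rotation increments, with
FD of the first volume defined as 0. Scrubbing drops the initial
`drop_initial = 5` volumes outright and *masks* (rather than deletes)
volumes with FD above `fd_thresh = 0.5` mm, so trains keep their time axis;
the zero gaps that masking introduces do split activation blocks, which
slightly inflates occurrences in high-motion sessions — documented,
deliberate. The FD threshold and radius are conventions, configurable.

### Reliable change and PLSC

For every clinical score and every temporal property, change is expressed
as `RCI = (after − before)/SEM_d`. The SEM of the difference uses the
Jacobson–Truax family form `sd_baseline * sqrt(2) * sqrt(1 − r)`. The
reliability `r` can be supplied (normative test–retest values); when it is
not, it is estimated as the pre/post Pearson correlation, clamped to
[0, 0.95], and reported loudly. Columns with zero baseline variance carry
no measurable reliable change and are dropped with a warning (this can
happen for coupling pairs that are never jointly active).

PLSC z-scores both blocks, decomposes `R = X^T Y/(n − 1)` by SVD, and
assesses each latent component by permuting the rows of X (p-value
`(1 + exceedances)/(n_perm + 1)`, compared rank by rank without Procrustes
alignment — the simplest defensible scheme) and by bootstrap resampling of
subjects (loadings = correlations of variables with latent scores,
sign-aligned to the original solution; *robust* means `|mean|/SD ≥ 2`, a
configurable convention). Permutation invariance to relabelling subjects
holds in distribution; the tests check it with a Monte Carlo error bound.

## 2. The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure of a paired-session
intervention study: contiguous network blobs on a 3-D lattice
(`make_network_atlas()`), block activity trains per network, HRF
convolution plus white noise, a motion record with occasional spikes, and a
clinical table with five scores plus gestational age and age at assessment.

Defaults (the package's study conditions, chosen once):

| parameter | default | why |
|---|---|---|
| volumes / TR | 105 volumes, 2 s | ~3.5 min of scan after dropping 5 dummies |
| baseline activity | 2 blocks per 100 volumes, 5–10 volumes each | ~15% duty cycle, in the range reported for transient network engagement |
| BOLD noise SD | 0.1 (network amplitude 1) | validation-phantom regime; enough to require genuine deconvolution |
| planted effect | networks 1–4 gain δ ~ N(10, 3) duration points in session 2 | a large, clinically-plausible engagement change |
| clinical coupling | scores 1–3 change by `1 × mean(δ)` + N(0, 1) noise | plants a strong, recoverable brain–behaviour correlation |
| motion spikes | 2% of volumes, 1 mm | exercises FD scrubbing |

Two design points deserve emphasis. First, the session mask is the whole
lattice, not the union of the blobs: if the networks partition the mask
exactly, the mean-centred maps are linearly dependent and the
back-projection regression is singular — background (noise-only) voxels
restore identifiability, just as non-network brain tissue does in real
data. Second, the planted session-2 duration increase is achieved by
*lengthening existing blocks* (adding blocks only when no room remains), so
the effect is confined to duration: occurrences, coupling and anticoupling
carry no planted signal, which is exactly the pattern the downstream PLSC
analyses are expected to find (duration significant, the rest null).

What the generator does **not** emulate: anatomical geometry and
registration error, spatially correlated or temporally autocorrelated
noise, HRF variability across subjects and regions, partial-volume and
vascular effects. Passing tests therefore demonstrate correctness of the
algorithms and sensible behaviour of the full chain under a known truth —
not performance on real scanner data.

## 3. Numerical choices and degenerate inputs

- TV proximal operator: exact single-sweep algorithm, validated against a
  box-constrained dual QP solved by L-BFGS-B.
- FISTA restart on objective increase gives a provably non-increasing
  trace; convergence is declared at relative change `< tol`.
- `lam = 0` (noiseless voxels) is allowed; the all-zero series returns an
  all-zero solution exactly.
- Collinear z-maps (pairwise `|cor| > 0.999`) abort the regression with the
  offending pair named.
- Zero-variance columns: errors in `plsc_fit()` (named column), NA with a
  warning in `static_correlation()`, dropped with a warning in
  `rci_matrix()`, redrawn resamples (counted) in `plsc_bootstrap()`.
- All randomness flows through explicit seeds (`withr::with_seed`);
  configurations without a seed fail validation before any stage runs.

## 4. Problem sizes

The bundled configuration (`default_config()`) runs 16 subjects × 2
sessions on an 8×8×8 lattice with 8 networks and 105 volumes — the full
pipeline completes in well under a minute on one core, which makes
ten-seed replication studies and permutation/bootstrap inference (1000
permutations, 500 bootstraps) routine. Larger cohorts (32 subjects, 12³
lattices) are supported by the same code paths; runtime grows linearly in
voxels × sessions.

## 5. Known limitations

- The spatial regularisation and subject-specific HRF estimation of the
  original total-activation formulation are out of scope.
- Per-timepoint OLS back-projection ignores innovation-consistency
  constraints.
- Occurrences are computed per iCAP (the pairwise "occurrences" reading
  that sometimes appears in descriptions of the framework is ambiguous;
  the per-iCAP convention is used, giving a width-8 feature block at
  K = 8).
- z-threshold duration measurement saturates for duty cycles near 50%.
- The SEM source for reliable change (normative vs in-sample) is a user
  decision; neither is asserted as canonical.

```{r example}
library(icapr)
cfg <- default_config(seed = 7)
res <- run_pipeline(cfg)
sapply(res$plsc, function(a) a$p[1])   # LC1 permutation p per analysis
res$recovery$per_network_cor           # planted-duration recovery
```
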