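---
title: "Benchmarking fMRIPrep denoising strategies with fcbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking fMRIPrep denoising strategies with fcbench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcbench)
```

## The problem

Resting-state fMRI connectivity is estimated from correlations between
regional BOLD time series, and those correlations are badly biased by
non-neuronal fluctuations — above all head motion, but also scanner
drift, physiological signals in white matter and CSF, and a global
component shared across the brain. fMRIPrep ships a broad table of
candidate nuisance regressors alongside each preprocessed scan and
deliberately leaves the choice of a denoising strategy to the analyst.
`fcbench` implements (i) a strategy-driven interface for retrieving
those regressors together with a volume-censoring sample mask, and
(ii) a benchmark that scores denoising strategies on a cohort of
connectomes with four established quality metrics.

## Confound retrieval

`load_confounds()` fetches categories of regressors from the
`*_desc-confounds_timeseries.tsv` file paired with a preprocessed BOLD
image: head motion (6 rigid-body parameters, optionally expanded with
first temporal derivatives and quadratic terms to 12, 12 or 24
columns), mean white-matter/CSF signals, the global signal, anatomical
CompCor components, ICA-AROMA regressors, discrete-cosine high-pass
terms, and non-steady-state indicators. Expansion columns are taken
from the precomputed fMRIPrep columns rather than recomputed, and only
the fMRIPrep >= 1.4 column dialect (`trans_x`, `rot_x`,
`*_derivative1`, `*_power2`, `cosine00`, `a_comp_cor_00`, ...) is
accepted; older dialects fail with an explicit error.
`load_confounds_strategy()` resolves a named strategy — the four
literature families (`simple`, `scrubbing`, `compcor`, `ica_aroma`) or
the ten registered benchmark strategies printed by
`list_strategies()` — into the corresponding parameter bundle.

Several behaviours were genuinely open and were fixed as follows:

* **Censoring inequality.** A volume is censored when framewise
  displacement (FD) or standardized DVARS *strictly exceeds* its
  threshold. The strict inequality is a convention; values exactly at
  threshold are retained.
* **Minimum segment length.** The scrubbing parameter (5 volumes) is
  interpreted as the minimal *retained* contiguous segment: after
  thresholding, any surviving run shorter than 5 volumes is censored
  as well, following the volume-censoring literature.
* **Missing derivatives.** fMRIPrep writes `n/a` at volume 1 of every
  derivative column (and of FD / std-DVARS). Derivative values are
  imputed to 0 there so the regressor matrix stays finite without
  dropping the volume; missing FD/std-DVARS never censor.
* **Demeaning order.** Confound columns are demeaned over the
  *retained* volumes only (censor first, then demean), so censored
  spikes cannot shift the regressor means.
* **Non-steady-state volumes** are folded into the sample mask rather
  than returned as one-hot spike regressors. Every strategy, including
  the high-pass-only baseline, therefore shares identical
  initial-volume handling, and spike columns never inflate regressor
  counts.
* **CompCor "all"** returns the smallest prefix of combined-mask
  components (in sidecar order) whose cumulative variance explained
  reaches 50%.
* **ICA-AROMA** follows the non-aggressive convention: the motion
  components are already removed from the `desc-smoothAROMAnonaggr`
  image, so the strategy contributes zero regressor columns and
  instead asserts the correct image variant. Combining fMRIPrep's
  global signal with ICA-AROMA is intentionally not offered.

## Signal extraction and cleaning

Parcel time series come from either a 3D label atlas (parcel value =
mean over member voxels) or a 4D probability-map atlas (per-volume
least-squares regression of the maps on the voxel vector; plain least
squares, no ridge penalty — rank-deficient maps are an error). The
package never resamples: image and atlas must already share grid and
affine, mirroring a workflow where atlases are resampled once,
upstream.

`clean_timeseries()` removes censored volumes *first* — from signals
and confounds alike — and then replaces each parcel series by its OLS
residual against the retained confound rows (intercept always
included). The ordering is observable: a spike confined to censored
volumes leaves the retained output bit-for-bit unchanged. Cleaned
series may be z-scored before export; Pearson correlation is
scale-invariant, so this affects only written time series, never the
connectome. High-pass filtering is regression-based only, through the
cosine columns.

Connectomes are Pearson correlation matrices; edge vectors take the
strictly-lower triangle in row-major order, and the same ordering is
used for inter-parcel Euclidean distances (computed from centers of
mass pushed through the voxel-to-world affine), so per-edge metrics
align by construction.

## Quality metrics

* **Loss of temporal degrees of freedom**: number of regressors plus
  censored volumes, with the dataset-dependent cosine count reported
  separately.
* **QC-FC**: per-edge partial correlation between subjects' mean FD
  and edge strength, with age and sex as covariates (residualize both
  on `[1, age, sex]`, correlate the residuals; two-sided p from the t
  transform with n − 4 degrees of freedom). Edges with p < 0.05 are
  counted as significant — optionally after Benjamini–Hochberg
  correction — and the median absolute partial correlation is
  reported alongside.
* **DM-FC**: absolute Pearson correlation between per-edge QC-FC and
  inter-parcel distance; missing edges are deleted pairwise.
* **Network modularity**: Louvain community detection run on the full
  modularity matrix, so the negative edges produced by global signal
  regression participate explicitly. The default signed scheme
  discounts the negative part of the modularity matrix by the total
  (positive plus negative) weight, the asymmetric convention for
  weighted brain graphs; a symmetric scheme and the resolution
  parameter (default γ = 1) are configurable. Each connectome is
  optimized from 100 seed-derived restarts and the max-Q partition
  kept, making results deterministic given the configured seed.

Mean FD enters the metrics from the shipped `framewise_displacement`
column, as in the benchmarked pipelines; the package's own
`framewise_displacement()` (translations plus rotations on a 50 mm
sphere, FD = 0 at the first volume) is used for validation and by the
simulator. Subject exclusion applies three tests: mean FD > 0.25 mm,
more than 80% of volumes censored at the 0.2 mm scrubbing rule
(short-segment removal included — the literature does not say whether
it should be, so the same mask rule as scrubbing is used throughout),
or less than one minute of scan retained.

Strategy similarity is the Pearson correlation between strategy-mean
edge vectors, ordered by average-linkage clustering on 1 − r (the
linkage method is a package choice; the leaves order of `hclust` is
deterministic with lower-index-first ties).

## The synthetic cohort

The simulator writes a complete fMRIPrep-style derivative tree —
4D NIfTI images in two variants, confounds TSV + JSON sidecar in the
supported dialect, participants table, label atlas, and a ground-truth
bundle — so every pipeline stage is testable without any download.
Its defaults define the benchmark cohort: 50 subjects, 200 volumes at
TR = 2 s with 4 cosine regressors (matching a roughly 400 s scan), 64
cubic parcels on a 12×12×12 grid of 3 mm voxels, and 4 planted network
blocks (within-block correlation 0.35, between 0.05).

Motion is built per subject from Gaussian parameter increments plus
sparse spikes (rate 0.06/volume); target mean FD is lognormal
(median 0.13 mm, σ_log = 0.35), matching the 0.1–0.2 mm range
reported for adult cohorts, and the FD column always equals the
formula applied to the written motion parameters. Contamination is
*spike-locked and additive*: six latent components, nonzero only at
spike volumes, load onto parcels through spatially smooth random
fields with covariance exp(−d/15 mm) plus a uniform floor of 0.4, and
scale with β × meanFD (β = 8). The floor reflects that motion couples
broadly across the brain; the smooth field gives every edge a
distance-decaying excess, the signature DM-FC measures. β = 8 makes a
spike artifact of order one signal-SD for a typical subject, the
regime where a baseline cohort shows a large fraction of
motion-correlated edges, as real benchmarks do. Because contamination
is additive and confined to spike volumes, regressing the generative
time courses — or censoring the spikes — removes it exactly, which is
what the recovery checks exploit. A shared global component
(amplitude 0.6), CSF/WM courses, cosine-basis drift, and ICA-AROMA
noise components (spike-coupled, removed from the
`smoothAROMAnonaggr` variant) complete the generative model; voxels
inherit their parcel's signal plus independent noise.

What the simulator does *not* emulate: hemodynamic autocorrelation,
cardiac/respiratory physiology, spatial noise structure within
parcels, susceptibility artifacts, or realistic anatomy. Passing
recovery checks therefore demonstrates that the pipeline measures what
it claims on data satisfying its assumptions — not that any strategy
is best on real data.

## Numerical choices and limitations

Scrubbing enumeration, OLS cleaning, partial correlation and label
extraction are each verified against independent brute-force oracles
(exhaustive run enumeration, explicit hat-matrix projection,
normal-equations residualization, per-voxel loops) to 1e-10 or
better. Zero-variance parcels yield NA edges with a warning and are
deleted pairwise in the metrics; zero residual variance makes a
partial correlation NA rather than an error. Cohorts below five
subjects cannot support the two-covariate partial correlation, so the
benchmark then reports NA for the motion-association metrics with a
warning. Problem sizes in the test suite are chosen small (8–64
parcels, 40–200 volumes, 3–50 subjects); the cohort-level recovery
check runs the full default cohort.
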