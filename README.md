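# fcbench

Benchmarking nuisance-regression ("denoising") strategies for
resting-state fMRI functional connectivity, built on fMRIPrep-style
derivatives.

fMRIPrep outputs minimally preprocessed BOLD images plus a wide table
of candidate confound time courses — motion parameters and their
expansions, tissue and global signals, anatomical CompCor components,
ICA-AROMA regressors, discrete-cosine drift terms — and leaves the
choice of denoising strategy to the analyst. `fcbench` is for
connectivity researchers who want to (a) retrieve exactly the
regressors a named strategy prescribes, with the matching
volume-censoring mask, and (b) score strategies on their own cohort
with standard quality metrics.

## What it computes

For each scan, a strategy *S* defines a confound matrix
**X**<sub>S</sub> and a set of retained volumes *K* (volumes with
FD<sub>t</sub> > φ mm or std-DVARS<sub>t</sub> > 3 censored, plus any
surviving run shorter than 5 volumes). Parcel signals **Y** are
cleaned by OLS residualization on the retained rows,

&nbsp;&nbsp;**Ŷ** = **Y**<sub>K</sub> − **X**<sub>S,K</sub>(**X**ᵀ**X**)⁻¹**X**ᵀ**Y**<sub>K</sub>,

and the connectome is the Pearson matrix of **Ŷ**. Across a cohort,
four metrics score each strategy:

* **DoF loss** — regressors used + volumes censored;
* **QC-FC** — per-edge partial correlation between subjects' mean
  framewise displacement (FD<sub>t</sub> = Σ|Δd| + 50·Σ|Δθ| mm) and
  edge strength, age and sex as covariates; summarized by the
  fraction of edges with p < 0.05 and the median |r|;
* **DM-FC** — |correlation| between per-edge QC-FC and inter-parcel
  Euclidean distance (distance-dependent motion artifact);
* **Louvain modularity Q** — signed-weight community detection, plus
  its partial correlation with mean FD.

Ten benchmark strategies are registered (`list_strategies()`):
`baseline`, `simple`, `simple+gsr`, `scrubbing.5`, `scrubbing.5+gsr`,
`scrubbing.2`, `scrubbing.2+gsr`, `compcor`, `compcor6`, `aroma`.
Subjects are excluded up front when mean FD > 0.25 mm, more than 80%
of volumes are censored at 0.2 mm, or less than one minute survives.

A bundled simulator (`simulate_cohort()`) writes a complete synthetic
derivative tree — NIfTI images, confounds TSV + JSON sidecar,
participants table, atlas, ground truth — with planted network
structure, subject-varying motion, and spike-locked, distance-decaying
contamination, so the entire pipeline is testable offline.

## Worked example

```r
library(fcbench)

cfg  <- simulation_config(n_subjects = 8, n_volumes = 120, seed = 42)
tree <- file.path(tempdir(), "demo")
co   <- simulate_cohort(cfg, tree)

img <- file.path(tree, "sub-01", "func",
                 "sub-01_task-rest_desc-preproc_bold.nii.gz")
loaded <- load_confounds_strategy(img, "scrubbing.2")
loaded$confounds
#> <confound_selection> 120 volumes x 36 regressors (motion:24, tissue:8, cosine:4)
loaded$sample_mask
#> <sample_mask> 104/120 volumes retained (16 censored)
```

36 regressors = 24 motion terms (full expansion) + 8 WM/CSF terms
(full) + 4 cosine drift terms; 16 volumes fall to the 0.2 mm
scrubbing rule. Running the benchmark:

```r
out <- file.path(tempdir(), "demo_out")
res <- run_benchmark(tree, file.path(tree, "participants.tsv"),
                     co$atlas_path, co$lookup_path,
                     c("baseline", "simple+gsr", "scrubbing.2"), out)
subset(res$metrics, metric %in% c("qcfc_fraction_significant",
                                  "dmfc_absolute_r", "modularity_q_mean"))
#>     strategy atlas                    metric       value
#>     baseline atlas qcfc_fraction_significant 0.176587302
#>     baseline atlas           dmfc_absolute_r 0.100586943
#>     baseline atlas         modularity_q_mean 0.122160789
#>   simple+gsr atlas qcfc_fraction_significant 0.055555556
#>   simple+gsr atlas           dmfc_absolute_r 0.001442565
#>   simple+gsr atlas         modularity_q_mean 0.467781137
#>  scrubbing.2 atlas qcfc_fraction_significant 0.090773810
#>  scrubbing.2 atlas           dmfc_absolute_r 0.025941347
#>  scrubbing.2 atlas         modularity_q_mean 0.122894011
```

Reading the numbers: on the contaminated baseline, 17.7% of edges
correlate with subject motion and the artifact is distance-dependent
(DM-FC 0.10); both denoising strategies cut the motion-correlated
fraction and the distance dependence, and global signal regression
raises modularity (0.47 vs 0.12) by re-centering the correlation
distribution around zero. `out/` holds the per-subject QC report,
metric tables, the cross-strategy similarity matrix with its
clustering order, and a JSON echo of every setting.

## Methods

The generative model, metric definitions, and every deliberately fixed
convention (censoring inequality, demeaning order, signed-modularity
scheme, ...) are documented in
`vignettes/denoising-benchmark.Rmd`.
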