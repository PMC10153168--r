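Package: fcbench
Title: Denoising Strategy Benchmark for fMRIPrep Functional Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Strategy-driven retrieval of fMRIPrep nuisance regressors
    (motion expansions, tissue signals, global signal, anatomical CompCor,
    ICA-AROMA, discrete-cosine high-pass terms), motion scrubbing with
    sample masks, parcel time-series extraction and confound regression,
    Pearson connectome generation, and a benchmark of denoising quality
    built on four metrics: loss of temporal degrees of freedom, QC-FC
    (partial correlation between motion and connectivity), distance-
    dependent motion artifact (DM-FC), and Louvain network modularity.
    Includes a synthetic fMRIPrep-derivative generator with known ground
    truth so the full pipeline is testable without real data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
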