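# Fixtures built in code: no data files.

# Small simulation config used across tests (8 parcels on a 6^3 grid).
small_cfg <- function(seed = 1L, n_volumes = 40L, n_subjects = 3L, ...) {
  simulation_config(n_subjects = n_subjects, n_volumes = n_volumes,
                    grid = c(6L, 6L, 6L), n_parcels = 8L, n_blocks = 2L,
                    seed = seed, ...)
}

# Hand-built confounds data.frame with every dialect column family.
manual_conf_df <- function(n = 20, fd = NULL, dvars = NULL, seed = 99) {
  set.seed(seed)
  base_names <- c("trans_x", "trans_y", "trans_z",
                  "rot_x", "rot_y", "rot_z",
                  "csf", "white_matter", "global_signal")
  df <- as.data.frame(stats::setNames(
    lapply(base_names, function(i) rnorm(n)), base_names))
  for (nm in base_names) {
    d <- c(NA, diff(df[[nm]]))
    df[[paste0(nm, "_derivative1")]] <- d
    df[[paste0(nm, "_power2")]] <- df[[nm]]^2
    df[[paste0(nm, "_derivative1_power2")]] <- d^2
  }
  for (j in 0:3) df[[sprintf("cosine%02d", j)]] <- cos(pi * (1:n) * (j + 1) / n)
  df$framewise_displacement <- if (is.null(fd)) c(NA, abs(rnorm(n - 1, 0.1, 0.02))) else fd
  df$std_dvars <- if (is.null(dvars)) c(NA, abs(rnorm(n - 1, 1, 0.1))) else dvars
  for (j in 0:7) df[[sprintf("a_comp_cor_%02d", j)]] <- rnorm(n)
  for (j in 0:3) df[[sprintf("aroma_motion_%02d", j)]] <- rnorm(n)
  df
}

default_sidecar <- function() {
  sidecar_meta(data.frame(
    name = sprintf("a_comp_cor_%02d", 0:7),
    mask = "combined",
    cumulative_variance_explained = c(0.20, 0.35, 0.48, 0.51, 0.60,
                                      0.66, 0.71, 0.75)))
}

# Write a confounds TSV (+ optional JSON sidecar) next to a dummy BOLD
# path; returns the image path accepted by read_confounds_pair.
write_pair <- function(df, dir = tempfile("pair"),
                       variant = "preproc", sidecar = NULL,
                       sub = "sub-01") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stem <- file.path(dir, paste0(sub, "_task-rest"))
  img <- paste0(stem, "_desc-", variant, "_bold.nii.gz")
  file.create(img)
  write_confounds_tsv(confound_table(df), paste0(
    stem, "_desc-confounds_timeseries.tsv"))
  if (!is.null(sidecar)) {
    comp <- sidecar$components
    js <- stats::setNames(lapply(seq_len(nrow(comp)), function(i) list(
      Mask = comp$mask[i],
      CumulativeVarianceExplained = comp$cumulative_variance_explained[i])),
      comp$name)
    jsonlite::write_json(js, paste0(
      stem, "_desc-confounds_timeseries.json"), auto_unbox = TRUE)
  }
  img
}

# Independent brute-force scrubbing oracle: threshold pass, then censor
# every contiguous retained run shorter than min_seg, by explicit loop.
mask_oracle <- function(exceed, min_seg) {
  keep <- !exceed
  n <- length(keep)
  i <- 1
  while (i <= n) {
    if (keep[i]) {
      j <- i
      while (j < n && keep[j + 1]) j <- j + 1
      if (j - i + 1 < min_seg) keep[i:j] <- FALSE
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  which(keep)
}

# Tiny label atlas on an identity-scaled grid.
tiny_atlas <- function(dims = c(6, 6, 6), n_parcels = 3, seed = 5,
                       voxel = 1) {
  set.seed(seed)
  lab <- array(sample(0:n_parcels, prod(dims), replace = TRUE), dim = dims)
  for (k in seq_len(n_parcels)) lab[k, 1, 1] <- k  # no empty parcels
  aff <- diag(c(voxel, voxel, voxel, 1))
  fc_atlas(lab, aff, data.frame(index = seq_len(n_parcels),
                                name = paste0("p", seq_len(n_parcels))))
}

rand_ts <- function(n = 30, p = 5, seed = 1) {
  set.seed(seed)
  parcel_timeseries(matrix(rnorm(n * p), n, p), seq_len(p))
}
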