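# Synthetic fMRIPrep-derivative generator with known ground truth.
#
# The generator emulates the statistical structure the benchmark metrics
# assume: a block-structured "true" connectome shared by all subjects, a
# shared global signal, subject-varying motion (lognormal mean FD with
# spikes), and motion-coupled, distance-decaying edge contamination that
# is spike-locked -- so censoring the spike volumes, or regressing the
# generative nuisance time courses, removes the contamination exactly.

#' Simulation configuration
#'
#' Defaults describe the benchmark cohort: 50 subjects, 200 volumes at
#' TR = 2 s, a 12x12x12 grid of 3 mm voxels carved into 64 cubic parcels,
#' four planted network blocks, and four discrete-cosine regressors.
#'
#' @param n_subjects number of subjects.
#' @param n_volumes volumes per scan.
#' @param tr_seconds repetition time (s).
#' @param grid 3D voxel grid dimensions (must be divisible by the parcel
#'   grid).
#' @param n_parcels number of parcels (a perfect cube).
#' @param voxel_size_mm isotropic voxel size.
#' @param n_blocks planted network blocks (must divide n_parcels).
#' @param within_r,between_r target correlation within / between blocks.
#' @param global_amplitude amplitude of the shared global component
#'   (signal SD units).
#' @param fd_meanlog,fd_sdlog lognormal parameters of subjects' target
#'   mean FD (mm).
#' @param spike_rate per-volume probability of a motion spike.
#' @param spike_magnitude base spike displacement (mm).
#' @param contamination_beta edge-contamination loading per mm of mean FD.
#' @param contamination_floor spatially uniform part of the contamination
#'   loadings (motion couples broadly; the distance-decay term adds the
#'   near-edge excess).
#' @param distance_decay_mm spatial decay length of contamination.
#' @param n_contam_components number of spike-locked contamination
#'   components.
#' @param tissue_amplitude,drift_amplitude,aroma_amplitude amplitudes of
#'   the CSF/WM courses, cosine-basis drift and ICA-AROMA noise.
#' @param n_aroma,n_compcor,n_cosine,n_nss counts of AROMA components,
#'   CompCor columns, cosine regressors and non-steady-state volumes.
#' @param voxel_noise_sd independent voxel noise SD.
#' @param age_range,sex_prob cohort demographics generators.
#' @param seed base seed; every random quantity derives from it.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects = 50L, n_volumes = 200L,
                              tr_seconds = 2, grid = c(12L, 12L, 12L),
                              n_parcels = 64L, voxel_size_mm = 3,
                              n_blocks = 4L, within_r = 0.35,
                              between_r = 0.05, global_amplitude = 0.6,
                              fd_meanlog = log(0.13), fd_sdlog = 0.35,
                              spike_rate = 0.06, spike_magnitude = 0.35,
                              contamination_beta = 8.0,
                              contamination_floor = 0.4,
                              distance_decay_mm = 15,
                              n_contam_components = 6L,
                              tissue_amplitude = 0.15,
                              drift_amplitude = 0.4,
                              aroma_amplitude = 0.3, n_aroma = 6L,
                              n_compcor = 10L, n_cosine = 4L, n_nss = 2L,
                              voxel_noise_sd = 0.4,
                              age_range = c(21, 50), sex_prob = 0.5,
                              seed = 1L) {
  cfg <- structure(as.list(environment()), class = "simulation_config")
  ppa <- round(n_parcels^(1 / 3))
  if (ppa^3 != n_parcels) stop("n_parcels must be a perfect cube")
  if (any(grid %% ppa != 0)) stop("grid must be divisible by parcels/axis")
  if (n_parcels %% n_blocks != 0) stop("n_blocks must divide n_parcels")
  stopifnot(spike_rate >= 0, spike_magnitude >= 0, contamination_beta >= 0,
            voxel_noise_sd >= 0, n_volumes >= 10)
  # fail early on a non-PSD target matrix
  chol(block_sigma(cfg))
  cfg
}

block_partition <- function(config) {
  rep(seq_len(config$n_blocks),
      each = config$n_parcels / config$n_blocks)
}

block_sigma <- function(config) {
  part <- block_partition(config)
  s <- outer(part, part, function(a, b)
    ifelse(a == b, config$within_r, config$between_r))
  diag(s) <- 1
  s
}

#' Synthetic label atlas for the simulated cohort
#'
#' Parcels are cubic blocks tiling the grid; the affine is isotropic
#' `voxel_size_mm` with the grid centred at the origin.
#'
#' @param config a [simulation_config()].
#' @return An [fc_atlas] (labels kind).
#' @export
synthetic_atlas <- function(config) {
  g <- config$grid
  ppa <- round(config$n_parcels^(1 / 3))
  side <- g %/% ppa
  idx <- expand.grid(i = seq_len(g[1]), j = seq_len(g[2]), k = seq_len(g[3]))
  pi_ <- (idx$i - 1L) %/% side[1]
  pj <- (idx$j - 1L) %/% side[2]
  pk <- (idx$k - 1L) %/% side[3]
  lab <- array(as.integer(pk * ppa^2 + pj * ppa + pi_ + 1L), dim = g)
  aff <- diag(c(rep(config$voxel_size_mm, 3), 1))
  aff[1:3, 4] <- -config$voxel_size_mm * (g - 1) / 2
  lookup <- data.frame(index = seq_len(config$n_parcels),
                       name = sprintf("parcel_%03d",
                                      seq_len(config$n_parcels)))
  fc_atlas(lab, aff, lookup, kind = "labels")
}

ar1 <- function(n, phi = 0.3) {
  x <- stats::filter(stats::rnorm(n), phi, method = "recursive")
  as.numeric(scale(as.numeric(x)))
}

cosine_basis <- function(n, k) {
  t <- seq_len(n) - 0.5
  sapply(seq_len(k), function(j) cos(pi * t * j / n))
}

#' Simulate subject head motion and derived quality traces
#'
#' Rigid-body parameters are built from AR-free Gaussian increments plus
#' Poisson-like motion spikes whose magnitude scales with the subject's
#' target mean FD; the framewise-displacement trace is computed by
#' [framewise_displacement()] from the emitted parameters (50 mm radius),
#' so the column and the formula always agree.
#'
#' @param config a [simulation_config()].
#' @param subject_seed integer seed for this subject.
#' @return list: `params` (volumes x 6), `fd`, `std_dvars` (both with the
#'   volume-1 value `NA` as shipped by fMRIPrep), `spikes` (logical),
#'   `mean_fd`, `target_mean_fd`.
#' @export
simulate_motion <- function(config, subject_seed) {
  with_seed(subject_seed, {
    n <- config$n_volumes
    target <- stats::rlnorm(1, config$fd_meanlog, config$fd_sdlog)
    sigma <- 0.6 * target / (6 * sqrt(2 / pi))
    incr <- cbind(matrix(stats::rnorm(3 * n, 0, sigma), n, 3),
                  matrix(stats::rnorm(3 * n, 0, sigma / 50), n, 3))
    spikes <- c(FALSE, stats::runif(n - 1) < config$spike_rate)
    for (t in which(spikes)) {
      mag <- config$spike_magnitude +
        stats::rexp(1, 1 / (0.3 * config$spike_magnitude + target))
      w <- abs(stats::rnorm(6)); w <- w / sum(w)
      sgn <- sample(c(-1, 1), 6, replace = TRUE)
      incr[t, ] <- incr[t, ] + sgn * w * mag / c(1, 1, 1, 50, 50, 50)
    }
    params <- apply(incr, 2, cumsum)
    colnames(params) <- MOTION_BASE
    fd <- framewise_displacement(params)
    dv <- 1 + stats::rnorm(n, 0, 0.15) +
      spikes * (2.5 + abs(stats::rnorm(n, 0, 0.3)))
    fd[1] <- NA_real_
    dv[1] <- NA_real_
    list(params = params, fd = fd, std_dvars = dv, spikes = spikes,
         mean_fd = mean(fd, na.rm = TRUE), target_mean_fd = target)
  })
}

# All random per-subject material: motion, nuisance courses, latent
# parcel signals, voxel images for both variants, confounds table and
# sidecar. Cohort-level spatial loadings come in via `spatial`.
simulate_subject_data <- function(config, subject_index,
                                  spatial = cohort_spatial(config)) {
  seed <- config$seed + 7919L * subject_index
  motion <- simulate_motion(config, seed)
  with_seed(seed + 1L, {
    n <- config$n_volumes
    p <- config$n_parcels
    # network signal with planted block structure
    Z <- matrix(stats::rnorm(n * p), n, p) %*% spatial$chol_sigma
    # spike-locked contamination, loading beta * meanFD * exp(-d/lambda)
    m <- config$n_contam_components
    U <- matrix(stats::rnorm(n * m), n, m) * motion$spikes
    contam <- config$contamination_beta * motion$mean_fd *
      (U %*% t(spatial$contam_loadings))
    g <- stats::rnorm(n)
    csf <- ar1(n); wm <- ar1(n)
    drift_w <- matrix(stats::rnorm(config$n_cosine * p,
                                   0, config$drift_amplitude),
                      config$n_cosine, p)
    A <- sapply(seq_len(config$n_aroma), function(j)
      ar1(n, 0.5) + 1.5 * motion$spikes * stats::rnorm(n))
    Y <- Z + contam + config$global_amplitude * g +
      config$tissue_amplitude * (outer(csf, spatial$csf_loadings) +
                                 outer(wm, spatial$wm_loadings)) +
      spatial$cosines %*% drift_w
    aroma_noise <- config$aroma_amplitude * (A %*% t(spatial$aroma_loadings))
    nss <- seq_len(config$n_nss)
    Y[nss, ] <- Y[nss, ] + 3
    Y_preproc <- Y + aroma_noise
    lab <- as.vector(spatial$atlas$data)
    noise <- matrix(stats::rnorm(length(lab) * n, 0, config$voxel_noise_sd),
                    length(lab), n)
    vox_pre <- t(Y_preproc)[lab, , drop = FALSE] + noise
    vox_sm <- t(Y)[lab, , drop = FALSE] + noise
    global_col <- colMeans(vox_pre)

    conf <- build_confounds_df(config, motion, csf, wm, global_col,
                               spatial$cosines, A, U)
    list(motion = motion, confounds = conf$df, sidecar = conf$sidecar,
         latent = Y, vox_preproc = vox_pre, vox_smooth = vox_sm,
         truth = list(
           regressors = cbind(
             stats::setNames(as.data.frame(U),
                             sprintf("contam_%02d", seq_len(m) - 1L)),
             global = g, csf = csf, white_matter = wm,
             stats::setNames(as.data.frame(A),
                             sprintf("aroma_src_%02d",
                                     seq_len(config$n_aroma) - 1L))),
           mean_fd = motion$mean_fd, spikes = motion$spikes))
  })
}

# Shared-across-subjects spatial structure, deterministic from config.
cohort_spatial <- function(config) {
  atlas <- synthetic_atlas(config)
  geom <- centers_of_mass(atlas)
  with_seed(config$seed, {
    p <- config$n_parcels
    # smooth random fields with covariance exp(-d/lambda): every edge's
    # contamination decays with inter-parcel distance in expectation
    K <- exp(-geom$distance / config$distance_decay_mm)
    L <- t(chol(K + diag(1e-8, p)))
    W <- config$contamination_floor +
      L %*% matrix(stats::rnorm(p * config$n_contam_components),
                   p, config$n_contam_components)
    list(
      atlas = atlas, geometry = geom,
      chol_sigma = chol(block_sigma(config)),
      contam_loadings = W,
      csf_loadings = stats::runif(p, 0.5, 1.5),
      wm_loadings = stats::runif(p, 0.5, 1.5),
      aroma_loadings = matrix(stats::rnorm(p * config$n_aroma),
                              p, config$n_aroma),
      cosines = cosine_basis(config$n_volumes, config$n_cosine)
    )
  })
}

expand_column_set <- function(base_df) {
  out <- base_df
  for (nm in names(base_df)) {
    x <- base_df[[nm]]
    d <- c(NA_real_, diff(x))
    out[[paste0(nm, "_derivative1")]] <- d
    out[[paste0(nm, "_power2")]] <- x^2
    out[[paste0(nm, "_derivative1_power2")]] <- d^2
  }
  out
}

build_confounds_df <- function(config, motion, csf, wm, global_col,
                               cosines, A, U) {
  n <- config$n_volumes
  base <- as.data.frame(motion$params)
  base$csf <- csf
  base$white_matter <- wm
  base$global_signal <- global_col
  df <- expand_column_set(base)
  df$framewise_displacement <- motion$fd
  df$std_dvars <- motion$std_dvars
  for (j in seq_len(config$n_cosine)) {
    df[[sprintf("cosine%02d", j - 1L)]] <- cosines[, j]
  }
  # CompCor ladder: first two components track the tissue courses
  cumvar <- c(0.22, 0.36, 0.45, 0.52, 0.58, 0.63, 0.67, 0.70, 0.73, 0.75)
  ncc <- config$n_compcor
  stopifnot(ncc <= length(cumvar))
  comp_names <- sprintf("a_comp_cor_%02d", seq_len(ncc) - 1L)
  for (j in seq_len(ncc)) {
    df[[comp_names[j]]] <- switch(as.character(j), `1` = csf, `2` = wm,
                                  ar1(n))
  }
  for (j in seq_len(config$n_aroma)) {
    df[[sprintf("aroma_motion_%02d", j - 1L)]] <- A[, j]
  }
  for (j in seq_len(config$n_nss)) {
    col <- numeric(n); col[j] <- 1
    df[[sprintf("non_steady_state_outlier%02d", j - 1L)]] <- col
  }
  sidecar <- data.frame(
    name = comp_names, mask = "combined",
    cumulative_variance_explained = cumvar[seq_len(ncc)]
  )
  list(df = df, sidecar = sidecar)
}

#' Simulate one subject's confounds table and sidecar
#'
#' @param config a [simulation_config()].
#' @param subject_index 1-based subject index (drives the subject seed).
#' @return list: `table` (a [confound_table]), `sidecar` (a
#'   [sidecar_meta]).
#' @export
simulate_confounds_table <- function(config, subject_index) {
  dat <- simulate_subject_data(config, subject_index)
  list(table = confound_table(dat$confounds,
                              tr_seconds = config$tr_seconds),
       sidecar = sidecar_meta(dat$sidecar))
}

#' Simulate one subject's 4D BOLD images
#'
#' @param config a [simulation_config()].
#' @param subject_index 1-based subject index.
#' @return list: `preproc` and `smoothAROMAnonaggr` 4D arrays (with an
#'   `affine` attribute), plus `truth` (generative regressors, mean FD,
#'   spike indicators).
#' @export
simulate_subject_bold <- function(config, subject_index) {
  spatial <- cohort_spatial(config)
  dat <- simulate_subject_data(config, subject_index, spatial)
  g4 <- c(config$grid, config$n_volumes)
  pre <- array(as.vector(dat$vox_preproc), dim = g4)
  sm <- array(as.vector(dat$vox_smooth), dim = g4)
  attr(pre, "affine") <- spatial$atlas$affine
  attr(sm, "affine") <- spatial$atlas$affine
  list(preproc = pre, smoothAROMAnonaggr = sm, truth = dat$truth)
}

write_bold_nifti <- function(arr, affine, tr, path) {
  im <- RNifti::asNifti(arr)
  im <- RNifti::`sform<-`(im, structure(affine, code = 2L))
  im <- RNifti::`qform<-`(im, structure(affine, code = 2L))
  pd <- c(rep(abs(affine[1, 1]), 3), tr)[seq_along(dim(arr))]
  im <- RNifti::`pixdim<-`(im, pd)
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' Simulate a full fMRIPrep-style derivative tree
#'
#' Writes, under `out_dir`: one directory per subject
#' (`sub-XX/func/sub-XX_task-rest_desc-preproc_bold.nii.gz`, the
#' `desc-smoothAROMAnonaggr` variant, and the confounds TSV + JSON
#' sidecar), a `participants.tsv` with age and sex, the synthetic label
#' atlas (`atlas/`), and the ground-truth bundle (`ground_truth/`:
#' generative nuisance regressors per subject, cohort summary, planted
#' partition). Everything is reproducible from `(config, config$seed)`.
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, list: `root`, `atlas_path`, `lookup_path`,
#'   `subjects`, `truth` (per-subject list), `partition`, `config`.
#' @export
simulate_cohort <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  spatial <- cohort_spatial(config)
  atlas_dir <- file.path(out_dir, "atlas")
  dir.create(atlas_dir, showWarnings = FALSE)
  atlas_path <- file.path(atlas_dir, "atlas-synthblocks_dseg.nii.gz")
  lookup_path <- file.path(atlas_dir, "atlas-synthblocks_dseg.tsv")
  write_bold_nifti(spatial$atlas$data, spatial$atlas$affine,
                   config$tr_seconds, atlas_path)
  utils::write.table(spatial$atlas$lookup, lookup_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  demo <- with_seed(config$seed + 13L, data.frame(
    participant_id = sprintf("sub-%02d", seq_len(config$n_subjects)),
    age = round(stats::runif(config$n_subjects, config$age_range[1],
                             config$age_range[2])),
    sex = ifelse(stats::runif(config$n_subjects) < config$sex_prob,
                 "F", "M")
  ))
  utils::write.table(demo, file.path(out_dir, "participants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  gt_dir <- file.path(out_dir, "ground_truth")
  dir.create(gt_dir, showWarnings = FALSE)
  truth <- vector("list", config$n_subjects)
  names(truth) <- demo$participant_id
  for (s in seq_len(config$n_subjects)) {
    sub <- demo$participant_id[s]
    func_dir <- file.path(out_dir, sub, "func")
    dir.create(func_dir, showWarnings = FALSE, recursive = TRUE)
    stem <- file.path(func_dir, paste0(sub, "_task-rest"))
    dat <- simulate_subject_data(config, s, spatial)
    g4 <- c(config$grid, config$n_volumes)
    write_bold_nifti(array(as.vector(dat$vox_preproc), g4),
                     spatial$atlas$affine, config$tr_seconds,
                     paste0(stem, "_desc-preproc_bold.nii.gz"))
    write_bold_nifti(array(as.vector(dat$vox_smooth), g4),
                     spatial$atlas$affine, config$tr_seconds,
                     paste0(stem, "_desc-smoothAROMAnonaggr_bold.nii.gz"))
    write_confounds_tsv(confound_table(dat$confounds,
                                       tr_seconds = config$tr_seconds),
                        paste0(stem, "_desc-confounds_timeseries.tsv"))
    sidecar_js <- stats::setNames(lapply(seq_len(nrow(dat$sidecar)),
      function(i) list(Mask = dat$sidecar$mask[i],
                       CumulativeVarianceExplained =
                         dat$sidecar$cumulative_variance_explained[i])),
      dat$sidecar$name)
    jsonlite::write_json(sidecar_js,
                         paste0(stem, "_desc-confounds_timeseries.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.table(
      cbind(volume = seq_len(config$n_volumes), dat$truth$regressors),
      file.path(gt_dir, paste0(sub, "_desc-truth_regressors.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    truth[[s]] <- dat$truth
  }
  summary_df <- data.frame(
    participant_id = demo$participant_id, age = demo$age, sex = demo$sex,
    true_mean_fd = vapply(truth, `[[`, numeric(1), "mean_fd")
  )
  utils::write.table(summary_df, file.path(gt_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(parcel = seq_len(config$n_parcels),
               block = block_partition(config)),
    file.path(gt_dir, "partition.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(list(root = out_dir, atlas_path = atlas_path,
                 lookup_path = lookup_path, subjects = demo,
                 truth = truth, partition = block_partition(config),
                 config = config))
}
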