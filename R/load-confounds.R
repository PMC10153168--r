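# The two user-facing confound loaders.

VALID_CATEGORIES <- c("motion", "wm_csf", "global_signal", "scrub",
                      "compcor", "ica_aroma", "high_pass",
                      "non_steady_state")

#' Load strategy-specific confounds for one or more BOLD images
#'
#' The basic loader: fetch the requested categories of nuisance regressors
#' from the confounds file paired with `image_path`, and build the sample
#' mask of retained volumes. Categories are tuned through the per-category
#' arguments. Columns are demeaned over the retained volumes when
#' `demean = TRUE` (censoring first, then demeaning).
#'
#' Non-steady-state volumes, when flagged by the confounds file and the
#' `non_steady_state` category is requested, are folded into the sample
#' mask rather than returned as spike regressors, so every strategy shares
#' the same initial-volume handling.
#'
#' @param image_path path to a preprocessed BOLD file, or a list/vector of
#'   paths (results are returned per path, in order).
#' @param strategy character vector of categories among `motion`,
#'   `wm_csf`, `global_signal`, `scrub`, `compcor`, `ica_aroma`,
#'   `high_pass`, `non_steady_state`.
#' @param motion,wm_csf,global_signal expansion options
#'   (`basic`/`derivatives`/`power2`/`full`).
#' @param scrub minimal retained contiguous segment length in volumes.
#' @param fd_threshold framewise-displacement censoring threshold (mm).
#' @param std_dvars_threshold standardized-DVARS censoring threshold.
#' @param compcor CompCor mask, only `"anat_combined"`.
#' @param n_compcor `"all"` (50% cumulative variance) or a count.
#' @param ica_aroma `"full"` (non-aggressive, pre-denoised image) or
#'   `"basic"` (aggressive `aroma_motion_*` regressors).
#' @param demean demean regressors over retained volumes.
#' @param tr_seconds optional repetition time recorded on the parsed table.
#' @return list with elements `confounds` (a `confound_selection`) and
#'   `sample_mask` (a [sample_mask]); for multiple inputs, a list of such
#'   lists.
#' @export
load_confounds <- function(image_path,
                           strategy = c("motion", "high_pass", "wm_csf"),
                           motion = "full", wm_csf = "basic",
                           global_signal = "basic",
                           scrub = 5L, fd_threshold = 0.2,
                           std_dvars_threshold = 3,
                           compcor = "anat_combined", n_compcor = "all",
                           ica_aroma = "full",
                           demean = TRUE, tr_seconds = NA_real_) {
  if (length(image_path) > 1L || is.list(image_path)) {
    return(lapply(image_path, load_confounds, strategy = strategy,
                  motion = motion, wm_csf = wm_csf,
                  global_signal = global_signal, scrub = scrub,
                  fd_threshold = fd_threshold,
                  std_dvars_threshold = std_dvars_threshold,
                  compcor = compcor, n_compcor = n_compcor,
                  ica_aroma = ica_aroma, demean = demean,
                  tr_seconds = tr_seconds))
  }
  unknown <- setdiff(strategy, VALID_CATEGORIES)
  if (length(unknown)) {
    stop("unknown strategy categories: ", paste(unknown, collapse = ", "),
         "; valid: ", paste(VALID_CATEGORIES, collapse = ", "))
  }
  pair <- read_confounds_pair(image_path, tr_seconds = tr_seconds)
  table <- pair$table
  variant <- image_variant_of(image_path)

  sels <- list()
  if ("motion" %in% strategy) sels$motion <- expand_motion(table, motion)
  if ("wm_csf" %in% strategy) {
    sels$wm_csf <- select_tissue(table, "wm_csf", wm_csf)
  }
  if ("global_signal" %in% strategy) {
    sels$global <- select_tissue(table, "global_signal", global_signal)
  }
  if ("compcor" %in% strategy) {
    sels$compcor <- select_compcor(table, pair$meta, mask = compcor,
                                   n = n_compcor)
  }
  if ("ica_aroma" %in% strategy) {
    sels$aroma <- select_aroma(table, variant, option = ica_aroma)
  }
  if ("high_pass" %in% strategy) sels$cosine <- select_high_pass(table)

  selection <- if (length(sels)) bind_selections(sels)
               else empty_selection(table$n_volumes)

  nss <- if ("non_steady_state" %in% strategy) non_steady_state_flags(table)
         else rep(FALSE, table$n_volumes)
  mask <- if ("scrub" %in% strategy) {
    build_sample_mask(table, fd_threshold = fd_threshold,
                      std_dvars_threshold = std_dvars_threshold,
                      min_segment = scrub, extra_censor = nss)
  } else if (any(nss)) {
    sample_mask(which(!nss), table$n_volumes)
  } else {
    full_mask(table$n_volumes)
  }

  if (demean && ncol(selection$matrix) && length(mask$kept)) {
    mu <- colMeans(selection$matrix[mask$kept, , drop = FALSE])
    selection$matrix <- sweep(selection$matrix, 2, mu)
  }
  list(confounds = selection, sample_mask = mask)
}

#' Load a curated denoising strategy by name
#'
#' The higher-level loader: resolve `name` in the strategy registry (the
#' ten benchmark strategies or the four predefined families) and call
#' [load_confounds()] with the corresponding parameter bundle. For the
#' predefined families, `global_signal = "basic"` appends global-signal
#' regression (the `+gsr` variants).
#'
#' @param image_path path(s) to preprocessed BOLD file(s).
#' @param name a registered strategy name (see [list_strategies()]).
#' @param global_signal optional expansion option appended to a predefined
#'   family (ignored when the registry row already fixes it).
#' @param tr_seconds optional repetition time.
#' @return As [load_confounds()].
#' @export
load_confounds_strategy <- function(image_path, name,
                                    global_signal = NULL,
                                    tr_seconds = NA_real_) {
  spec <- fc_strategy(name)
  if (!is.null(global_signal) && spec$global_signal == "none") {
    if (spec$compcor_mask != "none" || spec$ica_aroma) {
      stop("strategy '", name, "' does not support global signal regression")
    }
    spec$global_signal <- global_signal
  }
  categories <- c(
    if (spec$high_pass) "high_pass",
    if (spec$motion != "none") "motion",
    if (spec$wm_csf != "none") "wm_csf",
    if (spec$global_signal != "none") "global_signal",
    if (!is.na(spec$scrub)) "scrub",
    if (spec$compcor_mask != "none") "compcor",
    if (spec$ica_aroma) "ica_aroma",
    "non_steady_state"
  )
  load_confounds(
    image_path, strategy = categories,
    motion = if (spec$motion == "none") "basic" else spec$motion,
    wm_csf = if (spec$wm_csf == "none") "basic" else spec$wm_csf,
    global_signal = if (spec$global_signal == "none") "basic"
                    else spec$global_signal,
    scrub = if (is.na(spec$scrub)) 5L else spec$scrub,
    fd_threshold = if (is.na(spec$fd_threshold)) 0.2 else spec$fd_threshold,
    std_dvars_threshold = if (is.na(spec$std_dvars_threshold)) 3
                          else spec$std_dvars_threshold,
    compcor = if (spec$compcor_mask == "none") "anat_combined"
              else spec$compcor_mask,
    n_compcor = if (all(is.na(spec$n_compcor))) "all" else spec$n_compcor,
    ica_aroma = "full",
    demean = spec$demean, tr_seconds = tr_seconds
  )
}

#' Expected image variant for a strategy
#'
#' @param name registered strategy name.
#' @return `"preproc"` or `"smoothAROMAnonaggr"`.
#' @export
strategy_image_variant <- function(name) fc_strategy(name)$image_variant
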