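# Volume censoring (scrubbing) and the sample mask.

#' Construct a sample mask
#'
#' @param kept strictly increasing 1-based indices of retained volumes.
#' @param n_volumes total number of volumes.
#' @return An object of class `sample_mask` with elements `kept`,
#'   `n_volumes` and `censored_count`.
#' @export
sample_mask <- function(kept, n_volumes) {
  kept <- as.integer(kept)
  if (length(kept)) {
    if (is.unsorted(kept, strictly = TRUE)) {
      stop("kept indices must be strictly increasing")
    }
    if (kept[1] < 1L || kept[length(kept)] > n_volumes) {
      stop("kept indices outside 1..n_volumes")
    }
  }
  structure(list(kept = kept, n_volumes = as.integer(n_volumes),
                 censored_count = as.integer(n_volumes) - length(kept)),
            class = "sample_mask")
}

#' @export
print.sample_mask <- function(x, ...) {
  cat("<sample_mask> ", length(x$kept), "/", x$n_volumes,
      " volumes retained (", x$censored_count, " censored)\n", sep = "")
  invisible(x)
}

full_mask <- function(n_volumes) sample_mask(seq_len(n_volumes), n_volumes)

# Core censoring rule over a logical exceed vector: drop flagged volumes,
# then drop any maximal run of contiguous retained volumes shorter than
# min_segment.
censor_runs <- function(exceed, min_segment) {
  keep <- !exceed
  if (!is.na(min_segment) && min_segment > 1L && any(keep)) {
    r <- rle(keep)
    short <- r$values & r$lengths < min_segment
    r$values[short] <- FALSE
    keep <- inverse.rle(r)
  }
  keep
}

#' Build a scrubbing sample mask from motion and signal-change traces
#'
#' A volume is censored when its framewise displacement exceeds
#' `fd_threshold` (mm) or its standardized DVARS exceeds
#' `std_dvars_threshold` (strict `>`); missing values at volume 1 never
#' censor. After thresholding, any maximal run of contiguous retained
#' volumes shorter than `min_segment` is censored as well, so no
#' under-length segment survives.
#'
#' @param table a [confound_table] carrying `framewise_displacement` and
#'   `std_dvars` columns.
#' @param fd_threshold framewise-displacement threshold in mm.
#' @param std_dvars_threshold standardized-DVARS threshold (unitless).
#' @param min_segment minimal retained contiguous segment length, in
#'   volumes (`NA` disables the run filter).
#' @param extra_censor optional logical vector of additional volumes to
#'   censor (e.g. non-steady-state volumes), applied before the run filter.
#' @return A [sample_mask].
#' @export
build_sample_mask <- function(table, fd_threshold, std_dvars_threshold = 3,
                              min_segment = 5L, extra_censor = NULL) {
  stopifnot(fd_threshold > 0, std_dvars_threshold > 0)
  need <- c("framewise_displacement", "std_dvars")
  missing <- setdiff(need, names(table$data))
  if (length(missing)) {
    stop("missing confound columns for scrubbing: ",
         paste(missing, collapse = ", "))
  }
  fd <- table$data$framewise_displacement
  dv <- table$data$std_dvars
  exceed <- (!is.na(fd) & fd > fd_threshold) |
    (!is.na(dv) & dv > std_dvars_threshold)
  if (!is.null(extra_censor)) exceed <- exceed | extra_censor
  keep <- censor_runs(exceed, min_segment)
  sample_mask(which(keep), table$n_volumes)
}
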