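# Framewise displacement and subject-level motion quality control.

#' Framewise displacement from rigid-body motion parameters
#'
#' FD at volume t is the sum of absolute volume-to-volume changes in the
#' three translations (mm) plus the three rotations (radians) converted to
#' arc length on a sphere of radius `rotation_radius`:
#' \deqn{FD_t = |\Delta d_{x,t}| + |\Delta d_{y,t}| + |\Delta d_{z,t}|
#'   + r(|\Delta \alpha_t| + |\Delta \beta_t| + |\Delta \gamma_t|)}
#' FD at the first volume is 0 by convention, so the mean is taken over
#' all volumes.
#'
#' @param params numeric matrix (volumes x 6): `trans_x`, `trans_y`,
#'   `trans_z` in mm then `rot_x`, `rot_y`, `rot_z` in radians.
#' @param rotation_radius sphere radius in mm (default 50).
#' @return Numeric FD series in mm, one value per volume.
#' @export
framewise_displacement <- function(params, rotation_radius = 50) {
  params <- as.matrix(params)
  stopifnot(ncol(params) == 6, nrow(params) >= 2, rotation_radius > 0)
  if (!all(is.finite(params))) stop("non-finite motion parameters")
  d <- abs(diff(params))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    rotation_radius * rowSums(d[, 4:6, drop = FALSE])
  c(0, fd)
}

#' Subject-level motion exclusion decision
#'
#' A scan is excluded when any of three criteria fails: mean framewise
#' displacement above `mean_fd_max`; more than `max_pct` percent of
#' volumes censored under the scrubbing rule at `scrub_fd` mm (including
#' short-segment removal with `min_segment`); or fewer than `min_minutes`
#' minutes of scan retained after that scrubbing.
#'
#' @param fd framewise-displacement series (mm), one value per volume.
#' @param tr_seconds repetition time in seconds.
#' @param mean_fd_max mean-FD exclusion threshold (mm, default 0.25).
#' @param scrub_fd scrubbing threshold used for the censoring criteria
#'   (mm, default 0.2).
#' @param max_pct maximal tolerated percentage of censored volumes
#'   (default 80).
#' @param min_minutes minimal retained scan duration (default 1).
#' @param min_segment minimal retained contiguous segment length used by
#'   the scrubbing rule (default 5).
#' @return list of class `qc_decision`: `mean_fd`, `pct_censored`,
#'   `minutes_retained`, `excluded`, `reasons`.
#' @export
subject_qc <- function(fd, tr_seconds, mean_fd_max = 0.25, scrub_fd = 0.2,
                       max_pct = 80.0, min_minutes = 1.0, min_segment = 5L) {
  stopifnot(tr_seconds > 0)
  fd <- as.numeric(fd)
  mean_fd <- mean(fd, na.rm = TRUE)
  exceed <- !is.na(fd) & fd > scrub_fd
  keep <- censor_runs(exceed, min_segment)
  pct <- 100 * (1 - mean(keep))
  minutes <- sum(keep) * tr_seconds / 60
  reasons <- character()
  if (mean_fd > mean_fd_max) {
    reasons <- c(reasons, sprintf("mean FD %.3f mm > %.2f mm",
                                  mean_fd, mean_fd_max))
  }
  if (pct > max_pct) {
    reasons <- c(reasons, sprintf(
      "%.1f%% of volumes censored at %.1f mm > %.1f%%", pct, scrub_fd,
      max_pct))
  }
  if (minutes < min_minutes) {
    reasons <- c(reasons, sprintf("%.2f min retained < %.1f min",
                                  minutes, min_minutes))
  }
  structure(list(mean_fd = mean_fd, pct_censored = pct,
                 minutes_retained = minutes,
                 excluded = length(reasons) > 0, reasons = reasons),
            class = "qc_decision")
}

#' @export
print.qc_decision <- function(x, ...) {
  cat(sprintf(
    "<qc_decision> mean FD %.3f mm, %.1f%% censored, %.2f min retained: %s\n",
    x$mean_fd, x$pct_censored, x$minutes_retained,
    if (x$excluded) paste("EXCLUDED -", paste(x$reasons, collapse = "; "))
    else "included"))
  invisible(x)
}

#' Write a per-subject motion QC report
#'
#' @param decisions named list of `qc_decision` objects (names are subject
#'   labels).
#' @param path output TSV path.
#' @return The report data.frame, invisibly.
#' @export
write_qc_report <- function(decisions, path) {
  df <- do.call(rbind, lapply(names(decisions), function(s) {
    d <- decisions[[s]]
    data.frame(subject = s, mean_fd = d$mean_fd,
               pct_censored = d$pct_censored,
               minutes_retained = d$minutes_retained,
               excluded = d$excluded,
               reasons = paste(d$reasons, collapse = "; "),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
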