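# Censoring + confound regression and connectome generation.

#' Denoise parcel time series by censoring and confound regression
#'
#' Censored volumes are removed first, from both the signals and the
#' confound matrix; each parcel series is then replaced by its
#' ordinary-least-squares residual against the retained confound rows
#' (an intercept is always included, so the output is demeaned even with
#' an empty confound set). Optionally each parcel is z-scored afterwards;
#' Pearson correlation is scale-invariant, so standardization only affects
#' exported series.
#'
#' @param ts a [parcel_timeseries].
#' @param selection a `confound_selection` (or a plain numeric matrix)
#'   whose rows align with the volumes of `ts`, or NULL for
#'   censoring/demeaning only.
#' @param mask a [sample_mask], or NULL to keep all volumes.
#' @param standardize z-score each parcel after regression (default
#'   FALSE).
#' @return A [parcel_timeseries] with `length(mask$kept)` volumes.
#' @export
clean_timeseries <- function(ts, selection = NULL, mask = NULL,
                             standardize = FALSE) {
  Y <- ts$series
  X <- if (is.null(selection)) matrix(numeric(0), nrow(Y), 0)
       else if (inherits(selection, "confound_selection")) selection$matrix
       else as.matrix(selection)
  if (nrow(X) != nrow(Y)) {
    stop("confound rows (", nrow(X), ") do not align with volumes (",
         nrow(Y), ")")
  }
  kept <- if (is.null(mask)) seq_len(nrow(Y)) else mask$kept
  Y <- Y[kept, , drop = FALSE]
  X <- cbind(`(intercept)` = 1, X[kept, , drop = FALSE])
  if (ncol(X) >= nrow(Y)) {
    stop("more confounds (", ncol(X), " incl. intercept) than retained ",
         "volumes (", nrow(Y), "): no residual degrees of freedom")
  }
  res <- qr.resid(qr(X), Y)
  if (standardize) {
    sds <- apply(res, 2, stats::sd)
    sds[sds == 0] <- 1
    res <- sweep(res, 2, sds, "/")
  }
  parcel_timeseries(res, ts$parcel_ids, ts$tr_seconds)
}

#' Pearson connectome of parcel time series
#'
#' @param ts a [parcel_timeseries] with at least 3 volumes.
#' @return list of class `connectome`: `matrix` (parcels x parcels Pearson
#'   correlations, unit diagonal; edges of zero-variance parcels are
#'   `NA` with a warning) and `parcel_ids`.
#' @export
pearson_connectome <- function(ts) {
  Y <- ts$series
  if (nrow(Y) < 3) stop("need at least 3 volumes for correlation")
  sds <- apply(Y, 2, stats::sd)
  flat <- sds == 0
  r <- suppressWarnings(stats::cor(Y))
  if (any(flat)) {
    warning("zero-variance parcels, edges set to NA: ",
            paste(ts$parcel_ids[flat], collapse = ", "))
    r[flat, ] <- NA_real_
    r[, flat] <- NA_real_
  }
  diag(r) <- 1
  structure(list(matrix = r, parcel_ids = ts$parcel_ids),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat("<connectome> ", nrow(x$matrix), " parcels, ",
      sum(is.na(x$matrix[lower.tri(x$matrix)])), " missing edges\n",
      sep = "")
  invisible(x)
}

# Row-major order of the strictly-lower triangle: (2,1), (3,1), (3,2), ...
lower_triangle_index <- function(p) {
  idx <- which(lower.tri(matrix(0, p, p)), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

#' Vectorize a symmetric parcel matrix into an edge vector
#'
#' Returns the strictly-lower-triangle entries in row-major order
#' ((2,1), (3,1), (3,2), ...), length p(p-1)/2. The same ordering is used
#' for connectomes and distance matrices so edge vectors align.
#'
#' @param x a `connectome` or a symmetric matrix.
#' @return Numeric edge vector.
#' @export
vectorize_connectome <- function(x) {
  m <- if (inherits(x, "connectome")) x$matrix else as.matrix(x)
  idx <- lower_triangle_index(nrow(m))
  m[idx]
}
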