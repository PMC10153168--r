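# Parcel time-series extraction from 4D images.

#' Construct a parcel time-series object
#'
#' @param series volumes x parcels numeric matrix (columns named by parcel
#'   id).
#' @param parcel_ids parcel identifiers, one per column.
#' @param tr_seconds repetition time (optional).
#' @return An object of class `parcel_timeseries`.
#' @export
parcel_timeseries <- function(series, parcel_ids, tr_seconds = NA_real_) {
  series <- as.matrix(series)
  stopifnot(ncol(series) == length(parcel_ids))
  colnames(series) <- as.character(parcel_ids)
  structure(list(series = series, parcel_ids = parcel_ids,
                 tr_seconds = tr_seconds),
            class = "parcel_timeseries")
}

#' @export
print.parcel_timeseries <- function(x, ...) {
  cat("<parcel_timeseries> ", nrow(x$series), " volumes x ",
      ncol(x$series), " parcels\n", sep = "")
  invisible(x)
}

check_grid <- function(image4d, atlas) {
  di <- dim(image4d)
  da <- dim(atlas$data)
  if (!identical(di[1:3], da[1:3])) {
    stop("image grid ", paste(di[1:3], collapse = "x"),
         " does not match atlas grid ", paste(da[1:3], collapse = "x"),
         "; resample before extraction")
  }
  img_aff <- attr(image4d, "affine")
  if (!is.null(img_aff) &&
      max(abs(img_aff - atlas$affine)) > 1e-4) {
    stop("image and atlas affines differ; resample before extraction")
  }
}

as_volume_matrix <- function(image4d) {
  di <- dim(image4d)
  stopifnot(length(di) == 4)
  matrix(as.vector(image4d), nrow = prod(di[1:3]), ncol = di[4])
}

#' Extract mean parcel time series with a label atlas
#'
#' The parcel signal at each volume is the mean over voxels carrying that
#' label. Parcels with no voxels yield a column of zeros with a warning;
#' the parcel id is retained so cohort matrices stay aligned.
#'
#' @param image4d 4D array (x, y, z, time); an `affine` attribute, when
#'   present, is checked against the atlas.
#' @param atlas a label-kind [fc_atlas] on the same grid.
#' @param tr_seconds repetition time recorded on the output.
#' @return A [parcel_timeseries].
#' @export
extract_labels <- function(image4d, atlas, tr_seconds = NA_real_) {
  stopifnot(atlas$kind == "labels")
  check_grid(image4d, atlas)
  ids <- parcel_ids(atlas)
  lab <- as.vector(atlas$data)
  vm <- as_volume_matrix(image4d)
  n_t <- ncol(vm)
  out <- matrix(0, n_t, length(ids))
  inside <- lab != 0
  sums <- rowsum(vm[inside, , drop = FALSE], lab[inside])
  counts <- tabulate(factor(lab[inside], levels = ids),
                     nbins = length(ids))
  have <- match(as.integer(rownames(sums)), ids)
  out[, have] <- t(sums / counts[have])
  if (any(counts == 0)) {
    warning("empty parcels (zero series kept): ",
            paste(ids[counts == 0], collapse = ", "))
  }
  parcel_timeseries(out, ids, tr_seconds)
}

#' Extract parcel time series with a probability-map atlas
#'
#' Per-volume parcel signals are the least-squares solution regressing the
#' spatial maps onto the volume's voxel vector, so overlapping or
#' disjoint-region maps are handled jointly.
#'
#' @param image4d 4D array (x, y, z, time).
#' @param atlas a maps-kind [fc_atlas] on the same grid.
#' @param tr_seconds repetition time recorded on the output.
#' @return A [parcel_timeseries].
#' @export
extract_maps <- function(image4d, atlas, tr_seconds = NA_real_) {
  stopifnot(atlas$kind == "maps")
  check_grid(image4d, atlas)
  ids <- parcel_ids(atlas)
  da <- dim(atlas$data)
  M <- matrix(as.vector(atlas$data), nrow = prod(da[1:3]), ncol = da[4])
  if (!all(is.finite(M))) stop("atlas maps must be finite")
  qrM <- qr(M)
  if (qrM$rank < ncol(M)) {
    bad <- setdiff(seq_len(ncol(M)), qrM$pivot[seq_len(qrM$rank)])
    stop("rank-deficient map matrix; collinear maps: ",
         paste(ids[bad], collapse = ", "))
  }
  vm <- as_volume_matrix(image4d)
  coefs <- qr.coef(qrM, vm)
  parcel_timeseries(t(coefs), ids, tr_seconds)
}
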