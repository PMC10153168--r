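# Atlas containers and parcel geometry.

#' Construct an atlas
#'
#' @param data 3D integer label array (`kind = "labels"`, background 0,
#'   parcel ids positive) or 4D real array of one spatial map per parcel
#'   (`kind = "maps"`).
#' @param affine 4x4 voxel-to-world transform (mm); voxel indices are
#'   0-based in the NIfTI convention.
#' @param lookup data.frame with columns `index` (parcel id) and `name`.
#' @param kind `"labels"` or `"maps"`; inferred from dimensionality when
#'   missing.
#' @return An object of class `fc_atlas`.
#' @export
fc_atlas <- function(data, affine, lookup, kind = NULL) {
  nd <- length(dim(data))
  if (is.null(kind)) kind <- if (nd == 3L) "labels" else "maps"
  if (kind == "labels") {
    stopifnot(nd == 3L)
    ids <- sort(unique(as.vector(data)))
    ids <- ids[ids != 0]
    if (any(ids < 0)) stop("label atlas must code background 0, parcels > 0")
  } else {
    stopifnot(nd == 4L)
  }
  stopifnot(is.matrix(affine), all(dim(affine) == c(4, 4)))
  stopifnot(all(c("index", "name") %in% names(lookup)))
  structure(list(kind = kind, data = data, affine = affine,
                 lookup = lookup[order(lookup$index), , drop = FALSE]),
            class = "fc_atlas")
}

#' @export
print.fc_atlas <- function(x, ...) {
  cat("<fc_atlas> ", x$kind, ", grid ",
      paste(dim(x$data)[1:3], collapse = "x"), ", ",
      nrow(x$lookup), " parcels\n", sep = "")
  invisible(x)
}

#' Read an atlas from a NIfTI file plus a label lookup TSV
#'
#' @param nifti_path path to a 3D label image or 4D probability-map image.
#' @param lookup_path TSV with columns `index` and `name`.
#' @return An [fc_atlas].
#' @export
read_atlas <- function(nifti_path, lookup_path) {
  img <- RNifti::readNifti(nifti_path)
  lookup <- utils::read.delim(lookup_path, sep = "\t")
  fc_atlas(as.array(img), xform_of(img), lookup)
}

xform_of <- function(img) {
  m <- RNifti::xform(img)
  attributes(m) <- list(dim = dim(m))
  m
}

parcel_ids <- function(atlas) atlas$lookup$index

# World coordinates (mm) of 0-based voxel indices (n x 3 matrix).
voxel_to_world <- function(affine, ijk) {
  ijk <- rbind(t(ijk), 1)
  t(affine %*% ijk)[, 1:3, drop = FALSE]
}

#' Parcel centers of mass and pairwise Euclidean distance
#'
#' For a label atlas, each parcel's center is the mean of its member
#' voxels' world coordinates (voxel indices pushed through the affine).
#' For a maps atlas, the center is the map-weighted mean of all voxel
#' coordinates. Empty parcels get missing centers with a warning.
#'
#' @param atlas an [fc_atlas].
#' @return list of class `parcel_geometry`: `centers` (parcels x 3, mm),
#'   `distance` (parcels x parcels, mm) and `parcel_ids`.
#' @export
centers_of_mass <- function(atlas) {
  ids <- parcel_ids(atlas)
  dims <- dim(atlas$data)[1:3]
  ijk <- as.matrix(expand.grid(i = seq_len(dims[1]) - 1L,
                               j = seq_len(dims[2]) - 1L,
                               k = seq_len(dims[3]) - 1L))
  xyz <- voxel_to_world(atlas$affine, ijk)
  centers <- matrix(NA_real_, length(ids), 3,
                    dimnames = list(ids, c("x", "y", "z")))
  if (atlas$kind == "labels") {
    lab <- as.vector(atlas$data)
    for (a in seq_along(ids)) {
      sel <- lab == ids[a]
      if (!any(sel)) {
        warning("empty parcel ", ids[a], ": center set to missing")
        next
      }
      centers[a, ] <- colMeans(xyz[sel, , drop = FALSE])
    }
  } else {
    p <- dim(atlas$data)[4]
    stopifnot(p == length(ids))
    for (a in seq_len(p)) {
      w <- as.vector(atlas$data[, , , a])
      sw <- sum(w)
      if (sw == 0) {
        warning("empty parcel ", ids[a], ": center set to missing")
        next
      }
      centers[a, ] <- colSums(xyz * w) / sw
    }
  }
  dist_mat <- as.matrix(stats::dist(centers))
  dimnames(dist_mat) <- list(ids, ids)
  structure(list(centers = centers, distance = dist_mat, parcel_ids = ids),
            class = "parcel_geometry")
}
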