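#' @keywords internal
"_PACKAGE"

BOLD_SUFFIXES <- c(
  preproc = "_desc-preproc_bold.nii.gz",
  smoothAROMAnonaggr = "_desc-smoothAROMAnonaggr_bold.nii.gz"
)

MOTION_BASE <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")

#' Construct a confound table
#'
#' A confound table holds the named nuisance time courses shipped in an
#' fMRIPrep `*_desc-confounds_timeseries.tsv` file: one row per acquired
#' volume, one column per regressor. Derivative columns
#' (`*_derivative1`, `*_derivative1_power2`) may carry a missing value at
#' volume 1 only, mirroring the "n/a" token fMRIPrep writes there.
#'
#' @param data data.frame of numeric columns, one row per volume.
#' @param tr_seconds repetition time in seconds (optional, `NA` if unknown).
#' @return An object of class `confound_table` with elements `data`,
#'   `n_volumes` and `tr_seconds`.
#' @export
confound_table <- function(data, tr_seconds = NA_real_) {
  stopifnot(is.data.frame(data))
  if (anyDuplicated(names(data))) {
    stop("confound column names must be unique")
  }
  # fMRIPrep writes "n/a" at volume 1 for temporal-difference columns.
  na_ok <- grepl("_derivative1($|_power2$)", names(data)) |
    names(data) %in% c("framewise_displacement", "std_dvars")
  for (j in which(!na_ok)) {
    if (anyNA(data[[j]])) {
      stop("missing values outside volume-1-undefined columns: ",
           names(data)[j])
    }
  }
  for (j in which(na_ok)) {
    bad <- which(is.na(data[[j]]))
    if (length(bad) && any(bad != 1L)) {
      stop("column ", names(data)[j],
           " has missing values beyond volume 1")
    }
  }
  structure(
    list(data = data, n_volumes = nrow(data), tr_seconds = tr_seconds),
    class = "confound_table"
  )
}

#' @export
print.confound_table <- function(x, ...) {
  cat("<confound_table> ", x$n_volumes, " volumes x ", ncol(x$data),
      " confounds", if (!is.na(x$tr_seconds)) paste0(", TR ", x$tr_seconds, " s"),
      "\n", sep = "")
  invisible(x)
}

#' Sidecar metadata for CompCor components
#'
#' @param components data.frame with columns `name`, `mask`
#'   (one of "CSF", "WM", "combined") and `cumulative_variance_explained`.
#' @return An object of class `sidecar_meta`.
#' @export
sidecar_meta <- function(components = data.frame(
                           name = character(), mask = character(),
                           cumulative_variance_explained = numeric())) {
  stopifnot(all(c("name", "mask", "cumulative_variance_explained") %in%
                  names(components)))
  for (m in unique(components$mask)) {
    cve <- components$cumulative_variance_explained[components$mask == m]
    if (is.unsorted(cve)) {
      stop("cumulative variance explained must be non-decreasing within mask ",
           m)
    }
  }
  structure(list(components = components), class = "sidecar_meta")
}

# Derive the confounds-file pair from a BOLD path.
confounds_path_for <- function(image_path) {
  hit <- NULL
  for (v in names(BOLD_SUFFIXES)) {
    if (endsWith(image_path, BOLD_SUFFIXES[[v]])) { hit <- v; break }
  }
  if (is.null(hit)) {
    stop("not an accepted BOLD file name (expected a path ending in ",
         paste(BOLD_SUFFIXES, collapse = " or "), "): ", image_path)
  }
  stem <- sub(paste0(BOLD_SUFFIXES[[hit]], "$"), "", image_path)
  list(variant = hit,
       tsv = paste0(stem, "_desc-confounds_timeseries.tsv"),
       json = paste0(stem, "_desc-confounds_timeseries.json"))
}

image_variant_of <- function(image_path) confounds_path_for(image_path)$variant

#' Read the confounds TSV + JSON sidecar paired with a BOLD image
#'
#' Given the path of a preprocessed BOLD file (ending in
#' `_desc-preproc_bold.nii.gz` or `_desc-smoothAROMAnonaggr_bold.nii.gz`),
#' locate and parse the sibling `*_desc-confounds_timeseries.tsv` and, when
#' present, its JSON sidecar describing CompCor components.
#'
#' @param image_path path to the BOLD image (the image itself is not read).
#' @param tr_seconds repetition time to record on the table (optional).
#' @return list with elements `table` (a [confound_table]) and
#'   `meta` (a [sidecar_meta], empty when no sidecar exists).
#' @export
read_confounds_pair <- function(image_path, tr_seconds = NA_real_) {
  pair <- confounds_path_for(image_path)
  if (!file.exists(pair$tsv)) {
    stop("no confounds file paired with image; expected: ", pair$tsv)
  }
  raw <- utils::read.delim(pair$tsv, sep = "\t", na.strings = "n/a",
                           check.names = FALSE)
  meta <- sidecar_meta()
  if (file.exists(pair$json)) {
    js <- jsonlite::read_json(pair$json)
    comp <- names(js)[vapply(js, function(x)
      is.list(x) && !is.null(x$Mask) && !is.null(x$CumulativeVarianceExplained),
      logical(1))]
    if (length(comp)) {
      comp <- sort(comp)
      meta <- sidecar_meta(data.frame(
        name = comp,
        mask = vapply(js[comp], function(x) as.character(x$Mask), character(1)),
        cumulative_variance_explained = vapply(
          js[comp], function(x) as.numeric(x$CumulativeVarianceExplained),
          numeric(1))
      ))
    }
  }
  list(table = confound_table(raw, tr_seconds = tr_seconds), meta = meta)
}

#' Write a confound table as an fMRIPrep-style TSV
#'
#' Finite values are written in full precision; missing derivative entries
#' use the "n/a" token, so a write/read round trip is lossless.
#'
#' @param table a [confound_table].
#' @param path output TSV path.
#' @export
write_confounds_tsv <- function(table, path) {
  df <- table$data
  out <- lapply(df, function(col) {
    s <- formatC(col, format = "g", digits = 17)
    s[is.na(col)] <- "n/a"
    s
  })
  mat <- do.call(cbind, out)
  utils::write.table(rbind(names(df), mat), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
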