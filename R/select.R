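# Per-category confound selection.
#
# Every selector returns a `confound_selection`: the regressor matrix
# (all volumes, censoring applied downstream), regressor names, and a
# per-category column count used by the degrees-of-freedom report.

CATEGORY_NAMES <- c("motion", "tissue", "global", "compcor", "aroma",
                    "cosine", "non_steady_state")

new_selection <- function(mat, counts = integer()) {
  full <- stats::setNames(integer(length(CATEGORY_NAMES)), CATEGORY_NAMES)
  full[names(counts)] <- counts
  if (sum(full) != ncol(mat)) {
    stop("category counts do not add up to the number of columns")
  }
  if (anyDuplicated(colnames(mat))) stop("duplicated regressor names")
  structure(list(matrix = mat, names = colnames(mat), counts = full),
            class = "confound_selection")
}

empty_selection <- function(n_volumes) {
  new_selection(matrix(numeric(0), nrow = n_volumes, ncol = 0,
                       dimnames = list(NULL, character(0))))
}

#' @export
print.confound_selection <- function(x, ...) {
  used <- x$counts[x$counts > 0]
  cat("<confound_selection> ", nrow(x$matrix), " volumes x ",
      ncol(x$matrix), " regressors",
      if (length(used)) paste0(" (", paste(names(used), used, sep = ":",
                                           collapse = ", "), ")"),
      "\n", sep = "")
  invisible(x)
}

# Concatenate selections column-wise.
bind_selections <- function(sels) {
  sels <- Filter(Negate(is.null), sels)
  if (!length(sels)) stop("nothing to bind")
  mat <- do.call(cbind, lapply(sels, `[[`, "matrix"))
  counts <- Reduce(`+`, lapply(sels, `[[`, "counts"))
  new_selection(mat, counts)
}

expansion_terms <- function(base, option) {
  switch(option,
    basic = base,
    derivatives = c(base, paste0(base, "_derivative1")),
    power2 = c(base, paste0(base, "_power2")),
    full = c(base, paste0(base, "_derivative1"), paste0(base, "_power2"),
             paste0(base, "_derivative1_power2")),
    stop("unknown expansion option '", option,
         "' (expected basic, derivatives, power2 or full)")
  )
}

# Pull named columns; derivative NA at volume 1 imputed to 0.
take_columns <- function(table, cols, category) {
  missing <- setdiff(cols, names(table$data))
  if (length(missing)) {
    stop("missing confound columns for category ", category, ": ",
         paste(missing, collapse = ", "))
  }
  mat <- as.matrix(table$data[cols])
  mat[is.na(mat)] <- 0
  storage.mode(mat) <- "double"
  new_selection(mat, stats::setNames(ncol(mat), category))
}

#' Select head-motion regressors
#'
#' Expansion options follow the fMRIPrep column dialect: `basic` keeps the
#' six rigid-body parameters, `derivatives` adds their first temporal
#' derivatives, `power2` their squares, and `full` all 24 terms. Expansion
#' columns are taken from the precomputed fMRIPrep columns, never
#' recomputed; the undefined derivative at volume 1 is imputed to 0.
#'
#' @param table a [confound_table].
#' @param option one of `"basic"`, `"derivatives"`, `"power2"`, `"full"`.
#' @return A `confound_selection` with 6, 12, 12 or 24 motion columns.
#' @export
expand_motion <- function(table, option = "basic") {
  take_columns(table, expansion_terms(MOTION_BASE, option), "motion")
}

#' Select tissue-signal regressors (WM/CSF or global signal)
#'
#' @param table a [confound_table].
#' @param category `"wm_csf"` (base columns `csf`, `white_matter`) or
#'   `"global_signal"` (base column `global_signal`).
#' @param option expansion option as in [expand_motion()].
#' @return A `confound_selection`; counts recorded under `tissue` or
#'   `global`.
#' @export
select_tissue <- function(table, category = c("wm_csf", "global_signal"),
                          option = "basic") {
  category <- match.arg(category)
  base <- if (category == "wm_csf") c("csf", "white_matter") else "global_signal"
  take_columns(table, expansion_terms(base, option),
               if (category == "wm_csf") "tissue" else "global")
}

#' Select anatomical CompCor components
#'
#' Components are taken from the combined WM+CSF mask listed in the JSON
#' sidecar. With `n = "all"`, the smallest prefix (in sidecar order) whose
#' cumulative variance explained reaches 50% is returned; an integer `n`
#' returns the first `n` components.
#'
#' @param table a [confound_table].
#' @param meta a [sidecar_meta] listing components and their cumulative
#'   variance explained.
#' @param mask only `"anat_combined"` is supported.
#' @param n `"all"` (50% variance cut-off) or a component count.
#' @param variance_threshold cumulative-variance cut-off used by
#'   `n = "all"` (default 0.5).
#' @return A `confound_selection` of CompCor columns.
#' @export
select_compcor <- function(table, meta, mask = "anat_combined", n = "all",
                           variance_threshold = 0.5) {
  if (!identical(mask, "anat_combined")) {
    stop("unsupported compcor mask '", mask, "'")
  }
  comp <- meta$components
  comp <- comp[comp$mask == "combined", , drop = FALSE]
  if (!nrow(comp)) {
    stop("missing confound columns for category compcor: ",
         "no combined-mask components in the sidecar")
  }
  if (identical(n, "all")) {
    k <- match(TRUE, comp$cumulative_variance_explained >= variance_threshold)
    if (is.na(k)) k <- nrow(comp)
  } else {
    k <- as.integer(n)
    if (k > nrow(comp)) {
      stop("missing confound columns for category compcor: requested ", k,
           " components but only ", nrow(comp), " available")
    }
  }
  take_columns(table, comp$name[seq_len(k)], "compcor")
}

#' Select ICA-AROMA regressors
#'
#' The benchmark uses fMRIPrep's non-aggressive denoising (`option =
#' "full"`): the motion components have already been removed from the
#' `desc-smoothAROMAnonaggr` image, so zero columns are returned and the
#' image variant is checked instead. `option = "basic"` returns the
#' `aroma_motion_*` columns for aggressive regression.
#'
#' @param table a [confound_table].
#' @param image_variant `"preproc"` or `"smoothAROMAnonaggr"`.
#' @param option `"full"` (non-aggressive, image-based) or `"basic"`
#'   (aggressive, column-based).
#' @return A `confound_selection` (zero columns for `"full"`).
#' @export
select_aroma <- function(table, image_variant, option = "full") {
  if (identical(option, "full")) {
    if (!identical(image_variant, "smoothAROMAnonaggr")) {
      stop("ica_aroma (non-aggressive) requires the ",
           "desc-smoothAROMAnonaggr image variant, got '", image_variant, "'")
    }
    return(empty_selection(table$n_volumes))
  }
  cols <- grep("^aroma_motion_", names(table$data), value = TRUE)
  if (!length(cols)) {
    stop("missing confound columns for category aroma: no aroma_motion_* ",
         "columns present (was fMRIPrep run with --use-aroma?)")
  }
  take_columns(table, sort(cols), "aroma")
}

#' Select discrete-cosine high-pass regressors
#'
#' @param table a [confound_table].
#' @param required error if no `cosine*` columns exist (default TRUE).
#' @return A `confound_selection` of all `cosine*` columns.
#' @export
select_high_pass <- function(table, required = TRUE) {
  cols <- grep("^cosine[0-9]+$", names(table$data), value = TRUE)
  if (!length(cols)) {
    if (required) {
      stop("missing confound columns for category high_pass: ",
           "no cosine* columns present")
    }
    return(empty_selection(table$n_volumes))
  }
  take_columns(table, sort(cols), "cosine")
}

#' Select non-steady-state outlier indicator columns
#'
#' Returns the one-hot `non_steady_state_outlier*` columns. In the
#' assembled strategies these volumes are folded into the sample mask
#' rather than kept as spike regressors, so all strategies share the same
#' initial-volume handling.
#'
#' @param table a [confound_table].
#' @return A `confound_selection` (empty when no outlier columns exist).
#' @export
select_non_steady_state <- function(table) {
  cols <- grep("^non_steady_state_outlier[0-9]+$", names(table$data),
               value = TRUE)
  if (!length(cols)) return(empty_selection(table$n_volumes))
  take_columns(table, sort(cols), "non_steady_state")
}

# Volumes flagged by any non-steady-state column (logical per volume).
non_steady_state_flags <- function(table) {
  sel <- select_non_steady_state(table)
  if (!ncol(sel$matrix)) return(rep(FALSE, table$n_volumes))
  rowSums(sel$matrix != 0) > 0
}
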