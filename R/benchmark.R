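# End-to-end benchmark: QC exclusion, per subject x strategy denoising,
# connectome generation, and the four quality metrics.

find_bold <- function(derivatives, subject, variant) {
  file.path(derivatives, subject, "func",
            paste0(subject, "_task-rest", BOLD_SUFFIXES[[variant]]))
}

# Map participants.tsv sex labels to the 0/1 coding used by the metrics.
encode_sex <- function(sex) {
  if (is.numeric(sex)) {
    stopifnot(all(sex %in% c(0, 1)))
    return(as.numeric(sex))
  }
  up <- toupper(as.character(sex))
  if (!all(up %in% c("F", "M", "FEMALE", "MALE"))) {
    stop("sex must be coded F/M (or 0/1)")
  }
  as.numeric(up %in% c("M", "MALE"))
}

#' Run the denoising benchmark on a derivative tree
#'
#' For every included subject (after motion quality control) and every
#' requested strategy: load the strategy's confounds and sample mask,
#' extract parcel time series with the atlas, censor + regress, and
#' compute the Pearson connectome. Per strategy the four quality metrics
#' are computed over the cohort (degrees-of-freedom loss, QC-FC, DM-FC,
#' Louvain modularity and its motion correlation), plus the
#' cross-strategy similarity matrix. All tables are written as TSV under
#' `out_dir`; outputs are deterministic given the inputs and the metric
#' configuration.
#'
#' @param derivatives root of the fMRIPrep-style derivative tree.
#' @param participants path to a participants TSV with columns
#'   `participant_id`, `age`, `sex`.
#' @param atlas_path path to the atlas NIfTI (3D labels or 4D maps).
#' @param lookup_path path to the atlas lookup TSV (`index`, `name`).
#' @param strategies character vector of registered strategy names.
#' @param out_dir output directory.
#' @param config a [metric_config()].
#' @param tr_seconds repetition time (s) used for the QC minutes
#'   criterion.
#' @param atlas_name label used in the output tables.
#' @return Invisibly, list: `metrics` (long data.frame), `similarity`,
#'   `qc` (per-subject decisions), `edges` (per-strategy subject x edge
#'   matrices), `included` subject ids.
#' @export
run_benchmark <- function(derivatives, participants, atlas_path,
                          lookup_path, strategies, out_dir,
                          config = metric_config(), tr_seconds = 2,
                          atlas_name = "atlas") {
  stopifnot(length(strategies) >= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  demo <- utils::read.delim(participants)
  atlas <- read_atlas(atlas_path, lookup_path)
  geom <- centers_of_mass(atlas)
  dist_edges <- vectorize_connectome(geom$distance)

  # motion QC from the shipped framewise_displacement column
  qc <- list()
  for (sub in demo$participant_id) {
    img <- find_bold(derivatives, sub, "preproc")
    tab <- read_confounds_pair(img)$table
    qc[[sub]] <- subject_qc(tab$data$framewise_displacement, tr_seconds)
  }
  write_qc_report(qc, file.path(out_dir, "motion_qc.tsv"))
  included <- names(qc)[!vapply(qc, `[[`, logical(1), "excluded")]
  if (!length(included)) stop("no subjects left after motion QC")
  demo <- demo[demo$participant_id %in% included, , drop = FALSE]

  pheno <- NULL
  if (length(included) >= 5) {
    pheno <- fc_phenotypes(
      mean_fd = vapply(qc[included], `[[`, numeric(1), "mean_fd"),
      age = demo$age, sex = encode_sex(demo$sex))
  } else {
    warning("fewer than 5 included subjects: motion-association metrics ",
            "(QC-FC, DM-FC, modularity-motion) reported as NA")
  }

  metrics <- list()
  edges_by_strategy <- list()
  for (strat in strategies) {
    variant <- strategy_image_variant(strat)
    edge_rows <- list()
    dof_rows <- q_values <- numeric(0)
    for (sub in included) {
      img_path <- find_bold(derivatives, sub, variant)
      loaded <- load_confounds_strategy(img_path, strat,
                                        tr_seconds = tr_seconds)
      img <- RNifti::readNifti(img_path)
      arr <- as.array(img)
      attr(arr, "affine") <- xform_of(img)
      ts <- if (atlas$kind == "labels") {
        extract_labels(arr, atlas, tr_seconds)
      } else {
        extract_maps(arr, atlas, tr_seconds)
      }
      cleaned <- clean_timeseries(ts, loaded$confounds,
                                  loaded$sample_mask, standardize = TRUE)
      conn <- pearson_connectome(cleaned)
      edge_rows[[sub]] <- vectorize_connectome(conn)
      dof <- dof_loss(loaded$confounds, loaded$sample_mask,
                      nrow(ts$series))
      dof_rows <- c(dof_rows, dof$total_loss)
      q_values <- c(q_values, louvain_q(conn, config)$Q)
    }
    edges <- do.call(rbind, edge_rows)
    edges_by_strategy[[strat]] <- edges
    if (!is.null(pheno)) {
      qr_ <- qcfc(edges, pheno, config)
      dm <- dmfc(qr_$r, dist_edges)
      mm <- modularity_motion(q_values, pheno)
    } else {
      qr_ <- list(fraction_significant = NA_real_,
                  median_absolute_r = NA_real_)
      dm <- NA_real_
      mm <- list(r = NA_real_)
    }
    metrics[[strat]] <- data.frame(
      strategy = strat, atlas = atlas_name,
      metric = c("dof_total_loss_mean", "qcfc_fraction_significant",
                 "qcfc_median_absolute_r", "dmfc_absolute_r",
                 "modularity_q_mean", "modularity_motion_r"),
      value = c(mean(dof_rows), qr_$fraction_significant,
                qr_$median_absolute_r, dm, mean(q_values), mm$r),
      stringsAsFactors = FALSE)
  }
  metrics_df <- do.call(rbind, c(metrics, make.row.names = FALSE))
  utils::write.table(metrics_df, file.path(out_dir, "metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  sim <- NULL
  if (length(strategies) >= 2) {
    mean_edges <- lapply(edges_by_strategy, colMeans)
    sim <- strategy_similarity(mean_edges)
    write_similarity(sim, file.path(out_dir, "strategy_similarity.tsv"))
  }
  echo <- list(strategies = strategies, atlas = atlas_name,
               tr_seconds = tr_seconds, sex_coding = "F=0, M=1",
               metric_config = unclass(config),
               included_subjects = included,
               excluded_subjects = setdiff(names(qc), included))
  jsonlite::write_json(echo, file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(metrics = metrics_df, similarity = sim, qc = qc,
                 edges = edges_by_strategy, included = included,
                 pheno = pheno))
}
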