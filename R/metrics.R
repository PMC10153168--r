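# Denoising-quality metrics over a cohort of connectomes.

#' Metric configuration
#'
#' @param alpha significance level for QC-FC edge tests (default 0.05;
#'   edges with p below alpha are deemed significant).
#' @param multiple_comparison `"none"` or `"fdr"`
#'   (Benjamini-Hochberg step-up applied to the QC-FC p-values).
#' @param louvain_seed integer seed for the Louvain restarts.
#' @param louvain_reps number of Louvain restarts per connectome
#'   (default 100; the max-Q partition is kept).
#' @param louvain_negative_scheme `"negative_asym"` or `"negative_sym"`.
#' @param louvain_gamma resolution parameter (default 1).
#' @return list of class `metric_config`.
#' @export
metric_config <- function(alpha = 0.05, multiple_comparison = "none",
                          louvain_seed = 42L, louvain_reps = 100L,
                          louvain_negative_scheme = "negative_asym",
                          louvain_gamma = 1) {
  stopifnot(alpha > 0, alpha < 1,
            multiple_comparison %in% c("none", "fdr"))
  structure(list(alpha = alpha, multiple_comparison = multiple_comparison,
                 louvain_seed = as.integer(louvain_seed),
                 louvain_reps = as.integer(louvain_reps),
                 louvain_negative_scheme = louvain_negative_scheme,
                 louvain_gamma = louvain_gamma),
            class = "metric_config")
}

#' Cohort phenotypes for the motion metrics
#'
#' @param mean_fd per-subject mean framewise displacement (mm).
#' @param age per-subject age (years).
#' @param sex per-subject binary code (0/1).
#' @return data.frame of class `fc_phenotypes`.
#' @export
fc_phenotypes <- function(mean_fd, age, sex) {
  stopifnot(length(age) == length(mean_fd), length(sex) == length(mean_fd))
  if (anyNA(mean_fd) || anyNA(age) || anyNA(sex)) {
    stop("phenotypes must have no missing values among included subjects")
  }
  if (!all(sex %in% c(0, 1))) stop("sex must be coded 0/1")
  if (length(mean_fd) < 5) stop("need at least 5 subjects (2 covariates + 3)")
  structure(data.frame(mean_fd = mean_fd, age = age, sex = sex),
            class = c("fc_phenotypes", "data.frame"))
}

#' QC-FC: per-edge partial correlation between motion and connectivity
#'
#' For each edge, the partial correlation between subjects' mean
#' framewise displacement and the edge's connectivity, with age and sex
#' as covariates. Summaries: the fraction of edges significant at
#' `config$alpha` (optionally after Benjamini-Hochberg correction) and
#' the median absolute partial correlation. Edges that are missing for
#' any subject are dropped pairwise (result `NA` for that edge).
#'
#' @param edges subjects x edges matrix of vectorized connectomes.
#' @param pheno an [fc_phenotypes] aligned with the rows of `edges`.
#' @param config a [metric_config()].
#' @return list of class `qcfc_result`: `r`, `p` (per edge),
#'   `fraction_significant`, `median_absolute_r`, `n_edges_tested`.
#' @export
qcfc <- function(edges, pheno, config = metric_config()) {
  edges <- as.matrix(edges)
  stopifnot(nrow(edges) == nrow(pheno))
  if (stats::sd(pheno$mean_fd) < 1e-12) {
    stop("mean framewise displacement is constant across subjects")
  }
  n <- nrow(edges)
  k <- 2L
  Z <- cbind(1, pheno$age, pheno$sex)
  qz <- qr(Z)
  rx <- qr.resid(qz, pheno$mean_fd)
  r <- p <- rep(NA_real_, ncol(edges))
  complete <- !apply(edges, 2, anyNA)
  if (any(complete)) {
    ry <- qr.resid(qz, edges[, complete, drop = FALSE])
    ssx <- sum(rx^2)
    ssy <- colSums(ry^2)
    rr <- as.vector(crossprod(ry, rx)) / sqrt(ssx * ssy)
    rr[ssy < 1e-24] <- NA_real_
    df <- n - 2L - k
    tt <- rr * sqrt(df / pmax(1 - rr^2, .Machine$double.eps))
    r[complete] <- rr
    p[complete] <- 2 * stats::pt(-abs(tt), df)
  }
  p_adj <- if (config$multiple_comparison == "fdr") {
    stats::p.adjust(p, method = "BH")
  } else p
  structure(list(
    r = r, p = p,
    fraction_significant = mean(p_adj < config$alpha, na.rm = TRUE),
    median_absolute_r = stats::median(abs(r), na.rm = TRUE),
    n_edges_tested = sum(!is.na(p))
  ), class = "qcfc_result")
}

#' @export
print.qcfc_result <- function(x, ...) {
  cat(sprintf(
    "<qcfc_result> %d edges: %.1f%% significant, median |r| = %.4f\n",
    x$n_edges_tested, 100 * x$fraction_significant, x$median_absolute_r))
  invisible(x)
}

#' DM-FC: distance dependence of the motion artifact
#'
#' Absolute Pearson correlation between inter-parcel Euclidean distance
#' and the per-edge QC-FC correlations; values near zero indicate little
#' residual distance-dependent motion artifact. Missing edges are removed
#' pairwise.
#'
#' @param qcfc_r per-edge QC-FC partial correlations.
#' @param distance per-edge Euclidean distances (mm), same edge order.
#' @return Absolute correlation (scalar); `NA` with a warning when either
#'   vector has zero variance.
#' @export
dmfc <- function(qcfc_r, distance) {
  stopifnot(length(qcfc_r) == length(distance))
  ok <- !is.na(qcfc_r) & !is.na(distance)
  if (sum(ok) < 3) stop("need at least 3 edges")
  x <- qcfc_r[ok]; y <- distance[ok]
  if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12) {
    warning("zero variance: distance dependence undefined")
    return(NA_real_)
  }
  abs(stats::cor(x, y))
}

#' Partial correlation between network modularity and motion
#'
#' @param q per-subject Louvain modularity values.
#' @param pheno an [fc_phenotypes].
#' @return As [partial_corr()] (age and sex as covariates).
#' @export
modularity_motion <- function(q, pheno) {
  partial_corr(pheno$mean_fd, q, cbind(pheno$age, pheno$sex))
}

#' Loss in temporal degrees of freedom
#'
#' The total loss is the number of regressors used plus the number of
#' censored volumes; the discrete-cosine count is reported separately as
#' the dataset-dependent component.
#'
#' @param selection a `confound_selection`.
#' @param mask a [sample_mask].
#' @param n_volumes scan length in volumes.
#' @return list of class `dof_report`: `n_regressors`, `breakdown`
#'   (per-category counts), `cosine_count`, `n_censored`, `total_loss`,
#'   `percent_of_scan`.
#' @export
dof_loss <- function(selection, mask, n_volumes) {
  n_reg <- ncol(selection$matrix)
  total <- n_reg + mask$censored_count
  structure(list(
    n_regressors = n_reg,
    breakdown = selection$counts,
    cosine_count = unname(selection$counts["cosine"]),
    n_censored = mask$censored_count,
    total_loss = total,
    percent_of_scan = 100 * total / n_volumes
  ), class = "dof_report")
}

#' @export
print.dof_report <- function(x, ...) {
  cat(sprintf(
    "<dof_report> %d regressors + %d censored volumes = %d (%.1f%% of scan)\n",
    x$n_regressors, x$n_censored, x$total_loss, x$percent_of_scan))
  invisible(x)
}
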