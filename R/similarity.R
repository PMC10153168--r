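# Similarity of denoised connectomes across strategies.

#' Correlation matrix of strategy-mean edge vectors
#'
#' Each strategy contributes its mean edge vector (across subjects, and
#' across atlases when several were used); the similarity is the pairwise
#' Pearson correlation of those vectors, with a leaves-order from
#' hierarchical clustering to reveal blocks of related strategies.
#'
#' @param mean_edges named list of equal-length edge vectors, or a
#'   strategies x edges matrix with row names.
#' @return list of class `strategy_similarity`: `matrix` (strategies x
#'   strategies Pearson r) and `ordering` (leaves order).
#' @export
strategy_similarity <- function(mean_edges) {
  if (is.list(mean_edges)) {
    lens <- lengths(mean_edges)
    if (length(unique(lens)) != 1) stop("edge vectors differ in length")
    mean_edges <- do.call(rbind, mean_edges)
  }
  m <- as.matrix(mean_edges)
  if (nrow(m) < 2) stop("need at least 2 strategies")
  r <- stats::cor(t(m), use = "pairwise.complete.obs")
  diag(r) <- 1
  structure(list(matrix = r, ordering = hierarchical_order(r)),
            class = "strategy_similarity")
}

#' Leaves order from average-linkage clustering of a similarity matrix
#'
#' Agglomerative clustering on distance 1 - r with average linkage; ties
#' between equal merge heights resolve to the lower index first (the
#' behaviour of [stats::hclust()]), so the ordering is deterministic.
#'
#' @param sim symmetric similarity (correlation) matrix.
#' @return Integer permutation of strategies (leaves order).
#' @export
hierarchical_order <- function(sim) {
  sim <- if (inherits(sim, "strategy_similarity")) sim$matrix
         else as.matrix(sim)
  if (nrow(sim) == 1) return(1L)
  d <- stats::as.dist(1 - sim)
  stats::hclust(d, method = "average")$order
}

#' Write a strategy-similarity matrix and its ordering to TSV
#'
#' @param sim a `strategy_similarity`.
#' @param path output TSV path; the ordering goes to
#'   `<path>.ordering.tsv`.
#' @export
write_similarity <- function(sim, path) {
  utils::write.table(sim$matrix, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  ord <- data.frame(position = seq_along(sim$ordering),
                    strategy = rownames(sim$matrix)[sim$ordering])
  utils::write.table(ord, paste0(path, ".ordering.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
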