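# Louvain community detection with signed-weight modularity.
#
# Operates on the full modularity matrix (Brain Connectivity Toolbox
# style), so negative edges -- common after global signal regression --
# are handled through an explicit positive/negative weighting scheme
# rather than being dropped.

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Signed modularity matrix. negative_asym discounts the negative part by
# 1/(s+ + s-); negative_sym scales both parts by 1/(s+ + s-).
modularity_matrix <- function(W, gamma = 1, scheme = "negative_asym") {
  W0 <- pmax(W, 0); W1 <- -pmin(W, 0)
  s0 <- sum(W0); s1 <- sum(W1)
  k0 <- rowSums(W0); k1 <- rowSums(W1)
  B <- matrix(0, nrow(W), ncol(W))
  d0 <- switch(scheme, negative_asym = 1 / s0,
               negative_sym = 1 / (s0 + s1),
               stop("unknown negative scheme '", scheme, "'"))
  if (s0 > 0) B <- B + (W0 - gamma * outer(k0, k0) / s0) * d0
  if (s1 > 0) B <- B - (W1 - gamma * outer(k1, k1) / s1) / (s0 + s1)
  (B + t(B)) / 2
}

# One Louvain run on a modularity matrix: local moving + aggregation.
louvain_once <- function(B) {
  n0 <- nrow(B)
  ci <- seq_len(n0)
  q_prev <- -Inf
  repeat {
    n <- nrow(B)
    M <- seq_len(n)
    Hnm <- B
    moved <- TRUE
    while (moved) {
      moved <- FALSE
      for (u in sample.int(n)) {
        ma <- M[u]
        dQ <- Hnm[u, ] - Hnm[u, ma] + B[u, u]
        dQ[ma] <- 0
        mb <- which.max(dQ)
        if (dQ[mb] > 1e-10) {
          moved <- TRUE
          M[u] <- mb
          Hnm[, mb] <- Hnm[, mb] + B[, u]
          Hnm[, ma] <- Hnm[, ma] - B[, u]
        }
      }
    }
    M <- match(M, unique(M))
    ci <- M[ci]
    nc <- max(M)
    P <- matrix(0, n, nc); P[cbind(seq_len(n), M)] <- 1
    B <- crossprod(P, B %*% P)
    q <- sum(diag(B))
    if (q - q_prev <= 1e-10) break
    q_prev <- q
  }
  list(Q = q_prev, partition = match(ci, unique(ci)))
}

#' Louvain network modularity of a connectome
#'
#' Community detection by the Louvain method on the weighted graph given
#' by the connectome (diagonal ignored). Negative weights enter through
#' the configured signed scheme (default `negative_asym`: the negative
#' part of the modularity matrix is discounted by the total weight). The
#' algorithm is restarted `config$louvain_reps` times from seed-derived
#' substreams and the partition with maximal modularity Q is kept, so
#' results are deterministic given `config$louvain_seed`.
#'
#' @param conn a `connectome` or a symmetric numeric matrix.
#' @param config a [metric_config()].
#' @return list: `Q` (modularity) and `partition` (integer community
#'   labels).
#' @export
louvain_q <- function(conn, config = metric_config()) {
  W <- if (inherits(conn, "connectome")) conn$matrix else as.matrix(conn)
  if (!all(is.finite(W))) stop("connectome must be finite for modularity")
  diag(W) <- 0
  if (all(W == 0)) {
    return(list(Q = 0, partition = seq_len(nrow(W))))
  }
  B <- modularity_matrix(W, gamma = config$louvain_gamma,
                         scheme = config$louvain_negative_scheme)
  best <- NULL
  for (r in seq_len(config$louvain_reps)) {
    fit <- with_seed(config$louvain_seed + r - 1L, louvain_once(B))
    if (is.null(best) || fit$Q > best$Q) best <- fit
  }
  best
}
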