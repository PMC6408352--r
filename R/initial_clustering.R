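#' Seed clustering of experiments from a similarity matrix
#'
#' Produces a hard clustering W of the experiment grid to seed the
#' refinement program. Any clustering method can stand here — the seed is
#' user-facing configuration, not merely an initialization — and externally
#' produced partitions can be supplied in the same CSV schema via
#' [read_assignment_csv()]. Three standard methods are built in:
#' average-linkage agglomerative clustering on the dissimilarity `1 - s`
#' (the deterministic default), k-means on the rows of the similarity
#' matrix, and spectral clustering (k-means on the leading eigenvectors of
#' the symmetrically normalized similarity).
#'
#' @param S_mat a `similarity_matrix` over a 2-axis experiment grid.
#' @param m maximum number of clusters (`1 <= m <=` number of experiments).
#' @param method `"agglomerative-average"`, `"kmeans-on-rows"` or
#'   `"spectral"`.
#' @param seed RNG seed for the stochastic methods (ignored by the
#'   agglomerative default).
#' @return a 0/1 assignment array `W` of shape `(n1, n2, m)` with unit cell
#'   sums; at most `m` slices are non-empty.
#' @export
cluster_flat <- function(S_mat, m,
                         method = c("agglomerative-average",
                                    "kmeans-on-rows", "spectral"),
                         seed = 0L) {
  method <- match.arg(method)
  V <- S_mat$values
  n <- nrow(V)
  if (m < 1L) stop2("m must be at least 1")
  if (m > n) stop2("m = ", m, " exceeds the number of experiments ", n)
  memb <- if (m == 1L) {
    rep(1L, n)
  } else if (method == "agglomerative-average") {
    d <- stats::as.dist(pmax(1 - V, 0))
    stats::cutree(stats::hclust(d, method = "average"), k = m)
  } else if (method == "kmeans-on-rows") {
    withr::with_seed(seed, stats::kmeans(V, centers = m, nstart = 10L)$cluster)
  } else {
    dg <- rowSums(pmax(V, 0))
    L <- pmax(V, 0) / sqrt(outer(dg, dg))
    ev <- eigen(L, symmetric = TRUE)$vectors[, seq_len(m), drop = FALSE]
    ev <- ev / pmax(sqrt(rowSums(ev^2)), .Machine$double.eps)
    withr::with_seed(seed, stats::kmeans(ev, centers = m, nstart = 10L)$cluster)
  }
  dims <- S_mat$dims
  if (length(dims) != 2L) {
    stop2("cluster_flat requires a 2-axis experiment grid")
  }
  W <- array(0, dim = c(dims, m))
  g <- rowmajor_grid(dims)
  W[cbind(g[, 1L], g[, 2L], memb)] <- 1
  W
}
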