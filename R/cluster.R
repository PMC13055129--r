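#' Shared-nearest-neighbor Leiden clustering
#'
#' Builds a k-nearest-neighbor graph in embedding space (Euclidean),
#' re-weights edges by the Jaccard overlap of neighborhoods
#' (shared-nearest-neighbor weighting, pruning weights below `prune`), and
#' partitions the graph with the Leiden algorithm under the modularity
#' objective.
#'
#' @param embedding Cells x dims numeric matrix (e.g. PCA scores).
#' @param k Neighbors per cell (default 15).
#' @param resolution Leiden resolution (default 0.3, coarse enough that
#'   homogeneous populations are not fragmented by modularity refinement).
#' @param seed Seed controlling the Leiden refinement; fixed seed gives a
#'   deterministic partition.
#' @param prune SNN weights below this are dropped (default 1/15).
#' @return Integer cluster labels (1-based), named by cell.
#' @export
knn_leiden <- function(embedding, k = 15, resolution = 0.3, seed = 0L,
                       prune = 1 / 15) {
  n <- nrow(embedding)
  if (k >= n) stop("k must be smaller than the number of cells")
  g <- snn_graph(embedding, k = k, prune = prune)
  set.seed(seed)
  part <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution, n_iterations = 10)
  labels <- igraph::membership(part)
  out <- as.integer(labels)
  names(out) <- rownames(embedding)
  out
}

# kNN + SNN(Jaccard) graph; neighborhoods include the cell itself.
snn_graph <- function(embedding, k = 15, prune = 1 / 15) {
  n <- nrow(embedding)
  d <- as.matrix(stats::dist(embedding))
  nb <- matrix(0L, n, k + 1)
  for (i in seq_len(n)) {
    nb[i, ] <- order(d[i, ])[seq_len(k + 1)]  # self is at distance 0
  }
  adj <- Matrix::sparseMatrix(
    i = rep(seq_len(n), each = k + 1),
    j = as.vector(t(nb)), x = 1, dims = c(n, n)
  )
  shared <- Matrix::tcrossprod(adj)
  jac <- shared
  jac@x <- jac@x / (2 * (k + 1) - jac@x)
  jac@x[jac@x < prune] <- 0
  jac <- Matrix::drop0(jac)
  Matrix::diag(jac) <- 0
  igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same cells;
#' 1 for identical partitions (up to label renaming), ~0 for independent
#' ones.
#'
#' @param a,b Label vectors of equal length.
#' @return Numeric scalar in [-1, 1].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
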