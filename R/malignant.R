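#' Annotate clusters with cell types by marker expression
#'
#' Each cluster is assigned the cell type whose marker genes have the
#' highest mean normalized expression over the cluster's cells. Ties are
#' broken by marker-map order with a warning.
#'
#' @param norm Cells x genes normalized matrix.
#' @param clusters Cluster labels, one per cell.
#' @param markers Named list: cell-type label -> character vector of marker
#'   genes (all present in `norm`).
#' @return Named character vector: cluster -> type label.
#' @export
score_cell_types <- function(norm, clusters, markers) {
  if (!length(markers)) stop("marker map is empty")
  missing <- setdiff(unlist(markers), colnames(norm))
  if (length(missing)) stop("marker genes absent from matrix: ",
                            paste(utils::head(missing, 5), collapse = ", "))
  cl <- sort(unique(as.character(clusters)))
  out <- character(length(cl))
  names(out) <- cl
  for (ci in cl) {
    cells <- which(as.character(clusters) == ci)
    if (!length(cells)) stop("empty cluster: ", ci)
    score <- vapply(markers, function(gs) {
      mean(Matrix::colMeans(norm[cells, gs, drop = FALSE]))
    }, numeric(1))
    best <- which(score == max(score))
    if (length(best) > 1) {
      warning("tied cell-type scores for cluster ", ci,
              "; keeping first label in marker-map order")
    }
    out[ci] <- names(markers)[best[1]]
  }
  out
}

#' Call malignant clusters by marker positivity and light-chain restriction
#'
#' A cluster is called malignant when (a) at least `fraction_threshold` of
#' its cells express the malignancy marker above `expr_threshold` log
#' counts, and (b) its light-chain restriction index -- the absolute
#' difference between cluster-mean log1p kappa and lambda expression --
#' is at least `restriction_threshold`. The index is symmetric in the two
#' chains; clonal B-cell populations express only one.
#'
#' @param norm Cells x genes normalized matrix.
#' @param clusters Cluster labels, one per cell.
#' @param marker_gene Malignancy marker gene id (CCND1-like).
#' @param kappa_gene,lambda_gene Light-chain gene ids.
#' @param expr_threshold Log-expression cutoff for marker positivity
#'   (default 1.0).
#' @param fraction_threshold Minimum marker-positive cell fraction
#'   (default 0.5).
#' @param restriction_threshold Minimum restriction index (default 1.0,
#'   roughly an e-fold skew).
#' @return data.frame with one row per cluster: `cluster`,
#'   `marker_fraction`, `restriction_index`, `malignant`.
#' @export
call_malignant <- function(norm, clusters, marker_gene, kappa_gene, lambda_gene,
                           expr_threshold = 1.0, fraction_threshold = 0.5,
                           restriction_threshold = 1.0) {
  genes <- c(marker_gene, kappa_gene, lambda_gene)
  if (anyDuplicated(genes)) stop("marker, kappa and lambda genes must be distinct")
  missing <- setdiff(genes, colnames(norm))
  if (length(missing)) stop("genes absent from matrix: ",
                            paste(missing, collapse = ", "))
  cl <- sort(unique(as.character(clusters)))
  res <- lapply(cl, function(ci) {
    cells <- which(as.character(clusters) == ci)
    frac <- mean(norm[cells, marker_gene] > expr_threshold)
    restrict <- abs(mean(norm[cells, kappa_gene]) - mean(norm[cells, lambda_gene]))
    data.frame(cluster = ci, marker_fraction = frac,
               restriction_index = restrict,
               malignant = frac >= fraction_threshold &
                 restrict >= restriction_threshold,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
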