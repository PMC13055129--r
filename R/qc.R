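#' Per-cell quality-control metrics
#'
#' @param counts Cells x genes non-negative integer matrix (sparse or dense).
#' @param mito_flags Logical vector, one per gene, marking mitochondrial
#'   genes (the `^MT-` set in real data).
#' @return data.frame with one row per cell: `cell`, `total_umi`,
#'   `n_genes`, `mito_frac` (0 for all-zero cells), `degenerate` (all-zero
#'   cell) and `low_quality` (unset here; see [apply_thresholds()]).
#' @export
compute_qc <- function(counts, mito_flags) {
  if (length(mito_flags) != ncol(counts)) {
    stop("mito_flags length (", length(mito_flags),
         ") does not match gene count (", ncol(counts), ")")
  }
  total <- Matrix::rowSums(counts)
  detected <- Matrix::rowSums(counts > 0)
  mito <- Matrix::rowSums(counts[, mito_flags, drop = FALSE])
  data.frame(
    cell = if (is.null(rownames(counts))) as.character(seq_len(nrow(counts))) else rownames(counts),
    total_umi = total,
    n_genes = detected,
    mito_frac = ifelse(total > 0, mito / total, 0),
    degenerate = total == 0,
    low_quality = NA,
    stringsAsFactors = FALSE
  )
}

#' QC thresholds
#'
#' Per-sample bounds on library size, detected genes and mitochondrial
#' fraction, plus the cluster-level exclusion cutoff: clusters whose
#' low-quality fraction exceeds `cluster_lowq_cutoff` are dropped wholesale.
#'
#' @param min_umi,max_umi Bounds on total UMI count.
#' @param min_genes,max_genes Bounds on detected genes.
#' @param max_mito Maximum mitochondrial fraction.
#' @param cluster_lowq_cutoff Low-quality cell fraction above which a whole
#'   cluster is excluded (strictly greater than; default 0.33).
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_umi = 500, max_umi = Inf,
                          min_genes = 200, max_genes = Inf,
                          max_mito = 0.15, cluster_lowq_cutoff = 0.33) {
  if (min_umi > max_umi || min_genes > max_genes) {
    stop("min bound exceeds max bound")
  }
  structure(list(min_umi = min_umi, max_umi = max_umi,
                 min_genes = min_genes, max_genes = max_genes,
                 max_mito = max_mito,
                 cluster_lowq_cutoff = cluster_lowq_cutoff),
            class = "qc_thresholds")
}

#' Flag low-quality cells against thresholds
#'
#' Cells are flagged, not removed: removal happens per cluster in
#' [drop_low_quality_clusters()]. All-zero (degenerate) cells are always
#' flagged.
#'
#' @param qc data.frame from [compute_qc()].
#' @param thresholds A `qc_thresholds` object.
#' @return `qc` with the `low_quality` column filled in.
#' @export
apply_thresholds <- function(qc, thresholds) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  t <- thresholds
  qc$low_quality <- qc$degenerate |
    qc$total_umi < t$min_umi | qc$total_umi > t$max_umi |
    qc$n_genes < t$min_genes | qc$n_genes > t$max_genes |
    qc$mito_frac > t$max_mito
  qc
}

#' Exclude low-quality clusters and cells
#'
#' Removes every cell of any cluster whose flagged fraction strictly exceeds
#' `cutoff`, then removes the remaining flagged cells from retained
#' clusters.
#'
#' @param labels Cluster labels, one per cell.
#' @param low_quality Logical flags aligned with `labels`.
#' @param cutoff Flagged-fraction cutoff (default 0.33; a cluster at exactly
#'   the cutoff is retained).
#' @return Logical vector: `TRUE` for retained cells.
#' @export
drop_low_quality_clusters <- function(labels, low_quality, cutoff = 0.33) {
  stopifnot(length(labels) == length(low_quality))
  frac <- tapply(low_quality, labels, mean)
  bad_clusters <- names(frac)[frac > cutoff]
  !(as.character(labels) %in% bad_clusters) & !low_quality
}
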