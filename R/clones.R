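#' Jointly cluster malignant cells into subclones by CNV profile
#'
#' Partitions diagnosis and relapse malignant cells together on their
#' smoothed copy-number residual profiles, so subclone labels are shared
#' across timepoints. Either graph-based Leiden clustering (on a PCA of the
#' profiles) or Ward.D2 hierarchical clustering cut at a fixed cluster count.
#'
#' @param profiles Cells x genes matrix of smoothed centered residuals
#'   (malignant cells from both timepoints).
#' @param method `"leiden"` or `"ward"`.
#' @param k Neighbors for the Leiden graph (default 15).
#' @param resolution Leiden resolution (default 0.05; subclone structure is
#'   coarse, and CNV profile blobs are large and dense, so a low resolution
#'   avoids modularity-driven splitting of homogeneous clones).
#' @param n_clusters Cluster count for the Ward dendrogram cut.
#' @param seed Seed for the Leiden refinement.
#' @return Integer subclone labels named by cell.
#' @export
cluster_subclones <- function(profiles, method = c("leiden", "ward"),
                              k = 15, resolution = 0.05, n_clusters = 3,
                              seed = 0L) {
  method <- match.arg(method)
  if (nrow(profiles) < 2) stop("need at least 2 cells")
  if (!all(is.finite(profiles))) stop("profiles must be finite")
  if (method == "leiden") {
    x <- sweep(profiles, 2, colMeans(profiles))
    emb <- pca_embed(x, variance_fraction = 0.015, max_components = 30)
    labels <- knn_leiden(emb$scores, k = min(k, nrow(profiles) - 1),
                         resolution = resolution, seed = seed)
  } else {
    hc <- stats::hclust(stats::dist(profiles), method = "ward.D2")
    labels <- stats::cutree(hc, k = n_clusters)
  }
  names(labels) <- rownames(profiles)
  labels
}

#' Subclone composition by sample
#'
#' Cross-tabulates subclone assignments against samples and normalizes to
#' per-sample proportions.
#'
#' @param assignment Subclone label per cell (named by cell).
#' @param cell_meta data.frame with `cell`, `sample`, `timepoint` covering
#'   the assigned cells.
#' @return data.frame: subclone, sample, timepoint, count, proportion; one
#'   row per subclone x sample (absent combinations have count 0).
#' @export
composition_table <- function(assignment, cell_meta) {
  meta <- cell_meta[match(names(assignment), cell_meta$cell), ]
  if (anyNA(meta$sample)) stop("cells missing from metadata")
  tab <- table(subclone = as.character(assignment), sample = meta$sample)
  tp <- vapply(colnames(tab), function(s)
    meta$timepoint[match(s, meta$sample)], character(1))
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out)[names(out) == "Freq"] <- "count"
  out$timepoint <- tp[out$sample]
  totals <- tapply(out$count, out$sample, sum)
  out$proportion <- ifelse(totals[out$sample] > 0,
                           out$count / totals[out$sample], 0)
  out[order(out$subclone, out$sample),
      c("subclone", "sample", "timepoint", "count", "proportion")]
}

#' Classify subclones as therapy-resistant or therapy-sensitive
#'
#' A subclone is therapy-resistant when it expanded or persisted from
#' diagnosis to relapse and therapy-sensitive when it was depleted or
#' reduced, operationalized by the ratio
#' `r = (p_rel + eps) / (p_dg + eps) >= theta`. With multiple relapse
#' compartments the ratio is computed per compartment and the combined label
#' is resistant if resistant in any of them. Subclones with zero diagnostic
#' cells are labeled `relapse_specific`.
#'
#' @param composition data.frame from [composition_table()].
#' @param theta Expansion/persistence ratio threshold (default 0.8: up to a
#'   20% relative drop still counts as persistent).
#' @param eps Pseudo-proportion; default half a cell's worth at diagnosis,
#'   `1 / (2 * n_dg)`.
#' @return data.frame: subclone, p_dg, p_rel (mean over relapse
#'   compartments), r (max over compartments), label.
#' @export
classify_resistance <- function(composition, theta = 0.8, eps = NULL) {
  dg <- composition[composition$timepoint == "diagnosis", ]
  rel <- composition[composition$timepoint == "relapse", ]
  if (length(unique(dg$sample)) != 1) stop("exactly one diagnosis sample required")
  if (nrow(rel) == 0) stop("no relapse sample present")
  n_dg <- sum(dg$count)
  if (is.null(eps)) eps <- 1 / (2 * n_dg)
  subclones <- unique(composition$subclone)
  out <- lapply(subclones, function(sc) {
    p_dg <- dg$proportion[dg$subclone == sc]
    if (!length(p_dg)) p_dg <- 0
    prel <- rel$proportion[rel$subclone == sc]
    r <- (prel + eps) / (p_dg + eps)
    n_dg_sc <- sum(dg$count[dg$subclone == sc])
    label <- if (n_dg_sc == 0) "relapse_specific"
      else if (any(r >= theta)) "resistant" else "sensitive"
    data.frame(subclone = sc, p_dg = p_dg, p_rel = mean(prel),
               r = max(r), label = label, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# direction of a binned copy value relative to diploid
.cnv_direction <- function(v, tol = 1e-9) {
  d <- integer(length(v))
  d[!is.na(v) & v > 2 + tol] <- 1L
  d[!is.na(v) & v < 2 - tol] <- -1L
  d[is.na(v)] <- NA_integer_
  d
}

#' Directional Jaccard similarity of two binned copy profiles
#'
#' The number of bins that are non-diploid in both profiles with the same
#' direction (gain/loss), divided by the number of bins non-diploid in
#' either. Symmetric; equals 1 iff the binned non-diploid patterns are
#' identical. Bins missing in either profile are excluded.
#'
#' @param a,b Numeric binned copy-value vectors on the same grid.
#' @return List: `score` (NA when both profiles are fully diploid),
#'   `shared` and `union` bin counts.
#' @export
cnv_profile_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  ok <- !is.na(a) & !is.na(b)
  da <- .cnv_direction(a[ok]); db <- .cnv_direction(b[ok])
  union_ <- sum(da != 0 | db != 0)
  shared <- sum(da != 0 & da == db)
  list(score = if (union_ == 0) NA_real_ else shared / union_,
       shared = shared, union = union_)
}

#' Match a diagnostic subclone to its most similar relapse subclone
#'
#' Bins the segment tables on a common 100 kb grid and scores each relapse
#' subclone by the directional Jaccard similarity of non-diploid bins
#' ([cnv_profile_similarity()]). The best-scoring relapse subclone is called
#' a precursor match when its score reaches `min_score`.
#'
#' @param dg_segments Segment table of the diagnostic subclone (chromosome,
#'   start, end, copy_number).
#' @param relapse_segments Named list of relapse subclone segment tables.
#' @param genome A `genome_model` supplying chromosome lengths.
#' @param bin_size Bin width in bp (default 100000).
#' @param min_score Match threshold on the similarity score (default 0.5).
#' @return data.frame with one row: `best_match`, `score`, `shared_bins`,
#'   `union_bins`, `call`; scores for all candidates attached as attribute
#'   `"scores"`.
#' @export
match_precursor <- function(dg_segments, relapse_segments, genome,
                            bin_size = 100000, min_score = 0.5) {
  a <- bin_segments(dg_segments, genome, bin_size = bin_size)$value
  if (all(.cnv_direction(a) == 0, na.rm = TRUE)) {
    warning("diagnostic profile is fully diploid; precursor score undefined")
    return(data.frame(best_match = NA_character_, score = NA_real_,
                      shared_bins = 0L, union_bins = 0L, call = FALSE,
                      stringsAsFactors = FALSE))
  }
  scores <- vapply(relapse_segments, function(seg) {
    b <- bin_segments(seg, genome, bin_size = bin_size)$value
    s <- cnv_profile_similarity(a, b)$score
    if (is.na(s)) 0 else s
  }, numeric(1))
  best <- names(scores)[which.max(scores)]
  b <- bin_segments(relapse_segments[[best]], genome, bin_size = bin_size)$value
  sim <- cnv_profile_similarity(a, b)
  out <- data.frame(best_match = best, score = sim$score,
                    shared_bins = sim$shared, union_bins = sim$union,
                    call = !is.na(sim$score) && sim$score >= min_score,
                    stringsAsFactors = FALSE)
  attr(out, "scores") <- scores
  out
}

#' Validate subclone segments against bulk segments
#'
#' Retains a subclone segment only when it overlaps (shares at least one bp
#' with) a bulk segment whose copy number deviates from 2 in the same
#' direction -- keeping only concordant gains or losses.
#'
#' @param subclone_segments Segment table of inferred subclone events
#'   (chromosome, start, end, copy_number; diploid rows are never retained).
#' @param bulk_segments Bulk segment table on the same genome.
#' @return The concordant subset of `subclone_segments`.
#' @export
validate_subclone_cnv <- function(subclone_segments, bulk_segments) {
  if (!nrow(subclone_segments)) return(subclone_segments)
  keep <- logical(nrow(subclone_segments))
  sdir <- .cnv_direction(subclone_segments$copy_number)
  bdir <- .cnv_direction(bulk_segments$copy_number)
  for (i in seq_len(nrow(subclone_segments))) {
    if (sdir[i] == 0) next
    ov <- bulk_segments$chromosome == subclone_segments$chromosome[i] &
      bulk_segments$start <= subclone_segments$end[i] &
      bulk_segments$end >= subclone_segments$start[i] &
      bdir == sdir[i]
    keep[i] <- any(ov)
  }
  subclone_segments[keep, , drop = FALSE]
}
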