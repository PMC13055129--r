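#' Benjamini-Hochberg adjustment with validation
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Step-up adjusted p-values (capped at 1).
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# Exact two-sided rank-sum p by dynamic programming over doubled ranks
# (doubling makes average ranks integral), i.e. full permutation
# enumeration of which nA of the N observations form group A.
ranksum_exact_p <- function(ranks2, a_idx) {
  nA <- length(a_idx)
  w_obs <- sum(ranks2[a_idx])
  maxS <- sum(sort(ranks2, decreasing = TRUE)[seq_len(nA)])
  # f[j+1, s+1] = number of nA-subsets of size j with doubled-rank sum s
  f <- matrix(0, nA + 1, maxS + 1)
  f[1, 1] <- 1
  for (r in ranks2) {
    jmax <- nA:1
    for (j in jmax) {
      cols <- which(f[j, ] > 0)
      tgt <- cols + r
      keep <- tgt <= maxS + 1
      f[j + 1, tgt[keep]] <- f[j + 1, tgt[keep]] + f[j, cols[keep]]
    }
  }
  dist <- f[nA + 1, ]
  total <- sum(dist)
  sums <- seq_along(dist) - 1
  mu <- sum(dist * sums) / total
  p <- sum(dist[abs(sums - mu) >= abs(w_obs - mu) - 1e-9]) / total
  min(1, p)
}

# Normal-approximation two-sided rank-sum p with tie correction.
ranksum_normal_p <- function(ranks, a_idx, n) {
  nA <- length(a_idx); nB <- n - nA
  w <- sum(ranks[a_idx])
  mu <- nA * (n + 1) / 2
  ties <- table(ranks)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- nA * nB / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(1)
  # continuity correction, as in the classical large-sample test
  2 * stats::pnorm(-max(abs(w - mu) - 0.5, 0) / sqrt(sigma2))
}

#' Wilcoxon rank-sum differential expression
#'
#' Tests genes passing the standard pre-filters: absolute log2 fold change
#' (difference of group means of `log2(1 + expr)`) at least `min_lfc` and
#' expression in at least `min_frac` of cells of either group. P-values use
#' average ranks; groups of at most 25 cells each are tested by exact
#' permutation enumeration (dynamic programming over rank sums), larger
#' groups by the tie-corrected normal approximation. BH adjustment is
#' applied over the tested genes.
#'
#' @param norm Cells x genes normalized matrix (natural-log scale; log2
#'   fold changes are derived by rescaling).
#' @param cells_a,cells_b Disjoint cell index/name vectors (>= 3 cells
#'   each).
#' @param min_lfc Pre-filter on |log2FC| (default 0.25).
#' @param min_frac Pre-filter on the expressing fraction (default 0.10).
#' @param exact_max Largest group size tested exactly (default 25).
#' @return data.frame: gene, l2fc (A minus B), frac_a, frac_b, p, adj_p;
#'   zero rows when no gene passes the pre-filter.
#' @export
wilcoxon_de <- function(norm, cells_a, cells_b, min_lfc = 0.25,
                        min_frac = 0.10, exact_max = 25) {
  a <- norm[cells_a, , drop = FALSE]
  b <- norm[cells_b, , drop = FALSE]
  if (nrow(a) < 3 || nrow(b) < 3) stop("each group needs >= 3 cells")
  if (length(intersect(rownames(a), rownames(b)))) stop("groups must be disjoint")
  l2fc <- (Matrix::colMeans(a) - Matrix::colMeans(b)) / log(2)
  frac_a <- Matrix::colMeans(a > 0)
  frac_b <- Matrix::colMeans(b > 0)
  test <- abs(l2fc) >= min_lfc & (frac_a >= min_frac | frac_b >= min_frac)
  genes <- colnames(norm)[test]
  if (!length(genes)) {
    return(data.frame(gene = character(), l2fc = numeric(),
                      frac_a = numeric(), frac_b = numeric(),
                      p = numeric(), adj_p = numeric(),
                      stringsAsFactors = FALSE))
  }
  nA <- nrow(a); nB <- nrow(b); n <- nA + nB
  exact <- max(nA, nB) <= exact_max
  p <- vapply(genes, function(g) {
    vals <- c(a[, g], b[, g])
    r <- rank(vals)
    if (exact) ranksum_exact_p(as.integer(round(2 * r)), seq_len(nA))
    else ranksum_normal_p(r, seq_len(nA), n)
  }, numeric(1))
  data.frame(gene = genes, l2fc = l2fc[test], frac_a = frac_a[test],
             frac_b = frac_b[test], p = p, adj_p = bh_adjust(p),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter a DE table to significant genes
#'
#' Significance requires adjusted p below `max_adj_p`, |log2FC| above
#' `min_abs_l2fc`, and expression in more than `min_frac` of the cells of
#' the higher-expressing group.
#'
#' @param de data.frame from [wilcoxon_de()].
#' @param max_adj_p,min_abs_l2fc,min_frac Thresholds (defaults 0.05, 0.8,
#'   0.25; all strict).
#' @return Character vector of significant genes.
#' @export
significant_genes <- function(de, max_adj_p = 0.05, min_abs_l2fc = 0.8,
                              min_frac = 0.25) {
  if (!nrow(de)) return(character())
  frac_high <- ifelse(de$l2fc > 0, de$frac_a, de$frac_b)
  de$gene[de$adj_p < max_adj_p & abs(de$l2fc) > min_abs_l2fc &
            frac_high > min_frac]
}

# ES of one gene set given hit positions in a ranked list.
# scores: |ranking metric| per position (descending list); weight applied
# already. Returns the signed running-sum extremum.
gsea_es <- function(hit_pos, scores_w, n) {
  m <- length(hit_pos)
  hit_pos <- sort(hit_pos)
  inc <- scores_w[hit_pos]
  if (sum(inc) == 0) inc <- rep(1, m)  # all-zero metric: fall back to uniform
  p_hit <- cumsum(inc) / sum(inc)
  miss <- (hit_pos - seq_len(m)) / (n - m)
  top <- max(p_hit - miss)              # running sum just after each hit
  bottom <- min(c(0, p_hit[-m]) - miss) # running sum just before each hit
  if (top >= abs(bottom)) top else bottom
}

#' Preranked gene set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov running-sum enrichment on a ranked gene list:
#' hits increment proportionally to |score|^weight, misses decrement
#' uniformly; ES is the signed extremum. The null is gene-label permutation
#' within the ranked list; NES divides ES by the mean |null ES| of matching
#' sign, and `p = (1 + #(|null ES| >= |ES|)) / (n_perm + 1)` (two-sided, so
#' null p-values are uniform regardless of the ES sign split). BH
#' adjustment across sets.
#'
#' @param scores Named numeric ranking metric (e.g. log2FC), no duplicate
#'   names; sorted internally in decreasing order.
#' @param gene_sets Named list of gene id vectors; sets are intersected with
#'   the ranked universe and sets smaller than `min_size` skipped with a
#'   message.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Permutation seed.
#' @param weight KS weight exponent (default 1; 0 gives the unweighted KS
#'   statistic whose running sum returns to 0).
#' @param min_size Minimum set size after intersection (default 5).
#' @return data.frame: set, size, es, nes, p, adj_p.
#' @export
preranked_gsea <- function(scores, gene_sets, n_perm = 1000, seed = 0L,
                           weight = 1, min_size = 5) {
  if (anyDuplicated(names(scores))) stop("duplicate genes in ranked list")
  ord <- order(scores, decreasing = TRUE)
  scores <- scores[ord]
  n <- length(scores)
  sw <- abs(scores)^weight
  set.seed(seed)
  res <- list()
  for (nm in names(gene_sets)) {
    hits <- which(names(scores) %in% gene_sets[[nm]])
    m <- length(hits)
    if (m < min_size || m >= n) {
      message("skipping set '", nm, "' (size ", m, " after intersection)")
      next
    }
    es <- gsea_es(hits, sw, n)
    null_es <- vapply(seq_len(n_perm), function(i) {
      gsea_es(sample.int(n, m), sw, n)
    }, numeric(1))
    same <- null_es[sign(null_es) == sign(es)]
    nes <- if (length(same)) es / mean(abs(same)) else NA_real_
    p <- (1 + sum(abs(null_es) >= abs(es))) / (n_perm + 1)
    res[[nm]] <- data.frame(set = nm, size = m, es = es, nes = nes, p = p,
                            stringsAsFactors = FALSE)
  }
  if (!length(res)) {
    return(data.frame(set = character(), size = integer(), es = numeric(),
                      nes = numeric(), p = numeric(), adj_p = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out$adj_p <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}

#' Expression-bin-matched module score
#'
#' Scores each cell for a gene program as the mean expression of the set
#' minus the mean expression of control genes drawn, for each set gene,
#' from the same average-expression bin (quantile bins of the genome-wide
#' average). Scores of a set behaving like the background center at 0.
#'
#' @param norm Cells x genes normalized matrix.
#' @param gene_set Character vector of program genes.
#' @param n_bins Number of average-expression bins (default 24).
#' @param n_control Controls drawn per set gene (default 100; capped at the
#'   bin size, so passing `Inf` uses every gene of the bin).
#' @param seed Sampling seed.
#' @return Numeric per-cell score named by cell.
#' @export
module_score <- function(norm, gene_set, n_bins = 24, n_control = 100,
                         seed = 0L) {
  gene_set <- intersect(gene_set, colnames(norm))
  if (!length(gene_set)) stop("gene set empty after intersection with matrix")
  if (ncol(norm) < n_bins) stop("need at least n_bins genes")
  avg <- Matrix::colMeans(norm)
  qs <- unique(stats::quantile(avg, probs = seq(0, 1, length.out = n_bins + 1)))
  bins <- cut(avg, breaks = qs, include.lowest = TRUE, labels = FALSE)
  names(bins) <- colnames(norm)
  set.seed(seed)
  controls <- unlist(lapply(gene_set, function(g) {
    pool <- names(bins)[bins == bins[g]]
    pool <- setdiff(pool, g)
    if (!length(pool)) return(character())
    sample(pool, min(n_control, length(pool)))
  }))
  set_mean <- Matrix::rowMeans(norm[, gene_set, drop = FALSE])
  # control mean over the sampled multiset (duplicates count)
  ctrl <- norm[, controls, drop = FALSE]
  ctrl_mean <- Matrix::rowMeans(ctrl)
  out <- set_mean - ctrl_mean
  names(out) <- rownames(norm)
  out
}

#' Assign cell-cycle phases from S and G2/M scores
#'
#' G1 when both scores are non-positive; otherwise the phase of the larger
#' score. An exact positive tie goes to S with a warning.
#'
#' @param s_scores,g2m_scores Aligned per-cell module scores.
#' @return Character vector of phases in {G1, S, G2M}.
#' @export
assign_phase <- function(s_scores, g2m_scores) {
  stopifnot(length(s_scores) == length(g2m_scores))
  phase <- rep("G1", length(s_scores))
  pos <- s_scores > 0 | g2m_scores > 0
  tie <- pos & s_scores == g2m_scores
  if (any(tie)) warning(sum(tie), " exact positive score ties assigned to S")
  phase[pos] <- ifelse(s_scores[pos] >= g2m_scores[pos], "S", "G2M")
  phase
}

#' Chi-square test of phase-composition shift per patient
#'
#' Pearson chi-square on the 2 x 3 (timepoint x phase) contingency table of
#' each patient, with BH correction across patients. Phases absent at both
#' timepoints are collapsed out of the table (reducing the degrees of
#' freedom) with a warning.
#'
#' @param tables Named list of 2 x 3 matrices (rows: diagnosis, relapse;
#'   columns: G1, S, G2M) of cell counts.
#' @return data.frame: patient, statistic, df, p, adj_p.
#' @export
phase_shift_test <- function(tables) {
  res <- lapply(names(tables), function(pt) {
    tab <- tables[[pt]]
    empty <- colSums(tab) == 0
    if (any(empty)) {
      warning("patient ", pt, ": collapsing phases absent at both timepoints: ",
              paste(colnames(tab)[empty], collapse = ", "))
      tab <- tab[, !empty, drop = FALSE]
    }
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    data.frame(patient = pt, statistic = unname(ct$statistic),
               df = unname(ct$parameter), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$adj_p <- bh_adjust(out$p)
  out
}
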