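#' Log-normalize a counts matrix
#'
#' Per-cell library-size normalization followed by a natural-log transform:
#' entry = `log(1 + count * scale / cell_total)`. A row (cell) operation
#' only; each cell's normalized vector is independent of all other cells.
#'
#' @param counts Cells x genes matrix of non-negative integers.
#' @param scale Scale factor (default 1e4).
#' @return Sparse cells x genes matrix of normalized log expression.
#' @export
log_normalize <- function(counts, scale = 1e4) {
  totals <- Matrix::rowSums(counts)
  if (any(totals == 0)) {
    bad <- rownames(counts)[which(totals == 0)]
    stop("cells with zero total counts cannot be normalized: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  x <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  x <- Matrix::Diagonal(x = scale / totals) %*% x
  x@x <- log1p(x@x)
  dimnames(x) <- dimnames(counts)
  x
}

#' Select highly variable genes by variance-stabilized standardized variance
#'
#' Ranks genes the way a VST-based selection does: a smooth mean-variance
#' trend (quadratic fit of log10 variance on log10 mean of the raw counts)
#' predicts each gene's expected sd; raw counts are standardized by the
#' predicted sd, clipped at `sqrt(n_cells)`, and genes are ranked by the
#' variance of the clipped standardized values.
#'
#' @param counts Cells x genes raw counts (sparse).
#' @param n_top Number of genes to select (default 2000).
#' @return Character vector of selected gene names, ordered by decreasing
#'   standardized variance; the full ranking is attached as attribute
#'   `"standardized_variance"`.
#' @export
select_hvg <- function(counts, n_top = 2000) {
  if (n_top > ncol(counts)) stop("n_top exceeds number of genes")
  x <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  n <- nrow(x)
  mu <- Matrix::colMeans(x)
  ex2 <- Matrix::colMeans(x^2)
  v <- (ex2 - mu^2) * n / (n - 1)

  fit_ok <- mu > 0 & v > 0
  lm_fit <- stats::lm(lv ~ stats::poly(lm10, 2),
                      data = data.frame(lv = log10(v[fit_ok]), lm10 = log10(mu[fit_ok])))
  sd_pred <- rep(NA_real_, ncol(x))
  sd_pred[fit_ok] <- sqrt(10^stats::predict(lm_fit))

  clip <- sqrt(n)
  std_var <- numeric(ncol(x))
  p <- x@p; xi <- x@i; xv <- x@x
  for (j in seq_len(ncol(x))) {
    if (!fit_ok[j]) { std_var[j] <- 0; next }
    nz <- if (p[j + 1] > p[j]) xv[(p[j] + 1):p[j + 1]] else numeric(0)
    z_nz <- pmin(pmax((nz - mu[j]) / sd_pred[j], -clip), clip)
    z0 <- pmin(pmax(-mu[j] / sd_pred[j], -clip), clip)
    n0 <- n - length(z_nz)
    s1 <- sum(z_nz) + n0 * z0
    s2 <- sum(z_nz^2) + n0 * z0^2
    std_var[j] <- (s2 - s1^2 / n) / (n - 1)
  }
  names(std_var) <- colnames(x)
  ord <- order(std_var, decreasing = TRUE)
  sel <- colnames(x)[ord[seq_len(n_top)]]
  attr(sel, "standardized_variance") <- std_var
  sel
}

#' Scale genes to zero mean and unit variance
#'
#' @param norm Cells x genes matrix (usually normalized log expression
#'   restricted to highly variable genes).
#' @param max_value Clip absolute scaled values (default 10, the common
#'   practice to bound outlier leverage).
#' @return Dense cells x genes matrix; zero-variance genes become all-zero
#'   columns.
#' @export
scale_genes <- function(norm, max_value = 10) {
  x <- as.matrix(norm)
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd == 0] <- Inf
  x <- sweep(sweep(x, 2, mu), 2, sd, "/")
  pmin(pmax(x, -max_value), max_value)
}

#' PCA embedding retaining components by explained variance
#'
#' Eigendecomposition of the gene-gene covariance (or the cell-cell Gram
#' matrix when cells are fewer than genes, which yields identical non-null
#' components). Components whose individual explained-variance fraction is
#' at least `variance_fraction` are kept, with a floor of 2 components.
#' Loadings are sign-fixed so the largest-magnitude loading of each
#' component is positive, making the embedding deterministic.
#'
#' @param x Dense cells x genes matrix, genes already scaled to zero mean
#'   and unit variance (see [scale_genes()]).
#' @param variance_fraction Per-component explained-variance threshold
#'   (default 0.015).
#' @param max_components Upper bound on returned components (default 50).
#' @return List with `scores` (cells x k), `loadings` (genes x k),
#'   `var_fraction` (per component, all computed components) and `k`.
#' @export
pca_embed <- function(x, variance_fraction = 0.015, max_components = 50) {
  n <- nrow(x)
  if (n < 2) stop("need at least 2 cells for PCA")
  total_var <- sum(x^2) / (n - 1)
  if (ncol(x) <= n) {
    cv <- crossprod(x) / (n - 1)
    eig <- eigen(cv, symmetric = TRUE)
    vals <- pmax(eig$values, 0)
    load <- eig$vectors
    scores_all <- x %*% load
  } else {
    gr <- tcrossprod(x) / (n - 1)
    eig <- eigen(gr, symmetric = TRUE)
    vals <- pmax(eig$values, 0)
    pos <- vals > 1e-12
    u <- eig$vectors[, pos, drop = FALSE]
    vals <- vals[pos]
    load <- crossprod(x, u) %*% diag(1 / sqrt(vals * (n - 1)), length(vals))
    scores_all <- u %*% diag(sqrt(vals * (n - 1)), length(vals))
  }
  var_fraction <- vals / total_var
  k <- max(2, sum(var_fraction >= variance_fraction))
  k <- min(k, length(vals), max_components, n - 1)
  load <- load[, seq_len(k), drop = FALSE]
  scores <- scores_all[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (load[which.max(abs(load[, j])), j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- rownames(x)
  rownames(load) <- colnames(x)
  list(scores = scores, loadings = load,
       var_fraction = var_fraction, k = k)
}
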