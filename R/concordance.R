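#' Bin a segment table on a uniform genomic grid
#'
#' Tiles each autosome with fixed-width bins starting at position 1 and
#' assigns each bin the mean copy number of all overlapping segments.
#' Following the stated dialect, the mean is unweighted across distinct
#' overlapping segments; a bp-weighted mean is available behind
#' `bp_weighted = TRUE`. Bins no segment touches are `NA`. Coordinates are
#' 1-based closed. Sex chromosomes (chrX/chrY) are dropped with a message.
#'
#' @param segments Segment table (chromosome, start, end, copy_number).
#' @param genome A `genome_model` supplying chromosome lengths.
#' @param bin_size Bin width in bp (default 100000).
#' @param bp_weighted Weight overlapping segments by covered bp instead of
#'   equally (default FALSE).
#' @return data.frame of class `binned_profile`: chromosome, start, end,
#'   `value`; attribute `bin_size`.
#' @export
bin_segments <- function(segments, genome, bin_size = 100000,
                         bp_weighted = FALSE) {
  if (bin_size <= 0) stop("bin_size must be positive")
  sex <- grepl("^(chr)?[XY]$", segments$chromosome)
  if (any(sex)) {
    message("dropping ", sum(sex), " sex-chromosome segments")
    segments <- segments[!sex, , drop = FALSE]
  }
  chroms <- genome$chromosomes[!grepl("^(chr)?[XY]$", genome$chromosomes$chromosome), ]
  out <- list()
  for (ci in seq_len(nrow(chroms))) {
    chr <- chroms$chromosome[ci]
    len <- chroms$length[ci]
    starts <- seq(1, len, by = bin_size)
    ends <- pmin(starts + bin_size - 1, len)
    acc <- numeric(length(starts)); wgt <- numeric(length(starts))
    segs <- segments[segments$chromosome == chr, , drop = FALSE]
    for (i in seq_len(nrow(segs))) {
      lo <- floor((segs$start[i] - 1) / bin_size) + 1
      hi <- floor((min(segs$end[i], len) - 1) / bin_size) + 1
      if (lo > length(starts)) next
      idx <- lo:min(hi, length(starts))
      w <- if (bp_weighted) {
        pmin(ends[idx], segs$end[i]) - pmax(starts[idx], segs$start[i]) + 1
      } else rep(1, length(idx))
      acc[idx] <- acc[idx] + w * segs$copy_number[i]
      wgt[idx] <- wgt[idx] + w
    }
    out[[chr]] <- data.frame(chromosome = chr, start = starts, end = ends,
                             value = ifelse(wgt > 0, acc / wgt, NA_real_),
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "bin_size") <- bin_size
  class(res) <- c("binned_profile", "data.frame")
  res
}

#' Subtract the diploid baseline from a binned profile
#'
#' @param profile A `binned_profile`.
#' @return The profile with every present bin decremented by 2; missing
#'   bins stay missing.
#' @export
normalize_baseline <- function(profile) {
  profile$value <- profile$value - 2
  profile
}

#' Spearman concordance of two binned copy profiles
#'
#' Spearman's rank correlation (average ranks for ties, two-sided test) over
#' bins present in both profiles. Undefined (NA with `defined = FALSE`) when
#' fewer than 3 shared bins exist or either profile is constant on them.
#'
#' @param a,b `binned_profile` objects on the same bin grid.
#' @return List: `rho`, `p_value`, `n` shared bins, `defined`.
#' @export
spearman_concordance <- function(a, b) {
  if (nrow(a) != nrow(b) || !all(a$start == b$start & a$chromosome == b$chromosome)) {
    stop("profiles are not on the same bin grid")
  }
  ok <- !is.na(a$value) & !is.na(b$value)
  x <- a$value[ok]; y <- b$value[ok]
  n <- sum(ok)
  if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("Spearman concordance undefined: need >= 3 shared bins and non-constant profiles")
    return(list(rho = NA_real_, p_value = NA_real_, n = n, defined = FALSE))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         alternative = "two.sided", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = n, defined = TRUE)
}
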