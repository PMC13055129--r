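#' Plant a clonal CNV architecture
#'
#' Expands a parent/child subclone specification into fully-resolved
#' subclones: each subclone's effective copy-number profile is its ancestors'
#' events overlaid in root-to-leaf order with private events overriding
#' inherited ones on overlap. Every subclone receives a full-coverage segment
#' table (constant-copy runs over every chromosome) derived from the overlay.
#'
#' @param genome A `genome_model`.
#' @param spec A list of subclone specifications, each a list with fields
#'   `id`, `parent` (`NA` for a founder), `events` (data.frame with columns
#'   chromosome, start, end, copy_number; may have zero rows) and
#'   `proportions` (named numeric, one entry per sample; per-sample values
#'   must sum to 1 across subclones). Parents must precede children.
#'
#' @return A list of `subclone` objects, each with `id`, `parent`,
#'   `private_events`, `proportions`, `segments` (full-coverage segment
#'   table with columns chromosome, start, end, copy_number) and `events`
#'   (the non-diploid rows of `segments`).
#' @export
plant_clonal_architecture <- function(genome, spec) {
  validate_genome(genome)
  ids <- vapply(spec, function(s) s$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate subclone ids")

  # per-sample proportions must sum to 1 over subclones
  samples <- unique(unlist(lapply(spec, function(s) names(s$proportions))))
  for (sm in samples) {
    tot <- sum(vapply(spec, function(s) {
      p <- s$proportions[[sm]]
      if (is.null(p) || is.na(p)) 0 else p
    }, numeric(1)))
    if (abs(tot - 1) > 1e-9) {
      stop(sprintf("subclone proportions for sample '%s' sum to %.12g, not 1", sm, tot))
    }
  }

  diploid <- data.frame(
    chromosome = genome$chromosomes$chromosome,
    start = 1,
    end = genome$chromosomes$length,
    copy_number = 2,
    stringsAsFactors = FALSE
  )

  out <- list()
  for (s in spec) {
    parent <- s$parent
    if (is.null(parent) || (length(parent) == 1 && is.na(parent))) {
      base <- diploid
    } else {
      if (is.null(out[[parent]])) stop("parent '", parent, "' not defined before child '", s$id, "'")
      base <- out[[parent]]$segments
    }
    segs <- base
    ev <- s$events
    if (!is.null(ev) && nrow(ev) > 0) {
      check_events(genome, ev)
      for (j in seq_len(nrow(ev))) {
        segs <- overlay_segment(segs, ev$chromosome[j], ev$start[j], ev$end[j],
                                ev$copy_number[j])
      }
    }
    segs <- merge_equal_runs(segs, genome)
    out[[s$id]] <- structure(
      list(id = s$id, parent = if (is.null(parent)) NA_character_ else parent,
           private_events = if (is.null(ev)) ev_empty() else ev,
           proportions = unlist(s$proportions),
           segments = segs,
           events = segs[segs$copy_number != 2, , drop = FALSE]),
      class = "subclone"
    )
  }
  out
}

ev_empty <- function() {
  data.frame(chromosome = character(), start = numeric(), end = numeric(),
             copy_number = numeric(), stringsAsFactors = FALSE)
}

check_events <- function(genome, ev) {
  stopifnot(all(c("chromosome", "start", "end", "copy_number") %in% names(ev)))
  if (any(ev$start >= ev$end)) stop("event with start >= end")
  if (any(ev$copy_number == 2)) stop("events must depart from the diploid state (copy_number != 2)")
  if (any(ev$copy_number < 0 | ev$copy_number > 6)) stop("copy_number outside [0, 6]")
  m <- match(ev$chromosome, genome$chromosomes$chromosome)
  if (anyNA(m)) stop("event on unknown chromosome")
  if (any(ev$start < 1) || any(ev$end > genome$chromosomes$length[m])) {
    stop("event outside chromosome bounds")
  }
}

# Overwrite [start, end] on one chromosome with copy `cn`, splitting
# overlapped runs. Coordinates are 1-based closed.
overlay_segment <- function(segs, chr, start, end, cn) {
  on <- segs$chromosome == chr
  keep <- segs[!on, , drop = FALSE]
  cur <- segs[on, , drop = FALSE]
  pieces <- list()
  for (i in seq_len(nrow(cur))) {
    s <- cur$start[i]; e <- cur$end[i]; v <- cur$copy_number[i]
    if (e < start || s > end) {
      pieces[[length(pieces) + 1]] <- c(s, e, v)
      next
    }
    if (s < start) pieces[[length(pieces) + 1]] <- c(s, start - 1, v)
    if (e > end) pieces[[length(pieces) + 1]] <- c(end + 1, e, v)
  }
  pieces[[length(pieces) + 1]] <- c(start, end, cn)
  m <- do.call(rbind, pieces)
  m <- m[order(m[, 1]), , drop = FALSE]
  rbind(keep, data.frame(chromosome = chr, start = m[, 1], end = m[, 2],
                         copy_number = m[, 3], stringsAsFactors = FALSE))
}

merge_equal_runs <- function(segs, genome) {
  out <- list()
  for (chr in genome$chromosomes$chromosome) {
    sc <- segs[segs$chromosome == chr, , drop = FALSE]
    sc <- sc[order(sc$start), , drop = FALSE]
    if (nrow(sc) == 0) next
    runs <- list(sc[1, ])
    for (i in seq_len(nrow(sc))[-1]) {
      last <- runs[[length(runs)]]
      if (sc$copy_number[i] == last$copy_number && sc$start[i] == last$end + 1) {
        runs[[length(runs)]]$end <- sc$end[i]
      } else {
        runs[[length(runs) + 1]] <- sc[i, ]
      }
    }
    out[[chr]] <- do.call(rbind, runs)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Copy number of each gene in a subclone (by the segment covering the gene
# start; events in practice align between genes, so the choice only matters
# for breakpoint-straddling genes).
gene_copy_numbers <- function(genome, subclone) {
  segs <- subclone$segments
  cn <- rep(2, nrow(genome$genes))
  for (i in seq_len(nrow(segs))) {
    hit <- genome$genes$chromosome == segs$chromosome[i] &
      genome$genes$start >= segs$start[i] & genome$genes$start <= segs$end[i]
    cn[hit] <- segs$copy_number[i]
  }
  cn
}

#' Expected bulk copy-number segments for a sample
#'
#' The expected bulk profile of a sample is the subclone-proportion-weighted
#' mean copy number, computed exactly on `bin_size` bins (bp-weighted within
#' bins where a subclone's copy number changes mid-bin) and merged into
#' constant-value runs.
#'
#' @param genome A `genome_model`.
#' @param subclones List of `subclone` objects from
#'   [plant_clonal_architecture()].
#' @param sample Sample id; every subclone must carry a proportion for it.
#' @param bin_size Bin width in bp used to discretize the expectation.
#'
#' @return A segment table (chromosome, start, end, copy_number) covering the
#'   genome, with real-valued mixture copy numbers.
#' @export
truth_bulk_segments <- function(genome, subclones, sample, bin_size = 100000) {
  props <- vapply(subclones, function(s) {
    p <- s$proportions[[sample]]
    if (is.null(p) || is.na(p)) stop("sample '", sample, "' unknown for subclone ", s$id)
    p
  }, numeric(1))
  out <- list()
  for (ci in seq_len(nrow(genome$chromosomes))) {
    chr <- genome$chromosomes$chromosome[ci]
    len <- genome$chromosomes$length[ci]
    starts <- seq(1, len, by = bin_size)
    ends <- pmin(starts + bin_size - 1, len)
    val <- numeric(length(starts))
    for (k in seq_along(subclones)) {
      segs <- subclones[[k]]$segments
      segs <- segs[segs$chromosome == chr, , drop = FALSE]
      val <- val + props[k] * bin_mean_bp_weighted(starts, ends, segs)
    }
    out[[chr]] <- data.frame(chromosome = chr, start = starts, end = ends,
                             copy_number = val, stringsAsFactors = FALSE)
  }
  merge_equal_runs(do.call(rbind, out), genome)
}

# bp-weighted mean copy number of full-coverage segments over each bin
bin_mean_bp_weighted <- function(starts, ends, segs) {
  val <- numeric(length(starts))
  wid <- numeric(length(starts))
  for (i in seq_len(nrow(segs))) {
    s <- segs$start[i]; e <- segs$end[i]
    ov_s <- pmax(starts, s); ov_e <- pmin(ends, e)
    w <- pmax(0, ov_e - ov_s + 1)
    val <- val + w * segs$copy_number[i]
    wid <- wid + w
  }
  ifelse(wid > 0, val / wid, NA_real_)
}
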