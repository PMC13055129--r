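#' Write a simulated experiment as a 10x-style triplet
#'
#' Writes `matrix.mtx` (MatrixMarket coordinate integer, genes x cells as in
#' the 10x convention), `features.tsv` (gene metadata incl. coordinates and
#' marker flags), `barcodes.tsv`, `cell_metadata.tsv` (sample, timepoint and
#' truth labels), and truth segment tables per subclone
#' (`truth_segments_<id>.tsv`) and per sample (`truth_bulk_<sample>.tsv`).
#' All coordinates are 1-based closed.
#'
#' @param sim A `sim_experiment`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment_10x <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::t(sim$counts), file.path(dir, "matrix.mtx"))
  utils::write.table(sim$gene_meta, file.path(dir, "features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(rownames(sim$counts), file.path(dir, "barcodes.tsv"))
  utils::write.table(sim$cell_meta, file.path(dir, "cell_metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sim$config)) {
    yaml::write_yaml(sim$config$markers, file.path(dir, "markers.yaml"))
  }
  for (id in names(sim$truth$subclone_segments)) {
    write_segments(sim$truth$subclone_segments[[id]],
                   file.path(dir, paste0("truth_segments_", id, ".tsv")))
  }
  for (sm in names(sim$truth$bulk_segments)) {
    write_segments(sim$truth$bulk_segments[[sm]],
                   file.path(dir, paste0("truth_bulk_", sm, ".tsv")))
  }
  invisible(dir)
}

#' Read a 10x-style triplet
#'
#' @param dir Directory holding `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv` (and optionally `cell_metadata.tsv`).
#' @return List: `counts` (cells x genes sparse integer matrix),
#'   `gene_meta`, `barcodes`, `cell_meta` (NULL when absent).
#' @export
read_counts_10x <- function(dir) {
  for (f in c("matrix.mtx", "features.tsv", "barcodes.tsv")) {
    if (!file.exists(file.path(dir, f))) {
      stop("missing file: ", file.path(dir, f))
    }
  }
  hdr <- readLines(file.path(dir, "matrix.mtx"), n = 50)
  hdr <- hdr[!startsWith(hdr, "%")][1]
  dims <- as.numeric(strsplit(trimws(hdr), "\\s+")[[1]])
  m <- suppressWarnings(Matrix::readMM(file.path(dir, "matrix.mtx")))
  if (length(dims) != 3 || Matrix::nnzero(m) != dims[3]) {
    stop("matrix.mtx header declares ", dims[3], " entries but ",
         Matrix::nnzero(m), " were read")
  }
  feats <- utils::read.delim(file.path(dir, "features.tsv"),
                             stringsAsFactors = FALSE)
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  if (nrow(m) != nrow(feats)) {
    stop("matrix has ", nrow(m), " rows but features.tsv lists ", nrow(feats), " genes")
  }
  if (ncol(m) != length(barcodes)) {
    stop("matrix has ", ncol(m), " columns but barcodes.tsv lists ",
         length(barcodes), " cells")
  }
  if (any(m@x != round(m@x)) || any(m@x < 0)) {
    stop("counts matrix must contain non-negative integers")
  }
  counts <- methods::as(Matrix::t(m), "CsparseMatrix")
  dimnames(counts) <- list(barcodes, feats$gene)
  meta_path <- file.path(dir, "cell_metadata.tsv")
  cell_meta <- if (file.exists(meta_path)) {
    utils::read.delim(meta_path, stringsAsFactors = FALSE)
  } else NULL
  list(counts = counts, gene_meta = feats, barcodes = barcodes,
       cell_meta = cell_meta)
}

#' Write a segment table TSV
#'
#' @param segments data.frame with columns chromosome, start, end,
#'   copy_number (1-based closed coordinates).
#' @param path Output path.
#' @export
write_segments <- function(segments, path) {
  utils::write.table(segments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read and validate a segment table TSV
#'
#' Expects a header with chromosome, start, end, copy_number; rows are
#' sorted by (chromosome, start). Errors name offending rows for
#' start > end, negative copy numbers, or overlapping same-chromosome
#' intervals.
#'
#' @param path Input path.
#' @return Validated, sorted segment table.
#' @export
read_segments <- function(path) {
  seg <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chromosome", "start", "end", "copy_number")
  if (!all(need %in% names(seg))) {
    stop("segment table must have columns: ", paste(need, collapse = ", "))
  }
  bad <- which(seg$start > seg$end)
  if (length(bad)) stop("start > end in rows: ", paste(bad, collapse = ", "))
  if (any(seg$copy_number < 0)) stop("negative copy numbers")
  seg <- seg[order(seg$chromosome, seg$start), ]
  for (chr in unique(seg$chromosome)) {
    sc <- seg[seg$chromosome == chr, ]
    if (nrow(sc) > 1 && any(sc$start[-1] <= sc$end[-nrow(sc)])) {
      i <- which(sc$start[-1] <= sc$end[-nrow(sc)])[1]
      stop("overlapping segments on ", chr, " (rows ",
           rownames(sc)[i], " and ", rownames(sc)[i + 1], ")")
    }
  }
  rownames(seg) <- NULL
  seg
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, tab-separated
#' `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path Input path.
#' @return Named list of gene id vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("malformed GMT line: ", substr(l, 1, 40))
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  sets
}
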