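#' Build a synthetic genome model
#'
#' Lays out `n_chromosomes` autosomes, each carrying `genes_per_chromosome`
#' non-overlapping genes in strictly increasing start order. Gene lengths and
#' intergenic gaps are drawn from uniform distributions so that breakpoints of
#' planted copy-number events never coincide trivially with bin edges.
#'
#' @param n_chromosomes Number of chromosomes (named `chr1..chrN`).
#' @param genes_per_chromosome Genes laid out on each chromosome.
#' @param seed Integer seed; the layout is deterministic given the seed.
#' @param gene_length_range Uniform range (bp) for gene lengths.
#' @param gap_range Uniform range (bp) for intergenic gaps.
#'
#' @return An object of class `genome_model`: a list with
#'   `chromosomes` (data.frame: chromosome, length) and
#'   `genes` (data.frame: gene, chromosome, start, end, genome-ordered).
#' @export
build_genome <- function(n_chromosomes, genes_per_chromosome, seed = 0L,
                         gene_length_range = c(2000, 8000),
                         gap_range = c(1000, 6000)) {
  if (n_chromosomes < 1 || genes_per_chromosome < 1) {
    stop("n_chromosomes and genes_per_chromosome must be >= 1")
  }
  set.seed(seed)
  genes <- vector("list", n_chromosomes)
  chrom_len <- numeric(n_chromosomes)
  chrom_names <- paste0("chr", seq_len(n_chromosomes))
  for (i in seq_len(n_chromosomes)) {
    len <- round(runif(genes_per_chromosome, gene_length_range[1], gene_length_range[2]))
    gap <- round(runif(genes_per_chromosome, gap_range[1], gap_range[2]))
    start <- cumsum(gap) + cumsum(c(0, len[-genes_per_chromosome])) + 1
    end <- start + len - 1
    genes[[i]] <- data.frame(
      gene = sprintf("G%s_%04d", i, seq_len(genes_per_chromosome)),
      chromosome = chrom_names[i],
      start = start, end = end,
      stringsAsFactors = FALSE
    )
    chrom_len[i] <- end[genes_per_chromosome] + round(mean(gap_range))
  }
  genes <- do.call(rbind, genes)
  rownames(genes) <- NULL
  structure(
    list(
      chromosomes = data.frame(chromosome = chrom_names, length = chrom_len,
                               stringsAsFactors = FALSE),
      genes = genes
    ),
    class = "genome_model"
  )
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("genome_model: %d chromosomes, %d genes, %.1f Mb\n",
              nrow(x$chromosomes), nrow(x$genes),
              sum(x$chromosomes$length) / 1e6))
  invisible(x)
}

validate_genome <- function(genome) {
  stopifnot(inherits(genome, "genome_model"))
  g <- genome$genes
  if (anyDuplicated(g$gene)) stop("duplicate gene ids in genome model")
  for (chr in genome$chromosomes$chromosome) {
    gc <- g[g$chromosome == chr, ]
    if (nrow(gc) == 0) next
    if (is.unsorted(gc$start, strictly = TRUE)) {
      stop("gene starts not strictly increasing on ", chr)
    }
    len <- genome$chromosomes$length[genome$chromosomes$chromosome == chr]
    if (any(gc$start < 1) || any(gc$end > len)) {
      stop("gene interval outside chromosome bounds on ", chr)
    }
  }
  invisible(genome)
}

# Position of each gene in genome order (chromosome rank, then start).
genome_gene_order <- function(genome) {
  chr_rank <- match(genome$genes$chromosome, genome$chromosomes$chromosome)
  order(chr_rank, genome$genes$start)
}
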