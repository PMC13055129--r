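#' Simulation configuration
#'
#' Collects every tunable of the synthetic scRNA-seq generator. Counts are
#' drawn from a negative binomial (gamma-Poisson) with mean
#' `libsize * rel_expr * (c/2)^alpha`, where `c` is the gene's copy number in
#' the cell's subclone (2 in normal cells) and homozygous deletions (`c = 0`)
#' are floored at `eps0` times baseline. Malignant cells express a
#' CCND1-like marker highly and exactly one immunoglobulin light chain
#' (light-chain restriction); normal B-like cells mix both chains. A
#' configurable fraction of malignant cells carries an S or G2/M expression
#' program (3x multiplier on the respective gene set).
#'
#' @param genome A `genome_model`; marker genes are chosen from it.
#' @param samples data.frame with columns `sample` and `timepoint`
#'   (`diagnosis` or `relapse`).
#' @param normal_counts Named integer vector: normal cells per cell type per
#'   sample (names must match `names(markers$cell_types)`).
#' @param malignant_count Malignant cells per sample (split across subclones
#'   by their configured proportions via multinomial draws).
#' @param lowq_count Planted low-quality cells per sample (low library size,
#'   high mitochondrial load), for exercising QC.
#' @param gene_mean_shape Gamma shape of the baseline relative expression.
#' @param libsize_meanlog,libsize_sdlog Log-normal library-size parameters
#'   (defaults give a median of ~5000 UMIs).
#' @param dispersion Shared NB size parameter (> 0).
#' @param alpha Dosage exponent: expression scales with `(c/2)^alpha`.
#' @param eps0 Mean multiplier for homozygous deletions.
#' @param marker_boost Fold-boost of cell-type / malignancy marker genes.
#' @param light_restricted Fold-boost of the restricted light chain in
#'   malignant cells (the excluded chain keeps factor 1, giving the
#'   configured restriction ratio, default 20:1).
#' @param light_normal Fold-boost of both light chains in normal B cells.
#' @param restricted_chain Which chain malignant cells are restricted to.
#' @param cycle_fractions Named vector `c(S=, G2M=)` of malignant-cell
#'   fractions carrying each program (defaults reflect the high
#'   proliferative fraction of mantle cell lymphoma); may be a named list
#'   keyed by sample to shift phase composition between timepoints.
#' @param cycle_multiplier Expression multiplier of program gene sets.
#' @param mito_share Target mitochondrial share of a normal transcriptome.
#' @param lowq_mito_boost Extra mitochondrial multiplier in planted
#'   low-quality cells.
#' @param lowq_libsize_factor Library-size shrinkage of low-quality cells.
#' @param markers Marker configuration as built by [default_markers()].
#' @param seed Integer seed; the counts matrix is bit-reproducible given the
#'   full configuration and seed.
#'
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(genome,
                              samples = data.frame(
                                sample = c("Dg", "Rel"),
                                timepoint = c("diagnosis", "relapse"),
                                stringsAsFactors = FALSE),
                              normal_counts = c(B = 150, T = 200, NK = 75, Mono = 75),
                              malignant_count = 1500,
                              lowq_count = 0,
                              gene_mean_shape = 0.6,
                              libsize_meanlog = log(5000),
                              libsize_sdlog = 0.35,
                              dispersion = 2.0,
                              alpha = 1.0,
                              eps0 = 0.05,
                              marker_boost = 8,
                              light_restricted = 20,
                              light_normal = 10,
                              restricted_chain = c("kappa", "lambda"),
                              cycle_fractions = c(S = 0.15, G2M = 0.12),
                              cycle_multiplier = 3,
                              mito_share = 0.06,
                              lowq_mito_boost = 15,
                              lowq_libsize_factor = 0.15,
                              markers = default_markers(genome),
                              seed = 1L) {
  restricted_chain <- match.arg(restricted_chain)
  stopifnot(dispersion > 0, alpha > 0, eps0 > 0,
            all(normal_counts >= 0), malignant_count >= 0,
            all(c("sample", "timepoint") %in% names(samples)))
  all_marker_genes <- unique(c(markers$malignant, markers$kappa, markers$lambda,
                               unlist(markers$cell_types), markers$s_genes,
                               markers$g2m_genes, markers$mito_genes))
  missing <- setdiff(all_marker_genes, genome$genes$gene)
  if (length(missing)) stop("marker genes absent from genome: ",
                            paste(utils::head(missing, 5), collapse = ", "))
  structure(list(
    samples = samples, normal_counts = normal_counts,
    malignant_count = malignant_count, lowq_count = lowq_count,
    gene_mean_shape = gene_mean_shape,
    libsize_meanlog = libsize_meanlog, libsize_sdlog = libsize_sdlog,
    dispersion = dispersion, alpha = alpha, eps0 = eps0,
    marker_boost = marker_boost, light_restricted = light_restricted,
    light_normal = light_normal, restricted_chain = restricted_chain,
    cycle_fractions = cycle_fractions, cycle_multiplier = cycle_multiplier,
    mito_share = mito_share, lowq_mito_boost = lowq_mito_boost,
    lowq_libsize_factor = lowq_libsize_factor,
    markers = markers, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Default marker gene configuration
#'
#' Deterministically picks marker genes from a genome model: a CCND1-like
#' malignancy marker (on chr11 when available, echoing t(11;14)-driven CCND1
#' overexpression), kappa/lambda-like light chains, small per-cell-type
#' marker sets for B/T/NK/monocyte-like populations, S and G2/M program gene
#' sets, and mitochondrially-flagged genes.
#'
#' @param genome A `genome_model`.
#' @param n_type_markers Markers per normal cell type.
#' @param n_cycle_genes Genes per cell-cycle program set (default 50,
#'   matching the size of the canonical S and G2/M phase lists).
#' @param n_mito Genes flagged as mitochondrial.
#' @return Named list with entries `malignant`, `kappa`, `lambda`,
#'   `cell_types`, `s_genes`, `g2m_genes`, `mito_genes`.
#' @export
default_markers <- function(genome, n_type_markers = 5, n_cycle_genes = 50,
                            n_mito = 10) {
  g <- genome$genes
  pool_n <- nrow(g) - 3
  if (pool_n < 7) stop("genome too small for a marker configuration")
  n_type_markers <- max(1, min(n_type_markers, floor(pool_n / 12)))
  n_cycle_genes <- max(1, min(n_cycle_genes, floor(pool_n / 5)))
  n_mito <- max(1, min(n_mito, floor(pool_n / 10)))
  pick_on <- function(chr, n, offset = 0) {
    idx <- which(g$chromosome == chr)
    if (length(idx) < n + offset) idx <- seq_len(nrow(g))
    g$gene[idx[seq_len(n) + offset]]
  }
  chrs <- genome$chromosomes$chromosome
  mal <- pick_on(if ("chr11" %in% chrs) "chr11" else chrs[1], 1, offset = 2)
  kap <- pick_on(if ("chr2" %in% chrs) "chr2" else chrs[1], 1, offset = 5)
  lam <- pick_on(if ("chr22" %in% chrs) "chr22" else chrs[length(chrs)], 1, offset = 5)
  used <- c(mal, kap, lam)
  pool <- setdiff(g$gene, used)
  take <- function(n) {
    x <- pool[seq_len(n)]
    pool <<- pool[-seq_len(n)]
    x
  }
  # spread picks across the genome so marker sets do not sit on one arm
  pool <- pool[order(seq_along(pool) %% 7, seq_along(pool))]
  types <- c("B", "T", "NK", "Mono")
  cell_types <- stats::setNames(lapply(types, function(t) take(n_type_markers)), types)
  list(
    malignant = mal, kappa = kap, lambda = lam,
    cell_types = cell_types,
    s_genes = take(n_cycle_genes),
    g2m_genes = take(n_cycle_genes),
    mito_genes = take(n_mito)
  )
}

#' Simulate a paired diagnosis/relapse single-cell experiment
#'
#' Draws a counts matrix and full truth labels for a planted clonal
#' architecture. See [simulation_config()] for the generative model.
#'
#' @param genome A `genome_model`.
#' @param subclones List of `subclone` objects from
#'   [plant_clonal_architecture()].
#' @param config A `sim_config`.
#'
#' @return An object of class `sim_experiment`: a list with `counts`
#'   (cells x genes sparse integer matrix), `cell_meta` (cell, sample,
#'   timepoint, population, malignant, phase, lowq), `gene_meta` (genome rows
#'   plus marker flags), `genome`, `subclones`, `config`, and `truth`
#'   (per-subclone segment tables and per-sample expected bulk segment
#'   tables over malignant subclones).
#' @export
simulate_counts <- function(genome, subclones, config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$dispersion <= 0) stop("dispersion must be > 0")
  clash <- intersect(names(subclones), c(names(config$normal_counts), "lowq"))
  if (length(clash)) stop("subclone ids collide with cell-type labels: ",
                          paste(clash, collapse = ", "))
  mk <- config$markers
  g <- genome$genes
  n_genes <- nrow(g)
  set.seed(config$seed)

  # baseline relative expression
  rel <- stats::rgamma(n_genes, shape = config$gene_mean_shape, scale = 1)
  idx <- function(ids) match(ids, g$gene)
  # markers and light chains sit at a high but unexceptional baseline;
  # cell-cycle program genes at a moderately high baseline (as the canonical
  # S/G2M genes are), so the 3x program multiplier is detectable
  hi <- stats::quantile(rel, 0.90)
  rel[idx(c(mk$malignant, mk$kappa, mk$lambda))] <- hi
  cyc <- c(mk$s_genes, mk$g2m_genes)
  # spread program-gene baselines over the upper expression range so they
  # share average-expression bins with background genes rather than with
  # each other (S and G2/M genes interleaved over the same quantiles)
  qs <- seq(0.55, 0.95, length.out = length(cyc))
  ord <- order(c(seq_along(mk$s_genes), seq_along(mk$g2m_genes)))
  rel[idx(cyc[ord])] <- stats::quantile(rel, qs)
  # scale mitochondrial genes to the target transcriptome share
  mito <- idx(mk$mito_genes)
  rel[mito] <- rel[mito] * (config$mito_share / (1 - config$mito_share)) *
    sum(rel[-mito]) / sum(rel[mito])
  rel <- rel / sum(rel)

  # cell table
  cells <- list()
  for (si in seq_len(nrow(config$samples))) {
    sm <- config$samples$sample[si]
    tp <- config$samples$timepoint[si]
    pops <- character(0)
    for (t in names(config$normal_counts)) {
      pops <- c(pops, rep(t, config$normal_counts[[t]]))
    }
    if (config$malignant_count > 0) {
      props <- vapply(subclones, function(s) s$proportions[[sm]], numeric(1))
      draw <- sample(names(subclones), config$malignant_count,
                     replace = TRUE, prob = props)
      pops <- c(pops, draw)
    }
    if (config$lowq_count > 0) pops <- c(pops, rep("lowq", config$lowq_count))
    cells[[si]] <- data.frame(
      sample = sm, timepoint = tp, population = pops,
      stringsAsFactors = FALSE
    )
  }
  cells <- do.call(rbind, cells)
  cells$cell <- sprintf("%s_c%05d", cells$sample, stats::ave(
    seq_len(nrow(cells)), cells$sample, FUN = seq_along))
  cells$malignant <- cells$population %in% names(subclones)
  n_cells <- nrow(cells)

  # cell-cycle program assignment (malignant cells only; normals rest in G1)
  cells$phase <- "G1"
  for (sm in unique(cells$sample)) {
    cf <- config$cycle_fractions
    if (is.list(cf)) cf <- cf[[sm]]
    mal_idx <- which(cells$sample == sm & cells$malignant)
    if (!length(mal_idx)) next
    u <- stats::runif(length(mal_idx))
    cells$phase[mal_idx[u < cf[["S"]]]] <- "S"
    cells$phase[mal_idx[u >= cf[["S"]] & u < cf[["S"]] + cf[["G2M"]]]] <- "G2M"
  }

  # library sizes
  libsize <- stats::rlnorm(n_cells, config$libsize_meanlog, config$libsize_sdlog)
  libsize[cells$population == "lowq"] <-
    libsize[cells$population == "lowq"] * config$lowq_libsize_factor

  # per-population expression multipliers
  restricted <- if (config$restricted_chain == "kappa") mk$kappa else mk$lambda
  excluded <- if (config$restricted_chain == "kappa") mk$lambda else mk$kappa
  pop_mult <- function(pop) {
    m <- rep(1, n_genes)
    # light chains are B-lineage restricted transcripts
    m[idx(c(mk$kappa, mk$lambda))] <- 0.05
    m[idx(mk$malignant)] <- 0.002  # CCND1-like: silent outside the tumor
    if (pop %in% names(subclones)) {
      m[idx(mk$cell_types$B)] <- config$marker_boost
      m[idx(mk$malignant)] <- config$marker_boost
      m[idx(restricted)] <- config$light_restricted
      m[idx(excluded)] <- 1
    } else if (pop %in% c("B", "lowq")) {
      m[idx(mk$cell_types$B)] <- config$marker_boost
      m[idx(c(mk$kappa, mk$lambda))] <- config$light_normal
    } else if (pop %in% names(mk$cell_types)) {
      m[idx(mk$cell_types[[pop]])] <- config$marker_boost
    } else stop("unknown population: ", pop)
    if (pop == "lowq") m[mito] <- m[mito] * config$lowq_mito_boost
    m
  }

  # dosage factors per subclone
  dosage <- lapply(subclones, function(s) {
    cn <- gene_copy_numbers(genome, s)
    ifelse(cn == 0, config$eps0, (cn / 2)^config$alpha)
  })

  mu <- matrix(0, nrow = n_genes, ncol = n_cells)
  for (pop in unique(cells$population)) {
    ci <- which(cells$population == pop)
    base <- rel * pop_mult(pop)
    if (pop %in% names(subclones)) base <- base * dosage[[pop]]
    mu[, ci] <- outer(base, libsize[ci])
  }
  s_idx <- idx(mk$s_genes); g2m_idx <- idx(mk$g2m_genes)
  mu[s_idx, cells$phase == "S"] <- mu[s_idx, cells$phase == "S"] * config$cycle_multiplier
  mu[g2m_idx, cells$phase == "G2M"] <- mu[g2m_idx, cells$phase == "G2M"] * config$cycle_multiplier

  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = config$dispersion),
                   nrow = n_genes, ncol = n_cells)
  dimnames(counts) <- list(g$gene, cells$cell)
  counts <- methods::as(Matrix::Matrix(t(counts), sparse = TRUE), "CsparseMatrix")

  gene_meta <- g
  gene_meta$is_mito <- g$gene %in% mk$mito_genes
  gene_meta$is_malignant_marker <- g$gene %in% mk$malignant
  gene_meta$is_light_chain <- g$gene %in% c(mk$kappa, mk$lambda)

  truth <- list(
    subclone_segments = stats::setNames(
      lapply(subclones, function(s) s$segments), names(subclones)),
    bulk_segments = stats::setNames(
      lapply(config$samples$sample, function(sm)
        truth_bulk_segments(genome, subclones, sm)),
      config$samples$sample)
  )

  structure(list(
    counts = counts,
    cell_meta = cells[, c("cell", "sample", "timepoint", "population",
                          "malignant", "phase")],
    gene_meta = gene_meta,
    genome = genome, subclones = subclones, config = config, truth = truth
  ), class = "sim_experiment")
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat(sprintf("sim_experiment: %d cells x %d genes; samples: %s; subclones: %s\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$cell_meta$sample), collapse = ", "),
              paste(names(x$subclones), collapse = ", ")))
  invisible(x)
}

genes_span <- function(genome, chr, from, to) {
  gc <- genome$genes[genome$genes$chromosome == chr, ]
  c(gc$start[from], gc$end[to])
}

#' Planted relapse architecture with a minor resistant precursor
#'
#' Builds the package's standard three-subclone scenario: subclones A/B/C
#' share two truncal events (an 11q-like gain and a 13q-like loss); each adds
#' private events; C's profile equals the dominant relapse profile and is
#' planted as a minor subclone at diagnosis. Proportions default to
#' 0.90/0.09/0.01 at diagnosis and 0.04/0.06/0.90 at relapse, so that C is
#' the therapy-resistant precursor of relapse and A/B are therapy-sensitive.
#' Every event spans a contiguous run of >= 30 genes.
#'
#' @param genome A `genome_model` with at least 22 chromosomes and ~150
#'   genes per chromosome (smaller genomes scale the event spans down).
#' @param dg_props,rel_props Named proportions of subclones A, B, C at
#'   diagnosis and relapse.
#' @param dg_sample,rel_sample Sample ids.
#' @return A list of `subclone` objects (see [plant_clonal_architecture()]).
#' @export
relapse_architecture <- function(genome,
                                 dg_props = c(A = 0.90, B = 0.09, C = 0.01),
                                 rel_props = c(A = 0.04, B = 0.06, C = 0.90),
                                 dg_sample = "Dg", rel_sample = "Rel") {
  n_chr <- nrow(genome$chromosomes)
  gpc <- sum(genome$genes$chromosome == genome$chromosomes$chromosome[1])
  sc <- function(i) min(i, gpc)  # clamp gene indices for small test genomes
  chr <- function(i) genome$chromosomes$chromosome[min(i, n_chr)]
  ev <- function(ch, from, to, cn) {
    sp <- genes_span(genome, ch, sc(from), sc(to))
    data.frame(chromosome = ch, start = sp[1], end = sp[2], copy_number = cn,
               stringsAsFactors = FALSE)
  }
  truncal <- rbind(ev(chr(11), 40, 160, 3), ev(chr(13), 50, 170, 1))
  pr <- function(id) {
    out <- c(dg_props[[id]], rel_props[[id]])
    names(out) <- c(dg_sample, rel_sample)
    as.list(out)
  }
  spec <- list(
    list(id = "cloneA", parent = NA, proportions = pr("A"),
         events = rbind(truncal,
                        ev(chr(1), 30, 150, 1),
                        ev(chr(9), 80, 200, 1))),
    list(id = "cloneB", parent = NA, proportions = pr("B"),
         events = rbind(truncal,
                        ev(chr(3), 20, 140, 4),
                        ev(chr(17), 60, 180, 1))),
    list(id = "cloneC", parent = NA, proportions = pr("C"),
         events = rbind(truncal,
                        ev(chr(19), 10, 130, 4),
                        ev(chr(22), 100, 220, 3),
                        ev(chr(6), 40, 160, 1)))
  )
  plant_clonal_architecture(genome, spec)
}

#' Standard full-scale benchmark experiment
#'
#' The package's reference scenario: a 22-chromosome genome with ~6000
#' genes, paired diagnosis/relapse samples of 500 normal + 1500 malignant
#' cells each, and the three-subclone architecture of
#' [relapse_architecture()] (dominant sensitive clone A, minor sensitive
#' clone B, and a 1% diagnostic precursor C that dominates relapse).
#'
#' @param seed Integer seed controlling genome layout, clonal sampling and
#'   counts.
#' @param malignant_count,normal_counts Cells per sample.
#' @return A `sim_experiment`.
#' @export
standard_experiment <- function(seed = 1L,
                                malignant_count = 1500,
                                normal_counts = c(B = 125, T = 200,
                                                  NK = 100, Mono = 75)) {
  genome <- build_genome(22, 273, seed = seed)
  arch <- relapse_architecture(genome)
  cfg <- simulation_config(genome, normal_counts = normal_counts,
                           malignant_count = malignant_count,
                           seed = seed + 1L)
  simulate_counts(genome, arch, cfg)
}
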