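#' Pipeline configuration
#'
#' Centralizes every stage parameter with its default. Unknown keys are
#' rejected so a config file cannot silently misspell a parameter.
#'
#' @param ... Overrides of the defaults listed below.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    # normalization / embedding / clustering
    scale = 1e4, n_hvg = 2000, pca_var_fraction = 0.015,
    k = 15, resolution = 0.3,
    # per-sample QC thresholds and the cluster exclusion rule
    min_umi = 500, max_umi = Inf, min_genes = 200, max_genes = Inf,
    max_mito = 0.15, cluster_lowq_cutoff = 0.33,
    # malignancy call
    expr_threshold = 1.0, fraction_threshold = 0.5,
    restriction_threshold = 1.0,
    # CNV inference
    cnv_min_mean = 0.1, cnv_clip = 3.0, cnv_window = 101,
    cnv_transition = 1e-6, cnv_sd_floor = 0.05, cnv_sd_amplifier = 3.0,
    # subclone clustering and longitudinal classification
    clone_method = "leiden", clone_k = 15, clone_resolution = 0.05,
    clone_n_clusters = 3, theta = 0.8, min_match_score = 0.5,
    bin_size = 100000,
    # differential expression / enrichment / cell cycle
    de_min_lfc = 0.25, de_min_frac = 0.10,
    sig_max_adj_p = 0.05, sig_min_abs_l2fc = 0.8, sig_min_frac = 0.25,
    gsea_n_perm = 1000, cycle_n_bins = 24, cycle_n_control = 100,
    run_de = TRUE, run_cycle = TRUE,
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  defaults[names(over)] <- over
  structure(defaults, class = "pipeline_config")
}

#' Write / read a pipeline config as YAML
#'
#' Round-trips losslessly; unknown keys in the file are rejected by
#' [pipeline_config()].
#'
#' @param config A `pipeline_config`.
#' @param path File path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

# per-gene segment table of a mean copy profile (one row per analyzed gene)
profile_to_segments <- function(values, gene_meta) {
  data.frame(chromosome = gene_meta$chromosome, start = gene_meta$start,
             end = gene_meta$end, copy_number = values,
             stringsAsFactors = FALSE)
}

#' Run the full clonotyping pipeline on a simulated experiment
#'
#' Executes QC -> clustering -> cell typing and malignancy calling -> CNV
#' inference -> joint subclone clustering, composition, resistance
#' classification and precursor matching -> bulk concordance -> downstream
#' statistics. All stochastic stages derive their seeds from
#' `config$seed`; two runs with the same input and config are identical.
#'
#' @param sim A `sim_experiment` (or a directory written by
#'   [write_experiment_10x()]; truth fields are then reloaded for the
#'   concordance stage).
#' @param config A `pipeline_config`.
#' @param out_dir Optional directory; when given, all result tables are
#'   written as TSVs.
#' @return A list of class `run_report`; see the elements written in the
#'   function body (qc, clusters, cell_types, malignant_calls, assignment,
#'   composition, resistance, precursor, concordance, de, counts per
#'   stage, ...).
#' @export
run_pipeline <- function(sim, config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(sim)) sim <- load_experiment(sim)
  report <- list(config = config, n_cells_in = nrow(sim$counts))

  ## --- QC ----------------------------------------------------------------
  thr <- qc_thresholds(min_umi = config$min_umi, max_umi = config$max_umi,
                       min_genes = config$min_genes, max_genes = config$max_genes,
                       max_mito = config$max_mito,
                       cluster_lowq_cutoff = config$cluster_lowq_cutoff)
  qc <- compute_qc(sim$counts, sim$gene_meta$is_mito)
  qc <- apply_thresholds(qc, thr)
  usable <- !qc$degenerate
  if (!any(usable)) stop("qc: all cells are degenerate (zero counts)")

  ## --- normalization + clustering ----------------------------------------
  counts <- sim$counts[usable, , drop = FALSE]
  norm <- log_normalize(counts, scale = config$scale)
  hvg <- select_hvg(counts, n_top = min(config$n_hvg, ncol(counts)))
  emb <- pca_embed(scale_genes(norm[, hvg, drop = FALSE]),
                   variance_fraction = config$pca_var_fraction)
  clusters <- knn_leiden(emb$scores, k = config$k,
                         resolution = config$resolution,
                         seed = config$seed + 1L)

  keep <- drop_low_quality_clusters(clusters, qc$low_quality[usable],
                                    cutoff = config$cluster_lowq_cutoff)
  if (!any(keep)) stop("qc: no cells retained after thresholds and the low-quality cluster rule")
  norm <- norm[keep, , drop = FALSE]
  clusters <- clusters[keep]
  meta <- sim$cell_meta[match(rownames(norm), sim$cell_meta$cell), ]
  report$qc <- qc
  report$n_cells_retained <- sum(keep)

  ## --- cell typing and malignancy -----------------------------------------
  mk <- sim$config$markers
  types <- score_cell_types(norm, clusters, mk$cell_types)
  calls <- call_malignant(norm, clusters,
                          marker_gene = mk$malignant, kappa_gene = mk$kappa,
                          lambda_gene = mk$lambda,
                          expr_threshold = config$expr_threshold,
                          fraction_threshold = config$fraction_threshold,
                          restriction_threshold = config$restriction_threshold)
  calls$type <- types[calls$cluster]
  is_mal <- calls$malignant[match(as.character(clusters), calls$cluster)]
  if (!any(is_mal)) stop("malignant: no malignant cluster identified")
  if (all(is_mal)) stop("malignant: no reference (non-malignant) cells left")
  report$clusters <- clusters
  report$cell_types <- types
  report$malignant_calls <- calls
  report$n_malignant <- sum(is_mal)

  ## --- CNV inference -------------------------------------------------------
  ref_cells <- rownames(norm)[!is_mal]
  program_genes <- unique(c(mk$s_genes, mk$g2m_genes, mk$kappa, mk$lambda,
                            mk$malignant))
  cnv <- infer_cnv(norm, sim$gene_meta, ref_cells,
                   min_mean = config$cnv_min_mean, clip = config$cnv_clip,
                   window = config$cnv_window,
                   transition = config$cnv_transition,
                   sd_floor = config$cnv_sd_floor,
                   sd_amplifier = config$cnv_sd_amplifier,
                   exclude_genes = program_genes)
  report$cnv_params <- cnv$params
  report$n_cnv_genes <- length(cnv$kept_genes)

  ## --- subclone clustering and longitudinal dynamics ----------------------
  mal_cells <- rownames(norm)[is_mal]
  assignment <- cluster_subclones(
    cnv$smoothed[mal_cells, , drop = FALSE],
    method = config$clone_method, k = config$clone_k,
    resolution = config$clone_resolution,
    n_clusters = config$clone_n_clusters, seed = config$seed + 2L)
  composition <- composition_table(assignment, meta)
  resistance <- classify_resistance(composition, theta = config$theta)

  mal_meta <- meta[match(mal_cells, meta$cell), ]
  states_mal <- cnv$states[mal_cells, , drop = FALSE]
  dg_cells <- mal_meta$timepoint == "diagnosis"
  seg_by <- function(sel) {
    grp <- stats::setNames(paste(assignment[sel]), mal_cells[sel])
    group_copy_segments(cnv$smoothed, cnv$gene_meta, grp,
                        reference_cells = ref_cells,
                        transition = config$cnv_transition,
                        sd_floor = config$cnv_sd_floor,
                        sd_amplifier = config$cnv_sd_amplifier,
                        mu_scale = cnv$mu_scale)
  }
  decoded <- list()
  precursor <- NULL
  if (any(dg_cells) && any(!dg_cells)) {
    decoded$dg <- seg_by(dg_cells)
    decoded$rel <- seg_by(!dg_cells)
    dg_segs <- decoded$dg$segments
    rel_segs <- decoded$rel$segments
    rel_list <- split(rel_segs, rel_segs$group)
    # full-coverage tables: diploid runs must enter the binned profiles as
    # copy 2, not as missing bins, or the Jaccard only sees shared events
    prec <- lapply(split(dg_segs, dg_segs$group), function(seg) {
      match_precursor(seg, rel_list,
                      sim$genome, bin_size = config$bin_size,
                      min_score = config$min_match_score)
    })
    precursor <- do.call(rbind, prec)
    precursor <- cbind(diagnostic_subclone = names(prec), precursor)
    rownames(precursor) <- NULL
  }
  report$assignment <- assignment
  report$composition <- composition
  report$resistance <- resistance
  report$precursor <- precursor

  ## --- concordance with truth bulk segments -------------------------------
  concord <- NULL
  if (!is.null(sim$truth$bulk_segments)) {
    concord <- lapply(names(sim$truth$bulk_segments), function(sm) {
      cells_sm <- mal_cells[mal_meta$sample == sm]
      if (length(cells_sm) < 2) return(NULL)
      # cell-proportion-weighted mixture of subclone-level decoded
      # profiles, mirroring how a bulk profile mixes its clones; falls
      # back to the per-cell state mean when clone decoding is absent
      tp_key <- if (unique(mal_meta$timepoint[mal_meta$sample == sm]) ==
                    "diagnosis") "dg" else "rel"
      inferred <- if (!is.null(decoded[[tp_key]])) {
        props <- table(paste(assignment[cells_sm])) / length(cells_sm)
        st <- decoded[[tp_key]]$states[names(props), , drop = FALSE]
        as.vector(crossprod(st, as.vector(props)))
      } else colMeans(states_mal[cells_sm, , drop = FALSE])
      a <- normalize_baseline(bin_segments(
        profile_to_segments(inferred, cnv$gene_meta), sim$genome,
        bin_size = config$bin_size))
      b <- normalize_baseline(bin_segments(
        sim$truth$bulk_segments[[sm]], sim$genome, bin_size = config$bin_size))
      sp <- spearman_concordance(a, b)
      data.frame(sample = sm, rho = sp$rho, n_bins = sp$n,
                 stringsAsFactors = FALSE)
    })
    concord <- do.call(rbind, concord)
  }
  report$concordance <- concord

  ## --- bulk validation of subclone events ---------------------------------
  if (!is.null(sim$truth$bulk_segments) && length(decoded)) {
    validated <- list()
    for (tp_key in names(decoded)) {
      tp <- if (tp_key == "dg") "diagnosis" else "relapse"
      for (sm in unique(mal_meta$sample[mal_meta$timepoint == tp])) {
        bulk <- sim$truth$bulk_segments[[sm]]
        if (is.null(bulk)) next
        segs <- decoded[[tp_key]]$segments
        ev <- segs[segs$copy_number != 2, , drop = FALSE]
        keep <- validate_subclone_cnv(ev, bulk)
        if (nrow(keep)) keep$sample <- sm
        validated[[paste(tp_key, sm)]] <- keep
      }
    }
    validated <- do.call(rbind, validated)
    rownames(validated) <- NULL
    report$validated_segments <- validated
  }

  ## --- downstream statistics ----------------------------------------------
  if (isTRUE(config$run_de)) {
    res_clones <- resistance$subclone[resistance$label == "resistant"]
    sens_clones <- resistance$subclone[resistance$label == "sensitive"]
    dg_names <- mal_cells[dg_cells]
    ga <- dg_names[paste(assignment[dg_names]) %in% res_clones]
    gb <- dg_names[paste(assignment[dg_names]) %in% sens_clones]
    if (length(ga) >= 3 && length(gb) >= 3) {
      de <- wilcoxon_de(norm, ga, gb, min_lfc = config$de_min_lfc,
                        min_frac = config$de_min_frac)
      report$de <- de
      report$significant_genes <- significant_genes(
        de, max_adj_p = config$sig_max_adj_p,
        min_abs_l2fc = config$sig_min_abs_l2fc,
        min_frac = config$sig_min_frac)
    }
  }
  if (isTRUE(config$run_cycle)) {
    s_score <- module_score(norm, mk$s_genes, n_bins = config$cycle_n_bins,
                            n_control = config$cycle_n_control,
                            seed = config$seed + 3L)
    g2m_score <- module_score(norm, mk$g2m_genes, n_bins = config$cycle_n_bins,
                              n_control = config$cycle_n_control,
                              seed = config$seed + 4L)
    phases <- assign_phase(s_score, g2m_score)
    report$phases <- data.frame(cell = rownames(norm), s_score = s_score,
                                g2m_score = g2m_score, phase = phases,
                                row.names = NULL, stringsAsFactors = FALSE)
    tp <- meta$timepoint
    if (length(unique(tp)) == 2) {
      tab <- table(factor(tp, c("diagnosis", "relapse")),
                   factor(phases, c("G1", "S", "G2M")))
      report$phase_shift <- phase_shift_test(list(patient = unclass(tab)))
    }
  }

  class(report) <- "run_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report: %d cells in, %d retained, %d malignant, %d CNV genes\n",
              x$n_cells_in, x$n_cells_retained, x$n_malignant, x$n_cnv_genes))
  cat("subclone composition:\n")
  print(x$composition, row.names = FALSE)
  cat("resistance labels:\n")
  print(x$resistance, row.names = FALSE)
  if (!is.null(x$concordance)) {
    cat("bulk concordance:\n")
    print(x$concordance, row.names = FALSE)
  }
  invisible(x)
}

# load a sim_experiment written by write_experiment_10x (truth included)
load_experiment <- function(dir) {
  raw <- read_counts_10x(dir)
  sub_files <- list.files(dir, pattern = "^truth_segments_", full.names = TRUE)
  bulk_files <- list.files(dir, pattern = "^truth_bulk_", full.names = TRUE)
  grab <- function(f, prefix) sub("\\.tsv$", "", sub(prefix, "", basename(f)))
  chroms <- unique(raw$gene_meta$chromosome)
  genome <- structure(list(
    chromosomes = data.frame(
      chromosome = chroms,
      length = vapply(chroms, function(ch)
        max(raw$gene_meta$end[raw$gene_meta$chromosome == ch]) + 3500,
        numeric(1)),
      stringsAsFactors = FALSE),
    genes = raw$gene_meta[, c("gene", "chromosome", "start", "end")]
  ), class = "genome_model")
  mk_path <- file.path(dir, "markers.yaml")
  config <- if (file.exists(mk_path)) {
    list(markers = yaml::read_yaml(mk_path))
  } else NULL
  structure(list(
    counts = raw$counts, cell_meta = raw$cell_meta, gene_meta = raw$gene_meta,
    genome = genome, subclones = NULL, config = config,
    truth = list(
      subclone_segments = stats::setNames(lapply(sub_files, read_segments),
                                          grab(sub_files, "truth_segments_")),
      bulk_segments = stats::setNames(lapply(bulk_files, read_segments),
                                      grab(bulk_files, "truth_bulk_"))
    )
  ), class = "sim_experiment")
}

# persist every result table of a run
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, name) {
    utils::write.table(x, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(report$qc, "qc.tsv")
  wt(data.frame(cell = names(report$clusters), cluster = report$clusters),
     "clusters.tsv")
  wt(report$malignant_calls, "malignant_calls.tsv")
  wt(data.frame(cell = names(report$assignment),
                subclone = report$assignment), "subclone_assignment.tsv")
  wt(report$composition, "composition.tsv")
  wt(report$resistance, "resistance.tsv")
  if (!is.null(report$precursor)) wt(report$precursor, "precursor_matches.tsv")
  if (!is.null(report$validated_segments)) {
    wt(report$validated_segments, "validated_segments.tsv")
  }
  if (!is.null(report$concordance)) wt(report$concordance, "concordance.tsv")
  if (!is.null(report$de)) wt(report$de, "de.tsv")
  if (!is.null(report$phases)) wt(report$phases, "phases.tsv")
  invisible(out_dir)
}
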