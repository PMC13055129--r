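test_that("simulation is bit-reproducible for a fixed config and seed", {
  g <- build_genome(3, 40, seed = 4)
  arch <- plant_clonal_architecture(g, list(
    list(id = "cloneA", parent = NA, events = NULL,
         proportions = list(Dg = 1, Rel = 1))))
  cfg <- simulation_config(g, normal_counts = c(B = 10, T = 10, NK = 5, Mono = 5),
                           malignant_count = 30, seed = 42)
  s1 <- simulate_counts(g, arch, cfg)
  s2 <- simulate_counts(g, arch, cfg)
  expect_identical(as.matrix(s1$counts), as.matrix(s2$counts))
  expect_identical(s1$cell_meta, s2$cell_meta)
})

test_that("copy-number dosage scales gene means as (c/2)^alpha with an eps0 floor", {
  g <- build_genome(2, 50, seed = 5)
  gc1 <- g$genes[g$genes$chromosome == "chr1", ]
  gc2 <- g$genes[g$genes$chromosome == "chr2", ]
  ev <- rbind(
    data.frame(chromosome = "chr1", start = gc1$start[10], end = gc1$end[30],
               copy_number = 4),
    data.frame(chromosome = "chr2", start = gc2$start[10], end = gc2$end[30],
               copy_number = 0))
  arch <- plant_clonal_architecture(g, list(
    list(id = "cloneDip", parent = NA, events = NULL,
         proportions = list(Dg = 0.5)),
    list(id = "cloneEv", parent = NA, events = ev,
         proportions = list(Dg = 0.5))))
  cfg <- simulation_config(g, samples = data.frame(sample = "Dg",
                                                   timepoint = "diagnosis"),
                           normal_counts = c(B = 0, T = 0, NK = 0, Mono = 0),
                           malignant_count = 1200, dispersion = 2, alpha = 1,
                           cycle_fractions = c(S = 0, G2M = 0), seed = 8)
  sim <- simulate_counts(g, arch, cfg)
  meta <- sim$cell_meta
  cnt <- sim$counts
  dip_cells <- meta$population == "cloneDip"
  ev_cells <- meta$population == "cloneEv"
  expect_true(sum(ev_cells) >= 500)

  # pick well-expressed unperturbed genes to control Monte-Carlo error
  amp_genes <- gc1$gene[10:30]
  del_genes <- gc2$gene[10:30]
  base_mean <- Matrix::colMeans(cnt[dip_cells, , drop = FALSE])
  ev_mean <- Matrix::colMeans(cnt[ev_cells, , drop = FALSE])

  check_ratio <- function(genes, ratio) {
    sel <- genes[base_mean[genes] > 0.5]
    expect_gt(length(sel), 5)
    for (gn in sel) {
      # NB with mean mu and size k has variance mu + mu^2/k; the baseline
      # is itself estimated, so both sampling errors enter
      mu <- base_mean[gn] * ratio
      se_ev <- sqrt((mu + mu^2 / cfg$dispersion) / sum(ev_cells))
      se_base <- ratio * sqrt((base_mean[gn] + base_mean[gn]^2 / cfg$dispersion) /
                                sum(dip_cells))
      expect_lt(abs(ev_mean[gn] - mu), 3 * sqrt(se_ev^2 + se_base^2) + 0.02 * mu)
    }
  }
  check_ratio(amp_genes, 2)      # 4 copies, alpha = 1 -> 2x baseline
  check_ratio(del_genes, 0.05)   # homozygous deletion -> eps0 floor
})

test_that("expected counts increase monotonically in copy number", {
  g <- build_genome(1, 60, seed = 6)
  gc <- g$genes
  states <- c(0, 1, 3, 4, 5)
  spec <- lapply(seq_along(states), function(i) {
    list(id = paste0("clone", states[i]), parent = NA,
         events = data.frame(chromosome = "chr1", start = gc$start[10],
                             end = gc$end[40], copy_number = states[i]),
         proportions = list(Dg = 1 / (length(states) + 1)))
  })
  spec[[length(spec) + 1]] <- list(id = "clone2", parent = NA, events = NULL,
                                   proportions = list(Dg = 1 / (length(states) + 1)))
  arch <- plant_clonal_architecture(g, spec)
  cfg <- simulation_config(g, samples = data.frame(sample = "Dg",
                                                   timepoint = "diagnosis"),
                           normal_counts = c(B = 0, T = 0, NK = 0, Mono = 0),
                           malignant_count = 1800,
                           cycle_fractions = c(S = 0, G2M = 0), seed = 9)
  sim <- simulate_counts(g, arch, cfg)
  genes <- gc$gene[10:40]
  mean_per_state <- vapply(c(0:5), function(s) {
    cells <- sim$cell_meta$population == paste0("clone", s)
    mean(Matrix::rowSums(sim$counts[cells, genes, drop = FALSE]))
  }, numeric(1))
  expect_true(all(diff(mean_per_state) > 0))
  # the c=0 floor stays below the single-copy mean
  expect_lt(mean_per_state[1], mean_per_state[2])
})

test_that("per-sample subclone counts follow the configured multinomial", {
  s <- med_sim()
  g2 <- s$genome
  arch <- make_test_arch(g2, dg_props = c(A = 0.5, B = 0.3, C = 0.2),
                         rel_props = c(A = 0.5, B = 0.3, C = 0.2))
  cfg <- simulation_config(g2, normal_counts = c(B = 0, T = 0, NK = 0, Mono = 0),
                           malignant_count = 2000, seed = 10)
  sim <- simulate_counts(g2, arch, cfg)
  for (sm in c("Dg", "Rel")) {
    obs <- table(factor(sim$cell_meta$population[sim$cell_meta$sample == sm],
                        c("cloneA", "cloneB", "cloneC")))
    p <- stats::chisq.test(obs, p = c(0.5, 0.3, 0.2))$p.value
    expect_gt(p, 0.001)
  }
})

test_that("marker structure encodes malignancy and light-chain restriction", {
  s <- med_sim()
  sim <- s$sim
  mk <- s$cfg$markers
  norm <- med_norm()
  mal <- sim$cell_meta$malignant
  bcell <- sim$cell_meta$population == "B"
  # malignant marker high in tumor, low in normals
  expect_gt(mean(norm[mal, mk$malignant] > 1), 0.8)
  expect_lt(mean(norm[!mal, mk$malignant] > 1), 0.1)
  # restriction: tumor skews to one chain, normal B mixes both
  skew_mal <- abs(mean(norm[mal, mk$kappa]) - mean(norm[mal, mk$lambda]))
  skew_b <- abs(mean(norm[bcell, mk$kappa]) - mean(norm[bcell, mk$lambda]))
  expect_gt(skew_mal, 1)
  expect_lt(skew_b, 0.5)
})
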