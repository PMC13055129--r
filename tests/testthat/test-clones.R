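test_that("joint clustering separates subclones with disjoint events", {
  set.seed(15)
  # synthetic smoothed profiles: two clones, disjoint shifted blocks
  n <- 60; g <- 120
  prof <- matrix(rnorm(2 * n * g, sd = 0.03), 2 * n, g)
  prof[1:n, 1:30] <- prof[1:n, 1:30] + 0.5
  prof[(n + 1):(2 * n), 61:90] <- prof[(n + 1):(2 * n), 61:90] - 0.5
  rownames(prof) <- paste0("c", seq_len(2 * n))
  truth <- rep(1:2, each = n)
  for (m in c("leiden", "ward")) {
    lab <- cluster_subclones(prof, method = m, n_clusters = 2, seed = 1)
    expect_equal(adjusted_rand_index(lab, truth), 1.0, info = m)
  }
  # identical profiles: a single cluster
  flat <- matrix(0.01, 40, g) + matrix(rnorm(40 * g, sd = 1e-3), 40, g)
  rownames(flat) <- paste0("f", 1:40)
  lab2 <- cluster_subclones(flat, method = "leiden", resolution = 0.1, seed = 1)
  expect_equal(length(unique(lab2)), 1)
  expect_error(cluster_subclones(prof, method = "kmeans"), "arg")
})

test_that("composition tables cross-tabulate and normalize per sample", {
  meta <- data.frame(cell = paste0("c", 1:10),
                     sample = rep(c("Dg", "Rel"), c(10, 0)),
                     timepoint = "diagnosis")
  assign <- setNames(rep("s1", 10), meta$cell)
  comp <- composition_table(assign, meta)
  expect_equal(comp$proportion, 1.0)
  expect_equal(comp$count, 10)

  # absent subclone-sample combination gets count 0, proportion 0
  meta2 <- data.frame(cell = paste0("c", 1:6),
                      sample = rep(c("Dg", "Rel"), each = 3),
                      timepoint = rep(c("diagnosis", "relapse"), each = 3))
  assign2 <- setNames(c("s1", "s1", "s1", "s2", "s2", "s2"), meta2$cell)
  comp2 <- composition_table(assign2, meta2)
  row <- comp2[comp2$subclone == "s2" & comp2$sample == "Dg", ]
  expect_equal(row$count, 0)
  expect_equal(row$proportion, 0)
})

test_that("recovered proportions sit within the multinomial confidence band", {
  s <- med_sim()
  meta <- s$sim$cell_meta
  mal <- meta[meta$malignant, ]
  assign <- setNames(mal$population, mal$cell)
  comp <- composition_table(assign, meta)
  for (clone in c("cloneA", "cloneB", "cloneC")) {
    p_true <- s$arch[[clone]]$proportions[["Dg"]]
    row <- comp[comp$subclone == clone & comp$sample == "Dg", ]
    n <- sum(comp$count[comp$sample == "Dg"])
    ci <- qbinom(c(0.005, 0.995), n, p_true) / n
    expect_gte(row$proportion, ci[1])
    expect_lte(row$proportion, ci[2])
  }
})

test_that("resistance classification follows the expansion/persistence ratio", {
  comp <- data.frame(
    subclone = rep(c("a", "b", "c", "d"), each = 2),
    sample = rep(c("Dg", "Rel"), 4),
    timepoint = rep(c("diagnosis", "relapse"), 4),
    count = c(10, 800, 900, 20, 100, 100, 0, 80),
    proportion = c(0.01, 0.80, 0.90, 0.02, 0.10, 0.10, 0, 0.08))
  res <- classify_resistance(comp, theta = 0.8)
  lab <- setNames(res$label, res$subclone)
  expect_equal(unname(lab["a"]), "resistant")        # 1% -> 80%: expanded
  expect_equal(unname(lab["b"]), "sensitive")        # 90% -> 2%: depleted
  expect_equal(unname(lab["c"]), "resistant")        # 10% -> 10%: persistent
  expect_equal(unname(lab["d"]), "relapse_specific") # zero diagnostic cells
})

test_that("resistance is monotone in the relapse proportion", {
  base <- function(p_rel) data.frame(
    subclone = rep(c("x", "y"), each = 2),
    sample = rep(c("Dg", "Rel"), 2),
    timepoint = rep(c("diagnosis", "relapse"), 2),
    count = c(50, round(100 * p_rel), 50, 100 - round(100 * p_rel)),
    proportion = c(0.5, p_rel, 0.5, 1 - p_rel))
  labels <- vapply(seq(0, 1, 0.05), function(p) {
    r <- classify_resistance(base(p))
    r$label[r$subclone == "x"]
  }, character(1))
  # once resistant, stays resistant as p_rel grows
  first_res <- match("resistant", labels)
  expect_true(all(labels[first_res:length(labels)] == "resistant"))
})

test_that("precursor matching scores directional overlap of non-diploid bins", {
  g <- build_genome(2, 50, seed = 16)
  seg <- function(chr, start, end, cn)
    data.frame(chromosome = chr, start = start, end = end, copy_number = cn)
  # full-coverage profiles (diploid elsewhere), as produced by state calling
  profile <- function(events) {
    plant_clonal_architecture(g, list(
      list(id = "p", parent = NA, events = events,
           proportions = list(Dg = 1))))$p$segments
  }
  a <- profile(rbind(seg("chr1", 1, 200000, 3), seg("chr2", 1, 100000, 1)))
  # identical event sets -> 1; disjoint -> 0
  expect_equal(cnv_profile_similarity(
    bin_segments(a, g)$value, bin_segments(a, g)$value)$score, 1.0)
  b <- profile(seg("chr2", 200001, 400000, 3))
  expect_equal(cnv_profile_similarity(
    bin_segments(a, g)$value, bin_segments(b, g)$value)$score, 0.0)

  # hand-counted Jaccard on a toy grid (100 kb bins): a is gain on chr1 bins
  # {1,2} and loss on chr2 bin {1}; cc shares all three and adds a gain on
  # chr2 bin {4} -> agree = 3, union = 4 -> 0.75
  cc <- profile(rbind(seg("chr1", 1, 200000, 5), seg("chr2", 1, 100000, 1),
                      seg("chr2", 300001, 400000, 4)))
  sim <- cnv_profile_similarity(bin_segments(a, g)$value,
                                bin_segments(cc, g)$value)
  expect_equal(sim$shared, 3)
  expect_equal(sim$union, 4)
  expect_equal(sim$score, 0.75)
  # symmetry
  expect_equal(cnv_profile_similarity(bin_segments(cc, g)$value,
                                      bin_segments(a, g)$value)$score, 0.75)

  m <- match_precursor(a, list(r1 = b, r2 = cc), g, min_score = 0.5)
  expect_equal(m$best_match, "r2")
  expect_true(m$call)
  expect_warning(
    m0 <- match_precursor(profile(NULL), list(r1 = b), g),
    "diploid")
  expect_false(m0$call)
})

test_that("bulk validation retains only direction-concordant overlapping segments", {
  seg <- function(chr, start, end, cn)
    data.frame(chromosome = chr, start = start, end = end, copy_number = cn)
  subcl <- rbind(seg("chr1", 100, 200, 3),   # overlaps bulk gain -> kept
                 seg("chr1", 300, 400, 1),   # overlaps bulk loss -> kept
                 seg("chr1", 500, 600, 3),   # overlaps bulk loss -> dropped
                 seg("chr2", 100, 200, 4))   # no bulk overlap -> dropped
  bulk <- rbind(seg("chr1", 150, 250, 2.8),
                seg("chr1", 250, 550, 1.3),
                seg("chr2", 300, 400, 3.5))
  out <- validate_subclone_cnv(subcl, bulk)
  expect_equal(nrow(out), 2)
  expect_equal(out$start, c(100, 300))

  # gain over an all-diploid bulk is dropped
  out2 <- validate_subclone_cnv(seg("chr1", 1, 1000, 3), seg("chr1", 1, 1e6, 2))
  expect_equal(nrow(out2), 0)
})
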