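test_that("gene mean filter keeps exactly the >= cutoff survivors in order", {
  means <- c(0.099, 0.1, 0, 0.5, 0.0999, 2, 0.1001, 0.05, 1, 0.2)
  norm <- Matrix::Matrix(rbind(means, means), sparse = TRUE)
  colnames(norm) <- paste0("g", 1:10)
  rownames(norm) <- c("a", "b")
  kept <- filter_genes_by_mean(norm, min_mean = 0.1)
  expect_equal(kept, paste0("g", c(2, 4, 6, 7, 9, 10)))
  expect_equal(filter_genes_by_mean(norm, min_mean = 0), colnames(norm))
  expect_error(filter_genes_by_mean(norm, min_mean = 10), "cutoff")
})

test_that("reference residuals center on the reference and clip extremes", {
  set.seed(10)
  x <- matrix(rnorm(200 * 20, mean = 2), 200, 20)
  rownames(x) <- paste0("c", 1:200)
  colnames(x) <- paste0("g", 1:20)
  res <- reference_residuals(x, reference_cells = 1:100)
  expect_true(all(abs(colMeans(res[1:100, ])) < 0.05))
  x2 <- x; x2[1, 1] <- 100
  res2 <- reference_residuals(x2, reference_cells = 101:200, clip = 3)
  expect_equal(res2[1, 1], 3)
  expect_true(all(res2 <= 3 & res2 >= -3))
})

test_that("triangular smoothing matches a brute-force oracle and conserves constants", {
  set.seed(11)
  chroms <- rep(c("chr1", "chr2"), c(13, 9))
  x <- matrix(rnorm(3 * 22), 3, 22)
  sm <- smooth_chromosome(x, chroms, window = 5)
  expect_equal(sm, brute_smooth(x, chroms, 5), tolerance = 1e-10)

  expect_equal(smooth_chromosome(x, chroms, window = 1), x)
  const <- matrix(2.5, 2, 22)
  expect_equal(smooth_chromosome(const, chroms, window = 7), const,
               tolerance = 1e-12)
  expect_error(smooth_chromosome(x, chroms, window = 4), "odd")

  # invariant to cell order
  sm_perm <- smooth_chromosome(x[c(3, 1, 2), ], chroms, window = 5)
  expect_equal(sm_perm, sm[c(3, 1, 2), ], tolerance = 1e-12)
})

test_that("per-cell median centering is exact and shift-invariant", {
  set.seed(12)
  x <- matrix(rnorm(50), 5, 10)
  cx <- center_cells(x)
  expect_true(all(abs(apply(cx, 1, median)) < 1e-12))
  expect_equal(center_cells(cx), cx)
  y <- x; y[2, ] <- y[2, ] + 0.7
  expect_equal(center_cells(y)[2, ], cx[2, ])
})

test_that("viterbi equals exhaustive path enumeration on short segments", {
  p0 <- hmm_params(sigma = 0.1)
  expect_equal(viterbi_states(rep(p0$mu[3], 10), p0), rep(2L, 10))

  set.seed(13)
  for (i in 1:25) {
    L <- sample(2:8, 1)
    params <- hmm_params(sigma = runif(1, 0.05, 0.6),
                         transition = 10^runif(1, -6, -1))
    obs <- runif(L, -4, 1.2)
    expect_equal(viterbi_states(obs, params), brute_viterbi(obs, params),
                 info = sprintf("instance %d (L=%d)", i, L))
  }
  expect_error(viterbi_states(numeric(0), p0), "empty")
})

test_that("a planted run is recovered with breakpoints within one position", {
  params <- hmm_params(sigma = 0.15, transition = 1e-6)
  set.seed(14)
  truth <- c(rep(2, 40), rep(4, 30), rep(2, 40))
  obs <- params$mu[truth + 1] + rnorm(length(truth), sd = 0.05)
  path <- viterbi_states(obs, params)
  expect_true(all(path[2:39] == 2))
  expect_true(all(path[42:69] == 4))
  expect_true(all(path[72:109] == 2))
})

test_that("hmm parameter validation enforces the uniform-switch model", {
  expect_error(hmm_params(sigma = 0), "sigma")
  expect_error(hmm_params(sigma = 1, transition = 0.3), "transition")
  p <- hmm_params(sigma = 0.1, eps0 = 0.05)
  expect_equal(p$mu, log(c(0.05, 1, 2, 3, 4, 5) / 2))
})

test_that("states collapse to segments with the majority-merge rule", {
  gene_meta <- data.frame(gene = paste0("g", 1:8), chromosome = "chr1",
                          start = seq(1, 71, 10), end = seq(5, 75, 10))
  # all-diploid group: no events
  st <- matrix(2L, 3, 8)
  seg <- states_to_segments(st, gene_meta, rep("s1", 3))
  expect_equal(nrow(seg), 1)
  expect_equal(seg$copy_number, 2)
  expect_equal(nrow(seg[seg$copy_number != 2, ]), 0)

  # two adjacent runs 3 then 1: boundary between gene 4 and gene 5
  st2 <- matrix(rep(c(3L, 3L, 3L, 3L, 1L, 1L, 1L, 1L), each = 2), 2, 8)
  seg2 <- states_to_segments(st2, gene_meta, rep("s1", 2))
  expect_equal(seg2$copy_number, c(3, 1))
  expect_equal(seg2$end[1], gene_meta$end[4])
  expect_equal(seg2$start[2], gene_meta$start[5])

  # majority vote with diploid-first tie-break
  st3 <- rbind(rep(3L, 8), rep(2L, 8))
  seg3 <- states_to_segments(st3, gene_meta, rep("s1", 2))
  expect_equal(seg3$copy_number, 2)
})

test_that("subclone mean profiles are arithmetic means per label", {
  x <- rbind(a = c(1, 2), b = c(1, 2), c = c(5, 6))
  prof <- subclone_mean_profile(x, c("s1", "s1", "s2"))
  expect_equal(prof["s1", ], c(1, 2), ignore_attr = TRUE)
  expect_equal(prof["s2", ], c(5, 6), ignore_attr = TRUE)
})

test_that("inference is self-consistent when query equals a homogeneous reference", {
  s <- med_sim()
  sim <- s$sim
  norm <- med_norm()
  # a single normal cell type: no copy-number events and no cross-type
  # marker heterogeneity, the clean-baseline setting
  tcells <- sim$cell_meta$cell[sim$cell_meta$population == "T"]
  cnv <- infer_cnv(norm[tcells, , drop = FALSE], sim$gene_meta, tcells,
                   window = 31)
  expect_gte(mean(cnv$states == 2), 0.99)
})

test_that("planted events are recovered with correct per-gene direction", {
  s <- med_sim()
  sim <- s$sim
  norm <- med_norm()
  ref <- sim$cell_meta$cell[!sim$cell_meta$malignant]
  cnv <- infer_cnv(norm, sim$gene_meta, ref, window = 31)

  # per-gene majority direction (gain/loss) across each subclone's cells
  for (clone in c("cloneA", "cloneB", "cloneC")) {
    cells <- sim$cell_meta$cell[sim$cell_meta$population == clone]
    st <- cnv$states[cells, , drop = FALSE]
    truth_cn <- clonotrace:::gene_copy_numbers(s$genome, s$arch[[clone]])
    names(truth_cn) <- s$genome$genes$gene
    truth_kept <- truth_cn[cnv$kept_genes]
    in_event <- truth_kept != 2
    dir_truth <- sign(truth_kept[in_event] - 2)
    maj <- apply(st[, in_event, drop = FALSE], 2, function(col) {
      sign(mean(sign(col - 2)))
    })
    acc <- mean(maj == dir_truth)
    expect_gte(acc, 0.9)
  }
})
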