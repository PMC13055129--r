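test_that("genome layout is ordered, bounded and deterministic", {
  g1 <- build_genome(1, 1, seed = 0)
  expect_equal(nrow(g1$genes), 1)
  expect_true(g1$genes$end <= g1$chromosomes$length)

  g <- build_genome(22, 300, seed = 1)
  expect_equal(nrow(g$genes), 6600)
  for (chr in g$chromosomes$chromosome) {
    gc <- g$genes[g$genes$chromosome == chr, ]
    expect_false(is.unsorted(gc$start, strictly = TRUE))
    expect_true(all(gc$start[-1] > gc$end[-nrow(gc)]))  # non-overlapping
  }
  expect_identical(build_genome(3, 50, seed = 9)$genes,
                   build_genome(3, 50, seed = 9)$genes)
  expect_error(build_genome(0, 10), "must be >= 1")
})

test_that("clonal architecture resolves inheritance and validates proportions", {
  g <- build_genome(3, 40, seed = 2)

  # diploid identity
  clones <- plant_clonal_architecture(g, list(
    list(id = "c1", parent = NA, events = NULL,
         proportions = list(Dg = 1, Rel = 1))))
  expect_equal(nrow(clones$c1$events), 0)
  expect_true(all(clones$c1$segments$copy_number == 2))

  # minor resistant clone proportion recorded exactly as planted
  spec2 <- list(
    list(id = "c1", parent = NA, events = NULL,
         proportions = list(Dg = 0.99, Rel = 0.1)),
    list(id = "c2", parent = NA, events = NULL,
         proportions = list(Dg = 0.01, Rel = 0.9)))
  clones2 <- plant_clonal_architecture(g, spec2)
  expect_equal(clones2$c2$proportions[["Dg"]], 0.01)

  # proportions must sum to one per sample
  expect_error(plant_clonal_architecture(g, list(
    list(id = "c1", parent = NA, events = NULL,
         proportions = list(Dg = 0.5)))), "sum to")

  # a child's private amplification overrides the parent's deletion
  gc <- g$genes[g$genes$chromosome == "chr1", ]
  parent_del <- data.frame(chromosome = "chr1", start = gc$start[5],
                           end = gc$end[30], copy_number = 1)
  child_amp <- data.frame(chromosome = "chr1", start = gc$start[10],
                          end = gc$end[20], copy_number = 4)
  clones3 <- plant_clonal_architecture(g, list(
    list(id = "p", parent = NA, events = parent_del,
         proportions = list(Dg = 0.6)),
    list(id = "k", parent = "p", events = child_amp,
         proportions = list(Dg = 0.4))))
  seg_k <- clones3$k$segments
  amp <- seg_k[seg_k$copy_number == 4, ]
  expect_equal(nrow(amp), 1)
  expect_equal(c(amp$start, amp$end), c(gc$start[10], gc$end[20]))
  # flanks of the parent's deletion remain deleted in the child
  expect_true(any(seg_k$copy_number == 1 & seg_k$start == gc$start[5]))

  # events outside chromosome bounds are rejected
  expect_error(plant_clonal_architecture(g, list(
    list(id = "c1", parent = NA,
         events = data.frame(chromosome = "chr1", start = 1,
                             end = g$chromosomes$length[1] + 10, copy_number = 3),
         proportions = list(Dg = 1)))), "bounds")
})

test_that("expected bulk segments are the proportion-weighted clone mixture", {
  g <- build_genome(2, 60, seed = 3)

  dip <- plant_clonal_architecture(g, list(
    list(id = "c1", parent = NA, events = NULL, proportions = list(Dg = 1))))
  bulk <- truth_bulk_segments(g, dip, "Dg")
  expect_true(all(bulk$copy_number == 2))

  # 50/50 mixture of diploid and a 4-copy segment -> 3.0 over the segment
  gc <- g$genes[g$genes$chromosome == "chr1", ]
  ev <- data.frame(chromosome = "chr1", start = 100001, end = 300000,
                   copy_number = 4)
  mix <- plant_clonal_architecture(g, list(
    list(id = "c1", parent = NA, events = NULL,
         proportions = list(Dg = 0.5)),
    list(id = "c2", parent = NA, events = ev, proportions = list(Dg = 0.5))))
  bulk2 <- truth_bulk_segments(g, mix, "Dg", bin_size = 100000)
  in_ev <- bulk2$chromosome == "chr1" & bulk2$start >= 100001 & bulk2$end <= 300000
  expect_true(all(abs(bulk2$copy_number[in_ev] - 3) < 1e-12))
  expect_true(all(abs(bulk2$copy_number[!in_ev] - 2) < 1e-12))

  # 0.9/0.09/0.01 mixture equals a per-bin brute-force weighted sum
  ev_b <- data.frame(chromosome = "chr2", start = 50001, end = 250000,
                     copy_number = 1)
  ev_c <- data.frame(chromosome = "chr1", start = 150001, end = 249999,
                     copy_number = 5)
  tri <- plant_clonal_architecture(g, list(
    list(id = "a", parent = NA, events = NULL, proportions = list(Dg = 0.9)),
    list(id = "b", parent = NA, events = ev_b, proportions = list(Dg = 0.09)),
    list(id = "c", parent = NA, events = ev_c, proportions = list(Dg = 0.01))))
  bulk3 <- truth_bulk_segments(g, tri, "Dg", bin_size = 100000)
  # brute force: per bin, per clone, average copy number over each bp block
  clone_cn_at <- function(clone, chr, lo, hi) {
    segs <- clone$segments[clone$segments$chromosome == chr, ]
    tot <- 0
    for (i in seq_len(nrow(segs))) {
      ov <- max(0, min(hi, segs$end[i]) - max(lo, segs$start[i]) + 1)
      tot <- tot + ov * segs$copy_number[i]
    }
    tot / (hi - lo + 1)
  }
  for (row in sample(nrow(bulk3), min(12, nrow(bulk3)))) {
    chr <- bulk3$chromosome[row]
    # locate the original 100 kb bin(s) covered by this merged run
    lo <- bulk3$start[row]; hi <- min(lo + 99999, bulk3$end[row])
    want <- 0.9 * clone_cn_at(tri$a, chr, lo, hi) +
      0.09 * clone_cn_at(tri$b, chr, lo, hi) +
      0.01 * clone_cn_at(tri$c, chr, lo, hi)
    expect_equal(bulk3$copy_number[row], want, tolerance = 1e-12)
  }
})
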