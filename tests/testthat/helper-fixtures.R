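# shared fixtures and independent oracles for the test suite

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# three-subclone architecture with explicit, non-overlapping events sized for
# small test genomes (each event spans >= 30 genes on >= 6-chromosome genomes)
make_test_arch <- function(genome,
                           dg_props = c(A = 0.90, B = 0.09, C = 0.01),
                           rel_props = c(A = 0.04, B = 0.06, C = 0.90)) {
  ev <- function(chr, from, to, cn) {
    gc <- genome$genes[genome$genes$chromosome == chr, ]
    data.frame(chromosome = chr, start = gc$start[from], end = gc$end[to],
               copy_number = cn, stringsAsFactors = FALSE)
  }
  truncal <- ev("chr5", 10, 55, 3)
  pr <- function(id) list(Dg = dg_props[[id]], Rel = rel_props[[id]])
  plant_clonal_architecture(genome, list(
    list(id = "cloneA", parent = NA, proportions = pr("A"),
         events = rbind(truncal, ev("chr1", 10, 69, 1))),
    list(id = "cloneB", parent = NA, proportions = pr("B"),
         events = rbind(truncal, ev("chr2", 10, 69, 4))),
    list(id = "cloneC", parent = NA, proportions = pr("C"),
         events = rbind(truncal, ev("chr3", 10, 69, 4), ev("chr4", 15, 74, 1)))
  ))
}

# medium simulation reused across module tests
med_sim <- function() cached("med_sim", function() {
  genome <- build_genome(6, 80, seed = 11)
  arch <- make_test_arch(genome)
  cfg <- simulation_config(
    genome,
    normal_counts = c(B = 60, T = 80, NK = 30, Mono = 30),
    malignant_count = 400, seed = 7
  )
  list(genome = genome, arch = arch, cfg = cfg,
       sim = simulate_counts(genome, arch, cfg))
})

med_norm <- function() cached("med_norm", function() {
  log_normalize(med_sim()$sim$counts)
})

# --- independent oracles ----------------------------------------------------

# brute-force triangular moving average, computed position by position
brute_smooth <- function(x, chroms, window) {
  m <- (window - 1) / 2
  out <- x
  for (r in seq_len(nrow(x))) {
    for (j in seq_len(ncol(x))) {
      idx <- seq(j - m, j + m)
      ok <- idx >= 1 & idx <= ncol(x) & chroms[pmin(pmax(idx, 1), ncol(x))] == chroms[j]
      idx <- idx[ok]
      w <- (m + 1 - abs(idx - j))
      out[r, j] <- sum(w * x[r, idx]) / sum(w)
    }
  }
  out
}

# exhaustive Viterbi: scores every one of 6^L state paths
brute_viterbi <- function(obs, params) {
  L <- length(obs)
  mu <- params$mu; sigma <- params$sigma
  log_stay <- log(1 - 5 * params$transition)
  log_switch <- log(params$transition)
  em <- function(s, o) -0.5 * ((o - mu[s + 1]) / sigma)^2
  scores <- log(params$initial) + em(0:5, obs[1])
  last <- 0:5
  paths <- matrix(0:5, ncol = 1)
  for (t in seq_len(L)[-1]) {
    k <- length(scores)
    trans <- outer(last, 0:5, function(a, b) ifelse(a == b, log_stay, log_switch))
    new_scores <- as.vector(sweep(trans, 2, em(0:5, obs[t]), "+") + scores)
    paths <- cbind(paths[rep(seq_len(k), 6), , drop = FALSE],
                   rep(0:5, each = k))
    scores <- new_scores
    last <- rep(0:5, each = k)
  }
  paths[which.max(scores), ]
}

# running-sum GSEA enrichment score computed by the definition, step by step
brute_gsea_es <- function(hit_pos, scores, weight = 1) {
  n <- length(scores)
  m <- length(hit_pos)
  inc <- abs(scores)^weight
  nr <- sum(inc[hit_pos])
  run <- 0; best <- 0
  for (i in seq_len(n)) {
    run <- run + if (i %in% hit_pos) inc[i] / nr else -1 / (n - m)
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# exact two-sided rank-sum p by complete subset enumeration
brute_ranksum_p <- function(x_a, x_b) {
  vals <- c(x_a, x_b)
  r <- rank(vals)
  nA <- length(x_a)
  n <- length(vals)
  mu <- nA * (n + 1) / 2
  w_obs <- sum(r[seq_len(nA)])
  combs <- utils::combn(n, nA)
  w_all <- apply(combs, 2, function(idx) sum(r[idx]))
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}
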