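test_that("simulated genomes hit the requested gap fraction deterministically", {
  # no gaps at all
  sim0 <- simulate_genome(genome_sim_spec(2, 1e4, 0, seed = 1))
  expect_equal(nrow(sim0$gaps), 0)

  # 2 x 10 Mbp at 7.6%: total gap length within +/-1% of target
  spec <- genome_sim_spec(2, 1e7, 0.076, seed = 42)
  sim <- simulate_genome(spec)
  expect_gte(total_bp(sim$gaps), 1.505e6)
  expect_lte(total_bp(sim$gaps), 1.535e6)
  # gaps disjoint and inside the genome
  gp <- sim$gaps
  same <- gp$chrom[-1] == gp$chrom[-nrow(gp)]
  expect_true(all(gp$start[-1][same] > gp$end[-nrow(gp)][same]))
  expect_true(all(gp$end <= sim$genome$lengths[gp$chrom]))

  # determinism
  sim2 <- simulate_genome(spec)
  expect_identical(as.data.frame(sim2$gaps), as.data.frame(sim$gaps))

  # stochastic gap-length laws also land on target
  spec_ln <- genome_sim_spec(2, 1e6, 0.1,
                             gap_length_law = list(law = "lognormal",
                                                   meanlog = 8, sdlog = 0.5),
                             seed = 3)
  sim_ln <- simulate_genome(spec_ln)
  expect_lt(abs(total_bp(sim_ln$gaps) - 0.1 * sim_ln$genome$total),
            0.01 * 0.1 * sim_ln$genome$total + 1)
})

test_that("single-element placement is uniform over feasible starts", {
  g <- toy_genome(chr1 = 10)
  sp <- accessible_space(g)
  keys <- withr::with_seed(7, {
    replicate(20000, placement_key(sample_uniform_placement(2, sp)))
  })
  counts <- table(factor(keys, levels = sprintf("%d-%d", 0:8, 2:10)))
  expect_equal(sum(counts), 20000)
  gof <- chisq.test(as.vector(counts), p = rep(1 / 9, 9))
  expect_gt(gof$p.value, 0.001)
})

test_that("placement tiles the space completely in the pigeonhole case", {
  g <- toy_genome(chr1 = 30)
  gaps <- interval_set("chr1", c(0, 25), c(5, 30), label = "gaps")
  sp <- accessible_space(g, gaps)   # single 20 bp run
  x <- sample_uniform_placement(c(7, 13), sp, seed = 3)
  expect_equal(total_bp(x), 20)
  expect_equal(base_overlap(x, gaps), 0)
})

test_that("mixed-length placements never intersect gaps and keep the multiset", {
  sim <- simulate_genome(genome_sim_spec(1, 1e4, 0.2, seed = 9))
  sp <- accessible_space(sim$genome, sim$gaps)
  hits <- withr::with_seed(10, {
    vapply(1:2000, function(i) {
      base_overlap(sample_uniform_placement(c(3, 5), sp), sim$gaps)
    }, numeric(1))
  })
  expect_equal(sum(hits), 0)
  y <- sample_uniform_placement(c(3, 5, 5, 11), sp, seed = 4)
  expect_equal(sort(segment_lengths(y)), c(3, 5, 5, 11))
  expect_error(sample_uniform_placement(rep(1000, 10), sp), "infeasible")
})

test_that("multi-run draws are uniform over all enumerated arrangements", {
  # 12 bp chromosome with a 2 bp gap -> two 5 bp accessible runs;
  # two elements of length 2: 22 feasible arrangements in total
  g <- toy_genome(chr1 = 12)
  gaps <- interval_set("chr1", 5, 7, label = "gaps")
  support <- enumerate_arrangements(c(2, 2), runs_of(g, gaps))
  expect_length(support, 22)
  sp <- accessible_space(g, gaps)
  keys <- withr::with_seed(21, {
    replicate(20000, placement_key(sample_uniform_placement(c(2, 2), sp)))
  })
  expect_true(all(keys %in% support))
  counts <- table(factor(keys, levels = support))
  gof <- chisq.test(as.vector(counts), p = rep(1 / length(support), length(support)))
  expect_gt(gof$p.value, 0.001)
})

test_that("single-run multi-element draws are uniform (order-statistics path)", {
  g <- toy_genome(chr1 = 10)
  support <- enumerate_arrangements(c(2, 2), runs_of(g))
  expect_length(support, 28)
  sp <- accessible_space(g)
  keys <- withr::with_seed(22, {
    replicate(20000, placement_key(sample_uniform_placement(c(2, 2), sp)))
  })
  counts <- table(factor(keys, levels = support))
  gof <- chisq.test(as.vector(counts), p = rep(1 / length(support), length(support)))
  expect_gt(gof$p.value, 0.001)
})

test_that("shuffling preserves the exact length multiset", {
  g <- toy_genome(chr1 = 5e4)
  withr::with_seed(31, {
    track <- random_iset(g, 100, max_len = 30, label = "t")
    shuf <- shuffle_track(track, g, seed = 5)
    expect_equal(sort(segment_lengths(shuf)), sort(segment_lengths(track)))
    expect_equal(n_intervals(shuf), n_intervals(track))
  })
})

test_that("absent gaps and an empty gap set induce the same placement law", {
  g <- toy_genome(chr1 = 20)
  track <- interval_set("chr1", c(0, 10), c(3, 12), label = "t")
  empty <- interval_set(character(0), numeric(0), numeric(0), label = "gaps")
  a <- shuffle_track(track, g, gaps = NULL, seed = 99)
  b <- shuffle_track(track, g, gaps = empty, seed = 99)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("arm-stratified shuffles put the requested counts strictly within arms", {
  g <- genome(c(chr1 = 1000), arm_split = c(chr1 = 400))
  track <- interval_set("chr1", seq(0, 90, by = 10), seq(5, 95, by = 10),
                        label = "t")  # 10 elements of length 5
  withr::with_seed(41, {
    for (i in 1:50) {
      s <- shuffle_track(track, g, arm_counts = c(p = 3, q = 7))
      expect_equal(sum(s$end <= 400), 3)
      expect_equal(sum(s$start >= 400), 7)
    }
  })
})

test_that("null pairs avoid gaps, are reproducible, and are independent", {
  sim <- simulate_genome(genome_sim_spec(1, 1e4, 0.2, seed = 51))
  spec <- track_sim_spec(20, list(law = "fixed", length = 50))
  pair <- simulate_null_pair(spec, spec, sim$genome, sim$gaps, seed = 8)
  expect_equal(base_overlap(pair$a, sim$gaps), 0)
  expect_equal(base_overlap(pair$b, sim$gaps), 0)
  pair2 <- simulate_null_pair(spec, spec, sim$genome, sim$gaps, seed = 8)
  expect_identical(as.data.frame(pair2$a), as.data.frame(pair$a))
  expect_identical(as.data.frame(pair2$b), as.data.frame(pair$b))

  # Per-window coverage of A and B uncorrelated over replicate pairs.
  # Each window's coverage is centred across replicates first: both tracks
  # avoid the same gaps, so raw window means share the accessibility
  # profile by design; independence concerns the fluctuations around it.
  wins <- data.frame(chrom = "chr1", start = seq(0, 9500, by = 500),
                     end = seq(500, 10000, by = 500))
  n_rep <- 500
  cov_a <- cov_b <- matrix(0, n_rep, nrow(wins))
  for (i in seq_len(n_rep)) {
    p <- simulate_null_pair(spec, spec, sim$genome, sim$gaps, seed = 1000 + i)
    cov_a[i, ] <- overlap_by_interval(p$a, wins)
    cov_b[i, ] <- overlap_by_interval(p$b, wins)
  }
  ra <- scale(cov_a, center = TRUE, scale = FALSE)
  rb <- scale(cov_b, center = TRUE, scale = FALSE)
  expect_lt(abs(cor(as.vector(ra), as.vector(rb))), 0.1)
})

test_that("mean overlap of independent unit-element pairs matches b_A*b_B/G_acc", {
  sim <- simulate_genome(genome_sim_spec(1, 1e4, 0.2, seed = 61))
  g_acc <- sim$genome$total - total_bp(sim$gaps)
  spec <- track_sim_spec(200, list(law = "fixed", length = 1))
  n_rep <- 2000
  ov <- withr::with_seed(62, {
    vapply(seq_len(n_rep), function(i) {
      p <- simulate_null_pair(spec, spec, sim$genome, sim$gaps)
      base_overlap(p$a, p$b)
    }, numeric(1))
  })
  expected <- 200 * 200 / g_acc
  se <- stats::sd(ov) / sqrt(n_rep)
  expect_lt(abs(mean(ov) - expected), 3 * se)
})

test_that("empirical and lognormal segment-length laws are honoured", {
  sim <- simulate_genome(genome_sim_spec(1, 1e5, 0.1, seed = 71))
  lens <- c(10, 20, 20, 35, 50)
  spec <- track_sim_spec(5, list(law = "empirical", lengths = lens))
  tr <- simulate_track(spec, sim$genome, sim$gaps, seed = 72)
  expect_equal(sort(segment_lengths(tr)), sort(lens))
  spec_ln <- track_sim_spec(40, list(law = "lognormal", meanlog = 3, sdlog = 0.4))
  tr_ln <- simulate_track(spec_ln, sim$genome, sim$gaps, seed = 73)
  expect_equal(n_intervals(tr_ln), 40)
  expect_true(all(segment_lengths(tr_ln) >= 1))
})
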