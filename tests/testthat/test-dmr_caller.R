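cfg <- dmr_config()

test_that("summarize_windows aggregates sites per window and context", {
  mt <- mk_methylome(pos = c(seq(10, 60, by = 10), 150, 250),
                     meth = c(rep(5L, 6), 2L, 0L),
                     total = c(rep(10L, 6), 4L, 8L))
  w <- summarize_windows(mt, "CG", cfg)
  expect_equal(nrow(w), 3L)
  first <- w[w$start == 0, ]
  expect_equal(first$n_sites, 6L)
  expect_equal(first$mean_cov, 10)
  expect_equal(first$level, 0.5)
  # no CHH sites anywhere -> nothing emitted for CHH
  expect_equal(nrow(summarize_windows(mt, "CHH", cfg)), 0L)
})

test_that("per-window levels match brute-force recomputation on random data", {
  set.seed(11)
  n <- 3000
  pos <- sort(sample.int(20000, n))
  total <- rpois(n, 8)
  meth <- rbinom(n, total, runif(n))
  mt <- mk_methylome(pos, meth, total)
  w <- summarize_windows(mt, "CG", cfg)
  for (i in sample(nrow(w), 50)) {
    sel <- pos > w$start[i] & pos <= w$end[i] & total > 0
    expect_equal(w$level[i], oracle_weighted_level(meth[sel], total[sel]))
    expect_equal(w$n_sites[i], sum(sel))
  }
  # windows tile without overlap
  expect_true(all(w$end - w$start == 100))
  expect_true(all(diff(w$start) >= 100))
})

test_that("candidate_windows applies eligibility in both samples and the
           per-context level threshold", {
  win <- function(n_sites, mean_cov, level, start = 0)
    data.frame(chrom = "chr1", start = start, end = start + 100,
               context = "CG", n_sites = n_sites, mean_cov = mean_cov,
               meth_sum = round(level * n_sites * mean_cov),
               total_sum = n_sites * mean_cov, level = level)
  # 0.10 vs 0.45, both eligible -> kept (diff 0.35 >= 0.30)
  got <- candidate_windows(win(6, 10, 0.10), win(6, 10, 0.45), "CG", cfg)
  expect_equal(nrow(got), 1L)
  expect_equal(got$delta, 0.35)
  # 5 sites in sample A -> dropped regardless of difference
  expect_equal(nrow(candidate_windows(win(5, 10, 0.0), win(10, 10, 1.0),
                                      "CG", cfg)), 0L)
  # low coverage in sample B -> dropped
  expect_equal(nrow(candidate_windows(win(6, 10, 0.0), win(6, 2.9, 1.0),
                                      "CG", cfg)), 0L)
  # identical summaries -> empty
  expect_equal(nrow(candidate_windows(win(8, 10, 0.5), win(8, 10, 0.5),
                                      "CG", cfg)), 0L)
  # CHH threshold is 0.10
  expect_equal(nrow(candidate_windows(
    within(win(6, 10, 0.10), context <- "CHH"),
    within(win(6, 10, 0.25), context <- "CHH"), "CHH", cfg)), 1L)
})

test_that("cytosine_fraction_filter keeps windows at >= 80% differential
           cytosines with sign agreement", {
  mk_pair <- function(ratios_a, ratios_b, depth = 10L) {
    pos <- seq(5, by = 9, length.out = length(ratios_a))
    list(a = mk_methylome(pos, as.integer(round(ratios_a * depth)),
                          rep(depth, length(pos))),
         b = mk_methylome(pos, as.integer(round(ratios_b * depth)),
                          rep(depth, length(pos))))
  }
  cand <- data.table::data.table(
    chrom = "chr1", start = 0L, end = 100L, context = "CG",
    n_sites_a = 10L, n_sites_b = 10L, mean_cov_a = 10, mean_cov_b = 10,
    level_a = 0.2, level_b = 0.65, delta = 0.45)
  # 9 of 10 cytosines at +0.5, one at 0 -> fraction 0.9 -> kept
  p <- mk_pair(rep(0.2, 10), c(rep(0.7, 9), 0.2))
  kept <- cytosine_fraction_filter(cand, p$a, p$b, cfg)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$diff_fraction, 0.9)
  # 7 of 10 differential -> 0.7 -> dropped
  p2 <- mk_pair(rep(0.2, 10), c(rep(0.7, 7), rep(0.2, 3)))
  expect_equal(nrow(cytosine_fraction_filter(cand, p2$a, p2$b, cfg)), 0L)
  # opposing-sign cytosines do not count as differential: 8 up + 2 down
  # gives fraction 0.8, not 1.0
  p3 <- mk_pair(rep(0.5, 10), c(rep(0.9, 8), 0.1, 0.1))
  k3 <- cytosine_fraction_filter(cand, p3$a, p3$b, cfg)
  expect_equal(k3$diff_fraction, 0.8)
  # ... and with 7 up + 3 down the window falls below 0.8 and is dropped
  p3b <- mk_pair(rep(0.5, 10), c(rep(0.9, 7), 0.1, 0.1, 0.1))
  expect_equal(nrow(cytosine_fraction_filter(cand, p3b$a, p3b$b, cfg)), 0L)
  # no co-covered cytosines -> dropped with warning
  p4 <- mk_pair(rep(0.2, 10), rep(0.7, 10))
  empty_b <- mk_methylome(1000, 0L, 5L)
  expect_warning(
    out <- cytosine_fraction_filter(cand, p4$a, empty_b, cfg),
    "no co-covered")
  expect_equal(nrow(out), 0L)
})

test_that("merging joins same-direction windows within 100 bp and final
           thresholds are size-dependent", {
  # 10 CG sites per window in windows [0,100) and [200,300): gap 100 -> merge
  mk <- function(level, depth = 20L) {
    pos <- c(seq(5, 95, by = 10), seq(205, 295, by = 10))
    mk_methylome(pos, as.integer(round(level * depth)),
                 rep(depth, length(pos)))
  }
  filt <- data.table::data.table(
    chrom = "chr1", start = c(0L, 200L), end = c(100L, 300L),
    context = "CG", level_a = 0.1, level_b = 0.6, delta = 0.5,
    diff_fraction = 1)
  dmr <- merge_and_finalize(filt, mk(0.1), mk(0.6), "CG", cfg)
  expect_equal(nrow(dmr), 1L)
  expect_equal(dmr$start, 0L)
  expect_equal(dmr$end, 300L)
  expect_equal(dmr$n_windows, 2L)
  expect_equal(dmr$direction, "hyper")
  # merged (>100 bp) CG region: |delta| 0.5 >= 0.30 retained; a single
  # 100-bp window with the same recomputed delta 0.5 < 0.60 is rejected
  single <- filt[1]
  mk1 <- function(level, depth = 20L)
    mk_methylome(seq(5, 95, by = 10),
                 as.integer(round(level * depth)), rep(depth, 10))
  expect_equal(nrow(merge_and_finalize(single, mk1(0.05), mk1(0.55),
                                       "CG", cfg)), 0L)
  expect_equal(nrow(merge_and_finalize(single, mk1(0.05), mk1(0.70),
                                       "CG", cfg)), 1L)
  # opposite-direction windows at gap 100 are not merged
  filt2 <- data.table::copy(filt)
  filt2$delta <- c(0.7, -0.7)
  pos2 <- c(seq(5, 95, by = 10), seq(205, 295, by = 10))
  a2 <- mk_methylome(pos2, c(rep(2L, 10), rep(16L, 10)), rep(20L, 20))
  b2 <- mk_methylome(pos2, c(rep(16L, 10), rep(2L, 10)), rep(20L, 20))
  two <- merge_and_finalize(filt2, a2, b2, "CG", cfg)
  expect_equal(nrow(two), 2L)
  expect_equal(two$direction, c("hyper", "hypo"))
})

test_that("call_dmrs of a table against itself is empty and swapping the
           samples flips direction on identical intervals", {
  sim <- simulate_methylome_pair(simulation_design(
    chrom_sizes = c(chr1 = 100000L), control_chrom = NULL,
    planted_dmrs = default_planted_dmrs(c(chr1 = 100000L), 10L, 10L),
    seed = 5))
  expect_equal(nrow(call_dmrs(sim$a, sim$a, "CG")), 0L)
  ab <- call_dmrs(sim$a, sim$b, "CG")
  ba <- call_dmrs(sim$b, sim$a, "CG")
  expect_equal(ab[, c("chrom", "start", "end")],
               ba[, c("chrom", "start", "end")])
  expect_equal(ab$direction,
               ifelse(ba$direction == "hyper", "hypo", "hyper"))
  expect_equal(ab$delta, -ba$delta)
})

test_that("every reported DMR passes its size-appropriate final threshold
           when recomputed from raw calls (self-audit)", {
  sim <- simulate_methylome_pair(simulation_design(
    chrom_sizes = c(chr1 = 200000L), control_chrom = NULL,
    planted_dmrs = default_planted_dmrs(c(chr1 = 200000L), 15L, 15L),
    seed = 9))
  dmrs <- call_dmrs(sim$a, sim$b, "CG")
  expect_gt(nrow(dmrs), 0L)
  a <- as.data.frame(sim$a)
  b <- as.data.frame(sim$b)
  for (i in seq_len(nrow(dmrs))) {
    sa <- a[a$context == "CG" & a$pos > dmrs$start[i] &
              a$pos <= dmrs$end[i] & a$total_reads > 0, ]
    sb <- b[b$context == "CG" & b$pos > dmrs$start[i] &
              b$pos <= dmrs$end[i] & b$total_reads > 0, ]
    delta <- oracle_weighted_level(sb$meth_reads, sb$total_reads) -
      oracle_weighted_level(sa$meth_reads, sa$total_reads)
    expect_equal(delta, dmrs$delta[i])
    thr <- if (dmrs$end[i] - dmrs$start[i] == 100) 0.60 else 0.30
    expect_gte(abs(delta), thr)
    expect_equal(dmrs$direction[i], if (delta > 0) "hyper" else "hypo")
  }
})
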