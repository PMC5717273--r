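test_that("Fisher's exact test matches enumeration, fisher.test and examples", {
  expect_equal(fisher_exact_two_sided(5, 5, 5, 5), 1)
  expect_equal(fisher_exact_two_sided(0, 10, 10, 0), 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_equal(fisher_exact_two_sided(30, 70, 10, 90),
               fisher_oracle(30, 70, 10, 90), tolerance = 1e-10)

  set.seed(99)
  for (i in 1:200) {
    tab <- matrix(rpois(4, sample(c(2, 10, 60), 1L)), 2L)
    if (sum(tab) == 0) next
    got <- fisher_exact_two_sided(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    expect_equal(got, fisher_oracle(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                 tolerance = 1e-10)
    expect_equal(got, stats::fisher.test(tab)$p.value, tolerance = 1e-9)
    # row swap (sample relabelling) must give a bit-identical p
    expect_identical(got, fisher_exact_two_sided(tab[2, 1], tab[2, 2],
                                                 tab[1, 1], tab[1, 2]))
  }
  expect_error(fisher_exact_two_sided(0, 0, 0, 0), "zero")
  expect_error(fisher_exact_two_sided(-1, 1, 1, 1), "non-negative")
})

test_that("Benjamini-Hochberg q-values follow the step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4L))
  expect_equal(bh_fdr(0.123), 0.123)
  set.seed(7)
  for (i in 1:50) {
    p <- runif(sample(1:200, 1L))
    q <- bh_fdr(p)
    expect_identical(q, bh_oracle(p))
    expect_true(all(q >= p & q <= 1))
  }
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("window scan applies the strict site-count filter and arithmetic", {
  # exactly 10 shared sites: dropped (needs strictly more than 10)
  pr10 <- flat_pair(seq(50L, 950L, by = 100L), 0.3, 0.1)
  w10 <- scan_windows(pr10$a, pr10$b,
                      dmr_params(window = 1000L, step = 1000L),
                      chrom_lengths = c(chr1 = 1000L))
  expect_equal(nrow(w10), 0L)

  # 11 shared sites: retained, with the documented effect sizes
  pr11 <- flat_pair(seq(50L, 950L, by = 90L), 0.3, 0.1)
  w11 <- scan_windows(pr11$a, pr11$b,
                      dmr_params(window = 1000L, step = 1000L),
                      chrom_lengths = c(chr1 = 1000L))
  expect_equal(nrow(w11), 1L)
  expect_equal(w11$n_sites, 11L)
  expect_equal(w11$ml_a, 0.3)
  expect_equal(w11$ml_b, 0.1)
  expect_equal(w11$fold_change, 3)
  expect_equal(w11$difference, 0.2)
  expect_equal(w11$p_value, fisher_exact_two_sided(33, 77, 11, 99))

  # identical samples: fold 1, diff 0 everywhere -> nothing selected
  same <- flat_pair(seq(50L, 1950L, by = 50L), 0.4, 0.4)
  ws <- scan_windows(same$a, same$b, dmr_params(),
                     chrom_lengths = c(chr1 = 2000L))
  expect_true(all(ws$fold_change == 1))
  expect_true(all(ws$difference == 0))
  expect_equal(nrow(select_potential_dmrs(ws, dmr_params())), 0L)
})

test_that("potential-DMR selection is strict at every threshold", {
  base <- data.table::data.table(chrom = "c1", start = 1L, end = 1000L,
                                 n_sites = 20L)
  mk <- function(fold, diff, p) {
    cbind(base, data.table::data.table(ml_a = 0.5, ml_b = 0.5 - diff,
                                       fold_change = fold,
                                       difference = diff, p_value = p))
  }
  params <- dmr_params()
  expect_equal(nrow(select_potential_dmrs(mk(3, 0.2, 1e-6), params)), 1L)
  expect_equal(nrow(select_potential_dmrs(mk(2, 0.2, 1e-6), params)), 0L)
  expect_equal(nrow(select_potential_dmrs(mk(3, 0.1, 1e-6), params)), 0L)
  expect_equal(nrow(select_potential_dmrs(mk(3, 0.2, 0.05), params)), 0L)
})

test_that("overlapping candidates merge to their union and re-test once", {
  # strong uniform contrast across chr1 so merged spans keep passing
  pos <- seq(25L, 2475L, by = 25L)
  pr <- flat_pair(pos, 0.45, 0.05, depth = 20L)
  pot <- data.table::data.table(chrom = "chr1",
                                start = c(100L, 600L), end = c(1100L, 1600L))
  out <- merge_and_retest(pot, pr$a, pr$b, dmr_params())
  expect_equal(nrow(out), 1L)
  expect_equal(out$start, 100L)
  expect_equal(out$end, 1600L)
  expect_equal(out$direction, "hyper")

  # disjoint candidates pass through unchanged (fixed point straight away)
  pot2 <- data.table::data.table(chrom = "chr1",
                                 start = c(100L, 1300L), end = c(1100L, 2300L))
  out2 <- merge_and_retest(pot2, pr$a, pr$b, dmr_params())
  expect_equal(out2$start, pot2$start)
  expect_equal(out2$end, pot2$end)

  # idempotence: feeding the result back reproduces it exactly
  again <- merge_and_retest(out2, pr$a, pr$b, dmr_params())
  expect_equal(again, out2)
})

test_that("swapping the samples flips every direction at identical coordinates", {
  cfg <- sim_config(genome_length_bp = 3e5, n_chroms = 1L, n_dmrs = 6L,
                    seed = 23L)
  sim <- simulate_methylome_pair(cfg)
  ab <- call_dmrs(sim$sample_a, sim$sample_b, sim$lambda_a, sim$lambda_b,
                  chrom_lengths = sim$chrom_lengths)
  ba <- call_dmrs(sim$sample_b, sim$sample_a, sim$lambda_b, sim$lambda_a,
                  chrom_lengths = sim$chrom_lengths)
  expect_gt(nrow(ab), 0L)
  expect_identical(ab$start, ba$start)
  expect_identical(ab$end, ba$end)
  expect_identical(ab$direction,
                   ifelse(ba$direction == "hyper", "hypo", "hyper"))
  expect_equal(ab$ml_a, ba$ml_b)
})

test_that("recovered planted regions increase with the planted shift", {
  counts <- integer(4L)
  deltas <- c(0.1, 0.2, 0.3, 0.4)
  for (i in seq_along(deltas)) {
    cfg <- sim_config(genome_length_bp = 4e5, n_chroms = 1L, n_dmrs = 8L,
                      dmr_delta = deltas[i], seed = 61L)
    sim <- simulate_methylome_pair(cfg)
    dmrs <- call_dmrs(sim$sample_a, sim$sample_b, sim$lambda_a, sim$lambda_b,
                      chrom_lengths = sim$chrom_lengths)
    ev <- evaluate_calls(dmrs, sim$truth, 0.3)
    counts[i] <- sum(ev$hits$recovered)
  }
  expect_true(all(diff(counts) >= 0L))
  expect_equal(counts[4L], 8L)
})

test_that("final DMRs are sorted, non-overlapping and satisfy the filters", {
  cfg <- sim_config(genome_length_bp = 4e5, n_chroms = 2L, n_dmrs = 8L,
                    seed = 37L)
  sim <- simulate_methylome_pair(cfg)
  dmrs <- call_dmrs(sim$sample_a, sim$sample_b, sim$lambda_a, sim$lambda_b,
                    chrom_lengths = sim$chrom_lengths)
  expect_gt(nrow(dmrs), 0L)
  expect_true(all(dmrs$fold_change > 2))
  expect_true(all(dmrs$difference > 0.1))
  expect_true(all(dmrs$q_value < 0.05))
  expect_true(all(dmrs$n_sites > 10L))
  same <- dmrs$chrom[-1L] == dmrs$chrom[-nrow(dmrs)]
  expect_true(all(!same | dmrs$start[-1L] > dmrs$end[-nrow(dmrs)]))
})

test_that("DMR level summary uses interpolated quartiles and ignores order", {
  one <- data.table::data.table(ml_a = 0.4, ml_b = 0.1)
  s1 <- dmr_level_summary(one)
  expect_equal(unlist(s1[s1$group == "a", c("min", "q1", "median", "q3", "max")],
                      use.names = FALSE),
               rep(0.4, 5L))
  four <- data.table::data.table(ml_a = c(0.1, 0.2, 0.3, 0.4),
                                 ml_b = c(0.4, 0.3, 0.2, 0.1))
  s4 <- dmr_level_summary(four)
  expect_equal(s4[s4$group == "a", ]$median, 0.25)
  shuffled <- four[c(3L, 1L, 4L, 2L), ]
  expect_equal(dmr_level_summary(shuffled), s4)
  expect_error(dmr_level_summary(four[0L, ]), "no DMRs")
})
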