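test_that("the printed triplet significance rule is applied exactly", {
  # 2-of-3 rule, window satisfied (span = 800 with 370-bp spacing)
  st <- make_stats(c(0.04, 0.20, 0.03), starts = c(0, 370, 740))
  tr <- scan_triplets(st)
  expect_equal(tr$span, 800)
  expect_true(tr$significant)
  expect_equal(tr$rule_fired, "two_of_three")

  # center rule
  st <- make_stats(c(0.09, 0.009, 0.09), starts = c(0, 370, 740))
  tr <- scan_triplets(st)
  expect_true(tr$significant)
  expect_equal(tr$rule_fired, "center")

  # window rule: span 1200 kills an otherwise significant triplet
  st <- make_stats(c(0.04, 0.20, 0.03), starts = c(0, 570, 1140))
  tr <- scan_triplets(st)
  expect_equal(tr$span, 1200)
  expect_false(tr$significant)

  # strict inequalities at the thresholds
  st <- make_stats(c(0.05, 0.05, 0.05), starts = c(0, 220, 440))
  tr <- scan_triplets(st)
  expect_false(tr$significant)
  expect_equal(tr$rule_fired, "none")
})

test_that("triplet enumeration is per chromosome and rejects unsorted input", {
  st <- make_stats(runif(10), chrom = rep(c("chr1", "chr2"), each = 5),
                   starts = rep(seq(0, 800, 200), 2))
  tr <- scan_triplets(st)
  expect_equal(nrow(tr), 2 * (5 - 2))
  expect_true(all(table(tr$chrom) == 3))

  bad <- st[c(2, 1, 3:10), ]
  expect_error(scan_triplets(bad), "sorted")
})

test_that("triplets sharing probes merge; separated triplets do not", {
  # probes 1..4 significant -> triplets (1,2,3) and (2,3,4) share probes and
  # merge; the >1000 bp gap after probe 4 stops any further triplet
  st <- make_stats(c(0.01, 0.01, 0.01, 0.01, 0.9, 0.9, 0.01, 0.01, 0.01),
                   starts = c(0, 200, 400, 600, 5000, 5200,
                              10000, 10200, 10400))
  reg <- call_regions(st)
  expect_equal(nrow(reg), 2L)
  expect_equal(reg$n_probes[1], 4L)
  expect_equal(reg$n_triplets[1], 2L)
  expect_equal(reg$start[1], st$start[1])
  expect_equal(reg$end[1], st$end[4])
  expect_equal(reg$region_id, c("R000001", "R000002"))
  expect_equal(reg$best_p[1], 0.01)
  expect_equal(reg$n_probes[2], 3L)
})

test_that("merged regions equal the exhaustive-enumeration oracle", {
  for (seed in 1:25) {
    st <- random_stats_instance(n = sample(60:200, 1), seed = seed)
    got <- call_regions(st)
    want <- oracle_regions(st)
    expect_equal(got[, c("chrom", "start", "end", "n_probes")], want,
                 info = sprintf("seed %d", seed))
  }
})

test_that("distant non-significant probes do not perturb called regions", {
  st <- make_stats(c(0.01, 0.01, 0.01, 0.8, 0.7),
                   starts = seq(1e5, by = 200, length.out = 5))
  base <- call_regions(st)
  pad_lo <- make_stats(rep(0.9, 3), starts = c(0, 300, 600))
  pad_hi <- make_stats(rep(0.9, 3), starts = c(2e5, 2e5 + 300, 2e5 + 600))
  padded <- rbind(pad_lo, st, pad_hi)
  padded$probe_id <- sprintf("q%03d", seq_len(nrow(padded)))
  class(padded) <- c("probe_stats", "data.frame")
  got <- call_regions(padded)
  expect_equal(got[, c("chrom", "start", "end", "n_probes", "best_p")],
               base[, c("chrom", "start", "end", "n_probes", "best_p")])
})

test_that("the permutation FDR is reproducible and guards its preconditions", {
  sim <- simulate_array(sim_config(n_genes = 60, genes_per_chrom = 30,
                                   seed = 9))
  f1 <- estimate_fdr(sim$probes, n_permutations = 5, seed = 42)
  f2 <- estimate_fdr(sim$probes, n_permutations = 5, seed = 42)
  expect_identical(f1, f2)
  expect_equal(f1$fdr, f1$mean_null_regions / max(f1$observed_regions, 1))

  expect_error(estimate_fdr(sim$probes, n_permutations = 0), "positive integer")
})

test_that("zero observed regions yields fdr 0 with a warning", {
  # probes 600 bp apart: every triplet spans 1260 bp > 1000, so the window
  # rule forbids any region regardless of the p-values
  df <- make_probe_table(n = 30, seed = 2, R = 2, spacing = 600)
  st <- probe_stats(df)
  expect_equal(nrow(call_regions(st)), 0L)
  expect_warning(f <- estimate_fdr(df, n_permutations = 3, seed = 1),
                 "fdr reported as 0")
  expect_equal(f$fdr, 0)
  expect_true(f$zero_observed)
})
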