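test_that("array simulation is a pure function of its seed", {
  cfg <- sim_config(n_genes = 50, genes_per_chrom = 25, seed = 5)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- simulate_array(cfg, dir = d1)
  s2 <- simulate_array(cfg, dir = d2)
  expect_identical(s1$probes, s2$probes)
  expect_identical(s1$truth, s2$truth)
  for (f in c("probes.tsv", "genes.bed", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("emitted files pass the io validators and round-trip", {
  d <- withr::local_tempdir()
  sim <- simulate_array(sim_config(n_genes = 40, genes_per_chrom = 20,
                                   seed = 2), dir = d)
  probes <- read_probe_table(file.path(d, "probes.tsv"))
  expect_equal(probes$probe_id, sim$probes$probe_id)
  expect_equal(probes$rep2_ip, sim$probes$rep2_ip, tolerance = 1e-9)
  genes <- read_gene_bed(file.path(d, "genes.bed"))
  expect_equal(genes$tss, sim$genes$tss)
  expect_equal(genes$strand, sim$genes$strand)
})

test_that("the probe grid tiles -5.5 kb to +2.5 kb around every TSS", {
  sim <- simulate_array(sim_config(n_genes = 30, genes_per_chrom = 15,
                                   seed = 3))
  expect_equal(nrow(sim$probes), 30 * 41)  # 8 kb window / 200 bp spacing + 1
  for (i in c(1, 17)) {
    g <- sim$genes[i, ]
    ids <- sprintf("P%07d", (i - 1) * 41 + 1:41)  # probes minted per gene
    p <- sim$probes[sim$probes$probe_id %in% ids, ]
    rel <- if (g$strand == "+") p$start - g$tss else g$tss - (p$end - 1)
    expect_equal(sort(rel), seq(-5500, 2500, by = 200))
  }
})

test_that("a zero effect size produces identically distributed channels", {
  sim <- simulate_array(sim_config(n_genes = 100, effect_size = 0, seed = 8))
  ks <- suppressWarnings(
    stats::ks.test(log2(sim$probes$rep1_ip), log2(sim$probes$rep1_ctl)))
  expect_gt(ks$p.value, 0.001)
})

test_that("spiked probes carry the configured enrichment", {
  cfg <- sim_config(n_genes = 200, effect_size = 2, seed = 4)
  sim <- simulate_array(cfg)
  tr <- sim$truth$true_regions
  inside <- rep(FALSE, nrow(sim$probes))
  for (r in seq_len(nrow(tr))) {
    inside <- inside | (sim$probes$chrom == tr$chrom[r] &
                          sim$probes$end > tr$start[r] &
                          sim$probes$start < tr$end[r])
  }
  lr <- log2(sim$probes$rep1_ip / sim$probes$rep1_ctl)
  expect_equal(mean(lr[inside]) - mean(lr[!inside]), cfg$effect_size,
               tolerance = 0.1)
  expect_equal(nrow(tr), round(0.05 * 200))
})

test_that("sequence simulation plants the motif where it says it does", {
  sim <- simulate_sequences(200, 300, gc = 0.5, consensus = "CACCAGGG",
                            plant_fraction = 1, seed = 6)
  expect_true(all(sim$truth$planted))
  ok <- vapply(seq_len(200), function(i) {
    at <- sim$truth$pos[i] + 1L
    w <- substr(sim$sequences[i], at, at + 7L)
    if (sim$truth$strand[i] == "+") w == "CACCAGGG" else w == "CCCTGGTG"
  }, logical(1))
  expect_true(all(ok))
  mc <- count_fraction(sim$sequences, "CACCAGGG", 0)
  expect_equal(mc$fraction, 1)
})

test_that("unplanted sequences hit the motif only at the binomial chance rate", {
  n <- 400; L <- 300
  sim <- simulate_sequences(n, L, gc = 0.5, consensus = "CACCAGGG",
                            plant_fraction = 0, seed = 10)
  mc <- count_fraction(sim$sequences, "CACCAGGG", 0)
  # both-strand chance hit probability per sequence under the uniform model
  h <- 1 - (1 - 2 / 4^8)^(L - 8 + 1)
  expect_lt(mc$fraction, h + 3 * sqrt(h * (1 - h) / n) + 1e-9)
})

test_that("simulated GC content matches the request", {
  sim <- simulate_sequences(1000, 200, gc = 0.5, plant_fraction = 0, seed = 12)
  gc <- mean(strsplit(paste(sim$sequences, collapse = ""), "")[[1]] %in%
               c("G", "C"))
  expect_lt(abs(gc - 0.5), 0.02)
})

test_that("reference sets carry exactly the designed overlap", {
  genes <- sprintf("g%04d", 1:2000)
  rs <- simulate_reference_sets(genes, n_setA_only = 30, n_setB_only = 100,
                                n_both = 120, seed = 3)
  expect_equal(length(rs$setA), 150)
  expect_equal(length(rs$setB), 220)
  expect_equal(length(intersect(rs$setA, rs$setB)), 120)
  r <- test_overlap(rs$setA, rs$setB, genes)
  expect_lt(r$p_value, 1e-10)  # designed heavy overlap

  rs2 <- simulate_reference_sets(genes, 30, 100, 120, seed = 3)
  expect_identical(rs, rs2)

  none <- simulate_reference_sets(genes, 40, 40, 0, seed = 4)
  expect_equal(length(intersect(none$setA, none$setB)), 0)
  expect_error(simulate_reference_sets(genes[1:10], 8, 8, 2, seed = 1),
               "exceed")
})
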