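test_that("trivial motif structure: homopolymer input and strand symmetry", {
  seqs <- setNames(strrep("A", 40)[rep(1, 5)], sprintf("s%d", 1:5))
  m <- find_motifs(seqs, k = 8, max_mismatches = 0, background = rep(0.25, 4))
  expect_equal(m$consensus[1], "AAAAAAAA")
  expect_equal(m$fraction[1], 1)

  set.seed(31)
  sim <- simulate_sequences(60, 120, consensus = "CACCAGGG",
                            plant_fraction = 0.4, seed = 31)
  fwd <- find_motifs(sim$sequences, k = 6, max_mismatches = 0)
  rc <- vapply(sim$sequences, function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))),
    character(1))
  rev <- find_motifs(rc, k = 6, max_mismatches = 0)
  expect_equal(fwd, rev)

  shuf <- find_motifs(sim$sequences[sample(length(sim$sequences))],
                      k = 6, max_mismatches = 0)
  expect_equal(fwd, shuf)
})

test_that("k longer than the shortest sequence is rejected", {
  expect_error(find_motifs(c(a = "ACGTAC"), k = 8), "shortest sequence")
  expect_error(find_motifs(c(a = "ACGTACGTACGT"), k = 3), "k must be")
  expect_error(count_fraction(c(a = "ACGT"), "ACGTACGT"), "longer")
})

test_that("count_fraction agrees with a brute-force both-strand oracle", {
  set.seed(7)
  sim <- simulate_sequences(100, 60, consensus = "GATTACAG",
                            plant_fraction = 0.3, seed = 7)
  for (mm in 0:1) {
    mc <- count_fraction(sim$sequences, "GATTACAG", mm)
    want <- vapply(sim$sequences, oracle_has_hit, logical(1),
                   consensus = "GATTACAG", max_mm = mm)
    expect_equal(mc$hits$hit, unname(want), info = sprintf("mm=%d", mm))
    expect_equal(mc$fraction, mean(want))
  }
  absent <- count_fraction(c(a = strrep("A", 50)), "CACCAGGG", 0)
  expect_equal(absent$fraction, 0)
})

test_that("exact counting equals plain substring search on both strands", {
  set.seed(17)
  sim <- simulate_sequences(80, 80, consensus = "TTGACGTC",
                            plant_fraction = 0.5, seed = 17)
  mc <- count_fraction(sim$sequences, "TTGACGTC", 0)
  want <- grepl("TTGACGTC", sim$sequences, fixed = TRUE) |
    grepl("GACGTCAA", sim$sequences, fixed = TRUE)  # reverse complement
  expect_equal(mc$hits$hit, unname(want))
})

test_that("query PWMs are per-position normalized and recover hit frequencies", {
  seqs <- setNames(rep(paste0("TT", "CACCAGGG", "TT"), 20),
                   sprintf("s%d", 1:20))
  pwm <- build_query_pwm(seqs, "CACCAGGG", 0)
  expect_equal(unname(rowSums(pwm)), rep(1, 8), tolerance = 1e-12)
  # with identical hits each column is nearly a point mass on the consensus
  expect_true(all(pwm[cbind(1:8, match(strsplit("CACCAGGG", "")[[1]],
                                       c("A", "C", "G", "T")))] > 0.9))

  # 10% per-base noise, many instances: recovered frequencies within 0.05
  set.seed(13)
  k <- 8; n <- 800
  cons <- strsplit("CACCAGGG", "")[[1]]
  noisy <- vapply(seq_len(n), function(i) {
    inst <- vapply(cons, function(b) {
      if (runif(1) < 0.1) sample(setdiff(c("A", "C", "G", "T"), b), 1) else b
    }, character(1))
    paste0(strrep("T", 10), paste(inst, collapse = ""), strrep("T", 10))
  }, character(1))
  names(noisy) <- sprintf("n%03d", seq_len(n))
  pwm2 <- build_query_pwm(noisy, "CACCAGGG", 2)
  gen <- matrix(0.1 / 3, nrow = 8, ncol = 4,
                dimnames = list(NULL, c("A", "C", "G", "T")))
  gen[cbind(1:8, match(cons, colnames(gen)))] <- 0.9
  expect_lt(max(abs(pwm2 - gen)), 0.05)
})

test_that("a PWM matched against itself scores 1 at offset 0", {
  lib <- read_pwm_library(system.file("extdata", "pwm_library_synthetic.txt",
                                      package = "chiptriplet"))
  q <- lib$CRE_like_synthetic
  m <- match_library(q, lib, n_null = 100, seed = 1)
  expect_equal(m$library_name[1], "CRE_like_synthetic")
  expect_equal(m$similarity[1], 1, tolerance = 1e-12)
  expect_equal(m$offset[1], 0L)
  expect_true(all(m$p_value > 0 & m$p_value <= 1))
  expect_error(match_library(q, list(), 100), "empty")
  expect_error(match_library(q, lib, n_null = 10), "n_null")
})

test_that("match_library with a fixed seed is reproducible and null p-values spread", {
  lib <- read_pwm_library(system.file("extdata", "pwm_library_synthetic.txt",
                                      package = "chiptriplet"))
  set.seed(5)
  q <- random_decoy_pwm(8)
  m1 <- match_library(q, lib, n_null = 100, seed = 7)
  m2 <- match_library(q, lib, n_null = 100, seed = 7)
  expect_identical(m1, m2)

  # random queries against one library entry: p-values spread over (0, 1]
  set.seed(23)
  ps <- vapply(1:20, function(i) {
    match_library(random_decoy_pwm(8), lib["TATA_like_synthetic"],
                  n_null = 100, seed = i)$p_value
  }, numeric(1))
  expect_gt(mean(ps), 0.15)
  expect_lt(mean(ps), 0.85)
  expect_gt(length(unique(ps)), 5)
})
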