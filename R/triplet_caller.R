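#' Scan consecutive probe triplets for joint significance
#'
#' The genome is scanned three consecutive probes at a time along each
#' chromosome.  A triplet is significant when its probes lie in a window of
#' `max_span` bp or less (end of third probe minus start of first) and either
#' at least 2 of the 3 probe p-values are below `p_two_of_three`, or the
#' center probe p-value is below `p_center` while both flanking p-values are
#' below `p_flank`.  All comparisons are strict.
#'
#' @param stats `probe_stats` data.frame sorted by `(chrom, start)`.
#' @param p_two_of_three Per-probe threshold for the 2-of-3 rule (default
#'   0.05).
#' @param p_center Center-probe threshold for the center rule (default 0.01).
#' @param p_flank Flanking-probe threshold for the center rule (default 0.1).
#' @param max_span Maximum window span in bp (default 1000).
#' @return A `data.frame` with one row per within-chromosome triplet: probe
#'   indices `i1`, `i2`, `i3` (row indices into `stats`), `chrom`, `span`,
#'   `rule_fired` (`two_of_three`, `center` or `none`) and `significant`.
#'   `rule_fired` records the p-value pattern regardless of the window
#'   constraint; `significant` additionally requires `span <= max_span`.
#' @export
scan_triplets <- function(stats, p_two_of_three = 0.05, p_center = 0.01,
                          p_flank = 0.1, max_span = 1000) {
  n <- nrow(stats)
  .assert(all(.genomic_order(stats$chrom, stats$start) == seq_len(n)),
          "probe statistics must be sorted by (chrom, start)")
  .assert(all(stats$p_value > 0 & stats$p_value <= 1),
          "p-values must lie in (0, 1]")
  empty <- data.frame(i1 = integer(), i2 = integer(), i3 = integer(),
                      chrom = character(), span = integer(),
                      rule_fired = character(), significant = logical(),
                      stringsAsFactors = FALSE)
  if (n < 3L) return(empty)
  i1 <- seq_len(n - 2L)
  same <- stats$chrom[i1] == stats$chrom[i1 + 1L] &
    stats$chrom[i1] == stats$chrom[i1 + 2L]
  i1 <- i1[same]
  if (!length(i1)) return(empty)
  p1 <- stats$p_value[i1]
  p2 <- stats$p_value[i1 + 1L]
  p3 <- stats$p_value[i1 + 2L]
  span <- stats$end[i1 + 2L] - stats$start[i1]
  two3 <- (p1 < p_two_of_three) + (p2 < p_two_of_three) +
    (p3 < p_two_of_three) >= 2L
  center <- p2 < p_center & p1 < p_flank & p3 < p_flank
  rule <- ifelse(two3, "two_of_three", ifelse(center, "center", "none"))
  data.frame(i1 = i1, i2 = i1 + 1L, i3 = i1 + 2L,
             chrom = stats$chrom[i1], span = span, rule_fired = rule,
             significant = rule != "none" & span <= max_span,
             stringsAsFactors = FALSE)
}

#' Merge significant triplets into bound regions
#'
#' Significant triplets that share at least one probe are merged transitively;
#' each resulting region's interval is the union of its member probes'
#' intervals.  Region ids are assigned in genomic order as `R000001`, ...
#'
#' @param triplets Output of [scan_triplets()] on the same `stats`.
#' @param stats The `probe_stats` data.frame the triplets index into.
#' @return A `data.frame` with columns `region_id`, `chrom`, `start`, `end`,
#'   `n_probes`, `n_triplets`, `best_p` (minimum member-probe p-value) and a
#'   `probe_from`/`probe_to` index range into `stats`.
#' @export
merge_triplets <- function(triplets, stats) {
  sig <- triplets[triplets$significant, , drop = FALSE]
  empty <- data.frame(region_id = character(), chrom = character(),
                      start = integer(), end = integer(), n_probes = integer(),
                      n_triplets = integer(), best_p = numeric(),
                      probe_from = integer(), probe_to = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(sig) == 0L) return(empty)
  sig <- sig[order(sig$i1), , drop = FALSE]
  # consecutive-window triplets share a probe iff their first indices differ
  # by at most 2 (and lie on the same chromosome)
  new_grp <- c(TRUE, diff(sig$i1) > 2L |
                 sig$chrom[-1L] != sig$chrom[-nrow(sig)])
  grp <- cumsum(new_grp)
  out <- do.call(rbind, lapply(split(seq_len(nrow(sig)), grp), function(rows) {
    from <- min(sig$i1[rows]); to <- max(sig$i3[rows])
    idx <- from:to
    data.frame(chrom = sig$chrom[rows[1L]],
               start = min(stats$start[idx]), end = max(stats$end[idx]),
               n_probes = length(idx), n_triplets = length(rows),
               best_p = min(stats$p_value[idx]),
               probe_from = from, probe_to = to, stringsAsFactors = FALSE)
  }))
  out <- out[.genomic_order(out$chrom, out$start), , drop = FALSE]
  out <- cbind(region_id = sprintf("R%06d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Call bound regions from probe statistics
#'
#' Composition of [scan_triplets()] and [merge_triplets()] with the standard
#' thresholds.
#'
#' @inheritParams scan_triplets
#' @return See [merge_triplets()].
#' @export
call_regions <- function(stats, p_two_of_three = 0.05, p_center = 0.01,
                         p_flank = 0.1, max_span = 1000) {
  tr <- scan_triplets(stats, p_two_of_three, p_center, p_flank, max_span)
  merge_triplets(tr, stats)
}

#' Empirical false discovery rate by permutation
#'
#' The FDR of the region caller is estimated by destroying the spatial
#' structure of the data: within each chromosome the probe log-ratios are
#' permuted uniformly at random across probe positions (the same permutation
#' applied to every replicate so inter-replicate correlation is preserved),
#' the full caller is re-run, and the null region counts are averaged.
#' `fdr = mean_null_regions / max(observed_regions, 1)`.
#'
#' @param probes Probe `data.frame` from [read_probe_table()].
#' @param n_permutations Number of permutations (>= 1; 10 by default).
#' @param seed Integer seed; the estimate is reproducible given the seed.
#' @param p_two_of_three,p_center,p_flank,max_span Caller thresholds, see
#'   [scan_triplets()].
#' @return An object of class `fdr_estimate`: `observed_regions`,
#'   `mean_null_regions`, `null_counts`, `fdr`, `n_permutations`, `seed`,
#'   and `zero_observed` (TRUE when no region was called on the observed
#'   data, in which case `fdr` is reported as 0 with a warning).
#' @export
estimate_fdr <- function(probes, n_permutations = 10, seed = 1,
                         p_two_of_three = 0.05, p_center = 0.01,
                         p_flank = 0.1, max_span = 1000) {
  .assert(.is_count(n_permutations) && n_permutations >= 1,
          "n_permutations must be a positive integer")
  probes <- probes[.genomic_order(probes$chrom, probes$start), , drop = FALSE]
  rownames(probes) <- NULL
  lr <- compute_log_ratios(probes)
  nulls <- apply(lr, 2L, fit_null_model)
  count <- function(lrm) {
    st <- probe_pvalues(probes, lrm, nulls)
    nrow(call_regions(st, p_two_of_three, p_center, p_flank, max_span))
  }
  observed <- count(lr)
  chrom_idx <- split(seq_len(nrow(probes)), probes$chrom)
  set.seed(seed)
  null_counts <- vapply(seq_len(n_permutations), function(b) {
    lrp <- lr
    for (idx in chrom_idx) lrp[idx, ] <- lr[sample(idx), , drop = FALSE]
    count(lrp)
  }, numeric(1L))
  zero <- observed == 0L
  fdr <- mean(null_counts) / max(observed, 1L)
  if (zero) {
    warning("no regions called on observed data; fdr reported as 0")
    fdr <- 0
  }
  structure(list(observed_regions = observed,
                 mean_null_regions = mean(null_counts),
                 null_counts = null_counts, fdr = fdr,
                 n_permutations = n_permutations, seed = seed,
                 zero_observed = zero),
            class = "fdr_estimate")
}

#' @export
print.fdr_estimate <- function(x, ...) {
  cat(sprintf(
    "fdr_estimate: %d observed regions, %.2f mean null regions (%d permutations), fdr = %.4g\n",
    x$observed_regions, x$mean_null_regions, x$n_permutations, x$fdr))
  invisible(x)
}
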