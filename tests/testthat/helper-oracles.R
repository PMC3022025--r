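# Test fixtures and independent brute-force oracles.

# Minimal probe_stats data.frame from explicit p-values and coordinates.
make_stats <- function(p, starts = seq(0, by = 200, length.out = length(p)),
                       chrom = "chr1", probe_len = 60) {
  df <- data.frame(
    probe_id = sprintf("p%03d", seq_along(p)), chrom = chrom,
    start = as.integer(starts), end = as.integer(starts + probe_len),
    combined_z = qnorm(p, lower.tail = FALSE), p_value = p,
    stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start), ]
  rownames(df) <- NULL
  class(df) <- c("probe_stats", "data.frame")
  df
}

# Small probe intensity table with R replicates.
make_probe_table <- function(n = 12, seed = 1, R = 2, chrom = "chr1",
                             spacing = 200) {
  set.seed(seed)
  df <- data.frame(
    probe_id = sprintf("p%03d", seq_len(n)), chrom = chrom,
    start = as.integer(seq(0, by = spacing, length.out = n)),
    end = as.integer(seq(0, by = spacing, length.out = n) + 60),
    stringsAsFactors = FALSE)
  for (k in seq_len(R)) {
    df[[sprintf("rep%d_ip", k)]] <- exp(rnorm(n, 7, 0.4))
    df[[sprintf("rep%d_ctl", k)]] <- exp(rnorm(n, 7, 0.4))
  }
  attr(df, "n_replicates") <- R
  df
}

# Exhaustive-window region oracle: enumerate every within-chromosome
# consecutive triple, apply the significance rule, then merge triplets that
# share any probe index by transitive closure over probe sets.  Independent
# of scan_triplets/merge_triplets internals.
oracle_regions <- function(stats, p23 = 0.05, pc = 0.01, pf = 0.1,
                           max_span = 1000) {
  n <- nrow(stats)
  sets <- list()
  for (i in seq_len(max(0L, n - 2L))) {
    idx <- c(i, i + 1L, i + 2L)
    if (length(unique(stats$chrom[idx])) != 1L) next
    p <- stats$p_value[idx]
    span <- stats$end[idx[3L]] - stats$start[idx[1L]]
    fired <- sum(p < p23) >= 2L || (p[2L] < pc && p[1L] < pf && p[3L] < pf)
    if (fired && span <= max_span) sets[[length(sets) + 1L]] <- idx
  }
  # transitive merge by shared probe membership
  changed <- TRUE
  while (changed && length(sets) > 1L) {
    changed <- FALSE
    for (a in seq_along(sets)) {
      for (b in seq_along(sets)) {
        if (b <= a) next
        if (length(intersect(sets[[a]], sets[[b]]))) {
          sets[[a]] <- sort(union(sets[[a]], sets[[b]]))
          sets[[b]] <- NULL
          changed <- TRUE
          break
        }
      }
      if (changed) break
    }
  }
  if (!length(sets)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_probes = integer()))
  }
  out <- do.call(rbind, lapply(sets, function(s) {
    data.frame(chrom = stats$chrom[s[1L]], start = min(stats$start[s]),
               end = max(stats$end[s]), n_probes = length(s),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

# Random probe-stats instance with irregular spacing (spans straddle the
# 1000-bp window rule) and several chromosomes.
random_stats_instance <- function(n, seed) {
  set.seed(seed)
  chrom <- sort(sample(paste0("chr", 1:3), n, replace = TRUE))
  starts <- unlist(lapply(split(seq_len(n), chrom), function(idx) {
    cumsum(sample(c(100, 200, 350, 600), length(idx), replace = TRUE))
  }), use.names = FALSE)
  # mixture null/enriched p-values so significant triplets occur
  p <- ifelse(runif(n) < 0.25, runif(n, 1e-6, 0.05), runif(n))
  make_stats(p, starts = starts, chrom = chrom)
}

# All-pairs nearest-TSS assignment oracle.
oracle_assign <- function(regions, genes, max_distance = 10000) {
  out <- list()
  for (r in seq_len(nrow(regions))) {
    best_gene <- NA_character_; best_d <- Inf
    for (g in seq_len(nrow(genes))) {
      if (genes$chrom[g] != regions$chrom[r]) next
      tss <- genes$tss[g]
      d <- if (tss >= regions$start[r] && tss < regions$end[r]) 0 else
        min(abs(tss - regions$start[r]), abs(tss - (regions$end[r] - 1)))
      if (d < best_d || (d == best_d && genes$gene_id[g] < best_gene)) {
        best_d <- d; best_gene <- genes$gene_id[g]
      }
    }
    if (is.finite(best_d) && best_d < max_distance) {
      out[[length(out) + 1L]] <- data.frame(
        region_id = regions$region_id[r], gene_id = best_gene,
        distance = as.integer(best_d), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(region_id = character(), gene_id = character(),
                      distance = integer()))
  }
  do.call(rbind, out)
}

# Exhaustive hypergeometric upper tail by enumeration of all draws of
# size nB from a universe of size nU containing nA marked elements.
oracle_hyper_enum <- function(nU, nA, nB, n_overlap) {
  draws <- combn(nU, nB)
  hits <- colSums(draws <= nA)  # elements 1..nA are the marked set
  mean(hits >= n_overlap)
}

# Brute-force both-strand mismatch search used against count_fraction.
oracle_has_hit <- function(seq, consensus, max_mm) {
  k <- nchar(consensus)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(consensus)))
  for (i in seq_len(nchar(seq) - k + 1L)) {
    w <- substr(seq, i, i + k - 1L)
    mmf <- sum(strsplit(w, "")[[1L]] != strsplit(consensus, "")[[1L]] |
                 strsplit(w, "")[[1L]] == "N")
    mmr <- sum(strsplit(w, "")[[1L]] != strsplit(rc, "")[[1L]] |
                 strsplit(w, "")[[1L]] == "N")
    if (min(mmf, mmr) <= max_mm) return(TRUE)
  }
  FALSE
}

random_decoy_pwm <- function(nrow) {
  m <- matrix(runif(nrow * 4L, 0.02, 1), ncol = 4L)
  m <- m / rowSums(m)
  colnames(m) <- c("A", "C", "G", "T")
  m
}
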