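#' Simulation configuration for a synthetic promoter array
#'
#' Defaults emulate a two-color promoter tiling array in which probes cover
#' -5.5 kb to +2.5 kb around each gene's TSS, with two replicate
#' hybridizations, log-normal intensity noise and a multiplicative IP-channel
#' enrichment of `2^effect_size` on probes inside spiked bound regions.
#'
#' @param n_genes Number of genes on the array (default 2000).
#' @param window Length-2 vector, probe coverage in bp relative to the TSS
#'   (default `c(-5500, 2500)`).
#' @param probe_length Probe length in bp (default 60).
#' @param probe_spacing Probe start-to-start spacing in bp (default 200).
#' @param n_replicates Number of replicate hybridizations (default 2).
#' @param bound_fraction Fraction of genes receiving one true bound region
#'   (default 0.05).
#' @param region_width Width of each true region in bp (default 1000).
#' @param effect_size IP-channel enrichment inside true regions, in log2
#'   units (default 2).
#' @param noise_sd Per-channel log2 intensity noise standard deviation
#'   (default 0.5).
#' @param intensity_baseline Baseline fluorescence (default 1000).
#' @param genes_per_chrom Genes per synthetic chromosome (default 100).
#' @param seed Integer seed (default 1).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000, window = c(-5500, 2500),
                       probe_length = 60, probe_spacing = 200,
                       n_replicates = 2, bound_fraction = 0.05,
                       region_width = 1000, effect_size = 2, noise_sd = 0.5,
                       intensity_baseline = 1000, genes_per_chrom = 100,
                       seed = 1) {
  cfg <- list(n_genes = n_genes, window = window, probe_length = probe_length,
              probe_spacing = probe_spacing, n_replicates = n_replicates,
              bound_fraction = bound_fraction, region_width = region_width,
              effect_size = effect_size, noise_sd = noise_sd,
              intensity_baseline = intensity_baseline,
              genes_per_chrom = genes_per_chrom, seed = seed)
  .assert(cfg$n_genes >= 1 && cfg$probe_length > 0 && cfg$probe_spacing > 0 &&
            cfg$n_replicates >= 1 && cfg$noise_sd > 0 &&
            cfg$intensity_baseline > 0 && cfg$region_width > 0,
          "sim_config: sizes, spacings, noise and baseline must be positive")
  .assert(length(window) == 2L && window[1L] < window[2L],
          "sim_config: window must be (upstream, downstream) with upstream < downstream")
  .assert(cfg$bound_fraction > 0 && cfg$bound_fraction < 1,
          "sim_config: bound_fraction must lie in (0, 1)")
  .assert(cfg$region_width <= window[2L],
          "sim_config: region_width must fit inside the downstream coverage")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a two-color promoter array with spiked bound regions
#'
#' Genes are placed non-overlapping on synthetic chromosomes with random
#' strands; probes tile each gene's `window` (strand-oriented) at
#' `probe_spacing`.  A `bound_fraction` of genes receives one true region of
#' `region_width` bp whose strand-oriented start offset is uniform in
#' `[1, window[2] - region_width]` downstream of the TSS, so the region lies
#' fully inside probe coverage.  Control-channel intensities are log-normal
#' (`intensity_baseline * 2^N(0, noise_sd)`); the IP channel is additionally
#' multiplied by `2^effect_size` on probes overlapping a true region.
#'
#' @param config A [sim_config()] object.
#' @param dir Optional output directory; when given, `probes.tsv`,
#'   `genes.bed` and `truth.json` are written there.
#' @return A list with `probes` (probe data.frame), `genes` (gene
#'   data.frame) and `truth` (list: `bound_gene_ids`, `true_regions`
#'   data.frame with `chrom`, `start`, `end`, `gene_id`, and `config` echo).
#' @export
simulate_array <- function(config = sim_config(), dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ng <- config$n_genes
  gpc <- config$genes_per_chrom
  wlen <- config$window[2L] - config$window[1L]
  pitch <- wlen + config$probe_length + 2000  # gene-to-gene slot, no overlap
  chrom <- sprintf("chr%d", (seq_len(ng) - 1L) %/% gpc + 1L)
  slot <- (seq_len(ng) - 1L) %% gpc
  tss <- as.integer(slot * pitch - config$window[1L] + 1000L)
  strand <- sample(c("+", "-"), ng, replace = TRUE)
  genes <- data.frame(
    gene_id = sprintf("G%05d", seq_len(ng)), chrom = chrom, tss = tss,
    strand = strand, biotype = "protein_coding", stringsAsFactors = FALSE)

  # probe grid: strand-oriented offsets window[1] .. window[2] step spacing
  offs <- seq(config$window[1L], config$window[2L], by = config$probe_spacing)
  np_per <- length(offs)
  gidx <- rep(seq_len(ng), each = np_per)
  rel <- rep(offs, times = ng)
  pstart <- ifelse(strand[gidx] == "+", tss[gidx] + rel,
                   tss[gidx] - rel - config$probe_length + 1L)
  probes <- data.frame(
    probe_id = sprintf("P%07d", seq_along(pstart)),
    chrom = chrom[gidx], start = as.integer(pstart),
    end = as.integer(pstart + config$probe_length), stringsAsFactors = FALSE)

  # spike-in truth: exactly round(bound_fraction * n_genes) bound genes
  nb <- max(1L, round(config$bound_fraction * ng))
  bound <- sort(sample(ng, nb))
  max_off <- config$window[2L] - config$region_width
  off <- if (max_off >= 1) sample(max_off, nb, replace = TRUE) else rep(1L, nb)
  rs <- ifelse(strand[bound] == "+", tss[bound] + off,
               tss[bound] - off - config$region_width + 1L)
  truth_regions <- data.frame(
    chrom = chrom[bound], start = as.integer(rs),
    end = as.integer(rs + config$region_width),
    gene_id = genes$gene_id[bound], stringsAsFactors = FALSE)

  in_region <- rep(FALSE, nrow(probes))
  for (r in seq_len(nrow(truth_regions))) {
    hit <- probes$chrom == truth_regions$chrom[r] &
      probes$end > truth_regions$start[r] &
      probes$start < truth_regions$end[r]
    in_region <- in_region | hit
  }

  base <- config$intensity_baseline
  for (k in seq_len(config$n_replicates)) {
    ctl <- base * 2^rnorm(nrow(probes), 0, config$noise_sd)
    ip <- base * 2^(rnorm(nrow(probes), 0, config$noise_sd) +
                      config$effect_size * in_region)
    probes[[sprintf("rep%d_ip", k)]] <- ip
    probes[[sprintf("rep%d_ctl", k)]] <- ctl
  }
  probes <- probes[.genomic_order(probes$chrom, probes$start), , drop = FALSE]
  rownames(probes) <- NULL
  attr(probes, "n_replicates") <- config$n_replicates

  truth <- list(bound_gene_ids = genes$gene_id[bound],
                true_regions = truth_regions,
                config = unclass(config))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_probe_table(probes, file.path(dir, "probes.tsv"))
    write_gene_bed(genes, file.path(dir, "genes.bed"))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(probes = probes, genes = genes, truth = truth)
}

#' Simulate DNA sequences with a planted consensus motif
#'
#' Background bases are i.i.d. at the given GC content; in a
#' `plant_fraction` of sequences the consensus (or its reverse complement,
#' with equal probability) replaces the background at one uniform position.
#'
#' @param n Number of sequences.
#' @param length Sequence length in bp.
#' @param gc GC content in (0, 1) (default 0.5).
#' @param consensus Motif to plant (default `"CACCAGGG"`).
#' @param plant_fraction Fraction of sequences receiving one occurrence
#'   (default 0.5).
#' @param seed Integer seed.
#' @return A list with `sequences` (named character vector) and `truth`
#'   (data.frame `seq_name`, `planted`, `pos` 0-based, `strand`).
#' @export
simulate_sequences <- function(n, length, gc = 0.5, consensus = "CACCAGGG",
                               plant_fraction = 0.5, seed = 1) {
  .assert(plant_fraction >= 0 && plant_fraction <= 1,
          "plant_fraction must lie in [0, 1]")
  .assert(nchar(consensus) <= length, "consensus longer than sequence length")
  .assert(gc > 0 && gc < 1, "gc must lie in (0, 1)")
  set.seed(seed)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  k <- nchar(consensus)
  nm <- sprintf("seq%05d", seq_len(n))
  npl <- round(plant_fraction * n)
  planted_idx <- sort(sample(n, npl))
  seqs <- character(n)
  planted <- logical(n); pos <- rep(NA_integer_, n)
  strand <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    s <- sample(DNA_BASES, length, replace = TRUE, prob = p)
    if (i %in% planted_idx) {
      at <- sample(length - k + 1L, 1L)
      ins <- if (runif(1) < 0.5) consensus else .revcomp_chr(consensus)
      s[at:(at + k - 1L)] <- strsplit(ins, "")[[1L]]
      planted[i] <- TRUE
      pos[i] <- at - 1L
      strand[i] <- if (ins == consensus) "+" else "-"
    }
    seqs[i] <- paste(s, collapse = "")
  }
  names(seqs) <- nm
  list(sequences = seqs,
       truth = data.frame(seq_name = nm, planted = planted, pos = pos,
                          strand = strand, stringsAsFactors = FALSE))
}

#' Simulate two gene sets with a designed overlap
#'
#' Samples disjoint members so that the two sets share exactly `n_both`
#' genes, have `n_setA_only` and `n_setB_only` private genes, and all
#' members come from `genes`.
#'
#' @param genes Character vector: the gene universe.
#' @param n_setA_only,n_setB_only,n_both Designed membership counts.
#' @param seed Integer seed.
#' @return A list with `setA`, `setB` (character vectors) and `truth`
#'   (the designed counts).
#' @export
simulate_reference_sets <- function(genes, n_setA_only, n_setB_only, n_both,
                                    seed = 1) {
  need <- n_setA_only + n_setB_only + n_both
  .assert(need <= length(genes),
          "designed counts exceed the gene universe (%d > %d)",
          need, length(genes))
  set.seed(seed)
  picked <- sample(genes, need)
  both <- picked[seq_len(n_both)]
  a_only <- picked[n_both + seq_len(n_setA_only)]
  b_only <- picked[n_both + n_setA_only + seq_len(n_setB_only)]
  list(setA = sort(c(both, a_only)), setB = sort(c(both, b_only)),
       truth = list(n_setA_only = n_setA_only, n_setB_only = n_setB_only,
                    n_both = n_both))
}
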