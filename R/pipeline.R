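#' Run the full ChIP-chip analysis pipeline
#'
#' Orchestrates the stages probe statistics -> triplet region calling ->
#' permutation FDR -> nearest-TSS assignment -> (optional) gene-set overlap
#' -> TSS profile -> (optional) motif discovery and PWM matching, writing
#' tab-delimited stage outputs and a machine-readable JSON run report to
#' `outdir`.  Optional stages run only when their inputs are configured.
#'
#' The configuration is a named list (or path to a YAML file) with blocks:
#' \describe{
#'   \item{`seed`}{integer seed used for every stochastic step (default 1).}
#'   \item{`outdir`}{output directory (default `"chiptriplet_out"`).}
#'   \item{`simulate`}{optional: arguments for [sim_config()]; when present
#'     the array is simulated and ground truth is scored in the report.}
#'   \item{`inputs`}{alternative to `simulate`: `probe_table`, `gene_bed`,
#'     and optionally `sequences` (FASTA), `pwm_library`, `set_a`/`set_b`
#'     (gene-set files for the overlap test).}
#'   \item{`thresholds`}{`p_two_of_three` (0.05), `p_center` (0.01),
#'     `p_flank` (0.1), `max_span` (1000), `max_distance` (10000).}
#'   \item{`fdr`}{`n_permutations` (10).}
#'   \item{`motif`}{`k` (8), `max_mismatches` (1), `n_null` (200).}
#' }
#'
#' @param config Named list or path to a YAML config file.
#' @return The run report (list of class `run_report`), also written as
#'   `report.json` in `outdir`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    .assert(file.exists(config), "config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  seed <- config$seed %||% 1L
  outdir <- config$outdir %||% "chiptriplet_out"
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  thr <- config$thresholds %||% list()
  p23 <- thr$p_two_of_three %||% 0.05
  pc <- thr$p_center %||% 0.01
  pf <- thr$p_flank %||% 0.1
  span <- thr$max_span %||% 1000
  maxd <- thr$max_distance %||% 10000
  stage <- function(name) message(sprintf("[chiptriplet] stage: %s", name))

  report <- list(package = "chiptriplet",
                 version = as.character(utils::packageVersion("chiptriplet")),
                 seed = seed, config = config, complete = FALSE)

  result <- tryCatch({
    # --- inputs ---------------------------------------------------------
    truth <- NULL
    if (!is.null(config$simulate)) {
      stage("simulate")
      sim_args <- config$simulate
      sim_args$seed <- sim_args$seed %||% seed
      cfg <- do.call(sim_config, sim_args)
      sim <- simulate_array(cfg, dir = file.path(outdir, "simulated"))
      probes <- sim$probes; genes <- sim$genes; truth <- sim$truth
    } else {
      inp <- config$inputs %||% list()
      for (f in c("probe_table", "gene_bed")) {
        .assert(!is.null(inp[[f]]), "config: missing required input '%s'", f)
        .assert(file.exists(inp[[f]]), "input file not found: %s", inp[[f]])
      }
      stage("read inputs")
      probes <- read_probe_table(inp$probe_table)
      genes <- read_gene_bed(inp$gene_bed)
    }

    # --- probe stats ----------------------------------------------------
    stage("probe_stats")
    stats <- probe_stats(probes)
    write_probe_stats(stats, file.path(outdir, "probe_stats.tsv"))
    report$n_probes <- nrow(stats)

    # --- triplet caller -------------------------------------------------
    stage("triplet_caller")
    triplets <- scan_triplets(stats, p23, pc, pf, span)
    regions <- merge_triplets(triplets, stats)
    write_regions_bed(regions, file.path(outdir, "regions.bed"))
    report$n_triplets <- nrow(triplets)
    report$n_significant_triplets <- sum(triplets$significant)
    report$n_regions <- nrow(regions)

    # --- empirical FDR --------------------------------------------------
    stage("estimate_fdr")
    nperm <- (config$fdr %||% list())$n_permutations %||% 10
    fdr <- estimate_fdr(probes, n_permutations = nperm, seed = seed,
                        p_two_of_three = p23, p_center = pc, p_flank = pf,
                        max_span = span)
    report$fdr <- fdr$fdr
    report$mean_null_regions <- fdr$mean_null_regions

    # --- gene assignment ------------------------------------------------
    stage("gene_assignment")
    assignments <- assign_regions(regions, genes, max_distance = maxd)
    write_targets(assignments, file.path(outdir, "targets.tsv"))
    n_pc_array <- sum(genes$biotype == "protein_coding")
    summ <- summarize_targets(assignments, max(n_pc_array, 1L))
    report$n_assigned_regions <- summ$n_regions_assigned
    report$unique_gene_counts <- as.list(summ$unique_genes)
    report$fraction_of_array <- summ$fraction_of_array

    # --- overlap test (optional) ---------------------------------------
    inp <- config$inputs %||% list()
    if (!is.null(inp$set_a) || !is.null(inp$set_b)) {
      stage("overlap_enrichment")
      universe <- genes$gene_id
      targets <- unique(assignments$gene_id)
      report$overlaps <- lapply(c(a = "set_a", b = "set_b"), function(f) {
        if (is.null(inp[[f]])) return(NULL)
        ref <- intersect(read_gene_set(inp[[f]]), universe)
        r <- test_overlap(targets, ref, universe)
        list(file = inp[[f]], n_reference = r$n_setB,
             n_overlap = r$n_overlap, fold_enrichment = r$fold_enrichment,
             p_value = r$p_value)
      })
    }

    # --- TSS profile ----------------------------------------------------
    stage("tss_profile")
    profile <- compute_profile(regions, assignments, genes)
    write_profile(profile, file.path(outdir, "profile.tsv"))
    if (!profile$empty) {
      am <- which.max(profile$counts)
      report$profile_modal_bin <- c(profile$bin_edges[am],
                                    profile$bin_edges[am + 1L])
      report$profile_n_regions <- profile$n_in_range
    }

    # --- motif discovery (optional) ------------------------------------
    if (!is.null(inp$sequences)) {
      stage("motif_finder")
      mcfg <- config$motif %||% list()
      k <- mcfg$k %||% 8
      mm <- mcfg$max_mismatches %||% 1
      seqs <- read_fasta(inp$sequences)
      motifs <- find_motifs(seqs, k = k, max_mismatches = mm)
      write.table(motifs, file.path(outdir, "motifs.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      top <- motifs[1L, ]
      report$top_motif <- list(consensus = top$consensus,
                               fraction = top$fraction,
                               enrichment_z = top$enrichment_z)
      if (!is.null(inp$pwm_library)) {
        stage("pwm_match")
        lib <- read_pwm_library(inp$pwm_library)
        qpwm <- build_query_pwm(seqs, top$consensus, mm)
        matches <- match_library(qpwm, lib,
                                 n_null = mcfg$n_null %||% 200, seed = seed)
        write.table(matches, file.path(outdir, "pwm_matches.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        report$top_pwm_match <- as.list(matches[1L, ])
      }
    }

    # --- ground-truth scoring (simulation only) ------------------------
    if (!is.null(truth)) {
      report$truth_scores <- score_against_truth(regions, truth)
    }
    report$complete <- TRUE
    report
  }, error = function(e) {
    report$error <- conditionMessage(e)
    report
  })

  class(result) <- c("run_report", "list")
  jsonlite::write_json(.report_serializable(result),
                       file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!isTRUE(result$complete)) {
    .stopf("pipeline failed (partial outputs retained in %s): %s",
           outdir, result$error)
  }
  invisible(result)
}

.report_serializable <- function(x) {
  x <- unclass(x)
  rapply(x, function(v) v, how = "replace")
}

#' Score called regions against simulation ground truth
#'
#' A true region counts as recovered (sensitivity) when at least one called
#' region overlaps it; a called region counts as correct (precision) when it
#' overlaps at least one true region.  Boundary accuracy is the mean
#' absolute deviation between the called and true edges over matched pairs
#' (closest true region per called region).
#'
#' @param regions Called region `data.frame`.
#' @param truth Truth list from [simulate_array()].
#' @return A list with `n_true`, `n_called`, `sensitivity`, `precision`,
#'   `mean_boundary_error`.
#' @export
score_against_truth <- function(regions, truth) {
  tr <- truth$true_regions
  overlaps <- function(c1, s1, e1, c2, s2, e2) c1 == c2 & e1 > s2 & s1 < e2
  recovered <- vapply(seq_len(nrow(tr)), function(i) {
    any(overlaps(regions$chrom, regions$start, regions$end,
                 tr$chrom[i], tr$start[i], tr$end[i]))
  }, logical(1L))
  correct <- rep(FALSE, nrow(regions))
  bdev <- c()
  for (j in seq_len(nrow(regions))) {
    hit <- which(overlaps(tr$chrom, tr$start, tr$end,
                          regions$chrom[j], regions$start[j], regions$end[j]))
    if (length(hit)) {
      correct[j] <- TRUE
      i <- hit[which.min(abs(tr$start[hit] - regions$start[j]))]
      bdev <- c(bdev, abs(regions$start[j] - tr$start[i]),
                abs(regions$end[j] - tr$end[i]))
    }
  }
  list(n_true = nrow(tr), n_called = nrow(regions),
       sensitivity = if (nrow(tr)) mean(recovered) else NA_real_,
       precision = if (nrow(regions)) mean(correct) else NA_real_,
       mean_boundary_error = if (length(bdev)) mean(bdev) else NA_real_)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report (%s %s, seed %s): %s\n", x$package, x$version,
              x$seed, if (isTRUE(x$complete)) "complete" else "INCOMPLETE"))
  if (!is.null(x$n_regions)) {
    cat(sprintf("  %d probes -> %d regions (fdr %.4g), %d assigned\n",
                x$n_probes, x$n_regions, x$fdr,
                x$n_assigned_regions %||% NA))
  }
  invisible(x)
}
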