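#' Per-replicate median-centered log2 IP/control ratios
#'
#' For each replicate hybridization the enrichment signal of a probe is
#' `log2(ip / control)`; each replicate's log-ratios are then centered by
#' subtracting that replicate's median across all probes (per-array median
#' normalization), which removes global labeling/loading differences between
#' the two channels.
#'
#' @param probes Probe `data.frame` from [read_probe_table()] (or any
#'   data.frame with the same columns), sorted or unsorted.
#' @return A numeric matrix with one row per probe (in input order) and one
#'   column per replicate (`lr1`, `lr2`, ...).
#' @export
compute_log_ratios <- function(probes) {
  .assert(nrow(probes) >= 10L,
          "need at least 10 probes for a stable median normalization")
  reps <- .replicate_columns(names(probes))
  lr <- vapply(seq_along(reps$ip), function(k) {
    x <- log2(probes[[reps$ip[k]]] / probes[[reps$ctl[k]]])
    x - median(x)
  }, numeric(nrow(probes)))
  lr <- matrix(lr, nrow = nrow(probes))
  colnames(lr) <- sprintf("lr%d", seq_along(reps$ip))
  lr
}

#' Fit a robust null model to one replicate's log-ratios
#'
#' Most probes on a promoter array are unbound, so the bulk of the log-ratio
#' distribution estimates the null.  The model is a robust location/scale
#' pair: `center = median`, `spread = 1.4826 * MAD` (consistent for the
#' standard deviation under normality).
#'
#' @param log_ratios Numeric vector of at least 10 finite log-ratios.
#' @return An object of class `null_model` with fields `center` and `spread`.
#' @export
fit_null_model <- function(log_ratios) {
  x <- log_ratios[is.finite(log_ratios)]
  .assert(length(x) >= 10L, "need at least 10 finite log-ratios")
  center <- median(x)
  spread <- mad(x, center = center)  # constant 1.4826 is mad()'s default
  .assert(spread > 0, "degenerate input: zero spread (constant log-ratios)")
  structure(list(center = center, spread = spread), class = "null_model")
}

#' @export
print.null_model <- function(x, ...) {
  cat(sprintf("null_model: center %.4g, spread %.4g\n", x$center, x$spread))
  invisible(x)
}

#' Per-probe enrichment p-values from replicate z-averaging
#'
#' Each replicate's log-ratio is standardized against that replicate's null
#' model, the z-scores are averaged across replicates as
#' `combined_z = sum(z_k) / sqrt(R)` (unit variance under the null), and the
#' probe p-value is the one-sided upper-tail standard-normal probability:
#' only enrichment of IP over control can be significant, never depletion.
#'
#' @param probes Probe `data.frame` (for coordinates and ids), same row order
#'   as `log_ratios`.
#' @param log_ratios Matrix from [compute_log_ratios()].
#' @param nulls List of `null_model` objects, one per replicate; defaults to
#'   models fitted on each column of `log_ratios`.
#' @return A `data.frame` of class `probe_stats` with columns `probe_id`,
#'   `chrom`, `start`, `end`, the per-replicate log-ratios (`lr<k>`) and
#'   z-scores (`z<k>`), `combined_z` and `p_value`, sorted by
#'   `(chrom, start)`.
#' @export
probe_pvalues <- function(probes, log_ratios, nulls = NULL) {
  R <- ncol(log_ratios)
  .assert(nrow(log_ratios) == nrow(probes),
          "log_ratios and probes disagree on probe count")
  if (is.null(nulls)) nulls <- apply(log_ratios, 2L, fit_null_model)
  .assert(length(nulls) == R,
          "replicate count mismatch: %d null models for %d replicates",
          length(nulls), R)
  z <- vapply(seq_len(R), function(k) {
    (log_ratios[, k] - nulls[[k]]$center) / nulls[[k]]$spread
  }, numeric(nrow(log_ratios)))
  z <- matrix(z, nrow = nrow(log_ratios))
  combined_z <- rowSums(z) / sqrt(R)
  p <- pnorm(combined_z, lower.tail = FALSE)
  p <- pmax(p, .Machine$double.xmin)  # keep p in (0, 1]
  out <- data.frame(probe_id = probes$probe_id, chrom = probes$chrom,
                    start = probes$start, end = probes$end,
                    stringsAsFactors = FALSE)
  colnames(z) <- sprintf("z%d", seq_len(R))
  lr <- log_ratios
  colnames(lr) <- sprintf("lr%d", seq_len(R))
  out <- cbind(out, lr, z)
  out$combined_z <- combined_z
  out$p_value <- p
  out <- out[.genomic_order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("probe_stats", "data.frame")
  attr(out, "n_replicates") <- R
  out
}

#' One call from probe table to probe statistics
#'
#' Convenience composition of [compute_log_ratios()], [fit_null_model()] per
#' replicate and [probe_pvalues()].
#'
#' @inheritParams compute_log_ratios
#' @return See [probe_pvalues()].
#' @export
probe_stats <- function(probes) {
  lr <- compute_log_ratios(probes)
  probe_pvalues(probes, lr)
}

#' Write probe statistics as a tab-delimited table
#'
#' @param stats `probe_stats` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_probe_stats <- function(stats, path) {
  write.table(stats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
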