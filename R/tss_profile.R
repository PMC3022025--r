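#' Strand-oriented binding density relative to the TSS
#'
#' Every assigned region is represented by its midpoint `m`, transformed to a
#' TSS-relative coordinate with all genes centered and oriented the same way:
#' `r = m - tss` for `+` strand genes and `r = tss - m` for `-` strand genes,
#' so positive `r` always means downstream of the TSS.  The coordinates are
#' binned and a normalized density over the covered bins is returned.
#'
#' @param regions Region `data.frame` from [call_regions()].
#' @param assignments Output of [assign_regions()]; every `gene_id` must be
#'   present in `genes`.
#' @param genes Gene `data.frame` from [read_gene_bed()].
#' @param bin_edges Increasing integer vector of bin edges in bp relative to
#'   the TSS; default `seq(-5500, 2500, 250)`, matching a promoter array that
#'   covers -5.5 kb to +2.5 kb.
#' @return An object of class `tss_profile`: `bin_edges`, `counts` (per bin,
#'   left-closed right-open), `density` (counts normalized to sum 1; all `NA`
#'   with `empty = TRUE` when nothing falls in range), `n_assigned`, and
#'   `n_in_range`.
#' @export
compute_profile <- function(regions, assignments, genes,
                            bin_edges = seq(-5500, 2500, by = 250)) {
  .assert(length(bin_edges) >= 2L && all(diff(bin_edges) > 0),
          "bin_edges must be increasing with at least two values")
  missing <- setdiff(assignments$gene_id, genes$gene_id)
  if (length(missing)) .stopf("assigned gene not in annotation: %s",
                              missing[1L])
  nb <- length(bin_edges) - 1L
  counts <- integer(nb)
  if (nrow(assignments) > 0L) {
    ridx <- match(assignments$region_id, regions$region_id)
    .assert(!anyNA(ridx), "assignment references unknown region_id")
    gidx <- match(assignments$gene_id, genes$gene_id)
    m <- floor((regions$start[ridx] + regions$end[ridx]) / 2)
    r <- ifelse(genes$strand[gidx] == "+", m - genes$tss[gidx],
                genes$tss[gidx] - m)
    bin <- findInterval(r, bin_edges, rightmost.closed = FALSE)
    bin[r >= bin_edges[nb + 1L]] <- 0L  # beyond the last edge
    inr <- bin >= 1L & bin <= nb
    tab <- table(factor(bin[inr], levels = seq_len(nb)))
    counts <- as.integer(tab)
  }
  total <- sum(counts)
  structure(list(
    bin_edges = bin_edges, counts = counts,
    density = if (total > 0) counts / total else rep(NA_real_, nb),
    empty = total == 0L, n_assigned = nrow(assignments), n_in_range = total
  ), class = "tss_profile")
}

#' @export
print.tss_profile <- function(x, ...) {
  if (x$empty) {
    cat("tss_profile: empty (no assigned regions in range)\n")
  } else {
    am <- which.max(x$counts)
    cat(sprintf(
      "tss_profile: %d regions in [%d, %d) bp; modal bin [%d, %d)\n",
      x$n_in_range, x$bin_edges[1L], x$bin_edges[length(x$bin_edges)],
      x$bin_edges[am], x$bin_edges[am + 1L]))
  }
  invisible(x)
}

#' Write a TSS profile as a tab-delimited table
#'
#' Columns: `bin_start`, `bin_end`, `count`, `density`.
#'
#' @param profile `tss_profile` object from [compute_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  nb <- length(profile$bin_edges) - 1L
  df <- data.frame(bin_start = profile$bin_edges[-(nb + 1L)],
                   bin_end = profile$bin_edges[-1L],
                   count = profile$counts, density = profile$density)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
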