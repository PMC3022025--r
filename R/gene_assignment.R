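#' Assign bound regions to the closest TSS within 10 kb
#'
#' For every region the distance to each same-chromosome transcription start
#' site is 0 when the TSS lies inside the region (`start <= tss < end`) and
#' otherwise the gap to the nearest region endpoint,
#' `min(|tss - start|, |tss - (end - 1)|)`.  The region is assigned to the
#' gene with the minimal distance provided that distance is strictly below
#' `max_distance`; ties go to the lexicographically smallest `gene_id`.
#' Regions with no TSS in range stay unassigned.  A gene may collect several
#' regions; each region gets at most one gene.
#'
#' @param regions Region `data.frame` from [call_regions()].
#' @param genes Gene `data.frame` from [read_gene_bed()].
#' @param max_distance Strict upper bound on the assignment distance in bp
#'   (default 10000).
#' @return A `data.frame` with columns `region_id`, `gene_id`, `distance`,
#'   `biotype` — one row per assigned region.
#' @export
assign_regions <- function(regions, genes, max_distance = 10000) {
  out <- data.frame(region_id = character(), gene_id = character(),
                    distance = integer(), biotype = character(),
                    stringsAsFactors = FALSE)
  if (nrow(regions) == 0L || nrow(genes) == 0L) return(out)
  rows <- vector("list", nrow(regions))
  by_chrom <- split(seq_len(nrow(genes)), genes$chrom)
  for (r in seq_len(nrow(regions))) {
    gi <- by_chrom[[regions$chrom[r]]]
    if (is.null(gi)) next
    tss <- genes$tss[gi]
    s <- regions$start[r]; e <- regions$end[r]
    d <- ifelse(tss >= s & tss < e, 0L,
                pmin(abs(tss - s), abs(tss - (e - 1L))))
    ok <- d < max_distance
    if (!any(ok)) next
    gi <- gi[ok]; d <- d[ok]
    best <- gi[order(d, genes$gene_id[gi])][1L]
    rows[[r]] <- data.frame(region_id = regions$region_id[r],
                            gene_id = genes$gene_id[best],
                            distance = min(d),
                            biotype = genes$biotype[best],
                            stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (length(rows)) out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize target genes by biotype and array fraction
#'
#' Counts the unique target genes per biotype and reports the fraction of the
#' array covered: unique protein-coding targets divided by the number of
#' protein-coding genes represented on the array.
#'
#' @param assignments Output of [assign_regions()].
#' @param array_gene_total Number of (protein-coding) genes on the array
#'   (> 0).
#' @return An object of class `target_summary`: `n_regions_assigned`,
#'   `unique_genes` (named counts per biotype), `fraction_of_array`.
#' @export
summarize_targets <- function(assignments, array_gene_total) {
  .assert(.is_count(array_gene_total) && array_gene_total > 0,
          "array_gene_total must be a positive integer")
  biotypes <- c("protein_coding", "miRNA", "other")
  uniq <- unique(assignments[, c("gene_id", "biotype")])
  counts <- setNames(integer(length(biotypes)), biotypes)
  tab <- table(factor(uniq$biotype, levels = biotypes))
  counts[names(tab)] <- as.integer(tab)
  structure(list(
    n_regions_assigned = nrow(assignments),
    unique_genes = counts,
    fraction_of_array = unname(counts["protein_coding"]) / array_gene_total
  ), class = "target_summary")
}

#' @export
print.target_summary <- function(x, ...) {
  cat(sprintf(
    "target_summary: %d regions assigned; %d protein-coding, %d miRNA, %d other unique genes; %.1f%% of array\n",
    x$n_regions_assigned, x$unique_genes["protein_coding"],
    x$unique_genes["miRNA"], x$unique_genes["other"],
    100 * x$fraction_of_array))
  invisible(x)
}

#' Write target assignments as a tab-delimited table
#'
#' @param assignments Output of [assign_regions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_targets <- function(assignments, path) {
  write.table(assignments, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
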