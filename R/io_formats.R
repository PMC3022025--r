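#' Read a two-channel probe intensity table
#'
#' Reads the tab-delimited probe dialect used throughout the package: a header
#' line naming `probe_id`, `chrom`, `start`, `end` and then, for each replicate
#' hybridization `k = 1..R`, a pair of columns `rep<k>_ip` and `rep<k>_ctl`
#' holding the immunoprecipitated (e.g. Cy5) and control (e.g. Cy3)
#' fluorescence intensities.  Intervals are 0-based half-open.
#'
#' @param path Path to a tab-delimited probe table.
#' @return A `data.frame` with columns `probe_id`, `chrom`, `start`, `end` and
#'   the per-replicate intensity columns, sorted by `(chrom, start)`, with the
#'   replicate count in `attr(, "n_replicates")`.
#' @export
read_probe_table <- function(path) {
  .assert(file.exists(path), "probe table not found: %s", path)
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  req <- c("probe_id", "chrom", "start", "end")
  .assert(all(req %in% names(df)),
          "probe table must have columns %s", paste(req, collapse = ", "))
  reps <- .replicate_columns(names(df))
  .assert(length(reps$ip) >= 1L, "no rep<k>_ip/rep<k>_ctl column pairs found")
  validate_probe_table(df)
  df <- df[, c(req, as.vector(rbind(reps$ip, reps$ctl)))]
  df <- df[.genomic_order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "n_replicates") <- length(reps$ip)
  df
}

.replicate_columns <- function(nm) {
  ip <- grep("^rep[0-9]+_ip$", nm, value = TRUE)
  k <- sort(as.integer(sub("^rep([0-9]+)_ip$", "\\1", ip)))
  ip <- sprintf("rep%d_ip", k)
  ctl <- sprintf("rep%d_ctl", k)
  .assert(all(ctl %in% nm),
          "each rep<k>_ip column needs a matching rep<k>_ctl column")
  list(ip = ip, ctl = ctl, k = k)
}

#' Validate a probe table held in memory
#'
#' Checks the invariants of the probe container: unique probe ids,
#' `start < end`, and strictly positive intensities in every channel.
#' Violations are reported with the offending row number.
#'
#' @param df A probe `data.frame` as returned by [read_probe_table()].
#' @return The input, invisibly, if valid.
#' @export
validate_probe_table <- function(df) {
  reps <- .replicate_columns(names(df))
  bad <- which(!(df$start < df$end))
  if (length(bad)) .stopf("row %d: start must be < end", bad[1L])
  dup <- which(duplicated(df$probe_id))
  if (length(dup)) .stopf("row %d: duplicate probe_id '%s'",
                          dup[1L], df$probe_id[dup[1L]])
  for (col in c(reps$ip, reps$ctl)) {
    v <- df[[col]]
    bad <- which(!is.finite(v) | v <= 0)
    if (length(bad)) .stopf("row %d: non-positive intensity in column %s",
                            bad[1L], col)
  }
  invisible(df)
}

#' Write a probe table
#'
#' @param df Probe `data.frame` (see [read_probe_table()] for the dialect).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_probe_table <- function(df, path) {
  validate_probe_table(df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene annotations from a BED-like file
#'
#' Expects BED6 columns (`chrom`, `start`, `end`, `name`, `score`, `strand`)
#' plus an optional 7th `biotype` column (`protein_coding`, `miRNA` or
#' `other`; defaults to `protein_coding`).  The transcription start site is
#' the interval start for `+` strand genes and `end - 1` for `-` strand genes
#' (0-based).
#'
#' @param path Path to the BED-like file.
#' @return A `data.frame` with columns `gene_id`, `chrom`, `tss`, `strand`,
#'   `biotype`.
#' @export
read_gene_bed <- function(path) {
  .assert(file.exists(path), "gene BED not found: %s", path)
  df <- read.delim(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  .assert(ncol(df) >= 6L, "gene BED needs at least 6 columns")
  strand <- as.character(df[[6L]])
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad)) .stopf("row %d: unknown strand symbol '%s'",
                          bad[1L], strand[bad[1L]])
  biotype <- if (ncol(df) >= 7L) as.character(df[[7L]]) else
    rep("protein_coding", nrow(df))
  biotype[is.na(biotype) | biotype == ""] <- "protein_coding"
  bad <- which(!biotype %in% c("protein_coding", "miRNA", "other"))
  if (length(bad)) .stopf("row %d: unknown biotype '%s'",
                          bad[1L], biotype[bad[1L]])
  genes <- data.frame(
    gene_id = as.character(df[[4L]]),
    chrom = as.character(df[[1L]]),
    tss = ifelse(strand == "+", as.integer(df[[2L]]), as.integer(df[[3L]]) - 1L),
    strand = strand,
    biotype = biotype,
    stringsAsFactors = FALSE
  )
  dup <- which(duplicated(genes$gene_id))
  if (length(dup)) .stopf("row %d: duplicate gene_id '%s'",
                          dup[1L], genes$gene_id[dup[1L]])
  .assert(all(genes$tss >= 0), "negative TSS coordinate")
  genes
}

#' Write gene annotations as BED6(+biotype)
#'
#' Inverse of [read_gene_bed()]: each gene becomes a 1-bp feature anchored at
#' its TSS (start = tss, end = tss + 1 for `+`; start = tss, end = tss + 1
#' written strand-appropriately) with the biotype in column 7.
#'
#' @param genes Gene `data.frame` from [read_gene_bed()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_bed <- function(genes, path) {
  start <- ifelse(genes$strand == "+", genes$tss, genes$tss)
  end <- start + 1L
  out <- data.frame(genes$chrom, start, end, genes$gene_id, 0L, genes$strand,
                    genes$biotype)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write bound regions as BED5
#'
#' Columns: chrom, start, end, region_id, score, where the score is
#' `-log10(best_p)` capped at 300.  Intervals are 0-based half-open.
#'
#' @param regions Region `data.frame` from [merge_triplets()] or
#'   [call_regions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  if (nrow(regions) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  score <- pmin(-log10(regions$best_p), 300)
  out <- data.frame(regions$chrom, regions$start, regions$end,
                    regions$region_id, score)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a BED5 region file written by [write_regions_bed()]
#'
#' @param path Path to the BED file.
#' @return A `data.frame` with columns `region_id`, `chrom`, `start`, `end`,
#'   `score`.
#' @export
read_regions_bed <- function(path) {
  .assert(file.exists(path), "region BED not found: %s", path)
  if (file.size(path) == 0L) {
    return(data.frame(region_id = character(), chrom = character(),
                      start = integer(), end = integer(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  df <- read.delim(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  data.frame(region_id = as.character(df[[4L]]), chrom = as.character(df[[1L]]),
             start = as.integer(df[[2L]]), end = as.integer(df[[3L]]),
             score = as.numeric(df[[5L]]), stringsAsFactors = FALSE)
}

#' Read DNA sequences from a FASTA file
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that additionally
#' enforces the `{A,C,G,T,N}` alphabet.
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @return A named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  .assert(file.exists(path), "FASTA not found: %s", path)
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) .stopf("sequence '%s' contains characters outside A,C,G,T,N",
                       names(seqs)[which(bad)[1L]])
  seqs
}

#' Write DNA sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a PWM library in the minimal text format
#'
#' The format holds one record per motif: a line `>name`, followed by one line
#' per motif position with four tab-separated non-negative frequencies in the
#' order A, C, G, T.  Rows are renormalized to sum to 1; a zero-sum row is an
#' error.
#'
#' @param path Path to the PWM library file.
#' @return A named list of numeric matrices (rows = positions, columns
#'   `A,C,G,T`, each row summing to 1).
#' @export
read_pwm_library <- function(path) {
  .assert(file.exists(path), "PWM library not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  .assert(length(heads) >= 1L, "no '>' record headers in PWM library")
  bounds <- c(heads, length(lines) + 1L)
  pwms <- list()
  for (i in seq_along(heads)) {
    name <- sub("^>\\s*", "", lines[heads[i]])
    body <- lines[seq(heads[i] + 1L, bounds[i + 1L] - 1L)]
    .assert(length(body) >= 1L, "PWM '%s' has no rows", name)
    rows <- lapply(body, function(l) as.numeric(strsplit(l, "\t", fixed = TRUE)[[1L]]))
    .assert(all(lengths(rows) == 4L), "PWM '%s': each row needs 4 values", name)
    m <- do.call(rbind, rows)
    .assert(all(is.finite(m)) && all(m >= 0),
            "PWM '%s': negative or non-numeric frequency", name)
    rs <- rowSums(m)
    .assert(all(rs > 0), "PWM '%s': zero-sum row", name)
    m <- m / rs
    colnames(m) <- DNA_BASES
    pwms[[name]] <- m
  }
  pwms
}

#' Write a PWM library in the minimal text format
#'
#' @param pwms Named list of PWM matrices (rows = positions, 4 columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pwm_library <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (name in names(pwms)) {
    writeLines(paste0(">", name), con)
    m <- pwms[[name]]
    apply(m, 1L, function(r) writeLines(paste(format(r, scientific = FALSE,
                                                     trim = TRUE),
                                              collapse = "\t"), con))
  }
  invisible(path)
}

#' Read a gene set (one gene id per line)
#'
#' @param path Path to the gene-set file.
#' @return Character vector of unique gene ids.
#' @export
read_gene_set <- function(path) {
  .assert(file.exists(path), "gene set not found: %s", path)
  ids <- readLines(path)
  unique(trimws(ids[nzchar(trimws(ids))]))
}

#' Write a gene set (one gene id per line)
#'
#' @param ids Character vector of gene ids.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_set <- function(ids, path) {
  writeLines(ids, path)
  invisible(path)
}

#' Read a term-to-gene annotation table
#'
#' Two tab-separated columns: term id, gene id.
#'
#' @param path Path to the annotation file.
#' @return Named list mapping each term to its character vector of gene ids.
#' @export
read_annotation <- function(path) {
  .assert(file.exists(path), "annotation not found: %s", path)
  df <- read.delim(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  .assert(ncol(df) >= 2L, "annotation needs two columns (term, gene)")
  split(as.character(df[[2L]]), as.character(df[[1L]]))
}
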