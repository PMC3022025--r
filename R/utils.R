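# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.assert <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) .stopf(fmt, ...)
  invisible(TRUE)
}

DNA_BASES <- c("A", "C", "G", "T")

# Encode a DNA string as integer digits 0..3 (A,C,G,T); N (or any other
# IUPAC code) becomes 4, which mismatches every base.
.dna_digits <- function(seq) {
  x <- utf8ToInt(toupper(seq))
  d <- rep.int(4L, length(x))
  d[x == 65L] <- 0L  # A
  d[x == 67L] <- 1L  # C
  d[x == 71L] <- 2L  # G
  d[x == 84L] <- 3L  # T
  d
}

.digits_to_dna <- function(d) {
  paste(c(DNA_BASES, "N")[d + 1L], collapse = "")
}

.revcomp_chr <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Order probes/regions by (chrom, start) with a stable alphabetical
# chromosome order; coordinates are plain integers.
.genomic_order <- function(chrom, start) order(chrom, start)

.is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x == floor(x)
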