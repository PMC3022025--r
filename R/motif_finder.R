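# Exhaustive consensus-motif discovery over bound-region sequences and
# PWM-library matching.  k-mers are encoded as base-4 integers (A,C,G,T =
# 0..3); windows containing N are skipped; motifs are canonicalized over the
# reverse complement so hits are counted on both strands.

.window_codes <- function(digits, k) {
  n <- length(digits)
  if (n < k) return(integer(0))
  nw <- n - k + 1L
  d0 <- digits
  d0[d0 == 4L] <- 0L
  codes <- integer(nw)
  for (j in 0L:(k - 1L)) codes <- codes * 4L + d0[(1L + j):(nw + j)]
  cs <- c(0L, cumsum(digits == 4L))
  has_n <- (cs[(k + 1L):(n + 1L)] - cs[1L:nw]) > 0L
  codes[!has_n]
}

.rc_code <- function(codes, k) {
  res <- integer(length(codes))
  tmp <- codes
  for (j in seq_len(k)) {
    res <- res * 4L + (3L - tmp %% 4L)
    tmp <- tmp %/% 4L
  }
  res
}

.code_digits <- function(codes, k) {
  m <- matrix(0L, nrow = length(codes), ncol = k)
  tmp <- codes
  for (j in k:1L) {
    m[, j] <- tmp %% 4L
    tmp <- tmp %/% 4L
  }
  m
}

.neighbor_codes <- function(codes, k, m) {
  if (m == 0L || length(codes) == 0L) return(codes)
  expand1 <- function(cc) {
    out <- vector("list", 3L * k + 1L)
    out[[1L]] <- cc
    pos <- 2L
    for (j in 0L:(k - 1L)) {
      pw <- 4L^(k - 1L - j)
      dj <- (cc %/% pw) %% 4L
      for (b in 1L:3L) {
        out[[pos]] <- cc + (((dj + b) %% 4L) - dj) * pw
        pos <- pos + 1L
      }
    }
    unlist(out, use.names = FALSE)
  }
  nb <- expand1(codes)
  if (m >= 2L) nb <- unique(expand1(unique(nb)))
  nb
}

# order-0 background base probabilities with a +1 pseudocount
.fit_background <- function(sequences) {
  counts <- setNames(rep(1, 4L), DNA_BASES)
  for (s in sequences) {
    d <- .dna_digits(s)
    tab <- tabulate(d[d < 4L] + 1L, nbins = 4L)
    counts <- counts + tab
  }
  counts / sum(counts)
}

# P(a random k-mer under base probs p lies within m mismatches of the word
# with digit rows D); vectorized over rows of D
.p_within <- function(D, p, m) {
  pc <- matrix(p[D + 1L], nrow = nrow(D))
  p_exact <- apply(pc, 1L, prod)
  if (m == 0L) return(p_exact)
  q <- (1 - pc) / pc
  s1 <- rowSums(q)
  if (m == 1L) return(p_exact * (1 + s1))
  s2 <- (s1^2 - rowSums(q^2)) / 2
  p_exact * (1 + s1 + s2)
}

#' Exhaustive k-mer consensus motif discovery
#'
#' Every k-mer (canonicalized over its reverse complement) is scored by the
#' number of sequences carrying at least one occurrence within
#' `max_mismatches`, on either strand, against its expectation under an
#' order-0 background model: with per-window match probability `P`, a
#' sequence with `W` windows hits with probability `h = 1 - (1 - P)^W`, and
#' `enrichment_z = (observed - sum(h)) / sqrt(sum(h * (1 - h)))` under the
#' per-sequence binomial hit model.  The search is deterministic and
#' invariant to sequence order and to reverse-complementing the input.
#'
#' @param sequences Named character vector of DNA sequences (A,C,G,T,N).
#' @param k Motif length, 4..12 (default 8).
#' @param max_mismatches Allowed mismatches per occurrence, 0..2 (default 1).
#' @param background Either `NULL` (order-0 model fitted on `sequences`), a
#'   character vector of background sequences, or a numeric vector of 4 base
#'   probabilities (A,C,G,T).
#' @param top_n Number of top-ranked motifs to return (default 25).
#' @return A `data.frame` ranked by decreasing `enrichment_z` with columns
#'   `consensus`, `n_seqs_with_hit`, `n_seqs_total`, `fraction`,
#'   `expected_seqs`, `enrichment_z`.
#' @export
find_motifs <- function(sequences, k = 8, max_mismatches = 1,
                        background = NULL, top_n = 25) {
  .assert(length(sequences) > 0L, "no sequences")
  .assert(.is_count(k) && k >= 4 && k <= 12, "k must be an integer in 4..12")
  .assert(.is_count(max_mismatches) && max_mismatches >= 0 &&
            max_mismatches <= 2, "max_mismatches must be 0, 1 or 2")
  lens <- nchar(sequences)
  .assert(min(lens) >= k, "k is longer than the shortest sequence")
  k <- as.integer(k); m <- as.integer(max_mismatches)
  p_bg <- if (is.null(background)) {
    .fit_background(sequences)
  } else if (is.character(background)) {
    .fit_background(background)
  } else {
    .assert(is.numeric(background) && length(background) == 4L &&
              all(background > 0), "background must be 4 positive probabilities")
    background / sum(background)
  }
  nS <- length(sequences)
  cnt <- integer(4L^k)
  n_windows <- integer(nS)
  for (s in seq_len(nS)) {
    codes <- .window_codes(.dna_digits(sequences[[s]]), k)
    n_windows[s] <- length(codes)
    if (!length(codes)) next
    nb <- .neighbor_codes(codes, k, m)
    can <- pmin(nb, .rc_code(nb, k))
    u <- unique(can)
    cnt[u + 1L] <- cnt[u + 1L] + 1L
  }
  obs_codes <- which(cnt > 0L) - 1L
  if (!length(obs_codes)) {
    return(data.frame(consensus = character(), n_seqs_with_hit = integer(),
                      n_seqs_total = integer(), fraction = numeric(),
                      expected_seqs = numeric(), enrichment_z = numeric()))
  }
  D <- .code_digits(obs_codes, k)
  rc_codes <- .rc_code(obs_codes, k)
  Drc <- .code_digits(rc_codes, k)
  p_match <- .p_within(D, p_bg, m) +
    ifelse(rc_codes == obs_codes, 0, .p_within(Drc, p_bg, m))
  p_match <- pmin(p_match, 1)
  expected <- numeric(length(obs_codes))
  v <- numeric(length(obs_codes))
  for (W in unique(n_windows)) {
    nW <- sum(n_windows == W)
    h <- 1 - (1 - p_match)^W
    expected <- expected + nW * h
    v <- v + nW * h * (1 - h)
  }
  obs <- cnt[obs_codes + 1L]
  z <- (obs - expected) / sqrt(pmax(v, .Machine$double.eps))
  ord <- order(-z, obs_codes)
  keep <- head(ord, top_n)
  data.frame(
    consensus = vapply(obs_codes[keep], function(cc)
      .digits_to_dna(.code_digits(cc, k)[1L, ]), character(1L)),
    n_seqs_with_hit = obs[keep], n_seqs_total = nS,
    fraction = obs[keep] / nS, expected_seqs = expected[keep],
    enrichment_z = z[keep], stringsAsFactors = FALSE)
}

#' Count the fraction of sequences carrying a consensus motif
#'
#' Scans both strands of every sequence for occurrences of `consensus` with
#' at most `max_mismatches` mismatches; a sequence counts at most once.
#' `N` bases mismatch everything.
#'
#' @param sequences Named character vector of DNA sequences.
#' @param consensus Motif string over A,C,G,T.
#' @param max_mismatches Allowed mismatches (default 0).
#' @return An object of class `motif_count`: `consensus`, `max_mismatches`,
#'   `n_seqs_with_hit`, `n_seqs_total`, `fraction`, and a `hits` data.frame
#'   (`seq_name`, `hit`, `pos` 0-based forward-strand offset of the best
#'   occurrence, `strand`, `mismatches`).
#' @export
count_fraction <- function(sequences, consensus, max_mismatches = 0) {
  .assert(length(sequences) > 0L, "no sequences")
  .assert(grepl("^[ACGT]+$", consensus), "consensus must be over A,C,G,T")
  k <- nchar(consensus)
  .assert(min(nchar(sequences)) >= k, "consensus longer than shortest sequence")
  cd <- .dna_digits(consensus)
  rd <- rev(3L - cd)
  nS <- length(sequences)
  nm <- names(sequences) %||% as.character(seq_len(nS))
  hit <- logical(nS); pos <- rep(NA_integer_, nS)
  strand <- rep(NA_character_, nS); mism <- rep(NA_integer_, nS)
  for (s in seq_len(nS)) {
    d <- .dna_digits(sequences[[s]])
    nw <- length(d) - k + 1L
    mm_f <- integer(nw); mm_r <- integer(nw)
    for (j in 0L:(k - 1L)) {
      w <- d[(1L + j):(nw + j)]
      mm_f <- mm_f + (w != cd[j + 1L])
      mm_r <- mm_r + (w != rd[j + 1L])
    }
    best <- pmin(mm_f, mm_r)
    if (min(best) <= max_mismatches) {
      i <- which.min(best)  # leftmost best occurrence
      hit[s] <- TRUE
      pos[s] <- i - 1L
      strand[s] <- if (mm_f[i] <= mm_r[i]) "+" else "-"
      mism[s] <- best[i]
    }
  }
  structure(list(
    consensus = consensus, max_mismatches = max_mismatches,
    n_seqs_with_hit = sum(hit), n_seqs_total = nS,
    fraction = sum(hit) / nS,
    hits = data.frame(seq_name = nm, hit = hit, pos = pos, strand = strand,
                      mismatches = mism, stringsAsFactors = FALSE)
  ), class = "motif_count")
}

#' @export
print.motif_count <- function(x, ...) {
  cat(sprintf("motif_count: %s (<= %d mismatches) in %d of %d sequences (%.1f%%)\n",
              x$consensus, x$max_mismatches, x$n_seqs_with_hit,
              x$n_seqs_total, 100 * x$fraction))
  invisible(x)
}

#' Build a position-frequency matrix from motif occurrences
#'
#' Takes the best occurrence per sequence (leftmost, fewest mismatches,
#' forward strand preferred on ties; reverse-strand occurrences are
#' reverse-complemented into motif orientation), adds a pseudocount of 0.5
#' per cell, and normalizes each position to sum 1.
#'
#' @inheritParams count_fraction
#' @return A numeric matrix, rows = motif positions, columns `A,C,G,T`.
#' @export
build_query_pwm <- function(sequences, consensus, max_mismatches = 1) {
  mc <- count_fraction(sequences, consensus, max_mismatches)
  .assert(mc$n_seqs_with_hit >= 1L, "no occurrence of '%s' found", consensus)
  k <- nchar(consensus)
  counts <- matrix(0.5, nrow = k, ncol = 4L,
                   dimnames = list(NULL, DNA_BASES))
  h <- mc$hits[mc$hits$hit, , drop = FALSE]
  for (r in seq_len(nrow(h))) {
    w <- substr(sequences[[h$seq_name[r]]], h$pos[r] + 1L, h$pos[r] + k)
    if (h$strand[r] == "-") w <- .revcomp_chr(w)
    d <- .dna_digits(w)
    for (j in seq_len(k)) {
      if (d[j] < 4L) counts[j, d[j] + 1L] <- counts[j, d[j] + 1L] + 1
    }
  }
  counts / rowSums(counts)
}

# mean per-column Pearson correlation for one alignment offset; columns with
# zero variance on either side contribute 0
.aligned_cor <- function(q, l, shift) {
  kq <- nrow(q); kl <- nrow(l)
  t0 <- max(1L, shift + 1L); t1 <- min(kl, shift + kq)
  if (t1 - t0 + 1L < 4L) return(NA_real_)
  A <- q[(t0 - shift):(t1 - shift), , drop = FALSE]
  B <- l[t0:t1, , drop = FALSE]
  a <- A - rowMeans(A); b <- B - rowMeans(B)
  den <- sqrt(rowSums(a^2) * rowSums(b^2))
  cc <- ifelse(den > 0, rowSums(a * b) / den, 0)
  mean(cc)
}

.best_alignment <- function(q, l, min_overlap = 4L) {
  kq <- nrow(q); kl <- nrow(l)
  rc <- l[kl:1L, c("T", "G", "C", "A"), drop = FALSE]
  colnames(rc) <- DNA_BASES
  best <- list(similarity = -Inf, offset = NA_integer_,
               orientation = NA_character_)
  for (ori in c("forward", "reverse_complement")) {
    lm <- if (ori == "forward") l else rc
    for (shift in (min_overlap - kq):(kl - min_overlap)) {
      s <- .aligned_cor(q, lm, shift)
      if (!is.na(s) && s > best$similarity) {
        best <- list(similarity = s, offset = shift, orientation = ori)
      }
    }
  }
  best
}

#' Match a query PWM against a PWM library
#'
#' For every library PWM the best mean per-column Pearson correlation over
#' all alignment offsets with at least 4 aligned columns, in both
#' orientations, is computed.  Significance comes from a column-shuffling
#' null: the library PWM's positions are permuted `n_null` times and the
#' best similarity recomputed; `p = (1 + #{null >= observed}) / (n_null + 1)`.
#'
#' @param query Query PWM matrix (rows = positions, columns A,C,G,T), e.g.
#'   from [build_query_pwm()].
#' @param library Named list of library PWMs from [read_pwm_library()].
#' @param n_null Number of column-shuffled null comparisons per library
#'   entry (>= 100; default 200).
#' @param seed Integer seed for the shuffling null.
#' @return A `data.frame` ranked by decreasing similarity with columns
#'   `library_name`, `similarity`, `offset`, `orientation`, `p_value`.
#' @export
match_library <- function(query, library, n_null = 200, seed = 1) {
  .assert(length(library) > 0L, "empty PWM library")
  .assert(.is_count(n_null) && n_null >= 100, "n_null must be >= 100")
  set.seed(seed)
  res <- lapply(names(library), function(nmi) {
    l <- library[[nmi]]
    obs <- .best_alignment(query, l)
    null_sims <- vapply(seq_len(n_null), function(b) {
      .best_alignment(query, l[sample(nrow(l)), , drop = FALSE])$similarity
    }, numeric(1L))
    data.frame(library_name = nmi, similarity = obs$similarity,
               offset = obs$offset, orientation = obs$orientation,
               p_value = (1 + sum(null_sims >= obs$similarity)) / (n_null + 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(-out$similarity, out$library_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}
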