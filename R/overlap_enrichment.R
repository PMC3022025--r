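#' Hypergeometric gene-set overlap test
#'
#' Tests whether two gene sets drawn from a common universe overlap more than
#' expected by chance.  The p-value is the exact hypergeometric upper tail
#' `P(X >= n_overlap)` (equivalently a one-sided Fisher test on the 2x2
#' table); fold enrichment is observed over expected overlap,
#' `expected = |A| * |B| / |U|`.
#'
#' @param setA,setB Character vectors of gene ids, both subsets of
#'   `universe`.
#' @param universe Character vector: the gene universe (e.g. all genes on the
#'   array).
#' @return An object of class `overlap_result` with fields `n_universe`,
#'   `n_setA`, `n_setB`, `n_overlap`, `expected`, `fold_enrichment`,
#'   `p_value`.
#' @export
test_overlap <- function(setA, setB, universe) {
  universe <- unique(universe)
  .assert(length(universe) > 0L, "empty universe")
  setA <- unique(setA); setB <- unique(setB)
  outA <- setdiff(setA, universe); outB <- setdiff(setB, universe)
  if (length(outA)) .stopf("setA element not in universe: %s", outA[1L])
  if (length(outB)) .stopf("setB element not in universe: %s", outB[1L])
  nU <- length(universe); nA <- length(setA); nB <- length(setB)
  nov <- length(intersect(setA, setB))
  expected <- nA * nB / nU
  p <- phyper(nov - 1L, nA, nU - nA, nB, lower.tail = FALSE)
  p <- min(max(p, .Machine$double.xmin), 1)
  structure(list(n_universe = nU, n_setA = nA, n_setB = nB, n_overlap = nov,
                 expected = expected,
                 fold_enrichment = if (expected > 0) nov / expected else NA_real_,
                 p_value = p),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "overlap_result: %d/%d vs %d in universe %d; overlap %d (expected %.2f, fold %.2f), p = %.3g\n",
    x$n_setA, x$n_universe, x$n_setB, x$n_universe, x$n_overlap, x$expected,
    x$fold_enrichment, x$p_value))
  invisible(x)
}

#' Gene-set enrichment over an annotation collection
#'
#' Applies [test_overlap()] between a target gene set and every term of an
#' annotation (term -> gene set), with Benjamini-Hochberg adjustment across
#' terms.  Used e.g. for functional-category enrichment of caller targets.
#'
#' @param targets Character vector of target gene ids (subset of `universe`).
#' @param annotation Named list mapping each term to its gene ids (each a
#'   subset of `universe`), e.g. from [read_annotation()].
#' @param universe Gene universe.
#' @return A `data.frame` with one row per term (`term`, `n_term`,
#'   `n_overlap`, `expected`, `fold_enrichment`, `p_value`, `q_value`),
#'   sorted by increasing `p_value`.
#' @export
enrich_annotation <- function(targets, annotation, universe) {
  .assert(length(annotation) > 0L, "empty annotation")
  res <- lapply(names(annotation), function(term) {
    r <- test_overlap(targets, annotation[[term]], universe)
    data.frame(term = term, n_term = r$n_setB, n_overlap = r$n_overlap,
               expected = r$expected,
               fold_enrichment = ifelse(is.na(r$fold_enrichment), 0,
                                        r$fold_enrichment),
               p_value = r$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
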