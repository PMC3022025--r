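---
title: "Calling bound regions on two-color promoter arrays: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling bound regions on two-color promoter arrays: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chiptriplet)
```

## The problem

Chromatin immunoprecipitation followed by two-color promoter microarray
hybridization (ChIP-chip) reads out protein-DNA association as the ratio of
an immunoprecipitated channel (IP, e.g. Cy5) to a mock/control channel (e.g.
IgG, Cy3) on each of a few hundred thousand 60-mer probes tiled around
transcription start sites.  `chiptriplet` implements the downstream analysis
for this design: per-probe enrichment statistics, a probe-triplet region
caller with an empirical permutation FDR, nearest-TSS target assignment,
gene-set overlap statistics, strand-oriented TSS-relative binding profiles,
and consensus-motif discovery with PWM-library matching.  A synthetic-data
generator emulates the array design end to end with known ground truth.

All genomic intervals are 0-based half-open (BED convention); the underlying
array format is deliberately abstracted into a simple tab-delimited probe
table because vendor feature-extraction files carry nothing the method needs
beyond coordinates and two channel intensities per replicate.

## Per-probe error model

Probe intensities are modeled multiplicatively: the enrichment signal is
`log2(ip/control)` per replicate, median-centered per array to absorb global
labeling differences.  Because the vast majority of promoter-array probes are
unbound, the bulk of each replicate's log-ratio distribution estimates the
null, which we summarize robustly as `center = median` and
`spread = 1.4826 * MAD`.  Per-replicate z-scores are averaged as
`combined_z = sum(z_k)/sqrt(R)` (unit null variance), and the probe p-value
is the one-sided upper-tail normal probability — one-sided because only
enrichment of IP over control is biologically meaningful; depletion is never
called.

This model is intentionally the simplest one consistent with the
single-array two-channel workflow.  Its key property, verified by the test
suite on pure-null simulations, is *calibration*: under the null the p-values
are uniform, so the fraction of probes below any threshold α equals α.  Dye
swaps, loess/spatial normalization, background subtraction and cross-probe
variance shrinkage are out of scope; the region caller consumes only
p-values, so a more elaborate error model can be substituted without touching
anything downstream.

## The triplet caller

The genome is scanned three consecutive probes at a time along each
chromosome.  A triplet is significant when the three probes span at most
1000 bp (end of third minus start of first) and either

* at least 2 of the 3 probe p-values are below 0.05, or
* the center probe p-value is below 0.01 and both flanking p-values are
  below 0.1.

All comparisons are strict.  Significant triplets sharing at least one probe
merge transitively into *bound regions*; a region's interval is the union of
its member probes' intervals, and its score is the best member-probe
p-value.  Merging by shared probe membership is the natural closure of the
scanning rule; an exhaustive window-enumeration oracle in the test suite
confirms the implementation on hundreds of random instances.

The FDR of a run is estimated empirically: within each chromosome the probe
log-ratios are permuted uniformly at random (the same permutation for every
replicate, preserving inter-replicate correlation), the entire caller is
re-run, and `fdr = mean null region count / observed region count`.  The
estimate is a pure function of its seed.

### What the thresholds imply, quantitatively

A point worth stating plainly: with *calibrated* per-probe p-values, the
triplet thresholds fix the null behavior of the caller.  Under the null the
2-of-3 rule fires with probability about `3 * 0.05^2 * 0.95 + 0.05^3 ≈
0.0071` per window and the center rule adds roughly `1e-4`, i.e. ~0.7% of
null triplets are significant before merging.  On an array with tens of
thousands of probes this produces hundreds of null regions — which is
exactly what `estimate_fdr()` reports on the default synthetic arrays, and
why the FDR estimate is an integral part of the output rather than an
afterthought.  Historical implementations of this rule family reported much
lower false discovery rates; that is only possible if their (unpublished)
probe-level error models were strongly conservative relative to a calibrated
one.  We deliberately keep the error model calibrated and report the FDR
honestly instead of tuning the p-values to make the rule look stricter than
it is.  In practice this means that on data where true binding is sparse,
callers built on these thresholds should be read together with their FDR
estimate, and users wanting stricter lists should lower the thresholds in
the pipeline configuration rather than trust the defaults to be stringent.

## Target assignment and summaries

Each region is assigned to the closest transcription start site on its
chromosome, measured edge-to-TSS (0 when the TSS lies inside the region),
provided the distance is strictly below 10 kb; ties break to the
lexicographically smallest gene id.  One gene per region, but a gene may
accumulate several regions — target counts are therefore reported as
*unique* genes per biotype, together with the fraction of the array's
protein-coding genes hit.  Strand is ignored for distance (a TSS is a
point); whether a region sits upstream or downstream is the profile's job.

## Overlap statistics

Whether the caller's targets overlap a reference gene set (another factor's
targets, a chromatin-mark domain, a functional category) more than chance is
tested with the exact hypergeometric upper tail `P(X >= n_overlap)` —
equivalently one-sided Fisher — against a stated universe, by default all
genes on the array.  Fold enrichment is observed over expected
(`|A||B|/|U|`).  For collections of terms, Benjamini-Hochberg q-values are
added across terms.  The choice of universe matters: using a genome-wide
gene count instead of the array's gene complement inflates enrichment, so
the universe is an explicit argument, never a constant.

## TSS-relative profile

To ask *where* binding sits relative to genes, every gene is centered and
oriented: a region's midpoint `m` maps to `r = m - tss` on `+` strand genes
and `r = tss - m` on `-` strand genes, so positive coordinates are always
downstream.  Counts are binned (default 250-bp bins over −5.5 kb to
+2.5 kb, the array's design window) and normalized to a density.  The
midpoint is used because region boundaries are only probe-resolution
accurate anyway; a per-probe profile would re-weight long regions.  Density
necessarily collapses to zero at the edge of array coverage — an artifact of
the design window, not of biology — which is why the default bins stop at
the coverage boundary.

## Motif discovery and PWM matching

Consensus discovery is an exhaustive k-mer census: every k-mer
(canonicalized over reverse complement, both strands counted, a sequence
counting at most once) is scored against an order-0 background fitted on the
input, using the per-sequence binomial hit model: with per-window match
probability `P`, a sequence of `W` windows hits with probability
`h = 1 - (1-P)^W`, and `z = (obs - sum h)/sqrt(sum h(1-h))`.  For `k <= 8`
and at most 2 mismatches this explores the same space as suffix-tree motif
discoverers at desk-scale cost, and it is deterministic and invariant to
sequence order and strand flips.  Defaults are `k = 8`, one mismatch.  Note
that with mismatches allowed the *hit fraction* of a motif includes
neighbor matches and chance hits (a 500-bp random sequence has a ~30%
chance of a 1-mismatch hit to any given 8-mer), so exact fractions should
be computed with `count_fraction(..., max_mismatches = 0)`.

The discovered consensus is turned into a position-frequency matrix from the
best occurrence per sequence (pseudocount 0.5), and matched against a PWM
library by the mean per-column Pearson correlation over all alignment
offsets with at least 4 aligned columns, in both orientations.  Significance
per library entry comes from a column-shuffling null (the entry's positions
permuted, best similarity recomputed, add-one-corrected empirical p).  A
synthetic REST-like PWM ships as a fixture
(`inst/extdata/pwm_library_synthetic.txt`); it is hand-written for testing,
not derived from any licensed motif database.

## The synthetic generator

`simulate_array()` emulates the promoter-array design: genes placed
non-overlapping on synthetic chromosomes with random strands, probes tiling
−5.5 kb to +2.5 kb around each TSS (60-mers every 200 bp, 41 probes per
gene), two replicates, log-normal intensity noise
(`baseline * 2^N(0, noise_sd)`), and a configurable fraction of genes
carrying one true bound region whose IP intensities are multiplied by
`2^effect_size`.  Default conditions: 2000 genes (82k probes — large enough
to exercise every stage, small enough that the full pipeline runs in
seconds; array scale is reachable by config), 5% bound genes, 1000-bp
regions, effect +2 log2, noise 0.5, baseline 1000.  Planted regions start
uniformly within `[1, 2500 - region_width]` downstream of the TSS so they
lie fully inside probe coverage — a region truncated by the coverage edge
is undetectable by construction and would only blur recovery scoring.

The generator makes no attempt to model dye bias, spatial artifacts,
cross-hybridization, probe-specific affinity, or correlated noise.  Passing
recovery tests on these simulations therefore demonstrates algorithmic
correctness (the caller finds what the error model can see, boundaries are
probe-resolution accurate, the FDR estimator is calibrated), not robustness
to real-array pathologies.

`simulate_sequences()` plants a consensus at a uniform position and random
strand in a chosen fraction of i.i.d. background sequences;
`simulate_reference_sets()` builds gene-set pairs with an exactly designed
overlap.  Every generator is a pure function of its configuration and seed.

## Numerical and degenerate-input choices

* p-values are clamped to `(0, 1]`; extreme z-scores never produce p = 0.
* `fit_null_model()` refuses fewer than 10 probes or zero MAD (constant
  input) rather than returning a degenerate scale.
* Region boundary claims are probe-resolution: a called boundary is
  typically within one probe spacing of the true edge, and because a
  triplet adjacent to a bound run can fire on its two significant members,
  called regions systematically extend about one probe beyond the truth.
  Recovery is therefore scored on *mean absolute* edge deviation.
* `estimate_fdr()` with zero observed regions reports 0 with a warning
  instead of dividing by zero.
* Profile bins are left-closed right-open; ties in motif ranking break on
  the canonical k-mer code; assignment ties break lexicographically — all
  deterministic.

## Known limitations

* The error model is per-probe and per-array; replicate information enters
  only through z-averaging.  No replicate-concordance filtering is applied,
  so the caller's specificity is entirely governed by the triplet
  thresholds (see the quantitative note above).
* Region calling assumes probes sorted along chromosomes and does not model
  overlapping probe layouts.
* The motif engine's background is order-0; CpG-depleted or repetitive
  promoter sequence will inflate some k-mer scores relative to a Markov
  background.
* PWM match p-values are empirical with an add-one correction; with
  `n_null = 200` their floor is 1/201.

## Problem sizes used in the shipped checks

The test-suite and acceptance runs use the default 2000-gene array (82k
probes) for end-to-end recovery, 300–800-gene arrays for calibration and
profile checks, 500 sequences of 500 bp for motif recovery, and 10–20
permutations for FDR estimates.
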