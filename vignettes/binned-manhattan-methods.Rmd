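---
title: "Methods: binning, classification and display of GWAS summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: binning, classification and display of GWAS summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwasgrid)
```

## The model of the display

`gwasgrid` turns per-variant association results into a two-dimensional
count matrix. Genomic coordinates are discretised into chunks of
`chunk_bp` base pairs per chromosome (rows), and significance into chunks
of `pbin` on the −log10(p) scale (columns), capped at `cap_nlp`. Each
variant increments exactly one cell; a cell additionally remembers whether
*any* of its variants had minor allele frequency below `maf_threshold`
("low MAF") and whether any had a high-impact predicted consequence. The
matrix, not the variants, is what gets drawn — so the display cost and
memory are bounded by the number of cells, independent of how many
millions of variants went in, and the reader can distinguish a cell
holding one extreme variant from one holding a 200-variant haplotype
block.

## Parameters and defaults

| parameter | default | units | why |
|---|---|---|---|
| `chunk_bp` | 3,000,000 | bp | ~1,000 genome rows fit a portrait page at readable resolution |
| `pbin` | 0.125 | −log10(p) | 160 columns up to the cap; fine enough that the boundary column is sharp |
| `cap_nlp` | 20 | −log10(p) | p below 1e-20 carries no extra visual information; capping keeps the count and loses only the exact exponent |
| `maf_threshold` | 0.05 | frequency | conventional boundary for "low-frequency" variants |
| `fdr_q` | 0.05 | rate | standard FDR level for the grey/colour boundary |
| `table_capacity` | 130 | loci | the most rows the tabular annotation panel renders legibly on one A4 page |
| `high_impact_terms` | VEP HIGH set | — | Ensembl VEP release 110 HIGH-impact consequence terms, shipped as a text resource and overridable |

All of these live in the configuration file (rule table + `[options]`
block) and can be overridden per call.

## Coordinate conventions

Positions are 1-based. Genome bins are half-open in 1-based coordinates:
bin *k* covers `k*chunk_bp + 1 … (k+1)*chunk_bp`, so position
3,000,000 is in row 0 and 3,000,001 in row 1. Significance bins are
half-open on the −log10 scale, `[j·pbin, (j+1)·pbin)`, with values at or
beyond the cap assigned to the last bin; p = 1 maps to column 0. Row and
column indices are 0-based throughout the API. Chromosomes order
numerically 1–22, then X, Y, MT, then any other labels lexicographically.
Chromosome lengths are inferred as the maximum observed position unless a
lengths file is supplied — inference only matters for the last bin of each
chromosome and for range-checking the loci table.

## Degenerate inputs and the row-error policy

Real summary files contain `NA` rows, allele frequencies given for the
effect allele rather than the minor allele, and underflowed p = 0. The
readers therefore: skip rows with unparsable numerics (warn + count;
`strict = TRUE` makes the first one fatal); fold frequencies above 0.5 to
`1 − f` with a warning; and keep p = 0, assigning it to the capped bin,
consistent with the deliberate capping of extreme p-values. Variants on
chromosomes missing from a supplied lengths file are skipped with a
warning rather than silently misplaced. Record conservation (accepted +
skipped = rows read) is asserted in the test suite.

## The significance boundary

The boundary uses Benjamini–Hochberg over the full multiset of accepted
p-values: p\* is the largest p(k) with p(k) ≤ kq/m. FDR is the canonical
reading of a "user-defined significance" at a stated FDR level; a fixed
−log10(p) cut (`threshold_nlp`, with a `"genomewide"` preset for 5e-8) is
available where a fixed line is preferred. A whole column is either
significant or not: a cell is significant iff its column's *lower edge*
reaches −log10 p\*. This prevents the bin that straddles the threshold
from being half grey, half coloured; the tie at the boundary bin counts as
significant. If nothing is rejected, no cell is significant and the whole
plot is grey banding.

## Classification

A cell with count *n* matches the rule with the largest `min_count ≤ n`
and flags equal to the cell's flags. This generalises the shipped
1-vs-2+ scheme to configurations with more count tiers while keeping the
validated invariant that every (tier, maf, conseq) combination is covered
exactly once — the config reader rejects tables with gaps or overlaps,
naming the offending combination. Bubbles are drawn only on cells that are
both significant and matched to a `report = TRUE` rule; the bubble glyph
is the rule index, circled at a minimum legible radius.

## Label layout

Beyond the table capacity, loci are shown as name labels. Placement is a
deterministic two-phase algorithm: a force phase (pairwise box repulsion,
mostly vertical, with a weak spring to the anchor) followed by a sweep
pass that guarantees zero pairwise overlaps by moving each label, in a
deterministic order, to the nearest free vertical slot. Tie-breaking
jitter is drawn from the supplied seed, so a layout is exactly
reproducible; the caller's RNG state is saved and restored. Leader lines
are drawn when a label's displacement exceeds its own box size. When a
packing is infeasible on the canvas the function warns and returns its
best effort — it never throws. Box extents shrink when many labels
compete, down to half size.

## The synthetic-data generator

`simulate_gwas()` emulates: a null background (p uniform on (0,1), MAF
uniform on (0.001, 0.5), ~1% high-impact consequences) over 22 synthetic
autosomes whose lengths follow the human karyotype shape (longest
≈ 249 Mbp, a fixed constant so tests need no reference genome); plus
spiked loci as clusters whose −log10(p) decays log-linearly from the
sentinel over ±1.5 Mbp. Sentinel strength cycles through −log10(p) of
30, 12, 18, 25 — values chosen so that some loci exceed the cap (p =
1e-30 exercises the capped bin) and others sit between the FDR boundary
and the cap; annotation content cycles through the four flag combinations
so all eight default rules are realisable. It does *not* emulate linkage
disequilibrium structure, allele-frequency/effect-size correlation,
genomic inflation, or chromosome-specific variant density — so passing
tests demonstrate the correctness of binning, classification, gating and
rendering, not calibration of the FDR boundary on real, correlated GWAS
data (on real data BH over correlated tests is conservative-to-anticonservative
depending on the correlation; the boundary is a display device, not an
inference).

Problem sizes used in the shipped tests were chosen to keep the suite
quick while still exercising vectorised paths against naive per-record
oracles: 10,000-record streams for the conservation/equivalence checks,
1,000 random p-sets (each up to 500 values) for the FDR oracle, and one
million variants with 20 spiked loci for the end-to-end determinism run.

## Known limitations

- Input is delimited text only (optionally gzipped); VCF/BGEN parsing and
  liftover are out of scope.
- The FDR boundary is computed from the p-values that survive row
  validation; rows skipped by the error policy do not contribute.
- The annotation table's 130-row capacity is a legibility constant, not a
  hard algorithmic limit; it is configurable.
- TIFF output is raster at `tiff_dpi` (default 300); PDF is vector and is
  byte-reproducible modulo embedded timestamps.
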