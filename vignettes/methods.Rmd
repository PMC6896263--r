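---
title: "Methods: chip cleanup, accessibility matrices, and coverage-based CNV"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chip cleanup, accessibility matrices, and coverage-based CNV}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atacwell)
library(dplyr)
```

# The problem

Microfluidic single-nucleus ATAC-seq (snATAC-seq) on C1-style
high-throughput chips produces one tiny library per well. Two artifacts
dominate quality control on this platform:

* **Cross-well leakage** — identical read sequences appearing in several
  wells of the same chip, concentrated along chip rows and, to a lesser
  degree, columns. These reads cannot be biological (transposase
  insertion is effectively never base-identical across nuclei) and
  likely reflect spill-over of amplified material, with empty chambers
  the main recipients.
* **Sparsity** — a nucleus yields so few fragments that per-cell peak
  calls are unreliable without an external anchor, typically a bulk
  reference peak set from the same tumor type.

`atacwell` implements the full analysis spine for such an experiment:
a ground-truth chip simulator, the two-stage read cleanup, a binary
cell-by-peak accessibility matrix filtered against a bulk reference,
gene-level collapsing with marker scores, GC-matched coverage
normalization for arm-level copy-number inference (the 1p/19q
co-deletion that defines the oligodendroglioma subgroup of IDH-mutant
glioma), and a promoter co-accessibility search. Every stage takes and
returns tibbles or small S3 objects with `tidy()`, `glance()` and
`autoplot()` methods.

# The chip simulator

`simulate_chip(chip_config(...))` generates a rows x columns chip with
known ground truth, which is what makes every downstream stage testable
without external data.

* **Wells.** Each well is empty with probability `empty_well_rate`
  (default 0.10), otherwise a doublet with probability `doublet_rate`
  (default 0.08). Nuclei draw a subtype from `subtype_fractions`; the
  default two-subtype mix (145:336 vs 191:336) mirrors a cohort split
  between non-codeleted and codeleted tumors.
* **Genome and peaks.** A synthetic ~400 kb five-chromosome genome
  stands in for the real one (analogs of chromosomes 1 and 19 carry p/q
  arm boundaries; three chromosomes are neutral). Reference peaks are
  non-overlapping 500 bp intervals placed on disjoint slots within
  +/-1750 bp of gene TSSs, plus ~10% intergenic peaks — reference peak
  sets from bulk ATAC are non-overlapping intervals, and overlapping
  synthetic peaks would let one cell peak light several reference
  columns.
* **Accessibility model.** Each subtype has a per-peak open probability:
  a 0.3 baseline, with 20% of peaks acting as subtype markers (0.9 in
  the owning subtype, 0.05 elsewhere). Open peaks receive
  Poisson(`reads_per_open_peak`) reads; `n_background_reads` per
  nucleus land uniformly.
* **Deletions.** A subtype can carry hemizygous arm deletions
  (default: the codeleted subtype loses 1p and 19q); reads falling on a
  deleted arm survive with probability 1/2, so coverage on those arms is
  halved in expectation.
* **Sequence-level artifacts.** Reads carry i.i.d. random fixed-length
  sequences, so two non-copied reads essentially never collide
  (probability ~4^-50). PCR duplication adds exact within-well copies at
  `pcr_dup_rate` (optionally mutated at `pcr_substitution_rate`).
  Leakage picks `leak_donor_fraction` of occupied wells as donors; each
  donor feeds `leak_targets_per_donor` recipient wells sampled with
  weights 3 (same row), 1 (same column), 0.25 (elsewhere), times 3 if
  the recipient well is empty. The row-dominant geometry reproduces the
  observed pattern of contaminated chips; the small off-grid weight
  models diffuse background contamination and keeps the
  "neither-row-nor-column" baseline of the diagnostics nonzero; the
  empty-well multiplier encodes the observation that empty chambers are
  the main recipients, and has the statistical side effect of spreading
  each empty well's contamination across several donors, which
  stabilizes the pairwise sharing statistics. Donor fraction 0.25 and
  10 targets per donor were chosen so a single 8x8 chip contains enough
  contamination events (~150) for the row/column geometry statistics to
  be stable; with an order of magnitude fewer events the class means are
  dominated by one or two empty-well recipients and the row/column
  ordering becomes a coin flip.
* **Determinism.** All randomness flows from `rng_seed` through one
  `withr::with_seed()` block; identical configurations give
  byte-identical read stores.

What the simulator does **not** emulate: Tn5 insertion sequence bias,
fragment-size periodicity, chromatin contact structure, cell-cycle
coverage waves, or realistic error profiles. Passing tests therefore
demonstrate that the algorithms implement their definitions and recover
planted structure — not that they are robust to every artifact of real
chips.

# Read cleanup

The cleanup is two ordered stages, mirroring how such data must be
processed (deduplicate first, then purge, so PCR copies do not count as
cross-well evidence):

1. `dedup_within_well()` collapses, independently per well, groups of
   equal-length reads whose sequences differ by at most
   `max_substitutions` bases (default 0, exact duplicates). The
   representative kept is the lexicographically smallest sequence, and
   among equal sequences the smallest read identifier — an arbitrary but
   deterministic rule. For radius > 0, grouping is by connected
   components of the Hamming graph (union-find over distinct sequences),
   so chains of single-substitution mutants collapse together. Mutated
   leaked copies are deliberately *not* chased across wells; the radius
   applies within wells only.
2. `purge_cross_well()` removes every read whose exact sequence occurs
   in two or more distinct wells — from **all** wells carrying it. No
   donor attribution is attempted: which well originally owned the
   molecule is unknowable from sequence identity alone, so the purge
   sacrifices the donor's genuine copy to guarantee the survivors are
   well-unique. The accompanying `leakage_report` is computed on the
   pre-purge store.

`leakage_diagnostics()` quantifies the chip geometry of contamination:
for each pair of non-empty wells the shared-sequence fraction
`|shared| / min(|a|, |b|)` (the `min` denominator was chosen so that a
small, heavily contaminated well registers strongly), and the
row/column enrichment ratios of class means. A ratio whose numerator
and denominator are both zero is reported as 1 ("no evidence of
structure"); a positive numerator over a zero denominator is `Inf`.

`tss_profile()` is the standard promoter-proximality QC: signed distance
from each read midpoint to the nearest TSS (positive downstream with
respect to gene strand) and the fraction of reads within +/-2000 bp.
Reads on chromosomes absent from the annotation stay in the denominator
at infinite distance, so the fraction is conservative.

# The accessibility matrix

`overlap_with_reference()` sets entry (cell, peak) to 1 when some called
peak of the cell overlaps the reference peak by at least
`min_overlap_bp` bases (default 50, enforced strictly at the boundary:
49 bp is negative). Coordinates are 0-based half-open throughout;
overlap length is `max(0, min(ends) - max(starts))`. The interval
machinery is GenomicRanges.

`filter_cascade()` applies one ordered pass: drop peaks positive in
fewer than 5 cells, then cells with fewer than 50 positive peaks, then
cells with more than 3000 positive peaks (defaults; the demo pipeline
scales them to its 100-peak chip as 5/15/45, chosen from the design
means: singlet cells expect ~34 positive peaks, doublets ~52, so 45
sits between the two distributions at roughly 2.5 sigma from each). The
upper cut is the doublet guard; because a fixed count corresponds to a
dataset-specific percentile, the realized percentile of the cut in the
entry distribution is reported alongside. The cascade deliberately does
**not** iterate (removing cells can push peaks back below the
cell minimum; that is accepted as the method's stated one-pass
semantics), and an `iterate = TRUE` fixpoint mode is available — it
always terminates because each pass only shrinks the matrix.

`collapse_to_genes()` assigns each peak to the gene with the nearest
TSS when the peak lies within the promoter window (TSS -2000/+2000 by
default; peak-to-point distance is 0 if the TSS falls inside the peak),
then ORs member peaks per gene. Peaks assigned to no gene form an
intergenic bucket excluded from the gene view. Nearest-TSS is a stated
substitute for external annotators, and numbers that depend on the
peak-to-gene map (e.g. a gene count) will differ from runs using a
different annotator.

# Marker scores

For a gene and a cell group, `marker_counts()` tabulates `x_pos` (group
nuclei with peaks for the gene), `y_pos` (all nuclei with peaks),
`x_neg`, `y_neg` (the complements). Two scores contrast the group's
share of peak-positive nuclei with its share of peak-negative nuclei:

* enrichment (difference form): `x_pos/y_pos - (x_neg + 1)/y_neg`
* specificity (ratio form): `(x_pos/y_pos) / ((x_neg + 1)/y_neg)`

The `+1` pseudocount keeps the negative term positive. The printed
ratio-form chain is ambiguous under left-associative division; it is
parsed here as the ratio of the two difference-form terms, which is the
only reading under which the pseudocount serves its evident purpose of
preventing division by zero. `y_neg = 0` (gene open in every nucleus)
is guarded by `max(y_neg, 1)`; the pseudocount is not applied to
`y_neg`. Genes pass the ranking gate only when `x_pos > 10`, strictly.
`rank_markers()` sorts each group descending (ties broken by gene
identifier) and keeps gated-out genes in the table unranked. Both
scores are strictly increasing in `x_pos` and strictly decreasing in
`x_neg`; no significance is attached to either score (none is defined
for them).

# Coverage-based CNV inference

Chromosomes are tiled into windows (`tile_windows()`, canonical 10 Mb
windows with 2 Mb overlap, i.e. an 8 Mb step; "overlap" is read
literally, and the step is a first-class parameter because the upstream
method family has been described both ways). A trailing partial window
is kept when at least half a window long; a chromosome shorter than one
window becomes a single window. `window_coverage()` computes mean
per-base depth per cell and window, attributing only the overlapping
bases of boundary-straddling reads.

`match_gc_background()` selects, for each window, the `n_background`
(canonical 100) unmasked windows with the closest GC content, excluding
the window itself and all windows on `excluded_arms` — the putatively
altered arms (1p/19q) must not contaminate the copy-neutral background.
Ties break by genomic order; if fewer windows are eligible, all are
used with a warning. When no GC track is supplied, `window_gc()`
assigns a smooth deterministic synthetic profile (sinusoid around 0.5)
so the matching machinery is exercised without a reference sequence.

The normalized coverage of window w0 in a cell is

    CovNorm(w0) = mean_i log( (cov(w0) + 1) / (cov(w_i) + 1) )

with natural log ("log" without a base is read as ln, which makes the
hemizygous expectation -ln 2 ≈ -0.693; the base is configurable in the
sense that the output can be rescaled). A copy-neutral window sits near
0; halved coverage drives the value toward -ln 2 — but only at adequate
depth. The +1 pseudocount dominates when mean per-window depth is far
below 1, shrinking the log-ratio toward 0: at depth c on the background,
a hemizygous window reads `log((c/2 + 1)/(c + 1))`, which is -0.65 at
c = 24 and only -0.18 at c = 0.5. The arm-deletion recovery study
(`cnv_study_config()`) is therefore dimensioned so depth is high: 100
cells on a 50 kb five-chromosome genome, 1 kb disjoint windows, ~12,000
background reads of 100 bp per cell (≈24x depth), 30 GC-matched
background windows excluding 1p/19q. These sizes were fixed from the
bias formula above, before any test was run, and are stated here as the
package's own study design. The shallow demo chip, by contrast, shows
near-zero normalized coverage everywhere — the honest behavior of the
statistic at single-cell depth over small windows.

`call_arm_loss()` averages the track over an arm's unmasked windows and
calls a loss below a threshold, default -0.3 — midway between the
copy-neutral expectation 0 and -ln 2. Cells whose arm windows are all
masked are no-calls (`NA`). Masking (telomeric/centromeric/low-mapping
windows) is supplied as indices on the window table; the default is no
mask.

# Co-accessibility

`coaccessible_regions()` Pearson-correlates the query's binary vector
(a peak, or the OR over a gene's peaks) with every other peak across
cells. On binary vectors the Pearson coefficient *is* the phi
coefficient of the 2x2 presence table, so the search operates directly
on the peak-presence data model with no smoothing; the test suite
asserts equality against a contingency-table oracle. Hits exceed the
threshold strictly (default 0.2), the query and its member peaks are
excluded from their own hit list, and peaks constant across cells are
excluded as undefined. The search is genome-wide by default; a genomic
neighborhood restriction, if wanted, is a post-filter on the hit table.

# The demo pipeline

`run_pipeline()` chains every stage on one simulated chip and writes a
deterministic JSON report: simulate, dedup, purge (with
precision/recall against the planted leakage), TSS profile, matrix,
cascade, gene collapse, marker ranking grouped by true subtype
(clustering is out of scope here, so the known subtype stands in for
cluster labels), CNV with arm calls evaluated against the planted
deletions, and a co-accessibility query (the top specificity-ranked
marker by default). Problem sizes in the default demo — an 8x8 chip,
100 peaks, 40 genes, ~50,000 reads — were chosen so a full run takes a
few seconds; the CNV recovery study runs ~1.2 million coordinate-only
reads in under half a minute.

# Numerical and degenerate-input choices

* Deterministic tie-breaks everywhere: lexicographic representative in
  dedup; gene identifier order for equal marker scores; genomic order
  for equal GC distances; lower-position TSS for equidistant midpoints.
* Enrichment ratios with empty or all-zero classes report 1; a positive
  class over a zero baseline reports `Inf`.
* `filter_cascade()` that removes every cell raises an explicit
  empty-result error rather than returning a 0-row matrix.
* Percentages are rounded to one decimal at the reporting boundary
  (`open_promoter_fraction()`); nothing else is rounded.
* Loss calls use strict `<` against the threshold, so `-Inf` calls
  nothing and `+Inf` calls everything.

# Known limitations

* The purge removes a genuine molecule along with its leaked copies;
  on real data this is the price of guaranteed well-uniqueness, and
  mutated leaked copies in *other* wells are not chased at all.
* The binary matrix ignores fragment counts; a cell with one fragment
  in a peak equals a cell with fifty.
* Arm-level CNV inference requires per-window depth well above the +1
  pseudocount scale; at true single-cell depth over 10 Mb windows the
  statistic is strongly shrunk toward 0 and the default threshold will
  under-call.
* Nearest-TSS gene assignment is a simplification; enhancer-gene
  pairing is not modeled.
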