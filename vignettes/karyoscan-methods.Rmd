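---
title: "karyoscan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{karyoscan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyoscan)
```

`karyoscan` assesses a finished (typically mammalian-scale) genome assembly
after the fact: how contiguous is it, where are the windows that short-read
alignments flag as suspect, which chromosome ends carry telomeric arrays,
where do centromeric satellites concentrate, and how well does the assembly
preserve the marker order declared by SNP-chip manifests. This vignette
explains each method, the parameters that matter, and the design decisions
taken where conventions genuinely diverge.

## Assembly model and contiguity statistics

An assembly is modelled as a set of *objects* (chromosomes and unplaced
scaffolds) tiled exactly by *components* and *gaps*, the AGP v2 picture.
Two gap classes matter:

* **spanned** gaps (AGP linkage `yes`): asserted joins *within* a scaffold;
* **unspanned** gaps (linkage `no`, usually type `U`, 100 bp by convention):
  joins *between* scaffolds that are placed on the same chromosome.

Contigs break at **every** AGP gap line regardless of the declared gap
length; scaffolds break only at unspanned gaps. These are the NCBI
assembly-report conventions, and they are what public assembly summary
tables are computed under, so `assembly_stats()` follows them exactly.
When no AGP exists, `infer_layout_from_fasta()` falls back to the
assembly-stats heuristic: a run of at least `min_gap_n = 10` consecutive
`N` breaks a contig; shorter N-runs stay inside contigs. All such inferred
gaps are classified spanned, because bare sequence carries no linkage
evidence.

For a multiset of lengths $\{\ell_i\}$ sorted in descending order, with
$T = \sum_i \ell_i$:

$$\mathrm{N}x = \ell_k,\qquad \mathrm{L}x = k,\qquad
  k = \min\Big\{ j : \sum_{i \le j} \ell_i \ge \tfrac{x}{100}\,T \Big\}.$$

`nx()` implements this directly; the test suite holds it against an
independent prefix-walk oracle on randomly generated multisets, plus the
monotonicity (Nx non-increasing, Lx non-decreasing in $x$) and refinement
(splitting an element never increases N50) properties.

Mitochondrial sequence is counted in the chromosome number but excluded
from scaffold/contig N50 by default (`include_mt = FALSE`), matching how
the public summary rows are assembled. Coordinates are 1-based inclusive
internally for FASTA/AGP (AGP-native); every exported interval file is
0-based half-open BED. Whether "unlocalized" scaffolds should count as
unplaced is a reporting ambiguity we do not resolve: placement here is
object-level (an object either has a chromosome assignment or not).

## Window quality classification

Given per-window alignment summaries (from a coordinate-sorted BAM via
`windows_from_alignments()`, or precomputed TSV), windows of width 1,000 bp
(non-overlapping; configurable) are classified by:

* **LC** — GC-normalized depth below `lc_norm_depth_max` (0.25), or fewer
  than `min_reads` (4) reads;
* **HC** — GC-normalized depth above `hc_norm_depth_min` (2.0);
* **LPP** — fraction of properly paired reads below `proper_min` (0.80);
* **LLI** / **LSI** — more than `large_insert_max` / `small_insert_max`
  (0.10) of reads with absolute template length outside the improper-insert
  bounds (by default $[0.5\times, 2\times]$ the modal template length
  estimated from the data on a 10 bp grid).

**LQ** is the union HC ∪ LPP ∪ LLI ∪ LSI and **LQLC** additionally includes
LC. GC normalization divides each window's depth by the *median* depth of
its GC bin (bins of width 0.02; bins with fewer than 50 windows fall back
to the global median). The median, not the mean, is used so that collapsed
repeats cannot drag the reference depth of their own GC bin. Windows below
`min_reads` are not evaluated for the read-composition flags, whose
fractions are meaningless at such depth.

The underlying QC workflow in the literature does not publish its exact
cut-offs, so these defaults are conventional coverage-anomaly heuristics
and every one of them is exposed in `qc_thresholds()`. Exact reproduction
of any published category table is therefore not claimed; what the tests
pin down instead is behaviour: threshold monotonicity (relaxing any cut-off
never increases flagged bases), the category union arithmetic, and planted
anomaly recovery on synthetic tracks. A window intersecting a repeat mask
by a single base counts as intersecting (`subtract_mask()`), the usual
interval-intersection semantics.

## Telomere detection

Rather than delimiting tandem repeats with an external tandem-repeat
finder and counting motifs inside those regions, `find_motif_arrays()`
scans the sequence directly for exact occurrences of the vertebrate
hexamer `TTAGGG` and its reverse complement `CCCTAA`, and chains
occurrences whose starts lie within `max_gap = 48` bp (eight units) into
maximal arrays. The retention decision depends only on exact-unit counts,
span and density, so this direct scan replaces the external
repeat-delimiting step without changing the decision; that replacement is
deliberate and documented. Since `TTAGGG` cannot overlap itself, greedy
left-to-right counting of matches is exact.

An array is *reported* only if it contains at least 5 identical,
consecutive units (the seed-run rule). A reported array is *retained* as a
telomere candidate iff

* exact unit count $\ge 200$, and
* span $> 2{,}000$ bp (strict), and
* density $= 6\,u / \mathrm{span} > 0.5$ (strict),

with the span being the chained-motif span. The density denominator is a
convention choice; the raw counts and spans are all exposed so the
alternative (repeat-region span) can be recomputed downstream.
`classify_position()` labels retained arrays `p_end` / `q_end` /
`interstitial` using a 10 kb end window, with `p_end` taking precedence on
sequences shorter than two windows.

One consequence of the strict `> 2 kb` rule is worth knowing: a 334-unit
array spans exactly 2,004 bp, so at that minimal scale the loss of a
single terminal unit (one mutation) drops the chained span to 1,998 bp and
the array is rejected by the rule, not missed by the scanner. Mutation-
robustness is therefore assessed on 500-unit (3 kb) planted arrays, a
realistic scale for assembled telomeres, while boundary-exactness checks
use the minimal 334-unit scale.

## Centromere prediction

Three evidence streams are pooled in one 0-based coordinate space:

1. centromeric records from a default-library RepeatMasker annotation;
2. centromeric records from a novel-library (RepeatModeler-derived)
   annotation — consumed as just another `.out` file;
3. direct hits of known satellite monomers from
   `search_satellite_monomers()`.

`.out` records are first filtered by `filter_repeats()`: a record is
removed iff divergence $> 40\%$ or it covers $< 70\%$ of its repeat
consensus, both boundaries kept (a record at exactly 40.0 / 70.0 stays).
Consensus length is computed strand-aware from the repeat-coordinate
columns (`end + left`), which are swapped on `C`-strand rows — the parser
handles that dialect and the fixtures pin it down. Whether the
divergence/length filter is applied before or after centromere-class
selection is not documented in the source workflow; it is applied before
merging here and can be disabled (`apply_filter = FALSE`).

Centromeric records are selected by repeat class matching
`"Satellite/centr"` (and/or a user-supplied name regex — the upstream
pattern is unpublished). The pooled intervals are merged by
`merge_and_collapse()`: intervals overlapping or separated by at most
`collapse_dist = 500` bp are unioned, so output super-regions are pairwise
separated by strictly more than 500 bp. The published phrasing ("closer
than 500 bp") and this rule differ only when a gap is exactly 500 bp; we
collapse that case so the output separation invariant is strict. Merging
is idempotent and is tested against an $O(n^2)$ transitive-closure oracle.
Super-regions strictly longer than 5 kb become centromere candidates
(`call_centromeres()`; exactly 5,000 bp is rejected).

The monomer search is seed-and-extend: every non-overlapping $k$-mer
($k = 13$) of the monomer is an exact seed; each seed hit proposes an
ungapped, full-monomer-length alignment at the implied offset, kept when
identity $\ge 0.70$; both strands are searched and overlapping hits
merged. $k$, the ungapped extension and the identity floor are this
package's decisions — the upstream method states only that known monomers
were searched. Ungapped extension is adequate for satellite arrays whose
copies diverge mainly by substitution; indel-rich families would need a
gapped aligner and are a stated limitation.

## Marker order concordance

Markers from one or more chip manifests are numbered $1..N$ by manifest
coordinates under `karyotype_order()`: numeric chromosomes ascending, then
X, Y, MT, then all remaining scaffold names in natural sort order. Mapped
markers are numbered $1..M$ by assembly coordinates the same way; every
unmapped marker receives the literal rank value $-1$. Spearman's $\rho$ is
then the Pearson correlation of the average-rank-transformed vectors; the
$-1$ block forms ties, handled by average ranks (the upstream tie policy
is unstated; shared `-1` before rank transformation is the faithful
reading of the penalty rule). `spearman_rho()` uses
`stats::cor.test(method = "spearman", exact = FALSE)`, and the test suite
holds it to $10^{-12}$ against an independently coded rank-then-Pearson
oracle, with and without `-1` blocks.

Because unplaced scaffolds sort after all chromosomes, markers mapping to
them take the highest assembly ranks — the band at the top of a rank
dotplot. The pooled multi-chip list is ranked as one ordering (not
per-chip averages); a per-chip breakdown is reported alongside.

`marker_spacing()` measures distances between consecutive mapped markers
within chromosomes only, reporting mean, sample ($n-1$) SD — population
vs sample being unstated upstream, sample is used — and the largest gap as
the marker desert. A single spacing has SD 0 by convention.

`place_probes_exact()` is a synthetic-test substitute for an external
aligner: a probe maps iff it has exactly one exact occurrence over both
strands. The reported coordinate anchor is the leftmost aligned base by
default, with a strand-aware 3′ (variant-adjacent) anchor available,
since manifest conventions differ.

## The synthetic genome generator

`simulate_genome()` and its companions generate the study conditions that
every detector is validated against, from one seed (byte-identical outputs
per seed; the window track and probe set derive their streams from
`seed + 1` and `seed + 2` so stage order never matters):

* chromosome-scale sequences with per-chromosome GC (defaults: 1 Mb /
  0.8 Mb / 0.6 Mb at GC 0.42 / 0.46 / 0.40, plus three 50 kb unplaced
  scaffolds) — a desk-scale rendition of a 2.5 Gb assembly that keeps the
  default test and acceptance runs in tens of seconds;
* telomeric arrays of 334 exact units per chromosome end (`CCCTAA` strand
  at p ends), optionally mutated per base; flanking bases are resampled
  until motif-free so planted boundaries are the unambiguous truth;
* a centromeric array of a random 340 bp monomer near the midpoint, 147
  whole copies (~50 kb) at 5% per-copy divergence — whole copies only, so
  containment of the truth interval is well-defined;
* spanned gaps (three per chromosome, 200–800 bp) and one unspanned 100 bp
  gap per chromosome, emitted both as N-runs in sequence and as AGP
  `N`/`U` lines so both gap-counting paths are exercised;
* a depth track (`simulate_window_track()`): negative binomial with mean
  65 scaled by a smooth unimodal GC-bias curve (Gaussian bump peaking at
  GC 0.45, width 0.12) and dispersion `size = 100` (CV ≈ 0.16, typical of
  a good PCR-free short-read library at this depth). Planted anomalies:
  low-coverage intervals at 0.15×, collapsed repeats at 2.5×, misassembly
  junctions with proper-pair fraction 0.5 and large-insert fraction 0.3;
* a probe set (`simulate_probe_set()`): unique, pairwise non-overlapping
  70-mers sampled outside gaps and planted repeats, with configurable
  site dropout (Bernoulli per probe) and interval inversions applied to a
  derived assembly copy via `apply_structural_edit()`.

What the generator does **not** emulate: real interspersed repeat
landscapes and segmental duplications (probes are sampled to be effectively
single-copy, so multi-mapping ambiguity is absent), read-level artefacts
(the track is sampled at window level, not from reads), indel divergence in
satellites, and haplotype structure. Passing the synthetic recovery suite
therefore demonstrates that the detectors implement their rules correctly
and recover planted truth under calibrated noise — not that the default
thresholds are optimal for any particular real genome.

## Numerical conventions and degenerate inputs

* Strict vs inclusive boundaries follow the stated rules everywhere:
  retention keeps unit count ≥ 200 but span > 2,000 and density > 0.5;
  repeat filtering keeps divergence = 40 and coverage = 0.70 exactly;
  centromere calls require length > 5,000 strictly.
* `nx()` errors on an empty multiset; `gc_normalize()` errors when every
  window depth is zero (nothing to normalize to) and falls back to the
  median of non-zero depths when the global median is zero.
* Rank ties in manifests are broken by marker id, making rank assignment
  a total order and results reproducible.
* Duplicate placements keep the first occurrence; placements for unknown
  markers warn and are dropped.
* Empty inputs (no gaps, no repeats, headers-only `.out`) yield empty,
  correctly typed results rather than errors.

## Problem sizes

The default test-and-validation scale is the generator default above
(~2.5 Mb genome, ~2,550 windows, 600 probes, 20-replicate loops on 60–200
kb single-chromosome configurations). These sizes were chosen so the whole
synthetic suite exercises every code path — chaining, binning fallbacks,
both gap dialects, both strands — at interactive runtimes; every
statistic involved is scale-free (N50, fractions, ranks), so nothing about
the method changes at genome scale beyond memory and wall time.
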