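---
title: "Methods: dnd cluster detection, prophage co-occurrence and PT fitness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dnd cluster detection, prophage co-occurrence and PT fitness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dndphage)
library(tibble)
```

This vignette documents the statistical model, the defaults and the design
decisions behind `dndphage`, in enough detail to reimplement the package.

## Coordinates and ordinals

All user-facing coordinates are **1-based inclusive** (the GFF3 and
Bioconductor convention); a feature of width `w` satisfies
`end - start + 1 == w`. All adjacency and distance rules, however, operate
on **gene ordinals**: the 0-based rank of each CDS along its replicon,
ordered by start position (ties broken by end, then by gene id). Ordinals
are reassigned whenever a `genome_record()` is constructed, so they are
always consecutive `0..N-1` per replicon and invariant to input row order.
This separates the physical coordinate system (bp) from the comparative one
(ORF counts), which is what the cluster-adjacency and R–M linkage rules are
defined in.

## Dnd gene screening

`assign_dnd_genes()` keeps hits with e-value **strictly below** `1e-10` and
query coverage **at least** `0.5`. Query coverage comes from the `qcovhsp`
column of BLAST/DIAMOND tabular output when present, otherwise from
`aln_length / qlen`. Each query is assigned the family of its best
surviving hit: highest bitscore, ties broken by lower e-value, then
lexicographically by family, making the assignment deterministic. Only the
eight Dnd families (`dnd_families()`) participate; anything else is
ignored rather than an error, since screening tables typically mix targets.

## Cluster calling

A cluster type (`dndCD`, `dndBCDE`, `dndFGH`; see `dnd_cluster_types()`)
is called when one gene per member family occupies a window of consecutive
ordinals containing at most `max_gap` (default **0**, strict adjacency)
non-member CDS. Design decisions:

* **Gene order and strand are unconstrained** inside the window. Operon
  rearrangements are common; what matters is co-localization.
* **Duplicate families block a window** — a window containing two `dndC`
  genes and one `dndD` is not a `dndCD` call, but a sub-window containing
  exactly one of each still is.
* **Windows are minimal** (they start and end on member genes) and calls
  are selected **greedily left-to-right without reusing genes**, so calls
  never overlap and the result is deterministic.
* On **circular replicons** the ordinal sequence is unrolled
  (`ordinal + N` copies appended) so windows may cross the origin; a call
  with `ordinal_first > ordinal_last` wraps.

The test suite checks this implementation against an exhaustive
enumeration of every ordinal window on 500 random toy genomes (6–16 genes,
linear and circular, `max_gap` 0–2).

`dndFGH` calls are **R–M linked** when a `dndCD`/`dndBCDE` call lies within
30 ORFs on the same replicon. The ORF distance between spans is the count
between their nearest ends (adjacent spans = 1, overlapping = 0); circular
replicons use the shorter way around. The window bound is inclusive
(`distance <= 30`).

## Prophage taxonomy and abundance

Prophage regions arrive as external prediction tables
(`read_prophage_tsv()`). `assign_family()` implements majority rule: each
protein votes for the family of its best hit with bitscore ≥ 50; proteins
without qualifying hits — or with equal-best hits to different families —
abstain. The winning family needs a vote fraction ≥ 0.5 where the
denominator is **all** proteins of the region (not just voters), and must
be a unique argmax; an exact tie yields `"unclassified"`. This makes the
assignment conservative: low-confidence regions stay unclassified rather
than inheriting the plurality family.

## Co-occurrence statistics

`occurrence_by_taxon()` aggregates per-genome profiles to taxon level:
occurrence is the fraction of genomes with ≥ 1 copy, abundance the mean
count. Taxa need ≥ 100 genomes at genus rank (≥ 30 at species rank) —
fractions from smaller panels are too noisy to compare.

*Across taxa*, `across_taxon_association()` regresses feature occurrence on
prophage occurrence (OLS) and reports Pearson's r with the exact t-based
p-value. The label `significant_negative` requires all of R² > 0.5,
p < 0.001 and r < −0.7; this triple bar avoids calling weak but
"significant" trends in large panels.

*Within taxa*, counts are low-cardinality and heavily tied, so
`within_taxon_association()` uses Kendall's tie-corrected τ-b. The
p-value is exact for n ≤ 10 — a C++ enumeration of all distinct
arrangements of `y`, equivalent to the uniform permutation distribution of
S — and otherwise uses the tie-corrected normal approximation of S with a
continuity correction (|S| shrunk by 1), which keeps the test slightly
conservative on tied data. The measured type-I error at n = 500 genomes
over 1000 null panels is ≈ 0.052.

`eligibility_filter()` encodes two separate notions: a taxon enters the
analysis only when ≥ 30 of its genomes carry ≥ 1 prophage or dnd feature;
and a (taxon, feature) pair is *statistically unachievable* when the taxon
is too small or the feature (or prophages) is absent from it entirely —
`within_taxon_scan()` keeps such cells with `NA` statistics and a flag, so
heatmaps can cross them out instead of silently dropping them.

## PT sites and expression coupling

`scan_motifs()` finds GAAC/GTTC on the reference strand
(`Biostrings::matchPattern`, `fixed = TRUE`, so `N` never matches;
overlapping matches allowed). The double-stranded consensus means a GAAC
at position *i* implies a GTTC on the complementary strand whose modified
G sits opposite *i + 3*; `ds_pairs = TRUE` emits those partners.
`evaluate_motif_conventions()` computes the "fraction of motifs modified"
under three denominator conventions — per-class reference strand, both
strands, and double-stranded loci — because published percentages do not
always state which one they use. For GAAC/GTTC, both-strand totals equal
`GAAC_ref + GTTC_ref` (each motif is the other's reverse complement).

`modification_frequency()` converts counts per sequenced nucleotide to
expected modifications per molecule, using `2 * length` nt for
double-stranded molecules — e.g. 373 modifications per 10⁶ nt on a
14,745-bp plasmid gives ≈ 11 per molecule.

`map_sites_to_features()` assigns each site to every CDS whose 1-based
inclusive interval contains its position (a site can hit overlapping
genes); uncovered sites are intergenic. `deg_pt_coupling()` flags DEGs with
`fdr < 0.05` and linear fold change > 2 (`|log2fc| > 1`, strict and
two-sided) and compares PT-site content between DEGs and non-DEGs with a
pooled two-sided Student's t test.

## Relative fitness

Each serial transfer dilutes the coculture 1:D (default **D = 100**) and
the culture regrows to the same stationary density, so the population
expands exactly D-fold per transfer. A strain moving from fraction `f0` to
`fT` over `T` transfers realizes `log2(fT * D^T / f0)` doublings, and

> W = doublings(reference) / doublings(test)

is the relative fitness of the reference (default the non-test strain
"B"). Doublings are additive over consecutive intervals, and swapping the
reference maps W to 1/W. Fractions of exactly 0 or 1 (extinction/fixation)
are rejected rather than clamped. With the 20 °C competition fractions
(0.52 → 0.48 → 0.31, D = 100) the closed forms are W(T1 vs T0) ≈ 1.0354
and W(T5 vs T0) ≈ 1.0391.

## Synthetic generators

Every generator is a pure function of (parameters, seed) via
`withr::with_seed()`, so identical calls are byte-identical — the
package's determinism contract. Defaults emulate the census conditions the
association analysis was designed for:

* `panel_spec()`: 100 genomes per genus, 100 CDS per genome; cluster
  prevalences `dndCD` 3%, `dndBCDE` 1.8%, `dndFGH` 1.1%; prophage counts
  `Poisson(1.8 * exp(beta * I[dnd]))` with `beta = -1.5` (negative
  co-occurrence). Planting uses canonical gene order, so `dndBCDE` implies
  a `dndCD` sub-cluster, which the truth tables record as `implied`.
* `simulate_hit_table()`: true hits pass both screening thresholds
  comfortably; decoys fail e-value or coverage but may carry *higher*
  bitscores than true hits, so threshold filtering — not ranking — must
  remove them.
* `simulate_sequence_with_motifs()`: background sequence scrubbed of
  accidental GAAC/GTTC by rejection resampling, exact motif counts planted
  at non-overlapping slots, junctions repaired, and the final scan verified
  to equal the planted set; planted motif counts are therefore exactly
  recoverable.
* `simulate_competition()`: the deterministic trajectory inverts the
  doubling model day by day (solving `f*g + (1-f)*g^W = D` for the test
  strain's daily growth `g` with `uniroot`, tolerance 1e-12), so the daily
  doubling ratio is exactly W and the estimator recovers `true_W` exactly
  from the noise-free trajectory; colony sampling is binomial.

Scope and limits: genomes are single linear replicons with uniform gene
spacing; prophage regions do not overlap genes; hit scores are drawn
independently rather than from alignment physics. The generators exist to
exercise the statistics and parsers, not to imitate real genome structure.

## Numerical choices

* Exact Kendall p-values enumerate distinct permutations in C++
  (`std::next_permutation`), feasible for n ≤ 10 even with ties.
* The normal-approximation variance of S uses the standard tie-corrected
  form ((v0 − vt − vu)/18 + v1 + v2).
* OLS/Pearson/t tests/BH adjustment delegate to `stats` (`lm`, `cor.test`,
  `t.test`, `p.adjust`) rather than reimplementing them.
* JSON output is written with `digits = NA` (full precision); pipeline
  outputs contain no timestamps so reruns are byte-identical.

## Problem sizes

The property suite runs in minutes on one CPU: 1000 random tied vectors
(n ≤ 200) against a brute-force τ-b oracle; 500 random toy genomes against
exhaustive window enumeration; 1000 null panels of 500 genomes for the
type-I error of the within-taxon test; 200 panels for the negative-
dependence power check; 200 competition replicates of 100-colony sampling.

## Limitations

* Real modified-site percentages depend on which genome assembly is
  scanned; the motif-percentage check needs a genome download and fails
  offline.
* The within-taxon normal approximation is slightly conservative for very
  sparse binary features (few carriers); the exact test only covers
  n ≤ 10.
* Majority-rules taxonomy ignores hit e-values beyond the bitscore floor
  and treats all proteins as equally informative.
* The fitness model assumes regrowth to a fixed stationary density every
  transfer; deviations from 100-fold daily expansion bias W toward 1.
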