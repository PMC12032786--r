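---
title: "Replicate-consensus ChIP-Seq peaks and promoter target genes: methods"
author: "chipcons authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replicate-consensus ChIP-Seq peaks and promoter target genes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipcons)
```

This vignette documents the models, conventions, and numerical choices
behind `chipcons`, in the spirit of the methods sections of the mature
Bioconductor analysis packages: what each step assumes, which knobs matter,
and what the synthetic benchmark does and does not demonstrate.

## Coordinate conventions

All intervals live in `GRanges` containers and therefore use the
Bioconductor convention: 1-based, closed on both ends. The two on-disk
dialects are converted at the I/O boundary only: GFF3 is already 1-based
closed and passes through unchanged; narrowPeak/BED is 0-based half-open and
is shifted by one on read (`start+1`) and back on write. Keeping the
container's native convention everywhere means every `GenomicRanges` /
`IRanges` operation (overlaps, `reduce`, `promoters`) can be used without a
translation layer, at the cost of a one-line conversion in the two readers.

## Gene models, TSS, and promoter windows

`read_gene_annotation()` consumes gene-level GFF3 records (by default
feature types `gene` and `tRNA`) with exon children attached by `Parent=`.
Two deliberate strictness rules:

* **Strand `.` on a gene is an error**, not a default: the TSS — the first
  transcribed base, `start` on `+` and `end` on `-` — is undefined without
  strand, and silently defaulting would corrupt every downstream promoter
  call.
* **Duplicate gene IDs are an error**, since gene IDs are the join key for
  every later table.

The promoter is "`upstream` bp before to `downstream` bp after the TSS",
measured along the direction of transcription and *including the TSS base*,
so the unclamped width is `upstream + downstream + 1` (2001 bp at the
1000/1000 defaults). Including the TSS base avoids a one-base hole at the
single most informative coordinate; with symmetric extents the genomic
window is strand-independent. Windows of genes near chromosome ends are
clamped to `[1, chrom_length]`, never dropped — a truncated promoter is
still a promoter. Transcript isoforms, UTR inference and alternative TSS
selection are out of scope: one gene, one TSS.

## The consensus rule

Two peaks are "at the same locus ± `tol_bp` on either side" when each,
expanded by `tol_bp` on both sides, meets the other — equivalently when the
gap between them is at most `2·tol_bp` (10 bp at the default `tol_bp = 5`).
Because "± N bp on either side" can also be read as expanding only one of
the two intervals, `tol_mode = "single"` bounds the bridged gap by `tol_bp`
instead; `"both"` is the default.

Consensus construction is the transitive closure of this pairwise rule:
single-linkage clustering, implemented with
`GenomicRanges::reduce(min.gapwidth = maxgap + 1, with.revmap = TRUE)`.
Single linkage can chain — three peaks A–B–C where A and C do not match
directly still form one cluster — which we accept as the natural closure of
a pairwise rule. Each cluster is emitted when its members span at least
`min_support` (default 2) *distinct replicates*; several peaks from one
replicate count once. The consensus interval is the **union span** of the
members: replicates jittered by a few bp can satisfy the rule with an empty
intersection, so any intersection-based span could be empty while the union
preserves every covered base. The test suite checks the implementation
against a brute-force all-pairs union-find oracle on a thousand random
instances.

## Annotation

Each consensus peak is reduced to one **anchor point** so that it receives
exactly one feature category and peak-category proportions are well defined.
The anchor is the floor of the median of the member summits when any member
carries one (MACS2 column 10), else the floor midpoint of the union span;
the median is robust to a single badly-jittered replicate and deterministic.
Categories are assigned with the precedence

`promoter > exon > intron/gene_body > downstream > distal_intergenic`

where `downstream` means within `downstream_bp` (default 3000, the common
annotator convention) past the gene end in the direction of transcription,
and `exon`/`intron` require the gene to carry exon records (`gene_body`
otherwise; with no transcript models ingested, UTR categories are
deliberately collapsed into these). Among genes qualifying at the winning
category, the smallest |TSS distance| wins; exact ties break
lexicographically on `gene_id` for cross-platform determinism. The signed
distance is positive downstream of the TSS in the transcription direction.
The annotation logic is mirror-symmetric: reflecting genes, exons, and
anchors through any position preserves every category and distance, which
the suite verifies on random genomes.

`target_table()` then keeps promoter rows and drops genes with excluded
biotypes (default `tRNA`): tRNA genes are short, numerous, and their dense
promoter-like hits would otherwise inflate target counts.

## Set comparisons and statistics

Cross-condition comparisons are done at the **gene level** (genes with ≥ 1
promoter consensus peak, post-exclusion), the only level at which identity
across conditions is unambiguous; `partition_gene_sets()` returns the
disjoint Venn regions for 2–3 conditions. Assembly-style concordance is
reported as intersection-over-union, with intersection-over-smaller-set
alongside, because published "concordance rates" do not always state their
denominator.

Gene-set overlap uses the hypergeometric distribution with the
q/m/n/k parameterisation (overlap, prior-study targets, universe minus
prior, our targets). Both `P(X = q)` and the enrichment-appropriate upper
tail `P(X ≥ q)` are reported, the latter as the headline p-value; a
cumulative function applied where a density is meant (or vice versa) is a
classic source of silent error, so the two are kept visibly side by side.
The universe is an explicit argument: no default (all annotated genes?
orthologs only?) is defensible across annotations. Probabilities come from
`stats::dhyper`/`phyper` (log-space internally); tests pin them to exact
draw-counting oracles. No multiple-testing correction is applied by default
— results are reported raw, and the three mapping categories below are few.

Mapping-summary comparisons use Welch two-sample t-tests (`var_equal =
FALSE` default, pooled-variance optional) on per-sample category
**fractions**, not raw counts, so library-size differences between samples
do not masquerade as mapping differences. Orientation is fixed — t carries
the sign of `mean(group_b) − mean(group_a)` (updated minus original) — and
the degenerate zero-variance/equal-means case returns t = 0, p = 1.

## The synthetic benchmark

The generator emulates the statistical structure the analysis assumes, at
desk scale. Defaults (all `sim_config()` arguments):

| parameter | default | rationale |
|---|---|---|
| chromosome | 1 × 2 Mb | smallest size where 200 genes + intergenic background are comfortably non-degenerate |
| genes | 200, lengths 1–5 kb, ≥ 500 bp apart, 10% tRNA | gene-sized features with room for distinct promoters |
| conditions | 5 × 3 replicates | the motivating study design (sex/age/behavior groups of three birds) |
| planted targets | 40 per condition | enough for stable sensitivity/precision estimates |
| detection_prob | 0.9 | a called peak per replicate is likely but not certain; gives P(≥2 of 3) ≈ 0.97 |
| jitter_sd | 2 bp | boundary disagreement at the scale the ±5 bp rule is meant to absorb |
| peak width | 150–400 bp | typical narrowPeak widths |
| background | 50 peaks/replicate | replicate-private noise |
| promoter_offset_max | 500 bp | binding site well inside the ±1000 bp window |

Design points worth noting:

* **Hierarchical seeding.** One integer seed drives derived streams per
  genome, condition, and replicate, so adding a condition perturbs nothing
  else; every output is a pure function of the config.
* **Shared binding site, per-replicate jitter.** A planted target's anchor
  offset from its TSS is drawn once per condition and shared across
  replicates (a real binding site does not move between animals); only
  boundary jitter and detection dropout are per-replicate. Peak intervals
  are clamped so they stay in-bounds and always contain their summit.
* **Background avoids promoters by rejection sampling**, so a false target
  gene can arise only when background peaks from ≥ 2 replicates collide
  within the tolerance — making precision a meaningful measure of the
  consensus rule rather than of peak placement.
* **Mapping tables** perturb per-assembly mean fractions (defaults: uniquely
  mapped 0.645 vs 0.795, a 15-point gain for the updated assembly, with the
  multi- and un-mapped fractions decreasing) with Gaussian noise of sd
  0.015, the spread that puts the unique-fraction t statistic in the low
  twenties at n = 10 per group — the regime of real assembly comparisons.

What passing the benchmark does **not** show: real peak calls have
width/signal correlations, GC and mappability structure, copy-number
artifacts, and condition-dependent peak shapes, none of which are modeled;
detection dropout is independent across replicates, while real replicate
failures correlate with signal strength. The benchmark validates the
*bookkeeping and statistics* of the pipeline, not the upstream biology of
peak calling.

## Numerical and I/O choices

* narrowPeak writing uses up to six significant digits without scientific
  notation; round-trip equality is asserted on parsed values. Readers
  preserve input order, never silently drop lines, and report the first
  offending line number on malformed input. Gzip input is accepted.
* Peak strand is retained on read but ignored by all logic — strand of a
  TF binding event is not meaningful here.
* The pipeline's run config is YAML; all stage outputs are plain
  BED6/TSV/JSON with fixed number formatting, and the manifest records the
  tolerance mode, promoter extents, support threshold, and a config hash, so
  identical inputs yield byte-identical outputs (verified in the suite).
* Problem sizes in the test suite (random-instance counts, 20-seed
  benchmark, 1000-seed calibration) were chosen as the smallest sizes at
  which the checked properties are statistically meaningful.

## Known limitations

* One TSS per gene; no isoforms, no UTR categories.
* Consensus chaining (single linkage) can merge distinct nearby loci in
  peak-dense regions; at 2·tol = 10 bp this is rare but possible.
* `distal_intergenic` peaks on a chromosome with no annotated genes get no
  gene assignment (`NA`), since a cross-chromosome "nearest gene" is
  meaningless.
* The hypergeometric test treats genes as exchangeable; promoter length or
  mappability biases are not modeled.
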