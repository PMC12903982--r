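---
title: "Methods: the SV-methylation-expression cascade"
author: "svcascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the SV-methylation-expression cascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope and model

`svcascade` implements the downstream integration layer of a comparative
multi-omics study of two accessions (here called *wild* and *cultivar*)
expressed on one shared reference coordinate frame: structural variants
(SVs) remodel 3D genome organisation (TADs, A/B compartments), the
remodelling and the variant sequence itself shift DNA and RNA
methylation, and methylation shifts propagate to gene expression. The
package does not call SVs, align reads, or process Hi-C matrices; it
consumes the tabular outputs of upstream tools (SV tables, domain calls,
PC1 tracks, Bismark-style cytosine reports, TPM tables, direct-RNA
modification site tables) and performs the statistics and interval
integration that connect them.

All internal coordinates are 0-based half-open; GFF3 and cytosine
reports are converted at the file boundary. Insertions are anchored as
1-bp reference intervals `[pos, pos + 1)` carrying their inserted length
as a payload, so a single overlap engine (GenomicRanges/IRanges) serves
every track.

# Window methylation and DMR calling

The genome is tiled into non-overlapping 1-kb windows. Per context (CG,
CHG, CHH), methylated and total read counts are pooled across strands,
sites and replicates per window; a window without coverage in either
condition is excluded from testing *and* from the multiplicity
correction. Each remaining window is tested with a two-sided exact test
on the pooled 2x2 table (`fisher_window_test`): the p-value sums all
hypergeometric point masses not exceeding the observed table's mass,
the conventional two-sided rule. The implementation is a direct
`dhyper` summation and is checked in the test suite against a full
enumeration oracle (to 1e-12) and against `stats::fisher.test`.

Pooling replicates before testing follows the common pooled-dispersion
design of window-level DMR callers; a per-replicate regression variant
is deliberately out of scope. Multiple testing uses Benjamini-Hochberg
across all tested windows of a context — a conservative,
dependency-free default; the q-value column is the only place a
different adjustment would plug in.

A window is a DMR when it passes both the context's effect-size and
q-value thresholds:

| context | |delta| | q |
|---------|--------|------|
| CG | >= 0.20 | < 0.05 |
| CHG | >= 0.15 | < 0.01 |
| CHH | >= 0.10 | < 0.01 |

with `delta = freqC(B) - freqC(A)` on the 0-1 scale. `freqC` thresholds
elsewhere ("greater than 0.2") are likewise read on the 0-1 scale with
strict inequality.

RNA differential methylation loci (DMLs) reuse the same exact test on
(modified, unmodified) read counts per transcript site, matched by
(transcript, position, modification type), BH-adjusted per modification
type, with |delta| >= 0.20 and q < 0.05.

# InDel-acquired methylation (AMRs)

An InDel-AMR is methylation carried by the variant sequence itself
rather than by an epiallele on shared sequence. Operationally: 100-bp
tiles of the carrier methylome with `freqC > 0.2` (strict) that lie at
least 90% within a single InDel; each reported window is linked to the
InDel achieving the maximal overlap. Inversions are rejected by
definition. The 90% boundary case is accepted (`>=`), and both
thresholds are arguments.

Which accession's methylome "carries" the sequence depends on the
variant: for a deletion (sequence present in the reference/wild
accession, absent from the cultivar) it is the wild methylome on the
shared frame; for an insertion it is the inserting accession's own
frame, where the anchor must be expanded to the full inserted length
(`expand_insertions = TRUE`). The synthetic generator plants AMRs
inside deletions so that the whole analysis stays on one coordinate
frame; the carrier condition is a pipeline parameter.

# TAD comparison and SV co-occurrence

Differential TADs are classified from domain calls alone: a domain is
*conserved* iff the other condition has a domain with both boundaries
within a tolerance of 20 kb (one calling bin at 20-kb resolution),
otherwise *differential*. This boundary-matching rule replaces
contact-matrix testing, which requires Hi-C matrices that are outside
this package's inputs; externally computed conserved/differential
labels can be supplied directly to the downstream statistics, bypassing
`match_tads`. The differential-region set is the merged union of
differential domains from both conditions.

Three SV statistics follow. (1) SV counts per domain with a Welch
two-tailed t-test comparing conserved vs differential domains. (2) The
fraction of SVs overlapping (>= 1 bp) the differential-region set —
insertions count through their 1-bp anchor. (3) Boundary co-occurrence:
every domain edge becomes a 20-kb interval centred on the edge, the
genome is tiled into 10-Mb windows, and each window's proportion of
boundaries overlapping at least one SV is averaged (unweighted) over
windows that contain boundaries; windows without boundaries are
excluded rather than counted as zero.

# A/B compartments

The sign of a Hi-C PC1 eigenvector is arbitrary per chromosome. Bins
are labelled after orienting each chromosome's PC1 so that its Pearson
correlation with gene density is positive (A = gene-dense, active);
when gene density is uninformative, a methylation track orients with
the opposite sign convention. Oriented PC1 > 0 is A, < 0 is B, exactly
0 (or missing) is NA. A switch segment requires at least two
consecutive bins changing state between conditions (A2B or B2A);
single-bin flips are treated as stable, and NA bins break runs.

# SV merging and gene context

Cross-callset merging is type-aware: records of the same type whose
start positions chain within 1 kb (transitive) collapse to one
representative keeping the leftmost start and longest length.
Inversions additionally require >= 50% reciprocal overlap with the
cluster seed, so megabase-scale breakpoints with coincidentally close
starts stay separate; the distance mirrors the common SV-merging
default, and the reciprocal rule is a length-scale safety the package
adds for inversions. Each SV receives a single gene-context category
with priority exon > intron > upstream > downstream > intergenic;
upstream/downstream are strand-aware 1-kb flanks, and ties across genes
within a tier go to the nearest TSS.

# Expression and the cascade

Differential expression is a Welch two-tailed t-test on log2(TPM + 1)
across replicates with BH adjustment and
`log2FC = log2((mean_B + 1) / (mean_A + 1))`; genes below 1 TPM in
every sample are `not_expressed` and excluded from testing and
multiplicity. A DEG requires |log2FC| >= 1 and q < 0.05. This is a
deliberate stand-in for count-based negative-binomial modelling, which
needs raw counts rather than TPM; the cascade logic is agnostic to the
DE engine, and an externally computed DEG table with the same columns
drops in. The pseudocount of 1 stabilises fold changes of lowly
expressed genes and shrinks |log2FC| of moderately expressed ones; all
category comparisons use the same transform, so the ordering statistics
are unaffected.

Gene-level integration uses a *footprint* = gene body plus a
strand-aware 2-kb upstream flank, harmonised with the promoter window
that defines DPGs (DMR-associated proximal genes: a DMR within 2 kb
upstream of the TSS). Flags per gene: `sv_gene` (footprint overlaps any
SV), `dmg` (overlaps a DMR), `indel_dmg` (overlaps both a DMR and an
InDel), `indel_amg` (overlaps an InDel-AMR window). The resolved
category takes the highest priority among
InDel-AMG > InDel-DMG > DMG > SV-gene > genome-wide. A body-only mode
(no flank) is available since "harbouring" a variant is not localised
by the definitions. Expression impact compares |log2FC| across
categories with all pairwise Welch tests, BH-adjusted.

DEG proportions in a region set (e.g. inversions) are reported as
percentages *truncated* to two decimals — 78 of 801 prints as 9.73 —
matching the reporting convention of the numbers this reproduces,
alongside full precision.

# The synthetic generator

`simulate_multiomics()` emits a complete two-accession bundle with
planted truth so every stage is testable without external data.
Defaults (all overridable in `synth_config()`):

* **Scale**: 2 chromosomes x 10 Mb, 1,000 genes, 500 SVs, TADs of
  ~100 kb on a 20-kb grid. The full pipeline runs in a few minutes on
  one CPU; the vignette-scale problem sizes were chosen so the complete
  test suite stays interactive.
* **Genes** are placed with gene-dense arms and a gene-poor interior,
  giving the density gradient that A/B orientation relies on; two exons
  per gene.
* **TADs**: condition A domains are drawn on the 20-kb grid (mean 5
  bins); eligible domains (>= 4 bins) become differential with
  probability 0.4, and in condition B each differential run is
  re-partitioned with interior breakpoints shifted by two bins — beyond
  the matching tolerance by construction, while conserved domains copy
  exactly.
* **SVs**: ~48% insertions, ~50.5% deletions, ~1.5% inversions, lengths
  log-normal (median ~800 bp; inversions 50-500 kb). Each SV lies in a
  differential-TAD region with probability `p_link = 0.866`, emulating
  the observed co-location fraction; DEL/INV intervals are centred on
  the drawn point so the placement is faithful to the Bernoulli draws.
* **Methylome**: window-level simulation — per-window methylation
  probabilities (bimodal: methylated blocks vs open chromatin, CG
  0.85/0.08, CHG 0.65/0.05, CHH 0.25/0.03) realised as binomial counts
  over 3 synthetic cytosines per context per 1-kb window, 3 replicates,
  site coverage Poisson(10). Pooled window coverage ~90 stands in for
  deep replicated bisulfite data (the study-scale equivalent is ~100
  reads per site across replicates); per-read simulation is
  deliberately avoided as no downstream statistic needs it. Planted
  DMRs shift condition B by ±0.4. Deleted sequence has no cultivar
  reads; AMR-carrier deletions add one highly methylated CG site per
  100-bp tile in the wild methylome.
* **Cascade effects**: 80 genes with a promoter hyper-DMR only
  (expression suppressed by 2^1.2), 80 with promoter DMR + body InDel
  (2^2.2), 60 with an AMR-carrier promoter deletion (2^2.2, sign
  reversed: the methylated copy is the suppressed one). Background
  log2FC noise is N(0, 0.35) with 5% strong DEGs (±1.8); replicates are
  log-normal (sd 0.25 in log2). The effect sizes mirror the qualitative
  finding they exist to test: SV-coupled methylation changes move
  expression more than methylation alone.
* **RNA modifications**: m6A sites Poisson(1.2) and m5C Poisson(2.8)
  per transcript with Beta(2, 2) fractions; 20% of sites shift by 0.3
  between conditions; expression is multiplied by
  `exp(0.8 x (max m6A fraction + max m5C fraction))`, giving the
  modification-expression link and a ~92-94% m6A-in-m5C co-modification
  rate. The generator does not emulate motif structure or
  signal-level error; conclusions about real direct-RNA data rest on
  the upstream caller, not on these tables.

What passing tests on this generator do **not** show: robustness to
mosaic methylation autocorrelation, replicate batch effects,
coverage-biased bisulfite conversion, contact-matrix noise in TAD
calls, or SV genotyping error — none of which the generator emulates.

# Numerical choices and degenerate inputs

* Exact-test ties use the conventional `1 + 1e-7` relative tolerance at
  the observed mass; both totals zero is an error, one empty margin
  gives p = 1.
* BH is applied per context (DNA) / per modification type (RNA).
* Welch tests fall back to p = 1 (identical constants) or p = 0
  (different constants) when both groups are degenerate; groups with
  n < 2 are excluded from testing and reported descriptively.
* `tile_windows` keeps terminal partial windows; tiling is validated as
  a disjoint partition.
* Empty interval files warn and return empty frames; empty SV sets are
  an error where a fraction would be undefined.
* All randomness in the generator flows from one seed; identical
  configuration gives byte-identical output files.

# Known limitations

* The DE stand-in ignores count overdispersion; genes with very low
  replicate variance can reach small p-values on tiny fold changes (the
  |log2FC| >= 1 gate mitigates this).
* Boundary matching cannot see intra-domain contact changes; a domain
  with identical boundaries but altered internal contacts is called
  conserved.
* The AMR definition inherits the method's coarseness: any methylated
  100-bp window >= 90% inside an InDel qualifies, including windows
  whose methylation predates the variant.
* SLIM-style adjustment is not implemented; BH is used throughout.
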