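# svcascade

Gene-level integration of structural variation, 3D genome remodelling,
DNA/RNA methylation and expression for two-accession comparative
studies (e.g. a wild progenitor vs an elite cultivar on one shared
reference genome).

Comparative crop genomics increasingly finds that structural variants
(SVs) act on phenotypes indirectly: an insertion or deletion perturbs
topologically associating domains (TADs), the perturbed regions shift
DNA methylation — sometimes because the variant sequence itself carries
methylation — and the methylation shift changes gene expression.
`svcascade` implements the statistics and interval integration for that
cascade on top of standard upstream outputs (SV tables, TAD/PC1 calls,
Bismark-style cytosine reports, TPM tables, direct-RNA m6A/m5C site
tables). It is aimed at analysts who already have those files and need
the comparison layer: DMR/DML calling, InDel-AMR detection, TAD and
compartment comparison, SV enrichment statistics, and gene cascade
categories with expression-impact tests.

## The statistics at the core

* **DMR calling.** The genome is tiled into 1-kb windows; counts are
  pooled per window across sites, strands and replicates, and each
  window is tested with the two-sided exact test on the pooled 2x2
  table: p = sum of hypergeometric masses P(X) <= P(x_obs) with margins
  fixed. BH adjustment is per context; a window is a DMR at
  |Δ| ≥ 0.20 / q < 0.05 (CG), ≥ 0.15 / q < 0.01 (CHG),
  ≥ 0.10 / q < 0.01 (CHH), Δ = freqC(B) − freqC(A).
* **InDel-AMRs.** 100-bp windows of the carrier methylome with
  freqC > 0.2 lying ≥ 90% within one InDel — methylation carried by the
  variant sequence itself.
* **TAD comparison.** A domain is conserved iff the other condition has
  a domain with both boundaries within 20 kb; SV enrichment in
  differential vs conserved domains is a Welch two-tailed t-test, and
  boundary/SV co-occurrence is averaged over 10-Mb genome windows.
* **Compartments.** Per-chromosome PC1 orientation by correlation with
  gene density; A/B switches need ≥ 2 consecutive changed bins.
* **Cascade categories.** Per gene (body + 2-kb upstream footprint):
  SV-gene, DMG, InDel-DMG (InDel + DMR), InDel-AMG (overlaps an
  InDel-AMR), with |log2FC| compared across categories by pairwise
  Welch tests.
* **DEG stand-in.** Welch t-test on log2(TPM+1) replicates, BH FDR,
  DEG at |log2FC| ≥ 1 and q < 0.05; external DEG tables drop in.

A fully synthetic two-accession multi-omics generator
(`simulate_multiomics()`) plants SVs, DMRs, AMR-carrier deletions,
differential TADs, compartment switches and expression effects with a
ground-truth JSON, so the whole pipeline is testable end to end with no
external data.

## Worked example

```r
library(svcascade)

# generate a synthetic bundle and run the full pipeline on it
bundle <- simulate_multiomics(synth_config(seed = 1), "bundle")
cfg <- run_config(inputs = bundle_inputs("bundle"))
res <- run_pipeline(cfg, "out")
#> [setup] 2 chromosomes, 1000 genes, 500 SVs
#> [dmr] 59831 windows tested, 446 DMRs
#> [amr] 518 InDel-AMR windows (carrier A)
#> [tads] conserved/differential A: 177/28; SV fraction 0.840
#> [compartments] 3 A2B, 1 B2A segments
#> [annotate] exon 87, intron 75, upstream 75, downstream 18, intergenic 245
#> [degs] 76 up, 148 down of 1000 genes
#> [cascade] DMG 260, InDel-DMG 118, InDel-AMG 91

res$impact$summary
#>      category   n mean_abs_lfc median_abs_lfc
#> 1 genome-wide 595    0.3946469      0.2763739
#> 2     SV-gene  36    0.4637916      0.2011828
#> 3         DMG 132    0.8469324      0.8096512
#> 4   InDel-DMG  67    2.0777133      2.1221463
#> 5   InDel-AMG  90    1.7853750      1.9127548
```

Reading the table: genes whose promoter/body harbour both an InDel and
a DMR (InDel-DMG), or an InDel-borne acquired methylation region
(InDel-AMG), change expression far more (mean |log2FC| ~1.8-2.1) than
genes with a DMR alone (~0.8) or the genome-wide background (~0.4) —
the generator plants exactly this structure, and
`res$impact$tests` holds the pairwise Welch p-values. The realised SV
fraction in differential-TAD regions (0.840) matches the planted
co-location probability (0.866) within binomial sampling error of 500
SVs. `out/` contains one TSV per stage plus `report.md`/`report.json`;
every summary number is recomputable from the per-stage TSVs.

Single stages work standalone, e.g.

```r
calls <- lapply(reports, read_cytosine_report, min_coverage = 5)  # ">5 reads"
win <- tile_windows(layout, 1000)
cg_A <- pool_window_methylation(calls_wild, win, "CG")
cg_B <- pool_window_methylation(calls_cultivar, win, "CG")
dmrs <- call_dmrs(cg_A, cg_B, "CG")
```

A thin shell wrapper is included:
`Rscript inst/scripts/run_pipeline.R --simulate --outdir out --seed 1`.

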