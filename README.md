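# isomod

Isoform-level analysis of m6A epitranscriptome maps and poly(A) tail lengths
derived from nanopore direct RNA sequencing (DRS) summaries.

Short-read m6A profiling reports modifications per gene; DRS resolves them per
*isoform*, with a single-nucleotide position and a stoichiometry (the fraction
of modified reads). `isomod` implements the downstream analysis layer for such
data: it consumes the summary tables that site callers (m6anet-style per-sample
site tables, xPore-style differential tables) and tail estimators
(nanopolish-style per-read poly(A) tables) produce, together with a GTF
annotation and DE/DIU result tables, and answers the questions a tissue
comparison study asks of them:

* **Consensus site catalog** — high-confidence m6A sites (DRACH motif,
  coverage > 20 reads, modification probability > 0.9 in > 1 sample), lifted
  from transcript to genomic coordinates, with per-region modification rates,
  reproducibility classes, motif composition, a spike-in (SIRV) negative
  control and a lower-bound estimate of the fraction of reads carrying a site.
* **Region specificity** — commonly versus region-specifically modified genes
  and isoforms, netting out features whose specificity is explained by
  expression up-regulation (significant in both pairwise contrasts), plus
  summary tables of DEG/DEI/DIU margins and Kolmogorov–Smirnov comparison of
  metagene position distributions.
* **Hypermodification** — per-isoform modification load (sum of site rates),
  normalised by OLS regression on isoform length and exon density; the
  residual ranks hypermodified isoforms (top-*n* per region) and a coverage
  gate defines confidently unmodified isoforms.
* **Differential modification (DM)** — between isoforms sharing a genomic
  site, with the pooled two-proportion z test
  `z = (p1 − p2) / sqrt(p(1−p)(1/n1 + 1/n2))` on read counts reconstructed as
  `k = round(mod_ratio · n_reads)`, BH FDR < 0.05 and |Δrate| > 0.15, and a
  structural regression of Δrate on changes in distance to exon boundaries;
  and between brain regions at the same transcriptomic site via xPore-style
  tables (DRACH, |Δrate| > 0.3, FDR < 0.05, probability > 0.7 in > 1 sample).
* **Poly(A) tails** — per-(isoform, sample) median/IQR summaries (> 5 PASS
  reads, mitochondrial isoforms excluded), Mann–Whitney U comparisons of
  regions on those medians, differential poly(A) length within genes and
  between regions (> 50 reads, |Δmedian| > 20 nt, FDR < 0.05), and an
  IQR-based ranking of dynamic tails.
* **Statistical kernel** — two-proportion z, BH FDR, Mann–Whitney U (exact
  enumeration at small n), Spearman, hypergeometric overlap, and windowed
  genomic overlap (±5 nt) for RBP binding-site enrichment.
* **Synthetic data** — a deterministic generator that emits every input
  dialect above with planted, recorded truth (exclusion-zone rate suppression
  of ~100 nt around splice junctions and transcript ends, region rate shifts,
  DM sites, hypermodified / region-specific / unmodified isoforms, poly(A)
  medians coupled to isoform length), so every stage of the pipeline is
  verifiable without raw sequencing data.

## Worked example

```r
library(isomod)

cfg <- sim_config(seed = 42)          # 3 regions x 3 samples, ~100 genes
sim <- run_simulation(cfg)            # annotation, site/poly(A)/DE/xPore tables

calls   <- load_site_tables(sim$sites$meta, sim$sites$tables)
catalog <- build_consensus(calls, sim$models)
catalog
#> <m6a_catalog> 2382 consensus site(s) on 293 isoform(s); regions: CB, CN, PFC
#>   (prob > 0.9 in >= 2 samples)

region_detection_summary(catalog)$pct_high   # reproducible in >= 3 samples
#> [1] 95

dm <- within_gene_dm(catalog, sim$models)
fit <- dm_structure_model(dm$results)
round(fit$r_squared, 3)
#> [1] 0.092    # boundary-distance changes explain part of the rate differences

g <- global_region_test(summarize_polya(
  load_polya_tables(sim$polya$meta, sim$polya$tables, models = sim$models)))
g[, c("region_a", "region_b", "median_diff", "p_value")]
#>  region_a region_b median_diff      p_value
#>        CB       CN     14.8925 4.561508e-22
#>        CB      PFC      1.0100 8.247824e-02
#>        CN      PFC    -13.8825 9.023622e-16
```

The poly(A) comparison recovers the planted −16/−13 nt shifts of CN relative
to CB and PFC; the DM structure model recovers the planted exclusion-zone
effect (modification rates rise with distance to the downstream exon boundary
or transcript end).

The numbered scripts under `analysis/` run the same stages as a narrative
workflow (simulate → consensus catalog → specificity → hypermodification →
differential modification → poly(A)), printing what each stage found and
writing compact summary tables under `results/`.

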