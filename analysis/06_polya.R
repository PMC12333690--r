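#!/usr/bin/env Rscript
# Step 6: poly(A) tail analyses. Per-isoform medians, global between-region
# comparisons, differential poly(A) length within genes and between regions,
# and the dynamic (high-IQR) tail ranking.

suppressPackageStartupMessages(library(isomod))
dir.create("results", showWarnings = FALSE)

models <- parse_annotation("scratch/simdata/annotation.gtf")
meta <- read.delim("scratch/simdata/polya_meta.tsv")
records <- load_polya_tables(meta, models = models)
summaries <- summarize_polya(records)
cat(sprintf("%d per-(isoform, sample) summaries from %d PASS reads\n",
            nrow(summaries), nrow(records)))

g <- global_region_test(summaries)
cat("\nglobal median poly(A) comparisons:\n")
print(g, row.names = FALSE)
write.table(g, "results/polya_global_tests.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

info <- models_summary(models)
per_iso <- aggregate(median_length ~ isoform_id, summaries, median)
rho <- spearman_test(per_iso$median_length,
                     info$length[match(per_iso$isoform_id, info$transcript_id)])
cat(sprintf("\nmedian tail vs isoform length: rho = %.4f, p = %.3g\n",
            rho$statistic, rho$p_value))

map <- info[, c("transcript_id", "gene_id")]
wg <- within_gene_dpl(records, map)
cat(sprintf("within-gene DPL: %d isoform pairs tested, %d significant\n",
            if (is.null(wg)) 0 else nrow(wg),
            if (is.null(wg)) 0 else sum(wg$significant)))
br <- between_region_dpl(records)
cat(sprintf("between-region DPL: %d (isoform, region pair) tests, %d significant\n",
            if (is.null(br)) 0 else nrow(br),
            if (is.null(br)) 0 else sum(br$significant)))
if (!is.null(wg))
  write.table(wg[wg$significant, ], "scratch/dpl_within_gene_significant.tsv",
              sep = "\t", quote = FALSE, row.names = FALSE)
if (!is.null(br))
  write.table(br[br$significant, ], "scratch/dpl_between_region_significant.tsv",
              sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(
  n_dpl_within_gene = if (is.null(wg)) 0 else sum(wg$significant),
  n_dpl_between_region = if (is.null(br)) 0 else sum(br$significant)),
  "results/dpl_summary.tsv", sep = "\t", quote = FALSE, row.names = FALSE)

for (r in c("PFC", "CN", "CB")) {
  dyn <- dynamic_polya(records, r, top_n = 10)
  cat(sprintf("%s: most dynamic tail %s (IQR %.1f nt over %d reads)\n",
              r, dyn$isoform_id[1], dyn$iqr[1], dyn$n_reads[1]))
}
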