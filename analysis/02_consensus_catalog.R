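#!/usr/bin/env Rscript
# Step 2: read the per-sample site tables back from disk, apply the
# high-confidence consensus rules (probability > 0.9 in more than one
# sample, > 20 reads, DRACH motif), lift sites to genomic coordinates and
# summarise reproducibility, motif composition and the spike-in control.

suppressPackageStartupMessages(library(isomod))
dir.create("results", showWarnings = FALSE)

models <- parse_annotation("scratch/simdata/annotation.gtf")
meta <- read.delim("scratch/simdata/site_meta.tsv")
calls <- load_site_tables(meta)
catalog <- build_consensus(calls, models)
print(catalog)

rep_sum <- region_detection_summary(catalog)
cat(sprintf("%d of %d consensus sites (%d%%) detected in >= 3 samples of a region\n",
            rep_sum$n_high, rep_sum$n_sites, rep_sum$pct_high))

qc <- sirv_negative_control(calls)
cat(sprintf("spike-in control: %d of %d tested SIRV sites called modified (QC %s)\n",
            qc$n_modified, qc$n_sites_tested, if (qc$qc_pass) "pass" else "FAIL"))

frac <- estimate_modified_read_fraction(catalog)
cat(sprintf("lower-bound estimate: %.1f%% of tested reads carry >= 1 m6A site\n",
            100 * frac$fraction))

motifs <- motif_summary(catalog)
cat("top motifs among m6A sites:\n")
print(head(motifs[, c("kmer", "prop_modified", "prop_tested", "statistic", "fdr")], 5))

# full catalog to scratch (bulky); compact summaries to results
export_bed6(data.frame(chrom = catalog$sites$chrom, pos = catalog$sites$gpos,
                       strand = catalog$sites$strand,
                       name = paste0(catalog$sites$transcript_id, ":",
                                     catalog$sites$tx_pos)),
            "scratch/consensus_sites.bed")
write.table(as.data.frame(catalog$sites), "scratch/consensus_sites.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(motifs, "results/motif_summary.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(n_sites = rep_sum$n_sites, n_3plus = rep_sum$n_high,
                       pct_3plus = rep_sum$pct_high,
                       sirv_modified = qc$n_modified,
                       modified_read_fraction = round(frac$fraction, 4)),
            "results/catalog_summary.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("catalog in scratch/consensus_sites.{tsv,bed}; summaries in results/\n")
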