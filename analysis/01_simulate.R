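#!/usr/bin/env Rscript
# Step 1: generate the synthetic experiment all later steps analyse.
#
# Produces, under scratch/simdata/: a GTF annotation, per-sample m6anet-style
# site tables, nanopolish-style poly(A) tables, DE/DIU tables and an
# xPore-style differential table, all with recorded planted truth. The default
# study conditions are three regions (PFC, CN, CB) x three samples, ~100 genes
# with 2-4 isoforms, and ~5,000 tested site-isoform observations.

suppressPackageStartupMessages(library(isomod))

out_dir <- "scratch/simdata"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = 101L)
sim <- run_simulation(cfg)

models <- generate_annotation(cfg, gtf_path = file.path(out_dir, "annotation.gtf"))
site_meta <- write_sample_tables(sim$sites, out_dir, "sites")
polya_meta <- write_sample_tables(sim$polya, out_dir, "polya")
write.table(sim$xpore, file.path(out_dir, "xpore_diff.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
for (nm in names(sim$de))
  write.table(sim$de[[nm]], file.path(out_dir, paste0("de_", nm, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
write.table(site_meta, file.path(out_dir, "site_meta.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(polya_meta, file.path(out_dir, "polya_meta.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

iso <- sim$truth$isoforms
cat(sprintf("simulated %d isoforms in %d genes; %d tested site-isoform entries (%d modified)\n",
            sum(iso$human), cfg$n_genes, nrow(sim$truth$entries),
            sum(sim$truth$entries$modified)))
cat(sprintf("planted: %d region-specific, %d hypermodified, %d unmodified isoforms; %d within-gene DM sites; %d region-DM sites\n",
            sum(!is.na(iso$specific_region)), sum(iso$hypermod),
            sum(iso$unmodified), nrow(sim$truth$dm), nrow(sim$truth$region_dm)))
cat("tables written to", out_dir, "\n")
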