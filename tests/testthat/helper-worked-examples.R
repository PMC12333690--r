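# Fixtures encoding the published marginal counts of the study's summary
# tables, built programmatically so the summarisers can be run on them.
# Each builder returns exactly the inputs the corresponding summariser needs.

# reproducibility margin: 25,887 of 57,144 sites reach the >= 3-samples class
detection_margin_fixture <- function(n_sites = 57144, n_high = 25887) {
  data.frame(max_k = c(rep(3L, n_high), rep(2L, n_sites - n_high)))
}

# region-specific modification versus DE up-regulation margins (per region):
# n_specific features of which n_up are up-regulated in that region
specificity_margin_fixture <- function(region, n_specific, n_up,
                                       regions = c("PFC", "CN", "CB"),
                                       level = "isoform") {
  ids <- sprintf("%s_%s_%06d", level, region, seq_len(n_specific))
  calls <- data.frame(feature_id = ids, level = level,
                      regions_modified = region, n_regions = 1,
                      label = "specific", union_common = FALSE)
  others <- setdiff(regions, region)
  de <- do.call(rbind, lapply(others, function(o) {
    a <- min(region, o); b <- max(region, o)
    data.frame(feature_id = ids[seq_len(n_up)],
               comparison = paste0(a, "_vs_", b),
               logFC = if (a == region) 2 else -2, adj_p = 0.001)
  }))
  list(calls = calls, de = de)
}

# expression/usage margins of one region of the DE summary table
de_margin_fixture <- function(region = "PFC", n_deg = 4550, n_dei = 6779,
                              dei_no_deg = 1328, n_diu_gene = 199,
                              n_diu_iso = 251, diu_gene_no_deg = 121,
                              diu_iso_no_dei = 71,
                              regions = c("PFC", "CN", "CB")) {
  others <- setdiff(regions, region)
  up_rows <- function(ids, level) {
    do.call(rbind, lapply(others, function(o) {
      a <- min(region, o); b <- max(region, o)
      data.frame(feature_id = ids, level = level,
                 comparison = paste0(a, "_vs_", b),
                 logFC = if (a == region) 2 else -2, adj_p = 0.001)
    }))
  }
  deg_ids <- sprintf("DEG%05d", seq_len(n_deg))
  nodeg_ids <- sprintf("NDG%05d", seq_len(max(dei_no_deg, diu_gene_no_deg)))
  dei_ids <- sprintf("DEI%05d", seq_len(n_dei))
  # map DEIs onto genes: the first dei_no_deg isoforms sit on non-DEG genes
  map <- data.frame(
    transcript_id = dei_ids,
    gene_id = c(nodeg_ids[seq_len(dei_no_deg)],
                deg_ids[rep_len(seq_len(n_deg), n_dei - dei_no_deg)]))
  # DIU: n_diu_iso isoforms on n_diu_gene genes; diu_gene_no_deg genes lack a
  # DEG; diu_iso_no_dei isoforms are not DEIs
  diu_genes <- c(nodeg_ids[seq_len(diu_gene_no_deg)],
                 deg_ids[seq_len(n_diu_gene - diu_gene_no_deg)])
  diu_iso <- c(sprintf("DIU%05d", seq_len(diu_iso_no_dei)),
               dei_ids[seq_len(n_diu_iso - diu_iso_no_dei)])
  diu <- data.frame(isoform_id = diu_iso,
                    gene_id = diu_genes[rep_len(seq_len(n_diu_gene), n_diu_iso)],
                    region = region, dIF = 0.3, adj_p = 0.001)
  extra_map <- data.frame(transcript_id = setdiff(diu_iso, map$transcript_id),
                          gene_id = "NDGX")
  list(de_gene = up_rows(deg_ids, "gene"),
       de_isoform = up_rows(dei_ids, "isoform"),
       diu = diu, map = rbind(map, extra_map), regions = regions)
}

# hypermodified selections: union of 911 isoforms, 413 in > 1 region
hypermod_margin_fixture <- function(n_union = 911, n_multi = 413) {
  multi <- sprintf("HM%04d", seq_len(n_multi))
  single <- sprintf("HS%04d", seq_len(n_union - n_multi))
  third <- ceiling(length(single) / 3)
  list(PFC = c(multi, single[seq_len(third)]),
       CN = c(multi, single[(third + 1):(2 * third)]),
       CB = single[(2 * third + 1):length(single)])
}

# between-region DM direction margin: 1,666 of 2,218 sites up in CB
dm_direction_margin_fixture <- function(n_sites = 2218, n_cb_up = 1666) {
  data.frame(
    transcript_id = sprintf("tx%05d", seq_len(n_sites)),
    transcript_position = seq_len(n_sites),
    region_a = "CB", region_b = "CN",
    diff_mod_rate = c(rep(-0.4, n_cb_up), rep(0.4, n_sites - n_cb_up)),
    up_region = c(rep("CB", n_cb_up), rep("CN", n_sites - n_cb_up)))
}

# database-annotation margin: 21,119 of 29,596 genomic sites annotated
annotation_margin_fixture <- function(n_sites = 29596, n_annotated = 21119) {
  sites <- data.frame(chrom = "chr1", pos = seq_len(n_sites), strand = "+")
  list(sites = sites, external = sites[seq_len(n_annotated), ])
}
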