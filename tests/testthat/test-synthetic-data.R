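# The generator: determinism, structural validity, emission models, and
# consistency between truth and emitted tables.

test_that("generation is byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 9, n_genes = 8)
  p1 <- withr::local_tempfile(fileext = ".gtf")
  p2 <- withr::local_tempfile(fileext = ".gtf")
  generate_annotation(cfg, gtf_path = p1)
  generate_annotation(cfg, gtf_path = p2)
  expect_identical(readLines(p1), readLines(p2))

  s1 <- run_simulation(cfg)
  s2 <- run_simulation(cfg)
  expect_identical(s1$sites$tables, s2$sites$tables)
  expect_identical(s1$polya$tables, s2$polya$tables)
  expect_identical(s1$truth$entries, s2$truth$entries)
  expect_identical(s1$xpore, s2$xpore)

  # different seeds diverge
  s3 <- run_simulation(sim_config(seed = 10, n_genes = 8))
  expect_false(identical(s1$sites$tables, s3$sites$tables))
})

test_that("generated annotation is structurally valid with shared exons", {
  cfg <- sim_config(seed = 15, n_genes = 40)
  m <- generate_annotation(cfg)
  info <- models_summary(m)
  human <- info[grepl("^T\\d", info$transcript_id), ]
  # isoform count within the configured range
  expect_gte(nrow(human), cfg$n_genes * cfg$isoforms_per_gene[1] * 0.5)
  expect_lte(nrow(human), cfg$n_genes * cfg$isoforms_per_gene[2])
  expect_true(all(info$n_exons >= 1))
  expect_true(all(info$length > 0))
  for (tid in sample(info$transcript_id, 30)) {
    mod <- m[[tid]]
    if (!is.null(mod$cds_span)) {
      expect_gte(mod$cds_span[1], 0)
      expect_lte(mod$cds_span[2], spliced_length(mod))
    }
  }
  # sibling isoforms overlap in genomic exon space (shared sites exist)
  truth <- simulate_m6a_truth(m, cfg)
  shared <- truth$entries[, list(n_iso = data.table::uniqueN(transcript_id)),
                          by = "site_id"]
  expect_gt(mean(shared$n_iso >= 2), 0.2)
})

test_that("isoform count matches the recorded truth table", {
  cfg <- sim_config(seed = 21, n_genes = 25)
  sim <- run_simulation(cfg)
  info <- models_summary(sim$models)
  expect_setequal(sim$truth$isoforms$transcript_id, info$transcript_id)
})

test_that("exclusion zone suppresses rates near boundaries and only there", {
  cfg <- sim_config(seed = 33, n_genes = 40)
  truth <- simulate_m6a_truth(generate_annotation(cfg), cfg)
  ent <- truth$entries
  # unplanted modified entries: in-zone rate is the penalty multiple of the
  # shared base rate; compare siblings of the same genomic site
  planted_iso <- truth$isoforms$transcript_id[
    !is.na(truth$isoforms$specific_region) | truth$isoforms$hypermod |
      truth$isoforms$unmodified]
  clean <- ent[ent$modified & !ent$transcript_id %in% planted_iso &
                 !ent$site_id %in% truth$dm$site_id &
                 !paste(ent$transcript_id, ent$tx_pos) %in%
                 paste(truth$region_dm$transcript_id, truth$region_dm$tx_pos), ]
  in_zone <- clean$dist_up < cfg$exclusion_zone_width |
    clean$dist_down <= cfg$exclusion_zone_width
  by_site <- split(seq_len(nrow(clean)), clean$site_id)
  checked <- 0
  for (idx in by_site) {
    if (length(idx) < 2) next
    zi <- in_zone[idx]
    if (any(zi) && any(!zi)) {
      expect_lt(max(clean$rate_PFC[idx][zi]), min(clean$rate_PFC[idx][!zi]))
      checked <- checked + 1
    }
  }
  expect_gt(checked, 5)
})

test_that("planted differential sites carry the configured rate difference", {
  cfg <- sim_config(seed = 27, n_genes = 40)
  truth <- simulate_m6a_truth(generate_annotation(cfg), cfg)
  ent <- truth$entries
  # PFC carries no region shift, so the raised isoform sits exactly dm_delta
  # above the recorded base rate of its group
  for (i in seq_len(nrow(truth$dm))) {
    sid <- truth$dm$site_id[i]
    up <- truth$dm$transcript_id[i]
    up_rate <- ent$rate_PFC[ent$site_id == sid & ent$transcript_id == up]
    expect_equal(up_rate - truth$dm$base_rate[i], cfg$dm_delta, tolerance = 1e-9)
  }
  for (i in seq_len(nrow(truth$region_dm))) {
    row <- ent[ent$transcript_id == truth$region_dm$transcript_id[i] &
                 ent$tx_pos == truth$region_dm$tx_pos[i], ]
    up_r <- truth$region_dm$up_region[i]
    others <- setdiff(cfg$regions, up_r)
    expect_equal(row[[paste0("rate_", up_r)]] -
                   max(sapply(others, function(r) row[[paste0("rate_", r)]])),
                 cfg$region_dm_delta, tolerance = 1e-9)
  }
})

test_that("emitted site tables respect coverage, motif and sampling models", {
  cfg <- sim_config(seed = 12, n_genes = 30)
  sim <- run_simulation(cfg)
  for (tab in sim$sites$tables) {
    expect_true(all(tab$n_reads >= 21))
    expect_true(all(grepl("^[AGT][AG]AC[ACT]$", tab$kmer)))
    expect_true(all(tab$mod_ratio >= 0 & tab$mod_ratio <= 1))
  }
  # unmodified sites exceed the 0.9 probability threshold at (at most) the
  # configured Beta(1,20) tail, which is astronomically small
  ent <- sim$truth$entries
  t1 <- sim$sites$tables[[1]]
  r1 <- sim$sites$meta$region[1]
  unmod <- ent[[paste0("rate_", r1)]][match(paste(t1$transcript_id,
                                                  t1$transcript_position),
                                            paste(ent$transcript_id,
                                                  ent$tx_pos))] == 0
  expect_lte(mean(t1$probability_modified[unmod] > 0.9), 0.001)
  expect_gte(mean(t1$probability_modified[!unmod] > 0.9), 0.8)
})

test_that("emitted poly(A) tables match their truth and QC model", {
  cfg <- sim_config(seed = 18, n_genes = 30)
  sim <- run_simulation(cfg)
  tab <- do.call(rbind, sim$polya$tables)
  # non-PASS fraction within 2 points of the configured rate at this scale
  expect_lt(abs(mean(tab$qc_tag != "PASS") - cfg$polya_fail_rate), 0.02)
  # per-isoform sample medians sit near the regional truth at >= 100 reads
  rec <- load_polya_tables(sim$polya$meta, sim$polya$tables, models = sim$models)
  dt <- data.table::as.data.table(rec)
  pooled <- dt[, list(med = stats::median(polya_length), n = .N),
               by = c("isoform_id", "region")]
  pooled <- pooled[pooled$n >= 100, ]
  tru <- sim$truth$polya$true_median[match(paste(pooled$isoform_id, pooled$region),
                                           paste(sim$truth$polya$transcript_id,
                                                 sim$truth$polya$region))]
  expect_gte(mean(abs(pooled$med - tru) / tru <= 0.1), 0.95)
})

test_that("DE emission plants detectable up-regulation over uniform nulls", {
  cfg <- sim_config(seed = 24, n_genes = 60)
  sim <- run_simulation(cfg)
  iso <- sim$truth$isoforms
  de <- sim$de$isoform
  regions <- cfg$regions
  # planted expression-driven specific isoforms are flagged by the netting op
  pipe <- suppressMessages(run_pipeline(sim))
  res <- suppressMessages(expression_adjusted_specificity(
    pipe$specificity$isoform, de, regions))
  planted <- iso[!is.na(iso$specific_region) & !is.na(iso$up_region) &
                   iso$specific_region == iso$up_region, ]
  flagged <- res$calls$expression_driven[match(planted$transcript_id,
                                               res$calls$feature_id)]
  expect_true(all(flagged[!is.na(flagged)]))
  expect_gte(mean(!is.na(flagged)), 0.9)  # planted isoforms reach the catalog

  # null rows keep uniform-ish adjusted p (KS not rejected at alpha = 0.01)
  null_p <- de$adj_p[!de$feature_id %in%
                       iso$transcript_id[!is.na(iso$up_region)]]
  ks <- suppressWarnings(stats::ks.test(null_p, "punif"))
  expect_gt(ks$p.value, 0.01)

  # the Table-style summariser recovers the planted margins (all planted
  # features are counted; chance double-significance of nulls may add a few)
  map <- models_summary(sim$models)[, c("transcript_id", "gene_id")]
  s <- summarize_de_tables(sim$de$gene, de, sim$de$diu, map, regions)
  for (r in regions) {
    n_planted <- sum(iso$up_region == r, na.rm = TRUE)
    expect_gte(s$n_dei[s$region == r], n_planted)
    expect_lte(s$n_dei[s$region == r], n_planted + 3)
  }
  expect_gte(sum(s$n_diu_iso), sum(iso$diu))
})
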