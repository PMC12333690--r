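# Site ingestion, consensus rules and catalog summaries.

test_that("site-table loading enforces the motif, coverage and value rules", {
  tab <- data.frame(
    transcript_id = c("tx1", "tx1", "tx1", "tx1"),
    transcript_position = c(500, 510, 520, 530),
    n_reads = c(30, 25, 20, 40),
    probability_modified = c(0.95, 0.5, 0.9, 1.2),
    kmer = c("GGACT", "GGGGG", "AGACA", "TAACT"),
    mod_ratio = c(0.7, 0.2, 0.5, 0.4))
  expect_message(out <- load_site_table(tab, "s1", "PFC"), "rejected 3/4")
  expect_equal(nrow(out), 1)            # GGGGG motif, 20 reads, prob 1.2 all rejected
  expect_equal(out$tx_pos, 500)
  expect_equal(out$region, "PFC")

  # the 21-read boundary: exactly 21 reads is accepted ("more than 20")
  tab21 <- tab[1, ]; tab21$n_reads <- 21
  expect_silent(out <- load_site_table(tab21, "s1", "PFC"))
  expect_equal(nrow(out), 1)

  expect_error(load_site_table(tab[, -3], "s1", "PFC"), "missing column")

  # comma-separated dialect is autodetected from a file
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  expect_message(out <- load_site_table(path, "s2", "CB"))
  expect_equal(nrow(out), 1)
})

test_that("consensus requires probability > 0.9 in more than one sample", {
  m <- list(tx1 = two_exon_model())
  class(m) <- "transcript_models"
  calls <- rbind(
    call_row("s1", "PFC", "tx1", 10, 0.95, 0.6),
    call_row("s2", "PFC", "tx1", 10, 0.95, 0.8),
    call_row("s3", "CB",  "tx1", 10, 0.50, 0.1),
    call_row("s1", "PFC", "tx1", 50, 0.95, 0.5),  # detected once only
    call_row("s2", "PFC", "tx1", 50, 0.89, 0.5),
    call_row("s1", "PFC", "tx1", 90, 0.90, 0.5),  # 0.90 is not > 0.9
    call_row("s2", "PFC", "tx1", 90, 0.90, 0.5))
  cat <- build_consensus(calls, m)
  expect_equal(cat$sites$tx_pos, 10)
  expect_equal(cat$sites$gpos, 110)     # lifted through the annotation
  rs <- cat$region_stats
  expect_equal(rs$rate[rs$region == "PFC"], 0.7)     # mean over tested samples
  expect_equal(rs$n_detected[rs$region == "CB"], 0)

  # transcripts missing from the annotation are excluded with a message
  calls2 <- rbind(calls,
                  call_row("s1", "PFC", "ghost", 5, 0.99, 0.5),
                  call_row("s2", "PFC", "ghost", 5, 0.99, 0.5))
  expect_message(cat2 <- build_consensus(calls2, m), "absent from the annotation")
  expect_equal(nrow(cat2$sites), 1)
})

test_that("consensus size never grows when thresholds tighten", {
  sim <- small_sim()
  calls <- load_site_tables(sim$sites$meta, sim$sites$tables)
  base <- build_consensus(calls, sim$models)
  stricter_p <- build_consensus(calls, sim$models, prob_thr = 0.95)
  stricter_k <- build_consensus(calls, sim$models, min_detect_samples = 4)
  expect_lte(nrow(stricter_p$sites), nrow(base$sites))
  expect_lte(nrow(stricter_k$sites), nrow(base$sites))
  # and the stricter catalogs are subsets
  key <- function(x) paste(x$sites$transcript_id, x$sites$tx_pos)
  expect_true(all(key(stricter_p) %in% key(base)))
  expect_true(all(key(stricter_k) %in% key(base)))
  # per-region rate is invariant to sample order
  perm <- sample(nrow(calls))
  base_perm <- build_consensus(calls[perm, ], sim$models)
  rs_a <- base$region_stats[order(base$region_stats$transcript_id,
                                  base$region_stats$tx_pos,
                                  base$region_stats$region), ]
  rs_b <- base_perm$region_stats[order(base_perm$region_stats$transcript_id,
                                       base_perm$region_stats$tx_pos,
                                       base_perm$region_stats$region), ]
  expect_equal(rs_a$rate, rs_b$rate)
})

test_that("every consensus site lifts to a genomic position that round-trips", {
  sim <- small_sim()
  calls <- load_site_tables(sim$sites$meta, sim$sites$tables)
  cat <- build_consensus(calls, sim$models)
  for (i in sample(nrow(cat$sites), min(200, nrow(cat$sites)))) {
    m <- sim$models[[cat$sites$transcript_id[i]]]
    expect_equal(genome_to_tx(m, cat$sites$gpos[i]), cat$sites$tx_pos[i])
  }
})

test_that("reproducibility summary classes sites by maximum per-region support", {
  m <- list(tx1 = two_exon_model())
  class(m) <- "transcript_models"
  calls <- rbind(
    call_row(paste0("cb", 1:3), "CB", "tx1", 10, 0.95, 0.5),
    call_row(paste0("pfc", 1:3), "PFC", "tx1", 10, c(0.95, 0.95, 0.2), 0.5),
    call_row(paste0("cb", 1:3), "CB", "tx1", 50, c(0.95, 0.95, 0.3), 0.5))
  cat <- build_consensus(calls, m)
  s <- region_detection_summary(cat)
  expect_equal(s$n_sites, 2)
  expect_equal(s$n_high, 1)               # only tx1:10 reaches 3 samples in CB
  expect_equal(s$pct_high, 50)

  # empty catalog: no division error
  empty <- build_consensus(call_row("s1", "PFC", "tx1", 10, 0.2, 0.1), m)
  se <- region_detection_summary(empty)
  expect_equal(se$n_sites, 0)
  expect_true(is.na(se$pct_high))
})

test_that("per-region site rate averages tested samples and flags untested regions", {
  m <- list(tx1 = two_exon_model())
  class(m) <- "transcript_models"
  calls <- rbind(
    call_row("s1", "PFC", "tx1", 10, 0.95, 0.5),
    call_row("s2", "PFC", "tx1", 10, 0.95, 0.7),
    call_row("s3", "CB", "tx1", 10, 0.95, 0.66))
  cat <- build_consensus(calls, m)
  expect_equal(site_region_rate(cat, "tx1", 10, "PFC"), 0.6)
  expect_equal(site_region_rate(cat, "tx1", 10, "CB"), 0.66)
  expect_true(is.na(site_region_rate(cat, "tx1", 10, "CN")))
})

test_that("motif composition test equals the kernel z on constructed counts", {
  m <- list(tx1 = transcript_model("tx1", "g1", "chr1", "+", cbind(0, 5000)))
  class(m) <- "transcript_models"
  # 100 tested sites: 10 GGACT; 100 modified draws impossible at this scale,
  # so construct 30 GGACT among 100 modified via repeated positions
  tested <- data.frame(transcript_id = "tx1", tx_pos = 0:99,
                       kmer = c(rep("GGACT", 10), rep("AAACA", 90)))
  calls <- do.call(rbind, lapply(1:2, function(s)
    call_row(paste0("s", s), "PFC", "tx1", 0:99, 0.95, 0.5,
             kmer = c(rep("GGACT", 30), rep("AAACA", 70)))))
  cat <- build_consensus(calls, m)
  ms <- motif_summary(cat, tested)
  z_expected <- (0.3 - 0.1) / sqrt(0.2 * 0.8 * (2 / 100))
  expect_equal(ms$statistic[ms$kmer == "GGACT"], z_expected, tolerance = 1e-12)
  expect_equal(ms$prop_modified[ms$kmer == "GGACT"], 0.3)
  expect_equal(ms$prop_tested[ms$kmer == "GGACT"], 0.1)

  # uniform composition in both populations: all z = 0
  tested_u <- data.frame(transcript_id = "tx1", tx_pos = 0:1,
                         kmer = c("GGACT", "AAACA"))
  calls_u <- do.call(rbind, lapply(1:2, function(s)
    call_row(paste0("s", s), "PFC", "tx1", 0:1, 0.95, 0.5,
             kmer = c("GGACT", "AAACA"))))
  msu <- motif_summary(build_consensus(calls_u, m), tested_u)
  expect_true(all(msu$statistic == 0))
})

test_that("spike-in negative control counts sites above threshold", {
  calls <- rbind(
    call_row("s1", "PFC", "SIRV101", 10, 0.5, 0.1),
    call_row("s1", "PFC", "SIRV101", 20, 0.89, 0.1),
    call_row("s1", "PFC", "T001.1", 30, 0.99, 0.8))
  qc <- sirv_negative_control(calls)
  expect_equal(qc$n_modified, 0)
  expect_true(qc$qc_pass)
  calls$prob_mod[1] <- 0.95
  qc <- sirv_negative_control(calls)
  expect_equal(qc$n_modified, 1)
  expect_false(qc$qc_pass)
  expect_equal(sirv_negative_control(calls[3, ])$n_sites_tested, 0)
})

test_that("modified-read fraction composes site rates under independence", {
  m <- list(tx1 = transcript_model("tx1", "g1", "chr1", "+", cbind(0, 1000)))
  class(m) <- "transcript_models"
  mk <- function(ratios) {
    do.call(rbind, lapply(1:2, function(s)
      call_row(paste0("s", s), "PFC", "tx1", seq(10, by = 10,
                                                 length.out = length(ratios)),
               0.95, ratios)))
  }
  one <- build_consensus(mk(0.27), m)
  expect_equal(estimate_modified_read_fraction(one)$fraction, 0.27)
  two <- build_consensus(mk(c(0.5, 0.5)), m)
  expect_equal(estimate_modified_read_fraction(two)$fraction, 0.75)
  none <- build_consensus(call_row("s1", "PFC", "tx1", 10, 0.2, 0.1), m)
  expect_equal(estimate_modified_read_fraction(none)$fraction, 0)
})

test_that("external catalog intersection partitions genomic sites", {
  sites <- data.frame(chrom = "chr1", pos = c(10, 20, 30, 40, 50), strand = "+")
  self <- intersect_external_catalog(sites, sites)
  expect_equal(self$pct_annotated, 100)
  none <- intersect_external_catalog(sites, sites[0, ])
  expect_equal(none$pct_annotated, 0)
  three <- intersect_external_catalog(
    sites, data.frame(chrom = "chr1", pos = c(10, 30, 50, 99), strand = "+"))
  expect_equal(three$n_annotated, 3)
  expect_equal(three$pct_annotated, 60)
  # opposite strand does not match when both carry strand
  flip <- intersect_external_catalog(
    sites, data.frame(chrom = "chr1", pos = 10, strand = "-"))
  expect_equal(flip$n_annotated, 0)
})

test_that("observed rates track planted rates at binomial accuracy", {
  sim <- small_sim()
  calls <- load_site_tables(sim$sites$meta, sim$sites$tables)
  truth <- sim$truth$entries
  dt <- data.table::as.data.table(calls)
  obs <- dt[, list(obs_rate = mean(mod_ratio), n = sum(n_reads)),
            by = c("transcript_id", "tx_pos", "region")]
  key <- paste(obs$transcript_id, obs$tx_pos)
  within <- logical(0)
  for (r in sim$config$regions) {
    tr <- truth[[paste0("rate_", r)]][match(key, paste(truth$transcript_id,
                                                       truth$tx_pos))]
    sel <- obs$region == r & tr > 0
    se <- sqrt(tr[sel] * (1 - tr[sel]) / obs$n[sel])
    within <- c(within, abs(obs$obs_rate[sel] - tr[sel]) <= 4 * se)
  }
  expect_gte(mean(within), 0.95)
})
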