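# Differential modification between isoforms at shared genomic sites and
# between regions at the same transcriptomic site.

# two isoforms of one gene sharing exon [0,1000); tx3 on the opposite strand
dm_models <- function() {
  m <- list(
    txA = transcript_model("txA", "g1", "chr1", "+",
                           rbind(c(0, 1000), c(2000, 2500)),
                           cds_span = c(100, 1200)),
    txB = transcript_model("txB", "g1", "chr1", "+", cbind(0, 1000)),
    txC = transcript_model("txC", "g1", "chr1", "-", cbind(0, 1000)))
  class(m) <- "transcript_models"
  m
}

dm_calls <- function(ratio_a, ratio_b, n_reads = 50, pos = 500) {
  rbind(
    call_row(c("p1", "p2"), "PFC", "txA", pos, 0.95, ratio_a, n_reads),
    call_row(c("p1", "p2"), "PFC", "txB", pos, 0.95, ratio_b, n_reads))
}

test_that("shared-site grouping keys on genomic identity within a gene", {
  m <- dm_models()
  calls <- rbind(dm_calls(0.5, 0.5),
                 # same coordinate, opposite strand: genome position of tx_pos
                 # 499 on the minus strand of [0,1000) is 500
                 call_row(c("p1", "p2"), "PFC", "txC", 499, 0.95, 0.5),
                 # a private site on txA only
                 call_row(c("p1", "p2"), "PFC", "txA", 1100, 0.95, 0.5))
  cat <- build_consensus(calls, m)
  g <- group_shared_sites(cat)
  expect_equal(length(unique(g$group_id)), 1)
  expect_setequal(g$transcript_id, c("txA", "txB"))
  expect_true(all(g$strand == "+"))

  # hand-enumerated: 3 shared + 2 private genomic sites -> 3 groups
  calls2 <- rbind(dm_calls(0.5, 0.5, pos = 100), dm_calls(0.5, 0.5, pos = 200),
                  dm_calls(0.5, 0.5, pos = 300),
                  call_row(c("p1", "p2"), "PFC", "txA", 1100, 0.95, 0.5),
                  call_row(c("p1", "p2"), "PFC", "txA", 1200, 0.95, 0.5))
  g2 <- group_shared_sites(build_consensus(calls2, m))
  expect_equal(length(unique(g2$group_id)), 3)
})

test_that("within-gene DM applies the pooled z test with FDR and effect gates", {
  m <- dm_models()
  # identical rates: z = 0, never significant
  res <- suppressMessages(within_gene_dm(build_consensus(dm_calls(0.5, 0.5), m), m))
  expect_equal(res$results$z, 0)
  expect_false(any(res$results$significant))

  # 45/50 vs 15/50 pooled over 2 samples each: counts double, rates unchanged
  res <- suppressMessages(within_gene_dm(build_consensus(dm_calls(0.9, 0.3), m), m))
  row <- res$results
  expect_equal(row$rate_a - row$rate_b, 0.6)
  expect_equal(abs(row$z),
               0.6 / sqrt(0.6 * 0.4 * (1 / 100 + 1 / 100)), tolerance = 1e-9)
  expect_true(row$significant)
  expect_setequal(res$dm_isoforms, c("txA", "txB"))

  # structural covariates: txA site 500 has dist_down 500, txB has 500; equal
  expect_equal(row$d_dist_down, 0)

  # tiny p but |diff| = 0.10: the effect gate blocks significance
  res <- suppressMessages(within_gene_dm(
    build_consensus(dm_calls(0.55, 0.45, n_reads = 20000), m), m))
  expect_lt(res$results$p, 1e-10)
  expect_false(res$results$significant)

  # swapping members negates diff and z, leaves p unchanged
  z1 <- two_prop_z(45, 50, 15, 50); z2 <- two_prop_z(15, 50, 45, 50)
  expect_equal(z1$statistic, -z2$statistic)
  expect_equal(z1$p_value, z2$p_value)
})

test_that("modified read counts are reconstructed exactly from ratios", {
  m <- dm_models()
  cat <- build_consensus(dm_calls(0.42, 0.26, n_reads = 50), m)
  res <- suppressMessages(within_gene_dm(cat, m))
  expect_equal(res$results$k_a, 2 * round(0.42 * 50))
  expect_equal(res$results$n_a, 100)
})

test_that("the structure model recovers noiseless and noisy coefficients", {
  set.seed(47)
  n <- 80
  df <- data.frame(
    diff = NA, d_dist_down = sample(-500:500, n, TRUE),
    d_dist_up = sample(-500:500, n, TRUE),
    tx_region_a = sample(c("3UTR", "CDS"), n, TRUE),
    tx_region_b = sample(c("3UTR", "CDS"), n, TRUE))
  ind <- ifelse(df$tx_region_a == "3UTR" & df$tx_region_b == "CDS", 1,
                ifelse(df$tx_region_a == "CDS" & df$tx_region_b == "3UTR", -1, 0))
  # noiseless: exact recovery (summary warns about the perfect fit)
  df$diff <- 0.001 * df$d_dist_down
  fit <- suppressWarnings(dm_structure_model(df))
  expect_equal(unname(fit$coefficients["d_dist_down", "Estimate"]), 0.001,
               tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  # known coefficients + noise: 95% CIs cover in >= 90% of repetitions
  beta <- c(down = 4e-4, up = 1e-4, utr = 0.05)
  covered <- 0
  for (s in 1:10) {
    set.seed(100 + s)
    df$diff <- beta["down"] * df$d_dist_down + beta["up"] * df$d_dist_up +
      beta["utr"] * ind + rnorm(n, 0, 0.05)
    f <- dm_structure_model(df)
    ci <- stats::confint(f$fit)
    covered <- covered + all(
      ci["d_dist_down", 1] <= beta["down"], beta["down"] <= ci["d_dist_down", 2],
      ci["d_dist_up", 1] <= beta["up"], beta["up"] <= ci["d_dist_up", 2],
      ci["utr3_vs_cds", 1] <= beta["utr"], beta["utr"] <= ci["utr3_vs_cds", 2])
  }
  expect_gte(covered / 10, 0.9)

  # zero-variance predictor is dropped with a warning
  df0 <- df; df0$d_dist_up <- 0
  expect_warning(dm_structure_model(df0), "zero-variance")
})

xpore_fixture <- function() {
  data.frame(
    transcript_id = c("txA", "txA", "txA", "txA"),
    transcript_position = c(1, 2, 3, 4),
    kmer = c("GGACT", "GGGGG", "GGACT", "GGACT"),
    region_a = "CB", region_b = "CN",
    rate_a = c(0.8, 0.8, 0.8, 0.6),
    rate_b = c(0.45, 0.45, 0.1, 0.5),
    p_value = c(1e-6, 1e-6, 1e-6, 0.5))
}

test_that("between-region DM filters motif, effect, FDR and corroboration", {
  xt <- xpore_fixture()
  xt$diff_mod_rate <- xt$rate_b - xt$rate_a
  calls <- rbind(
    call_row(c("b1", "b2"), "CB", "txA", 1, 0.8, 0.8),
    call_row(c("b1", "b2"), "CB", "txA", 2, 0.8, 0.8),
    call_row(c("b1"), "CB", "txA", 3, 0.8, 0.8),      # only 1 supporting sample
    call_row(c("b1", "b2"), "CB", "txA", 4, 0.8, 0.6))
  res <- between_region_dm(xt, calls)
  # row 1 kept; row 2 non-DRACH; row 3 uncorroborated; row 4 small diff + p
  expect_equal(res$results$transcript_position, 1)
  expect_equal(res$results$up_region, "CB")
  expect_equal(res$n_excluded_uncorroborated, 1)

  # output is a subset of input rows and thresholds are monotone
  strict <- between_region_dm(xt, calls, diff_thr = 0.5)
  expect_lte(nrow(strict$results), nrow(res$results))
  stricter <- between_region_dm(xt, calls, prob_thr = 0.95)
  expect_lte(nrow(stricter$results), nrow(res$results))
})

test_that("direction summary and per-isoform consistency classes", {
  dmres <- data.frame(
    transcript_id = c("t1", "t1", "t2", "t3"),
    transcript_position = c(1, 2, 5, 9),
    region_a = "CB", region_b = "CN",
    diff_mod_rate = c(-0.4, -0.5, -0.4, 0.4),
    up_region = c("CB", "CB", "CB", "CN"))
  ds <- dm_direction_summary(dmres, "CB")
  expect_equal(ds$n_sites, 4)
  expect_equal(ds$n_up, 3)
  expect_equal(ds$pct_up, 75)
  cons <- dm_direction_consistency(dmres)
  expect_equal(cons$class[cons$transcript_id == "t1"], "consistent")
  expect_equal(cons$class[cons$transcript_id == "t2"], "single")
  opp <- rbind(dmres[1, ], within(dmres[2, ], diff_mod_rate <- 0.5))
  expect_equal(dm_direction_consistency(opp)$class, "opposing")
})

test_that("planted within-gene DM is recovered and null data stays null", {
  sim <- small_sim()
  pipe <- suppressMessages(run_pipeline(sim))
  rec <- evaluate_recovery(sim, pipe)
  expect_gte(rec$dm_recovered, 0.9)
  # null: single-seed spot check of the FDR-gated false-positive rate
  nul <- suppressMessages(dm_null_experiment(19, sim_config(n_genes = 30)))
  expect_lte(nul$fp_rate, 0.05 + 2 * sqrt(0.05 * 0.95 / nul$n_tests))
})
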