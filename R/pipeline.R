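# End-to-end convenience wrappers over the module functions, used by the
# analysis drivers, the test-bench recovery checks and the acceptance script.

#' Run the full synthetic experiment for one seed
#'
#' Generates annotation, planted truth and all emitted tables for a config.
#'
#' @param config A [sim_config()].
#' @return List with `config`, `models`, `truth`, `sites`, `polya`, `de`,
#'   `xpore`.
#' @export
run_simulation <- function(config) {
  models <- generate_annotation(config)
  truth <- simulate_m6a_truth(models, config)
  list(config = config, models = models, truth = truth,
       sites = emit_site_tables(truth, config),
       polya = emit_polya_tables(truth, config),
       de = emit_de_tables(truth, config),
       xpore = emit_xpore_table(truth, config))
}

#' Run the site-level pipeline on a simulated experiment
#'
#' Loads the emitted site tables, builds the consensus catalog and the
#' specificity, hypermodification and differential-modification results.
#'
#' @param sim Output of [run_simulation()].
#' @param top_n_hypermod Hypermodified selection size per region; the default
#'   scales the headline top-500 rule down to the synthetic catalog
#'   (a tenth of the profiled isoforms, at least 5).
#' @return List with `calls`, `catalog`, `specificity`, `hypermod`, `dm`.
#' @export
run_pipeline <- function(sim, top_n_hypermod = NULL) {
  calls <- load_site_tables(sim$sites$meta, sim$sites$tables)
  catalog <- build_consensus(calls, sim$models)
  spec_iso <- classify_specificity(catalog, "isoform")
  regions <- sim$config$regions
  profiles <- lapply(regions, function(r) {
    pr <- build_mod_profiles(catalog, sim$models, r)
    if (nrow(pr) >= 3L) normalize_m6a(pr) else NULL
  })
  names(profiles) <- regions
  hyper <- lapply(regions, function(r) {
    pr <- profiles[[r]]
    if (is.null(pr)) return(NULL)
    n_top <- if (is.null(top_n_hypermod)) max(5L, round(nrow(pr) / 10)) else
      top_n_hypermod
    select_hypermodified(pr, n_top)
  })
  names(hyper) <- regions
  dm <- within_gene_dm(catalog, sim$models)
  list(calls = calls, catalog = catalog,
       specificity = list(isoform = spec_iso),
       profiles = profiles, hypermod = hyper, dm = dm)
}

#' Score recovery of the planted truth by the pipeline
#'
#' Compares pipeline calls against the generator's recorded truth: the
#' fraction of planted region-specific isoforms called specific with the
#' correct region, the fraction of planted hypermodified (isoform, region)
#' combinations landing in the top decile of the normalised modification
#' score, and the fraction of planted within-gene DM (site, isoform) pairs
#' recovered as significant.
#'
#' @param sim Output of [run_simulation()].
#' @param pipe Output of [run_pipeline()].
#' @return List of recovery fractions and supporting counts.
#' @export
evaluate_recovery <- function(sim, pipe) {
  truth <- sim$truth
  iso <- truth$isoforms
  # region-specific recovery
  planted <- iso[!is.na(iso$specific_region), ]
  spec <- pipe$specificity$isoform
  hit <- spec$label[match(planted$transcript_id, spec$feature_id)] == "specific" &
    spec$regions_modified[match(planted$transcript_id, spec$feature_id)] ==
    planted$specific_region
  specific_recovery <- if (nrow(planted) > 0) mean(hit, na.rm = FALSE) else NA_real_
  specific_recovery[is.na(specific_recovery)] <- 0
  # hypermod: planted isoforms in the top decile of norm_score, per region
  hyp_ids <- iso$transcript_id[iso$hypermod]
  in_decile <- c()
  for (r in sim$config$regions) {
    pr <- pipe$profiles[[r]]
    if (is.null(pr)) next
    cut <- stats::quantile(pr$norm_score, 0.9, type = 7)
    present <- hyp_ids[hyp_ids %in% pr$isoform_id]
    in_decile <- c(in_decile,
                   pr$norm_score[match(present, pr$isoform_id)] >= cut)
  }
  hypermod_top_decile <- if (length(in_decile) > 0) mean(in_decile) else NA_real_
  # within-gene DM recovery: planted up-isoform participates in a significant
  # pair at the planted site in at least one region
  dm_truth <- truth$dm
  res <- pipe$dm$results
  dm_recovered <- NA_real_
  if (!is.null(res) && nrow(dm_truth) > 0) {
    sig <- res[res$significant, , drop = FALSE]
    sig_keys <- unique(c(paste(sig$chrom, sig$gpos, sig$strand, sig$iso_a),
                         paste(sig$chrom, sig$gpos, sig$strand, sig$iso_b)))
    ent <- truth$entries
    idx <- match(paste(dm_truth$site_id, dm_truth$transcript_id),
                 paste(ent$site_id, ent$transcript_id))
    truth_keys <- paste(ent$chrom[idx], ent$gpos[idx], ent$strand[idx],
                        dm_truth$transcript_id)
    dm_recovered <- mean(truth_keys %in% sig_keys)
  }
  list(specific_recovery = specific_recovery,
       n_specific_planted = nrow(planted),
       hypermod_top_decile = hypermod_top_decile,
       n_hypermod_checks = length(in_decile),
       dm_recovered = dm_recovered,
       n_dm_planted = nrow(dm_truth))
}

#' False-positive rate of within-gene DM calls on null data
#'
#' Runs the generator with all plantings and region effects disabled (equal
#' true rates across isoforms and regions) and reports the fraction of
#' significant within-gene DM pairs, which estimates the type-I error of the
#' FDR-gated test.
#'
#' @param seed Integer seed.
#' @param config Optional base config; plantings are disabled on top of it.
#' @return List with `fp_rate`, `n_tests`.
#' @export
dm_null_experiment <- function(seed, config = NULL) {
  if (is.null(config)) config <- sim_config()
  config$seed <- as.integer(seed)
  config$dm_fraction <- 0
  config$region_dm_fraction <- 0
  config$hypermod_fraction <- 0
  config$specific_fraction <- 0
  config$unmodified_fraction <- 0
  config$exclusion_penalty <- 1
  config$region_rate_shift[] <- 0
  config$coverage_const <- 100L
  models <- generate_annotation(config)
  truth <- simulate_m6a_truth(models, config)
  sites <- emit_site_tables(truth, config)
  calls <- load_site_tables(sites$meta, sites$tables)
  catalog <- build_consensus(calls, models)
  dm <- suppressMessages(within_gene_dm(catalog, models))
  res <- dm$results
  list(fp_rate = if (is.null(res)) NA_real_ else mean(res$significant),
       n_tests = if (is.null(res)) 0L else nrow(res))
}
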