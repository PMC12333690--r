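# Deterministic synthetic-data generator with recorded planted truth.
#
# The generator emulates the summary tables the pipeline consumes (annotation,
# per-sample m6anet-style site tables, xPore-style differential tables,
# nanopolish-style poly(A) tables, DE/DIU tables) at desk scale. It is
# sequence-free: DRACH 5-mers are assigned as labels, since no downstream stage
# needs nucleotide sequence beyond the motif label. Every random draw is driven
# by the config seed plus a fixed per-table offset, so outputs are fully
# deterministic under a seed.

DRACH_MOTIFS <- local({
  g <- expand.grid(D = c("A", "G", "T"), R = c("A", "G"), H = c("A", "C", "T"),
                   stringsAsFactors = FALSE)
  paste0(g$D, g$R, "AC", g$H)
})

# weights loosely mimic the observed DRACH composition (GGACT most common)
DRACH_WEIGHTS <- local({
  w <- rep(1, 18)
  names(w) <- DRACH_MOTIFS
  w["GGACT"] <- 6; w["GGACA"] <- 4; w["GGACC"] <- 3
  w["AGACT"] <- 3; w["TGACT"] <- 2.5; w["GAACT"] <- 2
  w / sum(w)
})

clip01 <- function(x, lo = 0.02, hi = 0.98) pmin(hi, pmax(lo, x))

#' Simulation configuration
#'
#' Defaults define the study conditions the whole test-bench runs under:
#' three brain-region labels with three samples each, ~100 genes with 2-4
#' isoforms sharing exons (so shared genomic sites exist), a tested-DRACH
#' density of one site per 100 exonic nt (~5k site-isoform observations),
#' a 100-nt exclusion zone around splice junctions and transcript ends that
#' multiplies modification rates by `exclusion_penalty`, additive per-region
#' rate shifts (CB highest, CN lowest), planted within-gene and between-region
#' differential-modification sites at |delta rate| 0.4, planted hypermodified,
#' region-specific and unmodified isoforms, read coverage of at least 21 reads,
#' and poly(A) medians lognormal around 80 nt coupled to isoform length at
#' Spearman 0.55 with a -16 nt shift in CN (and -3 nt in PFC) relative to CB.
#'
#' @param seed Integer seed; fully determines all emitted tables.
#' @param n_genes Number of multi-isoform genes.
#' @param isoforms_per_gene,exons_per_gene Integer ranges `c(min, max)`.
#' @param exon_length,intron_length Uniform integer ranges in nt.
#' @param tes_offsets,tss_offsets Candidate terminal-exon extensions (nt);
#'   each isoform samples one for its 3' end (alternative polyadenylation)
#'   and 5' start (alternative transcription start), so shared genomic sites
#'   can sit at different boundary distances in different isoforms.
#' @param regions Region labels.
#' @param samples_per_region Replicates per region.
#' @param site_density Tested DRACH sites per exonic nt.
#' @param p_site_modified Probability a tested site is truly modified.
#' @param rate_shape Beta shape parameters of the base modification rate.
#' @param exclusion_zone_width,exclusion_penalty Exclusion-zone width (nt) and
#'   the rate multiplier applied within it (1 disables the zone).
#' @param region_rate_shift Named additive rate shifts per region.
#' @param dm_fraction,dm_delta Fraction of shared genomic sites planted as
#'   differentially modified between isoforms, and the planted rate difference.
#' @param region_dm_fraction,region_dm_delta,region_dm_cb_up As above for
#'   between-region differential sites; `region_dm_cb_up` is the probability the
#'   up-regulated region is CB.
#' @param hypermod_fraction,hypermod_extra_sites,hypermod_rate Hypermodified
#'   isoform planting: fraction of isoforms, extra sites each, their rate.
#' @param specific_fraction Fraction of modified isoforms made region-specific.
#' @param unmodified_fraction Fraction of isoforms made fully unmodified.
#' @param coverage_mean,coverage_size Negative-binomial read coverage above the
#'   21-read floor; `coverage_const` (if set) forces constant coverage.
#' @param coverage_const Optional constant `n_reads`.
#' @param prob_mod_shape_mod,prob_mod_shape_unmod Beta shapes of the emitted
#'   modification probability for truly modified / unmodified sites.
#' @param polya_median,polya_spread Median (nt) and lognormal sdlog of the
#'   per-isoform true poly(A) median distribution.
#' @param polya_rho Target Spearman correlation of poly(A) median with isoform
#'   length (Gaussian copula calibrated so the true medians achieve it).
#' @param polya_region_shift Named additive nt shifts per region.
#' @param polya_read_sdlog Per-read lognormal noise around the isoform median.
#' @param polya_reads_mean Mean reads per isoform per sample.
#' @param polya_fail_rate Fraction of reads emitted with a non-PASS QC tag.
#' @param n_mito,n_sirv Mitochondrial decoy / unmodified spike-in transcripts.
#' @param sirv_sites_per_tx Tested DRACH sites per spike-in transcript.
#' @param specific_up_fraction Fraction of region-specific isoforms planted as
#'   up-regulated in their region (expression-driven specificity).
#' @param bg_up_fraction Fraction of other isoforms up-regulated somewhere.
#' @param de_effect Planted log2 fold change magnitude.
#' @param diu_n,diu_dif Planted differential-isoform-usage rows and their dIF.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 100L,
                       isoforms_per_gene = c(2L, 4L),
                       exons_per_gene = c(6L, 10L),
                       exon_length = c(100L, 400L),
                       intron_length = c(200L, 2000L),
                       tes_offsets = c(0L, 200L, 450L),
                       tss_offsets = c(0L, 150L),
                       regions = c("PFC", "CN", "CB"),
                       samples_per_region = 3L,
                       site_density = 1 / 100,
                       p_site_modified = 0.45,
                       rate_shape = c(4, 2),
                       exclusion_zone_width = 100L,
                       exclusion_penalty = 0.3,
                       region_rate_shift = c(PFC = 0, CN = -0.05, CB = 0.05),
                       dm_fraction = 0.05,
                       dm_delta = 0.4,
                       region_dm_fraction = 0.05,
                       region_dm_delta = 0.4,
                       region_dm_cb_up = 0.75,
                       hypermod_fraction = 0.02,
                       hypermod_extra_sites = 6L,
                       hypermod_rate = 0.9,
                       specific_fraction = 0.08,
                       unmodified_fraction = 0.08,
                       coverage_mean = 60,
                       coverage_size = 8,
                       coverage_const = NULL,
                       prob_mod_shape_mod = c(20, 1),
                       prob_mod_shape_unmod = c(1, 20),
                       polya_median = 80,
                       polya_spread = 0.45,
                       polya_rho = 0.55,
                       polya_region_shift = c(PFC = -3, CN = -16, CB = 0),
                       polya_read_sdlog = 0.30,
                       polya_reads_mean = 40,
                       polya_fail_rate = 0.10,
                       n_mito = 2L,
                       n_sirv = 8L,
                       sirv_sites_per_tx = 5L,
                       specific_up_fraction = 0.25,
                       bg_up_fraction = 0.08,
                       de_effect = 1.5,
                       diu_n = 20L,
                       diu_dif = 0.3) {
  cfg <- as.list(environment())
  stopifnot(cfg$seed == as.integer(cfg$seed),
            all(cfg$regions %in% names(cfg$region_rate_shift)),
            all(cfg$regions %in% names(cfg$polya_region_shift)),
            cfg$p_site_modified >= 0, cfg$p_site_modified <= 1,
            cfg$exclusion_penalty >= 0, cfg$exclusion_penalty <= 1)
  class(cfg) <- "sim_config"
  cfg
}

sample_range <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(seq(range[1], range[2]), n, replace = TRUE)
}

#' Generate a synthetic annotation
#'
#' Builds genes with multiple isoforms sharing exons (first and last exon are
#' always retained; internal exons are kept independently with probability
#' 0.75, and duplicate exon patterns are dropped), assigns a CDS to coding
#' isoforms, and appends mitochondrial decoy and unmodified spike-in
#' transcripts. Deterministic under `config$seed`.
#'
#' @param config A [sim_config()].
#' @param gtf_path Optional path; when given the annotation is also written as
#'   GTF via [write_gtf()].
#' @return A `transcript_models` list.
#' @export
generate_annotation <- function(config, gtf_path = NULL) {
  set.seed(config$seed)
  models <- list()
  chroms <- paste0("chr", 1:4)
  cursor <- stats::setNames(rep(10000, length(chroms)), chroms)
  for (g in seq_len(config$n_genes)) {
    gid <- sprintf("G%03d", g)
    chrom <- chroms[1L + (g - 1L) %% length(chroms)]
    strand <- sample(c("+", "-"), 1L)
    n_ex <- sample_range(1L, config$exons_per_gene)
    ex_len <- sample_range(n_ex, config$exon_length)
    in_len <- sample_range(max(n_ex - 1L, 0L), config$intron_length)
    starts <- cursor[chrom] + cumsum(c(0, ex_len[-n_ex] + in_len))
    gene_exons <- cbind(starts, starts + ex_len)
    cursor[chrom] <- gene_exons[n_ex, 2] + 10000
    k <- sample_range(1L, config$isoforms_per_gene)
    patterns <- list()
    for (attempt in seq_len(20L)) {
      if (length(patterns) >= k) break
      keep <- rep(TRUE, n_ex)
      if (n_ex > 2L)
        keep[2:(n_ex - 1L)] <- stats::runif(n_ex - 2L) < 0.75
      key <- paste(which(keep), collapse = ",")
      if (!key %in% names(patterns)) patterns[[key]] <- keep
    }
    # gene-level alternative transcription start / polyadenylation sites:
    # isoforms pick one of a few terminal-exon extensions, so the same
    # genomic site can sit at different boundary distances in different
    # isoforms (as with alternative 3'UTR lengths in real annotation)
    tes_ext <- sample(config$tes_offsets, length(patterns), replace = TRUE)
    tss_ext <- sample(config$tss_offsets, length(patterns), replace = TRUE)
    for (i in seq_along(patterns)) {
      tid <- sprintf("T%03d.%d", g, i)
      exons <- gene_exons[patterns[[i]], , drop = FALSE]
      if (strand == "+") {
        exons[nrow(exons), 2] <- exons[nrow(exons), 2] + tes_ext[i]
        exons[1, 1] <- exons[1, 1] - tss_ext[i]
      } else {
        exons[1, 1] <- exons[1, 1] - tes_ext[i]
        exons[nrow(exons), 2] <- exons[nrow(exons), 2] + tss_ext[i]
      }
      L <- sum(exons[, 2] - exons[, 1])
      noncoding <- stats::runif(1) < 0.15
      cds <- NULL
      biotype <- "lncRNA"
      if (!noncoding) {
        s <- max(1, round(0.15 * L))
        e <- min(L - 1, round(0.80 * L))
        if (e > s) {
          cds <- c(s, e)
          biotype <- "protein_coding"
        }
      }
      models[[tid]] <- transcript_model(tid, gid, chrom, strand, exons,
                                        cds_span = cds, biotype = biotype)
    }
  }
  for (i in seq_len(config$n_mito)) {
    tid <- sprintf("TMT.%d", i)
    st <- 1000 + (i - 1L) * 3000
    models[[tid]] <- transcript_model(tid, "G_MT", "chrM", "+",
                                      cbind(st, st + 1200), biotype = "protein_coding")
  }
  for (i in seq_len(config$n_sirv)) {
    tid <- sprintf("SIRV1%02d", i)
    st <- 1000 + (i - 1L) * 3000
    models[[tid]] <- transcript_model(tid, "SIRV_G1", "SIRV1", "+",
                                      cbind(st, st + 1500), biotype = "SIRV")
  }
  class(models) <- "transcript_models"
  if (!is.null(gtf_path)) write_gtf(models, gtf_path)
  models
}

merge_intervals <- function(mat) {
  mat <- mat[order(mat[, 1]), , drop = FALSE]
  out <- mat[1, , drop = FALSE]
  for (i in seq_len(nrow(mat))[-1]) {
    if (mat[i, 1] <= out[nrow(out), 2]) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], mat[i, 2])
    } else out <- rbind(out, mat[i, ])
  }
  out
}

#' Simulate the planted modification / poly(A) / expression truth
#'
#' Places tested DRACH sites on the exonic union of each gene (so sites are
#' shared across the isoforms containing them), assigns true modification
#' rates with the exclusion-zone penalty near splice junctions and transcript
#' ends and additive region shifts, and then plants, in order: region-specific
#' isoforms, unmodified isoforms, hypermodified isoforms (extra private sites),
#' within-gene differentially modified sites (one isoform raised by
#' `dm_delta`), and between-region differential sites (one region raised by
#' `region_dm_delta`). Poly(A) medians per isoform are coupled to isoform
#' length through a Gaussian copula calibrated to the target Spearman
#' correlation, with per-region shifts; expression truth marks planted
#' up-regulated isoforms/genes and differential-usage rows. All planted truths
#' are recorded.
#'
#' @param models Output of [generate_annotation()].
#' @param config The same [sim_config()].
#' @return A `sim_truth` list with elements `config`, `models`, `entries`
#'   (site-by-isoform table with per-region true rates), `isoforms` (planted
#'   flags), `dm`, `region_dm`, `polya`, and `de_up`/`diu` truth.
#' @export
simulate_m6a_truth <- function(models, config) {
  set.seed(config$seed + 1L)
  regions <- config$regions
  shift <- config$region_rate_shift
  info <- models_summary(models)
  human <- info$chrom %in% paste0("chr", 1:22) & info$chrom != "chrM"
  sirv <- startsWith(info$transcript_id, "SIRV")
  entries <- list()
  site_counter <- 0L
  for (gid in unique(info$gene_id[human])) {
    tids <- info$transcript_id[info$gene_id == gid]
    ex <- do.call(rbind, lapply(models[tids], `[[`, "exons"))
    ex <- merge_intervals(ex)
    bases <- unlist(lapply(seq_len(nrow(ex)), function(i) seq(ex[i, 1], ex[i, 2] - 1)))
    n_sites <- stats::rpois(1, length(bases) * config$site_density)
    n_sites <- min(n_sites, length(bases))
    if (n_sites == 0L) next
    gpos <- sort(sample(bases, n_sites))
    kmer <- sample(DRACH_MOTIFS, n_sites, replace = TRUE, prob = DRACH_WEIGHTS)
    modified <- stats::runif(n_sites) < config$p_site_modified
    base_rate <- ifelse(modified,
                        stats::rbeta(n_sites, config$rate_shape[1], config$rate_shape[2]),
                        0)
    site_ids <- sprintf("S%06d", site_counter + seq_len(n_sites))
    site_counter <- site_counter + n_sites
    for (tid in tids) {
      m <- models[[tid]]
      tx <- genome_to_tx(m, gpos)
      on_tx <- !is.na(tx)
      if (!any(on_tx)) next
      bd <- boundary_distances(m, tx[on_tx])
      in_zone <- bd$dist_up < config$exclusion_zone_width |
        bd$dist_down <= config$exclusion_zone_width
      rate <- base_rate[on_tx] * ifelse(in_zone, config$exclusion_penalty, 1)
      ent <- data.table::data.table(
        site_id = site_ids[on_tx], gene_id = gid, transcript_id = tid,
        chrom = m$chrom, gpos = gpos[on_tx], strand = m$strand,
        kmer = kmer[on_tx], tx_pos = tx[on_tx],
        dist_up = bd$dist_up, dist_down = bd$dist_down,
        modified = modified[on_tx])
      for (r in regions)
        ent[[paste0("rate_", r)]] <- ifelse(ent$modified,
                                            clip01(rate + shift[[r]]), 0)
      entries[[length(entries) + 1L]] <- ent
    }
  }
  # unmodified spike-in control sites
  for (tid in info$transcript_id[sirv]) {
    m <- models[[tid]]
    tx <- sort(sample(seq(102, m$spliced_length - 103),
                      config$sirv_sites_per_tx))
    g <- tx_to_genome(m, tx)
    bd <- boundary_distances(m, tx)
    ent <- data.table::data.table(
      site_id = sprintf("SIRV_S%04d", seq_along(tx) + 10000L * match(tid, info$transcript_id)),
      gene_id = "SIRV_G1", transcript_id = tid, chrom = m$chrom,
      gpos = g$pos, strand = m$strand,
      kmer = sample(DRACH_MOTIFS, length(tx), replace = TRUE, prob = DRACH_WEIGHTS),
      tx_pos = tx, dist_up = bd$dist_up, dist_down = bd$dist_down,
      modified = FALSE)
    for (r in regions) ent[[paste0("rate_", r)]] <- 0
    entries[[length(entries) + 1L]] <- ent
  }
  entries <- data.table::rbindlist(entries)
  rate_cols <- paste0("rate_", regions)

  iso <- data.table::data.table(
    transcript_id = info$transcript_id, gene_id = info$gene_id,
    length = info$length, human = human, sirv = sirv, mito = info$chrom == "chrM",
    specific_region = NA_character_, hypermod = FALSE, unmodified = FALSE,
    up_region = NA_character_, diu = FALSE)

  n_mod_entries <- entries[, list(n_mod = sum(modified), n_tested = .N),
                           by = "transcript_id"]
  iso <- merge(iso, n_mod_entries, by = "transcript_id", all.x = TRUE)
  iso$n_mod[is.na(iso$n_mod)] <- 0L
  iso$n_tested[is.na(iso$n_tested)] <- 0L

  # region-specific isoforms: wipe rates outside the target region; planted
  # only on isoforms whose specificity is supported by >= 2 modified sites
  eligible <- iso$transcript_id[iso$human & iso$n_mod >= 2L]
  n_spec <- round(config$specific_fraction * sum(iso$human))
  spec_ids <- sample(eligible, min(n_spec, length(eligible)))
  spec_regions <- sample(regions, length(spec_ids), replace = TRUE)
  iso$specific_region[match(spec_ids, iso$transcript_id)] <- spec_regions
  for (i in seq_along(spec_ids)) {
    rows <- entries$transcript_id == spec_ids[i]
    for (r in setdiff(regions, spec_regions[i]))
      data.table::set(entries, which(rows), paste0("rate_", r), 0)
  }

  # fully unmodified isoforms with enough tested motifs
  eligible <- iso$transcript_id[iso$human & iso$n_tested >= 2L &
                                  is.na(iso$specific_region)]
  n_unmod <- round(config$unmodified_fraction * sum(iso$human))
  unmod_ids <- sample(eligible, min(n_unmod, length(eligible)))
  iso$unmodified[iso$transcript_id %in% unmod_ids] <- TRUE
  rows <- which(entries$transcript_id %in% unmod_ids)
  data.table::set(entries, rows, "modified", FALSE)
  for (r in regions) data.table::set(entries, rows, paste0("rate_", r), 0)

  # hypermodified isoforms: extra private high-rate sites
  eligible <- iso$transcript_id[iso$human & is.na(iso$specific_region) &
                                  !iso$unmodified]
  n_hyp <- round(config$hypermod_fraction * sum(iso$human))
  hyp_ids <- sample(eligible, min(n_hyp, length(eligible)))
  iso$hypermod[iso$transcript_id %in% hyp_ids] <- TRUE
  extra <- list()
  for (tid in hyp_ids) {
    m <- models[[tid]]
    taken <- entries$tx_pos[entries$transcript_id == tid]
    pool <- setdiff(seq(0, m$spliced_length - 1L), taken)
    n_extra <- min(config$hypermod_extra_sites, length(pool))
    tx <- sort(sample(pool, n_extra))
    g <- tx_to_genome(m, tx)
    bd <- boundary_distances(m, tx)
    ent <- data.table::data.table(
      site_id = sprintf("H%s_%03d", tid, seq_len(n_extra)),
      gene_id = m$gene_id, transcript_id = tid, chrom = m$chrom,
      gpos = g$pos, strand = m$strand,
      kmer = sample(DRACH_MOTIFS, n_extra, replace = TRUE, prob = DRACH_WEIGHTS),
      tx_pos = tx, dist_up = bd$dist_up, dist_down = bd$dist_down,
      modified = TRUE)
    for (r in regions)
      ent[[paste0("rate_", r)]] <- clip01(config$hypermod_rate)
    extra[[tid]] <- ent
  }
  if (length(extra) > 0L)
    entries <- data.table::rbindlist(c(list(entries), extra))

  flagged <- iso$transcript_id[!is.na(iso$specific_region) | iso$unmodified |
                                 iso$hypermod]

  # within-gene DM: one isoform raised by dm_delta at a shared genomic site
  cand <- entries[modified & !transcript_id %in% flagged]
  grp <- cand[, list(n_iso = data.table::uniqueN(transcript_id)), by = "site_id"]
  grp <- grp[grp$n_iso >= 2L]
  n_dm <- round(config$dm_fraction * nrow(grp))
  dm_sites <- sample(grp$site_id, min(n_dm, nrow(grp)))
  dm_truth <- list()
  for (sid in dm_sites) {
    rows <- which(entries$site_id == sid & entries$modified &
                    !entries$transcript_id %in% flagged)
    r0 <- stats::runif(1, 0.15, 0.5)
    up_row <- sample(rows, 1L)
    for (r in regions) {
      data.table::set(entries, rows, paste0("rate_", r), clip01(r0 + shift[[r]]))
      data.table::set(entries, up_row, paste0("rate_", r),
                      clip01(r0 + config$dm_delta + shift[[r]]))
    }
    dm_truth[[sid]] <- data.table::data.table(
      site_id = sid, transcript_id = entries$transcript_id[up_row],
      tx_pos = entries$tx_pos[up_row], base_rate = r0, delta = config$dm_delta)
  }
  dm_truth <- if (length(dm_truth)) data.table::rbindlist(dm_truth) else
    data.table::data.table(site_id = character(0), transcript_id = character(0),
                           tx_pos = numeric(0), base_rate = numeric(0),
                           delta = numeric(0))

  # between-region DM: one region raised by region_dm_delta
  cand_rows <- which(entries$modified &
                       !entries$transcript_id %in% flagged &
                       !entries$site_id %in% dm_sites)
  n_rdm <- round(config$region_dm_fraction * length(cand_rows))
  rdm_rows <- sample(cand_rows, min(n_rdm, length(cand_rows)))
  up_region <- ifelse(stats::runif(length(rdm_rows)) < config$region_dm_cb_up,
                      "CB", sample(setdiff(regions, "CB"),
                                   length(rdm_rows), replace = TRUE))
  for (i in seq_along(rdm_rows)) {
    r0 <- stats::runif(1, 0.15, 0.5)
    for (r in regions)
      data.table::set(entries, rdm_rows[i], paste0("rate_", r), r0)
    data.table::set(entries, rdm_rows[i], paste0("rate_", up_region[i]),
                    clip01(r0 + config$region_dm_delta))
  }
  region_dm <- data.table::data.table(
    transcript_id = entries$transcript_id[rdm_rows],
    tx_pos = entries$tx_pos[rdm_rows],
    site_id = entries$site_id[rdm_rows],
    up_region = up_region, delta = config$region_dm_delta)

  # poly(A) truth: copula-coupled to isoform length, per-region shifts
  hn <- which(iso$human)
  n <- length(hn)
  z_len <- stats::qnorm((rank(iso$length[hn]) - 0.5) / n)
  rho_g <- 2 * sin(pi * config$polya_rho / 6)
  z <- rho_g * z_len + sqrt(1 - rho_g^2) * stats::rnorm(n)
  base_med <- stats::qlnorm(stats::pnorm(z), meanlog = log(config$polya_median),
                            sdlog = config$polya_spread)
  base_all <- rep(NA_real_, nrow(iso))
  base_all[hn] <- base_med
  base_all[iso$mito] <- 45
  base_all[iso$sirv] <- 35
  polya <- data.table::rbindlist(lapply(regions, function(r) {
    data.table::data.table(
      transcript_id = iso$transcript_id, region = r,
      true_median = ifelse(iso$human,
                           pmax(10, base_all + config$polya_region_shift[[r]]),
                           base_all))
  }))

  # expression truth: planted up-regulation and isoform usage
  spec_up <- spec_ids[stats::runif(length(spec_ids)) < config$specific_up_fraction]
  iso$up_region[match(spec_up, iso$transcript_id)] <-
    spec_regions[match(spec_up, spec_ids)]
  others <- iso$transcript_id[iso$human & is.na(iso$up_region)]
  bg_up <- sample(others, round(config$bg_up_fraction * length(others)))
  iso$up_region[match(bg_up, iso$transcript_id)] <-
    sample(regions, length(bg_up), replace = TRUE)
  diu_ids <- sample(iso$transcript_id[iso$human], min(config$diu_n, sum(iso$human)))
  iso$diu[iso$transcript_id %in% diu_ids] <- TRUE

  structure(list(config = config, models = models, entries = entries,
                 isoforms = iso, dm = dm_truth, region_dm = region_dm,
                 polya = polya, rate_cols = rate_cols),
            class = "sim_truth")
}

sim_samples <- function(config) {
  data.frame(
    sample_id = unlist(lapply(config$regions, function(r)
      sprintf("%s_s%d", r, seq_len(config$samples_per_region)))),
    region = rep(config$regions, each = config$samples_per_region),
    stringsAsFactors = FALSE)
}

draw_coverage <- function(n, config) {
  if (!is.null(config$coverage_const)) return(rep(config$coverage_const, n))
  21L + stats::rnbinom(n, size = config$coverage_size,
                       mu = max(config$coverage_mean - 21, 1))
}

#' Emit per-sample m6anet-style site tables
#'
#' For every sample, every tested site-isoform entry receives a read coverage
#' (>= 21 reads), a binomially sampled modified-read ratio at its true regional
#' rate, and a modification probability drawn from a Beta concentrated near 1
#' for truly modified sites and near 0 (with the configured false-positive
#' tail) for unmodified ones.
#'
#' @param truth Output of [simulate_m6a_truth()].
#' @param config The same [sim_config()].
#' @return List with `meta` (sample_id, region) and `tables` (named list of
#'   data.frames with columns transcript_id, transcript_position, n_reads,
#'   probability_modified, kmer, mod_ratio).
#' @export
emit_site_tables <- function(truth, config) {
  set.seed(config$seed + 2L)
  meta <- sim_samples(config)
  ent <- truth$entries
  tables <- vector("list", nrow(meta))
  names(tables) <- meta$sample_id
  for (i in seq_len(nrow(meta))) {
    r <- meta$region[i]
    rate <- ent[[paste0("rate_", r)]]
    n_reads <- draw_coverage(nrow(ent), config)
    k <- stats::rbinom(nrow(ent), n_reads, rate)
    mod_here <- rate > 0
    prob <- ifelse(mod_here,
                   stats::rbeta(nrow(ent), config$prob_mod_shape_mod[1],
                                config$prob_mod_shape_mod[2]),
                   stats::rbeta(nrow(ent), config$prob_mod_shape_unmod[1],
                                config$prob_mod_shape_unmod[2]))
    tables[[i]] <- data.frame(
      transcript_id = ent$transcript_id,
      transcript_position = ent$tx_pos,
      n_reads = n_reads,
      probability_modified = round(prob, 6),
      kmer = ent$kmer,
      mod_ratio = round(k / n_reads, 6))
  }
  list(meta = meta, tables = tables)
}

#' Emit per-sample nanopolish-style poly(A) tables
#'
#' Per-read tail lengths are lognormal around the isoform's true regional
#' median (so the sample median is consistent by construction), a configurable
#' fraction of reads carries a non-PASS QC tag, and mitochondrial decoy
#' isoforms are included so loaders can be shown to drop them.
#'
#' @inheritParams emit_site_tables
#' @return List with `meta` and `tables` (columns readname, contig, position,
#'   polya_length, qc_tag).
#' @export
emit_polya_tables <- function(truth, config) {
  set.seed(config$seed + 3L)
  meta <- sim_samples(config)
  med <- truth$polya
  tables <- vector("list", nrow(meta))
  names(tables) <- meta$sample_id
  for (i in seq_len(nrow(meta))) {
    r <- meta$region[i]
    mr <- med[med$region == r]
    n_reads <- stats::rnbinom(nrow(mr), size = 6, mu = config$polya_reads_mean)
    idx <- rep(seq_len(nrow(mr)), n_reads)
    lens <- stats::rlnorm(length(idx), meanlog = log(mr$true_median[idx]),
                          sdlog = config$polya_read_sdlog)
    tag <- ifelse(stats::runif(length(idx)) < config$polya_fail_rate,
                  sample(c("ADAPTER", "READ_FAILED_LOAD"), length(idx),
                         replace = TRUE, prob = c(0.7, 0.3)),
                  "PASS")
    tables[[i]] <- data.frame(
      readname = sprintf("%s_read%06d", meta$sample_id[i], seq_along(idx)),
      contig = mr$transcript_id[idx],
      position = 0L,
      polya_length = round(pmax(1, lens), 2),
      qc_tag = tag)
  }
  list(meta = meta, tables = tables)
}

#' Emit DE gene/isoform and DIU tables
#'
#' Planted up-regulated features receive adjusted p < 0.05 with a positive
#' effect in both pairwise contrasts against the other regions; all other rows
#' are null with uniform adjusted p. DIU rows carry the planted isoform-usage
#' change. Comparisons are labelled `"A_vs_B"` with a positive logFC meaning
#' up in A; each unordered region pair appears once, alphabetically.
#'
#' @inheritParams emit_site_tables
#' @return List with data.frames `gene`, `isoform` (feature_id, level,
#'   comparison, logFC, adj_p) and `diu` (isoform_id, gene_id, region, dIF,
#'   adj_p).
#' @export
emit_de_tables <- function(truth, config) {
  set.seed(config$seed + 4L)
  regions <- sort(config$regions)
  pairs <- utils::combn(regions, 2L)
  iso <- as.data.frame(truth$isoforms[truth$isoforms$human, ])
  up_df <- iso[!is.na(iso$up_region), c("gene_id", "up_region")]
  gene_up <- if (nrow(up_df) > 0) {
    stats::aggregate(up_region ~ gene_id, data = up_df,
                     FUN = function(x) paste(unique(x), collapse = ","))
  } else data.frame(gene_id = character(0), up_region = character(0))
  make_de <- function(ids, up_of, level) {
    out <- list()
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1, j]; b <- pairs[2, j]
      up <- up_of(ids)
      hit_a <- vapply(up, function(u) a %in% u, logical(1))
      hit_b <- vapply(up, function(u) b %in% u, logical(1))
      planted <- xor(hit_a, hit_b)
      lfc <- stats::rnorm(length(ids), 0, 0.3)
      lfc[planted] <- ifelse(hit_a[planted], 1, -1) *
        (config$de_effect + stats::rnorm(sum(planted), 0, 0.2))
      adjp <- stats::runif(length(ids))
      adjp[planted] <- 10^-stats::runif(sum(planted), 2, 8)
      out[[j]] <- data.frame(feature_id = ids, level = level,
                             comparison = paste0(a, "_vs_", b),
                             logFC = round(lfc, 4), adj_p = adjp)
    }
    do.call(rbind, out)
  }
  iso_up <- function(ids) {
    u <- iso$up_region[match(ids, iso$transcript_id)]
    lapply(u, function(x) if (is.na(x)) character(0) else x)
  }
  gene_ids <- unique(iso$gene_id)
  g_up <- function(ids) {
    u <- gene_up$up_region[match(ids, gene_up$gene_id)]
    lapply(u, function(x) if (is.na(x)) character(0) else strsplit(x, ",")[[1]])
  }
  de_iso <- make_de(iso$transcript_id, iso_up, "isoform")
  de_gene <- make_de(gene_ids, g_up, "gene")
  diu <- data.frame(
    isoform_id = iso$transcript_id, gene_id = iso$gene_id,
    region = sample(config$regions, nrow(iso), replace = TRUE),
    dIF = round(stats::rnorm(nrow(iso), 0, 0.05), 4),
    adj_p = stats::runif(nrow(iso)))
  planted <- iso$diu
  diu$dIF[planted] <- round(config$diu_dif + stats::rnorm(sum(planted), 0, 0.02), 4)
  diu$adj_p[planted] <- 10^-stats::runif(sum(planted), 2, 6)
  list(gene = de_gene, isoform = de_iso, diu = diu)
}

#' Emit an xPore-style between-region differential table
#'
#' One row per modified site-isoform entry and alphabetical region pair, with
#' pooled simulated read counts per region, observed rates, their difference
#' (second minus first region) and a pooled two-proportion p-value. Planted
#' between-region DM sites (recorded in `truth$region_dm`) carry the
#' configured rate difference.
#'
#' @inheritParams emit_site_tables
#' @return data.frame with columns transcript_id, transcript_position, kmer,
#'   region_a, region_b, rate_a, rate_b, diff_mod_rate, p_value.
#' @export
emit_xpore_table <- function(truth, config) {
  set.seed(config$seed + 5L)
  regions <- sort(config$regions)
  pairs <- utils::combn(regions, 2L)
  ent <- truth$entries[truth$entries$modified]
  out <- list()
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    ra <- ent[[paste0("rate_", a)]]
    rb <- ent[[paste0("rate_", b)]]
    na <- config$samples_per_region * draw_coverage(nrow(ent), config)
    nb <- config$samples_per_region * draw_coverage(nrow(ent), config)
    ka <- stats::rbinom(nrow(ent), na, ra)
    kb <- stats::rbinom(nrow(ent), nb, rb)
    z <- two_prop_z(kb, nb, ka, na)
    out[[j]] <- data.frame(
      transcript_id = ent$transcript_id, transcript_position = ent$tx_pos,
      kmer = ent$kmer, region_a = a, region_b = b,
      rate_a = round(ka / na, 6), rate_b = round(kb / nb, 6),
      diff_mod_rate = round(kb / nb - ka / na, 6),
      p_value = z$p_value)
  }
  do.call(rbind, out)
}

#' Write emitted per-sample tables to TSV files
#'
#' @param emitted Output of [emit_site_tables()] or [emit_polya_tables()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return The `meta` data.frame with an added `path` column.
#' @export
write_sample_tables <- function(emitted, dir, prefix = "sites") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- emitted$meta
  meta$path <- file.path(dir, sprintf("%s_%s.tsv", prefix, meta$sample_id))
  for (i in seq_len(nrow(meta)))
    utils::write.table(emitted$tables[[meta$sample_id[i]]], meta$path[i],
                       sep = "\t", quote = FALSE, row.names = FALSE)
  meta
}
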