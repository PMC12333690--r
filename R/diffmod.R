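# Differential modification (DM): between isoforms sharing a genomic m6A
# site within a region, and between regions at the same transcriptomic site.

#' Group catalog sites shared by multiple isoforms of a gene
#'
#' Groups consensus sites by genomic identity (chrom, position, strand) within
#' a gene; only groups with at least two member isoforms are returned.
#' Identical coordinates on opposite strands are never grouped.
#'
#' @param catalog An `m6a_catalog`.
#' @return data.frame of group members with a `group_id` column.
#' @export
group_shared_sites <- function(catalog) {
  s <- as.data.frame(catalog$sites)
  if (nrow(s) == 0L)
    return(data.frame(group_id = character(0), gene_id = character(0),
                      chrom = character(0), gpos = numeric(0),
                      strand = character(0), transcript_id = character(0),
                      tx_pos = numeric(0)))
  s$group_id <- paste(s$gene_id, s$chrom, s$gpos, s$strand, sep = ":")
  n_members <- table(s$group_id)
  s <- s[s$group_id %in% names(n_members)[n_members >= 2L], , drop = FALSE]
  s[order(s$group_id, s$transcript_id),
    c("group_id", "gene_id", "chrom", "gpos", "strand", "transcript_id", "tx_pos")]
}

# pooled modified/total read counts per (transcript, tx_pos, region),
# reconstructing per-sample modified reads as round(mod_ratio * n_reads)
pooled_counts <- function(calls) {
  dt <- data.table::as.data.table(calls)
  dt$k <- round(dt$mod_ratio * dt$n_reads)
  dt[, list(k = sum(k), n = sum(n_reads)),
     by = c("transcript_id", "tx_pos", "region")]
}

#' Within-gene differential modification between isoforms
#'
#' For every shared genomic site and region, compares all isoform pairs with a
#' pooled two-proportion z test on modified/total read counts summed over the
#' region's samples. P-values are BH-adjusted over all tests in the run; a
#' pair is significant iff FDR < `alpha` and the absolute rate difference
#' exceeds `min_diff`. Structural covariates (changes in distance to the
#' upstream/downstream boundary, transcript-region labels) are attached for
#' the structure model. An isoform is differentially modified if it
#' participates in at least one significant pair.
#'
#' @param catalog An `m6a_catalog`.
#' @param models `transcript_models` annotation (for boundary distances and
#'   transcript regions).
#' @param min_diff Minimum absolute modification-rate difference (default 0.15).
#' @param alpha FDR threshold (default 0.05).
#' @return List with `results` (one row per pair and region), `dm_isoforms`
#'   (isoforms in >= 1 significant pair), `n_groups`.
#' @export
within_gene_dm <- function(catalog, models, min_diff = 0.15, alpha = 0.05) {
  groups <- group_shared_sites(catalog)
  counts <- pooled_counts(catalog$calls)
  if (nrow(groups) == 0L)
    return(list(results = NULL, dm_isoforms = character(0), n_groups = 0L))
  # structural annotations per member
  mem_key <- unique(groups[, c("transcript_id", "tx_pos")])
  mem_key$dist_up <- NA_real_; mem_key$dist_down <- NA_real_
  mem_key$tx_region <- NA_character_
  for (tid in unique(mem_key$transcript_id)) {
    rows <- which(mem_key$transcript_id == tid)
    m <- models[[tid]]
    bd <- boundary_distances(m, mem_key$tx_pos[rows])
    mem_key$dist_up[rows] <- bd$dist_up
    mem_key$dist_down[rows] <- bd$dist_down
    mem_key$tx_region[rows] <- region_of(m, mem_key$tx_pos[rows])
  }
  pair_list <- list()
  for (gid in unique(groups$group_id)) {
    g <- groups[groups$group_id == gid, , drop = FALSE]
    idx <- utils::combn(nrow(g), 2L)
    pair_list[[gid]] <- data.frame(
      group_id = gid, gene_id = g$gene_id[1], chrom = g$chrom[1],
      gpos = g$gpos[1], strand = g$strand[1],
      iso_a = g$transcript_id[idx[1, ]], tx_pos_a = g$tx_pos[idx[1, ]],
      iso_b = g$transcript_id[idx[2, ]], tx_pos_b = g$tx_pos[idx[2, ]])
  }
  pairs <- do.call(rbind, pair_list)
  res_list <- list()
  for (r in sort(unique(counts$region))) {
    cr <- counts[counts$region == r, ]
    ka <- cr$k[match(paste(pairs$iso_a, pairs$tx_pos_a),
                     paste(cr$transcript_id, cr$tx_pos))]
    na <- cr$n[match(paste(pairs$iso_a, pairs$tx_pos_a),
                     paste(cr$transcript_id, cr$tx_pos))]
    kb <- cr$k[match(paste(pairs$iso_b, pairs$tx_pos_b),
                     paste(cr$transcript_id, cr$tx_pos))]
    nb <- cr$n[match(paste(pairs$iso_b, pairs$tx_pos_b),
                     paste(cr$transcript_id, cr$tx_pos))]
    ok <- !is.na(na) & !is.na(nb) & na > 0 & nb > 0
    if (sum(!ok) > 0L)
      message(r, ": skipped ", sum(!ok), " pair(s) with a member untested in the region")
    if (!any(ok)) next
    z <- two_prop_z(ka[ok], na[ok], kb[ok], nb[ok])
    out <- pairs[ok, , drop = FALSE]
    out$region <- r
    out$k_a <- ka[ok]; out$n_a <- na[ok]; out$k_b <- kb[ok]; out$n_b <- nb[ok]
    out$rate_a <- ka[ok] / na[ok]; out$rate_b <- kb[ok] / nb[ok]
    out$diff <- out$rate_a - out$rate_b
    out$z <- z$statistic
    out$p <- z$p_value
    ia <- match(paste(out$iso_a, out$tx_pos_a),
                paste(mem_key$transcript_id, mem_key$tx_pos))
    ib <- match(paste(out$iso_b, out$tx_pos_b),
                paste(mem_key$transcript_id, mem_key$tx_pos))
    out$d_dist_up <- mem_key$dist_up[ia] - mem_key$dist_up[ib]
    out$d_dist_down <- mem_key$dist_down[ia] - mem_key$dist_down[ib]
    out$tx_region_a <- mem_key$tx_region[ia]
    out$tx_region_b <- mem_key$tx_region[ib]
    res_list[[r]] <- out
  }
  results <- do.call(rbind, res_list)
  rownames(results) <- NULL
  results$fdr <- bh_fdr(results$p)
  results$significant <- results$fdr < alpha & abs(results$diff) > min_diff
  dm_iso <- unique(c(results$iso_a[results$significant],
                     results$iso_b[results$significant]))
  list(results = results, dm_isoforms = sort(dm_iso),
       n_groups = length(unique(groups$group_id)))
}

#' Structural regression for modification-rate differences
#'
#' OLS of the pairwise rate difference on the change in distance to the
#' downstream boundary, the change in distance to the upstream boundary, and a
#' 3'UTR-versus-CDS indicator (+1 when the first member sits in the 3'UTR and
#' the second in the CDS, -1 for the reverse, 0 otherwise). Zero-variance
#' predictors are dropped with a warning.
#'
#' @param dm_results The `results` data.frame from [within_gene_dm()] (or any
#'   data.frame with columns diff, d_dist_down, d_dist_up, tx_region_a,
#'   tx_region_b); at least 10 rows.
#' @return List with the fitted `lm` object, `coefficients`, `r_squared`,
#'   `p_value` (overall F), and the model data.
#' @export
dm_structure_model <- function(dm_results) {
  stopifnot(nrow(dm_results) >= 10L)
  df <- data.frame(
    diff = dm_results$diff,
    d_dist_down = dm_results$d_dist_down,
    d_dist_up = dm_results$d_dist_up,
    utr3_vs_cds = ifelse(dm_results$tx_region_a == "3UTR" &
                           dm_results$tx_region_b == "CDS", 1,
                         ifelse(dm_results$tx_region_a == "CDS" &
                                  dm_results$tx_region_b == "3UTR", -1, 0)))
  preds <- c("d_dist_down", "d_dist_up", "utr3_vs_cds")
  keep <- vapply(preds, function(p) stats::sd(df[[p]]) > 0, logical(1))
  if (any(!keep))
    warning("dropping zero-variance predictor(s): ",
            paste(preds[!keep], collapse = ", "))
  preds <- preds[keep]
  if (length(preds) == 0L) stop("no usable predictors")
  fit <- stats::lm(stats::reformulate(preds, response = "diff"), data = df)
  sm <- summary(fit)
  fp <- if (is.null(sm$fstatistic)) NA_real_ else
    stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
              lower.tail = FALSE)
  list(fit = fit, coefficients = stats::coef(sm), r_squared = sm$r.squared,
       p_value = unname(fp), data = df)
}

#' Between-region differential modification from an xPore-style table
#'
#' Filters differential rows to DRACH motifs, absolute rate difference above
#' `diff_thr`, BH-adjusted p below `alpha`, and corroboration by the site
#' tables: the site must have modification probability above `prob_thr` in at
#' least `min_samples` samples. The rate difference is
#' `rate_b - rate_a` with the region pair ordered alphabetically; `up_region`
#' records the region with the higher rate.
#'
#' @param xpore_table data.frame with transcript_id, transcript_position, kmer,
#'   region_a, region_b, rate_a, rate_b, diff_mod_rate (or computable), p_value.
#' @param calls Site calls (e.g. `catalog$calls`) used for corroboration.
#' @param diff_thr Minimum absolute rate difference (default 0.3).
#' @param alpha FDR threshold (default 0.05).
#' @param prob_thr Corroborating modification probability (default 0.7).
#' @param min_samples Corroborating sample count (default 2, i.e. > 1 sample).
#' @return List with `results` (kept rows with fdr, up_region), `n_input`,
#'   `n_excluded_uncorroborated`.
#' @export
between_region_dm <- function(xpore_table, calls, diff_thr = 0.3, alpha = 0.05,
                              prob_thr = 0.7, min_samples = 2L) {
  xt <- xpore_table
  if (!"diff_mod_rate" %in% names(xt))
    xt$diff_mod_rate <- xt$rate_b - xt$rate_a
  pair_swap <- xt$region_a > xt$region_b
  if (any(pair_swap)) {
    tmp_r <- xt$region_a[pair_swap]; tmp_v <- xt$rate_a[pair_swap]
    xt$region_a[pair_swap] <- xt$region_b[pair_swap]
    xt$region_b[pair_swap] <- tmp_r
    xt$rate_a[pair_swap] <- xt$rate_b[pair_swap]
    xt$rate_b[pair_swap] <- tmp_v
    xt$diff_mod_rate[pair_swap] <- -xt$diff_mod_rate[pair_swap]
  }
  n_input <- nrow(xt)
  xt <- xt[grepl(DRACH_REGEX, xt$kmer), , drop = FALSE]
  xt$fdr <- bh_fdr(xt$p_value)
  xt <- xt[abs(xt$diff_mod_rate) > diff_thr & xt$fdr < alpha, , drop = FALSE]
  dt <- data.table::as.data.table(calls)
  support <- dt[dt$prob_mod > prob_thr,
                list(n_support = .N), by = c("transcript_id", "tx_pos")]
  sup <- support$n_support[match(paste(xt$transcript_id, xt$transcript_position),
                                 paste(support$transcript_id, support$tx_pos))]
  corroborated <- !is.na(sup) & sup >= min_samples
  n_excl <- sum(!corroborated)
  xt <- xt[corroborated, , drop = FALSE]
  xt$up_region <- ifelse(xt$diff_mod_rate > 0, xt$region_b, xt$region_a)
  list(results = xt, n_input = n_input, n_excluded_uncorroborated = n_excl)
}

#' Direction summary of between-region DM sites
#'
#' Counts distinct DM sites (transcript, position) whose modification rate is
#' higher in `focus_region` in every pair involving it, and the percentage of
#' all DM sites they represent.
#'
#' @param dm_results `results` from [between_region_dm()], or any data.frame
#'   with transcript_id, transcript_position, up_region.
#' @param focus_region Region of interest (default `"CB"`).
#' @return List with `n_sites`, `n_up`, `pct_up` (2 decimals).
#' @export
dm_direction_summary <- function(dm_results, focus_region = "CB") {
  key <- paste(dm_results$transcript_id, dm_results$transcript_position)
  n_sites <- length(unique(key))
  up_key <- unique(key[dm_results$up_region == focus_region])
  down_key <- unique(key[dm_results$up_region != focus_region &
                           (dm_results$region_a == focus_region |
                              dm_results$region_b == focus_region)])
  n_up <- length(setdiff(up_key, down_key))
  list(n_sites = n_sites, n_up = n_up,
       pct_up = if (n_sites > 0) round(100 * n_up / n_sites, 2) else NA_real_)
}

#' Direction consistency of an isoform's DM sites
#'
#' For each isoform and region pair, classifies its differential sites as
#' `single` (one site), `consistent` (all signed differences agree), or
#' `opposing`.
#'
#' @param dm_results `results` from [between_region_dm()].
#' @return data.frame with transcript_id, region_a, region_b, n_sites, class.
#' @export
dm_direction_consistency <- function(dm_results) {
  dt <- data.table::as.data.table(dm_results)
  out <- dt[, list(
    n_sites = data.table::uniqueN(transcript_position),
    class = {
      s <- sign(diff_mod_rate)
      if (data.table::uniqueN(transcript_position) == 1L) "single"
      else if (length(unique(s)) == 1L) "consistent"
      else "opposing"
    }), by = c("transcript_id", "region_a", "region_b")]
  as.data.frame(out)
}
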