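# Consensus m6A site catalog: ingestion of per-sample site tables,
# high-confidence filtering, genomic lifting, and catalog-level summaries.

DRACH_REGEX <- "^[AGT][AG]AC[ACT]$"

#' Load a per-sample m6anet-style site table
#'
#' Reads a site table (tab- or comma-separated, autodetected) with columns
#' `transcript_id`, `transcript_position`, `n_reads`, `probability_modified`,
#' `kmer`, `mod_ratio`, validates each row and attaches the sample and region
#' labels. Rows with a non-DRACH 5-mer, fewer than 21 reads (sites are only
#' quantified at a coverage above 20 reads), or probabilities/ratios outside
#' \[0, 1\] are rejected; rejection counts are reported via `message()`.
#'
#' @param tsv_source Path to the table, or a data.frame already in memory.
#' @param sample_id,region Labels attached to every accepted row.
#' @param min_reads Minimum read coverage (default 21, i.e. more than 20 reads).
#' @return data.frame of validated calls with columns sample_id, region,
#'   transcript_id, tx_pos, n_reads, prob_mod, kmer, mod_ratio.
#' @export
load_site_table <- function(tsv_source, sample_id, region, min_reads = 21L) {
  df <- if (is.data.frame(tsv_source)) tsv_source else {
    header <- readLines(tsv_source, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
    utils::read.table(tsv_source, sep = sep, header = TRUE,
                      stringsAsFactors = FALSE)
  }
  required <- c("transcript_id", "transcript_position", "n_reads",
                "probability_modified", "kmer", "mod_ratio")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L)
    stop("site table is missing column(s): ", paste(missing_cols, collapse = ", "))
  n0 <- nrow(df)
  bad_kmer <- !grepl(DRACH_REGEX, df$kmer)
  low_cov <- df$n_reads < min_reads
  bad_prob <- df$probability_modified < 0 | df$probability_modified > 1 |
    df$mod_ratio < 0 | df$mod_ratio > 1 | df$transcript_position < 0
  keep <- !(bad_kmer | low_cov | bad_prob)
  n_rej <- sum(!keep)
  if (n_rej > 0L)
    message(sprintf("%s: rejected %d/%d rows (%d non-DRACH, %d low coverage, %d invalid values)",
                    sample_id, n_rej, n0, sum(bad_kmer), sum(low_cov & !bad_kmer),
                    sum(bad_prob & !bad_kmer & !low_cov)))
  out <- df[keep, required]
  data.frame(sample_id = sample_id, region = region,
             transcript_id = out$transcript_id,
             tx_pos = out$transcript_position,
             n_reads = out$n_reads,
             prob_mod = out$probability_modified,
             kmer = out$kmer,
             mod_ratio = out$mod_ratio,
             stringsAsFactors = FALSE)
}

#' Load all site tables of a simulated or real experiment
#'
#' @param meta data.frame with columns `sample_id`, `region` and either `path`
#'   (files on disk) or no path when `tables` supplies in-memory tables.
#' @param tables Optional named list of data.frames keyed by sample_id.
#' @param ... Passed to [load_site_table()].
#' @return Combined calls data.frame across all samples.
#' @export
load_site_tables <- function(meta, tables = NULL, ...) {
  out <- lapply(seq_len(nrow(meta)), function(i) {
    src <- if (!is.null(tables)) tables[[meta$sample_id[i]]] else meta$path[i]
    load_site_table(src, meta$sample_id[i], meta$region[i], ...)
  })
  do.call(rbind, out)
}

#' Build the high-confidence consensus catalog
#'
#' A transcriptomic site (transcript_id, tx_pos) enters the catalog iff its
#' modification probability strictly exceeds `prob_thr` in at least
#' `min_detect_samples` samples (the high-confidence rule: probability > 0.9
#' in more than one sample). Each catalog site carries its genomic lift and,
#' per region, the number of tested samples, the number of detecting samples,
#' and the unweighted mean modified-read ratio over tested samples.
#'
#' @param calls Combined calls from [load_site_tables()].
#' @param models `transcript_models` annotation; sites on transcripts absent
#'   from the annotation are excluded with a message.
#' @param prob_thr Detection probability threshold (strict inequality).
#' @param min_detect_samples Minimum number of detecting samples.
#' @return An `m6a_catalog`: list with `sites` (one row per consensus site),
#'   `region_stats` (per site and region), `calls`, `regions`, and the
#'   thresholds used.
#' @export
build_consensus <- function(calls, models, prob_thr = 0.9,
                            min_detect_samples = 2L) {
  dt <- data.table::as.data.table(calls)
  dt$det <- dt$prob_mod > prob_thr
  site_det <- dt[, list(n_detect = sum(det), kmer = kmer[1]),
                 by = c("transcript_id", "tx_pos")]
  keep <- site_det[site_det$n_detect >= min_detect_samples]
  known <- keep$transcript_id %in% names(models)
  if (any(!known)) {
    message("excluded ", sum(!known),
            " consensus site(s) on transcripts absent from the annotation")
    keep <- keep[known]
  }
  lift <- if (nrow(keep) > 0L) {
    data.table::rbindlist(lapply(split(keep, keep$transcript_id), function(s) {
      m <- models[[s$transcript_id[1]]]
      g <- tx_to_genome(m, s$tx_pos)
      data.table::data.table(transcript_id = s$transcript_id, tx_pos = s$tx_pos,
                             chrom = g$chrom, gpos = g$pos, strand = g$strand,
                             gene_id = m$gene_id)
    }))
  } else {
    data.table::data.table(transcript_id = character(0), tx_pos = numeric(0),
                           chrom = character(0), gpos = numeric(0),
                           strand = character(0), gene_id = character(0))
  }
  sites <- merge(keep, lift, by = c("transcript_id", "tx_pos"), sort = TRUE)
  site_key <- paste(sites$transcript_id, sites$tx_pos)
  dt_kept <- dt[paste(dt$transcript_id, dt$tx_pos) %in% site_key]
  region_stats <- dt_kept[, list(n_tested = .N, n_detected = sum(det),
                                 rate = mean(mod_ratio)),
                          by = c("transcript_id", "tx_pos", "region")]
  structure(list(sites = sites, region_stats = region_stats,
                 calls = dt, regions = sort(unique(dt$region)),
                 prob_thr = prob_thr, min_detect_samples = min_detect_samples),
            class = "m6a_catalog")
}

#' @export
print.m6a_catalog <- function(x, ...) {
  cat(sprintf("<m6a_catalog> %d consensus site(s) on %d isoform(s); regions: %s (prob > %g in >= %d samples)\n",
              nrow(x$sites), length(unique(x$sites$transcript_id)),
              paste(x$regions, collapse = ", "), x$prob_thr,
              x$min_detect_samples))
  invisible(x)
}

#' Per-site reproducibility classes and catalog-level percentages
#'
#' For every catalog site and region, reports the number of samples the site
#' was detected in; the catalog summary gives the number and percentage of
#' sites detected in at least `k_high` samples of some region (the
#' reproducibility headline: sites consistently identified in at least three
#' samples of a brain region).
#'
#' @param catalog An `m6a_catalog`, or a data.frame with columns
#'   `site` and `max_k` (per-site maximum detecting samples in a region) for
#'   summary-only use.
#' @param k_high Reproducibility class threshold (default 3).
#' @return List with `per_site` (site, region, k), `n_sites`, `n_high`,
#'   `pct_high` (rounded to whole percent as conventionally printed).
#' @export
region_detection_summary <- function(catalog, k_high = 3L) {
  if (is.data.frame(catalog)) {
    per_site <- NULL
    max_k <- catalog$max_k
    n_sites <- nrow(catalog)
  } else {
    rs <- catalog$region_stats
    per_site <- rs[, c("transcript_id", "tx_pos", "region", "n_detected"), with = FALSE]
    if (nrow(rs) == 0L) {
      return(list(per_site = per_site, n_sites = 0L, n_high = 0L,
                  pct_high = NA_real_))
    }
    mk <- rs[, list(max_k = max(n_detected)), by = c("transcript_id", "tx_pos")]
    max_k <- mk$max_k
    n_sites <- nrow(mk)
  }
  if (n_sites == 0L)
    return(list(per_site = per_site, n_sites = 0L, n_high = 0L,
                pct_high = NA_real_))
  n_high <- sum(max_k >= k_high)
  list(per_site = per_site, n_sites = n_sites, n_high = n_high,
       pct_high = round(100 * n_high / n_sites))
}

#' Mean modification rate of a catalog site in one region
#'
#' Unweighted mean of the modified-read ratio over the region's tested samples
#' (tested, not only detecting, to avoid conditioning on detection).
#'
#' @param catalog An `m6a_catalog`.
#' @param transcript_id,tx_pos Site identity.
#' @param region Region label.
#' @return The rate, or NA if the site was not tested in that region.
#' @export
site_region_rate <- function(catalog, transcript_id, tx_pos, region) {
  rs <- catalog$region_stats
  hit <- rs$transcript_id == transcript_id & rs$tx_pos == tx_pos &
    rs$region == region
  if (!any(hit)) return(NA_real_)
  rs$rate[hit][1]
}

#' DRACH motif composition of modified versus tested sites
#'
#' Proportions of each of the 18 DRACH 5-mers among all tested sites and among
#' consensus m6A sites, with a pooled two-proportion z test per motif
#' (BH-adjusted across motifs).
#'
#' @param catalog An `m6a_catalog`.
#' @param tested Optional data.frame of tested sites with a `kmer` column and
#'   site identity columns `transcript_id`, `tx_pos`; defaults to the unique
#'   tested sites in the catalog's calls.
#' @return data.frame with per-motif counts, proportions, z, p, fdr.
#' @export
motif_summary <- function(catalog, tested = NULL) {
  if (is.null(tested)) {
    tested <- unique(as.data.frame(
      catalog$calls[, c("transcript_id", "tx_pos", "kmer"), with = FALSE]))
  }
  stopifnot(nrow(tested) > 0L, nrow(catalog$sites) > 0L)
  n_tested <- nrow(tested)
  n_mod <- nrow(catalog$sites)
  k_tested <- vapply(DRACH_MOTIFS, function(m) sum(tested$kmer == m), numeric(1))
  k_mod <- vapply(DRACH_MOTIFS, function(m) sum(catalog$sites$kmer == m), numeric(1))
  z <- two_prop_z(k_mod, n_mod, k_tested, n_tested)
  out <- data.frame(kmer = DRACH_MOTIFS,
                    n_modified = k_mod, prop_modified = k_mod / n_mod,
                    n_tested = k_tested, prop_tested = k_tested / n_tested,
                    statistic = z$statistic, p_value = z$p_value)
  out$fdr <- bh_fdr(out$p_value)
  out[order(-out$prop_modified), ]
}

#' Spike-in negative control check
#'
#' Counts spike-in (SIRV) DRACH sites called modified above the probability
#' threshold in any sample; any such site raises a QC flag, since spike-ins
#' carry no m6A.
#'
#' @param calls Calls data.frame restricted to (or containing) spike-in rows.
#' @param prob_thr Detection threshold.
#' @param sirv_pattern Regex identifying spike-in transcript ids.
#' @return List with `n_modified`, `n_sites_tested`, `qc_pass`.
#' @export
sirv_negative_control <- function(calls, prob_thr = 0.9,
                                  sirv_pattern = "^SIRV") {
  sv <- calls[grepl(sirv_pattern, calls$transcript_id), , drop = FALSE]
  if (nrow(sv) == 0L)
    return(list(n_modified = 0L, n_sites_tested = 0L, qc_pass = TRUE))
  key <- paste(sv$transcript_id, sv$tx_pos)
  hot <- unique(key[sv$prob_mod > prob_thr])
  list(n_modified = length(hot), n_sites_tested = length(unique(key)),
       qc_pass = length(hot) == 0L)
}

#' Lower-bound estimate of the fraction of reads carrying an m6A site
#'
#' Per isoform, the probability that a read carries at least one modified
#' site is approximated under within-isoform independence of sites as
#' `1 - prod(1 - rate_s)` over the isoform's consensus sites (site rate =
#' mean modified-read ratio over all tested samples). The returned estimate is
#' the read-support-weighted mean over all isoforms tested for modification
#' (isoforms with no consensus site contribute zero), with weight equal to the
#' summed per-sample median site coverage of the isoform. Per-read
#' co-modification is not observable in site-level summaries, so this is an
#' explicit approximation, biased low.
#'
#' @param catalog An `m6a_catalog`.
#' @return List with `fraction` and the per-isoform table.
#' @export
estimate_modified_read_fraction <- function(catalog) {
  calls <- catalog$calls
  support <- calls[, list(weight = as.numeric(
    sum(tapply(n_reads, sample_id, stats::median)))), by = "transcript_id"]
  site_rate <- calls[paste(calls$transcript_id, calls$tx_pos) %in%
                       paste(catalog$sites$transcript_id, catalog$sites$tx_pos)]
  site_rate <- site_rate[, list(rate = mean(mod_ratio)),
                         by = c("transcript_id", "tx_pos")]
  p_iso <- site_rate[, list(p_any = 1 - prod(1 - rate)), by = "transcript_id"]
  tab <- merge(support, p_iso, by = "transcript_id", all.x = TRUE)
  tab$p_any[is.na(tab$p_any)] <- 0
  list(fraction = sum(tab$weight * tab$p_any) / sum(tab$weight),
       per_isoform = as.data.frame(tab))
}

#' Intersect catalog genomic sites with an external site list
#'
#' Flags each distinct genomic site of the catalog as previously annotated iff
#' it matches a position in the external list (exact chrom/pos match,
#' strand-aware when the external list carries strand).
#'
#' @param catalog An `m6a_catalog`, or a data.frame with `chrom`, `pos`
#'   (and optionally `strand`) giving genomic sites directly.
#' @param external data.frame with `chrom`, `pos`, optional `strand`.
#' @return List with `per_site` (annotated flag per distinct genomic site),
#'   `n_sites`, `n_annotated`, `pct_annotated` (rounded to 2 decimals).
#' @export
intersect_external_catalog <- function(catalog, external) {
  sites <- if (is.data.frame(catalog)) catalog else
    data.frame(chrom = catalog$sites$chrom, pos = catalog$sites$gpos,
               strand = catalog$sites$strand)
  use_strand <- "strand" %in% names(external) && "strand" %in% names(sites)
  keyify <- function(df) {
    if (use_strand) paste(df$chrom, df$pos, df$strand)
    else paste(df$chrom, df$pos)
  }
  sites <- sites[!duplicated(keyify(sites)), , drop = FALSE]
  annotated <- keyify(sites) %in% keyify(external)
  n <- nrow(sites)
  list(per_site = cbind(sites, annotated = annotated),
       n_sites = n, n_annotated = sum(annotated),
       pct_annotated = if (n > 0) round(100 * sum(annotated) / n, 2) else NA_real_)
}
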