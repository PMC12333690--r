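# Per-isoform modification load, length/exon-density normalisation via
# regression residuals, and hypermodified / unmodified isoform selection.

#' Per-isoform modification load in a region
#'
#' Counts the isoform's consensus sites detected in the region and sums their
#' per-region modification rates (mean modified-read ratio over the region's
#' tested samples).
#'
#' @param catalog An `m6a_catalog`.
#' @param region Region label.
#' @return data.frame with transcript_id, n_sites, sum_rate.
#' @export
isoform_mod_load <- function(catalog, region) {
  rs <- as.data.frame(catalog$region_stats)
  rs <- data.table::as.data.table(rs[rs$region == region & rs$n_detected > 0, ])
  if (nrow(rs) == 0L)
    return(data.frame(transcript_id = character(0), n_sites = integer(0),
                      sum_rate = numeric(0)))
  agg <- rs[, list(n_sites = .N, sum_rate = sum(rate)), by = "transcript_id"]
  as.data.frame(agg)
}

#' Build per-isoform modification profiles for a region
#'
#' Joins the region's modification load with the structural covariates from
#' the annotation (spliced length, exon density, 3'UTR length). Only isoforms
#' with at least one site detected in the region are profiled.
#'
#' @param catalog An `m6a_catalog`.
#' @param models `transcript_models` annotation.
#' @param region Region label.
#' @return data.frame with isoform_id, region, n_sites, sum_rate, length,
#'   exon_density, utr3_length.
#' @export
build_mod_profiles <- function(catalog, models, region) {
  load <- isoform_mod_load(catalog, region)
  load <- load[load$transcript_id %in% names(models), , drop = FALSE]
  info <- models_summary(models[load$transcript_id])
  data.frame(isoform_id = load$transcript_id, region = region,
             n_sites = load$n_sites, sum_rate = load$sum_rate,
             length = info$length[match(load$transcript_id, info$transcript_id)],
             exon_density = info$exon_density[match(load$transcript_id, info$transcript_id)],
             utr3_length = info$utr3_length[match(load$transcript_id, info$transcript_id)])
}

#' Normalise modification load for isoform length and exon density
#'
#' Ordinary least squares of the summed modification rate on spliced length
#' and exon density (with intercept); the residual is the normalised
#' modification score. A predictor with zero variance is dropped with a
#' warning rather than producing a rank-deficient fit.
#'
#' @param profiles Output of [build_mod_profiles()] (>= 3 rows).
#' @return `profiles` with an added `norm_score` column.
#' @export
normalize_m6a <- function(profiles) {
  stopifnot(nrow(profiles) >= 3L)
  preds <- c("length", "exon_density")
  keep <- vapply(preds, function(p) stats::sd(profiles[[p]]) > 0, logical(1))
  if (any(!keep))
    warning("dropping zero-variance predictor(s): ",
            paste(preds[!keep], collapse = ", "))
  preds <- preds[keep]
  if (length(preds) == 0L) {
    fit <- stats::lm(sum_rate ~ 1, data = profiles)
  } else {
    fit <- stats::lm(stats::reformulate(preds, response = "sum_rate"),
                     data = profiles)
  }
  profiles$norm_score <- stats::residuals(fit)
  profiles
}

#' Select the hypermodified isoforms of a region
#'
#' The top `top_n` isoforms by normalised modification score, with a
#' deterministic tie-break (norm_score desc, sum_rate desc, isoform_id asc).
#' Returns all eligible isoforms when fewer than `top_n` are available.
#'
#' @param profiles Scored profiles from [normalize_m6a()].
#' @param top_n Number of isoforms to select (default 500 per region).
#' @return data.frame of selected profiles, ranked.
#' @export
select_hypermodified <- function(profiles, top_n = 500L) {
  stopifnot("norm_score" %in% names(profiles))
  o <- order(-profiles$norm_score, -profiles$sum_rate, profiles$isoform_id)
  out <- profiles[o, , drop = FALSE]
  out <- utils::head(out, top_n)
  out$rank <- seq_len(nrow(out))
  out
}

#' Multi-region consistency of hypermodified selections
#'
#' Given per-region hypermodified selections, reports the size of their union
#' and the number and percentage of isoforms selected in more than one region.
#'
#' @param selections Named list (by region) of outputs of
#'   [select_hypermodified()], or of character vectors of isoform ids.
#' @return List with `n_union`, `n_multi`, `pct_multi` (2 decimals).
#' @export
hypermod_consistency <- function(selections) {
  ids <- lapply(selections, function(s)
    if (is.data.frame(s)) s$isoform_id else as.character(s))
  all_ids <- unlist(ids)
  tab <- table(all_ids)
  n_union <- length(tab)
  n_multi <- sum(tab > 1L)
  list(n_union = n_union, n_multi = n_multi,
       pct_multi = if (n_union > 0) round(100 * n_multi / n_union, 2) else NA_real_)
}

#' Select unmodified isoforms with adequate detection coverage
#'
#' Isoforms with zero consensus m6A sites that were nonetheless testable:
#' more than one distinct DRACH site quantified, and a modification
#' probability below 0.5 at every tested site in every sample.
#'
#' @param catalog An `m6a_catalog`.
#' @param min_tested Minimum distinct tested sites (default 2, i.e. > 1).
#' @param max_prob Probability ceiling across all tested sites and samples.
#' @return Character vector of isoform ids.
#' @export
select_unmodified <- function(catalog, min_tested = 2L, max_prob = 0.5) {
  calls <- catalog$calls
  per_iso <- calls[, list(n_tested = data.table::uniqueN(tx_pos),
                          p_max = max(prob_mod)), by = "transcript_id"]
  modified <- unique(catalog$sites$transcript_id)
  out <- per_iso[per_iso$n_tested >= min_tested & per_iso$p_max < max_prob &
                   !per_iso$transcript_id %in% modified, ]
  sort(out$transcript_id)
}
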