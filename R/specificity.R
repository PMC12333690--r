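# Common versus region-specific modification of genes and isoforms,
# expression-aware adjustment, and summary tables.

#' Classify features as commonly or region-specifically modified
#'
#' A site is "detected in a region" when its modification probability exceeded
#' the threshold in at least one sample of the region. At the isoform level a
#' feature is `common` iff at least one single site is detected in all
#' regions (not a union across sites), `specific` iff the union of regions
#' over all its sites has exactly one element, and `multi` otherwise. At the
#' gene level the site identity is genomic (chrom, pos, strand), with
#' per-region detection unioned over the member isoforms carrying the site.
#' A secondary column `union_common` records whether the union of regions
#' across sites covers all regions, for transparency.
#'
#' @param catalog An `m6a_catalog`.
#' @param level `"isoform"` or `"gene"`.
#' @param regions Region universe to classify against; defaults to the regions
#'   present in the catalog. Passing the full design explicitly keeps labels
#'   comparable when a region's samples are absent from the input.
#' @return data.frame with feature_id, level, regions_modified
#'   (comma-collapsed), n_regions, label, union_common.
#' @export
classify_specificity <- function(catalog, level = c("isoform", "gene"),
                                 regions = NULL) {
  level <- match.arg(level)
  rs <- catalog$region_stats[catalog$region_stats$n_detected > 0, ]
  all_regions <- if (is.null(regions)) catalog$regions else regions
  key <- catalog$sites
  if (level == "isoform") {
    rs$feature_id <- rs$transcript_id
    rs$site <- paste(rs$transcript_id, rs$tx_pos)
  } else {
    idx <- match(paste(rs$transcript_id, rs$tx_pos),
                 paste(key$transcript_id, key$tx_pos))
    rs$feature_id <- key$gene_id[idx]
    rs$site <- paste(key$chrom[idx], key$gpos[idx], key$strand[idx])
  }
  dt <- data.table::as.data.table(rs)
  site_reg <- dt[, list(n_reg_site = data.table::uniqueN(region)),
                 by = c("feature_id", "site")]
  per_feat <- dt[, list(
    regions_modified = paste(sort(unique(region)), collapse = ","),
    n_regions = data.table::uniqueN(region)), by = "feature_id"]
  full <- site_reg[, list(has_full_site = any(n_reg_site == length(all_regions))),
                   by = "feature_id"]
  out <- merge(per_feat, full, by = "feature_id")
  out$label <- ifelse(out$has_full_site, "common",
                      ifelse(out$n_regions == 1L, "specific", "multi"))
  out$union_common <- out$n_regions == length(all_regions)
  out$level <- level
  as.data.frame(out[, c("feature_id", "level", "regions_modified", "n_regions",
                        "label", "union_common"), with = FALSE])
}

# is feature up-regulated in `region` versus BOTH other regions?
# DE comparisons are "A_vs_B" with positive logFC meaning up in A.
feature_up_in_region <- function(feature_id, region, de, all_regions,
                                 alpha = 0.05) {
  others <- setdiff(all_regions, region)
  de_f <- de[de$feature_id == feature_id, , drop = FALSE]
  if (nrow(de_f) == 0L) return(NA)
  for (o in others) {
    fwd <- de_f$comparison == paste0(region, "_vs_", o)
    rev <- de_f$comparison == paste0(o, "_vs_", region)
    up <- (any(fwd & de_f$logFC > 0 & de_f$adj_p < alpha)) ||
      (any(rev & de_f$logFC < 0 & de_f$adj_p < alpha))
    if (!up) return(FALSE)
  }
  TRUE
}

#' Net expression-driven specificity out of region-specific calls
#'
#' A region-specific feature is flagged `expression_driven` iff it is
#' significantly up-regulated (adjusted p < `alpha`, positive effect) in its
#' region versus both other regions. Features absent from the DE tables get
#' `expression_driven = NA` and count as not up-regulated (conservative toward
#' region-specific modification), with a message. The summary reports, per
#' region, the number of specific features, the number not up-regulated, and
#' the rounded percentage.
#'
#' @param calls Output of [classify_specificity()].
#' @param de_records DE data.frame with feature_id, comparison (`"A_vs_B"`),
#'   logFC, adj_p.
#' @param regions All region labels.
#' @param alpha Significance threshold.
#' @return List with `calls` (input plus `expression_driven`) and `summary`
#'   (region, n_specific, n_up, n_not_up, pct_not_up).
#' @export
expression_adjusted_specificity <- function(calls, de_records, regions,
                                            alpha = 0.05) {
  spec <- calls$label == "specific"
  ed <- rep(NA, nrow(calls))
  n_missing <- 0L
  for (i in which(spec)) {
    r <- calls$regions_modified[i]
    up <- feature_up_in_region(calls$feature_id[i], r, de_records, regions, alpha)
    if (is.na(up)) n_missing <- n_missing + 1L
    ed[i] <- up
  }
  if (n_missing > 0L)
    message(n_missing, " specific feature(s) absent from DE tables; treated as not up-regulated")
  calls$expression_driven <- ed
  sdf <- calls[spec, , drop = FALSE]
  summary <- do.call(rbind, lapply(regions, function(r) {
    in_r <- sdf$regions_modified == r
    n <- sum(in_r)
    n_up <- sum(in_r & !is.na(sdf$expression_driven) & sdf$expression_driven)
    data.frame(region = r, n_specific = n, n_up = n_up, n_not_up = n - n_up,
               pct_not_up = if (n > 0) round(100 * (n - n_up) / n) else NA_real_)
  }))
  list(calls = calls, summary = summary)
}

#' Summarise DE/DEI/DIU tables per region
#'
#' Per region: the number of up-regulated genes (DEG) and isoforms (DEI; up
#' means significant with positive effect versus both other regions), DEIs
#' whose gene is not a DEG (count and percentage), isoforms and genes with
#' differential isoform usage (dIF > 0.2 and adjusted p < 0.05 applied here),
#' DIU genes without an up-regulated DEG, and DIU isoforms that are not DEIs.
#'
#' @param de_gene,de_isoform DE data.frames (feature_id, comparison, logFC, adj_p).
#' @param diu data.frame with isoform_id, gene_id, region, dIF, adj_p.
#' @param iso_gene_map data.frame mapping `transcript_id` to `gene_id`.
#' @param regions Region labels.
#' @param alpha,dif_thr Significance and usage-change thresholds.
#' @return data.frame, one row per region.
#' @export
summarize_de_tables <- function(de_gene, de_isoform, diu, iso_gene_map,
                                regions, alpha = 0.05, dif_thr = 0.2) {
  up_set <- function(de, r) {
    out <- NULL
    for (o in setdiff(regions, r)) {
      sig <- (de$comparison == paste0(r, "_vs_", o) & de$logFC > 0 &
                de$adj_p < alpha) |
        (de$comparison == paste0(o, "_vs_", r) & de$logFC < 0 &
           de$adj_p < alpha)
      ids <- unique(de$feature_id[sig])
      out <- if (is.null(out)) ids else intersect(out, ids)
    }
    out
  }
  pct <- function(num, den) if (den > 0) round(100 * num / den, 2) else NA_real_
  do.call(rbind, lapply(regions, function(r) {
    deg <- up_set(de_gene, r)
    dei <- up_set(de_isoform, r)
    dei_genes <- iso_gene_map$gene_id[match(dei, iso_gene_map$transcript_id)]
    dei_no_deg <- sum(!dei_genes %in% deg)
    du <- diu[diu$region == r & diu$dIF > dif_thr & diu$adj_p < alpha, , drop = FALSE]
    diu_iso <- unique(du$isoform_id)
    diu_gene <- unique(du$gene_id)
    data.frame(region = r,
               n_deg = length(deg), n_dei = length(dei),
               dei_no_deg = dei_no_deg, pct_dei_no_deg = pct(dei_no_deg, length(dei)),
               n_diu_gene = length(diu_gene), n_diu_iso = length(diu_iso),
               diu_gene_no_deg = sum(!diu_gene %in% deg),
               pct_diu_gene_no_deg = pct(sum(!diu_gene %in% deg), length(diu_gene)),
               diu_iso_no_dei = sum(!diu_iso %in% dei),
               pct_diu_iso_no_dei = pct(sum(!diu_iso %in% dei), length(diu_iso)))
  }))
}

#' Compare positional distributions of two site classes
#'
#' Two-sample Kolmogorov-Smirnov test on metagene coordinates of two site
#' classes (e.g. region-specific versus common sites).
#'
#' @param pos_a,pos_b Numeric metagene positions, each with at least 2 values.
#' @return data.frame with `statistic` (D), `p_value`, `n1`, `n2`.
#' @export
positional_class_compare <- function(pos_a, pos_b) {
  pos_a <- pos_a[!is.na(pos_a)]; pos_b <- pos_b[!is.na(pos_b)]
  if (length(pos_a) < 2L || length(pos_b) < 2L)
    stop("each site class needs at least 2 positions")
  kt <- suppressWarnings(stats::ks.test(pos_a, pos_b))
  data.frame(statistic = unname(kt$statistic), p_value = kt$p.value,
             n1 = length(pos_a), n2 = length(pos_b))
}
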