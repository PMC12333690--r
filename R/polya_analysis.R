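# Poly(A) tail length analysis: per-read loading, per-isoform summaries,
# global and differential (DPL) tests, and dynamic-tail ranking.

#' Load a per-sample nanopolish-style poly(A) table
#'
#' Keeps only reads with a `PASS` QC tag and positive tail length, attaches
#' sample and region labels, and drops mitochondrial isoforms (contig or
#' annotated chromosome in `chrM`/`MT`), which have systematically shorter
#' tails and are excluded from tail analyses.
#'
#' @param tsv_source Path to the table or a data.frame with at least columns
#'   `readname`, `contig`, `polya_length`, `qc_tag` (the contig is the
#'   isoform for transcriptome alignments).
#' @param sample_id,region Labels attached to each record.
#' @param models Optional `transcript_models`; when given, isoforms annotated
#'   on a mitochondrial contig are also excluded.
#' @return data.frame with read_id, sample_id, region, isoform_id, polya_length.
#' @export
load_polya <- function(tsv_source, sample_id, region, models = NULL) {
  df <- if (is.data.frame(tsv_source)) tsv_source else
    utils::read.table(tsv_source, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  required <- c("readname", "contig", "polya_length", "qc_tag")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L)
    stop("poly(A) table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  keep <- df$qc_tag == "PASS" & df$polya_length > 0
  mito_contigs <- c("chrM", "MT")
  mito <- df$contig %in% mito_contigs
  if (!is.null(models)) {
    chrom <- vapply(models, `[[`, character(1), "chrom")
    mito_iso <- names(models)[chrom %in% mito_contigs]
    mito <- mito | df$contig %in% mito_iso
  }
  out <- df[keep & !mito, , drop = FALSE]
  data.frame(read_id = out$readname, sample_id = sample_id, region = region,
             isoform_id = out$contig, polya_length = out$polya_length,
             stringsAsFactors = FALSE)
}

#' Load all poly(A) tables of an experiment
#'
#' @param meta data.frame with `sample_id`, `region` and either `path` or
#'   in-memory `tables`.
#' @param tables Optional named list of data.frames keyed by sample_id.
#' @param ... Passed to [load_polya()].
#' @return Combined records across samples.
#' @export
load_polya_tables <- function(meta, tables = NULL, ...) {
  out <- lapply(seq_len(nrow(meta)), function(i) {
    src <- if (!is.null(tables)) tables[[meta$sample_id[i]]] else meta$path[i]
    load_polya(src, meta$sample_id[i], meta$region[i], ...)
  })
  do.call(rbind, out)
}

#' Per-isoform, per-sample poly(A) summaries
#'
#' Median and interquartile range of tail length per (isoform, sample), kept
#' only with more than 5 supporting reads. Quantiles use linear interpolation
#' between order statistics (R type 7), the declared convention.
#'
#' @param records Output of [load_polya_tables()].
#' @param min_reads Minimum reads per isoform per sample (default 6, i.e. > 5).
#' @return data.frame with isoform_id, sample_id, region, n_reads,
#'   median_length, iqr.
#' @export
summarize_polya <- function(records, min_reads = 6L) {
  dt <- data.table::as.data.table(records)
  out <- dt[, list(region = region[1], n_reads = .N,
                   median_length = stats::median(polya_length),
                   iqr = stats::IQR(polya_length, type = 7)),
            by = c("isoform_id", "sample_id")]
  out <- out[out$n_reads >= min_reads, ]
  as.data.frame(out[order(out$isoform_id, out$sample_id), ])
}

#' Global poly(A) length comparison between regions
#'
#' Mann-Whitney U test on the per-(isoform, sample) median tail lengths for
#' every region pair (medians, not raw reads, so highly expressed isoforms do
#' not dominate), with the signed difference of group medians.
#'
#' @param summaries Output of [summarize_polya()].
#' @return data.frame with region_a, region_b, n_a, n_b, median_a, median_b,
#'   median_diff (a minus b), statistic, p_value.
#' @export
global_region_test <- function(summaries) {
  regions <- sort(unique(summaries$region))
  stopifnot(length(regions) >= 2L)
  pairs <- utils::combn(regions, 2L)
  do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    xa <- summaries$median_length[summaries$region == a]
    xb <- summaries$median_length[summaries$region == b]
    tst <- mwu(xa, xb)
    data.frame(region_a = a, region_b = b, n_a = length(xa), n_b = length(xb),
               median_a = stats::median(xa), median_b = stats::median(xb),
               median_diff = stats::median(xa) - stats::median(xb),
               statistic = tst$statistic, p_value = tst$p_value)
  }))
}

dpl_test_pairs <- function(grp_a, grp_b, labels, min_diff) {
  tst <- mwu(grp_a, grp_b)
  med_diff <- stats::median(grp_a) - stats::median(grp_b)
  cbind(labels,
        data.frame(n_a = length(grp_a), n_b = length(grp_b),
                   median_a = stats::median(grp_a), median_b = stats::median(grp_b),
                   median_diff = med_diff, statistic = tst$statistic,
                   p_value = tst$p_value))
}

#' Differential poly(A) length between isoforms of a gene
#'
#' Within each region and gene, compares per-read tail lengths (pooled over
#' the region's samples) between every pair of isoforms with more than 50
#' reads each, using the Mann-Whitney U test. P-values are BH-adjusted over
#' all tests; a pair is a differential-poly(A)-length (DPL) call iff FDR <
#' `alpha` and the absolute median difference exceeds `min_diff` nt.
#'
#' @param records Per-read records from [load_polya_tables()].
#' @param iso_gene_map data.frame with `transcript_id`, `gene_id`.
#' @param min_reads Minimum pooled reads per isoform per region (default 51).
#' @param min_diff Minimum absolute median difference in nt (default 20).
#' @param alpha FDR threshold.
#' @return data.frame of pairwise tests with `fdr` and `significant`.
#' @export
within_gene_dpl <- function(records, iso_gene_map, min_reads = 51L,
                            min_diff = 20, alpha = 0.05) {
  dt <- data.table::as.data.table(records)
  dt$gene_id <- iso_gene_map$gene_id[match(dt$isoform_id,
                                           iso_gene_map$transcript_id)]
  dt <- dt[!is.na(dt$gene_id), ]
  eligible <- dt[, list(n = .N), by = c("region", "gene_id", "isoform_id")]
  eligible <- eligible[eligible$n >= min_reads, ]
  res <- list()
  for (r in sort(unique(eligible$region))) {
    er <- eligible[eligible$region == r, ]
    for (g in unique(er$gene_id)) {
      isos <- sort(er$isoform_id[er$gene_id == g])
      if (length(isos) < 2L) next
      reads <- lapply(isos, function(i)
        dt$polya_length[dt$region == r & dt$isoform_id == i])
      names(reads) <- isos
      idx <- utils::combn(length(isos), 2L)
      for (j in seq_len(ncol(idx))) {
        a <- isos[idx[1, j]]; b <- isos[idx[2, j]]
        res[[length(res) + 1L]] <- dpl_test_pairs(
          reads[[a]], reads[[b]],
          data.frame(region = r, gene_id = g, iso_a = a, iso_b = b), min_diff)
      }
    }
  }
  if (length(res) == 0L) return(NULL)
  out <- do.call(rbind, res)
  out$fdr <- bh_fdr(out$p_value)
  out$significant <- out$fdr < alpha & abs(out$median_diff) > min_diff
  out
}

#' Differential poly(A) length of the same isoform between regions
#'
#' For every isoform and region pair with more than 50 pooled reads in each
#' region, compares per-read tail lengths with the Mann-Whitney U test, with
#' the same FDR and effect-size gates as [within_gene_dpl()].
#'
#' @inheritParams within_gene_dpl
#' @return data.frame of pairwise tests with `fdr` and `significant`.
#' @export
between_region_dpl <- function(records, min_reads = 51L, min_diff = 20,
                               alpha = 0.05) {
  dt <- data.table::as.data.table(records)
  eligible <- dt[, list(n = .N), by = c("region", "isoform_id")]
  eligible <- eligible[eligible$n >= min_reads, ]
  res <- list()
  for (iso in sort(unique(eligible$isoform_id))) {
    regs <- sort(eligible$region[eligible$isoform_id == iso])
    if (length(regs) < 2L) next
    idx <- utils::combn(length(regs), 2L)
    for (j in seq_len(ncol(idx))) {
      a <- regs[idx[1, j]]; b <- regs[idx[2, j]]
      res[[length(res) + 1L]] <- dpl_test_pairs(
        dt$polya_length[dt$isoform_id == iso & dt$region == a],
        dt$polya_length[dt$isoform_id == iso & dt$region == b],
        data.frame(isoform_id = iso, region_a = a, region_b = b), min_diff)
    }
  }
  if (length(res) == 0L) return(NULL)
  out <- do.call(rbind, res)
  out$fdr <- bh_fdr(out$p_value)
  out$significant <- out$fdr < alpha & abs(out$median_diff) > min_diff
  out
}

#' Rank isoforms by poly(A) tail variability
#'
#' Interquartile range of the pooled per-read tail lengths of each isoform
#' with more than 50 reads in the region; the top `top_n` by IQR are returned
#' with a deterministic tie-break (IQR desc, read count desc, isoform_id asc).
#'
#' @param records Per-read records.
#' @param region Region label.
#' @param min_reads Minimum pooled reads (default 51).
#' @param top_n Number of isoforms to report (default 250).
#' @return data.frame with isoform_id, n_reads, iqr, rank.
#' @export
dynamic_polya <- function(records, region, min_reads = 51L, top_n = 250L) {
  sel <- records$region == region
  dt <- data.table::as.data.table(as.data.frame(records)[sel, , drop = FALSE])
  agg <- dt[, list(n_reads = .N, iqr = stats::IQR(polya_length, type = 7)),
            by = "isoform_id"]
  agg <- agg[agg$n_reads >= min_reads, ]
  out <- as.data.frame(agg[order(-agg$iqr, -agg$n_reads, agg$isoform_id), ])
  out <- utils::head(out, top_n)
  if (nrow(out) > 0L) out$rank <- seq_len(nrow(out))
  out
}
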