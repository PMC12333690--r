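# Transcript models and coordinate services.
#
# Internal conventions (documented at the I/O seam):
#  - genomic exon intervals are 0-based half-open, sorted by genomic start;
#  - transcript (spliced) offsets are 0-based, matching m6anet's
#    transcript_position; on the minus strand offset 0 is the highest genomic
#    coordinate of the genomically-last exon;
#  - GTF input/output is 1-based inclusive and converted on read/write.

#' Construct a transcript model
#'
#' @param transcript_id,gene_id Identifiers.
#' @param chrom Chromosome / contig name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix (start, end) of 0-based half-open genomic
#'   exon intervals, ascending by start, non-overlapping, positive width.
#' @param cds_span Optional `c(start, end)` pair of 0-based spliced offsets
#'   (end exclusive) delimiting the coding region, stop codon included.
#' @param biotype Transcript biotype label.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons,
                             cds_span = NULL, biotype = NA_character_) {
  exons <- matrix(as.numeric(exons), ncol = 2)
  if (nrow(exons) < 1L) stop("transcript ", transcript_id, " has zero exons")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  widths <- exons[, 2] - exons[, 1]
  if (any(widths <= 0)) stop("exons must have positive length")
  if (is.unsorted(exons[, 1], strictly = TRUE) && nrow(exons) > 1L)
    stop("exons must be sorted ascending by genomic start")
  if (nrow(exons) > 1L && any(exons[-1, 1] < exons[-nrow(exons), 2]))
    stop("exons must not overlap")
  tx_lens <- if (strand == "+") widths else rev(widths)
  cum <- cumsum(tx_lens)
  L <- cum[length(cum)]
  if (!is.null(cds_span)) {
    cds_span <- as.numeric(cds_span)
    if (length(cds_span) != 2L || cds_span[1] < 0 || cds_span[1] >= cds_span[2] ||
        cds_span[2] > L)
      stop("cds_span must satisfy 0 <= start < end <= spliced_length")
  }
  structure(list(
    transcript_id = transcript_id, gene_id = gene_id, chrom = chrom,
    strand = strand, exons = exons, cds_span = cds_span, biotype = biotype,
    spliced_length = L, .cum = cum, .cum0 = c(0, cum[-length(cum)])
  ), class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s) %s:%s %d exon(s), %d nt%s\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand, nrow(x$exons),
              x$spliced_length,
              if (is.null(x$cds_span)) ", noncoding"
              else sprintf(", CDS [%d,%d)", x$cds_span[1], x$cds_span[2])))
  invisible(x)
}

#' Spliced length of a transcript model
#' @param model A `transcript_model`.
#' @return Total exonic length in nt.
#' @export
spliced_length <- function(model) model$spliced_length

check_tx_pos <- function(model, tx_pos) {
  if (any(tx_pos < 0 | tx_pos >= model$spliced_length))
    stop("tx_pos out of range [0, ", model$spliced_length, ") for ",
         model$transcript_id)
}

#' Map spliced transcript offsets to genomic positions
#'
#' Strand-aware bijection from 0-based transcript offsets onto exonic genomic
#' positions: the plus strand walks exons left to right, the minus strand from
#' the highest genomic coordinate downwards.
#'
#' @param model A `transcript_model`.
#' @param tx_pos Vector of 0-based spliced offsets.
#' @return data.frame with `chrom`, `pos` (0-based genomic), `strand`.
#' @export
tx_to_genome <- function(model, tx_pos) {
  check_tx_pos(model, tx_pos)
  idx <- findInterval(tx_pos, model$.cum0)      # transcript-order exon index
  off <- tx_pos - model$.cum0[idx]
  if (model$strand == "+") {
    g <- model$exons[idx, 1] + off
  } else {
    j <- nrow(model$exons) + 1L - idx           # genomic-order index
    g <- model$exons[j, 2] - 1 - off
  }
  data.frame(chrom = model$chrom, pos = as.numeric(g), strand = model$strand)
}

#' Map genomic positions back to spliced transcript offsets
#'
#' Inverse of [tx_to_genome()]; the position must be exonic.
#'
#' @param model A `transcript_model`.
#' @param gpos Vector of 0-based genomic positions on the model's chromosome.
#' @return Vector of 0-based spliced offsets (NA for non-exonic positions).
#' @export
genome_to_tx <- function(model, gpos) {
  gpos <- as.numeric(gpos)
  j <- findInterval(gpos, model$exons[, 1])
  ok <- j >= 1L & ifelse(j >= 1L, gpos < model$exons[pmax(j, 1L), 2], FALSE)
  out <- rep(NA_real_, length(gpos))
  if (any(ok)) {
    jj <- j[ok]
    off <- gpos[ok] - model$exons[jj, 1]
    if (model$strand == "+") {
      out[ok] <- model$.cum0[jj] + off
    } else {
      idx <- nrow(model$exons) + 1L - jj
      out[ok] <- model$.cum0[idx] + (model$exons[jj, 2] - 1 - gpos[ok])
    }
  }
  out
}

#' Distances to the flanking splice junctions / transcript ends
#'
#' Distances in spliced coordinates from a site to its nearest upstream and
#' downstream boundary, where boundaries are the splice junctions plus the
#' transcript start and end. The first base after a junction has `dist_up = 0`
#' (the junction lies immediately 5' of it); the transcript end is a downstream
#' boundary exactly like a junction, so `dist_down >= 1`.
#'
#' @param model A `transcript_model`.
#' @param tx_pos Vector of 0-based spliced offsets.
#' @return data.frame with `dist_up`, `dist_down`.
#' @export
boundary_distances <- function(model, tx_pos) {
  check_tx_pos(model, tx_pos)
  bounds <- c(0, model$.cum)
  i <- findInterval(tx_pos, bounds)
  data.frame(dist_up = tx_pos - bounds[i], dist_down = bounds[i + 1L] - tx_pos)
}

#' Transcript region of a spliced offset
#'
#' Partition of the transcript by the CDS span: `5UTR` before it, `CDS` within
#' (end-exclusive), `3UTR` after; `noncoding` when no CDS is annotated.
#'
#' @param model A `transcript_model`.
#' @param tx_pos Vector of 0-based spliced offsets.
#' @return Character vector in `{"5UTR","CDS","3UTR","noncoding"}`.
#' @export
region_of <- function(model, tx_pos) {
  check_tx_pos(model, tx_pos)
  if (is.null(model$cds_span)) return(rep("noncoding", length(tx_pos)))
  s <- model$cds_span[1]; e <- model$cds_span[2]
  ifelse(tx_pos < s, "5UTR", ifelse(tx_pos < e, "CDS", "3UTR"))
}

#' Metagene coordinate of a spliced offset
#'
#' Rescales a site into three concatenated unit-length segments: 5'UTR to
#' \[0,1), CDS to \[1,2), 3'UTR to \[2,3), using per-transcript fractional
#' scaling (position within the region divided by region length). Requires a
#' coding transcript; noncoding transcripts yield NA with a warning so they can
#' be excluded from metagene profiles.
#'
#' @param model A `transcript_model`.
#' @param tx_pos Vector of 0-based spliced offsets.
#' @return Numeric vector in \[0, 3), or NA for noncoding models.
#' @export
metagene_position <- function(model, tx_pos) {
  check_tx_pos(model, tx_pos)
  if (is.null(model$cds_span)) {
    warning("metagene position undefined for noncoding transcript ",
            model$transcript_id)
    return(rep(NA_real_, length(tx_pos)))
  }
  s <- model$cds_span[1]; e <- model$cds_span[2]; L <- model$spliced_length
  l5 <- s; lc <- e - s; l3 <- L - e
  ifelse(tx_pos < s, tx_pos / l5,
         ifelse(tx_pos < e, 1 + (tx_pos - s) / lc, 2 + (tx_pos - e) / l3))
}

#' Exon density of a transcript
#'
#' Spliced length divided by the number of exons (i.e. mean exon length); the
#' name follows the field's usage for this length-per-exon covariate.
#'
#' @param model A `transcript_model`.
#' @return nt per exon.
#' @export
exon_density <- function(model) model$spliced_length / nrow(model$exons)

#' 3'UTR length of a transcript
#' @param model A `transcript_model`.
#' @return Length in nt, or NA for noncoding transcripts.
#' @export
utr3_length <- function(model) {
  if (is.null(model$cds_span)) return(NA_real_)
  model$spliced_length - model$cds_span[2]
}

#' Map a spliced interval to genomic intervals
#'
#' Splits the spliced interval `[tx_start, tx_end)` at exon boundaries and
#' returns the corresponding genomic blocks (0-based half-open, ascending).
#'
#' @param model A `transcript_model`.
#' @param tx_start,tx_end Spliced interval, 0-based half-open.
#' @return Matrix with columns start, end.
#' @export
tx_span_to_genomic <- function(model, tx_start, tx_end) {
  stopifnot(tx_start >= 0, tx_end > tx_start, tx_end <= model$spliced_length)
  cuts <- sort(unique(c(tx_start, tx_end,
                        model$.cum[model$.cum > tx_start & model$.cum < tx_end])))
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(length(cuts) - 1L)) {
    a <- cuts[i]; b <- cuts[i + 1L]
    ga <- tx_to_genome(model, a)$pos
    gb <- tx_to_genome(model, b - 1)$pos
    out <- rbind(out, sort(c(ga, gb)) + c(0, 1))
  }
  out[order(out[, 1]), , drop = FALSE]
}

#' Parse a GTF annotation into transcript models
#'
#' Reads a GENCODE-dialect GTF via `rtracklayer`, groups exon features by
#' transcript, and converts CDS (plus stop_codon, when present) features into a
#' spliced CDS span per transcript. GTF's 1-based inclusive coordinates are
#' converted to the package's 0-based half-open convention. `transcript_biotype`
#' and `transcript_type` attributes are accepted as synonyms. Exons falling
#' outside plausible bounds (non-positive width) cause the transcript to be
#' rejected with a warning.
#'
#' @param gtf_source Path to a GTF file.
#' @return Named list of `transcript_model` objects (class `transcript_models`).
#' @export
parse_annotation <- function(gtf_source) {
  gr <- rtracklayer::import(gtf_source, format = "gtf")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  bio_col <- intersect(c("transcript_biotype", "transcript_type"), names(md))
  get_bio <- function(i) {
    if (length(bio_col) == 0L) return(NA_character_)
    b <- as.character(md[[bio_col[1]]][i])
    if (length(b) == 0L || all(is.na(b))) NA_character_ else b[!is.na(b)][1]
  }
  is_exon <- type == "exon"
  is_cds <- type %in% c("CDS", "stop_codon")
  declared <- unique(as.character(md$transcript_id[type == "transcript"]))
  with_exons <- unique(as.character(md$transcript_id[is_exon]))
  no_exons <- setdiff(declared, with_exons)
  if (length(no_exons) > 0L)
    stop("transcript(s) declared with zero exons: ",
         paste(utils::head(no_exons, 5), collapse = ", "))
  tx_ids <- with_exons
  exon_idx <- split(which(is_exon), as.character(md$transcript_id[is_exon]))
  cds_idx <- split(which(is_cds), as.character(md$transcript_id[is_cds]))
  models <- vector("list", length(tx_ids))
  names(models) <- tx_ids
  dropped <- character(0)
  for (tid in tx_ids) {
    ei <- exon_idx[[tid]]
    st <- GenomicRanges::start(gr)[ei] - 1L
    en <- GenomicRanges::end(gr)[ei]
    o <- order(st)
    exons <- cbind(st[o], en[o])
    strand <- as.character(GenomicRanges::strand(gr)[ei][1])
    chrom <- as.character(GenomicRanges::seqnames(gr)[ei][1])
    gid <- as.character(md$gene_id[ei][1])
    m <- tryCatch(
      transcript_model(tid, gid, chrom, strand, exons, biotype = get_bio(ei)),
      error = function(e) e)
    if (inherits(m, "error")) {
      dropped <- c(dropped, tid)
      next
    }
    ci <- cds_idx[[tid]]
    if (!is.null(ci) && length(ci) > 0L) {
      cst <- GenomicRanges::start(gr)[ci] - 1L
      cen <- GenomicRanges::end(gr)[ci] - 1L    # last covered base
      offs <- genome_to_tx(m, c(cst, cen))
      if (any(is.na(offs))) {
        warning("CDS outside exons for transcript ", tid, "; CDS dropped")
      } else {
        m <- transcript_model(tid, gid, chrom, strand, exons,
                              cds_span = c(min(offs), max(offs) + 1),
                              biotype = m$biotype)
      }
    }
    models[[tid]] <- m
  }
  if (length(dropped) > 0L) {
    warning("rejected ", length(dropped), " transcript(s) with invalid exons: ",
            paste(utils::head(dropped, 5), collapse = ", "))
    models <- models[!names(models) %in% dropped]
  }
  models <- models[!vapply(models, is.null, logical(1))]
  class(models) <- "transcript_models"
  models
}

#' Write transcript models as GTF
#'
#' Emits gene/transcript/exon/CDS records in GENCODE-dialect GTF (1-based
#' inclusive). Deterministic: models are written in list order, exons in
#' genomic order. The CDS span (stop codon included) is converted back to
#' genomic blocks.
#'
#' @param models A `transcript_models` list.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  lines <- character(0)
  fmt <- function(chrom, feat, start0, end0, strand, attrs) {
    sprintf("%s\tisomod\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, feat, as.integer(start0) + 1L, as.integer(end0), strand, attrs)
  }
  for (m in models) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s"; transcript_biotype "%s";',
                     m$gene_id, m$transcript_id,
                     if (is.na(m$biotype)) "unknown" else m$biotype)
    lines <- c(lines, fmt(m$chrom, "transcript", m$exons[1, 1],
                          m$exons[nrow(m$exons), 2], m$strand, attrs))
    for (i in seq_len(nrow(m$exons)))
      lines <- c(lines, fmt(m$chrom, "exon", m$exons[i, 1], m$exons[i, 2],
                            m$strand, attrs))
    if (!is.null(m$cds_span)) {
      blocks <- tx_span_to_genomic(m, m$cds_span[1], m$cds_span[2])
      for (i in seq_len(nrow(blocks)))
        lines <- c(lines, fmt(m$chrom, "CDS", blocks[i, 1], blocks[i, 2],
                              m$strand, attrs))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Summary table of transcript models
#'
#' @param models A `transcript_models` list.
#' @return data.frame with one row per transcript: ids, chrom, strand, spliced
#'   length, exon count, exon density, 3'UTR length, biotype, coding flag.
#' @export
models_summary <- function(models) {
  data.frame(
    transcript_id = vapply(models, `[[`, character(1), "transcript_id"),
    gene_id = vapply(models, `[[`, character(1), "gene_id"),
    chrom = vapply(models, `[[`, character(1), "chrom"),
    strand = vapply(models, `[[`, character(1), "strand"),
    length = vapply(models, `[[`, numeric(1), "spliced_length"),
    n_exons = vapply(models, function(m) nrow(m$exons), numeric(1)),
    exon_density = vapply(models, exon_density, numeric(1)),
    utr3_length = vapply(models, utr3_length, numeric(1)),
    biotype = vapply(models, `[[`, character(1), "biotype"),
    coding = !vapply(models, function(m) is.null(m$cds_span), logical(1)),
    row.names = NULL)
}

#' Export a site list as BED6
#'
#' 0-based half-open single-base intervals with a strand column.
#'
#' @param sites data.frame with columns `chrom`, `pos`, `strand`, and optionally
#'   `name` and `score`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_bed6 <- function(sites, path) {
  name <- if ("name" %in% names(sites)) sites$name else "."
  score <- if ("score" %in% names(sites)) sites$score else 0
  df <- data.frame(sites$chrom, as.integer(sites$pos),
                   as.integer(sites$pos) + 1L, name, score, sites$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
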