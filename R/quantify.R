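## Region-aware abundance quantification (ppm / rpkm), exon/intron
## enrichment, and per-transcript region ratios.
##
## A read is assigned to exactly one region by its 5' end (a read whose 5'
## end is the last ORF base counts as ORF even if its body extends into
## the 3'UTR), matching the counting rule that a piRNA is counted only
## when its 5' end maps to the ORF or 3'UTR.

#' Region-aware read quantification
#'
#' For every transcript and region (5'UTR, ORF, 3'UTR, and their union
#' "whole"), reports the count-weighted raw tally, ppm under the set's
#' normalization, and rpkm with a pseudocount:
#' `rpkm = (raw_count + pseudocount) / (region length in kb * norm_denominator / 1e6)`.
#'
#' @param set a normalized `ReadSet` in transcript space (genome-space
#'   records are projected through the models).
#' @param models list of `TranscriptModel`, named by id; non-coding models
#'   are skipped.
#' @param pseudocount added to the read count for rpkm (default 0.001).
#' @return `data.frame` with columns `transcript_id`, `region`,
#'   `raw_count`, `ppm`, `rpkm`.  Reads on unknown transcripts are skipped
#'   with a warning.
#' @export
quantify <- function(set, models, pseudocount = 0.001) {
  stopifnot(inherits(set, "ReadSet"))
  if (is.na(set$norm_denominator))
    stopf("ReadSet '%s' is not normalized; call normalization_factor() first",
          set$label)
  if (is.null(names(models)))
    names(models) <- vapply(models, `[[`, character(1), "transcript_id")
  rec <- project_to_transcripts(set$records, models)
  unknown <- setdiff(unique(rec$ref_id), names(models))
  if (length(unknown)) {
    warnf("skipping reads on %d unknown transcript(s)", length(unknown))
    rec <- rec[!ref_id %in% unknown]
  }
  coding <- Filter(function(m) m$coding, models)
  rows <- lapply(coding, function(m) {
    r <- rec[ref_id == m$transcript_id]
    lens <- region_lengths(m)
    if (nrow(r)) {
      reg <- region_of(m, r$five_prime)
      cnt <- tapply(r$count, factor(reg, levels = names(lens)), sum)
      cnt[is.na(cnt)] <- 0
    } else cnt <- stats::setNames(rep(0, 3), names(lens))
    lens <- c(lens, whole = m$spliced_length)
    cnt <- c(cnt, whole = sum(cnt))
    data.frame(transcript_id = m$transcript_id,
               region = names(lens), raw_count = as.numeric(cnt),
               region_length = as.integer(lens),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$ppm <- out$raw_count / set$norm_denominator * 1e6
  out$rpkm <- ifelse(out$region_length > 0,
                     (out$raw_count + pseudocount) /
                       (out$region_length / 1e3 * set$norm_denominator / 1e6),
                     NA_real_)
  out
}

## project genome-space records to transcript coordinates; transcript-space
## records pass through
project_to_transcripts <- function(rec, models) {
  gsp <- rec[space == "genome"]
  tsp <- rec[space == "transcript"]
  if (!nrow(gsp)) return(tsp)
  parts <- lapply(models, function(m) {
    r <- gsp[ref_id == m$chrom & strand == m$strand]
    if (!nrow(r)) return(NULL)
    tp <- genomic_to_transcript(m, r$five_prime)
    keep <- !is.na(tp)
    if (!any(keep)) return(NULL)
    r <- r[keep]
    r[, `:=`(ref_id = m$transcript_id, five_prime = tp[keep],
             space = "transcript")]
    r
  })
  data.table::rbindlist(c(list(tsp), parts))
}

#' Exon/intron read enrichment
#'
#' Length-corrected read-density ratio between the exonic and intronic
#' compartments of the primary-transcript spans of the models:
#' `fold = (exon reads / exon nt) / (intron reads / intron nt)`.
#' Densities are computed over the genomic union of each compartment;
#' transcripts without introns are excluded.  When no read is intronic the
#' fold is reported with a 0.001-read pseudocount and flagged.
#'
#' @param genome_reads `ReadSet` in genome space.
#' @param models list of `TranscriptModel`.
#' @return list with `frac_exon`, `frac_intron`, `fold_enrichment`,
#'   `exon_nt`, `intron_nt`, `pseudocount_used`.
#' @export
exon_intron_enrichment <- function(genome_reads, models) {
  stopifnot(inherits(genome_reads, "ReadSet"))
  multi <- Filter(function(m) nrow(m$exons) > 1, models)
  if (!length(multi)) stopf("no model with introns")
  by_chrom <- split(multi, vapply(multi, `[[`, character(1), "chrom"))
  exon_nt <- 0; intron_nt <- 0; exon_reads <- 0; intron_reads <- 0
  rec <- genome_reads$records[space == "genome"]
  for (chrom in names(by_chrom)) {
    ms <- by_chrom[[chrom]]
    exon_ir <- IRanges::reduce(do.call(c, unname(lapply(ms, function(m)
      IRanges::IRanges(m$exons$start + 1L, m$exons$end)))))
    span_ir <- IRanges::reduce(do.call(c, unname(lapply(ms, function(m)
      IRanges::IRanges(min(m$exons$start) + 1L, max(m$exons$end))))))
    intron_ir <- IRanges::setdiff(span_ir, exon_ir)
    exon_nt <- exon_nt + sum(IRanges::width(exon_ir))
    intron_nt <- intron_nt + sum(IRanges::width(intron_ir))
    r <- rec[ref_id == chrom]
    if (nrow(r)) {
      p <- IRanges::IRanges(r$five_prime + 1L, width = 1L)
      in_exon <- IRanges::overlapsAny(p, exon_ir)
      in_intron <- IRanges::overlapsAny(p, intron_ir)
      exon_reads <- exon_reads + sum(r$count[in_exon])
      intron_reads <- intron_reads + sum(r$count[in_intron])
    }
  }
  total <- exon_reads + intron_reads
  if (total == 0) stopf("no read falls within the primary-transcript spans")
  pseudo <- intron_reads == 0
  ir_eff <- if (pseudo) 0.001 else intron_reads
  fold <- (exon_reads / exon_nt) / (ir_eff / intron_nt)
  list(frac_exon = exon_reads / total, frac_intron = intron_reads / total,
       fold_enrichment = fold, exon_nt = exon_nt, intron_nt = intron_nt,
       pseudocount_used = pseudo)
}

#' Per-transcript region abundance ratio between two libraries
#'
#' Computes, per transcript, the ppm of `numerator` and `denominator`
#' reads in a region and their pseudocounted ratio
#' `(ppm_num + pseudocount) / (ppm_den + pseudocount)`, with the log2
#' ratio alongside.  This backs comparisons such as 5'P vs 5'OH RPFs,
#' monosome vs polysome RPFs, or CBP80 IP vs eIF4E IP RNA.
#'
#' @param numerator,denominator normalized `ReadSet`s.
#' @param models list of `TranscriptModel`.
#' @param region `"UTR5"`, `"ORF"`, `"UTR3"`, or `"whole"`.
#' @param pseudocount ppm pseudocount (default 0.001).
#' @return `data.frame` with `transcript_id`, `ppm_num`, `ppm_den`,
#'   `ratio`, `log2_ratio`, `flagged` (`TRUE` when the denominator ppm is
#'   0 and the ratio is pseudocount-dominated).
#' @export
region_ratio <- function(numerator, denominator, models,
                         region = c("UTR3", "UTR5", "ORF", "whole"),
                         pseudocount = 0.001) {
  region <- match.arg(region)
  qn <- quantify(numerator, models)
  qd <- quantify(denominator, models)
  qn <- qn[qn$region == region, c("transcript_id", "ppm")]
  qd <- qd[qd$region == region, c("transcript_id", "ppm")]
  m <- merge(qn, qd, by = "transcript_id", suffixes = c("_num", "_den"))
  m$ratio <- (m$ppm_num + pseudocount) / (m$ppm_den + pseudocount)
  m$log2_ratio <- log2(m$ratio)
  m$flagged <- m$ppm_den == 0
  m
}
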