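## Transposable-element content of transcript compartments.

#' TE content of transcript exons and introns
#'
#' For every transcript and compartment (exon, intron), the fraction of
#' compartment nucleotides covered by transposon annotations, split into
#' sense (TE strand equals transcript strand) and antisense.  Overlapping
#' TE annotations on the same strand are merged before counting, so the
#' fractions are invariant to how an annotation is split into pieces.
#'
#' @param models list of `TranscriptModel`.
#' @param te_intervals `data.frame` with columns `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, and optionally `family` (BED6: name
#'   carries the family).
#' @return `data.frame` with `transcript_id`, `compartment`,
#'   `compartment_nt`, `sense_fraction`, `antisense_fraction`.
#' @export
te_content <- function(models, te_intervals) {
  te <- as.data.frame(te_intervals)
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(te)))
  rows <- lapply(models, function(m) {
    exon_ir <- IRanges::reduce(IRanges::IRanges(m$exons$start + 1L, m$exons$end))
    span_ir <- IRanges::IRanges(min(m$exons$start) + 1L, max(m$exons$end))
    intron_ir <- IRanges::setdiff(span_ir, exon_ir)
    cov_frac <- function(comp_ir, sense) {
      comp_nt <- sum(IRanges::width(comp_ir))
      if (comp_nt == 0) return(NA_real_)
      want <- if (sense) m$strand else setdiff(c("+", "-"), m$strand)
      sel <- te$chrom == m$chrom & te$strand == want
      if (!any(sel)) return(0)
      te_ir <- IRanges::reduce(IRanges::IRanges(te$start[sel] + 1L, te$end[sel]))
      sum(IRanges::width(IRanges::intersect(te_ir, comp_ir))) / comp_nt
    }
    data.frame(
      transcript_id = m$transcript_id,
      compartment = c("exon", "intron"),
      compartment_nt = c(sum(IRanges::width(exon_ir)),
                         sum(IRanges::width(intron_ir))),
      sense_fraction = c(cov_frac(exon_ir, TRUE), cov_frac(intron_ir, TRUE)),
      antisense_fraction = c(cov_frac(exon_ir, FALSE), cov_frac(intron_ir, FALSE)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
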