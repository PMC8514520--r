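## Calling 3'UTR piRNA-producing loci (uppl).
##
## A transcript is called a uppl mRNA when (i) its piRNA abundance over
## counted regions (ORF + 3'UTR) exceeds 100 ppm (strict), (ii) at least
## 90% of those piRNAs map to the 3'UTR (inclusive), and (iii) its ORF
## carries an RPF abundance of at least 1 ppm (inclusive), evidencing
## translation.

#' Call uppl precursor transcripts
#'
#' @param pirna abundance table from [quantify()] on the piRNA library.
#' @param rpf abundance table from [quantify()] on the RPF library.
#' @param models list of `TranscriptModel`; transcripts present in the
#'   tables but absent from the models are skipped with a warning.
#' @param thresholds list with `ppm` (strict lower bound on piRNA ppm,
#'   default 100), `frac` (inclusive lower bound on the 3'UTR fraction,
#'   default 0.90), `rpf_ppm` (inclusive lower bound on ORF RPF ppm,
#'   default 1).
#' @return `data.frame` with `transcript_id`, `pirna_ppm`, `frac_utr3`,
#'   `rpf_orf_ppm`, `is_uppl`, `failed_criteria` (comma-separated labels,
#'   empty when called).
#' @export
call_uppl <- function(pirna, rpf, models,
                      thresholds = list(ppm = 100, frac = 0.90, rpf_ppm = 1)) {
  stopifnot(all(c("transcript_id", "region", "ppm") %in% names(pirna)),
            all(c("transcript_id", "region", "ppm") %in% names(rpf)))
  ids <- unique(pirna$transcript_id)
  known <- vapply(models, `[[`, character(1), "transcript_id")
  drop <- setdiff(ids, known)
  if (length(drop)) {
    warnf("skipping %d transcript(s) absent from the models", length(drop))
    ids <- setdiff(ids, drop)
  }
  rows <- lapply(ids, function(id) {
    p <- pirna[pirna$transcript_id == id, ]
    r <- rpf[rpf$transcript_id == id, ]
    orf_cnt <- sum(p$raw_count[p$region == "ORF"])
    utr3_cnt <- sum(p$raw_count[p$region == "UTR3"])
    counted <- orf_cnt + utr3_cnt
    pirna_ppm <- sum(p$ppm[p$region %in% c("ORF", "UTR3")])
    frac_utr3 <- if (counted > 0) utr3_cnt / counted else NA_real_
    rpf_orf_ppm <- if (nrow(r)) sum(r$ppm[r$region == "ORF"]) else 0
    failed <- character(0)
    if (!(pirna_ppm > thresholds$ppm)) failed <- c(failed, "pirna_ppm")
    if (!(isTRUE(frac_utr3 >= thresholds$frac))) failed <- c(failed, "frac_utr3")
    if (!(rpf_orf_ppm >= thresholds$rpf_ppm)) failed <- c(failed, "rpf_orf_ppm")
    data.frame(transcript_id = id, pirna_ppm = pirna_ppm,
               frac_utr3 = frac_utr3, rpf_orf_ppm = rpf_orf_ppm,
               is_uppl = length(failed) == 0L,
               failed_criteria = paste(failed, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
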