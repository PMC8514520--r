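## Metagene profiles: length-rescaled, trimmed-mean aggregated 5'-end
## coverage across a transcript cohort.

#' Metagene profile across 5'UTR / ORF / 3'UTR
#'
#' Each transcript's per-nucleotide 5'-end coverage is split by region,
#' each region linearly rescaled to the cohort's median region length, and
#' the cohort aggregated per bin with a trimmed mean (default 10% trimmed:
#' the top 10% and bottom 10% of transcripts at each bin are removed
#' before averaging, i.e. `mean(x, trim = 0.10)`).
#'
#' @param sets a `ReadSet` or list of `ReadSet`s in transcript space,
#'   pooled before profiling.  Normalized sets contribute ppm, otherwise
#'   raw counts.
#' @param models list of coding `TranscriptModel`s.
#' @param trim per-tail trim fraction in `[0, 0.5)`.
#' @param max_bins cap on the total grid size; when the summed median
#'   region lengths exceed it, each region grid is scaled down
#'   proportionally (stated downsampling).
#' @return an object of class `MetageneProfile`: list with `value`
#'   (numeric grid), `bin_region` (region label per bin), `region_bins`
#'   (bins per region), `median_lengths`, `n_transcripts`, `trim`.
#' @export
metagene <- function(sets, models, trim = 0.10, max_bins = 6000L) {
  if (inherits(sets, "ReadSet")) sets <- list(sets)
  if (trim < 0 || trim >= 0.5) stopf("trim must be in [0, 0.5)")
  coding <- Filter(function(m) m$coding, models)
  if (!length(coding)) stopf("no coding transcript model")
  lens <- t(vapply(coding, region_lengths, numeric(3)))
  med <- apply(lens, 2, stats::median)
  bins <- pmax(1L, as.integer(round(med)))
  if (sum(bins) > max_bins)
    bins <- pmax(1L, as.integer(round(bins * max_bins / sum(bins))))
  names(bins) <- c("UTR5", "ORF", "UTR3")

  ## pooled per-transcript 5'-end coverage
  recs <- data.table::rbindlist(lapply(sets, function(s) {
    r <- s$records[space == "transcript", .(ref_id, five_prime, count)]
    if (!is.na(s$norm_denominator))
      r[, count := count / s$norm_denominator * 1e6]
    r
  }))
  cov_by_tx <- if (nrow(recs))
    recs[, .(w = sum(count)), by = .(ref_id, five_prime)] else NULL

  rescale <- function(v, nb) {
    if (length(v) == nb) return(v)
    if (length(v) == 1L) return(rep(v, nb))
    stats::approx(seq_along(v), v, xout = seq(1, length(v), length.out = nb))$y
  }
  profiles <- lapply(coding, function(m) {
    v <- numeric(m$spliced_length)
    if (!is.null(cov_by_tx)) {
      r <- cov_by_tx[ref_id == m$transcript_id]
      if (nrow(r)) v[r$five_prime + 1L] <- r$w
    }
    rl <- region_lengths(m)
    segs <- list(UTR5 = if (rl[1] > 0) v[seq_len(rl[1])] else numeric(0),
                 ORF  = v[(rl[1] + 1):(rl[1] + rl[2])],
                 UTR3 = if (rl[3] > 0) v[(rl[1] + rl[2] + 1):m$spliced_length]
                        else numeric(0))
    unlist(lapply(names(bins), function(rg) {
      s <- segs[[rg]]
      if (!length(s)) rep(0, bins[[rg]]) else rescale(s, bins[[rg]])
    }), use.names = FALSE)
  })
  mat <- do.call(rbind, profiles)
  value <- apply(mat, 2, mean, trim = trim)
  structure(list(value = value,
                 bin_region = rep(names(bins), bins),
                 region_bins = bins, median_lengths = med,
                 n_transcripts = length(coding), trim = trim),
            class = "MetageneProfile")
}

#' @export
print.MetageneProfile <- function(x, ...) {
  cat(sprintf("MetageneProfile: %d transcripts, %d bins (UTR5 %d / ORF %d / UTR3 %d), %g%% trimmed mean\n",
              x$n_transcripts, length(x$value), x$region_bins[["UTR5"]],
              x$region_bins[["ORF"]], x$region_bins[["UTR3"]], 100 * x$trim))
  invisible(x)
}

#' @export
as.data.frame.MetageneProfile <- function(x, ...) {
  data.frame(bin = seq_along(x$value), region = x$bin_region, value = x$value)
}
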