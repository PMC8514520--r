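## 5'-end overlap distance spectrum and its Z-score.
##
## For each read b in Set B, the per-b spectrum is the fraction of Set-A
## 5' ends at each signed offset among the A reads falling in b's window
## (window nt upstream through window-1 nt downstream of b's 5' end).  The
## reported spectrum is the sum of per-b spectra divided by the total
## (count-weighted) number of reads in Set B, so B reads with no A read in
## their window dilute the spectrum toward zero.  Offset labels follow the
## field convention: there is no offset 0; offset 1 is exact 5'-end
## coincidence, offsets 2..window are 1..window-1 nt downstream, offsets
## -1..-window are 1..window nt upstream (all in the read's own 5'->3'
## orientation).

#' 5'-end overlap distance spectrum
#'
#' @param a,b `ReadSet`s in the same coordinate space.  Only same-reference,
#'   same-strand pairs are considered.
#' @param window half-window in nt (default 50, giving 100 offsets).
#' @param self set `TRUE` when `a` and `b` are the same library, to exclude
#'   the trivial pairing of each read with itself (used for phasing
#'   self-spectra, where offset 1 would otherwise be inflated by
#'   construction).
#' @return an object of class `DistanceSpectrum`: a list with `offsets`
#'   (integer labels), `value` (mean fraction per offset), `pair_counts`
#'   (raw count-weighted pair tallies), `n_b_total`, `window`, `self`.
#' @export
distance_spectrum <- function(a, b, window = 50L, self = FALSE) {
  stopifnot(inherits(a, "ReadSet"), inherits(b, "ReadSet"), window >= 1)
  window <- as.integer(window)
  if (b$total_count == 0) stopf("Set B is empty")
  if (length(unique(c(a$records$space, b$records$space))) > 1)
    stopf("Set A and Set B are in different coordinate spaces")
  offsets <- c(-window:-1L, 1:window)
  n_b_total <- sum(b$records$count)
  empty <- structure(list(offsets = offsets,
                          value = numeric(2L * window),
                          pair_counts = numeric(2L * window),
                          n_b_total = n_b_total,
                          window = window, self = self),
                     class = "DistanceSpectrum")
  if (a$total_count == 0) return(empty)

  au <- a$records[, .(acount = sum(count)), by = .(ref_id, strand, five_prime)]
  bu <- b$records[, .(bcount = sum(count)), by = .(ref_id, strand, five_prime)]
  deltas <- (-window):(window - 1L)
  nd <- length(deltas)
  grid <- bu[rep(seq_len(nrow(bu)), each = nd)]
  grid[, delta := rep(deltas, times = nrow(bu))]
  ## offsets are measured in the read's own orientation: on the minus
  ## strand "downstream" means decreasing coordinate
  grid[, apos := five_prime + ifelse(strand == "+", delta, -delta)]
  data.table::setkey(au, ref_id, strand, five_prime)
  grid[, acount := au[grid[, .(ref_id, strand, apos)],
                      on = c("ref_id", "strand", five_prime = "apos"),
                      x.acount]]
  grid[is.na(acount), acount := 0]
  if (self) grid[delta == 0L, acount := pmax(acount - 1, 0)]
  grid[, bkey := rep(seq_len(nrow(bu)), each = nd)]
  grid[, wtot := sum(acount), by = bkey]
  per_off <- grid[, .(
    value = sum(ifelse(wtot > 0, bcount * acount / wtot, 0)),
    pair_counts = sum(bcount * acount)), by = delta]
  val <- numeric(nd); pc <- numeric(nd)
  idx <- match(per_off$delta, deltas)
  val[idx] <- per_off$value / n_b_total
  pc[idx] <- per_off$pair_counts
  ## reorder from delta order (-w..w-1) to offset-label order (-w..-1, 1..w)
  ord <- match(c(-window:-1L, 0:(window - 1L)), deltas)
  structure(list(offsets = offsets, value = val[ord], pair_counts = pc[ord],
                 n_b_total = n_b_total, window = window, self = self),
            class = "DistanceSpectrum")
}

#' @export
print.DistanceSpectrum <- function(x, ...) {
  cat(sprintf("DistanceSpectrum: window %d, %d offsets, mass %.4f, value(1) = %.4g\n",
              x$window, length(x$offsets), sum(x$value),
              x$value[x$offsets == 1L]))
  invisible(x)
}

#' Convert a distance spectrum to a data.frame
#'
#' @param x a `DistanceSpectrum`.
#' @param ... unused.
#' @return `data.frame` with columns `offset`, `value`, `pair_count`.
#' @export
as.data.frame.DistanceSpectrum <- function(x, ...) {
  data.frame(offset = x$offsets, value = x$value, pair_count = x$pair_counts)
}

#' Overlap Z-score of a distance spectrum
#'
#' Standardizes the spectral value at the coincidence offset (+1) against
#' the background of all other offsets (positions -window..-1 and
#' 2..window), using the sample standard deviation.  The one-sided p-value
#' is the upper normal tail, matching the convention that Z = 1.96
#' corresponds to p = 0.025.
#'
#' @param spec a `DistanceSpectrum`.
#' @return an object of class `OverlapZ`: list with `z`, `focal_offset`,
#'   `focal_value`, `bg_mean`, `bg_sd`, `p_one_sided`.
#' @export
overlap_z <- function(spec) {
  stopifnot(inherits(spec, "DistanceSpectrum"))
  focal <- spec$value[spec$offsets == 1L]
  bg <- spec$value[spec$offsets != 1L]
  bg_sd <- stats::sd(bg)
  if (!is.finite(bg_sd) || bg_sd == 0) {
    ## a perfectly flat spectrum is a well-defined null (z = 0); a focal
    ## excess over a zero-variance background is not standardizable
    if (focal == mean(bg)) {
      return(structure(list(z = 0, focal_offset = 1L, focal_value = focal,
                            bg_mean = mean(bg), bg_sd = bg_sd,
                            p_one_sided = 0.5),
                       class = "OverlapZ"))
    }
    stopf("degenerate background: zero standard deviation across %d offsets",
          length(bg))
  }
  z <- (focal - mean(bg)) / bg_sd
  structure(list(z = z, focal_offset = 1L, focal_value = focal,
                 bg_mean = mean(bg), bg_sd = bg_sd,
                 p_one_sided = normal_upper_p(z)),
            class = "OverlapZ")
}

#' @export
print.OverlapZ <- function(x, ...) {
  cat(sprintf("OverlapZ: Z = %.3f (value %.4g vs background %.4g +/- %.3g), one-sided p = %.3g\n",
              x$z, x$focal_value, x$bg_mean, x$bg_sd, x$p_one_sided))
  invisible(x)
}
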