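## Footprint phasing: periodogram of the self distance spectrum.
##
## Elongating ribosomes step one codon at a time, so the 5' ends of
## ribosome-protected fragments from a translated ORF recur every 3 nt.
## Aligning the footprints to each other (a self 5'-overlap spectrum,
## excluding each read's trivial self-pair) yields a series whose 3-nt
## periodicity shows up as a spectral-density peak at frequency 1/3
## cycles/nt in the classical (Schuster) periodogram.

#' Classical periodogram of a spectrum series
#'
#' Mean-centers the input and computes `I(f_k) = |DFT(x)|^2 / n` at the
#' Fourier frequencies `f_k = k/n`, `k = 1..floor(n/2)`.  The relative
#' spectral density is normalized so the first reported frequency equals 1.
#'
#' @param series numeric vector, typically the downstream half (offsets
#'   1..window) of a self distance spectrum; length >= 6.
#' @return an object of class `PeriodogramResult`: list with `frequency`
#'   (cycles/nt), `spectral_density`, `relative_density`, `constant` flag.
#'   A constant input yields all-zero power and `constant = TRUE` (the
#'   relative density is then undefined and reported as `NA`).
#' @export
periodogram <- function(series) {
  stopifnot(is.numeric(series))
  n <- length(series)
  if (n < 6) stopf("periodogram needs a series of length >= 6, got %d", n)
  x <- series - mean(series)
  constant <- all(x == 0)
  k <- seq_len(n %/% 2)
  dens <- (Mod(stats::fft(x))^2 / n)[k + 1L]
  rel <- if (constant) rep(NA_real_, length(k)) else dens / dens[1]
  structure(list(frequency = k / n, spectral_density = dens,
                 relative_density = rel, n = n, constant = constant),
            class = "PeriodogramResult")
}

#' @export
print.PeriodogramResult <- function(x, ...) {
  if (x$constant) {
    cat("PeriodogramResult: constant series, zero power at all frequencies\n")
  } else {
    i <- which.max(x$spectral_density)
    cat(sprintf("PeriodogramResult: n = %d, peak at f = %.4f cycles/nt (period %.2f nt)\n",
                x$n, x$frequency[i], 1 / x$frequency[i]))
  }
  invisible(x)
}

#' @export
as.data.frame.PeriodogramResult <- function(x, ...) {
  data.frame(frequency = x$frequency, spectral_density = x$spectral_density,
             relative_density = x$relative_density)
}

#' Phasing periodogram of a read set
#'
#' Convenience composition: computes the self 5'-overlap distance spectrum
#' of `set` (excluding self-pairs), takes the downstream half (offsets
#' 1..window), and returns its periodogram.
#'
#' @param set a `ReadSet` (typically ORF-restricted RPFs).
#' @param window half-window of the self spectrum (default 50).
#' @return a list with elements `spectrum` (`DistanceSpectrum`) and
#'   `periodogram` (`PeriodogramResult`).
#' @export
phasing_periodogram <- function(set, window = 50L) {
  spec <- distance_spectrum(set, set, window = window, self = TRUE)
  downstream <- spec$value[spec$offsets >= 1L]
  list(spectrum = spec, periodogram = periodogram(downstream))
}

#' Dominant period of a periodogram
#'
#' @param pg a `PeriodogramResult`.
#' @return the period (nt) at the frequency maximizing the spectral
#'   density, or `NA` for a constant series.
#' @export
peak_period <- function(pg) {
  stopifnot(inherits(pg, "PeriodogramResult"))
  if (pg$constant) return(NA_real_)
  1 / pg$frequency[which.max(pg$spectral_density)]
}
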