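## First-nucleotide-matched simulated control reads.
##
## Negative controls for 5'-overlap analyses: a pool of k-mers is built by
## sliding a 1-nt window along each precursor, then sampled so the first-
## nucleotide composition of the controls matches the real library exactly
## (largest-remainder allocation).  Controls share the precursors' base
## composition and the real reads' 1U bias but carry no positional signal.

#' Largest-remainder allocation of n items to target proportions
#'
#' @param n total to allocate.
#' @param props nonnegative weights (normalized internally).
#' @return integer vector summing to `n`; ties in fractional remainders
#'   are broken in vector order.
#' @export
largest_remainder <- function(n, props) {
  stopifnot(n >= 0, all(props >= 0), sum(props) > 0)
  q <- n * props / sum(props)
  base <- floor(q)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(q - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Simulate first-nucleotide-matched control reads
#'
#' Builds the pool of all `read_length`-mers of the precursors (sliding
#' window of 1 nt, 5' to 3'), stratifies the pool by first nucleotide, and
#' samples `n` controls (with replacement, uniformly within each stratum)
#' so that the control first-nucleotide counts equal the largest-remainder
#' allocation of `n` to the real reads' first-nucleotide proportions.
#'
#' @param precursors named character vector or `DNAStringSet`; every
#'   precursor must be at least `read_length` nt.
#' @param real a `ReadSet` whose records carry sequences (count-weighted
#'   first-nucleotide composition is matched), or a named numeric vector
#'   of A/C/G/U proportions.
#' @param n number of control reads.
#' @param read_length control read length (default 28).
#' @param seed integer seed; sampling is reproducible.
#' @return an object of class `ControlReadPool`: list with `reads` (a
#'   `ReadSet` of placed, sequenced records), `first_nt_target`
#'   (proportions), `allocation` (exact counts), `read_length`, `seed`.
#' @export
simulate_control_reads <- function(precursors, real, n, read_length = 28L,
                                   seed = 1L) {
  if (is(precursors, "DNAStringSet")) precursors <- as.character(precursors)
  stopifnot(length(precursors) > 0, n >= 1, read_length >= 1)
  if (is.null(names(precursors)))
    names(precursors) <- paste0("precursor", seq_along(precursors))
  short <- nchar(precursors) < read_length
  if (any(short))
    stopf("precursor(s) shorter than read_length %d: %s", read_length,
          paste(names(precursors)[short], collapse = ", "))

  ## target first-nt proportions from the real library
  if (inherits(real, "ReadSet")) {
    rec <- real$records
    if (all(is.na(rec$sequence))) stopf("real reads carry no sequences")
    first <- toupper(chartr("T", "U", substr(rec$sequence, 1, 1)))
    ok <- first %in% BASES
    tgt <- tapply(rec$count[ok], factor(first[ok], levels = BASES), sum)
    tgt[is.na(tgt)] <- 0
  } else {
    tgt <- real[BASES]
    tgt[is.na(tgt)] <- 0
  }
  if (sum(tgt) == 0) stopf("real first-nucleotide composition is empty")
  target <- as.numeric(tgt) / sum(tgt)
  names(target) <- BASES
  alloc <- largest_remainder(n, target)
  names(alloc) <- BASES

  ## pool of all read_length-mers, indexed by (precursor, offset)
  pool <- data.table::rbindlist(lapply(names(precursors), function(id) {
    L <- nchar(precursors[[id]])
    data.table::data.table(ref_id = id, five_prime = 0:(L - read_length))
  }))
  pool[, first := toupper(chartr("T", "U", substr(
    precursors[ref_id], five_prime + 1L, five_prime + 1L)))]

  drawn <- with_seed(seed, {
    parts <- lapply(BASES, function(b) {
      k <- alloc[[b]]
      if (k == 0) return(NULL)
      stratum <- pool[first == b]
      if (!nrow(stratum))
        stopf("first-nucleotide stratum '%s' is empty in the %d-mer pool",
              b, read_length)
      stratum[sample.int(nrow(stratum), k, replace = TRUE)]
    })
    data.table::rbindlist(parts)
  })
  drawn[, sequence := substr(precursors[ref_id], five_prime + 1L,
                             five_prime + read_length)]
  rs <- read_set(data.table::data.table(
    ref_id = drawn$ref_id, space = "transcript", strand = "+",
    five_prime = drawn$five_prime, length = read_length,
    count = 1L, sequence = drawn$sequence, chemistry = "unknown"),
    label = "simulated_controls", category = "other")
  structure(list(reads = rs, first_nt_target = target, allocation = alloc,
                 read_length = as.integer(read_length), seed = seed),
            class = "ControlReadPool")
}

#' @export
print.ControlReadPool <- function(x, ...) {
  cat(sprintf("ControlReadPool: %d x %d-mers, first-nt allocation A=%d C=%d G=%d U=%d (seed %d)\n",
              sum(x$allocation), x$read_length, x$allocation[["A"]],
              x$allocation[["C"]], x$allocation[["G"]], x$allocation[["U"]],
              x$seed))
  invisible(x)
}
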