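## Position-specific nucleotide composition at read 5' ends.
##
## Primary piRNAs carry a strong uridine bias at their 5'-most position
## (the 1U bias); in vivo cleavage products inherit it, in vitro nuclease
## products do not.  The bias matrix profiles read positions p1..pK plus
## the base 1 nt upstream of the 5' end (u1), which lies outside the read
## and is therefore taken from the precursor sequence.

BASES <- c("A", "C", "G", "U")

#' Position-specific nucleotide bias of read 5' ends
#'
#' Count-weighted nucleotide frequencies at read positions `p1..pK` and at
#' `u1`, one nt upstream of the 5' end.  Read positions come from the
#' record's own sequence when present, otherwise they are sliced from the
#' precursor at the read's placement; `u1` always comes from the precursor
#' (reads placed at precursor position 0 contribute no u1 observation).
#' T is reported as U.  Per-position information content is
#' `2 - H` bits with `H = -sum(p log2 p)` (Shannon, `0 log 0 := 0`), so a
#' single-nucleotide position scores 2 bits and a uniform one 0 bits.
#'
#' @param reads a `ReadSet`; records need `sequence` or a placement on a
#'   precursor in `precursors`.
#' @param precursors named character vector or `DNAStringSet` of precursor
#'   (transcript) sequences; optional when all reads carry sequences and
#'   `u1` is not required.
#' @param K number of read positions profiled (default 10).
#' @return an object of class `BiasMatrix`: list with `positions`
#'   (`"u1", "p1", ..., "pK"`), `freq` and `counts` (position x ACGU
#'   matrices), `info_bits`, `n_used`, `n_skipped`.
#' @export
nucleotide_bias <- function(reads, precursors = NULL, K = 10L) {
  stopifnot(inherits(reads, "ReadSet"), K >= 1)
  K <- as.integer(K)
  if (!is.null(precursors) && is(precursors, "DNAStringSet"))
    precursors <- as.character(precursors)
  rec <- reads$records
  positions <- c("u1", paste0("p", seq_len(K)))
  counts <- matrix(0, nrow = K + 1L, ncol = 4L,
                   dimnames = list(positions, BASES))
  n_used <- 0; n_skipped <- 0
  if (nrow(rec)) {
    seqs <- rec$sequence
    ## fill missing sequences from precursor placements
    fill <- which(is.na(seqs))
    for (i in fill) {
      pid <- rec$ref_id[i]
      if (!is.null(precursors) && pid %in% names(precursors)) {
        seqs[i] <- substr(precursors[[pid]], rec$five_prime[i] + 1L,
                          rec$five_prime[i] + rec$length[i])
      }
    }
    usable <- !is.na(seqs) & nchar(seqs) > 0
    n_skipped <- sum(rec$count[!usable])
    n_used <- sum(rec$count[usable])
    if (n_used == 0) stopf("no read carries a sequence or a precursor placement")
    ur <- rec[usable]
    useq <- toupper(chartr("T", "U", seqs[usable]))
    for (k in seq_len(K)) {
      base <- substr(useq, k, k)
      ok <- base %in% BASES
      tab <- tapply(ur$count[ok], factor(base[ok], levels = BASES), sum)
      tab[is.na(tab)] <- 0
      counts[k + 1L, ] <- counts[k + 1L, ] + tab
    }
    ## u1: precursor base immediately upstream of the 5' end
    if (!is.null(precursors)) {
      up <- ur[five_prime > 0 & ref_id %in% names(precursors)]
      if (nrow(up)) {
        ubase <- toupper(chartr("T", "U", substr(
          unlist(precursors[up$ref_id], use.names = FALSE),
          up$five_prime, up$five_prime)))
        ok <- ubase %in% BASES
        tab <- tapply(up$count[ok], factor(ubase[ok], levels = BASES), sum)
        tab[is.na(tab)] <- 0
        counts["u1", ] <- tab
      }
    }
  } else {
    stopf("empty read set")
  }
  tot <- rowSums(counts)
  freq <- counts / ifelse(tot > 0, tot, 1)
  freq[tot == 0, ] <- NA_real_
  info <- apply(freq, 1, function(p) {
    if (anyNA(p)) return(NA_real_)
    h <- -sum(ifelse(p > 0, p * log2(p), 0))
    2 - h
  })
  structure(list(positions = positions, freq = freq, counts = counts,
                 info_bits = info, n_used = n_used, n_skipped = n_skipped),
            class = "BiasMatrix")
}

#' @export
print.BiasMatrix <- function(x, ...) {
  cat(sprintf("BiasMatrix: %d positions, %g reads used (%g skipped)\n",
              length(x$positions), x$n_used, x$n_skipped))
  m <- cbind(round(x$freq, 3), bits = round(x$info_bits, 3))
  print(m)
  invisible(x)
}

#' Write a bias matrix as TSV
#'
#' @param x a `BiasMatrix`.
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_bias_tsv <- function(x, path) {
  df <- data.frame(position = x$positions, x$freq, bits = x$info_bits,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
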