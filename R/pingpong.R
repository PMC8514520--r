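## Ping-pong 5'-5' overlap statistic.
##
## Secondary piRNAs made by PIWI slicer cleavage overlap the guide piRNA's
## 5' end by exactly 10 nt on the opposite strand.  The statistic tallies
## opposite-strand read pairs per 5'-5' overlap length g and standardizes
## the tally at g = 10 against all other overlap lengths.

#' Ping-pong 5'-5' overlap spectrum
#'
#' For a plus-strand read p and a minus-strand read q on the same
#' reference, the overlap length is `g = q.five_prime - p.five_prime + 1`
#' in plus-strand coordinates, where a minus-strand record's `five_prime`
#' is its 5'-most (genomically rightmost) template base.  Pair counts are
#' count-weighted (`p.count * q.count`).
#'
#' @param plus,minus `ReadSet`s carrying the two strands.  Records on the
#'   wrong strand for their set are ignored.
#' @param max_overlap largest overlap length tallied (default 50).
#' @param focal overlap length standardized against the rest (default 10,
#'   the canonical ping-pong geometry).
#' @return an object of class `PingPongResult`: list with
#'   `overlap_lengths` (1..max_overlap), `pair_count`, `z10`,
#'   `p_one_sided`, `focal`.
#' @export
pingpong <- function(plus, minus, max_overlap = 50L, focal = 10L) {
  stopifnot(inherits(plus, "ReadSet"), inherits(minus, "ReadSet"))
  max_overlap <- as.integer(max_overlap)
  stopifnot(max_overlap >= 2, focal >= 1, focal <= max_overlap)
  p <- plus$records[strand == "+"]
  q <- minus$records[strand == "-"]
  if (!nrow(p) || !nrow(q))
    stopf("pingpong requires non-empty plus and minus sets")
  pu <- p[, .(pcount = sum(count)), by = .(ref_id, five_prime)]
  qu <- q[, .(qcount = sum(count)), by = .(ref_id, five_prime)]
  ## enumerate overlap g for each plus position: q at p + g - 1
  grid <- pu[rep(seq_len(nrow(pu)), each = max_overlap)]
  grid[, g := rep(seq_len(max_overlap), times = nrow(pu))]
  grid[, qpos := five_prime + g - 1L]
  grid[, qcount := qu[grid[, .(ref_id, qpos)],
                      on = c("ref_id", five_prime = "qpos"), x.qcount]]
  grid[is.na(qcount), qcount := 0]
  tallies <- grid[, .(pair_count = sum(pcount * qcount)), by = g]
  pair_count <- numeric(max_overlap)
  pair_count[tallies$g] <- tallies$pair_count
  others <- pair_count[-focal]
  sd_o <- stats::sd(others)
  z10 <- if (is.finite(sd_o) && sd_o > 0)
    (pair_count[focal] - mean(others)) / sd_o else NA_real_
  structure(list(overlap_lengths = seq_len(max_overlap),
                 pair_count = pair_count,
                 focal = as.integer(focal),
                 z10 = z10,
                 p_one_sided = if (is.na(z10)) NA_real_ else normal_upper_p(z10)),
            class = "PingPongResult")
}

#' @export
print.PingPongResult <- function(x, ...) {
  am <- x$overlap_lengths[which.max(x$pair_count)]
  cat(sprintf("PingPongResult: argmax overlap %d nt (%.0f pairs), Z at %d = %s, one-sided p = %s\n",
              am, max(x$pair_count), x$focal,
              formatC(x$z10, digits = 3, format = "f"),
              formatC(x$p_one_sided, digits = 3, format = "g")))
  invisible(x)
}

#' @export
as.data.frame.PingPongResult <- function(x, ...) {
  data.frame(overlap = x$overlap_lengths, pair_count = x$pair_count)
}
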