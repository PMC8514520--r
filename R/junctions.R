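## Assignment of non-genome-matching reads to exon-exon junction
## sequences.  Reads whose precursor was spliced before processing fail to
## map to the genome but match junction sequences exactly, spanning the
## boundary.

#' Assign reads to exon-exon junction sequences
#'
#' A read is assigned to a junction iff its sequence occurs exactly (no
#' mismatches) in the junction sequence at an offset spanning the exon
#' boundary by at least 1 nt on both sides.  Reads matching several
#' junctions are counted once per distinct junction and flagged.
#'
#' @param reads a `ReadSet` whose records carry sequences.
#' @param junctions `data.frame` from [junction_sequences()] (columns
#'   `junction_id`, `boundary`, `sequence`); the flank used there should
#'   be at least the maximum read length minus 1.
#' @return list with `assignments` (`data.frame`: `junction_id`,
#'   `read_index`, `offset` 0-based within the junction sequence, `count`,
#'   `multi`), `per_junction` (count-weighted totals), `n_assigned`,
#'   `n_unassigned` (count-weighted).
#' @export
junction_read_assignment <- function(reads, junctions) {
  stopifnot(inherits(reads, "ReadSet"))
  jn <- as.data.frame(junctions)
  stopifnot(all(c("junction_id", "boundary", "sequence") %in% names(jn)))
  rec <- reads$records
  has_seq <- !is.na(rec$sequence)
  out <- list()
  n_hits_per_read <- integer(nrow(rec))
  for (i in which(has_seq)) {
    rs <- rec$sequence[i]
    L <- nchar(rs)
    for (j in seq_len(nrow(jn))) {
      hits <- gregexpr(rs, jn$sequence[j], fixed = TRUE)[[1]]
      if (hits[1] == -1L) next
      b <- jn$boundary[j]
      ## 0-based offset o spans the boundary iff o < b and o + L > b
      off <- hits - 1L
      off <- off[off < b & off + L > b]
      if (length(off)) {
        n_hits_per_read[i] <- n_hits_per_read[i] + 1L
        out[[length(out) + 1L]] <- data.frame(
          junction_id = jn$junction_id[j], read_index = i,
          offset = off[1], count = rec$count[i], stringsAsFactors = FALSE)
      }
    }
  }
  assignments <- if (length(out)) do.call(rbind, out) else
    data.frame(junction_id = character(), read_index = integer(),
               offset = integer(), count = numeric(),
               stringsAsFactors = FALSE)
  assignments$multi <- n_hits_per_read[assignments$read_index] > 1L
  per_junction <- if (nrow(assignments))
    tapply(assignments$count, assignments$junction_id, sum) else
    stats::setNames(numeric(0), character(0))
  assigned_reads <- unique(assignments$read_index)
  list(assignments = assignments,
       per_junction = per_junction,
       n_assigned = sum(rec$count[assigned_reads]),
       n_unassigned = sum(rec$count) - sum(rec$count[assigned_reads]))
}
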