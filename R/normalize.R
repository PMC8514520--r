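## Library normalization: choice of the denominator constituting one
## million for ppm.

#' Set the library normalization denominator
#'
#' Small-RNA libraries are conventionally normalized to the sum of miRNA
#' reads; polysome-fraction libraries to a spike-in oligo; ribosome
#' footprint libraries to the sum of reads mapping to mRNA protein-coding
#' regions (assuming bulk translation is stable); harringtonine-treated
#' libraries further to mitochondrial CDS reads; and an upper-quartile
#' option is provided for transcript-level abundance vectors.
#'
#' @param set a `ReadSet`.
#' @param method one of `"miRNA_sum"`, `"spike_in"`, `"mRNA_CDS_sum"`,
#'   `"mito_CDS_sum"`, `"upper_quartile"`.
#' @param aux what the method needs: a single count for `miRNA_sum`,
#'   `spike_in`, and `mito_CDS_sum`; for `mRNA_CDS_sum` either a count or
#'   a list `list(reads = <ReadSet>, models = <models>)` from which
#'   ORF-assigned reads are summed (by their 5' ends); for
#'   `upper_quartile` a numeric abundance vector.
#' @return the `ReadSet` with `norm_denominator` assigned; the ppm of a
#'   record is `count / norm_denominator * 1e6`.
#' @export
normalization_factor <- function(set,
                                 method = c("miRNA_sum", "spike_in",
                                            "mRNA_CDS_sum", "mito_CDS_sum",
                                            "upper_quartile"),
                                 aux) {
  method <- match.arg(method)
  denom <- switch(method,
    miRNA_sum = ,
    spike_in = ,
    mito_CDS_sum = {
      stopifnot(is.numeric(aux), length(aux) == 1L)
      as.numeric(aux)
    },
    mRNA_CDS_sum = {
      if (is.list(aux) && !is.null(aux$reads)) {
        cds_read_sum(aux$reads, aux$models)
      } else {
        stopifnot(is.numeric(aux), length(aux) == 1L)
        as.numeric(aux)
      }
    },
    upper_quartile = {
      stopifnot(is.numeric(aux))
      x <- aux[aux > 0]
      if (!length(x)) 0
      ## effective library size pinned to the upper-quartile transcript,
      ## scaled by the number of expressed transcripts (edgeR-style)
      else unname(stats::quantile(x, 0.75)) * length(x)
    })
  if (!is.finite(denom) || denom <= 0)
    stopf("normalization method %s produced a non-positive denominator", method)
  set$norm_denominator <- denom
  set
}

## count-weighted sum of reads whose 5' end lies in an ORF
cds_read_sum <- function(reads, models) {
  rec <- reads$records
  total <- 0
  for (id in intersect(unique(rec$ref_id), names(models))) {
    m <- models[[id]]
    if (!m$coding) next
    r <- rec[ref_id == id]
    reg <- region_of(m, r$five_prime)
    total <- total + sum(r$count[reg == "ORF"])
  }
  total
}

#' Parts-per-million of raw counts under a set's normalization
#'
#' @param set a normalized `ReadSet`.
#' @param counts raw (count-weighted) read tallies.
#' @return `counts / norm_denominator * 1e6`.
#' @export
ppm_of <- function(set, counts) {
  if (is.na(set$norm_denominator))
    stopf("ReadSet '%s' has no normalization denominator; call normalization_factor() first",
          set$label)
  counts / set$norm_denominator * 1e6
}
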