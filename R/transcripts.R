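## Transcript models and genome <-> transcript coordinate arithmetic.
##
## All coordinates are 0-based half-open internally.  BED input is consumed
## natively; GTF (1-based inclusive) is converted on read.  On the minus
## strand, transcript coordinate 0 is the genomically rightmost exonic base.

#' Construct a transcript model
#'
#' A transcript model records the exon structure of a spliced transcript
#' together with the ORF boundaries in transcript coordinates, partitioning
#' the spliced sequence into 5'UTR, ORF (stop codon included), and 3'UTR.
#'
#' @param transcript_id,gene_id identifiers.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons `data.frame` with integer columns `start`, `end`
#'   (0-based half-open genomic coordinates), non-overlapping.
#' @param cds_start_t,cds_end_t ORF boundaries in transcript coordinates,
#'   0-based half-open; `cds_end_t` is one past the stop codon.  Equal
#'   values flag a non-coding model, which region-aware operations reject.
#' @return an object of class `TranscriptModel`.
#' @export
transcript_model <- function(transcript_id, gene_id = transcript_id, chrom,
                             strand, exons, cds_start_t, cds_end_t) {
  stopifnot(is.character(transcript_id), nchar(chrom) > 0,
            strand %in% c("+", "-"))
  exons <- as.data.frame(exons)[, c("start", "end")]
  exons <- exons[order(exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  if (any(exons$start >= exons$end))
    stopf("transcript %s: exon with start >= end", transcript_id)
  if (nrow(exons) > 1 && any(exons$start[-1] < exons$end[-nrow(exons)]))
    stopf("transcript %s: overlapping exons", transcript_id)
  spliced_length <- sum(exons$end - exons$start)
  if (!(cds_start_t <= cds_end_t && cds_start_t >= 0 &&
        cds_end_t <= spliced_length))
    stopf("transcript %s: ORF boundaries [%d, %d) outside [0, %d)",
          transcript_id, cds_start_t, cds_end_t, spliced_length)
  ## cumulative spliced offset of each exon, walked in transcript order
  widths <- exons$end - exons$start
  tx_order <- if (strand == "+") seq_len(nrow(exons)) else rev(seq_len(nrow(exons)))
  cum <- integer(nrow(exons))
  cum[tx_order] <- cumsum(c(0L, widths[tx_order]))[seq_len(nrow(exons))]
  structure(list(
    transcript_id = transcript_id, gene_id = gene_id, chrom = chrom,
    strand = strand, exons = exons, cds_start_t = as.integer(cds_start_t),
    cds_end_t = as.integer(cds_end_t),
    spliced_length = as.integer(spliced_length),
    coding = cds_start_t < cds_end_t,
    .cumlen = cum
  ), class = "TranscriptModel")
}

#' @export
print.TranscriptModel <- function(x, ...) {
  cat(sprintf(
    "TranscriptModel %s (%s%s) %d exon(s), spliced %d nt, ORF [%d, %d)%s\n",
    x$transcript_id, x$chrom, x$strand, nrow(x$exons), x$spliced_length,
    x$cds_start_t, x$cds_end_t, if (x$coding) "" else " [non-coding]"))
  invisible(x)
}

#' Region lengths of a transcript model
#'
#' @param model a `TranscriptModel`.
#' @return named integer vector with elements `UTR5`, `ORF`, `UTR3`.
#' @export
region_lengths <- function(model) {
  c(UTR5 = model$cds_start_t,
    ORF  = model$cds_end_t - model$cds_start_t,
    UTR3 = model$spliced_length - model$cds_end_t)
}

#' Map genomic positions to transcript coordinates
#'
#' @param model a `TranscriptModel`.
#' @param gpos integer vector of 0-based genomic positions.
#' @return integer vector of transcript coordinates; `NA` where `gpos` is
#'   intronic or outside the exon span.
#' @export
genomic_to_transcript <- function(model, gpos) {
  ex <- model$exons
  idx <- findInterval(gpos, ex$start)
  inside <- idx >= 1L & gpos < ex$end[pmax(idx, 1L)]
  out <- rep(NA_integer_, length(gpos))
  i <- idx[inside]
  if (model$strand == "+") {
    out[inside] <- model$.cumlen[i] + (gpos[inside] - ex$start[i])
  } else {
    out[inside] <- model$.cumlen[i] + (ex$end[i] - 1L - gpos[inside])
  }
  out
}

#' Map transcript coordinates to genomic positions
#'
#' Inverse of [genomic_to_transcript()] on exonic positions.
#'
#' @param model a `TranscriptModel`.
#' @param tpos integer vector of transcript coordinates in
#'   `[0, spliced_length)`.
#' @return integer vector of 0-based genomic positions.
#' @export
transcript_to_genomic <- function(model, tpos) {
  if (any(tpos < 0 | tpos >= model$spliced_length, na.rm = TRUE))
    stopf("transcript %s: tpos out of range", model$transcript_id)
  ex <- model$exons
  widths <- ex$end - ex$start
  tx_order <- if (model$strand == "+") seq_len(nrow(ex)) else rev(seq_len(nrow(ex)))
  starts_t <- model$.cumlen[tx_order]          # transcript start of each exon
  j <- findInterval(tpos, starts_t)            # exon index in transcript order
  i <- tx_order[j]
  off <- tpos - starts_t[j]
  if (model$strand == "+") ex$start[i] + off else ex$end[i] - 1L - off
}

#' Region of a transcript position
#'
#' Assigns each transcript coordinate to the 5'UTR, ORF, or 3'UTR under the
#' half-open partition `[0, cds_start) / [cds_start, cds_end) /
#' [cds_end, spliced_length)`.
#'
#' @param model a coding `TranscriptModel`.
#' @param tpos integer vector of transcript coordinates.
#' @return character vector in `c("UTR5", "ORF", "UTR3")`.
#' @export
region_of <- function(model, tpos) {
  if (!model$coding)
    stopf("transcript %s is non-coding; no region partition", model$transcript_id)
  if (any(tpos < 0 | tpos >= model$spliced_length))
    stopf("transcript %s: tpos out of [0, %d)", model$transcript_id,
          model$spliced_length)
  ifelse(tpos < model$cds_start_t, "UTR5",
         ifelse(tpos < model$cds_end_t, "ORF", "UTR3"))
}

## ---- readers -------------------------------------------------------------

#' Load transcript models from BED12 or GTF
#'
#' BED12 `thickStart`/`thickEnd` or GTF `CDS` features define the ORF.  GTF
#' dialects that exclude the stop codon from CDS are handled by unioning
#' `stop_codon` features into the ORF span, so the 3'UTR always starts
#' after termination.
#'
#' @param path annotation file.
#' @param format `"auto"` (by extension), `"bed12"`, or `"gtf"`.
#' @return list of `TranscriptModel` objects, named by transcript id.
#' @export
load_transcripts <- function(path, format = c("auto", "bed12", "gtf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.(gtf|gff)(\\.gz)?$", path, ignore.case = TRUE))
      "gtf" else "bed12"
  }
  if (format == "bed12") load_transcripts_bed12(path) else load_transcripts_gtf(path)
}

load_transcripts_bed12 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  nfield <- lengths(strsplit(lines, "\t", fixed = TRUE))
  bad <- which(nfield != 12L)
  if (length(bad))
    stopf("malformed BED12 line %d: expected 12 fields, found %d",
          bad[1], nfield[bad[1]])
  gr <- rtracklayer::import(path, format = "bed")
  blocks <- gr$blocks
  thick <- gr$thick
  models <- vector("list", length(gr))
  for (k in seq_along(gr)) {
    bl <- blocks[[k]]
    chromStart <- BiocGenerics::start(gr)[k] - 1L   # back to 0-based
    exons <- data.frame(
      start = chromStart + BiocGenerics::start(bl) - 1L,
      end   = chromStart + BiocGenerics::end(bl))
    strand <- as.character(BiocGenerics::strand(gr))[k]
    if (!strand %in% c("+", "-"))
      stopf("BED12 record %s lacks a strand", gr$name[k])
    ts <- BiocGenerics::start(thick)[k] - 1L        # 0-based thickStart
    te <- BiocGenerics::end(thick)[k]               # exclusive thickEnd
    m <- bed_model(gr$name[k], as.character(GenomeInfoDb::seqnames(gr))[k],
                   strand, exons, ts, te)
    models[[k]] <- m
  }
  names(models) <- vapply(models, `[[`, character(1), "transcript_id")
  models
}

## shared: build a model from genomic ORF bounds (0-based half-open);
## ts == te means non-coding
bed_model <- function(id, chrom, strand, exons, ts, te) {
  if (te <= ts) {
    m <- transcript_model(id, chrom = chrom, strand = strand, exons = exons,
                          cds_start_t = 0L, cds_end_t = 0L)
    return(m)
  }
  probe <- transcript_model(id, chrom = chrom, strand = strand, exons = exons,
                            cds_start_t = 0L, cds_end_t = 0L)
  t1 <- genomic_to_transcript(probe, ts)
  t2 <- genomic_to_transcript(probe, te - 1L)
  if (is.na(t1) || is.na(t2))
    stopf("transcript %s: ORF boundary falls in an intron", id)
  transcript_model(id, chrom = chrom, strand = strand, exons = exons,
                   cds_start_t = min(t1, t2), cds_end_t = max(t1, t2) + 1L)
}

load_transcripts_gtf <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) stopf("GTF parse error in %s: %s",
                                           path, conditionMessage(e)))
  md <- as.data.frame(gr)
  if (!"transcript_id" %in% names(md))
    stopf("GTF %s lacks transcript_id attributes", path)
  keep <- md$type %in% c("exon", "CDS", "stop_codon")
  md <- md[keep, , drop = FALSE]
  models <- lapply(split(md, md$transcript_id), function(tx) {
    id <- tx$transcript_id[1]
    ex <- tx[tx$type == "exon", , drop = FALSE]
    if (!nrow(ex)) stopf("transcript %s has no exon features", id)
    exons <- data.frame(start = ex$start - 1L, end = ex$end)  # to 0-based
    strand <- as.character(ex$strand[1])
    chrom <- as.character(ex$seqnames[1])
    cds <- tx[tx$type %in% c("CDS", "stop_codon"), , drop = FALSE]
    if (!nrow(cds))
      return(bed_model(id, chrom, strand, exons, 0L, 0L))
    gid <- if ("gene_id" %in% names(tx) && !is.na(tx$gene_id[1]))
      tx$gene_id[1] else id
    m <- bed_model(id, chrom, strand, exons,
                   min(cds$start) - 1L, max(cds$end))
    m$gene_id <- gid
    m
  })
  models[order(names(models))]
}

## ---- junctions -----------------------------------------------------------

#' Exon-exon junction sequences
#'
#' For each adjacent exon pair the junction sequence is the last
#' `min(flank, exon length)` nt of the upstream exon followed by the first
#' `min(flank, exon length)` nt of the downstream exon, in transcript
#' orientation (reverse-complemented for minus-strand transcripts).
#'
#' @param model a `TranscriptModel`.
#' @param genome named character vector or `Biostrings::DNAStringSet` of
#'   chromosome sequences.
#' @param flank_nt flank length, >= 1.
#' @return `data.frame` with columns `junction_id`, `transcript_id`,
#'   `boundary` (0-based offset of the first downstream-exon base within
#'   `sequence`), and `sequence`.
#' @export
junction_sequences <- function(model, genome, flank_nt) {
  stopifnot(flank_nt >= 1)
  if (is(genome, "DNAStringSet")) genome <- as.character(genome)
  if (!model$chrom %in% names(genome))
    stopf("chromosome %s absent from genome FASTA", model$chrom)
  chromseq <- genome[[model$chrom]]
  ex <- model$exons
  n <- nrow(ex)
  if (n < 2)
    return(data.frame(junction_id = character(), transcript_id = character(),
                      boundary = integer(), sequence = character(),
                      stringsAsFactors = FALSE))
  ## exons in transcript order
  ord <- if (model$strand == "+") seq_len(n) else rev(seq_len(n))
  up <- ord[-n]; down <- ord[-1]
  res <- lapply(seq_len(n - 1L), function(j) {
    iu <- up[j]; id_ <- down[j]
    lu <- min(flank_nt, ex$end[iu] - ex$start[iu])
    ld <- min(flank_nt, ex$end[id_] - ex$start[id_])
    if (model$strand == "+") {
      s_up <- substr(chromseq, ex$end[iu] - lu + 1L, ex$end[iu])
      s_dn <- substr(chromseq, ex$start[id_] + 1L, ex$start[id_] + ld)
      seqs <- paste0(s_up, s_dn)
    } else {
      ## transcript 5'->3' runs right to left on the genome
      s_up <- substr(chromseq, ex$start[iu] + 1L, ex$start[iu] + lu)
      s_dn <- substr(chromseq, ex$end[id_] - ld + 1L, ex$end[id_])
      seqs <- revcomp(paste0(s_dn, s_up))
    }
    data.frame(junction_id = sprintf("%s.J%d", model$transcript_id, j),
               transcript_id = model$transcript_id,
               boundary = lu, sequence = seqs, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
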