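## Collapsed, 5'-end-anchored read sets.
##
## A ReadSet holds collapsed alignments: one record per distinct placement
## with a count carrying multiplicity.  All downstream statistics weight by
## count, matching ppm semantics.

read_columns <- c("ref_id", "space", "strand", "five_prime", "length",
                  "count", "sequence", "chemistry", "n_hits")

#' Construct a read set
#'
#' @param records `data.frame`/`data.table` with columns `ref_id`, `strand`
#'   (`"+"`/`"-"`), `five_prime` (0-based coordinate of the 5'-most nt),
#'   `length` (nt, > 0), and optionally `count` (multiplicity, default 1),
#'   `space` (`"genome"` or `"transcript"`, default `"transcript"`),
#'   `sequence`, `chemistry` (`"P5"`, `"OH5"`, `"unknown"`), `n_hits`.
#' @param label free-text library label.
#' @param category one of `"piRNA"`, `"RPF"`, `"degradome"`, `"RNAseq"`,
#'   `"other"`.
#' @param norm_denominator reads constituting one million for ppm; set by
#'   [normalization_factor()].
#' @return an object of class `ReadSet`.
#' @export
read_set <- function(records, label = "reads",
                     category = c("other", "piRNA", "RPF", "degradome", "RNAseq"),
                     norm_denominator = NA_real_) {
  category <- match.arg(category)
  rec <- data.table::as.data.table(records)
  need <- c("ref_id", "strand", "five_prime", "length")
  miss <- setdiff(need, names(rec))
  if (length(miss)) stopf("read records lack column(s): %s",
                          paste(miss, collapse = ", "))
  if (!"count" %in% names(rec)) rec[, count := 1L]
  if (!"space" %in% names(rec)) rec[, space := "transcript"]
  if (!"sequence" %in% names(rec)) rec[, sequence := NA_character_]
  if (!"chemistry" %in% names(rec)) rec[, chemistry := "unknown"]
  if (!"n_hits" %in% names(rec)) rec[, n_hits := 1L]
  rec <- rec[, read_columns, with = FALSE]
  if (nrow(rec)) {
    if (any(rec$length <= 0)) stopf("read with non-positive length")
    if (any(rec$five_prime < 0)) stopf("read with negative 5' coordinate")
    if (any(rec$count < 1)) stopf("read with count < 1")
    if (!all(rec$strand %in% c("+", "-"))) stopf("read strand must be + or -")
    bad <- !is.na(rec$sequence) & nchar(rec$sequence) != rec$length
    if (any(bad)) stopf("%d read(s) whose sequence length differs from the length field",
                        sum(bad))
  }
  structure(list(label = label, category = category, records = rec,
                 total_count = sum(rec$count),
                 norm_denominator = norm_denominator),
            class = "ReadSet")
}

#' @export
print.ReadSet <- function(x, ...) {
  cat(sprintf("ReadSet '%s' (%s): %d records, %s reads%s\n",
              x$label, x$category, nrow(x$records),
              format(x$total_count, big.mark = ","),
              if (is.na(x$norm_denominator)) ""
              else sprintf(", norm denominator %g", x$norm_denominator)))
  invisible(x)
}

#' Validate read coordinates against transcript models
#'
#' Checks `0 <= five_prime` and `five_prime + length <= spliced_length`
#' for transcript-space reads.
#'
#' @param set a `ReadSet` in transcript space.
#' @param models list of `TranscriptModel`, named by transcript id.
#' @return invisibly `TRUE`; errors on a violation.
#' @export
validate_reads <- function(set, models) {
  rec <- set$records[space == "transcript"]
  if (!nrow(rec)) return(invisible(TRUE))
  len <- vapply(models, `[[`, integer(1), "spliced_length")
  sl <- len[rec$ref_id]
  unknown <- is.na(sl)
  if (any(unknown))
    stopf("reads on unknown transcript(s): %s",
          paste(unique(rec$ref_id[unknown]), collapse = ", "))
  if (any(rec$five_prime + rec$length > sl))
    stopf("read extends past transcript end")
  invisible(TRUE)
}

## ---- filtering -----------------------------------------------------------

#' Filter reads by length
#'
#' Presets encode the standard library definitions: piRNA analyses keep
#' reads longer than 23 nt; ribosome-protected fragments (RPFs) keep
#' 26-32 nt.  An `n_hits` column, when present, is honoured so that only
#' uniquely mapping reads (`n_hits == 1`) survive; mapping itself is an
#' upstream concern.
#'
#' @param set a `ReadSet`.
#' @param min_len,max_len explicit bounds (inclusive); ignored when a
#'   preset is given.
#' @param preset `"piRNA"`, `"RPF"`, or `"none"`.
#' @param unique_only drop records with `n_hits > 1` (default `TRUE`).
#' @return a `ReadSet` with record order preserved.
#' @export
filter_reads <- function(set, min_len = NULL, max_len = NULL,
                         preset = c("none", "piRNA", "RPF"),
                         unique_only = TRUE) {
  preset <- match.arg(preset)
  rec <- set$records
  keep <- rep(TRUE, nrow(rec))
  if (preset == "piRNA") {
    keep <- rec$length > 23L
  } else if (preset == "RPF") {
    keep <- rec$length >= 26L & rec$length <= 32L
  } else {
    if (!is.null(min_len) && !is.null(max_len) && min_len > max_len)
      stopf("min_len > max_len")
    if (!is.null(min_len)) keep <- keep & rec$length >= min_len
    if (!is.null(max_len)) keep <- keep & rec$length <= max_len
  }
  if (unique_only) keep <- keep & rec$n_hits == 1L
  read_set(rec[keep], label = set$label, category = set$category,
           norm_denominator = set$norm_denominator)
}

## ---- readers / writers ---------------------------------------------------

#' Read a read table (TSV or BED6)
#'
#' The TSV dialect has a header line with at least `ref_id`, `strand`,
#' `five_prime`, `length` and optional `count`, `sequence`, `chemistry`,
#' `n_hits`, `space`.  BED6 encodes one (collapsed) read per line; the
#' score field carries the count and the 5' end is derived from the strand
#' (`chromStart` for `+`, `chromEnd - 1` for `-`).
#'
#' @param path input file.
#' @param format `"auto"`, `"tsv"`, or `"bed6"`.
#' @param space coordinate space of the records (BED6 input only;
#'   the TSV dialect may carry its own `space` column).
#' @param ... passed to [read_set()].
#' @return a `ReadSet`.
#' @export
read_reads <- function(path, format = c("auto", "tsv", "bed6"),
                       space = "transcript", ...) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("read file not found: %s", path)
  if (format == "auto")
    format <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE))
      "bed6" else "tsv"
  if (format == "tsv") {
    rec <- data.table::fread(path, sep = "\t", header = TRUE,
                             colClasses = list(character = "ref_id"))
    if (!"space" %in% names(rec)) rec[, space := space]
    read_set(rec, ...)
  } else {
    bed <- data.table::fread(path, sep = "\t", header = FALSE)
    if (ncol(bed) < 6) stopf("BED6 file %s has %d columns", path, ncol(bed))
    data.table::setnames(bed, 1:6,
                         c("chrom", "start", "end", "name", "score", "strand"))
    rec <- data.table::data.table(
      ref_id = as.character(bed$chrom),
      space = space,
      strand = bed$strand,
      five_prime = ifelse(bed$strand == "+", bed$start, bed$end - 1L),
      length = bed$end - bed$start,
      count = ifelse(is.na(bed$score) | bed$score < 1, 1L, as.integer(bed$score)))
    read_set(rec, ...)
  }
}

#' Write a read set as TSV
#'
#' @param set a `ReadSet`.
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_reads_tsv <- function(set, path) {
  data.table::fwrite(set$records, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}
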