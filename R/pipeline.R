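## End-to-end orchestration: simulate -> quantify -> signatures -> calls,
## with a machine-readable report.  The JSON report contains no wall-clock
## or host data, so identical (config, seed) runs are byte-identical.

#' Subset a read set to one transcript region
#'
#' Keeps records whose 5' end falls in `region` of its transcript model.
#'
#' @param set `ReadSet` in transcript space.
#' @param models list of `TranscriptModel`.
#' @param region `"UTR5"`, `"ORF"`, or `"UTR3"`.
#' @return a `ReadSet`.
#' @export
region_subset <- function(set, models, region = c("UTR3", "ORF", "UTR5")) {
  region <- match.arg(region)
  rec <- set$records
  keep <- logical(nrow(rec))
  for (id in intersect(unique(rec$ref_id), names(models))) {
    m <- models[[id]]
    if (!m$coding) next
    i <- which(rec$ref_id == id)
    keep[i] <- region_of(m, rec$five_prime[i]) == region
  }
  read_set(rec[keep], label = sprintf("%s_%s", set$label, region),
           category = set$category, norm_denominator = set$norm_denominator)
}

#' Run the full synthetic-signature pipeline
#'
#' Generates a synthetic cohort, quantifies the piRNA and RPF libraries,
#' computes the 5'-overlap spectrum of 3'UTR RPFs against 3'UTR piRNAs
#' with its Z-score, the ORF footprint phasing periodogram, 5'-end
#' nucleotide-bias matrices, the ping-pong spectrum, the piRNA metagene
#' profile, the RNA/RPF/piRNA partial correlation, and the uppl precursor
#' calls, writing TSVs plus a deterministic JSON report.
#'
#' @param config a `SyntheticConfig`.
#' @param out_dir output directory (created); `NULL` for no files.
#' @param window spectrum half-window (default 50).
#' @param max_overlap ping-pong window (default 50).
#' @param trim metagene trim (default 0.10).
#' @param thresholds uppl thresholds, see [call_uppl()].
#' @param log_transform transform applied to abundance triplets before the
#'   partial correlation (default log10 with 0.001 pseudocount).
#' @return an object of class `SignatureReport` (list).
#' @export
run_pipeline <- function(config, out_dir = NULL, window = 50L,
                         max_overlap = 50L, trim = 0.10,
                         thresholds = list(ppm = 100, frac = 0.90, rpf_ppm = 1),
                         log_transform = function(x) log10(x + 0.001)) {
  stopifnot(inherits(config, "SyntheticConfig"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  emit <- function(obj, file) {
    if (is.null(out_dir)) return(invisible(NULL))
    utils::write.table(obj, file.path(out_dir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  tr <- stage("simulate_transcriptome", make_transcriptome(config))
  if (!is.null(out_dir)) {
    write_bed12(tr$models, file.path(out_dir, "transcripts.bed"))
    write_fasta(tr$sequences, file.path(out_dir, "transcripts.fa"))
    write_fasta(tr$genome, file.path(out_dir, "genome.fa"))
    if (!is.null(tr$te))
      write_te_bed(tr$te, file.path(out_dir, "te.bed"))
  }
  pir <- stage("simulate_pirna", make_pirna_reads(config, tr$models, tr$sequences))
  rpf <- stage("simulate_rpf", make_rpf_reads(config, tr$models, pir))
  ## synthetic libraries carry no miRNA complement; normalize each library
  ## to its own mapped total (a miRNA-sum stand-in; see vignette)
  pir <- normalization_factor(pir, "miRNA_sum", aux = pir$total_count)
  rpf <- normalization_factor(rpf, "mRNA_CDS_sum",
                              aux = list(reads = rpf, models = tr$models))
  if (!is.null(out_dir)) {
    write_reads_tsv(pir, file.path(out_dir, "pirna_reads.tsv"))
    write_reads_tsv(rpf, file.path(out_dir, "rpf_reads.tsv"))
  }

  q_pir <- stage("quantify_pirna", quantify(pir, tr$models))
  q_rpf <- stage("quantify_rpf", quantify(rpf, tr$models))
  emit(q_pir, "pirna_abundance.tsv"); emit(q_rpf, "rpf_abundance.tsv")

  rpf_u3 <- region_subset(rpf, tr$models, "UTR3")
  rpf_orf <- region_subset(rpf, tr$models, "ORF")
  pir_u3 <- region_subset(pir, tr$models, "UTR3")

  spec <- stage("overlap_spectrum",
                distance_spectrum(rpf_u3, pir_u3, window = window))
  oz <- stage("overlap_z", overlap_z(spec))
  emit(as.data.frame(spec), "spectrum_rpf_vs_pirna_utr3.tsv")

  phas <- stage("phasing", phasing_periodogram(rpf_orf, window = window))
  emit(as.data.frame(phas$periodogram), "periodogram_orf_rpf.tsv")

  bias_pir <- stage("bias_pirna", nucleotide_bias(pir, tr$sequences))
  bias_rpf_u3 <- stage("bias_rpf_utr3", nucleotide_bias(rpf_u3, tr$sequences))
  if (!is.null(out_dir)) {
    write_bias_tsv(bias_pir, file.path(out_dir, "bias_pirna.tsv"))
    write_bias_tsv(bias_rpf_u3, file.path(out_dir, "bias_rpf_utr3.tsv"))
  }

  pp_reads <- stage("simulate_pingpong", make_pingpong_reads(config))
  pp <- stage("pingpong", pingpong(pp_reads$plus, pp_reads$minus,
                                   max_overlap = max_overlap))
  emit(as.data.frame(pp), "pingpong.tsv")

  mg <- stage("metagene", metagene(pir, tr$models, trim = trim))
  emit(as.data.frame(mg), "metagene_pirna.tsv")

  trip <- stage("simulate_triplets", make_abundance_triplets(config))
  pc <- stage("partial_correlation",
              partial_correlation(log_transform(trip$pirna),
                                  log_transform(trip$rpf),
                                  log_transform(trip$rna)))
  emit(trip, "abundance_triplets.tsv")

  calls <- stage("call_uppl", call_uppl(q_pir, q_rpf, tr$models,
                                        thresholds = thresholds))
  emit(calls, "uppl_calls.tsv")

  report <- structure(list(
    provenance = list(
      package = "pirnasig",
      version = as.character(utils::packageVersion("pirnasig")),
      seed = config$seed,
      config = unclass(config),
      parameters = list(window = window, max_overlap = max_overlap,
                        trim = trim, thresholds = thresholds)),
    overlap = list(z = oz$z, p_one_sided = oz$p_one_sided,
                   focal_value = oz$focal_value, bg_mean = oz$bg_mean,
                   bg_sd = oz$bg_sd, spectrum_mass = sum(spec$value)),
    phasing = list(peak_period = peak_period(phas$periodogram),
                   constant = phas$periodogram$constant),
    pingpong = list(z10 = pp$z10, p_one_sided = pp$p_one_sided,
                    argmax_overlap =
                      pp$overlap_lengths[which.max(pp$pair_count)]),
    bias = list(pirna_p1 = as.list(bias_pir$freq["p1", ]),
                pirna_p1_bits = bias_pir$info_bits[["p1"]],
                rpf_utr3_p1 = as.list(bias_rpf_u3$freq["p1", ]),
                rpf_utr3_p1_bits = bias_rpf_u3$info_bits[["p1"]]),
    coupling = list(r = pc$r, p = pc$p, n = pc$n,
                    mode = config$coupling),
    calls = list(n_uppl = sum(calls$is_uppl),
                 n_transcripts = nrow(calls),
                 median_frac_utr3 = stats::median(calls$frac_utr3,
                                                  na.rm = TRUE))),
    class = "SignatureReport")
  if (!is.null(out_dir))
    jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report
}

#' @export
print.SignatureReport <- function(x, ...) {
  cat("SignatureReport\n")
  cat(sprintf("  overlap Z (3'UTR RPF vs piRNA): %.2f (p = %.3g)\n",
              x$overlap$z, x$overlap$p_one_sided))
  cat(sprintf("  phasing peak period (ORF RPF self-spectrum): %.2f nt\n",
              x$phasing$peak_period))
  cat(sprintf("  ping-pong Z at %s: %.2f, argmax overlap %d nt\n",
              "10", x$pingpong$z10, x$pingpong$argmax_overlap))
  cat(sprintf("  piRNA p1 U fraction: %.3f (%.2f bits)\n",
              x$bias$pirna_p1$U, x$bias$pirna_p1_bits))
  cat(sprintf("  partial correlation (piRNA ~ RPF | RNA): r = %.3f (p = %.3g, %s)\n",
              x$coupling$r, x$coupling$p, x$coupling$mode))
  cat(sprintf("  uppl calls: %d / %d (median 3'UTR fraction %.3f)\n",
              x$calls$n_uppl, x$calls$n_transcripts,
              x$calls$median_frac_utr3))
  invisible(x)
}
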