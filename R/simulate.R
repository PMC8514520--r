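## Seeded synthetic-data generator.
##
## Emulates the statistical structure the analyses assume: a transcriptome
## with the long 3'UTRs characteristic of uppl mRNAs (or compact control
## mRNAs), 1U-biased piRNA reads concentrated on 3'UTRs, ribosome
## footprints with 3-nt ORF periodicity whose 3'UTR 5' ends coincide with
## piRNA 5' ends, opposite-strand ping-pong read pairs with a 10-nt 5'-5'
## overlap, embedded transposon fragments, and per-transcript
## RNA/RPF/piRNA abundance triplets with a coupled biogenesis structure.
## Every generator is byte-identical under a fixed (config, seed).

#' Synthetic-data generator configuration
#'
#' Defaults encode the stated world: uppl region medians 346 / 1314 /
#' 4583 nt (5'UTR / ORF / 3'UTR; the ORF median is rounded down from
#' 1315.5 to a codon multiple), control medians 77 / 945 / 392 nt; a
#' 3'UTR:ORF per-nt piRNA sampling weight of 31; a 1U probability of
#' 0.85; RPF frame fidelity 0.9; piRNA/RPF 5'-end coincidence rate 0.5;
#' ping-pong fraction 0.5 with the canonical 10-nt slicer geometry.
#'
#' @param seed master seed; each generator stage derives its own stream.
#' @param n_transcripts cohort size (default: 30 for `uppl`, 43 for
#'   `control`, the real cohort sizes).
#' @param preset `"uppl"` or `"control"`.
#' @param region_medians named vector (UTR5, ORF, UTR3) of median region
#'   lengths in nt; region lengths are log-normal around these.
#' @param region_sdlog log-sd of the region length sampler.
#' @param n_exons_range range of exon counts per transcript.
#' @param intron_meanlog,intron_sdlog intron length sampler (log-normal).
#' @param pi_density per-nt piRNA sampling weight per region.
#' @param p_1U probability a piRNA 5' end is restricted to a U position.
#' @param n_pirna,n_rpf,n_pingpong library sizes.
#' @param rpf_frame_fidelity probability an ORF RPF 5' end sits at a codon
#'   start.
#' @param rpf_orf_fraction fraction of RPF reads drawn from ORFs (the rest
#'   from 3'UTRs).
#' @param coincidence_rate probability a 3'UTR RPF 5' end is copied from a
#'   piRNA 5' end (rho).
#' @param pingpong_fraction fraction of minus-strand reads placed at the
#'   slicer offset from a plus-strand read (phi).
#' @param slicer_offset 5'-5' overlap of planted ping-pong pairs
#'   (default 10: cleavage across from guide nucleotides 10/11).
#' @param te_insert `"preset"` (the uppl preset embeds an antisense SINE
#'   fragment in most 3'UTRs, the control preset none), `NULL` to disable,
#'   or a list with `family`, `length`, `strand` (`"+"` sense / `"-"`
#'   antisense relative to the transcript), `region`, `prob`
#'   (per-transcript insertion probability).
#' @param coupling `"coupled"` or `"decoupled"` abundance triplets.
#' @param noise_sd log-scale sd of the piRNA-link noise in the abundance
#'   model (> 0): biogenesis noise around RPF in coupled mode, around RNA
#'   in decoupled mode.  As it vanishes, coupled piRNA abundance tracks
#'   ribosome occupancy exactly.
#' @param rpf_noise_sd log-scale sd of the RNA -> RPF (translation) link
#'   noise (> 0).
#' @return a list of class `SyntheticConfig`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_transcripts = NULL,
                             preset = c("uppl", "control"),
                             region_medians = NULL,
                             region_sdlog = 0.25,
                             n_exons_range = 1:4,
                             intron_meanlog = log(800), intron_sdlog = 0.5,
                             pi_density = c(UTR5 = 0, ORF = 1, UTR3 = 31),
                             p_1U = 0.85,
                             n_pirna = 20000L, n_rpf = 20000L,
                             n_pingpong = 2000L,
                             rpf_frame_fidelity = 0.9,
                             rpf_orf_fraction = 0.8,
                             coincidence_rate = 0.5,
                             pingpong_fraction = 0.5,
                             slicer_offset = 10L,
                             te_insert = "preset",
                             coupling = c("coupled", "decoupled"),
                             noise_sd = 0.3, rpf_noise_sd = 0.3) {
  preset <- match.arg(preset)
  coupling <- match.arg(coupling)
  if (is.null(region_medians))
    region_medians <- if (preset == "uppl")
      c(UTR5 = 346, ORF = 1314, UTR3 = 4583)
    else c(UTR5 = 77, ORF = 945, UTR3 = 392)
  if (is.null(n_transcripts))
    n_transcripts <- if (preset == "uppl") 30L else 43L
  if (identical(te_insert, "preset"))
    te_insert <- if (preset == "uppl")
      list(family = "SINE", length = 150L, strand = "-",
           region = "UTR3", prob = 0.8) else NULL
  probs <- c(p_1U, rpf_frame_fidelity, rpf_orf_fraction,
             coincidence_rate, pingpong_fraction)
  if (any(probs < 0 | probs > 1)) stopf("probabilities must lie in [0, 1]")
  if (noise_sd <= 0 || rpf_noise_sd <= 0) stopf("noise_sd must be > 0")
  if (!is.null(te_insert) &&
      te_insert$length >= region_medians[[te_insert$region]])
    stopf("TE insert longer than its target region median")
  structure(list(seed = as.integer(seed), n_transcripts = as.integer(n_transcripts),
                 preset = preset, region_medians = region_medians,
                 region_sdlog = region_sdlog, n_exons_range = n_exons_range,
                 intron_meanlog = intron_meanlog, intron_sdlog = intron_sdlog,
                 pi_density = pi_density, p_1U = p_1U,
                 n_pirna = as.integer(n_pirna), n_rpf = as.integer(n_rpf),
                 n_pingpong = as.integer(n_pingpong),
                 rpf_frame_fidelity = rpf_frame_fidelity,
                 rpf_orf_fraction = rpf_orf_fraction,
                 coincidence_rate = coincidence_rate,
                 pingpong_fraction = pingpong_fraction,
                 slicer_offset = as.integer(slicer_offset),
                 te_insert = te_insert, coupling = coupling,
                 noise_sd = noise_sd, rpf_noise_sd = rpf_noise_sd),
            class = "SyntheticConfig")
}

DNA <- c("A", "C", "G", "T")
STOPS <- c("TAA", "TAG", "TGA")

random_dna <- function(n) paste(sample(DNA, n, replace = TRUE), collapse = "")

## fixed synthetic consensus per TE family, derived from a family-specific
## stream so it is identical across sessions
te_consensus <- function(family, length = 300L) {
  seeds <- c(SINE = 9101L, LINE = 9102L, LTR = 9103L, DNA = 9104L)
  s <- if (family %in% names(seeds)) seeds[[family]] else
    9100L + sum(utf8ToInt(family))
  with_seed(s, random_dna(length))
}

## one ORF sequence: ATG + non-stop codons + one stop codon
random_orf <- function(len) {
  stopifnot(len %% 3 == 0, len >= 9)
  ncod <- len / 3 - 2L
  codons <- character(ncod)
  for (i in seq_len(ncod)) {
    repeat {
      cd <- random_dna(3)
      if (!cd %in% STOPS) break
    }
    codons[i] <- cd
  }
  paste0("ATG", paste(codons, collapse = ""), sample(STOPS, 1))
}

#' Generate a synthetic transcriptome
#'
#' Samples region lengths log-normally around the preset medians (ORF
#' lengths forced to codon multiples), splits transcripts into 1-4 exons
#' separated by log-normal introns, lays them head-to-tail on a synthetic
#' chromosome on alternating strands, and writes background sequence
#' i.i.d. uniform over A/C/G/T except for ORF codon structure and optional
#' TE inserts copied (reverse-complemented for antisense) from a fixed
#' synthetic consensus.
#'
#' @param config a `SyntheticConfig`.
#' @return list with `models` (named list of `TranscriptModel`),
#'   `sequences` (named character, spliced transcript sequences), `genome`
#'   (named character, chromosome sequences), `te` (`data.frame` of
#'   genomic TE intervals or `NULL`), `config`.
#' @export
make_transcriptome <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  with_seed(config$seed + 1000L, {
    n <- config$n_transcripts
    med <- config$region_medians
    sdl <- config$region_sdlog
    models <- vector("list", n)
    seqs <- character(n)
    te_rows <- list()
    chrom <- "chrS1"
    gcursor <- 1000L
    genome_parts <- list(random_dna(1000L))
    for (i in seq_len(n)) {
      u5 <- max(10L, round(stats::rlnorm(1, log(med[["UTR5"]]), sdl)))
      orf <- max(30L, round(stats::rlnorm(1, log(med[["ORF"]]), sdl)))
      orf <- as.integer(3L * round(orf / 3))
      u3 <- max(40L, round(stats::rlnorm(1, log(med[["UTR3"]]), sdl)))
      sl <- u5 + orf + u3
      tseq <- paste0(random_dna(u5), random_orf(orf), random_dna(u3))
      ## optional TE insert inside the 3'UTR
      te_t <- NULL
      ti <- config$te_insert
      if (!is.null(ti) && stats::runif(1) < ti$prob && u3 > ti$length + 2L) {
        cons <- te_consensus(ti$family, ti$length)
        ins <- if (ti$strand == "+") cons else revcomp(cons)
        at <- u5 + orf + sample.int(u3 - ti$length, 1)  # 0-based tpos
        tseq <- paste0(substr(tseq, 1, at), ins,
                       substr(tseq, at + ti$length + 1L, sl))
        te_t <- c(start = at, end = at + ti$length)
      }
      ## exon structure: split spliced length at random interior points
      k <- sample(config$n_exons_range, 1)
      k <- min(k, max(1L, sl %/% 100L))
      cuts <- if (k > 1) sort(sample(seq_len(sl - 1L), k - 1L)) else integer(0)
      widths <- diff(c(0L, cuts, sl))
      introns <- if (k > 1)
        pmax(60L, round(stats::rlnorm(k - 1L, config$intron_meanlog,
                                      config$intron_sdlog))) else integer(0)
      strand <- if (i %% 2L == 1L) "+" else "-"
      ## genomic exon intervals, walked left to right
      gstart <- gcursor
      starts <- integer(k); ends <- integer(k)
      pos <- gstart
      for (e in seq_len(k)) {
        starts[e] <- pos
        ends[e] <- pos + widths[if (strand == "+") e else k - e + 1L]
        pos <- ends[e] + if (e < k) introns[e] else 0L
      }
      exons <- data.frame(start = starts, end = ends)
      id <- sprintf("%s%03d", if (config$preset == "uppl") "uppl" else "ctrl", i)
      m <- transcript_model(id, chrom = chrom, strand = strand, exons = exons,
                            cds_start_t = u5, cds_end_t = u5 + orf)
      models[[i]] <- m
      seqs[i] <- tseq
      ## genome sequence under the exons (strand-aware), introns random
      gseq_len <- pos - gstart
      gchars <- strsplit(random_dna(gseq_len), NULL)[[1]]
      splice_chars <- strsplit(if (strand == "+") tseq else revcomp(tseq),
                               NULL)[[1]]
      off <- 0L
      for (e in seq_len(k)) {
        w <- ends[e] - starts[e]
        idx <- (starts[e] - gstart + 1L):(ends[e] - gstart)
        if (strand == "+") {
          gchars[idx] <- splice_chars[(off + 1L):(off + w)]
        } else {
          ## splice_chars is revcomp(tseq) laid left-to-right
          gchars[idx] <- splice_chars[(off + 1L):(off + w)]
        }
        off <- off + w
      }
      genome_parts[[length(genome_parts) + 1L]] <- paste(gchars, collapse = "")
      genome_parts[[length(genome_parts) + 1L]] <- random_dna(500L)
      ## TE interval in genome coordinates
      if (!is.null(te_t)) {
        tpos <- te_t[["start"]]:(te_t[["end"]] - 1L)
        gp <- sort(transcript_to_genomic(m, tpos))
        ir <- IRanges::reduce(IRanges::IRanges(gp + 1L, gp + 1L))
        gstrand <- if (ti$strand == "+") strand else setdiff(c("+", "-"), strand)
        te_rows[[length(te_rows) + 1L]] <- data.frame(
          chrom = chrom, start = BiocGenerics::start(ir) - 1L,
          end = BiocGenerics::end(ir), family = ti$family,
          strand = gstrand, transcript_id = id, stringsAsFactors = FALSE)
      }
      gcursor <- pos + 500L
    }
    names(models) <- vapply(models, `[[`, character(1), "transcript_id")
    names(seqs) <- names(models)
    genome <- stats::setNames(paste(unlist(genome_parts), collapse = ""), chrom)
    te <- if (length(te_rows)) do.call(rbind, te_rows) else NULL
    list(models = models, sequences = seqs, genome = genome, te = te,
         config = config)
  })
}

## sample read lengths and positions for one transcript region
sample_positions <- function(cand, k) cand[sample.int(length(cand), k, replace = TRUE)]

#' Generate a synthetic piRNA library
#'
#' 5' positions are drawn per region with per-nt weights
#' `pi_density * region length`; with probability `p_1U` a read's 5' end
#' is restricted to uridine (T) positions of the precursor, otherwise any
#' position.  Lengths are uniform on 24-32 nt; sequences are sliced from
#' the precursor; chemistry is 5'P.
#'
#' @param config a `SyntheticConfig`.
#' @param models,sequences from [make_transcriptome()].
#' @return a `ReadSet` (category `piRNA`), collapsed with counts.
#' @export
make_pirna_reads <- function(config, models, sequences) {
  stopifnot(inherits(config, "SyntheticConfig"))
  with_seed(config$seed + 2000L, {
    maxlen <- 32L
    slots <- data.table::rbindlist(lapply(models, function(m) {
      rl <- region_lengths(m)
      data.table::data.table(ref_id = m$transcript_id,
                             region = names(rl), len = as.numeric(rl),
                             w = config$pi_density[names(rl)] * as.numeric(rl))
    }))
    slots <- slots[w > 0]
    if (!nrow(slots)) stopf("all region sampling weights are zero")
    draw <- sample.int(nrow(slots), config$n_pirna, replace = TRUE,
                       prob = slots$w)
    tab <- tabulate(draw, nbins = nrow(slots))
    parts <- vector("list", nrow(slots))
    for (s in which(tab > 0)) {
      m <- models[[slots$ref_id[s]]]
      rl <- region_lengths(m)
      bounds <- switch(slots$region[s],
        UTR5 = c(0L, m$cds_start_t),
        ORF  = c(m$cds_start_t, m$cds_end_t),
        UTR3 = c(m$cds_end_t, m$spliced_length))
      ## candidate 5' positions leaving room for the longest read
      hi <- min(bounds[2] - 1L, m$spliced_length - maxlen)
      cand <- seq.int(bounds[1], hi)
      if (!length(cand)) next
      base <- substr(rep(sequences[[m$transcript_id]], length(cand)),
                     cand + 1L, cand + 1L)
      tpos_u <- cand[base == "T"]
      k <- tab[s]
      use_u <- stats::runif(k) < config$p_1U
      if (any(use_u) && !length(tpos_u)) {
        if (config$p_1U == 1)
          stopf("region %s of %s has no U position", slots$region[s],
                slots$ref_id[s])
        use_u[] <- FALSE
      }
      pos <- integer(k)
      if (any(use_u)) pos[use_u] <- sample_positions(tpos_u, sum(use_u))
      if (any(!use_u)) pos[!use_u] <- sample_positions(cand, sum(!use_u))
      len <- sample(24:32, k, replace = TRUE)
      parts[[s]] <- data.table::data.table(ref_id = m$transcript_id,
                                           five_prime = pos, length = len)
    }
    reads <- data.table::rbindlist(parts)
    reads <- reads[, .(count = .N), by = .(ref_id, five_prime, length)]
    reads[, sequence := substr(sequences[ref_id], five_prime + 1L,
                               five_prime + length)]
    read_set(data.table::data.table(reads, space = "transcript",
                                    strand = "+", chemistry = "P5"),
             label = sprintf("synthetic_pirna_%s", config$preset),
             category = "piRNA")
  })
}

#' Generate a synthetic ribosome-footprint library
#'
#' ORF reads: with probability `rpf_frame_fidelity` the 5' end sits at a
#' codon start (offset congruent to `cds_start_t` mod 3), otherwise
#' uniform within the ORF; chemistry 5'OH.  3'UTR reads: with probability
#' `coincidence_rate` the 5' end is copied from a sampled 3'UTR piRNA 5'
#' end and chemistry is 5'P, otherwise uniform with chemistry 5'OH.
#' Lengths are uniform 26-32 nt.
#'
#' @param config a `SyntheticConfig`.
#' @param models from [make_transcriptome()].
#' @param pirnas `ReadSet` from [make_pirna_reads()]; required when
#'   `coincidence_rate > 0`.
#' @return a `ReadSet` (category `RPF`).
#' @export
make_rpf_reads <- function(config, models, pirnas = NULL) {
  stopifnot(inherits(config, "SyntheticConfig"))
  rho <- config$coincidence_rate
  with_seed(config$seed + 3000L, {
    n_orf <- round(config$n_rpf * config$rpf_orf_fraction)
    n_utr3 <- config$n_rpf - n_orf
    maxlen <- 32L
    ids <- names(models)
    orf_w <- vapply(models, function(m) region_lengths(m)[["ORF"]], numeric(1))
    utr3_w <- vapply(models, function(m) region_lengths(m)[["UTR3"]], numeric(1))

    ## ORF footprints
    pick <- sample(ids, n_orf, replace = TRUE, prob = orf_w)
    orf_parts <- lapply(ids[orf_w > 0], function(id) {
      k <- sum(pick == id)
      if (!k) return(NULL)
      m <- models[[id]]
      hi <- min(m$cds_end_t - 1L, m$spliced_length - maxlen)
      cand <- seq.int(m$cds_start_t, hi)
      frame_ok <- cand[(cand - m$cds_start_t) %% 3L == 0L]
      inframe <- stats::runif(k) < config$rpf_frame_fidelity
      pos <- integer(k)
      if (any(inframe)) pos[inframe] <- sample_positions(frame_ok, sum(inframe))
      if (any(!inframe)) pos[!inframe] <- sample_positions(cand, sum(!inframe))
      data.table::data.table(ref_id = id, five_prime = pos,
                             length = sample(26:32, k, replace = TRUE),
                             chemistry = "OH5")
    })

    ## 3'UTR footprints
    utr3_parts <- NULL
    if (n_utr3 > 0) {
      if (rho > 0) {
        if (is.null(pirnas)) stopf("coincidence_rate > 0 requires a piRNA set")
        prec <- pirnas$records
        u3_start <- vapply(models, `[[`, integer(1), "cds_end_t")[prec$ref_id]
        prec <- prec[five_prime >= u3_start]
        if (!nrow(prec)) stopf("coincidence_rate > 0 but no 3'UTR piRNA")
      }
      copied <- stats::runif(n_utr3) < rho
      n_cp <- sum(copied)
      cp <- NULL
      if (n_cp > 0) {
        j <- sample.int(nrow(prec), n_cp, replace = TRUE, prob = prec$count)
        sl <- vapply(models, `[[`, integer(1), "spliced_length")[prec$ref_id[j]]
        len <- pmin(sample(26:32, n_cp, replace = TRUE),
                    sl - prec$five_prime[j])
        cp <- data.table::data.table(ref_id = prec$ref_id[j],
                                     five_prime = prec$five_prime[j],
                                     length = len, chemistry = "P5")
      }
      n_un <- n_utr3 - n_cp
      un <- NULL
      if (n_un > 0) {
        pick3 <- sample(ids, n_un, replace = TRUE, prob = utr3_w)
        un <- data.table::rbindlist(lapply(ids[utr3_w > 0], function(id) {
          k <- sum(pick3 == id)
          if (!k) return(NULL)
          m <- models[[id]]
          hi <- min(m$spliced_length - maxlen, m$spliced_length - 1L)
          cand <- seq.int(m$cds_end_t, max(m$cds_end_t, hi))
          data.table::data.table(ref_id = id,
                                 five_prime = sample_positions(cand, k),
                                 length = sample(26:32, k, replace = TRUE),
                                 chemistry = "OH5")
        }))
      }
      utr3_parts <- list(cp, un)
    }
    reads <- data.table::rbindlist(c(orf_parts, utr3_parts))
    reads <- reads[, .(count = .N), by = .(ref_id, five_prime, length, chemistry)]
    read_set(data.table::data.table(reads, space = "transcript", strand = "+"),
             label = sprintf("synthetic_rpf_%s", config$preset),
             category = "RPF")
  })
}

#' Generate synthetic ping-pong read pairs
#'
#' Plus-strand guide reads are uniform over the reference; a fraction
#' `pingpong_fraction` of minus-strand reads have their 5' end (in
#' plus-strand coordinates) placed `slicer_offset - 1` nt downstream of a
#' sampled plus read's 5' end, so the 5'-5' overlap equals
#' `slicer_offset`; the remainder are uniform.
#'
#' @param config a `SyntheticConfig`.
#' @param reference_length length of the (consensus) reference, >= 200.
#' @param ref_id reference name.
#' @return list with `plus` and `minus` `ReadSet`s.
#' @export
make_pingpong_reads <- function(config, reference_length = 5000L,
                                ref_id = "TEconsensus") {
  stopifnot(inherits(config, "SyntheticConfig"), reference_length >= 200)
  with_seed(config$seed + 4000L, {
    n <- config$n_pingpong
    L <- as.integer(reference_length)
    plen <- sample(24:32, n, replace = TRUE)
    ppos <- sample.int(L - 32L, n, replace = TRUE) - 1L
    planted <- stats::runif(n) < config$pingpong_fraction
    mlen <- sample(24:32, n, replace = TRUE)
    ## minus-strand five_prime is the rightmost template base (plus coords)
    mpos <- integer(n)
    if (any(planted)) {
      src <- sample.int(n, sum(planted), replace = TRUE)
      mpos[planted] <- ppos[src] + config$slicer_offset - 1L
    }
    if (any(!planted))
      mpos[!planted] <- sample.int(L - 33L, sum(!planted), replace = TRUE) + 31L
    mlen <- pmin(mlen, mpos + 1L)
    collapse <- function(dt) dt[, .(count = .N), by = .(ref_id, five_prime,
                                                        length, strand)]
    plus <- read_set(collapse(data.table::data.table(
      ref_id = ref_id, five_prime = ppos, length = plen, strand = "+")),
      label = "synthetic_pingpong_plus", category = "piRNA")
    minus <- read_set(collapse(data.table::data.table(
      ref_id = ref_id, five_prime = mpos, length = mlen, strand = "-")),
      label = "synthetic_pingpong_minus", category = "piRNA")
    list(plus = plus, minus = minus)
  })
}

#' Generate per-transcript RNA/RPF/piRNA abundance triplets
#'
#' `rna` is log-normal; `rpf = alpha * rna * exp(e1)` with
#' `e1 ~ normal(0, rpf_noise_sd)`.  In coupled mode piRNA abundance
#' follows ribosome occupancy, `pirna = beta * rpf * exp(e2)` (biogenic
#' coupling); in decoupled mode `pirna = gamma * rna * exp(e3)`,
#' independent of `rpf` given `rna`.  `e2`/`e3` are
#' `normal(0, noise_sd)` on the log scale, so shrinking `noise_sd` drives
#' the coupled partial correlation to 1.
#'
#' @param config a `SyntheticConfig` with `n_transcripts >= 10`.
#' @param alpha,beta,gamma scale constants.
#' @param rna_meanlog,rna_sdlog RNA abundance sampler.
#' @return `data.frame` with `transcript_id`, `rna`, `rpf`, `pirna`.
#' @export
make_abundance_triplets <- function(config, alpha = 0.5, beta = 2,
                                    gamma = 1, rna_meanlog = 3,
                                    rna_sdlog = 1) {
  stopifnot(inherits(config, "SyntheticConfig"))
  if (config$n_transcripts < 10) stopf("need n_transcripts >= 10")
  with_seed(config$seed + 5000L, {
    n <- config$n_transcripts
    rna <- stats::rlnorm(n, rna_meanlog, rna_sdlog)
    rpf <- alpha * rna * exp(stats::rnorm(n, 0, config$rpf_noise_sd))
    pirna <- if (config$coupling == "coupled")
      beta * rpf * exp(stats::rnorm(n, 0, config$noise_sd))
    else gamma * rna * exp(stats::rnorm(n, 0, config$noise_sd))
    data.frame(transcript_id = sprintf("tx%04d", seq_len(n)),
               rna = rna, rpf = rpf, pirna = pirna,
               stringsAsFactors = FALSE)
  })
}

## ---- emitters ------------------------------------------------------------

#' Write transcript models as BED12
#'
#' @param models list of `TranscriptModel`.
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_bed12 <- function(models, path) {
  lines <- vapply(models, function(m) {
    ex <- m$exons
    chromStart <- min(ex$start)
    if (m$coding) {
      g1 <- transcript_to_genomic(m, m$cds_start_t)
      g2 <- transcript_to_genomic(m, m$cds_end_t - 1L)
      thick <- c(min(g1, g2), max(g1, g2) + 1L)
    } else thick <- c(chromStart, chromStart)
    paste(m$chrom, chromStart, max(ex$end), m$transcript_id, 0, m$strand,
          thick[1], thick[2], "0,0,0", nrow(ex),
          paste0(paste(ex$end - ex$start, collapse = ","), ","),
          paste0(paste(ex$start - chromStart, collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write named sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write TE intervals as BED6
#'
#' @param te `data.frame` with `chrom`, `start`, `end`, `family`, `strand`.
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_te_bed <- function(te, path) {
  writeLines(paste(te$chrom, te$start, te$end, te$family, 0, te$strand,
                   sep = "\t"), path)
  invisible(path)
}
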