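test_that("generators are byte-identical under a fixed config and seed", {
  cfg <- synthetic_config(seed = 7, n_transcripts = 5,
                          n_pirna = 2000L, n_rpf = 2000L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  for (d in c(d1, d2)) {
    tr <- make_transcriptome(cfg)
    write_bed12(tr$models, file.path(d, "tx.bed"))
    write_fasta(tr$sequences, file.path(d, "tx.fa"))
    if (!is.null(tr$te)) write_te_bed(tr$te, file.path(d, "te.bed"))
    write_reads_tsv(make_pirna_reads(cfg, tr$models, tr$sequences),
                    file.path(d, "pir.tsv"))
  }
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
})

test_that("emitted BED12/FASTA round-trip losslessly through the readers", {
  cfg <- synthetic_config(seed = 4, n_transcripts = 6)
  tr <- make_transcriptome(cfg)
  bed <- withr::local_tempfile(fileext = ".bed")
  fa <- withr::local_tempfile(fileext = ".fa")
  write_bed12(tr$models, bed)
  write_fasta(tr$sequences, fa)
  back <- load_transcripts(bed)
  seqs <- read_fasta(fa)
  expect_setequal(names(back), names(tr$models))
  for (id in names(back)) {
    expect_equal(back[[id]]$exons, tr$models[[id]]$exons)
    expect_equal(back[[id]]$cds_start_t, tr$models[[id]]$cds_start_t)
    expect_equal(back[[id]]$cds_end_t, tr$models[[id]]$cds_end_t)
  }
  expect_identical(seqs[names(tr$sequences)], tr$sequences)
  ## TE inserts: sequence under the insert equals the (oriented) consensus
  expect_true(!is.null(tr$te))
})

test_that("generated reads satisfy the read-record bounds invariants", {
  cfg <- synthetic_config(seed = 10, n_transcripts = 8, n_pirna = 5000L,
                          n_rpf = 5000L)
  tr <- make_transcriptome(cfg)
  pir <- make_pirna_reads(cfg, tr$models, tr$sequences)
  rpf <- make_rpf_reads(cfg, tr$models, pir)
  expect_true(validate_reads(pir, tr$models))
  expect_true(validate_reads(rpf, tr$models))
  ## piRNA sequences really are precursor substrings
  rec <- pir$records
  expect_true(all(substr(tr$sequences[rec$ref_id], rec$five_prime + 1L,
                         rec$five_prime + rec$length) == rec$sequence))
})

test_that("uppl region-length sampler hits the stated medians (n = 500)", {
  cfg <- synthetic_config(seed = 3, n_transcripts = 500, te_insert = NULL)
  tr <- make_transcriptome(cfg)
  lens <- t(vapply(tr$models, region_lengths, numeric(3)))
  expect_lt(abs(stats::median(lens[, "UTR3"]) - 4583) / 4583, 0.10)
  expect_lt(abs(stats::median(lens[, "ORF"]) - 1314) / 1314, 0.10)
  ## ORF lengths are codon multiples
  expect_true(all(lens[, "ORF"] %% 3 == 0))
})

test_that("piRNA generator: 1U bias and region density are recoverable", {
  cfg <- synthetic_config(seed = 8, n_pirna = 100000L, p_1U = 0.85)
  tr <- make_transcriptome(cfg)
  pir <- make_pirna_reads(cfg, tr$models, tr$sequences)
  bm <- nucleotide_bias(pir, tr$sequences, K = 1L)
  fU <- unname(bm$freq["p1", "U"])
  ## invert f = p + (1 - p) * u with u the weighted background U frequency
  ## over the generator's candidate positions
  wsum <- 0; usum <- 0
  for (m in tr$models) {
    sq <- tr$sequences[[m$transcript_id]]
    for (rg in c("ORF", "UTR3")) {
      b <- if (rg == "ORF") c(m$cds_start_t, m$cds_end_t)
           else c(m$cds_end_t, m$spliced_length)
      hi <- min(b[2] - 1L, m$spliced_length - 32L)
      cand <- seq.int(b[1], hi)
      u <- mean(substr(rep(sq, length(cand)), cand + 1L, cand + 1L) == "T")
      w <- cfg$pi_density[[rg]] * (b[2] - b[1])
      wsum <- wsum + w; usum <- usum + w * u
    }
  }
  ubar <- usum / wsum
  p_hat <- (fU - ubar) / (1 - ubar)
  expect_lt(abs(p_hat - 0.85), 0.02)

  ## per-nt density ratio ~31 with equal region lengths -> ~31x count ratio
  cfg_eq <- synthetic_config(seed = 9, n_transcripts = 10, n_pirna = 100000L,
                             region_medians = c(UTR5 = 60, ORF = 999,
                                                UTR3 = 1000),
                             region_sdlog = 1e-9, te_insert = NULL)
  tr2 <- make_transcriptome(cfg_eq)
  pir2 <- make_pirna_reads(cfg_eq, tr2$models, tr2$sequences)
  q <- quantify(normalization_factor(pir2, "miRNA_sum", aux = 1e6),
                tr2$models)
  ratio <- sum(q$raw_count[q$region == "UTR3"]) /
    sum(q$raw_count[q$region == "ORF"])
  expect_lt(abs(ratio / (31 * 1000 / 999) - 1), 0.05)
})

test_that("RPF generator: frame fidelity is recoverable to +/- 0.02", {
  cfg <- synthetic_config(seed = 14, rpf_frame_fidelity = 0.9,
                          n_rpf = 100000L, rpf_orf_fraction = 1,
                          coincidence_rate = 0, te_insert = NULL)
  tr <- make_transcriptome(cfg)
  rpf <- make_rpf_reads(cfg, tr$models)
  rec <- rpf$records
  cds <- vapply(tr$models, `[[`, integer(1), "cds_start_t")
  inframe <- (rec$five_prime - cds[rec$ref_id]) %% 3L == 0L
  obs <- sum(rec$count[inframe]) / sum(rec$count)
  ## per-transcript null in-frame fraction over the candidate range,
  ## weighted by that transcript's reads
  q_t <- vapply(tr$models, function(m) {
    hi <- min(m$cds_end_t - 1L, m$spliced_length - 32L)
    cand <- seq.int(m$cds_start_t, hi)
    mean((cand - m$cds_start_t) %% 3L == 0L)
  }, numeric(1))
  w_t <- vapply(names(tr$models), function(id)
    sum(rec$count[rec$ref_id == id]), numeric(1))
  qbar <- sum(q_t * w_t) / sum(w_t)
  f_hat <- (obs - qbar) / (1 - qbar)
  expect_lt(abs(f_hat - 0.9), 0.02)
  ## fidelity 1 puts every ORF 5' end at a codon start
  cfg1 <- synthetic_config(seed = 15, rpf_frame_fidelity = 1,
                           n_rpf = 3000L, rpf_orf_fraction = 1,
                           coincidence_rate = 0, n_transcripts = 5,
                           te_insert = NULL)
  tr1 <- make_transcriptome(cfg1)
  r1 <- make_rpf_reads(cfg1, tr1$models)$records
  cds1 <- vapply(tr1$models, `[[`, integer(1), "cds_start_t")
  expect_true(all((r1$five_prime - cds1[r1$ref_id]) %% 3L == 0L))
})

test_that("RPF generator: the piRNA coincidence rate rho is recoverable", {
  cfg <- synthetic_config(seed = 18, coincidence_rate = 0.5,
                          rpf_orf_fraction = 0, n_rpf = 100000L,
                          n_pirna = 100000L)
  tr <- make_transcriptome(cfg)
  pir <- make_pirna_reads(cfg, tr$models, tr$sequences)
  rpf <- make_rpf_reads(cfg, tr$models, pir)
  rec <- rpf$records
  ## count-weighted fraction of 3'UTR RPF 5' ends sitting on a piRNA 5' end
  pk <- unique(pir$records[, c("ref_id", "five_prime")])
  pk_key <- paste(pk$ref_id, pk$five_prime)
  hit <- paste(rec$ref_id, rec$five_prime) %in% pk_key
  m_obs <- sum(rec$count[hit]) / sum(rec$count)
  ## chance-hit probability per transcript over the uniform candidate range
  q_t <- vapply(tr$models, function(m) {
    cand <- seq.int(m$cds_end_t, m$spliced_length - 32L)
    p <- pk$five_prime[pk$ref_id == m$transcript_id]
    length(intersect(p, cand)) / length(cand)
  }, numeric(1))
  w_t <- vapply(tr$models, function(m) region_lengths(m)[["UTR3"]],
                numeric(1))
  qbar <- sum(q_t * w_t) / sum(w_t)
  rho_hat <- (m_obs - qbar) / (1 - qbar)
  expect_lt(abs(rho_hat - 0.5), 0.02)
  ## chemistry marks the copied reads as in vivo 5'P
  expect_setequal(unique(rec$chemistry), c("P5", "OH5"))
  expect_error(make_rpf_reads(cfg, tr$models, pirnas = NULL), "piRNA")
})

test_that("ping-pong generator: phi recoverable on a long reference", {
  cfg <- synthetic_config(seed = 22, pingpong_fraction = 0.5,
                          n_pingpong = 100000L)
  rs <- make_pingpong_reads(cfg, reference_length = 2000000L)
  p <- rs$plus$records; q <- rs$minus$records
  targets <- unique(p$five_prime + cfg$slicer_offset - 1L)
  hit <- q$five_prime %in% targets
  m_obs <- sum(q$count[hit]) / sum(q$count)
  L <- 2000000L
  qnull <- length(intersect(targets, 32:(L - 2L))) / (L - 33L)
  phi_hat <- (m_obs - qnull) / (1 - qnull)
  expect_lt(abs(phi_hat - 0.5), 0.02)
  ## phi = 1 concentrates the spectrum at the slicer offset (a sparse,
  ## long reference keeps incidental opposite-strand pairs negligible)
  cfg1 <- synthetic_config(seed = 23, pingpong_fraction = 1,
                           n_pingpong = 200L)
  rs1 <- make_pingpong_reads(cfg1, reference_length = 2000000L)
  pp <- pingpong(rs1$plus, rs1$minus)
  expect_equal(pp$overlap_lengths[which.max(pp$pair_count)], 10L)
  expect_gte(pp$pair_count[10] / sum(pp$pair_count), 0.9)
})

test_that("abundance triplets realize the requested coupling structure", {
  lg <- function(v) log10(v + 0.001)
  cfg_c <- synthetic_config(seed = 30, n_transcripts = 1000,
                            coupling = "coupled", noise_sd = 0.3)
  t_c <- make_abundance_triplets(cfg_c)
  r_c <- partial_correlation(lg(t_c$pirna), lg(t_c$rpf), lg(t_c$rna))$r
  expect_gt(r_c, 0.5)

  cfg_d <- synthetic_config(seed = 30, n_transcripts = 1000,
                            coupling = "decoupled", noise_sd = 0.3)
  t_d <- make_abundance_triplets(cfg_d)
  r_d <- partial_correlation(lg(t_d$pirna), lg(t_d$rpf), lg(t_d$rna))$r
  expect_lt(abs(r_d), 0.1)

  cfg_0 <- synthetic_config(seed = 31, n_transcripts = 1000,
                            coupling = "coupled", noise_sd = 0.01)
  t_0 <- make_abundance_triplets(cfg_0)
  expect_gt(partial_correlation(lg(t_0$pirna), lg(t_0$rpf), lg(t_0$rna))$r,
            0.99)
  expect_error(synthetic_config(noise_sd = 0), "noise_sd")
  expect_error(make_abundance_triplets(
    synthetic_config(n_transcripts = 5)), "n_transcripts >= 10")
})

test_that("config validation rejects malformed worlds", {
  expect_error(synthetic_config(p_1U = 1.2), "probabilities")
  expect_error(synthetic_config(
    te_insert = list(family = "SINE", length = 5000L, strand = "-",
                     region = "UTR3", prob = 1)), "longer than")
  ## p_1U = 1 with a U-free region is a stratum-exhausted error
  cfg <- synthetic_config(seed = 2, n_transcripts = 1, p_1U = 1,
                          n_pirna = 10L, te_insert = NULL)
  tr <- make_transcriptome(cfg)
  seqs <- tr$sequences
  seqs[[1]] <- gsub("T", "A", seqs[[1]])
  expect_error(make_pirna_reads(cfg, tr$models, seqs), "no U position")
})
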