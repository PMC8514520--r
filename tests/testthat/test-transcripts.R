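test_that("region partition follows the half-open convention", {
  m <- toy_model()
  expect_equal(unname(region_lengths(m)), c(30L, 60L, 10L))
  expect_equal(sum(region_lengths(m)), m$spliced_length)
  expect_equal(region_of(m, m$cds_start_t), "ORF")
  expect_equal(region_of(m, m$cds_end_t), "UTR3")
  expect_equal(region_of(m, m$cds_start_t - 1L), "UTR5")
  ## every position gets exactly one region
  reg <- region_of(m, 0:(m$spliced_length - 1L))
  expect_equal(unname(table(reg)[c("UTR5", "ORF", "UTR3")]),
               unname(region_lengths(m)), ignore_attr = TRUE)
  expect_error(region_of(m, m$spliced_length), "out of")
  expect_error(region_of(m, -1L), "out of")
})

test_that("coordinate mapping and round-trip identity, both strands", {
  m <- toy_model()
  expect_equal(genomic_to_transcript(m, 100L), 0L)
  expect_true(is.na(genomic_to_transcript(m, 99L)))
  expect_true(is.na(genomic_to_transcript(m, 200L)))

  mm <- toy_minus_model()
  ## first transcript base of a minus-strand model = genomic end - 1 of the
  ## genomically last interval
  expect_equal(genomic_to_transcript(mm, 339L), 0L)
  expect_equal(transcript_to_genomic(mm, 0L), 339L)
  ## intronic position
  expect_true(is.na(genomic_to_transcript(mm, 200L)))

  for (m2 in list(m, mm)) {
    tp <- 0:(m2$spliced_length - 1L)
    gp <- transcript_to_genomic(m2, tp)
    expect_equal(genomic_to_transcript(m2, gp), tp)
    ## genomic -> transcript -> genomic over all exonic positions
    gall <- unlist(lapply(seq_len(nrow(m2$exons)), function(i)
      m2$exons$start[i]:(m2$exons$end[i] - 1L)))
    expect_equal(transcript_to_genomic(m2, genomic_to_transcript(m2, gall)),
                 gall)
  }
})

test_that("round-trip holds on randomized synthetic models", {
  cfg <- synthetic_config(seed = 42, n_transcripts = 6,
                          region_medians = c(UTR5 = 50, ORF = 150, UTR3 = 120),
                          te_insert = NULL)
  tr <- make_transcriptome(cfg)
  for (m in tr$models) {
    tp <- 0:(m$spliced_length - 1L)
    expect_equal(genomic_to_transcript(m, transcript_to_genomic(m, tp)), tp)
  }
})

test_that("BED12 write/load round-trips models, ORFs may span junctions", {
  models <- list(toy_model(), toy_minus_model())
  names(models) <- vapply(models, `[[`, character(1), "transcript_id")
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed12(models, path)
  back <- load_transcripts(path, format = "bed12")
  expect_setequal(names(back), names(models))
  for (id in names(models)) {
    expect_equal(back[[id]]$exons, models[[id]]$exons)
    expect_equal(back[[id]]$cds_start_t, models[[id]]$cds_start_t)
    expect_equal(back[[id]]$cds_end_t, models[[id]]$cds_end_t)
    expect_equal(back[[id]]$strand, models[[id]]$strand)
  }
  ## the minus-strand model has 2 blocks and a thick region spanning both:
  ## its ORF crosses the junction
  expect_equal(nrow(back$toyM$exons), 2L)
  expect_true(back$toyM$cds_start_t < 50L && back$toyM$cds_end_t > 50L)
})

test_that("malformed BED12 errors with the line number", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100\ttx1\t0\t+\t0\t100\t0\t1\t100,\t0,",
               "chr1\t0\t100"), path)
  expect_error(load_transcripts(path, "bed12"), "line 2")
})

test_that("GTF loading converts coordinates and honours stop_codon", {
  path <- withr::local_tempfile(fileext = ".gtf")
  attr1 <- 'gene_id "g1"; transcript_id "tx1";'
  writeLines(c(
    paste("chr1", "src", "exon", 101, 200, ".", "+", ".", attr1, sep = "\t"),
    paste("chr1", "src", "CDS", 131, 187, ".", "+", ".", attr1, sep = "\t"),
    paste("chr1", "src", "stop_codon", 188, 190, ".", "+", ".", attr1,
          sep = "\t")), path)
  m <- load_transcripts(path, "gtf")[["tx1"]]
  ## 1-based inclusive GTF -> 0-based half-open; stop codon inside the ORF
  expect_equal(m$exons, data.frame(start = 100L, end = 200L))
  expect_equal(m$cds_start_t, 30L)
  expect_equal(m$cds_end_t, 90L)   # 187 + 3 nt stop, transcript coord 90
  expect_equal(m$gene_id, "g1")
})

test_that("non-coding models are flagged and rejected by region ops", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t0\t100\tnc1\t0\t+\t0\t0\t0\t1\t100,\t0,", path)
  m <- load_transcripts(path, "bed12")[["nc1"]]
  expect_false(m$coding)
  expect_error(region_of(m, 10L), "non-coding")
})

test_that("junction sequences: count, length, and minus-strand revcomp", {
  genome <- c(chr1 = paste(rep("ACGT", 200), collapse = ""))
  m <- toy_model()
  expect_equal(nrow(junction_sequences(m, genome, 30L)), 0L)

  m2 <- transcript_model("j2", chrom = "chr1", strand = "+",
                         exons = data.frame(start = c(40L, 300L),
                                            end = c(140L, 400L)),
                         cds_start_t = 0L, cds_end_t = 60L)
  jn <- junction_sequences(m2, genome, 30L)
  expect_equal(nrow(jn), 1L)        # 2 exons -> exactly 1 junction
  expect_equal(nchar(jn$sequence), 60L)
  expect_equal(jn$boundary, 30L)
  chrom <- genome[["chr1"]]
  expect_equal(jn$sequence,
               paste0(substr(chrom, 111, 140), substr(chrom, 301, 330)))

  ## minus strand: hand reverse-complement of a tiny constructed case
  g2 <- c(c2 = "AACCGGTTACGTACGTAAGG")
  mm <- transcript_model("jm", chrom = "c2", strand = "-",
                         exons = data.frame(start = c(2L, 12L),
                                            end = c(6L, 16L)),
                         cds_start_t = 0L, cds_end_t = 6L)
  jn2 <- junction_sequences(mm, g2, 3L)
  ## upstream exon (transcript order) = genomic [12,16): CGTA; its last 3 nt
  ## in transcript orientation = revcomp(CGT); downstream exon [2,6): CCGG,
  ## first 3 in transcript orientation = revcomp(CGG)
  up <- revcomp(substr(g2[["c2"]], 13, 15))   # genomic [12,15)
  dn <- revcomp(substr(g2[["c2"]], 4, 6))     # genomic [3,6)
  expect_equal(jn2$sequence, paste0(up, dn))
})

test_that("model invariants are enforced", {
  expect_error(transcript_model("bad", chrom = "chr1", strand = "+",
                                exons = data.frame(start = 10L, end = 10L),
                                cds_start_t = 0L, cds_end_t = 0L),
               "start >= end")
  expect_error(transcript_model("bad", chrom = "chr1", strand = "+",
                                exons = data.frame(start = c(0L, 5L),
                                                   end = c(10L, 20L)),
                                cds_start_t = 0L, cds_end_t = 3L),
               "overlapping")
  expect_error(transcript_model("bad", chrom = "chr1", strand = "+",
                                exons = data.frame(start = 0L, end = 10L),
                                cds_start_t = 0L, cds_end_t = 11L),
               "ORF boundaries")
})
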