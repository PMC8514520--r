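norm_toy <- function(records, denom = 1e6) {
  normalization_factor(read_set(records), "miRNA_sum", aux = denom)
}

test_that("ppm/rpkm arithmetic including the 0.001 pseudocount", {
  m <- transcript_model("t2k", chrom = "c", strand = "+",
                        exons = data.frame(start = 0L, end = 4000L),
                        cds_start_t = 1000L, cds_end_t = 2000L)  # 3'UTR 2 kb
  ## 100 reads with 5' ends in the 3'UTR, denominator 1e6
  set <- norm_toy(data.frame(ref_id = "t2k", strand = "+",
                             five_prime = 2000L + seq_len(100L) * 10L,
                             length = 26L))
  q <- quantify(set, list(t2k = m))
  u3 <- q[q$region == "UTR3", ]
  expect_equal(u3$ppm, 100)
  expect_equal(u3$rpkm, 50.0005)           # (100 + .001) / (2 kb * 1)
  ## empty region of length 1 kb -> rpkm = pseudocount / 1
  orf <- q[q$region == "ORF", ]
  expect_equal(orf$raw_count, 0)
  expect_equal(orf$rpkm, 0.001)
})

test_that("5'-end region assignment; region sums equal the whole", {
  m <- toy_model()
  ## 5' end on the last ORF base, body extending into the 3'UTR -> ORF
  set <- norm_toy(data.frame(ref_id = "toy1", strand = "+",
                             five_prime = c(89L, 90L, 0L), length = 9L,
                             count = c(2L, 3L, 1L)))
  q <- quantify(set, list(toy1 = m))
  expect_equal(q$raw_count[q$region == "ORF"], 2)
  expect_equal(q$raw_count[q$region == "UTR3"], 3)
  expect_equal(q$raw_count[q$region == "UTR5"], 1)
  expect_equal(q$raw_count[q$region == "whole"],
               sum(q$raw_count[q$region != "whole"]))
})

test_that("quantify is linear in counts and warns on unknown transcripts", {
  m <- toy_model()
  r1 <- data.frame(ref_id = "toy1", strand = "+", five_prime = 40L,
                   length = 20L, count = 5L)
  q1 <- quantify(norm_toy(r1), list(toy1 = m))
  r2 <- r1; r2$count <- 15L
  q2 <- quantify(norm_toy(r2), list(toy1 = m))
  expect_equal(q2$ppm, q1$ppm * 3)
  expect_true(all(q2$rpkm >= q1$rpkm))   # monotone for fixed lengths

  r3 <- rbind(r1, data.frame(ref_id = "ghost", strand = "+", five_prime = 0L,
                             length = 20L, count = 1L))
  expect_warning(quantify(norm_toy(r3), list(toy1 = m)), "unknown")
})

test_that("genome-space reads are projected through the models", {
  m <- toy_model()   # exon [100, 200)
  set <- norm_toy(data.frame(ref_id = "chr1", space = "genome", strand = "+",
                             five_prime = c(140L, 50L), length = 20L))
  q <- quantify(set, list(toy1 = m))
  expect_equal(q$raw_count[q$region == "ORF"], 1)  # tpos 40
  expect_equal(sum(q$raw_count[q$region == "whole"]), 1)  # intergenic dropped
})

test_that("exon/intron enrichment matches the arithmetic oracle", {
  ## exon 1 kb total, intron 9 kb: 99 exonic + 1 intronic reads -> fold 891
  m <- transcript_model("sp", chrom = "c", strand = "+",
                        exons = data.frame(start = c(0L, 9500L),
                                           end = c(500L, 10000L)),
                        cds_start_t = 0L, cds_end_t = 300L)
  reads <- read_set(data.frame(
    ref_id = "c", space = "genome", strand = "+",
    five_prime = c(sample(c(0:499, 9500:9999), 99, replace = TRUE),
                   5000L),
    length = 26L))
  res <- exon_intron_enrichment(reads, list(sp = m))
  expect_equal(res$fold_enrichment, (99 / 1000) / (1 / 9000))
  expect_equal(res$frac_exon, 0.99)
  expect_false(res$pseudocount_used)

  ## equal densities -> fold 1
  eq <- read_set(data.frame(ref_id = "c", space = "genome", strand = "+",
                            five_prime = c(100L, 5000L), length = 26L,
                            count = c(1L, 9L)))
  expect_equal(exon_intron_enrichment(eq, list(sp = m))$fold_enrichment, 1)

  ## all exonic -> pseudocounted, flagged, monotone in exon count
  allex <- read_set(data.frame(ref_id = "c", space = "genome", strand = "+",
                               five_prime = c(10L, 20L), length = 26L))
  r1 <- exon_intron_enrichment(allex, list(sp = m))
  expect_true(r1$pseudocount_used)
  more <- read_set(data.frame(ref_id = "c", space = "genome", strand = "+",
                              five_prime = c(10L, 20L, 30L), length = 26L))
  expect_gt(exon_intron_enrichment(more, list(sp = m))$fold_enrichment,
            r1$fold_enrichment)
  ## single-exon models cannot contribute
  expect_error(exon_intron_enrichment(allex, list(toy1 = toy_model())),
               "introns")
})

test_that("region ratios apply the symmetric pseudocount", {
  m <- toy_model()
  num <- norm_toy(data.frame(ref_id = "toy1", strand = "+",
                             five_prime = 95L, length = 5L, count = 10L), 1e6)
  den0 <- norm_toy(data.frame(ref_id = "toy1", strand = "+",
                              five_prime = 40L, length = 5L, count = 10L), 1e6)
  rr <- region_ratio(num, den0, list(toy1 = m), region = "UTR3")
  expect_equal(rr$ratio, 10.001 / 0.001)   # pseudocount-dominated
  expect_true(rr$flagged)

  rr2 <- region_ratio(num, num, list(toy1 = m), region = "UTR3")
  expect_equal(rr2$ratio, 1)
  expect_equal(rr2$log2_ratio, 0)

  ## three-transcript fixture against hand arithmetic
  ms <- list(toy1 = m,
             t2 = transcript_model("t2", chrom = "c", strand = "+",
                                   exons = data.frame(start = 0L, end = 300L),
                                   cds_start_t = 50L, cds_end_t = 200L),
             t3 = transcript_model("t3", chrom = "c", strand = "+",
                                   exons = data.frame(start = 0L, end = 300L),
                                   cds_start_t = 0L, cds_end_t = 150L))
  nr <- norm_toy(data.frame(ref_id = c("toy1", "t2", "t3"), strand = "+",
                            five_prime = c(95L, 250L, 200L), length = 5L,
                            count = c(2L, 4L, 8L)), 1e6)
  dr <- norm_toy(data.frame(ref_id = c("toy1", "t2", "t3"), strand = "+",
                            five_prime = c(95L, 250L, 200L), length = 5L,
                            count = c(1L, 2L, 2L)), 1e6)
  rr3 <- region_ratio(nr, dr, ms, region = "UTR3")
  rr3 <- rr3[order(rr3$transcript_id), ]
  expect_equal(rr3$ratio, (c(4, 8, 2) + 0.001) / (c(2, 2, 1) + 0.001))
})
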