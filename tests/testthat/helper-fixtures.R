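## Shared fixtures and independent brute-force oracles.

## plus-strand single-exon toy: exon [100, 200), thick [130, 190)
## -> 5'UTR 30 nt, ORF 60 nt, 3'UTR 10 nt
toy_model <- function() {
  transcript_model("toy1", chrom = "chr1", strand = "+",
                   exons = data.frame(start = 100L, end = 200L),
                   cds_start_t = 30L, cds_end_t = 90L)
}

## minus-strand two-exon toy with a junction
toy_minus_model <- function() {
  transcript_model("toyM", chrom = "chr1", strand = "-",
                   exons = data.frame(start = c(100L, 300L),
                                      end = c(160L, 340L)),
                   cds_start_t = 10L, cds_end_t = 70L)
}

mk_reads <- function(five_prime, length = 26L, strand = "+", ref_id = "t1",
                     count = 1L, ...) {
  n <- length(five_prime)
  read_set(data.frame(ref_id = rep_len(ref_id, n),
                      strand = rep_len(strand, n),
                      five_prime = five_prime,
                      length = rep_len(length, n),
                      count = rep_len(count, n), ...))
}

## random read fixture over a small reference, both strands / two refs
random_fixture <- function(seed, n = 150, L = 400L) {
  set.seed(seed)
  read_set(data.frame(
    ref_id = sample(c("r1", "r2"), n, replace = TRUE),
    strand = sample(c("+", "-"), n, replace = TRUE),
    five_prime = sample.int(L, n, replace = TRUE) - 1L,
    length = sample(24:32, n, replace = TRUE),
    count = sample(1:3, n, replace = TRUE)))
}

## O(|A| x |B|) distance-spectrum oracle, straight from the definition
bf_spectrum <- function(a, b, window = 50L, self = FALSE) {
  arec <- as.data.frame(a$records)
  brec <- as.data.frame(b$records)
  offsets <- c(-window:-1L, 1:window)
  val <- stats::setNames(numeric(2 * window), offsets)
  pc <- stats::setNames(numeric(2 * window), offsets)
  nb <- sum(brec$count)
  for (i in seq_len(nrow(brec))) {
    tall <- stats::setNames(numeric(2 * window), offsets)
    for (j in seq_len(nrow(arec))) {
      if (arec$ref_id[j] != brec$ref_id[i] ||
          arec$strand[j] != brec$strand[i]) next
      d <- if (brec$strand[i] == "+")
        arec$five_prime[j] - brec$five_prime[i]
      else brec$five_prime[i] - arec$five_prime[j]
      if (d < -window || d > window - 1L) next
      off <- as.character(if (d >= 0) d + 1L else d)
      tall[off] <- tall[off] + arec$count[j]
    }
    if (self) tall["1"] <- max(tall["1"] - 1, 0)
    tot <- sum(tall)
    if (tot > 0) val <- val + brec$count[i] * tall / tot
    pc <- pc + brec$count[i] * tall
  }
  list(value = unname(val) / nb, pair_counts = unname(pc))
}

## O(|plus| x |minus|) ping-pong oracle
bf_pingpong <- function(plus, minus, max_overlap = 50L) {
  p <- as.data.frame(plus$records[plus$records$strand == "+"])
  q <- as.data.frame(minus$records[minus$records$strand == "-"])
  pc <- numeric(max_overlap)
  for (i in seq_len(nrow(p))) for (j in seq_len(nrow(q))) {
    if (p$ref_id[i] != q$ref_id[j]) next
    g <- q$five_prime[j] - p$five_prime[i] + 1L
    if (g >= 1 && g <= max_overlap)
      pc[g] <- pc[g] + p$count[i] * q$count[j]
  }
  pc
}

## direct-summation DFT periodogram oracle
bf_periodogram <- function(x) {
  n <- length(x)
  x <- x - mean(x)
  k <- seq_len(n %/% 2)
  vapply(k, function(kk) {
    t <- seq_len(n) - 1L
    re <- sum(x * cos(2 * pi * kk * t / n))
    im <- sum(x * sin(2 * pi * kk * t / n))
    (re^2 + im^2) / n
  }, numeric(1))
}

## uniform read sets for null calibration
uniform_set <- function(n, L, strand = "+", ref_id = "r") {
  read_set(data.frame(ref_id = ref_id, strand = strand,
                      five_prime = sample.int(L, n, replace = TRUE) - 1L,
                      length = 26L))
}

## abundance tables in the quantify() schema, for caller tests
abt <- function(id, orf_count, utr3_count, denom = 1e6) {
  data.frame(transcript_id = id,
             region = c("UTR5", "ORF", "UTR3", "whole"),
             raw_count = c(0, orf_count, utr3_count, orf_count + utr3_count),
             ppm = c(0, orf_count, utr3_count, orf_count + utr3_count) /
               denom * 1e6,
             stringsAsFactors = FALSE)
}

## one-transcript caller fixture realizing the requested ppm / fraction
call_one <- function(pirna_ppm, frac, rpf_ppm) {
  utr3 <- pirna_ppm * frac
  orf <- pirna_ppm - utr3
  m <- transcript_model("tx", chrom = "c", strand = "+",
                        exons = data.frame(start = 0L, end = 1000L),
                        cds_start_t = 100L, cds_end_t = 700L)
  call_uppl(abt("tx", orf, utr3), abt("tx", rpf_ppm, 0), list(tx = m))
}
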