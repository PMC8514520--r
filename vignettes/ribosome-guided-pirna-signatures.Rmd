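---
title: "Detecting ribosome-guided piRNA biogenesis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting ribosome-guided piRNA biogenesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pirnasig)
```

## The biological model

Some protein-coding mRNAs in amniote testes moonlight as piRNA
precursors: after the pioneer rounds of translation, post-termination 80S
ribosomes that fail to recycle migrate into the 3′UTR, and the piRNA
processing machinery cleaves the RNA at the ribosome's 5′ boundary.  The
observable consequences, and the statistics this package computes for
them, are:

1. piRNA 5′ ends and 3′UTR ribosome-footprint (RPF) 5′ ends coincide
   (overlap distance spectrum, `distance_spectrum()` / `overlap_z()`);
2. 3′UTR RPFs carry in-vivo 5′-monophosphate ends and a 1U bias, unlike
   the in-vitro 5′OH fragments from translated ORFs (`nucleotide_bias()`,
   `region_ratio()` for 5′P:5′OH comparisons);
3. ORF RPFs phase with the 3-nt codon step (`phasing_periodogram()`);
4. piRNA abundance tracks ribosome occupancy beyond what transcript
   abundance explains (`partial_correlation()`);
5. precursors are spliced, polyadenylated mRNAs (junction-mapping reads,
   `junction_sequences()` / `junction_read_assignment()`, exon/intron
   densities, `exon_intron_enrichment()`);
6. embedded transposon fragments yield antisense TE piRNAs that engage
   ping-pong amplification (`te_content()`, `pingpong()`).

## The distance spectrum, precisely

For read sets *A* and *B* on a shared coordinate space, only
same-reference, same-strand pairs are considered.  For each *b* in *B*
the window covers 50 nt upstream through 49 nt downstream of *b*'s 5′ end
*in the read's own orientation* (so "downstream" is decreasing coordinate
on the minus strand).  There is no offset 0: offset +1 is exact
coincidence, offsets +2…+50 are 1…49 nt downstream, −1…−50 are 1…50 nt
upstream — 100 offsets in all.  The per-*b* spectrum is the fraction of
*A* 5′ ends (weighted by collapsed-read counts) at each offset among the
*A* reads in the window; the reported spectrum is the sum of per-*b*
spectra divided by the total count of *B*.  Consequences worth knowing:

- the spectrum's mass is ≤ 1, with the deficit contributed by *B* reads
  whose windows contain no *A* read;
- the statistic is invariant to library depth of *A* per window (each
  window is normalized before averaging), which is what makes the
  Z-score across offsets meaningful.

The Z-score standardizes offset +1 against the other 99 offsets using the
*sample* standard deviation (the dispersion convention is not dictated by
the spectrum's definition; n−1 is the conservative choice and is fixed
here so results are reproducible).  p-values are one-sided upper normal
tails, matching the Z = 1.96 ↔ p = 0.025 convention.  A perfectly flat
spectrum is treated as a well-defined null (Z = 0, p = 0.5); a focal
excess over a zero-variance background raises an error rather than
returning infinity.

For self-spectra (phasing), each read's trivial pairing with itself is
excluded, otherwise offset +1 would be inflated by construction.

## Ping-pong

For a plus-strand read *p* and minus-strand read *q* (whose `five_prime`
is its 5′-most base in plus-strand coordinates), the 5′–5′ overlap is
*g = q₅ − p₅ + 1*.  Pair counts are count-weighted products, and *z₁₀*
standardizes *g* = 10 against overlaps 1…50 excluding 10 — mirroring the
overlap-Z construction, since no alternative background is canonical.

## Periodogram

The classical (Schuster) periodogram of the mean-centered downstream half
(offsets +1…+50) of the self spectrum: *I(f_k) = |DFT(x)|²/n* at Fourier
frequencies *k/n*, *k* = 1…⌊n/2⌋, with relative density normalized to the
first reported frequency.  With the default 50-point series the grid
frequency nearest 1/3 is 17/50 = 0.34 (period 2.94 nt); tests therefore
ask that the spectral peak's period *rounds* to 3 nt.  A constant series
is reported as zero power and flagged, not an error.  The exact
periodogram variant used upstream of this convention is not fully
specified anywhere; the classical one is implemented and documented, and
the dual-route unit tests pin it to a direct-summation DFT oracle.

## Normalization and quantification

`normalization_factor()` sets the denominator constituting one million
for ppm: the miRNA-read sum for small-RNA libraries, a spike-in count for
fraction libraries (the rescaling convention for spike-ins is
deliberately left as a user-supplied denominator), the mRNA-CDS-mapped
sum for RPF libraries, the mitochondrial-CDS sum for harringtonine
experiments, and an upper-quartile option for abundance vectors (75th
percentile of nonzero values × number of expressed transcripts, the
edgeR-style effective library size) standing in for full transcript
quantification, which is out of scope.

Reads are assigned to 5′UTR/ORF/3′UTR *by their 5′ end only* (a read whose
5′ end is the last ORF base is an ORF read even though its body extends
into the 3′UTR).  rpkm adds the 0.001 pseudocount to the *read count*
(the convention "a pseudo count of 0.001" does not say where it is
added; count-side is implemented and configurable).  Ratio analyses
(5′P:5′OH, monosome:polysome, CBP80:eIF4E) use the same 0.001 pseudocount
on both ppm terms for symmetry.

The metagene profile rescales each transcript's per-region coverage to
the cohort's *median* region length by linear interpolation and
aggregates per bin with a 10% trimmed mean — 10% from *each* tail, the
standard statistical meaning (`mean(x, trim = 0.10)`).

The uppl caller applies a strict > 100 ppm piRNA threshold and inclusive
≥ 0.90 3′UTR fraction and ≥ 1 ppm ORF RPF thresholds, with the 3′UTR
fraction computed over counted (ORF + 3′UTR) piRNAs only.

## Matched simulated controls

The negative control for overlap analyses is a pool of all 28-mers of the
precursors (sliding window of 1 nt), sampled so the control
first-nucleotide counts equal the largest-remainder allocation of *n* to
the real library's first-nucleotide proportions.  Exact matching (rather
than independent multinomial draws) makes the control sharper and
testable; sampling is with replacement within strata (whether the
original procedure replaced is unstated; with-replacement is implemented
and documented).  One subtlety the test suite makes explicit:
composition-matched controls are slightly *positively* confounded with
the coincidence offset whenever the real library's first-nt composition
deviates from the precursor background, because both sets then
preferentially occupy the same base-class positions.  The null
calibration statement (controls vs real within |Z| ≤ 3) therefore holds
for composition-balanced fixtures; against 1U-biased real reads the
proper comparison is controls vs a *third* set, which is how the control
pool is used in the pipeline.

## The synthetic world

The generator's defaults are the stated world, fixed once:

| parameter | default | basis |
|---|---|---|
| uppl region medians | 346 / 1314 / 4583 nt | reported uppl 5′UTR/ORF/3′UTR medians (ORF rounded to a codon multiple from 1315.5) |
| control region medians | 77 / 945 / 392 nt | reported control-mRNA medians |
| cohort sizes | 30 uppl / 43 control | reported cohort sizes |
| region length spread | log-normal, sdlog 0.25 | unreported; a ±1 sd span of ~0.6–1.6× the median is typical of real length distributions |
| piRNA density weights | 3′UTR:ORF:5′UTR = 31:1:0 per nt | the reported >31-fold 3′UTR excess, read as the sampling weight (with equal region lengths it reproduces a 31× count ratio; with uppl lengths the count ratio is larger and the length-normalized ratio ≈ 8×, matching the reported pairing of 31-fold and 8-fold) |
| p(1U) | 0.85 | typical primary-piRNA 1U fraction; recovered exactly in expectation since the background is i.i.d. uniform |
| piRNA lengths | uniform 24–32 nt | only the >23 nt filter is stated; no generative distribution is |
| RPF lengths | uniform 26–32 nt | the RPF size selection |
| frame fidelity | 0.9 | strong but imperfect phasing, the realistic regime for testis Ribo-seq |
| coincidence rate ρ | 0.5 | no quantitative value is reported; 0.5 is chosen for testability (detectable but not degenerate) |
| ping-pong φ, slicer offset | 0.5, 10 nt | canonical slicer geometry; φ chosen for testability |
| TE insert (uppl preset) | antisense SINE fragment, 150 nt, in 80% of 3′UTRs | uppl 3′UTRs embed SINE fragments, mostly antisense-functional |
| abundance noise | rpf_noise_sd 0.3, noise_sd 0.3 | the translation-link and biogenesis-link noises are separate parameters: with both at 0.3 the coupled partial correlation is ≈ 1/√2 ≈ 0.7, matching the magnitude reported for real 3′UTRs, and shrinking the biogenesis noise drives r → 1 |

Background sequence is i.i.d. uniform A/C/G/T (making the 1U-recovery
expectation closed-form), except that ORFs are ATG + non-stop codons +
one stop codon so that translation frame is well defined.  Each generator
stage derives its own RNG stream from the master seed and restores the
session RNG afterwards; identical (config, seed) pairs give byte-identical
files.

What the generator does *not* emulate — hence what a green test does not
establish: sequencing error, adapter artifacts and ligation bias;
multimapping ambiguity (all synthetic reads are uniquely placed);
RNA-secondary-structure or motif-dependent cleavage preferences; the
exonuclease trimming that shapes real piRNA 3′ ends; developmental
dynamics; and inter-library biological variability.  Green acceptance
tests establish that the statistics detect the planted structures at the
stated effect sizes, not that real libraries contain them.

## Numerical conventions and degenerate inputs

- All coordinates are 0-based half-open; GTF is converted on read; the
  minus strand places transcript coordinate 0 at the genomically
  rightmost exonic base.  Stop codons excluded from GTF CDS features are
  unioned back into the ORF so the 3′UTR starts after termination.
- "Uniquely mapping" is honoured through an optional `n_hits` field
  (records with `n_hits` > 1 are dropped by `filter_reads()` by default);
  alignment itself is upstream.
- Collapsed reads: every statistic weights by `count`.
- Junction assignment is exact-match (the upstream aligner's 1-mismatch
  tolerance is an alignment concern; exactness keeps the oracle trivial);
  a read must span the boundary by ≥ 1 nt on both sides.
- Empty set B in a spectrum is an error; empty set A is an all-zero
  spectrum.  Zero normalization denominators are errors.  Transcripts
  absent from models are skipped with a warning, never silently.
- Partial correlation is transform-agnostic; the pipeline log10-transforms
  ppm with a 0.001 pseudocount first (the residual-plot convention leaves
  the transform unstated, so it is configurable and recorded in the
  report's provenance).
- Yates continuity correction defaults on for 2×2 chi-square tests: it is
  what reproduces the printed p = 0.55 for the splice-site table
  (207/4 vs 326/3) and matches the default of standard environments.

## Known limitations

- The phasing analysis implements only the self-spectrum periodicity; no
  head-to-tail (3′-to-5′) phasing statistic is defined here, since the
  underlying procedure defines none.
- TE analyses operate on genomic TE annotations; consensus-space
  remapping of TE reads is upstream.
- The CLI takes flags and JSON manifests rather than a YAML config (no
  YAML parser among the supported dependencies).
- `exon_intron_enrichment()` pools compartments across the cohort (union
  densities); per-locus enrichment can be had by calling it per model.

## A minimal end-to-end run

```{r example, eval = FALSE}
cfg <- synthetic_config(seed = 1, preset = "uppl")
report <- run_pipeline(cfg, out_dir = tempfile("pirnasig_run"))
print(report)
```
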