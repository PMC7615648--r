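---
title: "Methods: DNA-encoded RNAPII termination at T-tracts"
author: "tterm authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DNA-encoded RNAPII termination at T-tracts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Canonical mRNA 3′-end formation in budding yeast couples cleavage at the
poly(A) site (by the Ysh1 endonuclease, within the cleavage and
polyadenylation machinery) with torpedo-style degradation of the
downstream nascent RNA by the 5′→3′ exonuclease Rat1, which dislodges the
polymerase. A second, DNA-encoded route exists: elongating RNAPII can
dissociate spontaneously at runs of thymidines on the non-template
(coding) strand. In 3′-end sequencing data this spontaneous termination
is nearly invisible in wild-type cells — the RNA 3′ ends it produces are
uncapped and co-transcriptionally degraded — but becomes prominent when
Ysh1 or Rat1 is depleted from the nucleus (anchor-away), shifting 3′-end
signal from poly(A) sites to T-tract 3′ ends. `tterm` implements the
genome-scale computations behind this analysis, plus the single-molecule
FRET trajectory analysis used to observe termination in vitro, and a
synthetic-data generator with known truth against which every stage is
tested.

# Coordinate and track conventions

All internal coordinates are 0-based half-open; GFF3 (1-based closed) is
converted at the I/O boundary (`start − 1`), BED passes through
unchanged. Signal tracks store one non-negative value per base per
strand; minus-strand signal lives in its own file
(`*.minus.bedgraph`) and is never negated. bedGraph output run-length
encodes adjacent equal values, omits zero runs, and prints values with 17
significant digits so that a write/read round trip preserves every value
bit-exactly — this is asserted as a property test.

# Tract scanning

`find_homopolymer_runs()` reports maximal runs of a single base (N never
extends a run). Its correctness is established against an independent
regular-expression oracle on 1,000 random kilobase sequences at
`min_len` 1, 5 and 8. `scan_extended_orfs()` extends each
protein-coding, non-mitochondrial ORF 500 bp downstream on its own
strand and scans the coding-strand sequence for runs ≥ 5 bp. Runs that
cannot be resolved to a single gene are discarded: those overlapping two
same-strand extended ORFs, and those inside the overlap of a convergent
opposite-strand ORF pair. "Convergent" is not defined operationally in
the source analysis; we define it as an overlapping opposite-strand pair
whose plus-strand gene lies 5′-most, so the two 3′ ends face each other
inside the overlap, and we discard runs overlapping the ORF-overlap
region. The run-length frequency table spans 5–20 bp with a `20+`
accumulator bin, and a run straddling the ORF/flank boundary counts once
in each region tally (the "overlapping" reading, rather than
"contained").

For the ±500 bp profiles around termination sites, each window is read
on the site strand and, per base, the single largest run contributes
only its strand-aware 3′-end position to one of 100 ten-bp bins. Two
choices were open and are fixed here: ties for "largest" go to the
5′-most run on the site strand, and a "run" requires length ≥ 2 (both
configurable).

# Coverage and normalization

`three_prime_end_track()` counts the most 3′ transcribed base of each
read. With a reverse library prep (as in 3′-end sequencing), the
sequenced read's 5′-most aligned base marks the transcript 3′ end on the
opposite strand; a `forward` mode is provided for completeness. SAM/BAM
input is filtered at mapping quality 255 (unique alignments) *before*
counting, and `mapped_reads` — the denominator of the
`1e6 / mapped_reads` scale factor — is the number of reads passing that
filter. Replicates are merged by summing raw counts (and read totals)
before scaling. Replicate QC sums both strands in consecutive
left-closed 1 kb bins (final partial bin included) and computes Spearman
correlations with average ranks for ties.

# The island caller

The spontaneous-termination-site caller computes, per base and strand,
`r = (t + c) / (w + c)` between per-million-scaled treatment and control
tracks with pseudocount `c = 3` (so `r = 1` where both are zero), then
reports maximal runs of `r > 2` (strictly; `t = 9, w = 3, c = 3` gives
exactly 2 and is excluded) inside the 1 kb downstream of each
protein-coding gene's ORF 3′ end, on the gene's strand. Width-1 islands
are retained, islands separated by a single sub-threshold base are not
merged, and one gene may contribute several islands. The island — an
interval, not a point — defines "the termination site": the target
sequence for motif analysis is the 10 nt immediately 5′ of the island on
the gene strand and the background the 10 nt immediately 3′ of it.
Target or background windows may overlap the island's neighbours; no
exclusion is applied.

K-mer enrichment replaces de novo motif discovery with a transparent
statistic: for every k-mer (k = 5..10) present in the targets, region-level
hit counts (a region counts once, no reverse-strand matching) enter a
one-sided Fisher exact test against the background regions, with
Benjamini–Hochberg correction across all tested k-mers and ranking by
q-value then fold. This is a stand-in; it does not reproduce
position-weight-matrix refinement and is never claimed to.

# Poly(A) sites and terminator tracts

Poly(A) sites are kept at score strictly greater than 3, merged into
non-overlapping intervals where they overlap (score = maximum; abutting
intervals stay separate), and each merged interval assigned to the
nearest same-strand upstream gene whose ORF 3′ end lies within 500 bp
(inclusive). A gene's canonical site is its assigned site nearest the
ORF end — needed for distance distributions but not stated in the source
analysis. Terminator-tract discovery scans the 1 kb downstream of the
canonical site's 3′ edge on the gene strand at `min_len` 5, 6, 7 or 8
(the sets are provably nested), discarding tracts within 50 bp
(edge-to-edge, inclusive — the most conservative reading) of *any* kept
poly(A) site and tracts overlapping sn/snoRNA/rRNA/tRNA annotation.

# Metagene matrices and the blacklist

`signal_matrix()` reads the ±20 bp window around each anchor on the
anchor's strand (minus-strand anchors read the minus-strand track
right-to-left), so each row is 5′→3′ in transcription direction. The
outlier blacklist interprets "the top 100 most extreme positive values"
per sample as the 100 anchors with the largest row-maximum (ties broken
by row order) — per-value extremes map to anchors through their windows,
and the row maximum is the deterministic equivalent for the delta-like
3′-end signal. The blacklist is the union across samples, so the same
anchors are excluded from every condition's profile.

# smFRET analysis

FRET efficiency is `E = A / (A + D)` per frame, masked where the total
intensity is zero; histograms use 0.02 bins over [0, 1]. Idealization is
a maximum-likelihood Gaussian-emission HMM (Baum–Welch EM with a
deterministic quantile-seeded k-means initialization, Viterbi decoding,
states under 1% occupancy merged into their nearest neighbour) — a
deliberate stand-in for empirical-Bayes HMM model selection, which is
out of scope. Post-synchronization histograms re-zero each trace at its
transcription start, defined as the first frame where `E < 0.75` holds
for at least k = 3 consecutive frames; the sustained-crossing rule
operationalizes the exclusion of false decreases due to single noisy
frames (the exact rule used by the original synchronization script is
not published, so k is exposed in the interface). Traces that never
cross are excluded and counted. Each included trace contributes frames
from 10 s before its start onward into 0.05 FRET × 10 s bins; values on
a bin edge go to the upper bin, enforced with a small epsilon because
0.3 / 0.05 floats just below 6. Donor/acceptor crosstalk and gamma
correction are not modelled.

# The synthetic world

`simulate_genome()` builds non-overlapping genes on both strands of an
i.i.d. uniform background in which every unplanted homopolymer run ≥ 5
is broken by resampling — so every run a scanner finds is planted by
construction, and planted runs are kept maximal at exactly their planted
length by guard bases. Each gene gets a 1 bp poly(A) site 50–200 bp
downstream of its ORF end (score drawn in (4, 60), i.e. above the
filter), and non-control genes get 1–3 T-tracts of 6–10 bp placed
60–950 bp downstream of the poly(A) site — inside the 1 kb scan window
and beyond the 50 bp exclusion zone. About 30% of tract genes also carry
an ORF-internal T-tract, and a disjoint 20% control subset carries a C-
or G-tract instead. Low-score decoy poly(A) entries exercise the strict
score filter. The strand-aware 3′ end of every terminator T-tract is a
truth termination point.

`simulate_end_reads()` draws per-gene expression weights once per call
(log-normal, sdlog 0.5 — a typical dynamic range for a small gene set)
and allocates each replicate's `library_size` reads by a single
multinomial draw over 3′-end positions: a fraction at the canonical
poly(A) site (±2 bp discrete-triangular jitter, modelling cleavage
heterogeneity; tract points get no jitter so truth recovery stays
unambiguous), a fraction split across the gene's truth points, and a
fraction uniform over the gene ± 1 kb. The condition presets are
(frac_polyA, frac_tract, frac_noise) = WT (0.90, 0.02, 0.08), Ysh1AA
(0.30, 0.45, 0.25), Rat1AA (0.55, 0.35, 0.10); no quantitative effect
sizes are published for these shifts, so the presets are free parameters
of the stated world, exposed in the config and never tuned against test
outcomes. Optional gamma multipliers on per-gene totals provide
negative-binomial-like overdispersion across replicates (default off).

## What a green test does and does not establish

The generator emulates the *geometry* of the real data (strand-aware
placement, jitter, replicate structure), not yeast sequence composition,
nucleosome effects, or CUT/sn-snoRNA biology. One consequence deserves
emphasis. At the default preset depth (50 genes, 200k reads × 2
replicates per condition), coverage density is far higher than in a real
genome: ~8,000 reads per gene with 25% uniform noise puts ~0.8 noise
reads per downstream base, and after per-million scaling (factor 2.5) a
base with two treatment noise reads and no control reads already exceeds
ratio 2. The island caller therefore returns one to two orders of
magnitude more noise islands than truth islands (measured: precision
0.013 at recall 0.96), and the excess noise regions also wash out the
T-rich motif enrichment. This is a property of the stated synthetic
world, not of the caller: with the background fraction lowered to 0.001
and all else equal, the same code achieves precision ≈ 0.99, recall
≈ 0.96, and ranks `TTTTTTTT` as the top 8-mer at q ≈ 2e-9 (asserted as
a unit test). Recall also has a geometric ceiling just under 1: planted
tracts may sit up to ~1.15 kb past the ORF end (poly(A) offset up to
200 bp plus tract offset up to 950 bp) while islands are confined to the
1 kb downstream of the ORF end.

# Numerical and design choices

* Strict inequalities throughout where the source analysis prints them
  (`score > 3`, `ratio > 2`), with the boundary cases pinned by tests.
* The ratio is computed on replicate-merged, scaled tracks.
* Heatmap rows are exported in descending row-sum order (the original
  plotting tool's ordering is unstated); recorded in output metadata.
* QC bins sum both strands jointly (unstated in the source; fixed and
  documented here).
* Annotation source is user input; no release is pinned.
* The pipeline's stages are all reachable as plain R functions; the
  `run_pipeline()` orchestrator plus this package's function surface are
  the command-line interface, and `scripts/acceptance.R` is the thin
  script entry point. Reruns under one seed are bit-identical, enforced
  via md5 checksums in the run manifest.

# Known limitations

* The k-mer enrichment and the maximum-likelihood HMM are declared
  stand-ins for de novo motif discovery and empirical-Bayes HMM
  inference respectively; they reproduce the *kind* of output, not the
  original tools' numbers.
* Trace classification (`classify_fret_trace()`) is an interpretation
  layer with configurable thresholds, not a published algorithm.
* bigWig export/reading is not implemented; bedGraph is the native
  format.
* The default synthetic preset's noise density makes per-base island
  precision uninformative, as analysed above.
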