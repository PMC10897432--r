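---
title: "Classifying the regulatory architecture of nascent transcription initiation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying the regulatory architecture of nascent transcription initiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nascentarch)
```

## The problem

Capped-small RNA sequencing (csRNA-seq) captures 5'-capped short nascent
RNAs and therefore marks transcription initiation at single-base,
strand-specific resolution. In a plant genome such as *Arabidopsis
thaliana* this makes several layers of non-coding regulatory architecture
visible that steady-state RNA-seq misses, because the RNA exosome degrades
most of the corresponding transcripts before they accumulate: antisense
TSSs inside protein-coding gene bodies, divergent (non-coding/protein-
coding) promoter pairs, bidirectional non-coding promoters, and transcribed
enhancers producing eRNAs. `nascentarch` implements the classification and
scoring rules for all of these layers as a tested, reusable pipeline, plus
a synthetic-data generator that plants every feature class with known
ground truth so that each detector can be validated end to end without any
sequencing data.

All genomic coordinates inside the package are 0-based half-open; the only
conversion happens at the GFF3 boundary (`read_gff3()` / `write_gff3()`),
which prevents off-by-one drift between modules. Minus-strand signal is
stored as magnitudes, with strandedness carried by the file (one bedGraph
per strand) or the query.

## Peak metrics and normalization

For each TSS peak the **summit** is the position of maximal 5' read-start
pileup within the peak (ties broken leftmost so that results are
reproducible), and the **80% width** is the length of the smallest
contiguous window holding at least `ceiling(0.8 * N)` of the peak's `N`
read starts (the rounding direction is a convention; ceiling was chosen
and the brute-force oracle in the test suite pins the definition down
exactly). Sharp promoters give widths of a few bases; dispersed initiation
gives wide windows.

Between-library normalization is trimmed-mean-of-M-values (TMM)
implemented from its definition: the reference sample is the one whose
75th count quantile over library size is closest to the sample mean; each
library's factor is the inverse-variance-weighted mean of M-values after
trimming 30% on M and 5% on A; factors are rescaled to geometric mean 1,
and CPM is `count / (library size x factor) x 1e6`. The test suite checks
the implementation against edgeR's `calcNormFactors()` to 1e-8 on random
count matrices, keeping the implementation and the oracle on separate code
paths. Note that exact TMM is *not* invariant to rescaling a single
library (the weight of each feature changes relative to the reference
term); it is invariant to rescaling all libraries jointly, and that is the
property the tests assert.

Heatmap rows around anchors (summits, pair midpoints) are built per
window: values are capped at the window's 90th percentile, min-max
rescaled to [0, 1] (an all-equal window maps to 0 rather than dividing by
zero), and the rescaled antisense values are subtracted from the rescaled
sense values, giving rows in [-1, 1]. The percentile trim is per-window,
not per-heatmap. Minus-strand windows are reversed so downstream always
points right; windows that run off a chromosome are zero-padded and
flagged rather than dropped.

## Annotation rules

A peak is assigned to a same-strand transcript when its summit is (a)
inside the annotated 5' UTR, (b) within 500 bp upstream to 200 bp
downstream of the annotated TSS, or (c) within the first 25% of the
transcript length. The "5' region" of a transcript is interpreted as the
annotated 5' UTR when one exists and as empty otherwise - the other two
criteria carry the assignment in the common case, and this reading avoids
inventing a fixed window the annotation does not state. Assignment uses
the summit; with several matching transcripts the nearest annotated TSS
wins, and remaining ties go to the lexicographically smallest gene id so
that reruns are identical.

Categories: assigned peaks become `mRNA`, `lncRNA` or `otherNcRNA`
depending on the gene biotype (the long non-coding list covers antisense
lncRNA, lncRNA, novel transcribed regions, other RNA, pseudogenes and TE
genes; the small-RNA list covers miRNA, pre-tRNA, snRNA, snoRNA; anything
else falls back to `otherNcRNA` with a warning rather than an error).
Unassigned peaks with a reconstructed transcript starting within 50 bp of
the summit become `putativeLncRNA`, and `unstable` otherwise. Transcript
candidates are first filtered to length >= 200 bp and 5' ends within 50 bp
of a peak summit; same-strand overlaps keep the longest candidate (ties
leftmost) to produce a deterministic non-overlapping set.

ACRs are labelled by their summit through a strict priority ladder -
Intergenic, then Intragenic (inside a gene with at least one assigned TSS
peak), then TE, then Promoter (-400/+100 bp of any detected TSS, in
transcription orientation) - with later rules overwriting earlier ones.
The tests compare the implementation against a literal apply-rules-in-order
oracle on randomized layouts.

## Antisense, bidirectional and enhancer calls

An antisense TSS is a non-coding peak whose summit lies on the opposite
strand of a protein-coding gene body extended 200 bp past the TTS. The
summit is the measured position throughout (the alternative - peak edges -
would make the proximal/distal boundary depend on peak width). Nested or
overlapping host genes resolve to the nearest gene TSS. Each host gene is
represented by its highest-expressed assigned sense peak (maximum CPM over
non-mutant samples). Antisense TSSs are `proximal` when strictly inside
the first half of the gene body *and* strictly more than 1 kb from the
TTS, else `distal`; both boundary equalities resolve to distal, reading
"within the first 50%" as exclusive. The sense:antisense statistic is the
ratio of maximum CPM values across non-mutant samples; its genome-wide
median sits near 8:1, which is also the default amplitude ratio of the
generator.

Bidirectional promoters are divergent summit pairs: a minus-strand summit
at or left of a plus-strand summit (`m <= p`, `m == p` allowed), within
500 bp summit-to-summit. Each peak joins at most one pair; candidates are
accepted greedily by ascending distance with ties broken by the leftmost
minus member, which makes the matching injective and order-independent.
Pair types are pc-pc, nc-pc and nc-nc depending on whether members are
`mRNA`. The correlation-versus-distance table enumerates all candidates to
2 kb without the 500 bp cut, leaving smoothing to the plotting layer.
Correlation groups use strict bounds (correlating r > 0.25,
anti-correlating r < -0.25); group comparisons are standard two-sided
rank-sum tests with Holm correction, not re-derived.

Enhancer candidates come from nc-nc pairs (the summit-spanning region
grown symmetrically to >= 500 bp) and intergenic unidirectional non-coding
TSSs (500 bp centered on the summit). Candidates overlapping a detected
protein-coding promoter window are trimmed: the promoter windows are
subtracted and the longest remaining piece kept (ties leftmost), dropping
the candidate if less than 500 bp survives. This replaces a manual
curation step with a deterministic rule, because manual edits are not
reproducible. Activity is the summed CPM-scaled signal over the region on
both strands; per-gene links are Pearson correlations between activity and
the CPM of protein-coding TSSs whose summit lies within 5 kb of the region
edge (edge-to-summit; 0 when inside). The null distribution draws random
inter-chromosomal enhancer-gene pairs under a caller-supplied seed; its
size is a configuration value since no canonical size exists. Target genes
are those with any link at r >= 0.5 (inclusive). Ranking by "total signal
intensity" is within the named sample (configurable), descending with ties
by id.

## Exosome sensitivity

Calls are made from mutant-versus-wild-type differential tables with
positive log2 fold change meaning higher in the mutant: `sensitive`
requires log2FC >= +2 (upregulated only - the sign restriction follows
from the biology: exosome loss stabilizes transcripts, it does not silence
them) with q < 0.05; `insensitive` requires |log2FC| < 1, q > 0.05 and
maximum expression above 1 CPM (csRNA-seq) or 0.1 TPM (total RNA-seq);
everything else, including q exactly 0.05, is `unclassified`. The two
gates are provably disjoint. Overlap between mutants is a hypergeometric
upper tail computed with `stats::phyper`, cross-checked in the tests
against exhaustive enumeration for every universe up to 12.

## The synthetic-data generator

`simulate_dataset()` plants, by default, the "mini" study conditions: 3
chromosomes of 500 kb; 150 protein-coding genes (3-5 kb); 30 proximal and
30 distal antisense TSSs at safe margins from the class boundaries (18-38%
and 62-90% of the gene body) so that a few bases of summit noise cannot
flip a class; 40 divergent nc-pc promoters and 20 nc-nc pairs at 150-400
bp; 20 intergenic unidirectional ncTSSs; 20 enhancer-gene links with
target r = 0.8 placed within 5 kb; ACRs over every promoter and enhancer
plus intergenic, intragenic and TE decoys; and 20 exosome-sensitive
features shared unevenly between two mutants. Features are laid out as
non-interfering cassettes placed round-robin across chromosomes, and an
infeasible packing aborts before any output is written.

Read starts follow a two-sided geometric decay around the summit,
`P(offset d) ~ (1 - p) p^|d|` with p = 0.7, which reproduces sharp summits
with a tunable 80% width; per-sample totals are negative-binomial
(dispersion 0.1) around a stage-profile amplitude. Each feature's
time-course profile is one of six unimodal stage bumps plus feature
-specific noise, with the bump carrying 15% of the variance. That weight
matters: standardized profiles built from bumps alone would force the mean
correlation of unrelated feature pairs to about -0.2, which would corrupt
the inter-chromosomal null; at 15% the null stays within +/-0.05 of zero
while planted pairs - which share the full latent profile - still reach
their targets. Pair correlations are planted by mixing
(`g_y = r g_x + sqrt(1 - r^2) eta`) and rejection-resampled up to 10 times
until the realized correlation of the simulated counts is within 0.15 of
target, acknowledging that r estimates at n = 6 samples are noisy. One
deterministic read is placed at every summit in every sample so the truth
invariant "every planted TSS has nonzero signal at its summit" holds even
for weak features. Background noise is uniform at 0.5 read starts per kb
per strand per sample. Mutant samples reuse the final-stage profile, with
sensitive features scaled by `2^lfc`, `lfc ~ U(2, 4)`. Differential tables
are emitted directly from planted intents (the differential fit itself is
consumed, not modelled), with q-values drawn inside or outside the gates
as required.

What the generator does **not** emulate: sequence content (no FASTA, no
motifs), replicate structure and peak calling (truth peaks stand in for a
caller's output), mappability artefacts, overdispersed background hotspots
and correlated noise between neighbouring features. Passing the recovery
tests therefore demonstrates that the classification rules are
implemented correctly and are robust to sampling noise at realistic
depths - not that the pipeline would be robust to every artefact of real
libraries.

## Problem sizes and numerical choices

The test suite runs the mini genome (310 planted TSSs, 8 samples, about
50k reads per sample) twice - noise-free, expecting 100% recovery of every
class with no false positives among truth peaks, and at default noise,
expecting >= 95% per class and >= 90% of enhancer links - plus 1000
random peaks against the brute-force width oracle, 100 random matrices
against the TMM oracle, 10^4 randomized inputs for the partition
properties, 10^4 null draws, and a byte-identical double run of the full
pipeline. These sizes keep the whole suite under a minute on one core
while leaving each estimate's Monte-Carlo error far below the asserted
margins.

Degenerate inputs are handled by explicit policy rather than silence:
constant expression profiles give an undefined-correlation flag (`NA`)
excluded from downstream groupings; a zero antisense or pair minimum makes
the ratio undefined and flagged; all-equal heatmap windows map to zero;
peaks without signal are dropped with a warning by `annotate_summits()`
and are an error in the scalar `find_summit()`/`width80()`.

## Worked example

```{r example, eval = FALSE}
library(nascentarch)

sim <- simulate_dataset(sim_config(seed = 1))
merged <- merge_tracks(sim$tracks)
peaks <- annotate_summits(sim$peaks, merged)
norm <- tmm_normalize(quantify_peaks(peaks, sim$tracks))
peaks <- assign_tss(peaks, sim$annotation) |>
  categorize_tss(sim$annotation, sim$transcripts)
mask <- sim$samples$sample[sim$samples$type == "wildtype"]

antisense <- find_antisense(peaks, sim$annotation, norm$cpm, mask) |>
  classify_antisense() |>
  sense_antisense_ratio(norm$cpm, mask) |>
  pair_correlation(norm$cpm, mask)
table(antisense$antisense_class)
plot_ratio_density(antisense)
```

The full chain, including stage outputs on disk and a manifest with MD5
digests, is `run_pipeline(out_dir, config = sim_config(seed = 1))`;
`scripts/acceptance.R` runs it headlessly and reports the recovery and
summary statistics as JSON.

## Known limitations

- The pipeline consumes peak calls, reconstructed transcripts and
  differential tables; it does not re-implement peak calling, assembly or
  differential testing.
- Enhancer-gene links are marginal correlations over few samples; they are
  a screening statistic, not a causal claim, and the inter-chromosomal
  null is the only calibration offered.
- With only six non-mutant samples, pair correlations are noisy; the
  strict group bounds (0.25/0.5) partially compensate, but individual pair
  r values should not be over-interpreted.
- The greedy one-pair-per-peak matching is a modelling choice for
  multi-partner promoter clusters; alternative matchings would change pair
  counts at dense loci.
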