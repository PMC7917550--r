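---
title: "Models and methods: transcription termination at piRNA loci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: transcription termination at piRNA loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pirnaterm)
```

## The biological model

C. elegans piRNAs (21U-RNAs) are transcribed by RNA polymerase II from
thousands of discrete genomic loci. Each mature 21U-RNA begins with a
uridine (the "5' U"); its capped precursor initiates exactly 2 nt upstream
of that uridine, which this package calls the locus TSS. Transcription at
these loci terminates within a few tens of nucleotides, and the package
implements the analyses that dissect how:

* **Two pause sites.** Chromatin-bound (nascent) precursor lengths are
  bimodal: a major population of ~28 nt and a minor one of ~48 nt,
  interpreted as two successive Pol II pause positions. Nucleoplasmic
  (released) precursors are unimodal at ~28 nt.
* **Termination signal.** An AT-rich stretch downstream of the 21U-RNA
  promotes pausing and termination at the first site. The stronger the
  signal, the smaller the fraction of polymerases that reach the second
  pause.
* **Integrator cleavage.** Polymerases that transit the first pause are
  terminated by the Integrator endonuclease (INTS-11), which cleaves the
  nascent RNA around +38 while Pol II sits near +58. This releases a
  ~38 nt capped RNA and leaves a 5'-monophosphate degradation fragment
  spanning roughly +38 to +58, i.e. a median length of 20 nt.
* **Perturbations.** Loss of TFIIS (which rescues backtracked Pol II)
  shifts both apparent pause sites downstream by 2-3 nt — the second peak
  moves from ~48 to ~51 nt — and reduces cleavage-fragment yield.
  Depleting INTS-11 depletes fragments, lowers precursor levels, extends a
  long precursor tail to ~75 nt and licenses CAGE-detectable readthrough
  at a small fraction of motif-dependent loci.

Every analysis stage is formulated against this model, and the bundled
generator simulates exactly this structure so the pipeline can be validated
end to end by parameter recovery.

## Coordinate conventions

Coordinates are BED-style: 0-based, half-open, strand-aware. Two offset
frames recur:

* **tss frame** — 0 at the precursor TSS, increasing downstream along the
  locus strand;
* **u5 frame** — 0 at the 21U-RNA 5' U; always tss-frame minus 2.

A read's "3' offset" is its *half-open* end in offset space, so
`three - five` is the read length. Under this convention the cleavage
arithmetic is internally consistent: a fragment with 5' end at +38 and
half-open 3' end at +58 has length 20. Published descriptions of the
fragment-collection window mix the two frames (+25..+50 is variously
anchored at the TSS or at the 5' U); rather than resolving the ambiguity,
every windowed operation takes an explicit `frame` argument and the default
is the tss frame.

## Termination-signal score

The termination signal is scored as the A/T fraction of the sense strand
in a configurable window, by default tss-frame `[0, 50)` (the whole
transcription unit to +50); `[27, 52)` gives the variant restricted to the
region downstream of the 21U-RNA. A/T fraction is a monotone surrogate for
the melting-temperature-style signatures used elsewhere; it needs no
thermodynamic tables and is invariant under reverse complementation, which
makes the strand handling trivially correct. Loci are stratified into
equal-sized percentile bins of this score (`assign_signal_bins()`); bin 1
is always the weakest signal.

## The synthetic-data generator

`sim_config()` fixes the generative model; `simulate_loci()` builds a
genome and annotation, and three samplers emit libraries. Key choices:

* **Locus layout.** Loci sit ~400 nt apart on synthetic contigs with
  random strands, far enough apart that no read or window of one locus can
  touch another.
* **Sequence planting.** The downstream window receives an exact count of
  A/T bases so that rescoring the emitted FASTA reproduces the intended
  signal score (drawn uniformly on [0.2, 1.0]); the 5' U is forced to T;
  motif-dependent loci get GTTTC at u5-frame [-42, -38). 5% of loci carry
  a planted unannotated 21U start (a T within +/-5 nt of the annotated 5'
  U), with a base swap conserving the window's A/T count.
* **Abundance.** Per-locus expression is lognormal (`abundance_sdlog`
  = 1.2, mean 1), reflecting the orders-of-magnitude spread of real piRNA
  locus expression. This heavy tail is what keeps cleavage-fragment
  detection unsaturated, so that the number of detected loci per signal
  bin can fall with signal strength as the model predicts.
* **Pause choice.** Each polymerase reaches the second pause with
  probability `plogis(qlogis(p_pause2_base) + signal_coupling *
  (score - 0.5))`; defaults 0.25 and -6 give roughly 60% transit at the
  weakest loci and ~2% at the strongest, a strong but not degenerate
  coupling. The marginal pause-1/pause-2 mixture is then about 0.75/0.25,
  a free parameter of the model.
* **Lengths and offsets** are rounded Normal draws (peaks 28 and 48, sd
  2 nt; cleavage ends 38 and 58, sd 1.5 nt), truncated to [18, 75] —
  matching the size selection of short-capped libraries. A mechanistic
  kinetic simulator would add nothing the analyses could detect.
* **Fragment yield.** Pause-2 events yield a detectable fragment with
  probability `fragment_rate` = 0.5 (times the preset factor). At the
  default depth (500 loci x 120 expected reads) this produces >5,000
  fragments while leaving low-abundance, strong-signal loci undetected —
  the regime in which the signal-bin trend is visible.
* **CAGE counts** follow a discrete power law with reverse-cumulative
  exponent 1.25 (the classic CAGE tag-count law); emitting piRNA loci are
  truncated below at 5 tags, background promoter CTSSs at 1. Fragment
  spans are Normal(450, 80) — lower bounds on readthrough length, as the
  mate end comes from random priming.
* **Genotype presets** encode the direction and approximate magnitude of
  the published perturbations: tfiis (+2/+3 nt shifts, fragment factor
  0.4, chromatin abundance x1.5), ints11_kd (fragment factor 0.2,
  abundance x0.6, tail to 75 nt, readthrough x3.6 so ~3.6% of
  motif-dependent loci emit), and their combination. The abundance factor
  is applied uniformly to both compartments; modelling the tfiis
  compartment asymmetry was not needed by any analysis here.

All randomness flows from the single config seed: each sampler derives a
deterministic stream from it, so a fixture set is byte-reproducible.

What the generator does **not** emulate: sequencing error, quality scores,
mappability artifacts, multi-mapping reads, UMI duplication structure,
trans effects between loci, or genuine nucleotide-level sequence biases
beyond the planted motif and A/T content. Passing recovery tests therefore
shows that the analysis code measures what it claims under the stated
model — not that the model captures every property of real libraries.

## Precursor quantification

A capped read is a precursor of a locus iff it starts exactly at the locus
TSS (strand-aware) and is at least 18 nt long. The exact-match rule is
deliberate; a `slack` knob exists but defaults to 0. Library-size options
mirror practice: total reads at annotated TSSs, total miRNA counts, total
non-structural reads (a structural-RNA exclusion list is an input, not
hard-coded), or median-of-ratios size factors computed from a miRNA count
table. The median-of-ratios estimator is implemented directly (it is a
one-line formula) and cross-checked in the tests against an established
implementation. Fold changes use normalized means, a mean-count filter
(> 5 by default) and one pseudocount.

## Length statistics

Two weighting schemes run in parallel everywhere: **reads** (each read
counts) and **sequences** (each distinct precursor sequence counts once).
Because all precursors of a locus share their 5' end, a "unique sequence"
is operationalized as a unique (locus, length) pair; the nucleotide string
adds no information. Medians use the *lower-median* convention (the lower
middle element for even sample sizes) so that every reported statistic is
an observed integer length, reproducible across platforms; means are
ordinary weighted means. The trimming analysis bins loci by their fraction
of long (> 38 nt) chromatin precursors — 5 percentile bins by default, the
bin count being unstated in the source analyses — and inspects per-locus
nucleoplasmic medians per bin (all < 30 nt under the wild-type model,
the signature of post-release trimming).

## Bootstrap peak localization

The pause-peak procedure resamples 3,000 unique precursor sequences
without replacement, 2,000 times at full scale (200 at desk scale),
with sampling probability weighted by read count. Sampling uses
exponential sort keys (`rexp(n)/w`), which is distributionally identical
to successive weighted draws with renormalization but runs in O(n log n);
the equivalence is pinned in the tests against exhaustive enumeration of
ordered draws on small populations. Each resample gets a Gaussian kernel
density (bandwidth: Silverman's rule unless overridden) evaluated on a
0.1-nt grid extended 3 bandwidths past the data range; all strict local
maxima are found, the two densest are kept and ordered by position. A
second maximum below 1% of the first's density is discarded as a
smoothing artifact; degenerate input (a point mass) reports a single
peak. Bandwidth sensitivity is part of the test suite: a very wide
bandwidth merges the two pause components into one peak, as it should.

## The 5'P fragment pipeline

Filter order is fixed and each stage only removes reads:

1. drop reads > 15 nt initiating exactly at an annotated 5' U;
2. detect unannotated 21U starts: positions within +/-5 nt of an annotated
   5' U (excluding it) where at least 2 reads of exactly 21 nt initiate
   and the genomic base is a sense-strand T;
3. apply the same removal rule at those positions;
4. profile the surviving 5' and 3' ends (CPM of non-structural reads) and
   collect fragments whose 5' offset lies in the window (default
   tss-frame [25, 50)), with no minimum fragment length.

The 2-read detection threshold is a package default (no published value
exists); the first-base rule uses the genome, not the read, because the
21U definition is genomic. Reported 3'-end positions use the half-open
convention throughout, so the fragment 3' profile is expected to centre at
+58.

## CAGE readthrough

Tag counts per CTSS are normalized onto a referent power law: the observed
reverse-cumulative distribution is fitted by least squares on log-log
scale within a count range (default [5, 1000], at least 5 distinct
support values), and counts are mapped as
`x* = (c/c_ref)^(-1/alpha_ref) * x^(alpha/alpha_ref)` with
`c_ref = total_ref / zeta(alpha_ref)` so the referent law totals one
million tags. Defaults `alpha_ref = 1.25` and the fit range are config
values recorded in the fit object — the reference parameters used in the
published analysis are not stated, so any quantity depending on them is
treated as configuration-sensitive. The transform is strictly monotone
(ranks are preserved) and collapses to a rescaling when the data already
follow the referent exponent. Fold changes at the precursor TSS (u5-frame
-2) include loci with signal in at least one condition and add 0.01 TPM to
both sides. Replicates are merged by summing raw counts before
normalization. Downsampling saturation draws 15 multinomial subsamples
per depth per replicate, counts loci detected at -2, and averages
replicates within subsample index.

## Problem sizes and numerical tolerances

The default simulator configuration — 500 loci, ~60,000 chromatin reads,
~7,000 unique precursor sequences, >5,000 cleavage fragments — is the
package's standard validation scale: large enough that the bootstrap
medians and fragment statistics sit well inside +/-1 nt of the generating
parameters, small enough that the whole recovery suite runs in seconds.
Tests use a reduced 80-locus configuration for module-level checks.
Monte-Carlo assertions (inclusion probabilities, goodness of fit) use
fixed seeds and tolerances derived from their sampling error at the stated
trial counts.

## Known limitations

* The simulator's pause model is a two-component mixture, not a kinetic
  model; dwell times, backtracking dynamics and initiation rates are out
  of scope.
* Precursor identity is (locus, length); analyses that would need actual
  precursor sequences (e.g. nucleotide composition of 3' ends) are not
  supported.
* The power-law fit is ordinary least squares on the reverse-cumulative
  curve; for shallow libraries (fewer than ~2,000 CTSS positions) the
  exponent estimate is noticeably biased and should not be interpreted.
* Differential-expression testing, intron retention, repeat analyses and
  coverage-track processing are deliberately outside the package.
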