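# pirnaterm

Analysis of RNA polymerase II transcription termination at *C. elegans*
piRNA (21U-RNA) loci, for researchers studying small-RNA biogenesis and
promoter-proximal pausing.

piRNA precursors are short capped RNAs initiating exactly 2 nt upstream of
the mature 21U-RNA first uridine. Their chromatin-bound length
distribution is bimodal — Pol II pauses near +28 and +48 of the precursor
TSS — and termination past the second pause is carried out by the
Integrator endonuclease, which cleaves the nascent RNA near +38 while the
polymerase sits near +58, leaving a 5′-monophosphate degradation fragment
of median length 20 nt. The package implements the quantitative pipeline
around this model:

* **Precursor quantification** — strand-aware identification of capped
  reads at locus TSSs, median-of-ratios size factors, per-locus
  log2 fold changes (`identify_precursors()`,
  `size_factors_median_of_ratios()`, `per_locus_log2fc()`).
* **Length analysis** — read- and sequence-weighted length distributions,
  per-locus medians (lower-median convention), detection matrices,
  chromatin-vs-nucleoplasm trimming bins (`length_distribution()`,
  `per_locus_length_stats()`, `trimming_bins()`).
* **Pause-peak bootstrap** — 2,000 weighted subsamples of 3,000 unique
  precursor sequences (without replacement, probability ∝ read count),
  Gaussian kernel density, the two dominant local maxima
  (`bootstrap_peaks()`, `find_peaks()`, `weighted_subsample()`).
* **Cleavage-fragment pipeline** — removal of mature 21U-RNAs at
  annotated and unannotated starts, 5′/3′ end profiles in CPM, fragment
  collection in a TSS-frame window, termination-signal stratification
  (`remove_mature_reads()`, `detect_unannotated_21u()`,
  `end_profiles()`, `collect_fragments()`,
  `fragments_by_signal_bin()`).
* **CAGE readthrough** — upstream CTSS counting at u5-frame −2, referent
  power-law normalization to TPM, readthrough fold changes with a
  0.01-TPM pseudocount, pair-span distributions, depth-downsampling
  saturation (`count_upstream()`, `powerlaw_normalize()`,
  `downsample_saturation()`).
* **Synthetic data** — a generator implementing the two-pause /
  Integrator-cleavage model with genotype presets (wild type, *tfiis*,
  *ints-11* knock-down), emitting FASTA/BED/TSV fixtures so the whole
  pipeline runs without external data (`sim_config()`,
  `simulate_loci()`, `write_fixture_set()`).

Coordinates are BED-style 0-based half-open throughout; a read's 3′
position is its half-open end, so a +38..+58 fragment has length 20.

## Worked example

```r
library(pirnaterm)

config <- sim_config(seed = 7L)                 # 500 loci, default model
sim <- simulate_loci(config)

# chromatin-bound capped reads -> precursors -> pause peaks
chromatin <- simulate_capped_reads(sim, genotype_preset("wild_type"),
                                   "chromatin")
precursors <- identify_precursors(chromatin, sim$loci)
boot <- bootstrap_peaks(precursors, n_boot = 200, n_sample = 3000,
                        seed = 8L)
print(boot)
#> Weighted bootstrap of nascent-RNA length peaks
#>   200 resamples of 3000 sequences
#>   peak1 median 28.00 nt (n = 200)
#>   peak2 median 47.96 nt (n = 200)

# 5'P library -> strip mature 21U-RNAs -> cleavage fragments
fivep <- simulate_5p_reads(sim)
filtered <- remove_mature_reads(fivep, sim$loci)
filtered <- remove_unannotated_mature(
  filtered, detect_unannotated_21u(filtered, sim$loci, sim$genome))
profile <- end_profiles(filtered, sim$loci,
                        normalizer = nonstructural_total(filtered))
profile_argmax(profile, "five", c(25, 50))
#> [1] 38
fragments <- collect_fragments(filtered, sim$loci)
weighted_lower_median(fragments$length, fragments$count)
#> [1] 20
```

The bootstrap medians sit at the two pause positions (28 and 48 nt), the
filtered 5′-monophosphate ends peak at +38 of the precursor TSS, and the
collected degradation fragments have a median length of 20 nt — the
geometry of Integrator cleavage downstream of the second pause.

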