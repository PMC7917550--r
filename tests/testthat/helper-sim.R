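# Shared fixtures: a desk-scale simulation reused across test files (module
# tests use this smaller configuration; acceptance tests build the default
# one themselves).

small_config <- sim_config(n_loci = 80L, reads_per_locus_mean = 60,
                           mirna_count = 20L, cage_background = 200L,
                           seed = 42L)
small_sim <- simulate_loci(small_config)

# hand-built locus table (bypasses file I/O) for arithmetic-level tests
mk_loci <- function(chrom, strand, u5, id = paste0("p", seq_along(u5)),
                    motif_class = "motif_dependent") {
  data.frame(locus_id = id, chrom = chrom, strand = strand,
             u5_pos = as.integer(u5), motif_class = motif_class,
             signal_score = NA_real_, signal_bin = NA_integer_,
             tss_pos = as.integer(ifelse(strand == "+", u5 - 2L, u5 + 2L)),
             stringsAsFactors = FALSE)
}

mk_reads <- function(chrom, strand, start, end, count = 1L,
                     library = "capped_short") {
  data.frame(chrom = chrom, strand = strand, start = as.integer(start),
             end = as.integer(end), count = as.integer(count),
             library = library, stringsAsFactors = FALSE)
}
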