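# The two-pause / cleavage generative model.

test_that("simulated loci carry planted motifs and exact signal scores", {
  sim <- small_sim
  loci <- sim$loci
  expect_equal(nrow(loci), 80L)
  expect_equal(sum(loci$motif_class == "motif_dependent"),
               round(0.8 * 80))

  # rescoring the emitted genome recovers the generator's intended scores
  rescored <- termination_signal(loci, sim$genome)
  expect_lt(max(abs(rescored$signal_score - loci$signal_score)), 0.02)

  # GTTTC on the sense strand at u5-frame [-42, -38) for motif-dependent loci
  md <- loci[loci$motif_class == "motif_dependent", ][1:10, ]
  for (i in seq_len(nrow(md))) {
    gi <- from_offset(-42L, -37L, md[i, ], frame = "u5")
    s <- Biostrings::subseq(sim$genome[[gi$chrom]], gi$start + 1L, gi$end)
    if (md$strand[i] == "-") s <- Biostrings::reverseComplement(s)
    expect_equal(as.character(s), "GTTTC")
  }

  # the 5' U really is a T on the sense strand
  for (i in 1:10) {
    b <- as.character(Biostrings::subseq(sim$genome[[loci$chrom[i]]],
                                         loci$u5_pos[i] + 1L,
                                         loci$u5_pos[i] + 1L))
    if (loci$strand[i] == "-") b <- chartr("ACGT", "TGCA", b)
    expect_equal(b, "T")
  }

  # non-overlapping: loci on a contig are >= 300 nt apart
  for (ch in unique(loci$chrom)) {
    u <- sort(loci$u5_pos[loci$chrom == ch])
    if (length(u) > 1) expect_true(all(diff(u) >= 300))
  }
})

test_that("the generator is deterministic given the config seed", {
  s1 <- simulate_loci(small_config)
  s2 <- simulate_loci(small_config)
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(s1$loci, s2$loci)
  expect_identical(simulate_capped_reads(s1, compartment = "chromatin"),
                   simulate_capped_reads(s2, compartment = "chromatin"))
  expect_identical(simulate_cage_pairs(s1), simulate_cage_pairs(s2))
})

test_that("capped-read length structure matches the two-pause model", {
  sim <- small_sim
  wt <- genotype_preset("wild_type")
  chrom <- simulate_capped_reads(sim, wt, "chromatin")
  nuc <- simulate_capped_reads(sim, wt, "nucleoplasm")
  lc <- rep(chrom$end - chrom$start, chrom$count)
  ln <- rep(nuc$end - nuc$start, nuc$count)
  expect_gt(length(ln), 3000)
  # nucleoplasm: unimodal at peak1; mode within 1 nt
  mode_n <- as.integer(names(which.max(table(ln))))
  expect_lte(abs(mode_n - small_config$peak1_pos), 1L)
  expect_lt(mean(ln > 42), 0.01)
  # chromatin: a clear second population near peak2
  expect_gt(mean(lc > 42), 0.05)
  # tfiis preset shifts the second component to 51
  tf <- simulate_capped_reads(sim, genotype_preset("tfiis"), "chromatin")
  lt <- rep(tf$end - tf$start, tf$count)
  long <- lt[lt > 42]
  mode2 <- as.integer(names(which.max(table(long))))
  expect_lte(abs(mode2 - 51L), 1L)
})

test_that("strong termination signals suppress pause-2 transit and fragments", {
  sim <- small_sim
  loci <- sim$loci
  chrom <- simulate_capped_reads(sim, compartment = "chromatin")
  pre <- identify_precursors(chrom, loci)
  frac2 <- vapply(split(pre, pre$locus_id), function(r)
    sum(r$count[r$length > 40]) / sum(r$count), numeric(1))
  score <- loci$signal_score[match(names(frac2), loci$locus_id)]
  expect_lt(cor(score, frac2, method = "spearman"), -0.5)

  fp <- simulate_5p_reads(sim)
  f2 <- remove_mature_reads(fp, loci)
  fr <- collect_fragments(f2, loci)
  nfrag <- vapply(split(fr$count, fr$locus_id), sum, numeric(1))
  all_frag <- setNames(rep(0, nrow(loci)), loci$locus_id)
  all_frag[names(nfrag)] <- nfrag
  expect_lt(cor(loci$signal_score, all_frag, method = "spearman"), -0.3)

  # conservation: every fragment locus had at least one pause-2 event
  ev <- attr(fp, "pause2_events")
  expect_true(all(ev$events[match(names(nfrag), ev$locus_id)] >= 1))
})

test_that("a zero fragment rate leaves the 5'P library without window reads", {
  cfg0 <- sim_config(n_loci = 40L, fragment_rate = 0, mirna_count = 10L,
                     seed = 9L)
  sim0 <- simulate_loci(cfg0)
  fp <- simulate_5p_reads(sim0)
  f2 <- remove_mature_reads(fp, sim0$loci)
  sites <- data.frame(chrom = sim0$loci$chrom, strand = sim0$loci$strand,
                      pos = sim0$loci$unannot_pos)
  f3 <- remove_unannotated_mature(f2, sites[!is.na(sites$pos), ])
  fr <- collect_fragments(f3, sim0$loci)
  expect_equal(nrow(fr), 0L)
})

test_that("simulated CAGE counts are heavy-tailed and seed-reproducible", {
  sim <- small_sim
  pairs <- simulate_cage_pairs(sim)
  ct <- ctss_table(pairs)
  # rank-frequency approximately linear in log-log
  cnt <- sort(ct$count, decreasing = TRUE)
  cnt <- cnt[cnt > 0]
  fit <- lm(log(cnt) ~ log(seq_along(cnt)))
  expect_gt(summary(fit)$r.squared, 0.8)
  # readthrough_factor = 0 silences motif-dependent loci
  p0 <- genotype_preset("wild_type")
  p0$readthrough_factor <- 0
  pairs0 <- simulate_cage_pairs(sim, p0)
  ct0 <- ctss_table(pairs0)
  md <- sim$loci[sim$loci$motif_class == "motif_dependent", ]
  cu <- count_upstream(ct0, md)
  expect_equal(sum(cu$minus2), 0L)
})

test_that("write_fixture_set emits a reproducible, complete fixture", {
  out <- file.path(tempdir(), "fixture-test")
  unlink(out, recursive = TRUE)
  cfg <- sim_config(n_loci = 30L, reads_per_locus_mean = 20,
                    mirna_count = 10L, cage_background = 50L, seed = 5L)
  man <- write_fixture_set(out, cfg)
  expect_equal(length(man$samples), 2L * 4L * 3L)
  seeds <- vapply(man$samples, `[[`, 1L, "seed")
  libs <- vapply(man$samples, `[[`, "", "library")
  expect_true(all(tapply(seeds, paste(libs,
    vapply(man$samples, `[[`, "", "preset")), function(s)
      length(unique(s)) == 2L)))
  expect_error(write_fixture_set(out, cfg), "not empty")

  # re-running reproduces files byte-identically
  out2 <- file.path(tempdir(), "fixture-test2")
  unlink(out2, recursive = TRUE)
  write_fixture_set(out2, cfg)
  f1 <- file.path(out, "wild_type_rep1_fivep_small.bed")
  f2 <- file.path(out2, "wild_type_rep1_fivep_small.bed")
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(file.path(out, "genome.fa")),
                   readLines(file.path(out2, "genome.fa")))

  # the fixture loads back through the package's own readers
  loci <- load_loci(file.path(out, "loci.tsv"))
  expect_equal(nrow(loci), 30L)
  reads <- read_alignments(f1, "fivep_small")
  expect_gt(sum(reads$count), 0)
})
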