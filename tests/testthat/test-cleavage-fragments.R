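# The 5'P degradation-fragment pipeline: mature removal, unannotated-21U
# detection, end profiling and fragment collection.

test_that("mature removal drops only long reads starting exactly at the 5' U", {
  loci <- mk_loci("chrI", "+", 1000L)
  reads <- mk_reads("chrI", "+",
                    start = c(1000L, 1000L, 1007L, 1036L),
                    end   = c(1021L, 1014L, 1028L, 1056L),
                    count = 1L, library = "fivep_small")
  kept <- remove_mature_reads(reads, loci)
  # 21-mer at u5 removed; 14-mer at u5 kept (rule is > 15 nt); 21-mer at
  # u5+7 kept; downstream fragment kept
  expect_equal(kept$start, c(1000L, 1007L, 1036L))
  expect_equal(kept$end[1], 1014L)
})

test_that("unannotated 21U detection applies window, count and first-base rules", {
  genome <- Biostrings::DNAStringSet(c(chrI = paste0(
    strrep("C", 1000),
    "TCTGCCCCCC", strrep("C", 90))))
  # u5 at 1000 (T); planted T at u5+2 (pos 1002); G-like C at 1003
  loci <- mk_loci("chrI", "+", 1000L)
  mk21 <- function(start, count) mk_reads("chrI", "+", start, start + 21L,
                                          count, "fivep_small")
  reads <- rbind(mk21(1002L, 3L),    # T start, in window, enough reads
                 mk21(1003L, 5L),    # C start: first-base rule fails
                 mk21(1007L, 5L),    # pos u5+7: outside +/-5 window
                 mk21(1004L, 1L))    # T? pos 1004 is C; count 1 anyway
  hits <- detect_unannotated_21u(reads, loci, genome, min_reads = 2L)
  expect_equal(hits$pos, 1002L)
  expect_equal(hits$offset, 2L)
  # removal at the putative site mirrors the annotated rule
  kept <- remove_unannotated_mature(reads, hits)
  expect_false(1002L %in% kept$start)
  expect_true(1003L %in% kept$start)
})

test_that("planted unannotated sites are recovered with no false positives", {
  sim <- small_sim
  loci <- sim$loci
  fp <- simulate_5p_reads(sim)
  f1 <- remove_mature_reads(fp, loci)
  hits <- detect_unannotated_21u(f1, loci, sim$genome)
  planted <- loci[!is.na(loci$unannot_pos), ]
  found <- paste(hits$chrom, hits$strand, hits$pos)
  want <- paste(planted$chrom, planted$strand, planted$unannot_pos)
  expect_gte(mean(want %in% found), 0.95)
  expect_true(all(found %in% want))            # specificity on clean loci
})

test_that("each pipeline stage only removes reads, in fixed order", {
  sim <- small_sim
  fp <- simulate_5p_reads(sim)
  f1 <- remove_mature_reads(fp, sim$loci)
  hits <- detect_unannotated_21u(f1, sim$loci, sim$genome)
  f2 <- remove_unannotated_mature(f1, hits)
  expect_lte(sum(f1$count), sum(fp$count))
  expect_lte(sum(f2$count), sum(f1$count))
  expect_lt(sum(f2$count), sum(fp$count))      # mature reads existed
})

test_that("end profiles are CPM-normalized counts of 5' and 3' ends", {
  loci <- mk_loci("chrI", "+", 1000L)          # tss 998
  reads <- mk_reads("chrI", "+", 998L + 38L, 998L + 58L, 1L, "fivep_small")
  prof <- end_profiles(reads, loci, normalizer = 1e6)
  expect_equal(prof$five_cpm[prof$offset == 38], 1)
  expect_equal(prof$three_cpm[prof$offset == 58], 1)
  expect_equal(sum(prof$five_cpm), 1)          # conservation of in-range reads
  expect_equal(sum(prof$coverage_cpm), 20)     # 20 covered positions
  expect_error(end_profiles(reads, loci, normalizer = 0), "positive")
  # u5 frame shifts the apparent offsets by -2
  prof_u5 <- end_profiles(reads, loci, frame = "u5", normalizer = 1e6)
  expect_equal(prof_u5$five_cpm[prof_u5$offset == 36], 1)
})

test_that("fragment collection honours the window boundaries", {
  loci <- mk_loci("chrI", "+", 1000L)
  reads <- mk_reads("chrI", "+",
                    start = 998L + c(38L, 25L, 24L, 50L),
                    end   = 998L + c(58L, 45L, 44L, 70L),
                    count = 1L, library = "fivep_small")
  fr <- collect_fragments(reads, loci)
  expect_setequal(fr$five_off, c(38L, 25L))    # 24 below, 50 at open end
  expect_equal(fr$length, fr$three_off - fr$five_off)
})

test_that("wild-type simulation reproduces the cleavage geometry", {
  sim <- small_sim
  fp <- simulate_5p_reads(sim)
  f1 <- remove_mature_reads(fp, sim$loci)
  f2 <- remove_unannotated_mature(
    f1, detect_unannotated_21u(f1, sim$loci, sim$genome))
  norm <- nonstructural_total(f2)
  prof <- end_profiles(f2, sim$loci, normalizer = norm)
  expect_lte(abs(profile_argmax(prof, "five", c(25, 50)) - 38L), 1L)
  fr <- collect_fragments(f2, sim$loci)
  expect_gt(sum(fr$count), 300)
  expect_lte(abs(weighted_lower_median(fr$length, fr$count) - 20L), 1L)
  expect_lte(abs(weighted_lower_median(fr$three_off, fr$count) - 58L), 1L)
  # parameter recovery of the cleavage means
  expect_lte(abs(weighted_lower_median(fr$five_off, fr$count) - 38L), 1L)
})

test_that("fragment detection declines across termination-signal bins", {
  loci <- assign_signal_bins(small_sim$loci, 5L)
  fp <- simulate_5p_reads(small_sim)
  f1 <- remove_mature_reads(fp, loci)
  fr <- collect_fragments(f1, loci)
  norm <- nonstructural_total(f1)
  fb <- fragments_by_signal_bin(fr, loci, norm)
  expect_equal(sum(fb$summary$n_detected), length(unique(fr$locus_id)))
  expect_equal(sum(fb$summary$n_loci), nrow(loci))
  tt <- trend_permutation_test(fb$summary$n_detected)
  expect_lt(tt$rho, 0)
  # empty fragment set reports zero everywhere
  fb0 <- fragments_by_signal_bin(fr[0, ], loci, norm)
  expect_true(all(fb0$summary$n_detected == 0))
})

test_that("structural-RNA exclusion shrinks the normalizer", {
  reads <- mk_reads("chrI", "+", c(100L, 500L), c(130L, 530L), c(4L, 6L))
  expect_equal(nonstructural_total(reads), 10)
  rrna <- data.frame(chrom = "chrI", start = 90L, end = 140L)
  expect_equal(nonstructural_total(reads, rrna), 6)
})
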