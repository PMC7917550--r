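# CAGE upstream counting, power-law normalization, readthrough fold
# changes, pair lengths and saturation.

test_that("upstream counting is windowed, strand-aware and split-invariant", {
  loci <- mk_loci("chrI", "+", 1000L)          # tss (u5-frame -2) at 998
  ctss <- data.frame(chrom = "chrI", strand = "+",
                     pos = c(998L, 995L, 989L, 987L, 998L),
                     count = c(3L, 2L, 1L, 9L, 0L))
  ctss <- ctss[1:4, ]
  cu <- count_upstream(ctss, loci)
  expect_equal(cu$profile$tags[cu$profile$offset == -2], 3L)
  expect_equal(cu$profile$tags[cu$profile$offset == -5], 2L)
  expect_equal(sum(cu$profile$tags), 5L)       # -11 and -13 fall outside
  expect_true(all(cu$profile$unique_positions <= pmax(cu$profile$tags, 1)))
  expect_equal(unname(cu$minus2["p1"]), 3L)
  # splitting a count-k CTSS into k count-1 rows changes nothing
  split_ctss <- ctss[rep(1:4, ctss$count), ]
  split_ctss$count <- 1L
  agg <- ctss_table(mk_reads(split_ctss$chrom, split_ctss$strand,
                             split_ctss$pos, split_ctss$pos + 400L,
                             split_ctss$count, "cage"))
  cu2 <- count_upstream(agg, loci)
  expect_equal(cu2$profile$tags, cu$profile$tags)
})

test_that("power-law normalization is a monotone identity at the referent", {
  set.seed(201)
  k <- 1:10000
  counts <- sample(k, 4000, replace = TRUE, prob = k^(-2.25))
  res <- powerlaw_normalize(counts)
  # alpha recovered near the generating reverse-cumulative exponent
  expect_lt(abs(res$fit$alpha - 1.25), 0.1)
  # monotone transform preserving ranks
  o <- order(counts)
  expect_true(all(diff(res$tpm[o]) >= 0))
  expect_equal(cor(rank(counts), rank(res$tpm)), 1)
  # log-log slope of tpm vs raw is 1 at alpha == alpha_ref
  res_fix <- powerlaw_normalize(counts, alpha_ref = res$fit$alpha)
  fit <- lm(log(res_fix$tpm) ~ log(counts))
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.01)
  expect_error(powerlaw_normalize(c(1L, 2L, 2L, 3L)), "at least 5")
})

test_that("simulated CAGE counts recover the generating exponent", {
  cfg <- sim_config(n_loci = 50L, cage_background = 4000L, mirna_count = 5L,
                    seed = 31L)
  sim <- simulate_loci(cfg)
  ct <- ctss_table(simulate_cage_pairs(sim))
  res <- powerlaw_normalize(ct$count)
  expect_lt(abs(res$fit$alpha - cfg$cage_alpha), 0.1)
})

test_that("readthrough fold changes follow the pseudocount inclusion rule", {
  a <- c(l1 = 0, l2 = 0, l3 = 2)
  b <- c(l1 = 0, l2 = 0.99, l3 = 2)
  fc <- readthrough_fold_change(a, b)
  expect_false("l1" %in% names(fc))            # zero in both: excluded
  expect_equal(unname(fc["l2"]), log2(1.00 / 0.01))
  expect_equal(unname(fc["l3"]), 0)

  # Integrator depletion raises readthrough at motif-dependent loci
  sim <- small_sim
  md <- sim$loci[sim$loci$motif_class == "motif_dependent", ]
  tab <- function(preset) {
    ct <- ctss_table(simulate_cage_pairs(sim, genotype_preset(preset)))
    cu <- count_upstream(ct, md)
    cu$minus2
  }
  wt <- tab("wild_type"); kd <- tab("ints11_kd")
  fc_sim <- readthrough_fold_change(wt, kd)
  expect_gt(sum(kd > 0), sum(wt > 0))
  expect_gte(median(fc_sim), 0)
})

test_that("pair spans at the precursor TSS peak around 400-500 nt", {
  loci <- mk_loci("chrI", "+", 1000L)
  single <- mk_reads("chrI", "+", 998L, 998L + 450L, 2L, "cage")
  d <- pair_length_distribution(single, loci, normalizer = 1e6)
  expect_equal(d$length, 450L)
  expect_equal(d$cpm, 2)
  # CPM scales inversely with the normalizer
  d2 <- pair_length_distribution(single, loci, normalizer = 2e6)
  expect_equal(d2$cpm, 1)
  # missing mate coordinates are skipped with a warning
  broken <- single
  broken$end[1] <- NA
  expect_warning(d3 <- pair_length_distribution(rbind(single, broken),
                                                loci, 1e6),
                 "unpaired")
  expect_equal(d3$cpm, 2)

  pairs <- simulate_cage_pairs(small_sim)
  dd <- pair_length_distribution(pairs, small_sim$loci,
                                 normalizer = sum(pairs$count))
  mode_len <- dd$length[which.max(dd$cpm)]
  expect_gt(sum(dd$count[dd$length >= 350 & dd$length <= 550]),
            0.6 * sum(dd$count))
  expect_true(mode_len >= 300 && mode_len <= 600)
})

test_that("saturation curves rise monotonely and flatten at depth", {
  set.seed(202)
  pairs1 <- simulate_cage_pairs(small_sim, seed = 51L)
  pairs2 <- simulate_cage_pairs(small_sim, seed = 52L)
  reps <- list(ctss_table(pairs1), ctss_table(pairs2))
  depths <- c(0.05, 0.25, 0.5, 0.75, 1.0)
  sat <- downsample_saturation(reps, small_sim$loci, depths, n_rep = 15L,
                               seed = 8L)
  means <- tapply(sat$detected, sat$depth, mean)
  expect_true(all(diff(means) >= 0))
  # full depth reproduces the undownsampled detection exactly
  full <- sat$detected[sat$depth == 1.0]
  direct <- mean(vapply(reps, function(ct)
    sum(count_upstream(ct, small_sim$loci)$minus2 > 0), numeric(1)))
  expect_true(all(full == direct))
  # library depth >> emitting loci: the curve has flattened
  expect_lt((means["1"] - means["0.75"]) / means["1"], 0.05)
  # vanishing depth detects nothing
  sat0 <- downsample_saturation(reps, small_sim$loci, 1e-6, n_rep = 3L,
                                seed = 9L)
  expect_true(all(sat0$detected == 0))
  expect_error(downsample_saturation(reps, small_sim$loci, 1e9), "exceeds")
})
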