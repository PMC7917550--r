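## Multi-stage 5'-monophosphate degradation-fragment pipeline.
##
## Stage order is fixed: (1) remove mature 21U-RNA reads at annotated
## starts; (2) detect unannotated 21U starts within +/-5 nt; (3) remove
## mature reads at those; (4) profile the surviving 5'P ends around piRNA
## TSSs and collect putative Integrator cleavage fragments. Each stage only
## ever removes reads.

## locus lookup for read 5' ends at given tss-frame offsets:
## named vector key -> index into loci, plus parallel offset vector
.offset_lookup <- function(loci, offsets) {
  n <- nrow(loci)
  k <- length(offsets)
  strand <- rep(loci$strand, each = k)
  pos <- rep(loci$tss_pos, each = k) +
    ifelse(strand == "+", rep(offsets, n), -rep(offsets, n))
  list(key = .pos_key(rep(loci$chrom, each = k), strand, pos),
       locus = rep(seq_len(n), each = k),
       offset = rep(offsets, n))
}

#' Remove mature 21U-RNA reads at annotated starts
#'
#' Drops reads longer than `min_len_rule` nt whose 5' end sits exactly at an
#' annotated 21U-RNA 5' U (strand-aware). Everything else is retained.
#'
#' @param reads 5'P small-RNA aligned reads.
#' @param loci locus data frame.
#' @param min_len_rule reads must exceed this length to be removed.
#' @return Filtered reads.
#' @export
remove_mature_reads <- function(reads, loci, min_len_rule = 15L) {
  .check_reads(reads)
  at_u5 <- .pos_key(reads$chrom, reads$strand, .read_5p(reads)) %in%
    .pos_key(loci$chrom, loci$strand, loci$u5_pos)
  len <- reads$end - reads$start
  reads[!(at_u5 & len > min_len_rule), , drop = FALSE]
}

#' Detect unannotated 21U-RNA starts
#'
#' Scans positions within +/- `window` nt of each annotated 5' U (excluding
#' the annotated position itself) for 21-mer reads initiating there whose
#' genomic first base on the sense strand is T. Positions with at least
#' `min_reads` such reads are reported as putative unannotated 21U-RNAs.
#' Run after [remove_mature_reads()].
#'
#' @param reads filtered 5'P reads.
#' @param loci locus data frame.
#' @param genome [Biostrings::DNAStringSet] for the first-base check.
#' @param window half-width of the scan window (nt).
#' @param min_reads minimum read count at a position.
#' @return Data frame `locus_id`, `chrom`, `strand`, `pos`, `offset` (u5
#'   frame), `count`.
#' @export
detect_unannotated_21u <- function(reads, loci, genome, window = 5L,
                                   min_reads = 2L) {
  .check_reads(reads)
  offs <- setdiff(seq.int(-window, window), 0L)
  n <- nrow(loci)
  k <- length(offs)
  strand <- rep(loci$strand, each = k)
  pos <- rep(loci$u5_pos, each = k) +
    ifelse(strand == "+", rep(offs, n), -rep(offs, n))
  cand <- data.frame(locus_id = rep(loci$locus_id, each = k),
                     chrom = rep(loci$chrom, each = k), strand = strand,
                     pos = pos, offset = rep(offs, n),
                     stringsAsFactors = FALSE)
  len <- reads$end - reads$start
  r21 <- reads[len == 21L, , drop = FALSE]
  if (nrow(r21) == 0L) return(cand[0, ])
  counts <- rowsum(r21$count, .pos_key(r21$chrom, r21$strand, .read_5p(r21)))
  cand$count <- as.integer(counts[match(.pos_key(cand$chrom, cand$strand,
                                                 cand$pos), rownames(counts))])
  cand <- cand[!is.na(cand$count) & cand$count >= min_reads, , drop = FALSE]
  if (nrow(cand) == 0L) return(cand)
  first_base <- vapply(seq_len(nrow(cand)), function(i) {
    b <- as.character(Biostrings::subseq(genome[[cand$chrom[i]]],
                                         cand$pos[i] + 1L, cand$pos[i] + 1L))
    if (cand$strand[i] == "+") b else .complement[[b]]
  }, character(1L))
  out <- cand[first_base == "T", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove mature reads at unannotated 21U starts
#'
#' The removal rule of [remove_mature_reads()] applied at the putative
#' positions found by [detect_unannotated_21u()].
#'
#' @param reads filtered 5'P reads.
#' @param sites data frame with `chrom`, `strand`, `pos`.
#' @inheritParams remove_mature_reads
#' @return Filtered reads.
#' @export
remove_unannotated_mature <- function(reads, sites, min_len_rule = 15L) {
  .check_reads(reads)
  if (is.null(sites) || nrow(sites) == 0L) return(reads)
  at <- .pos_key(reads$chrom, reads$strand, .read_5p(reads)) %in%
    .pos_key(sites$chrom, sites$strand, sites$pos)
  len <- reads$end - reads$start
  reads[!(at & len > min_len_rule), , drop = FALSE]
}

#' TSS-relative end profiles of 5'P reads
#'
#' Aggregated over loci: counts per million (of `normalizer` reads) of read
#' 5' ends, half-open 3' ends, and read coverage at each offset of the
#' chosen frame, plus unique-sequence counts. A read enters the profile of
#' a locus when its 5' end lies within `offset_range` of that locus.
#'
#' @param reads filtered 5'P reads.
#' @param loci locus data frame.
#' @param frame `"tss"` or `"u5"`.
#' @param offset_range half-open offset interval profiled.
#' @param normalizer library size (non-structural mapped reads); must be
#'   positive.
#' @return An `end_profile` data frame: `offset`, `five_cpm`, `three_cpm`,
#'   `coverage_cpm`, `five_seqs`, `three_seqs`, with the normalizer stored
#'   as an attribute.
#' @export
end_profiles <- function(reads, loci, frame = c("tss", "u5"),
                         offset_range = c(-20L, 80L), normalizer) {
  frame <- match.arg(frame)
  .check_reads(reads)
  if (missing(normalizer) || is.null(normalizer) || normalizer <= 0)
    stop("normalizer (non-structural library size) must be positive")
  shift <- if (frame == "u5") 2L else 0L   # tss-frame = u5-frame + 2
  offs <- seq.int(offset_range[1L], offset_range[2L] - 1L)
  lk <- .offset_lookup(loci, offs + shift)
  hit <- match(.pos_key(reads$chrom, reads$strand, .read_5p(reads)), lk$key)
  ok <- !is.na(hit)
  five <- lk$offset[hit[ok]] - shift
  len <- (reads$end - reads$start)[ok]
  cnt <- reads$count[ok]
  three <- five + len
  grid <- offs
  tally <- function(at, w) {
    out <- numeric(length(grid))
    keep <- at >= grid[1L] & at <= grid[length(grid)]
    if (any(keep)) {
      t0 <- rowsum(w[keep], at[keep])
      out[match(as.integer(rownames(t0)), grid)] <- as.numeric(t0)
    }
    out
  }
  five_n <- tally(five, cnt)
  three_n <- tally(three, cnt)
  ## coverage by difference array over the grid
  cov <- numeric(length(grid) + 1L)
  lo <- pmax(five, grid[1L]) - grid[1L] + 1L
  hi <- pmin(three, grid[length(grid)] + 1L) - grid[1L] + 1L
  for (i in seq_along(five)) {
    if (hi[i] <= lo[i]) next
    cov[lo[i]] <- cov[lo[i]] + cnt[i]
    cov[hi[i]] <- cov[hi[i]] - cnt[i]
  }
  coverage_n <- cumsum(cov)[seq_along(grid)]
  five_s <- tally(five, rep(1L, length(five)))
  three_s <- tally(three, rep(1L, length(three)))
  cpm <- function(x) x / normalizer * 1e6
  out <- data.frame(offset = grid, five_cpm = cpm(five_n),
                    three_cpm = cpm(three_n), coverage_cpm = cpm(coverage_n),
                    five_seqs = five_s, three_seqs = three_s)
  structure(out, normalizer = normalizer, frame = frame,
            class = c("end_profile", "data.frame"))
}

#' Offset of maximal signal in a profile window
#'
#' @param profile an [end_profiles()] result.
#' @param what `"five"`, `"three"` or `"coverage"`.
#' @param window half-open offset window searched (default: whole profile).
#' @return The offset with maximal CPM inside the window.
#' @export
profile_argmax <- function(profile, what = c("five", "three", "coverage"),
                           window = NULL) {
  what <- match.arg(what)
  col <- paste0(what, "_cpm")
  sub <- if (is.null(window)) profile else
    profile[profile$offset >= window[1L] & profile$offset < window[2L], ]
  sub$offset[which.max(sub[[col]])]
}

#' Collect putative Integrator cleavage fragments
#'
#' Reads whose 5' end falls within the collection window (default tss-frame
#' `[25, 50)`) of a locus become fragment records of that locus. No minimum
#' length is applied to fragments.
#'
#' @param reads filtered 5'P reads.
#' @param loci locus data frame.
#' @param window half-open 5'-offset collection window.
#' @param frame `"tss"` (default) or `"u5"`.
#' @return Fragment data frame: `locus_id`, `five_off`, `three_off`,
#'   `length`, `count`, plus the genomic interval columns.
#' @export
collect_fragments <- function(reads, loci, window = c(25L, 50L),
                              frame = c("tss", "u5")) {
  frame <- match.arg(frame)
  .check_reads(reads)
  shift <- if (frame == "u5") 2L else 0L
  offs <- seq.int(window[1L], window[2L] - 1L)
  lk <- .offset_lookup(loci, offs + shift)
  hit <- match(.pos_key(reads$chrom, reads$strand, .read_5p(reads)), lk$key)
  ok <- !is.na(hit)
  out <- data.frame(
    locus_id = loci$locus_id[lk$locus[hit[ok]]],
    five_off = lk$offset[hit[ok]] - shift,
    stringsAsFactors = FALSE)
  out$length <- (reads$end - reads$start)[ok]
  out$three_off <- out$five_off + out$length
  out$count <- reads$count[ok]
  out$chrom <- reads$chrom[ok]
  out$strand <- reads$strand[ok]
  out$start <- reads$start[ok]
  out$end <- reads$end[ok]
  rownames(out) <- NULL
  out[c("locus_id", "five_off", "three_off", "length", "count",
        "chrom", "strand", "start", "end")]
}

#' Cleavage-fragment detection across termination-signal bins
#'
#' Per signal bin: the number of loci with at least one collected fragment
#' and the distribution of per-locus fragment CPM among detected loci.
#'
#' @param fragments output of [collect_fragments()].
#' @param loci locus data frame with `signal_bin` assigned.
#' @param normalizer library size for CPM.
#' @return List with `summary` (data frame `bin`, `n_loci`, `n_detected`)
#'   and `per_locus` (data frame `locus_id`, `bin`, `cpm`).
#' @export
fragments_by_signal_bin <- function(fragments, loci, normalizer) {
  if (any(is.na(loci$signal_bin)))
    stop("loci must carry signal bins (see assign_signal_bins)")
  if (normalizer <= 0) stop("normalizer must be positive")
  bins <- sort(unique(loci$signal_bin))
  cnt <- if (nrow(fragments)) rowsum(fragments$count, fragments$locus_id) else
    matrix(numeric(0))
  det_ids <- rownames(cnt)
  per_locus <- data.frame(
    locus_id = det_ids,
    bin = loci$signal_bin[match(det_ids, loci$locus_id)],
    cpm = as.numeric(cnt) / normalizer * 1e6,
    stringsAsFactors = FALSE)
  per_locus <- per_locus[!is.na(per_locus$bin), , drop = FALSE]
  summary <- data.frame(
    bin = bins,
    n_loci = as.integer(table(factor(loci$signal_bin, levels = bins))),
    n_detected = as.integer(table(factor(per_locus$bin, levels = bins))))
  list(summary = summary, per_locus = per_locus)
}

#' Rank-correlation permutation test for a monotone trend over bins
#'
#' Tests whether per-bin values decrease with bin index using the Spearman
#' correlation and its exact permutation distribution (all orderings of the
#' values when feasible, otherwise Monte-Carlo).
#'
#' @param values per-bin values (e.g. detected-locus counts, weakest bin
#'   first).
#' @param n_perm Monte-Carlo size when exact enumeration is infeasible.
#' @param seed optional RNG seed for the Monte-Carlo branch.
#' @return List with `rho` and one-sided `p_value` for a decreasing trend.
#' @export
trend_permutation_test <- function(values, n_perm = 10000L, seed = NULL) {
  k <- length(values)
  idx <- seq_len(k)
  rho_obs <- stats::cor(idx, values, method = "spearman")
  if (k <= 7L) {
    perms <- .permutations(k)
    rhos <- apply(perms, 1L, function(p) stats::cor(idx, values[p],
                                                    method = "spearman"))
  } else {
    if (!is.null(seed)) set.seed(seed)
    rhos <- replicate(n_perm, stats::cor(idx, sample(values),
                                         method = "spearman"))
  }
  list(rho = rho_obs, p_value = mean(rhos <= rho_obs + 1e-12))
}

.permutations <- function(k) {
  if (k == 1L) return(matrix(1L))
  sub <- .permutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i)
    cbind(i, sub + (sub >= i))))
}
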