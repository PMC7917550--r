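## Capped piRNA precursor identification, count tables, size factors and
## fold changes.

#' Identify capped piRNA precursor reads
#'
#' A capped read is a precursor of a locus iff it lies on the locus strand
#' with its 5' end exactly at the locus TSS (2 nt upstream of the 21U-RNA
#' 5' U) and is at least `min_len` nt long. An optional `slack` widens the
#' 5'-end match to +/- `slack` nt (default 0: the match is exact). Reads
#' matching no locus are dropped. Records are collapsed per (locus, length):
#' each row is one unique precursor sequence with its read count.
#'
#' @param reads capped short-RNA aligned reads.
#' @param loci locus data frame.
#' @param min_len minimum precursor length (nt).
#' @param slack allowed 5'-end offset from the TSS (nt).
#' @param sample_id,compartment optional labels stored on the records.
#' @return Precursor data frame: `locus_id`, `length`, `count` (+ labels).
#' @export
identify_precursors <- function(reads, loci, min_len = 18L, slack = 0L,
                                sample_id = NA_character_,
                                compartment = NA_character_) {
  .check_reads(reads)
  tss_key <- .pos_key(loci$chrom, loci$strand, loci$tss_pos)
  if (anyDuplicated(tss_key))
    stop("two loci share a TSS and strand: ",
         paste(loci$locus_id[duplicated(tss_key) |
                               duplicated(tss_key, fromLast = TRUE)],
               collapse = ", "))
  offs <- seq.int(-slack, slack)
  lookup <- stats::setNames(rep(loci$locus_id, each = length(offs)),
                            .pos_key(rep(loci$chrom, each = length(offs)),
                                     rep(loci$strand, each = length(offs)),
                                     rep(loci$tss_pos, each = length(offs)) +
                                       ifelse(rep(loci$strand, each = length(offs)) == "+",
                                              rep(offs, nrow(loci)),
                                              -rep(offs, nrow(loci)))))
  hit <- lookup[.pos_key(reads$chrom, reads$strand, .read_5p(reads))]
  len <- reads$end - reads$start
  keep <- !is.na(hit) & len >= min_len
  if (!any(keep))
    return(data.frame(locus_id = character(0), length = integer(0),
                      count = integer(0), sample_id = character(0),
                      compartment = character(0)))
  rec <- data.frame(locus_id = unname(hit[keep]), length = len[keep],
                    count = reads$count[keep], stringsAsFactors = FALSE)
  agg <- rowsum(rec$count, paste(rec$locus_id, rec$length))
  first <- rec[!duplicated(paste(rec$locus_id, rec$length)), , drop = FALSE]
  first$count <- as.integer(agg[match(paste(first$locus_id, first$length),
                                      rownames(agg))])
  first$sample_id <- sample_id
  first$compartment <- compartment
  first <- first[order(first$locus_id, first$length), , drop = FALSE]
  rownames(first) <- NULL
  first
}

#' Library size from annotated TSS positions
#'
#' Total multiplicity of reads whose 5' end falls on any annotated TSS — the
#' denominator used to normalize short-capped RNA libraries.
#'
#' @param reads aligned reads.
#' @param tss data frame of annotated TSSs with columns `chrom`, `pos`,
#'   `strand`.
#' @return Total count (integer).
#' @export
tss_library_size <- function(reads, tss) {
  .check_reads(reads)
  if (is.null(tss) || nrow(tss) == 0L) stop("empty TSS annotation")
  at <- .pos_key(reads$chrom, reads$strand, .read_5p(reads)) %in%
    .pos_key(tss$chrom, tss$strand, tss$pos)
  sum(reads$count[at])
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over features (rows with
#' nonzero counts in every sample) of the ratio of the feature's count to
#' its geometric mean across samples — the standard count-normalization
#' estimator for sequencing libraries.
#'
#' @param table count matrix, features x samples.
#' @return Named numeric vector of per-sample size factors.
#' @export
size_factors_median_of_ratios <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("counts must be non-negative")
  use <- rowSums(table == 0) == 0L
  if (!any(use))
    stop("no feature has nonzero counts in all samples")
  lg <- log(table[use, , drop = FALSE])
  ref <- rowMeans(lg)
  sf <- apply(lg, 2L, function(col) exp(stats::median(col - ref)))
  stats::setNames(sf, colnames(table))
}

#' Per-locus log2 fold changes between two conditions
#'
#' Counts are divided by their sample size factors; loci whose mean
#' normalized count across all samples of both conditions exceeds
#' `min_mean` are kept; the fold change is
#' `log2((mean_B + pseudocount) / (mean_A + pseudocount))` on normalized
#' means.
#'
#' @param table_a,table_b count matrices (features x samples) for the two
#'   conditions; row names must agree.
#' @param sf_a,sf_b per-sample size factors (default 1).
#' @param min_mean mean normalized-count filter.
#' @param pseudocount added to both normalized means.
#' @return Named numeric vector of log2 fold changes for kept loci.
#' @export
per_locus_log2fc <- function(table_a, table_b, sf_a = NULL, sf_b = NULL,
                             min_mean = 5, pseudocount = 1) {
  table_a <- as.matrix(table_a); table_b <- as.matrix(table_b)
  if (is.null(rownames(table_a)) || is.null(rownames(table_b)) ||
      !identical(rownames(table_a), rownames(table_b)))
    stop("the two count tables must have identical feature (row) names")
  if (is.null(sf_a)) sf_a <- rep(1, ncol(table_a))
  if (is.null(sf_b)) sf_b <- rep(1, ncol(table_b))
  na <- sweep(table_a, 2L, sf_a, "/")
  nb <- sweep(table_b, 2L, sf_b, "/")
  keep <- rowMeans(cbind(na, nb)) > min_mean
  a <- rowMeans(na)[keep]; b <- rowMeans(nb)[keep]
  log2((b + pseudocount) / (a + pseudocount))
}

#' Total precursor abundance relative to control
#'
#' For each replicate pair (columns matched by position), the ratio of
#' treatment to control total counts after dividing by the per-sample size
#' factors.
#'
#' @param control,treatment count matrices with one column per replicate;
#'   the two must have the same number of columns.
#' @param sf_control,sf_treatment per-sample size factors (default 1).
#' @return Numeric vector of per-replicate ratios.
#' @export
total_abundance_relative <- function(control, treatment,
                                     sf_control = NULL, sf_treatment = NULL) {
  control <- as.matrix(control); treatment <- as.matrix(treatment)
  if (ncol(control) != ncol(treatment))
    stop("control and treatment must have the same number of replicates")
  if (is.null(sf_control)) sf_control <- rep(1, ncol(control))
  if (is.null(sf_treatment)) sf_treatment <- rep(1, ncol(treatment))
  vapply(seq_len(ncol(control)), function(i)
    sum(treatment[, i] / sf_treatment[i]) / sum(control[, i] / sf_control[i]),
    numeric(1L))
}

#' Precursor count table across samples
#'
#' Convenience assembly of a loci x samples count matrix from a list of
#' precursor record frames (as returned by [identify_precursors()]).
#'
#' @param records named list of precursor data frames, one per sample.
#' @param loci locus data frame fixing the row set.
#' @return Integer matrix, loci x samples.
#' @export
precursor_count_table <- function(records, loci) {
  stopifnot(is.list(records), length(records) >= 1L)
  if (is.null(names(records)) || any(!nzchar(names(records))))
    names(records) <- paste0("sample", seq_along(records))
  mat <- sapply(records, function(r) {
    tot <- rowsum(r$count, r$locus_id)
    out <- stats::setNames(rep(0L, nrow(loci)), loci$locus_id)
    out[rownames(tot)] <- as.integer(tot)
    out
  })
  mat <- as.matrix(mat)
  rownames(mat) <- loci$locus_id
  mat
}
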