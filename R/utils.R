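## Small shared numeric helpers. Median conventions are fixed package-wide:
## the lower median is used for even sample sizes so that every reported
## length statistic is an observed integer length.

#' Lower median
#'
#' Median using the lower-middle element for even sample sizes, so the result
#' is always an observed value (integer lengths stay integers).
#'
#' @param x numeric vector.
#' @return A single value; `NA` for empty input.
#' @export
lower_median <- function(x) {
  n <- length(x)
  if (n == 0L) return(NA_real_)
  sort(x)[ceiling(n / 2)]
}

#' Weighted lower median
#'
#' Lower median of `x` where each value carries an integer multiplicity
#' `w` (equivalent to `lower_median(rep(x, w))` without expansion).
#'
#' @param x numeric vector of values.
#' @param w non-negative weights (read counts).
#' @return A single value; `NA` when total weight is zero.
#' @export
weighted_lower_median <- function(x, w) {
  stopifnot(length(x) == length(w))
  keep <- w > 0
  x <- x[keep]; w <- w[keep]
  if (length(x) == 0L) return(NA_real_)
  o <- order(x)
  x <- x[o]; w <- w[o]
  total <- sum(w)
  target <- ceiling(total / 2)
  x[which(cumsum(w) >= target)[1L]]
}

## equal-sized percentile bins by value rank; bin 1 = smallest values
.percentile_bins <- function(values, n_bins) {
  n <- length(values)
  r <- rank(values, ties.method = "first")
  as.integer(ceiling(r * n_bins / n))
}

## deterministic seed derivation: one user seed fans out to per-stage
## streams; stays below 2^31
.derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}

.complement <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

## key strings used for strand-aware position joins
.pos_key <- function(chrom, strand, pos) paste(chrom, strand, pos, sep = ":")

## validate an aligned-read data frame (BED-style half-open intervals)
.check_reads <- function(reads) {
  need <- c("chrom", "strand", "start", "end", "count")
  miss <- setdiff(need, names(reads))
  if (length(miss))
    stop("reads are missing columns: ", paste(miss, collapse = ", "))
  if (nrow(reads) && any(reads$end <= reads$start))
    stop("reads must satisfy end > start (half-open intervals)")
  if (nrow(reads) && any(reads$count <= 0))
    stop("read multiplicities must be positive")
  invisible(reads)
}

## genomic position of the 5' and 3' (half-open) ends of reads
.read_5p <- function(reads) ifelse(reads$strand == "+", reads$start, reads$end - 1L)

## collapse identical intervals, summing multiplicities
.aggregate_reads <- function(reads) {
  if (nrow(reads) == 0L) return(reads)
  key <- paste(reads$chrom, reads$strand, reads$start, reads$end, reads$library)
  agg <- rowsum(reads$count, key)
  first <- reads[!duplicated(key), , drop = FALSE]
  first$count <- as.integer(agg[match(paste(first$chrom, first$strand,
                                            first$start, first$end,
                                            first$library), rownames(agg))])
  rownames(first) <- NULL
  first[order(first$chrom, first$start, first$end, first$strand), , drop = FALSE]
}

#' Library size excluding structural RNA
#'
#' Total read multiplicity after discarding reads overlapping a set of
#' structural-RNA intervals (rRNA/tRNA/snRNA), the denominator used for
#' counts-per-million of non-structural mapped reads.
#'
#' @param reads aligned reads (`chrom`, `strand`, `start`, `end`, `count`).
#' @param structural optional data frame of intervals with columns `chrom`,
#'   `start`, `end` (0-based half-open); `NULL` means nothing is excluded.
#' @return Total count as a single number.
#' @export
nonstructural_total <- function(reads, structural = NULL) {
  .check_reads(reads)
  if (is.null(structural) || nrow(structural) == 0L) return(sum(reads$count))
  drop <- rep(FALSE, nrow(reads))
  for (chr in unique(structural$chrom)) {
    s <- structural[structural$chrom == chr, , drop = FALSE]
    i <- which(reads$chrom == chr)
    if (!length(i)) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(reads$start[i] + 1L, reads$end[i]),
      IRanges::IRanges(s$start + 1L, s$end))
    drop[i[unique(S4Vectors::queryHits(hits))]] <- TRUE
  }
  sum(reads$count[!drop])
}
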