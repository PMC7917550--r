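## Length distributions, per-locus length statistics, length shifts,
## detection matrices and the nucleoplasmic-trimming analysis.
##
## Two weighting schemes run through everything: "reads" weights each
## record by its read multiplicity; "sequences" counts each distinct
## (locus, length) precursor sequence once. Medians use the package-wide
## lower-median convention (see lower_median), so reported lengths are
## always observed integer lengths.

#' Length distribution of precursor records
#'
#' @param records precursor data frame (`locus_id`, `length`, `count`).
#' @param weight_by `"reads"` (multiplicities) or `"sequences"` (each
#'   distinct record once).
#' @param normalize return mass summing to 1 (default) or raw counts.
#' @return A `length_distribution`: data frame with columns `length`,
#'   `count`, `mass`.
#' @export
length_distribution <- function(records, weight_by = c("reads", "sequences"),
                                normalize = TRUE) {
  weight_by <- match.arg(weight_by)
  if (is.null(records) || nrow(records) == 0L)
    stop("no records: cannot form a length distribution")
  w <- if (weight_by == "reads") records$count else rep(1L, nrow(records))
  tot <- rowsum(w, records$length)
  out <- data.frame(length = as.integer(rownames(tot)), count = as.numeric(tot))
  out <- out[order(out$length), , drop = FALSE]
  out$mass <- if (normalize) out$count / sum(out$count) else out$count
  rownames(out) <- NULL
  structure(out, weight_by = weight_by, class = c("length_distribution",
                                                  "data.frame"))
}

#' Summary statistics of a length distribution
#'
#' @param dist a [length_distribution()].
#' @return List with `mode` (length of maximal mass), `median` (weighted
#'   lower median) and `mean`.
#' @export
distribution_stats <- function(dist) {
  list(mode = dist$length[which.max(dist$count)],
       median = weighted_lower_median(dist$length, dist$count),
       mean = sum(dist$length * dist$count) / sum(dist$count))
}

#' Per-locus precursor length statistics
#'
#' For every locus with at least one record: the lower median and mean of
#' lengths over unique sequences, and over reads (count-weighted).
#'
#' @param records precursor data frame.
#' @return Data frame `locus_id`, `median_seq`, `mean_seq`, `median_read`,
#'   `mean_read`.
#' @export
per_locus_length_stats <- function(records) {
  if (is.null(records) || nrow(records) == 0L)
    return(data.frame(locus_id = character(0), median_seq = numeric(0),
                      mean_seq = numeric(0), median_read = numeric(0),
                      mean_read = numeric(0)))
  sp <- split(records, records$locus_id)
  out <- do.call(rbind, lapply(sp, function(r) data.frame(
    locus_id = r$locus_id[1L],
    median_seq = lower_median(r$length),
    mean_seq = mean(r$length),
    median_read = weighted_lower_median(r$length, r$count),
    mean_read = sum(r$length * r$count) / sum(r$count),
    stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Per-locus length shifts between two samples
#'
#' For every locus present in both statistics tables, `stat_b - stat_a` for
#' the chosen statistic.
#'
#' @param stats_a,stats_b outputs of [per_locus_length_stats()].
#' @param stat which column to difference.
#' @return Named numeric vector of shifts (names = locus ids).
#' @export
length_shift <- function(stats_a, stats_b,
                         stat = c("median_read", "median_seq",
                                  "mean_read", "mean_seq")) {
  stat <- match.arg(stat)
  shared <- intersect(stats_a$locus_id, stats_b$locus_id)
  if (!length(shared)) stop("no shared loci between the two samples")
  a <- stats::setNames(stats_a[[stat]], stats_a$locus_id)[shared]
  b <- stats::setNames(stats_b[[stat]], stats_b$locus_id)[shared]
  b - a
}

#' Binary detection matrix of precursor lengths per locus
#'
#' Entry (locus, length) is 1 iff at least one precursor of that length was
#' observed at that locus. Rows can be ordered by termination-signal score
#' for heat-map display; the matrix itself is the contract.
#'
#' @param records precursor data frame.
#' @param lengths integer length grid (default: observed range).
#' @return Binary integer matrix, loci x lengths.
#' @export
detection_matrix <- function(records, lengths = NULL) {
  if (is.null(lengths))
    lengths <- seq(min(records$length), max(records$length))
  loci <- sort(unique(records$locus_id))
  mat <- matrix(0L, length(loci), length(lengths),
                dimnames = list(loci, lengths))
  i <- match(records$locus_id, loci)
  j <- match(records$length, lengths)
  ok <- !is.na(j)
  mat[cbind(i[ok], j[ok])] <- 1L
  mat
}

#' Nucleoplasmic trimming analysis
#'
#' Loci are binned by the fraction of their chromatin-bound precursor reads
#' longer than `long_threshold`; within each bin the distribution of
#' per-locus nucleoplasmic median lengths (both weightings) is returned.
#' Loci must be detected in both compartments. If every locus has the same
#' long fraction (e.g. all zero) a single bin is formed.
#'
#' @param chromatin_records,nucleoplasm_records precursor data frames.
#' @param long_threshold length (nt) above which a chromatin read counts as
#'   long.
#' @param n_bins number of percentile bins of the long fraction.
#' @return Data frame `locus_id`, `frac_long`, `bin`, `median_seq`,
#'   `median_read`.
#' @export
trimming_bins <- function(chromatin_records, nucleoplasm_records,
                          long_threshold = 38L, n_bins = 5L) {
  shared <- intersect(chromatin_records$locus_id, nucleoplasm_records$locus_id)
  if (!length(shared)) stop("no loci present in both compartments")
  ch <- chromatin_records[chromatin_records$locus_id %in% shared, ]
  nu <- nucleoplasm_records[nucleoplasm_records$locus_id %in% shared, ]
  long <- rowsum(ch$count * (ch$length > long_threshold), ch$locus_id)
  tot <- rowsum(ch$count, ch$locus_id)
  frac <- stats::setNames(as.numeric(long) / as.numeric(tot), rownames(tot))
  ns <- per_locus_length_stats(nu)
  out <- data.frame(locus_id = ns$locus_id,
                    frac_long = unname(frac[ns$locus_id]),
                    median_seq = ns$median_seq,
                    median_read = ns$median_read,
                    stringsAsFactors = FALSE)
  out$bin <- if (length(unique(out$frac_long)) == 1L) 1L else
    .percentile_bins(out$frac_long, n_bins)
  out[c("locus_id", "frac_long", "bin", "median_seq", "median_read")]
}
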