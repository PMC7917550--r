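## Weighted bootstrap localization of the two nascent-RNA length peaks.
##
## The population resampled is the set of unique precursor sequences (one
## entry per (locus, length) with its read count). Each resample draws
## n_sample sequences without replacement with inclusion probability
## increasing in read count, fits a Gaussian kernel density to the sampled
## lengths and records the positions of the two dominant local maxima.

#' Weighted subsample of unique sequences
#'
#' Draws `n_sample` distinct sequences without replacement, weighting the
#' sampling probability by read count. Implemented with exponential sort
#' keys (`rexp(n)/w`, keep the `n_sample` smallest), which is
#' distributionally identical to successive weighted draws with
#' renormalization.
#'
#' @param records data frame of unique sequences with columns `length` and
#'   `count`.
#' @param n_sample number of sequences to draw.
#' @return Integer vector of sampled lengths (length `n_sample`).
#' @export
weighted_subsample <- function(records, n_sample) {
  n <- nrow(records)
  if (n < n_sample)
    stop("population has ", n, " unique sequences; ", n_sample,
         " requested (short by ", n_sample - n, ")")
  if (n == n_sample) return(records$length)
  keys <- stats::rexp(n) / records$count
  records$length[order(keys)[seq_len(n_sample)]]
}

#' Locate the two dominant peaks of a length distribution
#'
#' Fits a Gaussian kernel density (default bandwidth: Silverman's rule) on a
#' 0.1-nt grid spanning `[min - 3*bw, max + 3*bw]`, finds all strict local
#' maxima, keeps the two of greatest density and orders them by position.
#' A second maximum whose density is below `min_rel_density` of the first is
#' treated as a smoothing artifact and dropped. Degenerate input (all
#' lengths equal) yields a single peak at that value.
#'
#' @param lengths numeric vector of precursor lengths.
#' @param bandwidth kernel bandwidth in nt (`NULL` = Silverman).
#' @param min_rel_density relative-density floor for the second peak.
#' @return A `peak_estimate` list: `peak1`, `peak2` (`NA` if absent) and the
#'   smoothed `curve` (data frame `x`, `y`).
#' @export
find_peaks <- function(lengths, bandwidth = NULL, min_rel_density = 0.01) {
  stopifnot(length(lengths) >= 1L)
  if (length(unique(lengths)) == 1L)
    return(structure(list(peak1 = lengths[1L], peak2 = NA_real_,
                          curve = data.frame(x = lengths[1L], y = Inf)),
                     class = "peak_estimate"))
  bw <- if (is.null(bandwidth)) stats::bw.nrd0(lengths) else bandwidth
  from <- min(lengths) - 3 * bw
  to <- max(lengths) + 3 * bw
  n_grid <- max(64L, as.integer(round((to - from) / 0.1)) + 1L)
  d <- stats::density(lengths, bw = bw, from = from, to = to, n = n_grid)
  y <- d$y
  loc <- which(diff(sign(diff(y))) == -2L) + 1L
  if (!length(loc)) loc <- which.max(y)
  top <- loc[order(y[loc], decreasing = TRUE)]
  top <- top[seq_len(min(2L, length(top)))]
  if (length(top) == 2L && y[top[2L]] < min_rel_density * y[top[1L]])
    top <- top[1L]
  px <- sort(d$x[top])
  structure(list(peak1 = px[1L],
                 peak2 = if (length(px) == 2L) px[2L] else NA_real_,
                 curve = data.frame(x = d$x, y = y)),
            class = "peak_estimate")
}

#' Bootstrap distribution of the two pause-peak positions
#'
#' Repeats [weighted_subsample()] + [find_peaks()] `n_boot` times and
#' collects the peak positions. Resamples lacking a second maximum
#' contribute nothing to `peak2_positions`. Fully reproducible from `seed`.
#'
#' @param records unique-sequence data frame (`length`, `count`), e.g. from
#'   [identify_precursors()] with replicates merged.
#' @param n_boot number of resamples.
#' @param n_sample sequences per resample.
#' @param bandwidth passed to [find_peaks()].
#' @param seed optional RNG seed.
#' @return A `bootstrap_result` list: `n_boot`, `n_sample`, `seed`,
#'   `peak1_positions`, `peak2_positions`.
#' @export
bootstrap_peaks <- function(records, n_boot = 2000L, n_sample = 3000L,
                            bandwidth = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(records) < n_sample)
    stop("population has ", nrow(records), " unique sequences; ", n_sample,
         " requested (short by ", n_sample - nrow(records), ")")
  p1 <- numeric(n_boot)
  p2 <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    pk <- find_peaks(weighted_subsample(records, n_sample), bandwidth)
    p1[b] <- pk$peak1
    p2[b] <- pk$peak2
  }
  structure(list(n_boot = n_boot, n_sample = n_sample, seed = seed,
                 peak1_positions = p1, peak2_positions = p2[!is.na(p2)]),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("Weighted bootstrap of nascent-RNA length peaks\n")
  cat(sprintf("  %d resamples of %d sequences\n", x$n_boot, x$n_sample))
  cat(sprintf("  peak1 median %.2f nt (n = %d)\n",
              stats::median(x$peak1_positions), length(x$peak1_positions)))
  if (length(x$peak2_positions))
    cat(sprintf("  peak2 median %.2f nt (n = %d)\n",
                stats::median(x$peak2_positions), length(x$peak2_positions)))
  invisible(x)
}
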