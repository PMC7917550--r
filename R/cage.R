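## CAGE-side readthrough analysis: upstream CTSS counting, referent
## power-law normalization, fold changes, paired-end fragment lengths and
## downsampling saturation.
##
## A CTSS table is a data frame (chrom, strand, pos, count): one row per
## CAGE-supported transcription start site per sample. piRNA precursor
## initiation is read out at u5-frame position -2, i.e. the precursor TSS.

## genomic position of a u5-frame offset for each locus
.u5_offset_pos <- function(loci, offset) {
  ifelse(loci$strand == "+", loci$u5_pos + offset, loci$u5_pos - offset)
}

#' Count CAGE tags upstream of 21U-RNAs
#'
#' For each u5-frame offset in `offsets` (negative = upstream of the mature
#' piRNA 5' U), the total tag count and the number of distinct CTSS
#' positions across loci; per-locus counts at -2 (the precursor TSS) are
#' returned separately.
#'
#' @param ctss CTSS data frame (`chrom`, `strand`, `pos`, `count`).
#' @param loci locus data frame.
#' @param offsets integer u5-frame offsets (default `-10:-1`).
#' @return List with `profile` (data frame `offset`, `tags`,
#'   `unique_positions`) and `minus2` (named per-locus tag counts at -2).
#' @export
count_upstream <- function(ctss, loci, offsets = -10:-1) {
  key <- .pos_key(ctss$chrom, ctss$strand, ctss$pos)
  tags <- integer(length(offsets))
  uniq <- integer(length(offsets))
  for (i in seq_along(offsets)) {
    pos <- .u5_offset_pos(loci, offsets[i])
    hit <- match(.pos_key(loci$chrom, loci$strand, pos), key)
    tags[i] <- sum(ctss$count[hit[!is.na(hit)]])
    uniq[i] <- sum(!is.na(hit) & ctss$count[hit] > 0)
  }
  pos2 <- .u5_offset_pos(loci, -2L)
  hit2 <- match(.pos_key(loci$chrom, loci$strand, pos2), key)
  minus2 <- ifelse(is.na(hit2), 0L, ctss$count[hit2])
  list(profile = data.frame(offset = offsets, tags = tags,
                            unique_positions = uniq),
       minus2 = stats::setNames(as.integer(minus2), loci$locus_id))
}

#' Referent power-law normalization of CTSS counts
#'
#' CAGE tag counts follow an approximate power law: the reverse-cumulative
#' count `r(x)` (number of CTSSs with at least `x` tags) is linear in
#' `log r` vs `log x`. The observed law `r = c x^-alpha` is fitted by least
#' squares over the distinct count values inside `fit_range`, and each raw
#' count is mapped onto a referent law with exponent `alpha_ref` totalling
#' `total_ref` tags:
#' `x* = (c / c_ref)^(-1/alpha_ref) * x^(alpha/alpha_ref)`,
#' with `c_ref = total_ref / zeta(alpha_ref)` (the zeta factor makes the
#' referent law sum to `total_ref` tags). The transform is strictly
#' monotone, so CTSS ranks are preserved; when the data already follow the
#' referent exponent it reduces to a rescaling.
#'
#' @param counts integer vector of raw per-CTSS tag counts.
#' @param alpha_ref referent exponent (default 1.25).
#' @param total_ref referent library size (default 1e6, i.e. values are
#'   normalized tags per million).
#' @param fit_range count interval used for the fit.
#' @return List with `tpm` (normalized values, zeros preserved) and `fit`
#'   (a `powerlaw_fit`: `alpha`, `log_intercept`, `alpha_ref`, `total_ref`,
#'   `fit_range`, `n_support`).
#' @export
powerlaw_normalize <- function(counts, alpha_ref = 1.25, total_ref = 1e6,
                               fit_range = c(5L, 1000L)) {
  x <- sort(unique(counts[counts >= fit_range[1L] & counts <= fit_range[2L]]))
  if (length(x) < 5L)
    stop("power-law fit needs at least 5 distinct count values in [",
         fit_range[1L], ", ", fit_range[2L], "]; found ", length(x))
  r <- vapply(x, function(v) sum(counts >= v), numeric(1L))
  fit <- stats::lm(log(r) ~ log(x))
  alpha <- -unname(stats::coef(fit)[2L])
  log_c <- unname(stats::coef(fit)[1L])
  c_ref <- total_ref / pracma::zeta(alpha_ref)
  scale <- exp((log_c - log(c_ref)) / alpha_ref)   # (c/c_ref)^(1/alpha_ref)
  tpm <- ifelse(counts > 0, scale * counts^(alpha / alpha_ref), 0)
  list(tpm = tpm,
       fit = structure(list(alpha = alpha, log_intercept = log_c,
                            alpha_ref = alpha_ref, total_ref = total_ref,
                            fit_range = fit_range, n_support = length(x)),
                       class = "powerlaw_fit"))
}

#' Readthrough log2 fold changes at the precursor TSS
#'
#' Per-locus log2 fold change of normalized CAGE signal at u5-frame -2
#' between two conditions. Loci with zero signal in both conditions are
#' excluded; `pseudocount` TPM is added to both sides.
#'
#' @param tpm_a,tpm_b named per-locus TPM vectors (condition A = reference).
#' @param pseudocount added to both values (default 0.01 TPM).
#' @return Named numeric vector of log2 fold changes for included loci.
#' @export
readthrough_fold_change <- function(tpm_a, tpm_b, pseudocount = 0.01) {
  ids <- union(names(tpm_a), names(tpm_b))
  a <- ifelse(is.na(tpm_a[ids]), 0, tpm_a[ids])
  b <- ifelse(is.na(tpm_b[ids]), 0, tpm_b[ids])
  keep <- a > 0 | b > 0
  stats::setNames(log2((b[keep] + pseudocount) / (a[keep] + pseudocount)),
                  ids[keep])
}

#' Fragment-length distribution of pairs initiating at the precursor TSS
#'
#' Tag pairs whose 5' end sits at u5-frame -2 of a locus are retrieved and
#' the histogram of their outer spans is returned in counts per million of
#' `normalizer` mapped fragments. These spans are lower bounds on
#' readthrough transcript length (the mate end comes from random priming).
#' Records with missing mate coordinates are skipped with a warning.
#'
#' @param pairs aligned pair data frame (`chrom`, `strand`, `start`, `end`,
#'   `count`, outer span coordinates).
#' @param loci locus data frame.
#' @param normalizer total mapped fragments.
#' @return Data frame `length`, `count`, `cpm`.
#' @export
pair_length_distribution <- function(pairs, loci, normalizer) {
  if (normalizer <= 0) stop("normalizer must be positive")
  bad <- is.na(pairs$start) | is.na(pairs$end)
  if (any(bad)) {
    warning(sum(bad), " unpaired records skipped")
    pairs <- pairs[!bad, , drop = FALSE]
  }
  .check_reads(pairs)
  at <- .pos_key(pairs$chrom, pairs$strand, .read_5p(pairs)) %in%
    .pos_key(loci$chrom, loci$strand, .u5_offset_pos(loci, -2L))
  sel <- pairs[at, , drop = FALSE]
  if (nrow(sel) == 0L)
    return(data.frame(length = integer(0), count = numeric(0),
                      cpm = numeric(0)))
  span <- sel$end - sel$start
  tot <- rowsum(sel$count, span)
  out <- data.frame(length = as.integer(rownames(tot)),
                    count = as.numeric(tot))
  out <- out[order(out$length), , drop = FALSE]
  out$cpm <- out$count / normalizer * 1e6
  rownames(out) <- NULL
  out
}

#' Saturation of piRNA locus detection with sequencing depth
#'
#' For each target depth, draws `n_rep` multinomial subsamples of tags from
#' each replicate library, counts loci with at least one tag at the
#' precursor TSS (u5-frame -2), and averages replicate counts within each
#' subsample index.
#'
#' @param ctss_reps list of CTSS data frames, one per replicate.
#' @param loci locus data frame.
#' @param depths subsample sizes; values <= 1 are interpreted as fractions
#'   of each library, larger values as absolute tag counts. A depth larger
#'   than a library is an error.
#' @param n_rep subsamples per depth.
#' @param seed optional RNG seed.
#' @return Data frame `depth`, `subsample`, `detected` (replicate-averaged).
#' @export
downsample_saturation <- function(ctss_reps, loci, depths, n_rep = 15L,
                                  seed = NULL) {
  stopifnot(is.list(ctss_reps), length(ctss_reps) >= 1L)
  if (!is.null(seed)) set.seed(seed)
  tss_keys <- .pos_key(loci$chrom, loci$strand, .u5_offset_pos(loci, -2L))
  prep <- lapply(ctss_reps, function(ct) {
    list(count = ct$count, total = sum(ct$count),
         at_tss = match(.pos_key(ct$chrom, ct$strand, ct$pos), tss_keys))
  })
  res <- list()
  for (d in depths) {
    det <- matrix(0, n_rep, length(prep))
    for (r in seq_along(prep)) {
      p <- prep[[r]]
      size <- if (d <= 1) round(d * p$total) else as.integer(d)
      if (size > p$total)
        stop("depth ", d, " exceeds library size ", p$total)
      keep <- !is.na(p$at_tss)
      for (j in seq_len(n_rep)) {
        sub <- stats::rmultinom(1L, size, p$count)[, 1L]
        det[j, r] <- length(unique(p$at_tss[keep & sub > 0]))
      }
    }
    res[[length(res) + 1L]] <- data.frame(depth = d,
                                          subsample = seq_len(n_rep),
                                          detected = rowMeans(det))
  }
  do.call(rbind, res)
}
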