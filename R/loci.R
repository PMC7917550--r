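## piRNA locus annotation: I/O, derived TSS coordinates, termination-signal
## scoring and percentile binning.
##
## A locus table is a plain data frame with columns
##   locus_id, chrom, strand, u5_pos, motif_class, signal_score, signal_bin
## plus the derived tss_pos. u5_pos is the 0-based genomic coordinate of the
## mature 21U-RNA first nucleotide (the 5' U); the precursor TSS sits exactly
## 2 nt upstream of it on the locus strand.

.locus_tss <- function(u5_pos, strand) {
  ifelse(strand == "+", u5_pos - 2L, u5_pos + 2L)
}

.finish_loci <- function(loci) {
  loci$u5_pos <- as.integer(loci$u5_pos)
  loci$tss_pos <- as.integer(.locus_tss(loci$u5_pos, loci$strand))
  if (is.null(loci$signal_score)) loci$signal_score <- NA_real_
  if (is.null(loci$signal_bin)) loci$signal_bin <- NA_integer_
  dup <- duplicated(loci$locus_id)
  if (any(dup))
    stop("duplicate locus_id: ", paste(unique(loci$locus_id[dup]), collapse = ", "))
  rownames(loci) <- NULL
  loci
}

#' Load a piRNA locus annotation
#'
#' Reads a locus annotation from BED6 (name column = locus id; an optional
#' 7th column gives the motif class) or from a TSV with header columns
#' `locus_id chrom u5_pos strand motif_class`. In BED input the 21U-RNA
#' occupies the record interval, so the 5' U is `start` on the plus strand
#' and `end - 1` on the minus strand. The precursor TSS (2 nt upstream of
#' the 5' U on the locus strand) is derived and stored as `tss_pos`.
#'
#' @param path path to a BED or TSV annotation.
#' @param motif_class default motif class used when the file carries none.
#' @return A locus data frame (see Details) with one row per locus.
#' @export
load_loci <- function(path, motif_class = "motif_dependent") {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty annotation: ", path)
  is_tsv <- grepl("locus_id", lines[[1L]])
  if (is_tsv) {
    tab <- utils::read.table(text = lines, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    need <- c("locus_id", "chrom", "u5_pos", "strand", "motif_class")
    miss <- setdiff(need, names(tab))
    if (length(miss)) stop("TSV annotation missing columns: ",
                           paste(miss, collapse = ", "))
    .validate_locus_rows(tab$strand, tab$u5_pos, seq_len(nrow(tab)) + 1L, path)
    loci <- tab[need]
  } else {
    fields <- strsplit(lines, "\t| +")
    nf <- lengths(fields)
    if (any(nf < 6L))
      stop("BED annotation ", path, ": line ", which(nf < 6L)[1L],
           " has fewer than 6 fields")
    mat <- t(vapply(fields, function(f) f[1:6], character(6L)))
    start <- suppressWarnings(as.integer(mat[, 2L]))
    end <- suppressWarnings(as.integer(mat[, 3L]))
    strand <- mat[, 6L]
    .validate_locus_rows(strand, start, seq_along(lines), path)
    if (any(is.na(end)) || any(end <= start, na.rm = TRUE))
      stop("BED annotation ", path, ": line ",
           which(is.na(end) | end <= start)[1L], " has an invalid interval")
    cls <- ifelse(nf >= 7L, vapply(fields, function(f) f[7L] %||% "", ""),
                  motif_class)
    cls[!nzchar(cls) | is.na(cls)] <- motif_class
    loci <- data.frame(
      locus_id = mat[, 4L], chrom = mat[, 1L], strand = strand,
      u5_pos = ifelse(strand == "+", start, end - 1L),
      motif_class = cls, stringsAsFactors = FALSE)
  }
  .finish_loci(loci)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

.validate_locus_rows <- function(strand, coord, line_no, path) {
  bad <- which(!(strand %in% c("+", "-")))
  if (length(bad))
    stop("annotation ", path, ": line ", line_no[bad[1L]],
         " has malformed strand '", strand[bad[1L]], "'")
  coord <- suppressWarnings(as.numeric(coord))
  bad <- which(is.na(coord) | coord < 0)
  if (length(bad))
    stop("annotation ", path, ": line ", line_no[bad[1L]],
         " has a negative or non-numeric coordinate")
}

#' Read strand-aware alignments from BED6
#'
#' One record per unique (interval, strand) pair; the BED score column holds
#' the read multiplicity. Coordinates are kept 0-based half-open.
#'
#' @param path BED6 file.
#' @param library library type label, one of `"capped_short"`,
#'   `"fivep_small"`, `"cage"`.
#' @return An aligned-read data frame with columns `chrom`, `strand`,
#'   `start`, `end`, `count`, `library`.
#' @export
read_alignments <- function(path, library = c("capped_short", "fivep_small", "cage")) {
  library <- match.arg(library)
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "name",
                                         "count", "strand"))
  reads <- data.frame(chrom = tab$chrom, strand = tab$strand,
                      start = as.integer(tab$start), end = as.integer(tab$end),
                      count = as.integer(tab$count), library = library,
                      stringsAsFactors = FALSE)
  .check_reads(reads)
  reads
}

#' Write alignments as BED6
#'
#' @param reads aligned-read data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(reads, path) {
  .check_reads(reads)
  bed <- data.frame(reads$chrom, reads$start, reads$end,
                    if (is.null(reads$library)) "read" else reads$library,
                    reads$count, reads$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Map reads into TSS- or u5-relative offset space
#'
#' Offsets count nucleotides downstream along the locus strand, with 0 at
#' the reference nucleotide (the precursor TSS or the 21U-RNA 5' U). A
#' read's 5' offset is the offset of its 5' end; its 3' offset is its
#' half-open end in offset space, so `three - five` equals the read length.
#' u5-frame offsets equal tss-frame offsets minus 2.
#'
#' @param reads aligned-read data frame.
#' @param locus a single locus (one row of a locus table).
#' @param frame `"tss"` or `"u5"`.
#' @return Data frame with columns `five` and `three`; both are `NA` for
#'   reads on a different chromosome or strand than the locus.
#' @export
to_offset <- function(reads, locus, frame = c("tss", "u5")) {
  frame <- match.arg(frame)
  .check_reads(reads)
  stopifnot(nrow(locus) == 1L)
  tss <- locus$tss_pos
  ok <- reads$chrom == locus$chrom & reads$strand == locus$strand
  if (locus$strand == "+") {
    five <- reads$start - tss
    three <- reads$end - tss
  } else {
    five <- tss - (reads$end - 1L)
    three <- tss - reads$start + 1L
  }
  if (frame == "u5") { five <- five - 2L; three <- three - 2L }
  five[!ok] <- NA_integer_; three[!ok] <- NA_integer_
  data.frame(five = as.integer(five), three = as.integer(three))
}

#' Map offset intervals back to genomic coordinates
#'
#' Inverse of [to_offset()]: given 5'/3' offsets in the chosen frame,
#' reconstruct the 0-based half-open genomic interval on the locus strand.
#'
#' @param five,three integer offsets (`three` half-open, `three > five`).
#' @param locus a single locus row.
#' @inheritParams to_offset
#' @return Data frame with `chrom`, `strand`, `start`, `end`.
#' @export
from_offset <- function(five, three, locus, frame = c("tss", "u5")) {
  frame <- match.arg(frame)
  stopifnot(nrow(locus) == 1L, all(three > five))
  if (frame == "u5") { five <- five + 2L; three <- three + 2L }
  tss <- locus$tss_pos
  if (locus$strand == "+") {
    start <- tss + five; end <- tss + three
  } else {
    start <- tss - three + 1L; end <- tss - five + 1L
  }
  data.frame(chrom = locus$chrom, strand = locus$strand,
             start = as.integer(start), end = as.integer(end))
}

#' Score the termination signal of each locus
#'
#' The termination signal is the A/T fraction of the sense strand within a
#' window given in offset space (default tss-frame `[0, 50)`, spanning the
#' transcription unit from the TSS to +50). Because A/T content is invariant
#' under reverse complementation, the count is taken directly on the
#' reference sequence of the window. Higher values mean stronger
#' pausing/termination signals.
#'
#' @param loci locus data frame.
#' @param genome a [Biostrings::DNAStringSet] of contigs named like `chrom`.
#' @param window half-open offset interval `c(lo, hi)`.
#' @param frame `"tss"` (default) or `"u5"`.
#' @return `loci` with `signal_score` filled in.
#' @export
termination_signal <- function(loci, genome, window = c(0L, 50L),
                               frame = c("tss", "u5")) {
  frame <- match.arg(frame)
  stopifnot(length(window) == 2L, window[2L] > window[1L])
  if (frame == "u5") window <- window + 2L
  widths <- Biostrings::width(genome)
  names(widths) <- names(genome)
  lo <- window[1L]; hi <- window[2L]
  plus <- loci$strand == "+"
  start1 <- ifelse(plus, loci$tss_pos + lo + 1L, loci$tss_pos - hi + 2L)
  end1 <- ifelse(plus, loci$tss_pos + hi, loci$tss_pos - lo + 1L)
  if (any(is.na(match(loci$chrom, names(genome)))))
    stop("locus chromosome missing from genome")
  clen <- widths[loci$chrom]
  if (any(start1 < 1L | end1 > clen))
    stop("termination-signal window extends past contig end for locus ",
         loci$locus_id[which(start1 < 1L | end1 > clen)[1L]])
  score <- vapply(seq_len(nrow(loci)), function(i) {
    s <- Biostrings::subseq(genome[[loci$chrom[i]]], start1[i], end1[i])
    as.numeric(Biostrings::letterFrequency(s, "AT")) / (hi - lo)
  }, numeric(1L))
  loci$signal_score <- score
  loci
}

#' Assign equal-sized percentile bins of termination-signal strength
#'
#' Loci are ranked by `signal_score` and split into `n_bins` equal-sized
#' percentile bins; bin 1 holds the weakest signals. If every score is
#' identical the split is meaningless: all loci land in bin 1 and a warning
#' is emitted.
#'
#' @param loci scored locus data frame.
#' @param n_bins number of bins (>= 2).
#' @return `loci` with `signal_bin` filled in.
#' @export
assign_signal_bins <- function(loci, n_bins = 5L) {
  stopifnot(n_bins >= 2L)
  if (any(is.na(loci$signal_score)))
    stop("all loci must be scored before binning (see termination_signal)")
  if (length(unique(loci$signal_score)) == 1L) {
    warning("all termination-signal scores identical; assigning a single bin")
    loci$signal_bin <- 1L
    return(loci)
  }
  loci$signal_bin <- .percentile_bins(loci$signal_score, n_bins)
  loci
}
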