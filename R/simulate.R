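## Synthetic-data generator for the two-pause / Integrator-cleavage model of
## piRNA transcription termination.
##
## The generative picture: Pol II initiates 2 nt upstream of the mature
## 21U-RNA 5' U and pauses ~28 nt downstream of the TSS. A paused polymerase
## either terminates there (releasing a ~28 nt short-capped precursor) or
## resumes and arrests again at ~48 nt. Transcription past the second pause
## triggers endonucleolytic cleavage of the nascent RNA at ~+38, releasing a
## ~38 nt capped product and leaving a 5'-monophosphate degradation fragment
## whose 3' (half-open) end sits near +58 — a median fragment length of
## 20 nt. Stronger AT-rich termination signals downstream of the 21U-RNA
## make termination at the first pause more likely, depleting both the
## second-pause precursor population and the cleavage fragments.

#' Simulation configuration
#'
#' Full parameterization of the two-pause + cleavage generative model.
#' Lengths and offsets are rounded draws from Normal components; pause-site
#' choice is Bernoulli per polymerase with a logit-linear dependence on the
#' locus termination-signal score.
#'
#' @param n_loci number of piRNA loci.
#' @param frac_motif_dependent fraction of loci carrying the upstream GTTTC
#'   (Ruby) motif.
#' @param peak1_pos,peak1_sd first pause: short-capped precursor length mode
#'   (nt) and its spread.
#' @param peak2_pos,peak2_sd second pause component.
#' @param p_pause2_base probability that a polymerase at a locus with
#'   mid-range termination signal (score 0.5) proceeds to the second pause.
#' @param signal_coupling slope (<= 0) linking `signal_score - 0.5` to the
#'   log-odds of reaching the second pause; more negative means stronger
#'   suppression of pause-2 transit at AT-rich loci.
#' @param cleavage5_mu,cleavage5_sd TSS-frame 5' offset of the cleavage
#'   position (the degradation fragment 5' end).
#' @param cleavage3_mu,cleavage3_sd TSS-frame half-open 3' offset of the
#'   degradation fragment (the Pol II front at cleavage time).
#' @param fragment_rate fraction of pause-2 events yielding a detectable
#'   5'P degradation fragment.
#' @param readthrough_frac fraction of motif-dependent loci emitting long
#'   capped (CAGE-detectable) readthrough RNAs.
#' @param reads_per_locus_mean mean capped reads per locus before the
#'   per-locus abundance factor.
#' @param abundance_sdlog log-sd of the per-locus lognormal abundance factor
#'   (piRNA locus expression spans orders of magnitude).
#' @param mature_reads_mean mean mature 21U-RNA reads per locus in 5'P
#'   libraries.
#' @param mirna_count number of background miRNA loci (normalization
#'   features for 5'P libraries).
#' @param mirna_reads_mean mean reads per miRNA locus.
#' @param unannotated_frac fraction of loci with an additional unannotated
#'   21U-RNA start within +/-5 nt of the annotated 5' U.
#' @param tail_frac under presets with `tail_extension_max > 0`, probability
#'   that a pause-2 length is replaced by a uniform draw up to the tail
#'   maximum (loss of cleavage lets precursors run long).
#' @param max_len capped-library upper length cut (library size selection).
#' @param cage_alpha reverse-cumulative power-law exponent of simulated
#'   CAGE tag counts.
#' @param cage_indep_frac fraction of motif-independent loci emitting CAGE
#'   tags (these loci overlap ordinary promoters).
#' @param cage_min_tags minimum tag count of an emitting piRNA locus.
#' @param cage_background number of background (non-piRNA) CTSS positions.
#' @param pair_len_mean,pair_len_sd CAGE fragment (outer span) length model.
#' @param seed master seed; every downstream simulation derives its stream
#'   from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_loci = 500L,
                       frac_motif_dependent = 0.8,
                       peak1_pos = 28L, peak1_sd = 2,
                       peak2_pos = 48L, peak2_sd = 2,
                       p_pause2_base = 0.25,
                       signal_coupling = -6,
                       cleavage5_mu = 38L, cleavage5_sd = 1.5,
                       cleavage3_mu = 58L, cleavage3_sd = 1.5,
                       fragment_rate = 0.5,
                       readthrough_frac = 0.01,
                       reads_per_locus_mean = 120,
                       abundance_sdlog = 1.2,
                       mature_reads_mean = 80,
                       mirna_count = 60L,
                       mirna_reads_mean = 30,
                       unannotated_frac = 0.05,
                       tail_frac = 0.3,
                       max_len = 75L,
                       cage_alpha = 1.25,
                       cage_indep_frac = 0.45,
                       cage_min_tags = 5L,
                       cage_background = 500L,
                       pair_len_mean = 450, pair_len_sd = 80,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_loci >= 1L,
            cfg$peak2_pos > cfg$peak1_pos,
            cfg$cleavage3_mu > cfg$cleavage5_mu,
            cfg$signal_coupling <= 0)
  probs <- c("frac_motif_dependent", "p_pause2_base", "fragment_rate",
             "readthrough_frac", "unannotated_frac", "tail_frac",
             "cage_indep_frac")
  for (p in probs)
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must lie in [0,1]")
  structure(cfg, class = "sim_config")
}

#' Genotype presets
#'
#' Modifiers applied on top of [sim_config()]:
#' * `wild_type` — identity (no shifts, unit factors).
#' * `tfiis` — loss of TFIIS-stimulated cleavage of backtracked Pol II
#'   shifts the apparent pause sites downstream (+2 / +3 nt), reduces
#'   Integrator fragment yield and increases chromatin-bound precursor
#'   abundance.
#' * `ints11_kd` — depletion of the Integrator endonuclease: fragments
#'   largely lost, precursor levels drop, an upper length tail extends to
#'   75 nt, and readthrough rises to ~3.6% of motif-dependent loci.
#' * `tfiis_ints11_kd` — both perturbations combined.
#'
#' @param name preset name.
#' @return A `genotype_preset` list with fields `name`, `peak1_shift`,
#'   `peak2_shift`, `fragment_rate_factor`, `precursor_abundance_factor`,
#'   `tail_extension_max`, `readthrough_factor`.
#' @export
genotype_preset <- function(name = c("wild_type", "tfiis", "ints11_kd",
                                     "tfiis_ints11_kd")) {
  name <- match.arg(name)
  p <- switch(name,
    wild_type = list(peak1_shift = 0L, peak2_shift = 0L,
                     fragment_rate_factor = 1, precursor_abundance_factor = 1,
                     tail_extension_max = 0L, readthrough_factor = 1),
    tfiis = list(peak1_shift = 2L, peak2_shift = 3L,
                 fragment_rate_factor = 0.4, precursor_abundance_factor = 1.5,
                 tail_extension_max = 0L, readthrough_factor = 1),
    ints11_kd = list(peak1_shift = 0L, peak2_shift = 0L,
                     fragment_rate_factor = 0.2, precursor_abundance_factor = 0.6,
                     tail_extension_max = 75L, readthrough_factor = 3.6),
    tfiis_ints11_kd = list(peak1_shift = 2L, peak2_shift = 3L,
                           fragment_rate_factor = 0.1,
                           precursor_abundance_factor = 0.9,
                           tail_extension_max = 75L, readthrough_factor = 3.6))
  structure(c(list(name = name), p), class = "genotype_preset")
}

## probability of transiting to the second pause site given the signal score
.p_pause2 <- function(config, score) {
  stats::plogis(stats::qlogis(config$p_pause2_base) +
                  config$signal_coupling * (score - 0.5))
}

## discrete power-law sampler: P(k) propto k^-(alpha_tail + 1)
.rpowerlaw <- function(n, alpha_tail, xmin = 1L, xmax = 10000L) {
  k <- xmin:xmax
  sample(k, n, replace = TRUE, prob = k^(-(alpha_tail + 1)))
}

#' Simulate a genome and piRNA locus annotation
#'
#' Builds synthetic contigs with non-overlapping piRNA loci (~400 nt apart),
#' plants the GTTTC core motif upstream of motif-dependent loci, forces a T
#' at every 21U-RNA 5' U, and writes each locus's downstream window so that
#' its A/T fraction equals a target termination-signal score drawn uniformly
#' from [0.2, 1.0] (an exact count of A/T bases is placed, so rescoring the
#' emitted sequence recovers the intended score). A fraction of loci carry a
#' planted unannotated 21U start (a T within +/-5 nt of the annotated 5' U);
#' planting swaps bases so the window A/T count is conserved. A dedicated
#' contig carries background miRNA loci. Per-locus lognormal abundance
#' factors model the heavy-tailed expression of piRNA loci.
#'
#' @param config a [sim_config()].
#' @return A `pirna_sim` list with elements `genome`
#'   ([Biostrings::DNAStringSet]), `loci` (locus data frame with extra
#'   columns `abundance`, `unannot_pos`), `mirna` (miRNA annotation) and
#'   `config`.
#' @export
simulate_loci <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.derive_seed(config$seed, "loci"))
  n <- config$n_loci
  spacing <- 400L
  per_contig <- 100L
  n_contig <- ceiling(n / per_contig)
  contig_of <- rep(seq_len(n_contig), each = per_contig)[seq_len(n)]
  idx_on <- stats::ave(seq_len(n), contig_of, FUN = seq_along)
  chrom_names <- paste0("chr", as.roman(seq_len(n_contig)))

  strand <- sample(c("+", "-"), n, replace = TRUE)
  u5 <- 200L + (idx_on - 1L) * spacing
  n_motif <- round(n * config$frac_motif_dependent)
  motif_class <- c(rep("motif_dependent", n_motif),
                   rep("motif_independent", n - n_motif))[sample.int(n)]
  score_target <- stats::runif(n, 0.2, 1.0)
  n_at <- pmax(1L, as.integer(round(50 * score_target)))
  abundance <- stats::rlnorm(n, -config$abundance_sdlog^2 / 2,
                             config$abundance_sdlog)
  unannot <- stats::runif(n) < config$unannotated_frac
  unannot_off <- ifelse(unannot, sample(c(-5:-1, 1:5), n, replace = TRUE),
                        NA_integer_)

  ## background sequence per contig, then per-locus planting
  contigs <- lapply(seq_len(n_contig), function(ci) {
    len <- 200L + sum(contig_of == ci) * spacing + 200L
    sample(c("A", "C", "G", "T"), len, replace = TRUE,
           prob = c(0.3, 0.2, 0.2, 0.3))
  })

  tss <- .locus_tss(u5, strand)
  ## write a sense-strand base at tss-frame offset `off` of locus i
  put <- function(seqv, i, off, base) {
    g <- if (strand[i] == "+") tss[i] + off else tss[i] - off
    seqv[g + 1L] <- if (strand[i] == "+") base else .complement[[base]]
    seqv
  }
  for (i in seq_len(n)) {
    ci <- contig_of[i]
    sv <- contigs[[ci]]
    ## downstream window [0, 50): exact A/T count = n_at[i], u5 (offset 2) = T
    at_off <- c(2L, sample(setdiff(0:49, 2L), n_at[i] - 1L))
    for (off in 0:49) {
      base <- if (off %in% at_off) {
        if (off == 2L) "T" else sample(c("A", "T"), 1L)
      } else sample(c("G", "C"), 1L)
      sv <- put(sv, i, off, base)
    }
    ## Ruby motif GTTTC on the sense strand, u5-frame [-42, -38)
    if (motif_class[i] == "motif_dependent") {
      mb <- strsplit("GTTTC", "")[[1L]]
      for (k in 0:4) sv <- put(sv, i, -40L + k, mb[k + 1L])
    }
    ## unannotated 21U start: plant a T, conserving the window A/T count
    if (unannot[i]) {
      o <- unannot_off[i] + 2L              # tss-frame offset of the new start
      if (o >= 0L && o < 50L && !(o %in% at_off)) {
        cand <- setdiff(at_off, c(2L, o))
        if (length(cand))
          sv <- put(sv, i, cand[sample.int(length(cand), 1L)],
                    sample(c("G", "C"), 1L))
      }
      sv <- put(sv, i, o, "T")
    }
    contigs[[ci]] <- sv
  }

  genome <- Biostrings::DNAStringSet(vapply(contigs, paste, "", collapse = ""))
  names(genome) <- chrom_names[seq_len(n_contig)]

  ## background miRNA loci on their own contig
  m <- config$mirna_count
  mir_len <- 200L + m * 200L + 200L
  mir_seq <- sample(c("A", "C", "G", "T"), mir_len, replace = TRUE,
                    prob = c(0.3, 0.2, 0.2, 0.3))
  genome <- c(genome, Biostrings::DNAStringSet(paste(mir_seq, collapse = "")))
  names(genome)[length(genome)] <- "chrMir"
  mirna <- data.frame(mirna_id = sprintf("mir-%03d", seq_len(m)),
                      chrom = "chrMir", strand = "+",
                      start = 200L + (seq_len(m) - 1L) * 200L,
                      stringsAsFactors = FALSE)
  mirna$end <- mirna$start + 22L

  loci <- data.frame(
    locus_id = sprintf("21ur-%04d", seq_len(n)),
    chrom = chrom_names[contig_of], strand = strand, u5_pos = u5,
    motif_class = motif_class, signal_score = n_at / 50,
    stringsAsFactors = FALSE)
  loci <- .finish_loci(loci)
  loci$abundance <- abundance
  loci$unannot_pos <- ifelse(unannot,
                             ifelse(strand == "+", u5 + unannot_off,
                                    u5 - unannot_off),
                             NA_integer_)
  structure(list(genome = genome, loci = loci, mirna = mirna,
                 config = config), class = "pirna_sim")
}

## build capped/5'P read intervals from per-read locus indices and lengths;
## all reads start at the locus 5' reference position `ref`
.reads_from_lengths <- function(loci, idx, len, ref, library) {
  strand <- loci$strand[idx]
  start <- ifelse(strand == "+", ref[idx], ref[idx] + 1L - len)
  end <- ifelse(strand == "+", ref[idx] + len, ref[idx] + 1L)
  .aggregate_reads(data.frame(
    chrom = loci$chrom[idx], strand = strand,
    start = as.integer(start), end = as.integer(end),
    count = 1L, library = library, stringsAsFactors = FALSE))
}

#' Simulate short-capped RNA reads
#'
#' Chromatin-bound reads: each polymerase proceeds to the second pause with
#' probability `p(pause2 | signal_score)` and yields a length drawn from the
#' second Normal component (plus any preset pause-site shift and, for
#' Integrator-depleted presets, an extended upper tail); otherwise the first
#' component. Nucleoplasmic reads are released first-pause products only.
#' All reads initiate at the locus TSS; lengths are truncated to at least
#' 18 nt and at most `max_len`.
#'
#' @param sim a `pirna_sim` from [simulate_loci()].
#' @param preset a [genotype_preset()].
#' @param compartment `"chromatin"` or `"nucleoplasm"`.
#' @param seed optional; defaults to a stream derived from the config seed,
#'   the preset and the compartment.
#' @return Aligned-read data frame (`library = "capped_short"`).
#' @export
simulate_capped_reads <- function(sim, preset = genotype_preset("wild_type"),
                                  compartment = c("chromatin", "nucleoplasm"),
                                  seed = NULL) {
  stopifnot(inherits(sim, "pirna_sim"), inherits(preset, "genotype_preset"))
  compartment <- match.arg(compartment)
  config <- sim$config
  loci <- sim$loci
  if (is.null(seed))
    seed <- .derive_seed(config$seed, paste("capped", preset$name, compartment))
  set.seed(seed)
  n_i <- stats::rpois(nrow(loci), config$reads_per_locus_mean * loci$abundance *
                        preset$precursor_abundance_factor)
  p2 <- .p_pause2(config, loci$signal_score)
  if (compartment == "chromatin") {
    k2 <- stats::rbinom(nrow(loci), n_i, p2)
  } else {
    k2 <- integer(nrow(loci))                  # released pause-1 products only
  }
  k1 <- n_i - k2
  idx <- c(rep(seq_len(nrow(loci)), k1), rep(seq_len(nrow(loci)), k2))
  len1 <- round(stats::rnorm(sum(k1), config$peak1_pos + preset$peak1_shift,
                             config$peak1_sd))
  len2 <- round(stats::rnorm(sum(k2), config$peak2_pos + preset$peak2_shift,
                             config$peak2_sd))
  if (preset$tail_extension_max > 0L && sum(k2)) {
    ext <- stats::runif(sum(k2)) < config$tail_frac
    lo <- config$peak2_pos + preset$peak2_shift
    len2[ext] <- sample(seq(lo, preset$tail_extension_max),
                        sum(ext), replace = TRUE)
  }
  len <- pmin(pmax(c(len1, len2), 18L), config$max_len)
  .reads_from_lengths(loci, idx, as.integer(len), loci$tss_pos, "capped_short")
}

#' Simulate a direct 5'-monophosphate small-RNA library
#'
#' A mixture of (i) mature 21U-RNAs — 21-mers starting at the annotated 5' U,
#' plus 21-mers at planted unannotated starts; (ii) Integrator cleavage
#' (degradation) fragments — per pause-2 polymerase event, with probability
#' `fragment_rate * fragment_rate_factor`, a fragment with TSS-frame 5'
#' offset ~ round(Normal(`cleavage5_mu`, `cleavage5_sd`)) and half-open 3'
#' offset ~ round(Normal(`cleavage3_mu`, `cleavage3_sd`)), redrawn if the 3'
#' offset does not exceed the 5' offset; and (iii) background miRNA-locus
#' 22-mers used for library-size normalization.
#'
#' The per-locus pause-2 event counts are attached as
#' `attr(, "pause2_events")`; a locus can only emit fragments if it had at
#' least one pause-2 event.
#'
#' @inheritParams simulate_capped_reads
#' @return Aligned-read data frame (`library = "fivep_small"`).
#' @export
simulate_5p_reads <- function(sim, preset = genotype_preset("wild_type"),
                              seed = NULL) {
  stopifnot(inherits(sim, "pirna_sim"), inherits(preset, "genotype_preset"))
  config <- sim$config
  loci <- sim$loci
  if (is.null(seed))
    seed <- .derive_seed(config$seed, paste("fivep", preset$name))
  set.seed(seed)
  n <- nrow(loci)

  ## (i) mature 21U-RNAs at annotated and unannotated starts
  m_i <- stats::rpois(n, config$mature_reads_mean * loci$abundance)
  mature <- .reads_from_lengths(loci, rep(seq_len(n), m_i),
                                rep(21L, sum(m_i)), loci$u5_pos, "fivep_small")
  ## planted unannotated starts are expressed species by construction, so
  ## each emits at least two reads on top of its abundance-scaled draw
  has_un <- which(!is.na(loci$unannot_pos))
  un_i <- integer(n)
  un_i[has_un] <- 2L + stats::rpois(length(has_un),
                                    0.3 * config$mature_reads_mean *
                                      loci$abundance[has_un])
  unmature <- .reads_from_lengths(loci, rep(seq_len(n), un_i),
                                  rep(21L, sum(un_i)), loci$unannot_pos,
                                  "fivep_small")

  ## (ii) cleavage fragments, conditional on pause-2 polymerase events
  events <- stats::rpois(n, config$reads_per_locus_mean * loci$abundance *
                           .p_pause2(config, loci$signal_score))
  f_i <- stats::rbinom(n, events,
                       config$fragment_rate * preset$fragment_rate_factor)
  nf <- sum(f_i)
  idx <- rep(seq_len(n), f_i)
  five <- as.integer(round(stats::rnorm(nf, config$cleavage5_mu,
                                        config$cleavage5_sd)))
  three <- as.integer(round(stats::rnorm(nf, config$cleavage3_mu,
                                         config$cleavage3_sd)))
  while (any(bad <- three <= five)) {
    three[bad] <- as.integer(round(stats::rnorm(sum(bad), config$cleavage3_mu,
                                                config$cleavage3_sd)))
  }
  frag <- if (nf) {
    gi <- from_offset_many(five, three, loci[idx, , drop = FALSE])
    .aggregate_reads(data.frame(gi, count = 1L, library = "fivep_small",
                                stringsAsFactors = FALSE))
  } else mature[0, ]

  ## (iii) miRNA background
  mir <- sim$mirna
  b_i <- stats::rpois(nrow(mir), config$mirna_reads_mean)
  bidx <- rep(seq_len(nrow(mir)), b_i)
  mirna_reads <- .aggregate_reads(data.frame(
    chrom = mir$chrom[bidx], strand = mir$strand[bidx],
    start = mir$start[bidx], end = mir$start[bidx] + 22L,
    count = 1L, library = "fivep_small", stringsAsFactors = FALSE))

  out <- .aggregate_reads(rbind(mature, unmature, frag, mirna_reads))
  attr(out, "pause2_events") <- data.frame(locus_id = loci$locus_id,
                                           events = events)
  out
}

## vectorized offset -> genomic for one locus per row of `loci_rows`
from_offset_many <- function(five, three, loci_rows) {
  plus <- loci_rows$strand == "+"
  tss <- loci_rows$tss_pos
  data.frame(chrom = loci_rows$chrom, strand = loci_rows$strand,
             start = as.integer(ifelse(plus, tss + five, tss - three + 1L)),
             end = as.integer(ifelse(plus, tss + three, tss - five + 1L)),
             stringsAsFactors = FALSE)
}

#' Simulate CAGE tag pairs
#'
#' Readthrough transcription captured as paired-end CAGE fragments whose 5'
#' end sits at the precursor TSS (u5-frame -2) and whose outer span follows
#' Normal(`pair_len_mean`, `pair_len_sd`). A fraction
#' `readthrough_frac * readthrough_factor` of motif-dependent loci and
#' `cage_indep_frac` of motif-independent loci emit tags; per-locus tag
#' counts follow a discrete power law (reverse-cumulative exponent
#' `cage_alpha`) truncated below at `cage_min_tags`. Background CTSS
#' positions (ordinary promoters) with power-law counts from 1 upward are
#' added on the same contigs.
#'
#' @inheritParams simulate_capped_reads
#' @return Aligned-read data frame (`library = "cage"`) with extra columns
#'   `locus_id` (`NA` for background) and `source`.
#' @export
simulate_cage_pairs <- function(sim, preset = genotype_preset("wild_type"),
                                seed = NULL) {
  stopifnot(inherits(sim, "pirna_sim"), inherits(preset, "genotype_preset"))
  config <- sim$config
  loci <- sim$loci
  if (is.null(seed))
    seed <- .derive_seed(config$seed, paste("cage", preset$name))
  set.seed(seed)
  p_emit <- ifelse(loci$motif_class == "motif_dependent",
                   min(1, config$readthrough_frac * preset$readthrough_factor),
                   config$cage_indep_frac)
  emitting <- which(stats::runif(nrow(loci)) < p_emit)
  k <- if (length(emitting))
    .rpowerlaw(length(emitting), config$cage_alpha,
               xmin = config$cage_min_tags) else integer(0)
  idx <- rep(emitting, k)
  spans <- pmax(100L, as.integer(round(stats::rnorm(length(idx),
                                                    config$pair_len_mean,
                                                    config$pair_len_sd))))
  pirna <- if (length(idx)) {
    gi <- from_offset_many(0L, spans, loci[idx, , drop = FALSE])
    data.frame(gi, count = 1L, library = "cage",
               locus_id = loci$locus_id[idx], source = "pirna",
               stringsAsFactors = FALSE)
  } else NULL

  ## background CTSSs away from locus TSSs
  nb <- config$cage_background
  widths <- Biostrings::width(sim$genome)
  chroms <- setdiff(names(sim$genome), "chrMir")
  bchrom <- sample(chroms, nb, replace = TRUE)
  bpos <- vapply(bchrom, function(ch)
    sample(500:(widths[[match(ch, names(sim$genome))]] - 600L), 1L), 1L)
  bstrand <- sample(c("+", "-"), nb, replace = TRUE)
  clash <- .pos_key(bchrom, bstrand, bpos) %in%
    .pos_key(loci$chrom, loci$strand, loci$tss_pos)
  bpos[clash] <- bpos[clash] + 7L
  bk <- .rpowerlaw(nb, config$cage_alpha, xmin = 1L)
  bidx <- rep(seq_len(nb), bk)
  bspan <- pmax(100L, as.integer(round(stats::rnorm(length(bidx),
                                                    config$pair_len_mean,
                                                    config$pair_len_sd))))
  background <- data.frame(
    chrom = bchrom[bidx], strand = bstrand[bidx],
    start = as.integer(ifelse(bstrand[bidx] == "+", bpos[bidx],
                              bpos[bidx] + 1L - bspan)),
    end = as.integer(ifelse(bstrand[bidx] == "+", bpos[bidx] + bspan,
                            bpos[bidx] + 1L)),
    count = 1L, library = "cage", locus_id = NA_character_,
    source = "background", stringsAsFactors = FALSE)

  out <- rbind(pirna, background)
  key <- paste(out$chrom, out$strand, out$start, out$end)
  agg <- rowsum(out$count, key)
  first <- out[!duplicated(key), , drop = FALSE]
  first$count <- as.integer(agg[match(paste(first$chrom, first$strand,
                                            first$start, first$end),
                                      rownames(agg))])
  rownames(first) <- NULL
  first[order(first$chrom, first$start, first$end), , drop = FALSE]
}

#' Collapse reads or tag pairs to a CTSS table
#'
#' Counts tags per distinct 5'-end position (chrom, strand, pos).
#'
#' @param reads aligned-read data frame (typically CAGE pairs).
#' @return CTSS data frame with columns `chrom`, `strand`, `pos`, `count`.
#' @export
ctss_table <- function(reads) {
  .check_reads(reads)
  pos <- .read_5p(reads)
  key <- .pos_key(reads$chrom, reads$strand, pos)
  agg <- rowsum(reads$count, key)
  first <- !duplicated(key)
  out <- data.frame(chrom = reads$chrom[first], strand = reads$strand[first],
                    pos = pos[first], stringsAsFactors = FALSE)
  out$count <- as.integer(agg[match(.pos_key(out$chrom, out$strand, out$pos),
                                    rownames(agg))])
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Write a complete fixture set
#'
#' Emits the genome FASTA, locus and miRNA annotations, per-sample alignment
#' BEDs (two replicates for each preset: capped chromatin, capped
#' nucleoplasm, 5'P, CAGE) and a YAML manifest mapping samples to files,
#' presets and seeds. Re-running with the same config reproduces every file
#' byte-identically.
#'
#' @param outdir output directory.
#' @param config a [sim_config()].
#' @param presets character vector of preset names.
#' @param n_reps replicates per preset.
#' @param force overwrite a non-empty directory.
#' @return The manifest (invisibly), as written to `manifest.yaml`.
#' @export
write_fixture_set <- function(outdir, config = sim_config(),
                              presets = c("wild_type", "tfiis", "ints11_kd",
                                          "tfiis_ints11_kd"),
                              n_reps = 2L, force = FALSE) {
  if (dir.exists(outdir) && length(dir(outdir)) && !force)
    stop("output directory ", outdir, " is not empty (use force = TRUE)")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_loci(config)
  Biostrings::writeXStringSet(sim$genome, file.path(outdir, "genome.fa"))
  utils::write.table(sim$loci[c("locus_id", "chrom", "u5_pos", "strand",
                                "motif_class")],
                     file.path(outdir, "loci.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$mirna, file.path(outdir, "mirna.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  samples <- list()
  for (pn in presets) {
    preset <- genotype_preset(pn)
    for (rep_i in seq_len(n_reps)) {
      for (lib in c("capped_short", "fivep_small", "cage")) {
        tag <- paste(pn, rep_i, lib)
        seed <- .derive_seed(config$seed, tag)
        reads <- switch(lib,
          capped_short = simulate_capped_reads(sim, preset, "chromatin",
                                               seed = seed),
          fivep_small = simulate_5p_reads(sim, preset, seed = seed),
          cage = simulate_cage_pairs(sim, preset, seed = seed))
        fname <- sprintf("%s_rep%d_%s.bed", pn, rep_i, lib)
        write_alignments(reads, file.path(outdir, fname))
        samples[[length(samples) + 1L]] <- list(
          name = sprintf("%s_rep%d_%s", pn, rep_i, lib),
          preset = pn, replicate = rep_i, library = lib,
          file = fname, seed = seed)
      }
    }
  }
  manifest <- list(genome = "genome.fa", loci = "loci.tsv",
                   mirna = "mirna.tsv", config_seed = config$seed,
                   samples = samples)
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  invisible(manifest)
}
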