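#' Simulation configuration
#'
#' Ground-truth generator settings emulating a transcriptome with
#' reassigned/ambiguous stop codons, AU-rich very short 3' UTRs, poly(A)
#' tails, and ribosome-protected fragments with terminating 3' ends 11/12
#' nt past stops. One integer seed governs all stages; each stage derives
#' its own substream deterministically, so identical configurations give
#' bit-identical outputs.
#'
#' @param seed Integer master seed.
#' @param code [GeneticCodeTable-class] the transcriptome is written in.
#' @param n_transcripts,n_families,family_length Cohort size, number of
#'   protein families and family length in coding codons (stop excluded).
#'   `n_families = NULL` (default) gives each transcript its own family —
#'   the single-copy, single-isoform gene cohort the positional analyses
#'   assume; shared families (n_families < n_transcripts) induce
#'   positional composition lumps that real multi-gene cohorts do not
#'   have.
#' @param conservation_shape Beta shape parameters for per-column
#'   modal-residue frequency.
#' @param substitution_rate Per-column amino-acid substitution probability
#'   per transcript.
#' @param sense_usage Overall fraction of codons drawn as each
#'   context-dependent ("ambiguous") sense codon (default 0.1%).
#' @param utr_zero_prob,utr_nb_size,utr_nb_mu Zero-inflated negative
#'   binomial 3' UTR lengths (defaults give median 22 nt).
#' @param tail_min,tail_mean Poly(A) tail lengths: `tail_min` plus a
#'   Poisson excess with the given mean above the minimum.
#' @param leader_max Maximum 5' leader length (uniform 0..leader_max; the
#'   reading frame is `leader %% 3`).
#' @param utr_at A+T fraction of UTR/leader background composition.
#' @param stop_probs Stop-codon identity probabilities (restricted to the
#'   code's stop set and renormalised).
#' @param utr_stop_prob Per-UTR-codon probability of an in-frame stop-set
#'   codon (mean inter-stop spacing of about five codons, together with
#'   the AU-rich background).
#' @param depletion_factor Multiplier on ambiguous-codon sense usage
#'   within `depletion_window` (1 = no depletion).
#' @param depletion_window Codon-bin range `c(lo, hi)`, lo <= d < hi,
#'   where the suppression applies.
#' @param evalue_fail_prob Fraction of alignment records drawn with a
#'   conditional e-value above the 1e-10 threshold (exercises the filter).
#' @param rpf Footprint settings; see Details.
#'
#' @details The `rpf` list understands: `stop_depth` (mean stop-situated
#' footprints per transcript), `elong_depth` (mean elongating footprints),
#' `length_probs` (named over 25..32 nt), `frame3_prob` (elongating 3'
#' ends on codon position 3), `term_prob` (terminating ends exactly 11/12
#' nt past the stop 3' nt; the remainder fall slightly short, 8-10 nt),
#' `readthrough` (a single per-transcript rate, or
#' `list(zero_prob=, mean=)` for a zero-inflated exponential), and
#' `error_rate` (per-base sequencing error).
#' @return A `sim_config` list.
#' @export
simConfig <- function(seed = 1L,
                      code = ciliateGeneticCode("ambiguous"),
                      n_transcripts = 2000L,
                      n_families = NULL,
                      family_length = 160L,
                      conservation_shape = c(5, 1),
                      substitution_rate = 0.05,
                      sense_usage = 0.001,
                      utr_zero_prob = 0.1,
                      utr_nb_size = 12,
                      utr_nb_mu = 24,
                      tail_min = 8L,
                      tail_mean = 30,
                      leader_max = 8L,
                      utr_at = 0.7,
                      stop_probs = c(TAA = 0.7, TAG = 0.15, TGA = 0.15),
                      utr_stop_prob = 0.2,
                      depletion_factor = 0.3,
                      depletion_window = c(-90, -42),
                      evalue_fail_prob = 0.1,
                      rpf = list()) {
  rpf_def <- list(
    stop_depth = 40, elong_depth = 20,
    length_probs = c(`25` = 0.03, `26` = 0.05, `27` = 0.08, `28` = 0.10,
                     `29` = 0.12, `30` = 0.35, `31` = 0.15, `32` = 0.12),
    frame3_prob = 0.8, term_prob = 0.9,
    term_offsets = c(11L, 12L), jitter_offsets = 8:10,
    readthrough = list(zero_prob = 0.9, mean = 0.15),
    error_rate = 0.001
  )
  rpf <- utils::modifyList(rpf_def, rpf)
  if (is.null(n_families)) n_families <- n_transcripts
  cfg <- list(
    seed = as.integer(seed), code = code,
    n_transcripts = as.integer(n_transcripts),
    n_families = as.integer(n_families),
    family_length = as.integer(family_length),
    conservation_shape = conservation_shape,
    substitution_rate = substitution_rate,
    sense_usage = sense_usage,
    utr_zero_prob = utr_zero_prob, utr_nb_size = utr_nb_size,
    utr_nb_mu = utr_nb_mu,
    tail_min = as.integer(tail_min), tail_mean = tail_mean,
    leader_max = as.integer(leader_max), utr_at = utr_at,
    stop_probs = stop_probs, utr_stop_prob = utr_stop_prob,
    depletion_factor = depletion_factor,
    depletion_window = depletion_window,
    evalue_fail_prob = evalue_fail_prob,
    rpf = rpf
  )
  probs <- c(substitution_rate, sense_usage, utr_zero_prob, utr_at,
             utr_stop_prob, depletion_factor, evalue_fail_prob,
             rpf$frame3_prob, rpf$term_prob, rpf$error_rate)
  if (any(probs < 0 | probs > 1))
    stop("all proportions must lie in [0, 1]", call. = FALSE)
  if (-depletion_window[1] > 3 * family_length)
    stop("depletion window extends beyond the coding sequence",
         call. = FALSE)
  if (depletion_window[1] >= depletion_window[2])
    stop("depletion window must be an increasing range", call. = FALSE)
  if (!length(intersect(names(stop_probs), stopSet(code))))
    stop("stop_probs covers no codon of the code's stop set", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

.randTriplets <- function(n, at) {
  p <- c(A = at / 2, T = at / 2, C = (1 - at) / 2, G = (1 - at) / 2)
  m <- matrix(sample(names(p), 3L * n, TRUE, prob = p), ncol = 3L)
  paste0(m[, 1L], m[, 2L], m[, 3L])
}

.randBases <- function(n, at) {
  p <- c(A = at / 2, T = at / 2, C = (1 - at) / 2, G = (1 - at) / 2)
  sample(names(p), n, TRUE, prob = p)
}

.stopDraw <- function(n, cfg) {
  ss <- intersect(names(cfg$stop_probs), stopSet(cfg$code))
  pr <- cfg$stop_probs[ss] / sum(cfg$stop_probs[ss])
  sample(ss, n, TRUE, prob = pr)
}

#' Simulate a poly(A)-tailed transcriptome with ground truth
#'
#' Coding sequences are drawn from family consensus proteins with rare
#' amino-acid substitutions; ambiguous ("stop") sense codons are inserted
#' at the configured overall usage but suppressed by `depletion_factor`
#' within the proximal depletion window; 3' UTRs are AU-rich and very
#' short (zero-length allowed) with in-frame downstream stop-set codons at
#' the configured spacing; poly(A) tails are appended. Because terminal
#' genomic adenosines are indistinguishable from the untemplated tail, the
#' ground-truth poly(A) site is canonicalised to the start of the maximal
#' terminal A run (tail length extended accordingly).
#'
#' @param cfg A [simConfig()] object.
#' @return list: `transcripts` (annotated `DNAStringSet`, see
#'   [transcriptSet()]), `truth` (per-transcript data.frame: family,
#'   frame, cds_start/cds_end incl. stop, stop_start/stop_codon,
#'   utr_drawn/utr_length (canonical), polya_site, tail_length,
#'   downstream_stop1), `families` (consensus and conservation matrices),
#'   `codons`/`aa` (per-transcript true codon and amino-acid matrices),
#'   `cfg`.
#' @export
simulateTranscriptome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_transcripts; L <- cfg$family_length
  map <- codonAssignments(cfg$code)
  amb <- ambiguousCodons(cfg$code)

  consensus <- matrix(sample(AMINO_ACIDS, cfg$n_families * L, TRUE),
                      cfg$n_families, L)
  conservation <- matrix(
    stats::rbeta(cfg$n_families * L, cfg$conservation_shape[1],
                 cfg$conservation_shape[2]),
    cfg$n_families, L)

  fam <- sample.int(cfg$n_families, n, TRUE)
  aa <- consensus[fam, , drop = FALSE]
  sub <- matrix(stats::runif(n * L) < cfg$substitution_rate, n, L)
  if (any(sub))
    aa[sub] <- vapply(aa[sub], function(a)
      sample(setdiff(AMINO_ACIDS, a), 1L), character(1))

  leader_len <- sample.int(cfg$leader_max + 1L, n, TRUE) - 1L
  frame <- leader_len %% 3L
  utr_drawn <- ifelse(stats::runif(n) < cfg$utr_zero_prob, 0L,
                      stats::rnbinom(n, size = cfg$utr_nb_size,
                                     mu = cfg$utr_nb_mu))
  tail_len <- cfg$tail_min + stats::rpois(n, cfg$tail_mean - cfg$tail_min)

  ## codon-bin offset d of coding codon k, given the planned UTR length:
  ## d_k = -3 * (L + 2 - k + ceiling(utr/3))
  kmat <- matrix(rep(seq_len(L), each = n), n, L)
  dmat <- -3L * (L + 2L - kmat + ceiling(utr_drawn / 3))
  suppressed <- dmat >= cfg$depletion_window[1] &
    dmat < cfg$depletion_window[2]

  codons <- matrix(NA_character_, n, L)
  p_amb <- cfg$sense_usage * 20
  for (a in unique(as.vector(aa))) {
    syn <- names(map)[map == a]
    a_amb <- intersect(syn, amb)
    a_std <- setdiff(syn, a_amb)
    for (sup in c(FALSE, TRUE)) {
      i <- which(aa == a & suppressed == sup)
      if (!length(i)) next
      if (length(a_amb)) {
        pa <- p_amb * if (sup) cfg$depletion_factor else 1
        pr <- c(rep(pa, length(a_amb)),
                rep((1 - pa * length(a_amb)) / length(a_std),
                    length(a_std)))
        codons[i] <- sample(c(a_amb, a_std), length(i), TRUE, prob = pr)
      } else {
        codons[i] <- sample(a_std, length(i), TRUE)
      }
    }
  }

  stop_codon <- .stopDraw(n, cfg)

  ## UTR built as in-frame codons (stop-set with prob utr_stop_prob, else
  ## AU-rich background), then cut to the drawn length; the cut bases are
  ## replaced by tail adenosines under the 0/1/2 borrowing convention.
  n_ucod <- ceiling(utr_drawn / 3)
  tot_ucod <- sum(n_ucod)
  ucod <- character(tot_ucod)
  is_stop <- stats::runif(tot_ucod) < cfg$utr_stop_prob
  ucod[is_stop] <- .stopDraw(sum(is_stop), cfg)
  ucod[!is_stop] <- .randTriplets(sum(!is_stop), cfg$utr_at)
  u_tx <- rep.int(seq_len(n), n_ucod)
  utr_full <- character(n)
  utr_full[] <- ""
  if (tot_ucod) {
    parts <- vapply(split(ucod, u_tx), paste, character(1), collapse = "")
    utr_full[as.integer(names(parts))] <- parts
  }
  utr_str <- substr(utr_full, 1L, utr_drawn)

  ## first downstream in-frame stop-set codon (within the kept UTR span)
  ds1 <- rep(NA_integer_, n)
  if (tot_ucod) {
    stop_pos_in_utr <- tapply(seq_len(tot_ucod), u_tx, function(j) {
      w <- which(is_stop[j])
      if (length(w)) w[1L] else NA_integer_
    })
    tx_with <- as.integer(names(stop_pos_in_utr))
    ds1[tx_with] <- as.integer(stop_pos_in_utr)
  }

  leader_str <- vapply(seq_len(n), function(i)
    paste(.randBases(leader_len[i], cfg$utr_at), collapse = ""),
    character(1))
  cds_str <- apply(codons, 1L, paste, collapse = "")
  body <- paste0(leader_str, cds_str, stop_codon, utr_str)

  cds_start <- leader_len + 1L
  cds_end <- leader_len + 3L * (L + 1L)          # includes the stop codon
  stop_start <- leader_len + 3L * L + 1L
  ds1_start <- ifelse(is.na(ds1) | (3L * ds1 > utr_drawn + 2L),
                      NA_integer_, cds_end + 3L * (ds1 - 1L) + 1L)

  ## canonicalise the poly(A) site over terminal templated adenosines
  k_a <- nchar(body) - nchar(sub("A*$", "", body))
  polya_site <- nchar(body) - k_a + 1L
  tail_total <- tail_len + k_a
  utr_len <- pmax(0L, polya_site - stop_start - 3L)

  seqs <- paste0(body, strrep("A", tail_len))
  ids <- sprintf("tx%05d", seq_len(n))
  transcripts <- transcriptSet(
    stats::setNames(seqs, ids),
    frame = frame, cds_start = cds_start, cds_end = cds_end,
    polya_site = polya_site
  )
  truth <- data.frame(
    transcript_id = ids, family = fam, frame = frame,
    cds_start = cds_start, cds_end = cds_end,
    stop_start = stop_start, stop_codon = stop_codon,
    utr_drawn = utr_drawn, utr_length = as.integer(utr_len),
    polya_site = as.integer(polya_site),
    tail_length = as.integer(tail_total),
    downstream_stop1 = as.integer(ds1_start),
    length = nchar(seqs),
    stringsAsFactors = FALSE
  )
  list(transcripts = transcripts, truth = truth,
       families = list(consensus = consensus, conservation = conservation),
       codons = codons, aa = aa, fam = fam, cfg = cfg)
}

#' Simulate a profile-alignment record stream from a simulated cohort
#'
#' One record per family column per transcript: the consensus amino acid
#' is the family consensus (substituted residues therefore contribute
#' off-consensus codon/amino-acid pairs, the noise the real method sees),
#' the matched codon is the true coding codon, conservation is the
#' family's per-column value, and conditional e-values are drawn with the
#' configured fraction above the filtering threshold.
#'
#' @param sim A [simulateTranscriptome()] result.
#' @return data.frame of profile-alignment records (see
#'   [readAlignmentRecords()]).
#' @export
simulateAlignmentRecords <- function(sim) {
  cfg <- sim$cfg
  set.seed(cfg$seed + 51001L)
  n <- cfg$n_transcripts; L <- cfg$family_length
  tx <- rep(sim$truth$transcript_id, each = L)
  col <- rep(seq_len(L), times = n)
  fam <- rep(sim$fam, each = L)
  idx <- cbind(fam, col)
  N <- n * L
  fail <- stats::runif(N) < cfg$evalue_fail_prob
  ev <- ifelse(fail, 10^stats::runif(N, -10, -4),
               10^stats::runif(N, -40, -11))
  data.frame(
    profile_id = sprintf("fam%03d", fam),
    transcript_id = tx,
    frame = paste0("+", rep(sim$truth$frame, each = L) + 1L),
    column_index = col,
    consensus_aa = sim$families$consensus[idx],
    column_conservation = sim$families$conservation[idx],
    matched_codon = as.vector(t(sim$codons)),
    conditional_evalue = ev,
    stringsAsFactors = FALSE
  )
}

.drawReadthroughRates <- function(rt, n) {
  if (is.numeric(rt) && length(rt) == 1L) return(rep(rt, n))
  r <- ifelse(stats::runif(n) < rt$zero_prob, 0,
              pmin(1, stats::rexp(n, rate = 1 / rt$mean)))
  r
}

#' Simulate ribosome-protected fragments for a simulated cohort
#'
#' Elongating footprints tile the coding sequence with a 3'-end frame
#' bias; terminating footprints place their 3' ends 11/12 nt past the
#' primary stop's 3' nt (with a configurable fraction falling slightly
#' short); readthrough footprints (drawn per stop-situated read at the
#' transcript's true rate) extend at least 13 nt beyond the primary stop
#' and terminate at the first downstream stop-set codon when one exists.
#' Sequencing errors are applied at the configured rate (at most 2 per
#' read).
#'
#' @param sim A [simulateTranscriptome()] result.
#' @param sam Optional path: write the footprints as SAM against the
#'   simulated transcripts.
#' @return `GRanges` of footprints with `read_id`, `mismatches`, `class`
#'   (terminating/elongating/readthrough) and `seq` metadata; the true
#'   per-transcript readthrough rates are in the `true_rates` attribute.
#' @export
simulateRPFs <- function(sim, sam = NULL) {
  cfg <- sim$cfg; r <- cfg$rpf
  set.seed(cfg$seed + 52002L)
  tr <- sim$truth
  n <- nrow(tr)
  rates <- .drawReadthroughRates(r$readthrough, n)

  n_stop <- stats::rpois(n, r$stop_depth)
  tx1 <- rep.int(seq_len(n), n_stop)
  is_rt <- stats::runif(length(tx1)) < rates[tx1]
  stop3 <- tr$stop_start + 2L
  end1 <- integer(length(tx1))
  ## terminating reads
  it <- which(!is_rt)
  precise <- stats::runif(length(it)) < r$term_prob
  off <- integer(length(it))
  off[precise] <- sample(r$term_offsets, sum(precise), TRUE)
  off[!precise] <- sample(r$jitter_offsets, sum(!precise), TRUE)
  end1[it] <- stop3[tx1[it]] + off
  ## readthrough reads: terminate at the first downstream stop when present
  ir <- which(is_rt)
  if (length(ir)) {
    ds <- tr$downstream_stop1[tx1[ir]]
    has_ds <- !is.na(ds)
    e <- integer(length(ir))
    e[has_ds] <- ds[has_ds] + 2L + sample(r$term_offsets, sum(has_ds), TRUE)
    e[!has_ds] <- stop3[tx1[ir][!has_ds]] + sample(13:21, sum(!has_ds), TRUE)
    e <- pmax(e, stop3[tx1[ir]] + 13L)
    end1[ir] <- pmin(e, tr$length[tx1[ir]])
  }
  class1 <- ifelse(is_rt, "readthrough", "terminating")

  n_el <- stats::rpois(n, r$elong_depth)
  tx2 <- rep.int(seq_len(n), n_el)
  L <- cfg$family_length
  k <- sample.int(L - 12L, length(tx2), TRUE) + 12L  # leave room upstream
  e2 <- tr$cds_start[tx2] - 1L + 3L * k
  inf3 <- stats::runif(length(tx2)) < r$frame3_prob
  shift <- integer(length(tx2))
  shift[!inf3] <- sample(c(-1L, 1L), sum(!inf3), TRUE)
  end2 <- e2 + shift

  tx_all <- c(tx1, tx2)
  end_all <- c(end1, end2)
  class_all <- c(class1, rep("elongating", length(tx2)))
  len <- sample(as.integer(names(r$length_probs)), length(tx_all), TRUE,
                prob = r$length_probs)
  start_all <- pmax(1L, end_all - len + 1L)

  ord <- order(tx_all, start_all, end_all)
  tx_all <- tx_all[ord]; end_all <- end_all[ord]
  start_all <- start_all[ord]; class_all <- class_all[ord]

  seqs <- substring(as.character(sim$transcripts)[tx_all],
                    start_all, end_all)
  n_err <- pmin(2L, stats::rbinom(length(seqs), nchar(seqs), r$error_rate))
  for (i in which(n_err > 0L)) {
    b <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    pos <- sample.int(length(b), n_err[i])
    for (p in pos) b[p] <- sample(setdiff(.NUC, b[p]), 1L)
    seqs[i] <- paste(b, collapse = "")
  }

  gr <- GenomicRanges::GRanges(
    seqnames = factor(tr$transcript_id[tx_all],
                      levels = tr$transcript_id),
    ranges = IRanges::IRanges(start = start_all, end = end_all),
    read_id = sprintf("read%07d", seq_along(tx_all)),
    mismatches = n_err,
    class = class_all,
    seq = seqs
  )
  GenomeInfoDb::seqlengths(gr) <- stats::setNames(tr$length,
                                                  tr$transcript_id)
  attr(gr, "true_rates") <- rates
  if (!is.null(sam)) writeSamFile(gr, sim$transcripts, sam)
  gr
}

#' Write footprints as a SAM file against reference transcripts
#'
#' @param rpfs Footprint `GRanges` with `read_id`, `mismatches` and `seq`
#'   metadata.
#' @param transcripts Reference `DNAStringSet` (for header lengths).
#' @param path Output SAM path.
#' @export
writeSamFile <- function(rpfs, transcripts, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", names(transcripts),
                  "\tLN:", Biostrings::width(transcripts)))
  w <- GenomicRanges::width(rpfs)
  rec <- paste(rpfs$read_id, 0L,
               as.character(GenomicRanges::seqnames(rpfs)),
               GenomicRanges::start(rpfs), 255L, paste0(w, "M"),
               "*", 0L, 0L, rpfs$seq, strrep("I", w),
               paste0("NM:i:", rpfs$mismatches), sep = "\t")
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Write simulated ground truth as JSON
#' @param sim A [simulateTranscriptome()] result.
#' @param path Output path.
#' @export
writeGroundTruth <- function(sim, path) {
  jsonlite::write_json(
    list(code = codeName(sim$cfg$code),
         seed = sim$cfg$seed,
         transcripts = sim$truth),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
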