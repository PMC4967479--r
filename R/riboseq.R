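#' Read mapped ribosome-protected fragments (SAM/BAM)
#'
#' Loads primary alignments into transcript-space `GRanges` (seqnames =
#' transcript id, 1-based closed ranges) with metadata columns `read_id`
#' and `mismatches`. Mismatch counts come from the standard edit-distance
#' (NM) tag when present, else are recomputed against the reference
#' transcripts. Unmapped and secondary/supplementary records are dropped
#' and counted in the `rejects` attribute.
#'
#' @param path SAM or BAM file (SAM is converted on the fly).
#' @param transcripts Optional reference `DNAStringSet` for mismatch
#'   recomputation when no NM tag is present.
#' @return `GRanges` of footprints with a `rejects` attribute.
#' @export
readRPFs <- function(path, transcripts = NULL) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                             indexDestination = TRUE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "qwidth", "seq"),
    tag = "NM"
  )
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  n_in <- length(b$flag)
  unmapped <- bitwAnd(b$flag, 4L) != 0L
  secondary <- bitwAnd(b$flag, 256L) != 0L | bitwAnd(b$flag, 2048L) != 0L
  keep <- !unmapped & !secondary
  nm <- b$tag$NM
  if (is.null(nm)) nm <- rep(NA_integer_, n_in)
  nm <- nm[keep]
  rng <- GenomicRanges::GRanges(
    seqnames = droplevels(b$rname[keep]),
    ranges = IRanges::IRanges(start = b$pos[keep],
                              width = b$qwidth[keep]),
    read_id = b$qname[keep]
  )
  if (anyNA(nm)) {
    if (is.null(transcripts))
      stop("alignments lack NM tags; supply reference transcripts to ",
           "recompute mismatch counts", call. = FALSE)
    i <- which(is.na(nm))
    refs <- as.character(transcripts[as.character(
      GenomicRanges::seqnames(rng)[i])])
    ref_piece <- substr(refs, GenomicRanges::start(rng)[i],
                        GenomicRanges::end(rng)[i])
    reads <- as.character(b$seq[keep][i])
    nm[i] <- mapply(function(a, b2) {
      sum(strsplit(a, "")[[1]] != strsplit(b2, "")[[1]])
    }, ref_piece, reads)
  }
  rng$mismatches <- as.integer(nm)
  attr(rng, "rejects") <- c(unmapped = sum(unmapped),
                            secondary = sum(secondary))
  rng
}

#' Filter footprints on length and mismatches
#'
#' Retains footprints whose length lies in `[len_min, len_max]` and whose
#' mismatch count is at most `max_mismatch`; rejects are counted by reason.
#'
#' @param rpfs `GRanges` of footprints (from [readRPFs()] or the
#'   simulator).
#' @param len_min,len_max Length bounds, nt (defaults 25 and 32).
#' @param max_mismatch Maximum mismatches (default 1).
#' @return Filtered `GRanges` with a `rejects` attribute.
#' @export
filterRPFs <- function(rpfs, len_min = 25, len_max = 32, max_mismatch = 1) {
  w <- GenomicRanges::width(rpfs)
  mm <- rpfs$mismatches
  bad_len <- w < len_min | w > len_max
  bad_mm <- !bad_len & mm > max_mismatch
  out <- rpfs[!bad_len & !bad_mm]
  attr(out, "rejects") <- c(length = sum(bad_len), mismatch = sum(bad_mm))
  out
}

.frameOf <- function(pos, frame) ((pos - 1L - frame) %% 3L) + 1L

#' Per-length footprint frame distributions
#'
#' For each footprint length, the fraction of 5' starts and 3' ends at
#' codon positions 1-3 of the transcript's reading frame.
#'
#' @param rpfs Footprint `GRanges`.
#' @param transcripts Annotated `DNAStringSet` (needs `frame` in `mcols`).
#' @return data.frame: length, n, start_frame1..3, end_frame1..3.
#' @export
frameDistribution <- function(rpfs, transcripts) {
  fr <- mcols(transcripts)$frame[
    match(as.character(GenomicRanges::seqnames(rpfs)), names(transcripts))]
  if (anyNA(fr))
    stop("reading frame unknown for some mapped transcripts", call. = FALSE)
  w <- GenomicRanges::width(rpfs)
  f5 <- .frameOf(GenomicRanges::start(rpfs), fr)
  f3 <- .frameOf(GenomicRanges::end(rpfs), fr)
  res <- lapply(sort(unique(w)), function(len) {
    i <- w == len
    data.frame(
      length = len, n = sum(i),
      start_frame1 = mean(f5[i] == 1L), start_frame2 = mean(f5[i] == 2L),
      start_frame3 = mean(f5[i] == 3L),
      end_frame1 = mean(f3[i] == 1L), end_frame2 = mean(f3[i] == 2L),
      end_frame3 = mean(f3[i] == 3L)
    )
  })
  do.call(rbind, res)
}

#' Footprint 3'-end metaprofile around anchor codons
#'
#' Counts footprint 3' ends at each offset relative to the anchor codon,
#' pooled over anchors, with the anchor codon occupying offsets 1-3 (so a
#' terminating end 11 nt past a stop's 3' nt sits at offset 14). Anchors
#' outside the transcript bounds are skipped and counted.
#'
#' @param rpfs Footprint `GRanges`.
#' @param anchors data.frame with `transcript_id`, `anchor_start` (1-based
#'   first base of the anchor codon) and optionally `class`.
#' @param transcripts The reference `DNAStringSet` (for bounds checking).
#' @param flank Profile half-width, nt (default 30; offsets span
#'   `1 - flank` to `3 + flank`).
#' @param rpf_length A single length to restrict to, `NULL` to pool all
#'   lengths into one column, or `"all"` for per-length columns.
#' @param anchor_class Label stored on the profile.
#' @return A [MetaProfile-class].
#' @export
endMetaprofile <- function(rpfs, anchors, transcripts, flank = 30,
                           rpf_length = NULL, anchor_class = "all") {
  offs <- seq(1L - flank, 3L + flank)
  lens_in <- GenomicRanges::width(rpfs)
  if (!is.null(rpf_length) && !identical(rpf_length, "all")) {
    rpfs <- rpfs[lens_in == rpf_length]
    lens_in <- GenomicRanges::width(rpfs)
  }
  tlen <- stats::setNames(Biostrings::width(transcripts), names(transcripts))
  in_bounds <- anchors$anchor_start >= 1L &
    anchors$anchor_start + 2L <= tlen[anchors$transcript_id]
  skipped <- sum(!in_bounds)
  anchors <- anchors[in_bounds, , drop = FALSE]
  by_len <- identical(rpf_length, "all")
  len_lev <- if (by_len) sort(unique(lens_in)) else "all"
  counts <- matrix(0L, length(offs), length(len_lev),
                   dimnames = list(as.character(offs),
                                   as.character(len_lev)))
  ends <- GenomicRanges::end(rpfs)
  tx <- as.character(GenomicRanges::seqnames(rpfs))
  ends_by_tx <- split(seq_along(rpfs), tx)
  for (k in seq_len(nrow(anchors))) {
    j <- ends_by_tx[[anchors$transcript_id[k]]]
    if (is.null(j)) next
    o <- ends[j] - anchors$anchor_start[k] + 1L
    sel <- o >= offs[1L] & o <= offs[length(offs)]
    if (!any(sel)) next
    if (by_len) {
      t2 <- table(factor(o[sel], levels = offs),
                  factor(lens_in[j][sel], levels = len_lev))
      counts <- counts + matrix(as.integer(t2), nrow(counts), ncol(counts))
    } else {
      t1 <- table(factor(o[sel], levels = offs))
      counts[, 1L] <- counts[, 1L] + as.integer(t1)
    }
  }
  prof <- new("MetaProfile", offsets = as.integer(offs), counts = counts,
              anchorClass = anchor_class)
  attr(prof, "skipped_anchors") <- skipped
  prof
}

setMethod("show", "MetaProfile", function(object) {
  cat("MetaProfile (", object@anchorClass, " anchors): ",
      sum(object@counts), " footprint 3' ends over offsets ",
      object@offsets[1L], "..", object@offsets[length(object@offsets)],
      "\n", sep = "")
})

#' Classify the termination signature of a stop-anchored metaprofile
#'
#' Reports the two modal 3'-end offsets downstream of the stop codon's 3'
#' nt and the fraction of all profile ends falling on them; flags a
#' termination signature when that fraction exceeds `threshold`.
#' Terminating footprints characteristically end 11-12 nt past the stop's
#' last base.
#'
#' @param profile A stop-anchored [MetaProfile-class].
#' @param threshold Signature flag threshold on the modal fraction
#'   (default 0.5).
#' @return list: `modal_offsets` (relative to the stop 3' nt, decreasing
#'   count order), `modal_fraction`, `signature` flag, `n_ends`.
#' @export
classifyTermination <- function(profile, threshold = 0.5) {
  pooled <- rowSums(profile@counts)
  if (sum(pooled) == 0L) stop("empty metaprofile", call. = FALSE)
  down <- profile@offsets > 3L
  dn_counts <- pooled[down]
  dn_offsets <- profile@offsets[down] - 3L  # relative to stop 3' nt
  ord <- order(dn_counts, decreasing = TRUE)
  top <- ord[seq_len(min(2L, sum(dn_counts > 0)))]
  frac <- sum(dn_counts[top]) / sum(pooled)
  list(
    modal_offsets = dn_offsets[top],
    modal_fraction = frac,
    signature = frac > threshold,
    n_ends = sum(pooled)
  )
}

#' Per-transcript stop-codon readthrough estimation
#'
#' For each transcript with a primary-stop call, counts terminating
#' footprints (3' end exactly `term_offsets` nt past the stop's 3' nt) and
#' downstream-extending footprints (3' end at least `min_downstream` nt
#' past it). The default per-transcript rate is
#' downstream / (downstream + terminating), the stop-anchored denominator;
#' `method = "density"` instead contrasts per-nt end densities over
#' equal-width windows downstream (starting at `min_downstream`) and
#' upstream of the stop. Cohort summaries are over covered transcripts
#' (terminating + downstream counts strictly above `coverage_min`).
#'
#' @param rpfs Footprint `GRanges`.
#' @param stops [findPrimaryStop()] output (`transcript_id`, `stop_start`).
#' @param min_downstream Minimum extension past the stop 3' nt to count as
#'   readthrough, nt (default 13).
#' @param coverage_min Coverage filter: a transcript is covered when
#'   terminating + downstream footprints exceed this (default 20).
#' @param term_offsets Offsets past the stop 3' nt taken as the
#'   termination signature (default 11 and 12).
#' @param method `"stop_anchored"` (default) or `"density"`.
#' @param density_window Window width for the density method, nt.
#' @return list: `per_transcript` data.frame (transcript_id, n_stop,
#'   n_downstream, rate, covered) and `summary` (n_covered, mean_rate,
#'   median_rate, fraction_zero — covered transcripts only).
#' @export
estimateReadthrough <- function(rpfs, stops, min_downstream = 13,
                                coverage_min = 20,
                                term_offsets = c(11L, 12L),
                                method = c("stop_anchored", "density"),
                                density_window = 30) {
  method <- match.arg(method)
  ends <- GenomicRanges::end(rpfs)
  tx <- as.character(GenomicRanges::seqnames(rpfs))
  idx_by_tx <- split(ends, tx)
  res <- lapply(seq_len(nrow(stops)), function(k) {
    e <- idx_by_tx[[stops$transcript_id[k]]]
    stop3 <- stops$stop_start[k] + 2L
    if (is.null(e)) e <- integer()
    off <- e - stop3
    n_stop <- sum(off %in% term_offsets)
    n_down <- sum(off >= min_downstream)
    rate <- if (method == "stop_anchored") {
      if (n_stop + n_down > 0) n_down / (n_down + n_stop) else NA_real_
    } else {
      dn <- sum(off >= min_downstream & off < min_downstream + density_window)
      up <- sum(off <= 0L & off > -density_window)
      if (dn + up > 0) dn / (dn + up) else NA_real_
    }
    data.frame(transcript_id = stops$transcript_id[k],
               n_stop = n_stop, n_downstream = n_down, rate = rate,
               covered = (n_stop + n_down) > coverage_min,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, res)
  cov <- per[per$covered & !is.na(per$rate), , drop = FALSE]
  list(
    per_transcript = per,
    summary = list(
      n_covered = nrow(cov),
      mean_rate = if (nrow(cov)) mean(cov$rate) else NA_real_,
      median_rate = if (nrow(cov)) stats::median(cov$rate) else NA_real_,
      fraction_zero = if (nrow(cov)) mean(cov$rate == 0) else NA_real_,
      method = method
    )
  )
}

#' Per-base footprint coverage of one transcript
#'
#' Coverage at position p is the number of retained footprints overlapping
#' p (all bases of each footprint contribute).
#'
#' @param rpfs Footprint `GRanges`.
#' @param transcript_id Transcript to profile.
#' @param transcript_length Length of the transcript, nt.
#' @return Integer vector of length `transcript_length`.
#' @export
coverageTrack <- function(rpfs, transcript_id, transcript_length) {
  r <- rpfs[as.character(GenomicRanges::seqnames(rpfs)) == transcript_id]
  delta <- integer(transcript_length + 1L)
  s <- pmax(GenomicRanges::start(r), 1L)
  e <- pmin(GenomicRanges::end(r), transcript_length)
  ok <- s <= e
  for (i in which(ok)) {
    delta[s[i]] <- delta[s[i]] + 1L
    delta[e[i] + 1L] <- delta[e[i] + 1L] - 1L
  }
  cumsum(delta)[seq_len(transcript_length)]
}
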