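#' Detect a terminal poly(A) tail
#'
#' Finds the longest terminal adenosine run, tolerating at most
#' `max_mismatch` non-A bases inside it; any non-A prefix is trimmed so the
#' reported tail starts on an A. A call is made only when the trimmed run
#' reaches `min_tail` nucleotides.
#'
#' @param seqs DNAStringSet or character vector of transcript (or read)
#'   sequences.
#' @param min_tail Minimum tail length (default 8, must be >= 5).
#' @param max_mismatch Non-A bases tolerated inside the run (default 1).
#' @return data.frame with one row per input: `transcript_id`,
#'   `polya_site` (1-based first tail A, NA when no tail), `tail_length`,
#'   `supporting_reads` (0: sequence-derived call).
#' @examples
#' detectPolyA(c(x = paste0("CCGCT", strrep("A", 8))))
#' @export
detectPolyA <- function(seqs, min_tail = 8, max_mismatch = 1) {
  stopifnot(min_tail >= 5, max_mismatch >= 0)
  ids <- names(seqs)
  seqs <- toupper(as.character(seqs))
  if (is.null(ids)) ids <- as.character(seq_along(seqs))
  site <- rep(NA_integer_, length(seqs))
  tlen <- rep(NA_integer_, length(seqs))
  for (i in seq_along(seqs)) {
    b <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    n <- length(b)
    mm <- 0L
    start <- n + 1L
    for (p in rev(seq_len(n))) {
      if (b[p] != "A") {
        mm <- mm + 1L
        if (mm > max_mismatch) break
      }
      start <- p
    }
    while (start <= n && b[start] != "A") start <- start + 1L
    if (start <= n && n - start + 1L >= min_tail) {
      site[i] <- start
      tlen[i] <- n - start + 1L
    }
  }
  data.frame(transcript_id = ids, polya_site = site, tail_length = tlen,
             supporting_reads = 0L, stringsAsFactors = FALSE)
}

## Tail borrowing: number of tail A's (0/1/2) needed to complete the final
## codon of the reading-frame grid at the poly(A) junction.
.tailBorrow <- function(polya_site, frame) {
  upstream <- polya_site - 1L - frame   # nt from grid origin to last non-tail base
  (3L - upstream %% 3L) %% 3L
}

#' Call the primary stop codon in the terminal window
#'
#' The primary stop is the most 5' in-frame stop-set codon whose first base
#' lies within `window` nt upstream of the poly(A) site. Following the
#' transcript-end convention, the final in-frame "codon" may borrow 0, 1 or
#' 2 tail adenosines to complete its triplet, so a stop codon abutting (or
#' sharing adenosines with) the tail is callable. Transcripts whose window
#' contains no stop-set codon yield no call (explicitly absent, not an
#' error); a stop immediately followed by the tail gives `utr_length` 0.
#'
#' @param transcripts Annotated `DNAStringSet` (needs `frame` in `mcols`).
#' @param polya data.frame from [detectPolyA()] (or ground truth) with
#'   `transcript_id` and `polya_site`.
#' @param stop_set Codons that can act as stops (default the standard three;
#'   use `stopSet(code)` for variant/ambiguous codes).
#' @param window Search window upstream of the poly(A) site, nt (default 60).
#' @return data.frame with one row per called transcript: `transcript_id`,
#'   `stop_codon`, `stop_start` (1-based first base), `utr_length`
#'   (excludes the stop codon and the tail), `n_downstream_stops` and
#'   `downstream_stops` (comma-separated 1-based starts of later in-frame
#'   stop-set codons before the tail).
#' @export
findPrimaryStop <- function(transcripts, polya,
                            stop_set = c("TAA", "TAG", "TGA"),
                            window = 60) {
  stopifnot(length(stop_set) > 0)
  frames <- mcols(transcripts)$frame
  if (any(is.na(frames[names(transcripts) %in% polya$transcript_id])))
    stop("reading frame unknown for some transcripts; supply frame ",
         "annotation (e.g. from the profile-alignment stage)", call. = FALSE)
  idx <- match(polya$transcript_id, names(transcripts))
  res <- vector("list", nrow(polya))
  for (k in seq_len(nrow(polya))) {
    i <- idx[k]
    if (is.na(i) || is.na(polya$polya_site[k])) next
    s <- as.character(transcripts[[i]])
    frame <- frames[i]
    ps <- polya$polya_site[k]
    b <- min(.tailBorrow(ps, frame), polya$tail_length[k] %||% 2L)
    if (b != .tailBorrow(ps, frame)) next  # tail too short to complete frame
    E <- ps - 1L + b                       # effective in-frame end
    aug <- paste0(substr(s, 1L, ps - 1L), strrep("A", b))
    p_first <- frame + 1L
    starts <- seq(p_first, E - 2L, by = 3L)
    starts <- starts[starts >= ps - window & starts >= 1L]
    if (!length(starts)) next
    cods <- substring(aug, starts, starts + 2L)
    hit <- which(cods %in% stop_set)
    if (!length(hit)) next
    p_stop <- starts[hit[1L]]
    down <- starts[hit[-1L]]
    res[[k]] <- data.frame(
      transcript_id = polya$transcript_id[k],
      stop_codon = cods[hit[1L]],
      stop_start = p_stop,
      utr_length = max(0L, ps - p_stop - 3L),
      n_downstream_stops = length(down),
      downstream_stops = paste(down, collapse = ","),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(transcript_id = character(), stop_codon = character(),
                      stop_start = integer(), utr_length = integer(),
                      n_downstream_stops = integer(),
                      downstream_stops = character(),
                      stringsAsFactors = FALSE)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarise a 3' UTR length distribution
#'
#' Lengths exclude the stop codon and the poly(A) tail.
#'
#' @param calls data.frame from [findPrimaryStop()].
#' @return list with `n`, `median`, `q1`, `q3`, `fraction_zero` and a
#'   1-nt-resolution `histogram` data.frame (utr_length, count).
#' @export
utrLengthDistribution <- function(calls) {
  if (is.null(calls) || nrow(calls) == 0L)
    stop("no primary-stop calls to summarise", call. = FALSE)
  len <- calls$utr_length
  hist <- as.data.frame(table(utr_length = len), stringsAsFactors = FALSE)
  hist$utr_length <- as.integer(hist$utr_length)
  names(hist)[2] <- "count"
  list(
    n = length(len),
    median = stats::median(len),
    q1 = unname(stats::quantile(len, 0.25)),
    q3 = unname(stats::quantile(len, 0.75)),
    fraction_zero = mean(len == 0L),
    histogram = hist
  )
}

#' Positional codon counts toward the poly(A) site
#'
#' Walks in-frame codons backward from each transcript's poly(A) site.
#' Codon bins are indexed d = -3, -6, ... by the codon's first-base offset;
#' the final codon (d = -3) borrows 0, 1 or 2 tail adenosines to complete
#' its triplet, and the borrow count is recorded. Transcripts shorter than
#' the window contribute their covered bins only.
#'
#' @param transcripts Annotated `DNAStringSet` (needs `frame`).
#' @param polya data.frame with `transcript_id`, `polya_site`,
#'   `tail_length`.
#' @param window Upstream extent in nt (default 240).
#' @param region `"all"` counts every codon (terminal stacked-bar
#'   convention); `"coding"` restricts to codons strictly 5' of each
#'   transcript's primary stop (requires `stops`).
#' @param stops [findPrimaryStop()] output, required for
#'   `region = "coding"`.
#' @return A [PositionalCodonCounts-class].
#' @export
positionalCodonCounts <- function(transcripts, polya, window = 240,
                                  region = c("all", "coding"),
                                  stops = NULL) {
  region <- match.arg(region)
  if (region == "coding" && is.null(stops))
    stop("region = 'coding' needs primary-stop calls", call. = FALSE)
  frames <- mcols(transcripts)$frame
  idx <- match(polya$transcript_id, names(transcripts))
  stop_at <- if (!is.null(stops))
    stats::setNames(stops$stop_start, stops$transcript_id)
  d_all <- list(); cod_all <- list()
  borrow_used <- c(`0` = 0L, `1` = 0L, `2` = 0L)
  n_used <- 0L
  for (k in seq_len(nrow(polya))) {
    i <- idx[k]
    if (is.na(i) || is.na(polya$polya_site[k])) next
    frame <- frames[i]
    ps <- polya$polya_site[k]
    b <- .tailBorrow(ps, frame)
    if (b > (polya$tail_length[k] %||% 0L)) next
    E <- ps - 1L + b
    m_max <- min(window %/% 3L, (E - frame) %/% 3L)
    if (m_max < 1L) next
    starts <- E - 3L * seq_len(m_max) + 1L
    if (region == "coding") {
      sa <- stop_at[polya$transcript_id[k]]
      if (is.na(sa)) next
      starts <- starts[starts <= sa - 3L]
      if (!length(starts)) { n_used <- n_used + 1L; next }
    }
    s <- as.character(transcripts[[i]])
    aug <- paste0(substr(s, 1L, ps - 1L), strrep("A", b))
    cods <- substring(aug, starts, starts + 2L)
    d_all[[length(d_all) + 1L]] <- -(E - starts + 1L) - 0L  # = -3m
    cod_all[[length(cod_all) + 1L]] <- cods
    borrow_used[as.character(b)] <- borrow_used[as.character(b)] + 1L
    n_used <- n_used + 1L
  }
  d_lev <- -seq(3L, window, by = 3L)
  tab <- table(
    factor(unlist(d_all), levels = d_lev),
    factor(unlist(cod_all), levels = CODONS)
  )
  counts <- matrix(as.integer(tab), length(d_lev), 64L,
                   dimnames = list(as.character(d_lev), CODONS))
  new("PositionalCodonCounts", counts = counts,
      nTranscripts = n_used, tailCompletion = borrow_used,
      region = region)
}

setMethod("show", "PositionalCodonCounts", function(object) {
  cat("PositionalCodonCounts (", object@region, "): ",
      sum(object@counts), " codons from ", object@nTranscripts,
      " transcripts over ", nrow(object@counts), " bins (d = -3 .. ",
      rownames(object@counts)[nrow(object@counts)], ")\n", sep = "")
})

#' Write positional codon counts as TSV (d, codon, count)
#' @param counts A [PositionalCodonCounts-class].
#' @param path Output path.
#' @export
writePositionalCounts <- function(counts, path) {
  df <- as.data.frame(as.table(counts@counts), stringsAsFactors = FALSE)
  names(df) <- c("d", "codon", "count")
  df$codon <- rnaCodon(df$codon)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.dInRange <- function(d, range) d >= range[1] & d < range[2]

#' Proximal-vs-distal codon depletion test
#'
#' Compares a codon's frequency (codon count over all-codon count) between
#' a proximal window just upstream of the stop-codon region and a distal
#' coding-sequence window, via a two-sided binomial test of the proximal
#' count against the distal frequency. The default proximal window
#' \[-90, -42) sits upstream of the approximately -39 nt boundary below
#' which most "stop"-set codons are true stops or 3'-UTR codons; the
#' default distal window pools everything below -240 nt.
#'
#' @param counts A [PositionalCodonCounts-class] (use `region = "coding"`
#'   when 3' UTRs would otherwise contaminate the proximal window).
#' @param codon Codon(s) to test (DNA triplets).
#' @param proximal,distal Half-open d ranges `c(lo, hi)` meaning
#'   lo <= d < hi; disjoint.
#' @param alpha Flagging level (default 0.01).
#' @param test `"binomial"` (default) tests the proximal count against the
#'   distal frequency taken as known — simple, but mildly anticonservative
#'   because the distal rate is itself estimated; `"fisher"` is the exact
#'   two-sample contrast of the proximal/distal count table.
#' @return data.frame per codon: counts, rates, `ratio`
#'   (proximal/distal), `p_value`, and `flagged` (depletion direction and
#'   p < alpha).
#' @export
stopDepletionTest <- function(counts, codon,
                              proximal = c(-90, -42),
                              distal = c(-Inf, -240),
                              alpha = 0.01,
                              test = c("binomial", "fisher")) {
  test <- match.arg(test)
  d <- as.numeric(rownames(counts@counts))
  prox <- .dInRange(d, proximal)
  dist <- .dInRange(d, distal)
  if (!any(prox) || !any(dist))
    stop("empty proximal or distal range for these counts", call. = FALSE)
  if (any(prox & dist)) stop("ranges must be disjoint", call. = FALSE)
  prox_tot <- sum(counts@counts[prox, ])
  dist_tot <- sum(counts@counts[dist, ])
  res <- lapply(codon, function(cd) {
    pc <- sum(counts@counts[prox, cd])
    dc <- sum(counts@counts[dist, cd])
    pr <- if (prox_tot > 0) pc / prox_tot else NA_real_
    dr <- if (dist_tot > 0) dc / dist_tot else NA_real_
    ratio <- if (!is.na(dr) && dr > 0) pr / dr else NA_real_
    p <- if (!is.na(dr) && dr > 0 && prox_tot > 0) {
      if (test == "binomial")
        stats::binom.test(pc, prox_tot, p = dr)$p.value
      else
        stats::fisher.test(matrix(c(pc, prox_tot - pc, dc, dist_tot - dc),
                                  2L))$p.value
    } else NA_real_
    data.frame(codon = cd, proximal_count = pc, proximal_total = prox_tot,
               distal_count = dc, distal_total = dist_tot,
               proximal_rate = pr, distal_rate = dr, ratio = ratio,
               p_value = p,
               flagged = !is.na(p) && !is.na(ratio) && ratio < 1 && p < alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Per-position base frequencies upstream of poly(A) sites
#'
#' @param transcripts DNAStringSet.
#' @param polya data.frame with `transcript_id`, `polya_site`.
#' @param window Upstream extent in nt (default 240).
#' @param stability_region Offset range over which the flatness summary
#'   (max absolute deviation from each base's regional mean) is computed;
#'   defaults to the region where stop-codon decline is assessed.
#' @return data.frame (offset, A, C, G, T, n) with attribute
#'   `max_abs_deviation` (named per base).
#' @export
baseFrequencyProfile <- function(transcripts, polya, window = 240,
                                 stability_region = c(-90, -42)) {
  idx <- match(polya$transcript_id, names(transcripts))
  mat <- matrix(NA_character_, nrow(polya), window)
  for (k in seq_len(nrow(polya))) {
    i <- idx[k]
    if (is.na(i) || is.na(polya$polya_site[k])) next
    ps <- polya$polya_site[k]
    lo <- max(1L, ps - window)
    frag <- substr(as.character(transcripts[[i]]), lo, ps - 1L)
    b <- strsplit(frag, "", fixed = TRUE)[[1]]
    if (length(b))
      mat[k, (window - length(b) + 1L):window] <- b
  }
  offs <- seq(-window, -1L)
  freq <- t(apply(mat, 2L, function(col) {
    col <- col[!is.na(col)]
    n <- length(col)
    c(A = sum(col == "A"), C = sum(col == "C"),
      G = sum(col == "G"), T = sum(col == "T"), n = n) / max(n, 1L) *
      c(1, 1, 1, 1, max(n, 1L))
  }))
  out <- data.frame(offset = offs, freq)
  reg <- out$offset >= stability_region[1] & out$offset < stability_region[2]
  dev <- vapply(c("A", "C", "G", "T"), function(bs) {
    v <- out[[bs]][reg]
    if (!length(v)) return(NA_real_)
    max(abs(v - mean(v)))
  }, numeric(1))
  attr(out, "max_abs_deviation") <- dev
  out
}
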