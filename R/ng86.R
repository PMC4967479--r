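## Nei-Gojobori (1986) pathway counting, evaluated under an arbitrary
## genetic-code table so that reassignment-aware dN/dS is available (needed
## for genes with in-frame reassigned codons).

.NUC <- c("A", "C", "G", "T")

## Per-codon synonymous site count: at each position, the synonymous
## fraction among non-stop single-base alternatives. n_pos + s_pos = 1, so
## N + S = 3 * (codon count) exactly.
.ng86SynSites <- function(codon, map) {
  b <- strsplit(codon, "", fixed = TRUE)[[1]]
  aa <- map[codon]
  s <- 0
  for (pos in 1:3) {
    alts <- .NUC[.NUC != b[pos]]
    newc <- vapply(alts, function(x) {
      bb <- b; bb[pos] <- x; paste(bb, collapse = "")
    }, character(1))
    ok <- map[newc] != "*"
    if (any(ok))
      s <- s + sum(map[newc[ok]] == aa) / sum(ok)
  }
  s
}

## Pathway-averaged synonymous/nonsynonymous differences between two sense
## codons. Pathways passing through a stop codon are excluded; if every
## pathway is blocked, all pathways are used with stop-creating steps
## counted as nonsynonymous.
.ng86Diffs <- function(c1, c2, map) {
  b1 <- strsplit(c1, "", fixed = TRUE)[[1]]
  b2 <- strsplit(c2, "", fixed = TRUE)[[1]]
  pos <- which(b1 != b2)
  k <- length(pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  perms <- switch(k,
    `1` = list(pos),
    `2` = list(pos, rev(pos)),
    `3` = {
      p <- pos
      list(p[c(1, 2, 3)], p[c(1, 3, 2)], p[c(2, 1, 3)],
           p[c(2, 3, 1)], p[c(3, 1, 2)], p[c(3, 2, 1)])
    })
  walk <- function(order) {
    cur <- b1
    sd <- 0; nd <- 0; blocked <- FALSE
    for (p in order) {
      nxt <- cur; nxt[p] <- b2[p]
      a1 <- map[paste(cur, collapse = "")]
      a2 <- map[paste(nxt, collapse = "")]
      if (a2 == "*" && paste(nxt, collapse = "") != c2) blocked <- TRUE
      if (a2 == "*" || a1 == "*") nd <- nd + 1
      else if (a1 == a2) sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd, blocked = as.numeric(blocked))
  }
  res <- vapply(perms, walk, numeric(3))
  open <- res["blocked", ] == 0
  if (any(open)) res <- res[, open, drop = FALSE]
  c(sd = mean(res["sd", ]), nd = mean(res["nd", ]))
}

#' Pairwise dN/dS by Nei-Gojobori (1986) counting
#'
#' Pathway-averaged synonymous/nonsynonymous site and difference counts
#' with Jukes-Cantor correction, evaluated under the supplied genetic-code
#' table (so reassigned codons are treated as the sense codons they are).
#' Site counts are averaged over the two sequences.
#'
#' @param seq1,seq2 Gapless, equal-length, in-frame DNA coding sequences
#'   with no internal stops under `code` (remove gap-containing codon
#'   columns upstream, e.g. with [readCodonAlignment()]).
#' @param code A [GeneticCodeTable-class] (default standard).
#' @return list: `N`, `S` (expected site counts), `Nd`, `Sd` (observed
#'   differences), `pN`, `pS`, `dN`, `dS` (Jukes-Cantor), `ratio`
#'   (dN/dS; NA with `ratio_defined = FALSE` when dS is 0 or saturated).
#' @examples
#' ng86Dnds("TTTGCT", "TTCGCT")$Sd  # one synonymous difference
#' @export
ng86Dnds <- function(seq1, seq2, code = standardGeneticCode()) {
  seq1 <- .checkDNA(seq1); seq2 <- .checkDNA(seq2)
  if (nchar(seq1) != nchar(seq2) || nchar(seq1) %% 3L != 0L)
    stop("sequences must be equal-length and a multiple of 3", call. = FALSE)
  map <- codonAssignments(code)
  cod1 <- .splitCodons(seq1); cod2 <- .splitCodons(seq2)
  if (any(map[cod1] == "*") || any(map[cod2] == "*"))
    stop("internal stop codon under the supplied code", call. = FALSE)
  S1 <- sum(vapply(cod1, .ng86SynSites, numeric(1), map = map))
  S2 <- sum(vapply(cod2, .ng86SynSites, numeric(1), map = map))
  S <- (S1 + S2) / 2
  N <- 3 * length(cod1) - S
  d <- vapply(seq_along(cod1), function(i)
    .ng86Diffs(cod1[i], cod2[i], map), numeric(2))
  Sd <- sum(d["sd", ]); Nd <- sum(d["nd", ])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) if (p >= 0.75) NA_real_ else -3 / 4 * log(1 - 4 * p / 3)
  dS <- jc(pS); dN <- jc(pN)
  defined <- !is.na(dS) && !is.na(dN) && dS > 0
  list(N = N, S = S, Nd = Nd, Sd = Sd, pN = pN, pS = pS,
       dN = dN, dS = dS,
       ratio = if (defined) dN / dS else NA_real_,
       ratio_defined = defined)
}

#' Read a pairwise codon alignment from FASTA
#'
#' Reads the first two records of an aligned FASTA and removes every codon
#' column in which either sequence carries a gap, returning gapless
#' in-frame sequences ready for [ng86Dnds()].
#'
#' @param path FASTA path (two aligned sequences; `-` gaps; length a
#'   multiple of 3).
#' @return list with `seq1`, `seq2` (character scalars) and `ids`.
#' @export
readCodonAlignment <- function(path) {
  x <- Biostrings::readBStringSet(path)
  if (length(x) < 2L) stop("need two aligned sequences", call. = FALSE)
  s1 <- toupper(as.character(x[[1]])); s2 <- toupper(as.character(x[[2]]))
  if (nchar(s1) != nchar(s2) || nchar(s1) %% 3L != 0L)
    stop("aligned sequences must be equal length, a multiple of 3",
         call. = FALSE)
  c1 <- .splitCodons(s1); c2 <- .splitCodons(s2)
  keep <- !grepl("-", c1, fixed = TRUE) & !grepl("-", c2, fixed = TRUE)
  list(seq1 = paste(c1[keep], collapse = ""),
       seq2 = paste(c2[keep], collapse = ""),
       ids = names(x)[1:2])
}
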