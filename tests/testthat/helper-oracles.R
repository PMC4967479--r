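## Independent brute-force oracles: every function here is a plain-loop
## reimplementation kept deliberately separate from the package's
## vectorised code paths.

oracle_translate_standard <- function(seq, stops_as_x = FALSE) {
  ## seqinr's translator is the independent reference for the standard code
  aa <- seqinr::translate(seqinr::s2c(tolower(seq)), ambiguous = FALSE)
  aa[aa == "X"] <- "X"
  if (stops_as_x) aa[aa == "*"] <- "X"
  paste(aa, collapse = "")
}

oracle_revcomp <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(seq, "")[[1]]]), collapse = "")
}

oracle_filter <- function(records, evalue_max = 1e-10,
                          conservation_min = 0.5) {
  keep <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    cd <- records$matched_codon[i]
    keep[i] <- records$conditional_evalue[i] < evalue_max &&
      records$column_conservation[i] >= conservation_min &&
      !grepl("N", cd, fixed = TRUE)
  }
  records[keep, , drop = FALSE]
}

oracle_matrix <- function(records) {
  m <- matrix(0L, 64, 20, dimnames = list(CODONS, AMINO_ACIDS))
  for (i in seq_len(nrow(records))) {
    cd <- records$matched_codon[i]
    aa <- records$consensus_aa[i]
    if (aa %in% AMINO_ACIDS) m[cd, aa] <- m[cd, aa] + 1L
  }
  m
}

oracle_normalize <- function(counts, mode) {
  out <- matrix(0, 64, 20, dimnames = dimnames(counts))
  if (mode == "per_amino_acid") {
    for (j in 1:20) {
      tot <- sum(counts[, j])
      if (tot > 0) out[, j] <- counts[, j] / tot
    }
  } else {
    for (i in 1:64) {
      tot <- sum(counts[i, ])
      if (tot > 0) out[i, ] <- counts[i, ] / tot
    }
  }
  out
}

## Codon-by-codon backward walk from the poly(A) site with 0/1/2 tail
## borrowing; returns data.frame(d, codon).
oracle_positional_walk <- function(seq, frame, polya_site, window) {
  upstream <- polya_site - 1 - frame
  b <- (3 - upstream %% 3) %% 3
  aug <- paste0(substr(seq, 1, polya_site - 1), strrep("A", b))
  E <- polya_site - 1 + b
  out <- NULL
  m <- 1
  repeat {
    p <- E - 3 * m + 1
    if (p < 1 || 3 * m > window) break
    out <- rbind(out, data.frame(d = -3 * m,
                                 codon = substr(aug, p, p + 2)))
    m <- m + 1
  }
  out
}

oracle_coverage <- function(starts, ends, len) {
  v <- integer(len)
  for (p in seq_len(len)) v[p] <- sum(starts <= p & ends >= p)
  v
}

## NG86 oracles: recursive path enumeration, independent of the package's
## permutation-table implementation.
oracle_ng86_sites <- function(codon, map) {
  b <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) {
    syn <- 0; valid <- 0
    for (nt in c("A", "C", "G", "T")) {
      if (nt == b[pos]) next
      alt <- b; alt[pos] <- nt
      alt <- paste(alt, collapse = "")
      if (map[alt] == "*") next
      valid <- valid + 1
      if (map[alt] == map[codon]) syn <- syn + 1
    }
    if (valid > 0) s <- s + syn / valid
  }
  s
}

oracle_ng86_diffs <- function(c1, c2, map) {
  if (c1 == c2) return(c(sd = 0, nd = 0))
  paths <- list()
  recurse <- function(cur, sd, nd, blocked) {
    if (cur == c2) {
      paths[[length(paths) + 1]] <<- c(sd = sd, nd = nd,
                                       blocked = blocked)
      return(invisible())
    }
    b1 <- strsplit(cur, "")[[1]]; b2 <- strsplit(c2, "")[[1]]
    for (pos in which(b1 != b2)) {
      nxt <- b1; nxt[pos] <- b2[pos]
      nxt <- paste(nxt, collapse = "")
      step_blocked <- blocked || (map[nxt] == "*" && nxt != c2)
      syn <- map[cur] != "*" && map[nxt] != "*" && map[cur] == map[nxt]
      recurse(nxt, sd + as.numeric(syn), nd + as.numeric(!syn),
              step_blocked)
    }
  }
  recurse(c1, 0, 0, FALSE)
  m <- do.call(rbind, paths)
  open <- m[, "blocked"] == 0
  if (any(open)) m <- m[open, , drop = FALSE]
  c(sd = mean(m[, "sd"]), nd = mean(m[, "nd"]))
}

## Small random record generator used by several tests.
random_records <- function(n, seed) {
  set.seed(seed)
  data.frame(
    profile_id = "p1",
    transcript_id = sprintf("t%04d", seq_len(n)),
    frame = "+1",
    column_index = seq_len(n),
    consensus_aa = sample(c(AMINO_ACIDS, "B"), n, TRUE,
                          prob = c(rep(1, 20), 0.02)),
    column_conservation = stats::runif(n),
    matched_codon = ifelse(stats::runif(n) < 0.03,
                           "TNA", sample(CODONS, n, TRUE)),
    conditional_evalue = 10^stats::runif(n, -20, -5),
    stringsAsFactors = FALSE
  )
}

md5_of <- function(paths) unname(tools::md5sum(paths))
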