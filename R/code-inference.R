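#' Profile-alignment record streams
#'
#' One record per aligned (consensus amino acid, underlying codon) pair from
#' a profile-HMM search of six-frame translations: `profile_id`,
#' `transcript_id`, `frame`, `column_index`, `consensus_aa`,
#' `column_conservation` (modal-residue frequency in the profile's source
#' alignment column), `matched_codon`, `conditional_evalue`.
#'
#' @param path TSV path with the columns above.
#' @return data.frame.
#' @export
readAlignmentRecords <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = list(matched_codon = "character"))
  need <- c("profile_id", "transcript_id", "frame", "column_index",
            "consensus_aa", "column_conservation", "matched_codon",
            "conditional_evalue")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("record stream lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df
}

#' @rdname readAlignmentRecords
#' @param records data.frame of records.
#' @export
writeAlignmentRecords <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Filter profile-alignment records
#'
#' A record passes iff its conditional e-value is strictly below
#' `evalue_max`, its column conservation is at least `conservation_min`
#' (inclusive) and its matched codon is a valid triplet with no N.
#' Malformed records (missing values, bad codon, conservation outside
#' \[0,1\], negative e-value) are rejected and counted, never silently
#' dropped.
#'
#' @param records data.frame of profile-alignment records.
#' @param evalue_max Strict upper bound on the conditional e-value
#'   (default 1e-10).
#' @param conservation_min Inclusive lower bound on column conservation
#'   (default 0.5).
#' @return The retained records, with attribute `rejects`, a named count of
#'   rejections by reason (evalue, conservation, codon_N, malformed).
#' @export
filterRecords <- function(records, evalue_max = 1e-10, conservation_min = 0.5) {
  stopifnot(evalue_max > 0, conservation_min >= 0)
  codon <- toupper(records$matched_codon)
  cons <- records$column_conservation
  ev <- records$conditional_evalue
  malformed <- is.na(codon) | is.na(cons) | is.na(ev) |
    nchar(codon) != 3L | grepl("[^ACGTN]", codon) |
    cons < 0 | cons > 1 | ev < 0
  hasN <- !malformed & grepl("N", codon, fixed = TRUE)
  bad_ev <- !malformed & !hasN & ev >= evalue_max
  bad_cons <- !malformed & !hasN & !bad_ev & cons < conservation_min
  keep <- !(malformed | hasN | bad_ev | bad_cons)
  out <- records[keep, , drop = FALSE]
  out$matched_codon <- codon[keep]
  attr(out, "rejects") <- c(
    malformed = sum(malformed), codon_N = sum(hasN),
    evalue = sum(bad_ev), conservation = sum(bad_cons)
  )
  out
}

#' Accumulate the 64 x 20 codon/amino-acid count matrix
#'
#' m\[i, j\] = number of filtered records pairing matched codon i with
#' consensus amino acid j. Records whose consensus symbol is not one of the
#' 20 standard letters are rejected and counted.
#'
#' @param records Filtered records (see [filterRecords()]).
#' @return A [CodonAminoMatrix-class] holding counts only
#'   (`normalizationMode = "none"`).
#' @export
accumulateMatrix <- function(records) {
  aa <- toupper(records$consensus_aa)
  ok <- aa %in% AMINO_ACIDS
  counts <- table(
    factor(records$matched_codon[ok], levels = CODONS),
    factor(aa[ok], levels = AMINO_ACIDS)
  )
  counts <- matrix(as.integer(counts), 64L, 20L,
                   dimnames = list(CODONS, AMINO_ACIDS))
  obj <- new("CodonAminoMatrix", counts = counts,
             normalized = matrix(0, 64L, 20L,
                                 dimnames = list(CODONS, AMINO_ACIDS)),
             normalizationMode = "none")
  attr(obj, "rejected_aa") <- sum(!ok)
  obj
}

#' Normalise a codon/amino-acid count matrix
#'
#' Per-amino-acid mode divides each amino-acid column j by its total
#' (M = m\[i,j\] / sum_i m\[i,j\]) — the scaling used for sequence-logo
#' export. Per-codon mode divides each codon row i by its total — the
#' per-codon shares used for code calling. Zero marginals yield zero
#' rows/columns, never NaN.
#'
#' @param m A [CodonAminoMatrix-class] (or 64 x 20 count matrix).
#' @param mode `"per_amino_acid"` or `"per_codon"`.
#' @return A [CodonAminoMatrix-class] with `normalized` filled in.
#' @export
normalizeMatrix <- function(m, mode = c("per_amino_acid", "per_codon")) {
  mode <- match.arg(mode)
  counts <- if (methods::is(m, "CodonAminoMatrix")) m@counts else m
  stopifnot(all(counts >= 0))
  if (mode == "per_amino_acid") {
    tot <- colSums(counts)
    norm <- sweep(counts, 2L, ifelse(tot > 0, tot, 1), "/")
    norm[, tot == 0] <- 0
  } else {
    tot <- rowSums(counts)
    norm <- sweep(counts, 1L, ifelse(tot > 0, tot, 1), "/")
    norm[tot == 0, ] <- 0
  }
  new("CodonAminoMatrix", counts = counts, normalized = unname(norm) |>
        matrix(64L, 20L, dimnames = list(CODONS, AMINO_ACIDS)),
      normalizationMode = mode)
}

#' Call a genetic code from a codon/amino-acid matrix
#'
#' Per codon, the call is the amino acid with the maximal per-codon share,
#' made only when the codon's total support reaches `min_support` and the
#' winning share exceeds the runner-up's by at least `ambiguity_margin`
#' (ties flag `UNASSIGNED`). Codons never observed (e.g. dedicated stop
#' codons, which do not occur inside coding sequence) are `UNASSIGNED`.
#'
#' @param m A [CodonAminoMatrix-class] (counts are used; normalisation mode
#'   of the input is irrelevant).
#' @param min_support Minimum total pairs per codon (default 10).
#' @param ambiguity_margin Minimum top-minus-runner-up share (default 0.1).
#' @return A [GeneticCodePrediction-class].
#' @export
predictCode <- function(m, min_support = 10, ambiguity_margin = 0.1) {
  stopifnot(min_support >= 1, ambiguity_margin >= 0, ambiguity_margin < 1)
  counts <- if (methods::is(m, "CodonAminoMatrix")) m@counts else m
  support <- rowSums(counts)
  share <- sweep(counts, 1L, ifelse(support > 0, support, 1), "/")
  top_j <- max.col(share, ties.method = "first")
  top_fraction <- share[cbind(seq_len(64L), top_j)]
  share2 <- share
  share2[cbind(seq_len(64L), top_j)] <- -Inf
  run_j <- max.col(share2, ties.method = "first")
  runner_fraction <- share[cbind(seq_len(64L), run_j)]
  call <- AMINO_ACIDS[top_j]
  unassigned <- support < min_support |
    (top_fraction - runner_fraction) < ambiguity_margin
  call[unassigned] <- "UNASSIGNED"
  top_fraction[support == 0] <- 0
  runner_fraction[support == 0] <- 0
  new("GeneticCodePrediction",
      calls = data.frame(
        codon = CODONS,
        call = call,
        support = as.numeric(support),
        top_fraction = top_fraction,
        runner_up = AMINO_ACIDS[run_j],
        runner_up_fraction = runner_fraction,
        stringsAsFactors = FALSE
      ),
      minSupport = min_support, ambiguityMargin = ambiguity_margin)
}

#' @describeIn predictCode the per-codon call table.
#' @param pred A [GeneticCodePrediction-class].
#' @export
codeCalls <- function(pred) pred@calls

setMethod("show", "GeneticCodePrediction", function(object) {
  n_called <- sum(object@calls$call != "UNASSIGNED")
  cat("GeneticCodePrediction:", n_called, "of 64 codons called",
      "(min_support", object@minSupport, ", margin",
      object@ambiguityMargin, ")\n")
  dev <- object@calls$call != "UNASSIGNED" &
    object@calls$call != Biostrings::GENETIC_CODE[CODONS]
  if (any(dev))
    cat("  non-standard:",
        paste0(rnaCodon(object@calls$codon[dev]), "=",
               object@calls$call[dev], collapse = " "), "\n")
})

setMethod("show", "CodonAminoMatrix", function(object) {
  cat("CodonAminoMatrix: ", sum(object@counts), " aligned pairs, ",
      sum(rowSums(object@counts) > 0), "/64 codons observed",
      " (normalisation: ", object@normalizationMode, ")\n", sep = "")
})

#' Score a prediction against a known genetic-code table
#'
#' A sense codon is correct when its call equals the table's amino acid; a
#' dedicated stop codon is correct when it is left `UNASSIGNED` (stops
#' never occur inside coding sequence, so no sense call should arise).
#'
#' @param pred A [GeneticCodePrediction-class].
#' @param code The true [GeneticCodeTable-class].
#' @return Number of the 64 codons scored correct.
#' @export
codeRecovery <- function(pred, code) {
  truth <- codonAssignments(code)[pred@calls$codon]
  expected <- ifelse(truth == "*", "UNASSIGNED", truth)
  sum(pred@calls$call == expected)
}

#' Export / import the logo probability matrix
#'
#' The exported table has the 64 codons (TCAG-major order, RNA style) as
#' rows and the 20 amino-acid symbols as columns, holding the normalised
#' entries — the input expected by third-party sequence-logo renderers.
#'
#' @param m A normalised [CodonAminoMatrix-class].
#' @param path Output TSV path.
#' @export
exportLogoMatrix <- function(m, path) {
  stopifnot(methods::is(m, "CodonAminoMatrix"),
            m@normalizationMode != "none")
  df <- data.frame(codon = rnaCodon(CODONS), m@normalized,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname exportLogoMatrix
#' @param mode Normalisation mode recorded on import.
#' @return `importLogoMatrix` returns a [CodonAminoMatrix-class] whose
#'   `normalized` slot holds the table (counts are zero).
#' @export
importLogoMatrix <- function(path, mode = "per_amino_acid") {
  df <- utils::read.delim(path, check.names = FALSE)
  norm <- as.matrix(df[, AMINO_ACIDS])
  rownames(norm) <- chartr("Uu", "Tt", df$codon)
  norm <- norm[CODONS, , drop = FALSE]
  new("CodonAminoMatrix",
      counts = matrix(0L, 64L, 20L, dimnames = list(CODONS, AMINO_ACIDS)),
      normalized = norm, normalizationMode = mode)
}

#' Write a prediction report (TSV and JSON)
#' @param pred A [GeneticCodePrediction-class].
#' @param tsv,json Output paths (either may be NULL).
#' @export
writePredictionReport <- function(pred, tsv = NULL, json = NULL) {
  df <- codeCalls(pred)
  df$codon <- rnaCodon(df$codon)
  if (!is.null(tsv))
    utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(
      list(min_support = pred@minSupport,
           ambiguity_margin = pred@ambiguityMargin,
           calls = df),
      json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(pred)
}
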