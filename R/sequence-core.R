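.checkDNA <- function(seq) {
  if (length(seq) == 0L || any(!nzchar(seq)))
    stop("empty DNA input", call. = FALSE)
  seq <- toupper(seq)
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad))
    stop("non-DNA characters in input (allowed: A/C/G/T/N)", call. = FALSE)
  seq
}

.splitCodons <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return(character())
  substring(seq, seq(1L, by = 3L, length.out = n),
            seq(3L, by = 3L, length.out = n))
}

#' Translate DNA with an arbitrary genetic-code table
#'
#' Translates in-frame from the first base. Codons containing N translate
#' to `"X"`. With `stops_as_x = TRUE` (the convention used when building
#' six-frame peptide databases for profile searches) dedicated stop codons
#' are also recorded as `"X"`; otherwise they appear as `"*"`.
#'
#' @param seq Character vector of DNA sequences (A/C/G/T/N), each of length
#'   >= 3.
#' @param code A [GeneticCodeTable-class] (default standard).
#' @param stops_as_x Record stops as "X"?
#' @return Character vector of amino-acid strings, lengths
#'   `floor(nchar(seq)/3)`.
#' @examples
#' translateDNA("ATGTGG")               # "MW"
#' translateDNA("TGA", stops_as_x = TRUE) # "X"
#' @export
translateDNA <- function(seq, code = standardGeneticCode(), stops_as_x = FALSE) {
  seq <- .checkDNA(seq)
  if (any(nchar(seq) < 3L))
    stop("sequences must be at least one codon long", call. = FALSE)
  lut <- codonAssignments(code)
  vapply(seq, function(s) {
    aa <- unname(lut[.splitCodons(s)])
    aa[is.na(aa)] <- "X"
    if (stops_as_x) aa[aa == "*"] <- "X"
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Reverse-complement a DNA string
#' @param seq Character vector of DNA sequences.
#' @return Reverse complements (N preserved).
#' @export
revComp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(.checkDNA(seq))))
}

#' Six-frame translation
#'
#' Frames `+1/+2/+3` read the forward strand shifted by 0/1/2 bases; frames
#' `-1/-2/-3` read the reverse complement likewise.
#'
#' @inheritParams translateDNA
#' @param seq A single DNA string of length >= 3.
#' @return Named character vector of the six translations.
#' @export
sixFrameTranslate <- function(seq, code = standardGeneticCode(), stops_as_x = TRUE) {
  seq <- .checkDNA(seq)
  stopifnot(length(seq) == 1L)
  rc <- revComp(seq)
  shift <- function(s, k) substring(s, k, nchar(s))
  keep <- function(s) nchar(s) >= 3L
  out <- c("+1" = shift(seq, 1), "+2" = shift(seq, 2), "+3" = shift(seq, 3),
           "-1" = shift(rc, 1),  "-2" = shift(rc, 2),  "-3" = shift(rc, 3))
  vapply(out, function(s) if (keep(s)) translateDNA(s, code, stops_as_x) else "",
         character(1))
}

#' Attach coding annotations to a transcript set
#'
#' Transcripts travel as a [Biostrings::DNAStringSet] whose `mcols` carry
#' the coding annotation used throughout the package: `frame` (0/1/2,
#' forward strand), `cds_start`/`cds_end` (1-based, inclusive; the span is a
#' multiple of 3 and includes the stop codon when one is annotated) and
#' `polya_site` (1-based position of the first untemplated tail adenosine,
#' NA when absent).
#'
#' @param seqs A `DNAStringSet` or named character vector.
#' @param frame,cds_start,cds_end,polya_site Per-transcript annotation
#'   vectors (recycled NA when omitted).
#' @return A `DNAStringSet` with populated `mcols`.
#' @export
transcriptSet <- function(seqs, frame = NA_integer_, cds_start = NA_integer_,
                          cds_end = NA_integer_, polya_site = NA_integer_) {
  if (!methods::is(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  n <- length(seqs)
  mcols(seqs) <- DataFrame(
    frame = as.integer(rep_len(frame, n)),
    cds_start = as.integer(rep_len(cds_start, n)),
    cds_end = as.integer(rep_len(cds_end, n)),
    polya_site = as.integer(rep_len(polya_site, n))
  )
  bad <- !is.na(mcols(seqs)$cds_start) & !is.na(mcols(seqs)$cds_end) &
    (mcols(seqs)$cds_end - mcols(seqs)$cds_start + 1L) %% 3L != 0L
  if (any(bad))
    stop("CDS span must be a multiple of 3 (transcripts: ",
         paste(head(names(seqs)[bad], 5), collapse = ", "), ")", call. = FALSE)
  seqs
}

#' Read transcripts (FASTA) with an optional annotation table
#'
#' @param fasta Path to a FASTA file (wrapped lines tolerated; the name is
#'   the first whitespace-delimited token, the remainder of the header is
#'   kept as the `description` metadata column).
#' @param annotation Optional path to a TSV with columns `transcript_id`,
#'   `frame`, `cds_start`, `cds_end`, `polya_site` (1-based inclusive).
#' @return A `DNAStringSet` with `mcols` as in [transcriptSet()].
#' @export
readTranscripts <- function(fasta, annotation = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  desc <- names(seqs)
  ids <- sub("\\s.*$", "", desc)
  names(seqs) <- ids
  seqs <- transcriptSet(seqs)
  mcols(seqs)$description <- sub("^\\S+\\s*", "", desc)
  if (!is.null(annotation)) {
    ann <- utils::read.delim(annotation, stringsAsFactors = FALSE)
    i <- match(ids, ann$transcript_id)
    for (col in c("frame", "cds_start", "cds_end", "polya_site"))
      if (col %in% names(ann))
        mcols(seqs)[[col]] <- as.integer(ann[[col]][i])
  }
  seqs
}

#' Write transcripts and their annotation table
#' @param transcripts Annotated `DNAStringSet` (see [transcriptSet()]).
#' @param fasta,annotation Output paths (annotation TSV skipped when NULL).
#' @export
writeTranscripts <- function(transcripts, fasta, annotation = NULL) {
  Biostrings::writeXStringSet(transcripts, fasta)
  if (!is.null(annotation)) {
    df <- data.frame(
      transcript_id = names(transcripts),
      frame = mcols(transcripts)$frame,
      cds_start = mcols(transcripts)$cds_start,
      cds_end = mcols(transcripts)$cds_end,
      polya_site = mcols(transcripts)$polya_site
    )
    utils::write.table(df, annotation, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(fasta)
}

#' Codon usage over annotated coding sequences
#'
#' Counts every in-frame codon inside the annotated CDS span (stop codon
#' included when the annotation includes it). Codons containing N are
#' excluded from both counts and the denominator. Transcripts lacking CDS
#' annotation are skipped with a warning and reported in the `skipped`
#' attribute.
#'
#' @param transcripts Annotated `DNAStringSet` (see [transcriptSet()]).
#' @param code [GeneticCodeTable-class] used for the amino-acid column of
#'   the report.
#' @return data.frame (codon, amino_acid, count, fraction) over the 64
#'   codons, with attributes `total` and `skipped`.
#' @export
codonUsage <- function(transcripts, code = standardGeneticCode()) {
  m <- mcols(transcripts)
  has <- !is.na(m$cds_start) & !is.na(m$cds_end)
  if (!any(has)) stop("no transcript carries CDS annotation", call. = FALSE)
  if (any(!has))
    warning(sum(!has), " transcript(s) without CDS annotation skipped")
  seqs <- as.character(transcripts[has])
  starts <- m$cds_start[has]; ends <- m$cds_end[has]
  codons <- unlist(lapply(seq_along(seqs), function(i) {
    .splitCodons(substr(seqs[i], starts[i], ends[i]))
  }), use.names = FALSE)
  codons <- codons[!grepl("N", codons, fixed = TRUE)]
  counts <- table(factor(codons, levels = CODONS))
  total <- sum(counts)
  out <- data.frame(
    codon = CODONS,
    amino_acid = unname(codonAssignments(code)[CODONS]),
    count = as.integer(counts),
    fraction = if (total > 0) as.numeric(counts) / total else 0,
    stringsAsFactors = FALSE
  )
  attr(out, "total") <- total
  attr(out, "skipped") <- sum(!has)
  out
}

#' Write a codon-usage report as TSV
#' @param usage Result of [codonUsage()].
#' @param path Output path.
#' @export
writeCodonUsage <- function(usage, path) {
  out <- usage
  out$codon <- rnaCodon(out$codon)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
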