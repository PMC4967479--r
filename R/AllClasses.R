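#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
NULL

## The 64 DNA codons in TCAG-major order (first base slowest), the order used
## for all matrices, logo exports and reports.
.TCAG <- c("T", "C", "A", "G")

#' The 64 DNA codons in TCAG-major order
#'
#' Codons are keyed as DNA (`TGA`, not `UGA`) internally; reports may print
#' RNA-style via [rnaCodon()].
#' @format Character vector of length 64.
#' @export
CODONS <- paste0(
  rep(.TCAG, each = 16),
  rep(rep(.TCAG, each = 4), 4),
  rep(.TCAG, 16)
)

#' The 20 standard amino-acid symbols (alphabetical)
#' @format Character vector of length 20.
#' @export
AMINO_ACIDS <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

#' Genetic-code table
#'
#' A 64-codon to amino-acid/stop mapping, standard or variant, with an
#' optional set of context-dependent ("ambiguous") codons that are read as
#' sense within coding sequence but can act as stops near transcript ends.
#'
#' @slot name Short label for the code.
#' @slot mapping Named character vector of length 64 (names are the DNA
#'   codons in TCAG-major order); values are amino-acid one-letter symbols
#'   or `"*"` for a dedicated stop.
#' @slot ambiguousSet Codons flagged as context-dependent; must be a subset
#'   of the sense codons of `mapping`.
#' @export
setClass("GeneticCodeTable", representation(
  name = "character",
  mapping = "character",
  ambiguousSet = "character"
))

setValidity("GeneticCodeTable", function(object) {
  msg <- character()
  if (length(object@mapping) != 64L || !identical(sort(names(object@mapping)), sort(CODONS)))
    msg <- c(msg, "mapping must have exactly the 64 DNA codons as names")
  if (!all(object@mapping %in% c(AMINO_ACIDS, "*")))
    msg <- c(msg, "mapping values must be standard amino-acid symbols or '*'")
  sense <- names(object@mapping)[object@mapping != "*"]
  if (!all(object@ambiguousSet %in% sense))
    msg <- c(msg, "ambiguousSet must be a subset of sense codons")
  if (length(msg)) msg else TRUE
})

#' Codon/amino-acid count matrix
#'
#' The 64 x 20 count matrix m[i, j] of aligned (codon i, consensus amino
#' acid j) pairs, together with a normalised form. Per-amino-acid
#' normalisation divides each amino-acid column by its total (the form used
#' for sequence logos); per-codon normalisation divides each codon row by
#' its total (the form used for code calling).
#'
#' @slot counts 64 x 20 integer matrix, rows `CODONS`, columns `AMINO_ACIDS`.
#' @slot normalized 64 x 20 numeric matrix (zero where the relevant marginal
#'   is zero; never NaN).
#' @slot normalizationMode `"per_amino_acid"` or `"per_codon"`.
#' @export
setClass("CodonAminoMatrix", representation(
  counts = "matrix",
  normalized = "matrix",
  normalizationMode = "character"
))

setValidity("CodonAminoMatrix", function(object) {
  msg <- character()
  if (!identical(dim(object@counts), c(64L, 20L)))
    msg <- c(msg, "counts must be 64 x 20")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
  if (length(object@normalizationMode) &&
      !object@normalizationMode %in% c("per_amino_acid", "per_codon", "none"))
    msg <- c(msg, "unknown normalizationMode")
  if (length(msg)) msg else TRUE
})

#' Genetic-code prediction
#'
#' Per-codon calls from a [CodonAminoMatrix]: the amino acid with the
#' maximal per-codon share, its support (total pair count for the codon),
#' the winning share, and the runner-up. Codons with insufficient support or
#' an ambiguous margin are `UNASSIGNED`; dedicated stop codons never occur
#' inside coding sequence and therefore surface as `UNASSIGNED` here
#' (candidate-stop labelling is the transcript-end module's job).
#'
#' @slot calls data.frame with columns codon, call, support, top_fraction,
#'   runner_up, runner_up_fraction.
#' @slot minSupport,ambiguityMargin The thresholds used.
#' @export
setClass("GeneticCodePrediction", representation(
  calls = "data.frame",
  minSupport = "numeric",
  ambiguityMargin = "numeric"
))

#' Positional codon counts upstream of poly(A) sites
#'
#' Codon counts indexed by the 3-nt-resolved offset d of the codon's first
#' base upstream of the poly(A) site (d = -3 is the final codon, which may
#' borrow 0/1/2 tail adenosines to complete its triplet).
#'
#' @slot counts Integer matrix, rows = offsets d (as character, e.g. "-3"),
#'   columns = the 64 codons.
#' @slot nTranscripts Number of transcripts contributing.
#' @slot tailCompletion Named integer vector: how many final codons borrowed
#'   0, 1 or 2 tail nucleotides.
#' @slot region `"all"` (3' UTR and stop included, as in terminal
#'   stacked-bar displays) or `"coding"` (codons 5' of the primary stop only).
#' @export
setClass("PositionalCodonCounts", representation(
  counts = "matrix",
  nTranscripts = "integer",
  tailCompletion = "integer",
  region = "character"
))

#' Footprint 3'-end metaprofile
#'
#' Counts of ribosome-protected-fragment 3' ends at each offset relative to
#' an anchor codon. Offsets follow the display convention in which the
#' anchor codon occupies positions 1-3, so a terminating footprint ending
#' 11 nt after the stop codon's 3' nt sits at offset 14.
#'
#' @slot offsets Integer vector of offsets.
#' @slot counts Integer matrix, rows = offsets, columns = RPF lengths (a
#'   single pooled column named "all" unless per-length profiles were asked
#'   for).
#' @slot anchorClass One of "sense", "stop", "all".
#' @export
setClass("MetaProfile", representation(
  offsets = "integer",
  counts = "matrix",
  anchorClass = "character"
))
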