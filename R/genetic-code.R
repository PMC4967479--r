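#' Construct a genetic-code table
#'
#' @param name Short label.
#' @param mapping Named character vector of length 64 mapping DNA codons to
#'   amino-acid symbols or `"*"`.
#' @param ambiguousSet Codons read as sense in coding sequence but acting as
#'   stops near transcript ends.
#' @return A [GeneticCodeTable-class] object.
#' @examples
#' std <- standardGeneticCode()
#' codonAssignments(std)[["TGG"]]
#' @export
GeneticCodeTable <- function(name, mapping, ambiguousSet = character()) {
  mapping <- mapping[CODONS]
  new("GeneticCodeTable", name = name, mapping = mapping,
      ambiguousSet = unname(ambiguousSet))
}

#' The standard nuclear genetic code
#' @return A [GeneticCodeTable-class].
#' @export
standardGeneticCode <- function() {
  GeneticCodeTable("standard", Biostrings::GENETIC_CODE[CODONS])
}

#' Ciliate-style variant genetic codes
#'
#' Variant nuclear codes arising from stop-codon reassignment:
#' \describe{
#'   \item{`"UAR=Q"`}{UAA/UAG -> glutamine; UGA remains the stop
#'     (Tetrahymena/Oxytricha-like).}
#'   \item{`"UGA=W"`}{UGA -> tryptophan; UAA/UAG remain stops
#'     (Blepharisma-like).}
#'   \item{`"UGA=C"`}{UGA -> cysteine (Euplotes-like).}
#'   \item{`"UAR=Y"`}{UAA/UAG -> tyrosine; UGA remains the stop
#'     (Mesodiniidae-like).}
#'   \item{`"UAR=Q+UGA=W"` (alias `"ambiguous"`)}{all three standard stops
#'     reassigned (UAA/UAG -> Q, UGA -> W) and flagged context-dependent:
#'     no codon is a dedicated stop (Condylostoma-like).}
#' }
#' @param variant One of the labels above.
#' @return A [GeneticCodeTable-class].
#' @examples
#' amb <- ciliateGeneticCode("ambiguous")
#' stopSet(amb)
#' @export
ciliateGeneticCode <- function(variant = c("UAR=Q", "UGA=W", "UGA=C",
                                           "UAR=Y", "UAR=Q+UGA=W",
                                           "ambiguous")) {
  variant <- match.arg(variant)
  m <- Biostrings::GENETIC_CODE[CODONS]
  amb <- character()
  if (variant == "ambiguous") variant <- "UAR=Q+UGA=W"
  switch(variant,
    "UAR=Q" = { m["TAA"] <- "Q"; m["TAG"] <- "Q" },
    "UGA=W" = { m["TGA"] <- "W" },
    "UGA=C" = { m["TGA"] <- "C" },
    "UAR=Y" = { m["TAA"] <- "Y"; m["TAG"] <- "Y" },
    "UAR=Q+UGA=W" = {
      m["TAA"] <- "Q"; m["TAG"] <- "Q"; m["TGA"] <- "W"
      amb <- c("TAA", "TAG", "TGA")
    }
  )
  GeneticCodeTable(variant, m, ambiguousSet = amb)
}

#' @describeIn GeneticCodeTable codon -> amino-acid mapping (named character).
#' @param code A [GeneticCodeTable-class].
#' @export
codonAssignments <- function(code) code@mapping

#' @describeIn GeneticCodeTable label of the code.
#' @export
codeName <- function(code) code@name

#' @describeIn GeneticCodeTable context-dependent codons.
#' @export
ambiguousCodons <- function(code) code@ambiguousSet

#' @describeIn GeneticCodeTable codons able to act as stop: dedicated stops
#'   plus the ambiguous set.
#' @export
stopSet <- function(code) {
  sort(unique(c(names(code@mapping)[code@mapping == "*"], code@ambiguousSet)))
}

#' @describeIn GeneticCodeTable codons translated as sense.
#' @export
senseCodons <- function(code) names(code@mapping)[code@mapping != "*"]

setMethod("show", "GeneticCodeTable", function(object) {
  n_stop <- sum(object@mapping == "*")
  cat("GeneticCodeTable '", object@name, "': ",
      64L - n_stop, " sense codons, ", n_stop, " dedicated stops\n", sep = "")
  if (length(object@ambiguousSet))
    cat("  context-dependent (ambiguous):",
        paste(rnaCodon(object@ambiguousSet), collapse = " "), "\n")
  dev <- which(object@mapping != Biostrings::GENETIC_CODE[CODONS])
  if (length(dev))
    cat("  reassigned vs standard:",
        paste0(rnaCodon(names(object@mapping)[dev]), "=",
               object@mapping[dev], collapse = " "), "\n")
})

#' Print a DNA codon in RNA style
#'
#' @param codon Character vector of DNA triplets.
#' @return The same triplets with T replaced by U (report convenience).
#' @export
rnaCodon <- function(codon) chartr("Tt", "Uu", codon)

#' Write / read a genetic-code table as JSON
#'
#' The editable on-disk form holds the 64 assignments plus the ambiguous
#' set; round-trips losslessly.
#' @param code A [GeneticCodeTable-class].
#' @param path File path.
#' @return `writeGeneticCode` returns `path` invisibly; `readGeneticCode`
#'   returns a [GeneticCodeTable-class].
#' @export
writeGeneticCode <- function(code, path) {
  jsonlite::write_json(
    list(name = code@name,
         mapping = as.list(code@mapping),
         ambiguous_set = code@ambiguousSet),
    path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

#' @rdname writeGeneticCode
#' @export
readGeneticCode <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  GeneticCodeTable(x$name, unlist(x$mapping)[CODONS],
                   ambiguousSet = as.character(x$ambiguous_set))
}
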