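#' Stop-codon usage among identified primary stops
#'
#' Fractions of TAA/TAG/TGA among primary-stop calls, per species. Species
#' with fewer than `min_stops` identified stops are excluded (too few for
#' a stable usage estimate).
#'
#' @param calls A [findPrimaryStop()] data.frame (single species) or a
#'   named list of them (one per species).
#' @param min_stops Minimum identified stops per species (default 50).
#' @return data.frame: species, n, count_TAA/TAG/TGA, frac_TAA/TAG/TGA.
#' @export
stopCodonUsage <- function(calls, min_stops = 50) {
  if (is.data.frame(calls)) calls <- list(species1 = calls)
  if (!length(calls)) stop("no primary-stop calls supplied", call. = FALSE)
  rows <- lapply(names(calls), function(sp) {
    cc <- calls[[sp]]$stop_codon
    n <- length(cc)
    if (n < min_stops) return(NULL)
    cnt <- table(factor(cc, levels = c("TAA", "TAG", "TGA")))
    data.frame(species = sp, n = n,
               count_TAA = as.integer(cnt["TAA"]),
               count_TAG = as.integer(cnt["TAG"]),
               count_TGA = as.integer(cnt["TGA"]),
               frac_TAA = as.numeric(cnt["TAA"]) / n,
               frac_TAG = as.numeric(cnt["TAG"]) / n,
               frac_TGA = as.numeric(cnt["TGA"]) / n,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    stop("no species reaches min_stops = ", min_stops, call. = FALSE)
  do.call(rbind, rows)
}

#' Base composition at fourfold-degenerate third positions
#'
#' A codon third position is fourfold-degenerate when all four third-base
#' variants encode the same amino acid under the supplied code (proxy for
#' neutral base composition). Codons translating to stop under the code
#' are excluded.
#'
#' @param transcripts Annotated `DNAStringSet` with CDS annotation.
#' @param code A [GeneticCodeTable-class].
#' @return list: `fractions` (named A/C/G/T), `n_sites`.
#' @export
fourfoldComposition <- function(transcripts, code = standardGeneticCode()) {
  map <- codonAssignments(code)
  prefixes <- unique(substr(CODONS, 1, 2))
  four <- prefixes[vapply(prefixes, function(px) {
    aas <- map[paste0(px, .NUC)]
    all(aas != "*") && length(unique(aas)) == 1L
  }, logical(1))]
  m <- mcols(transcripts)
  has <- !is.na(m$cds_start) & !is.na(m$cds_end)
  if (!any(has)) stop("no CDS annotation", call. = FALSE)
  seqs <- as.character(transcripts[has])
  codons <- unlist(lapply(which(has), function(i) {
    j <- match(i, which(has))
    .splitCodons(substr(seqs[j], m$cds_start[i], m$cds_end[i]))
  }), use.names = FALSE)
  codons <- codons[!grepl("N", codons, fixed = TRUE) & map[codons] != "*"]
  third <- substr(codons[substr(codons, 1, 2) %in% four], 3, 3)
  if (!length(third))
    stop("no fourfold-degenerate sites in these coding sequences",
         call. = FALSE)
  cnt <- table(factor(third, levels = .NUC))
  list(fractions = stats::setNames(as.numeric(cnt) / length(third), .NUC),
       n_sites = length(third))
}

#' Regression of UAA stop usage on neutral A composition
#'
#' Linear fit of per-species TAA stop-codon usage against the A fraction
#' at fourfold-degenerate sites, with a two-sided test of zero slope.
#'
#' @param species_table data.frame with columns `species`, `uaa_fraction`
#'   (TAA share of primary stops) and `a4_fraction` (A share at fourfold
#'   sites).
#' @return list: `slope`, `intercept`, `r` (correlation coefficient),
#'   `p_value`, `n`, and the underlying `fit` (an `lm`).
#' @export
uaaCompositionFit <- function(species_table) {
  stopifnot(all(c("uaa_fraction", "a4_fraction") %in% names(species_table)))
  if (nrow(species_table) < 3L)
    stop("need at least 3 species for a slope test", call. = FALSE)
  fit <- stats::lm(uaa_fraction ~ a4_fraction, data = species_table)
  sm <- summary(fit)
  list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r = stats::cor(species_table$a4_fraction, species_table$uaa_fraction),
    p_value = sm$coefficients[2, 4],
    n = nrow(species_table),
    fit = fit
  )
}
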