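#' Normalize gene symbols
#'
#' Gene identifiers arriving from curated herb-target and drug-target tables
#' mix capitalizations ("gabrb1" vs "GABRB1"). All set algebra in the package
#' runs on normalized symbols: whitespace-stripped, uppercased tokens. The
#' transformation is idempotent, and symbols that normalize to the empty
#' string are rejected.
#'
#' @param x character vector of raw gene identifiers
#' @return character vector of normalized symbols, same length as \code{x}
#' @examples
#' normalizeGeneSymbols(c(" alb ", "gabrb1"))  # "ALB" "GABRB1"
#' @export
normalizeGeneSymbols <- function(x) {
  if (!is.character(x)) stop("gene symbols must be character")
  out <- toupper(trimws(x))
  if (any(!nzchar(out) | is.na(out)))
    stop("gene symbol empty after normalization")
  out
}

#' Is a symbol a cytochrome P450 isozyme?
#'
#' CYP isozymes are excluded from target spaces because their primary role is
#' xenobiotic metabolism rather than therapeutic action. A symbol counts as a
#' CYP isozyme when it matches the pattern \code{CYP} followed by a digit
#' (CYP3A4, CYP2D6, ...). The bare prefix "CYP" alone is deliberately not
#' enough: tokens such as "CYPX" or gene names that merely start with CYP are
#' retained, as are UGT-family symbols.
#'
#' @param gene character vector of normalized gene symbols
#' @return logical vector, TRUE where the symbol names a CYP isozyme
#' @examples
#' isCyp(c("CYP3A4", "UGT1A9", "CYPX"))  # TRUE FALSE FALSE
#' @export
isCyp <- function(gene) {
  grepl("^CYP[0-9]", gene)
}
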