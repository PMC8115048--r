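#' Nitrogen-cycle gene catalog
#'
#' The curated catalog of nitrogen-metabolism gene symbols searched for among
#' viral scaffolds, with KEGG ortholog identifiers and case-insensitive
#' keyword patterns used to codify manual curation of functional annotations.
#' Shipped as an editable TSV so the curation is reproducible.
#'
#' @param path Optional path to an alternative catalog TSV
#'   (columns `symbol`, `ko`, `keywords`).
#' @return A data.frame with one row per gene symbol.
#' @export
ncycle_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ncycle_catalog.tsv",
                        package = "amgkit", mustWork = TRUE)
  }
  cat <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("symbol", "ko", "keywords") %in% names(cat)))
  if (anyDuplicated(cat$symbol)) stop("duplicate symbols in catalog")
  cat
}

#' Reference amino-acid sequences for AMG cassette construction
#'
#' Synthetic stand-in proteins (one per catalog symbol) that the scaffold
#' generator back-translates into real open reading frames. These are
#' artificial sequences bundled so ORF construction needs no database; they
#' are not database proteins.
#'
#' @return Named character vector of amino-acid strings keyed by gene symbol.
#' @export
amg_proteins <- function() {
  path <- system.file("extdata", "amg_proteins_synthetic.tsv",
                      package = "amgkit", mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  setNames(tab$protein, tab$symbol)
}
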