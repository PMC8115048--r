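#' Annotation confidence ranking
#'
#' Functional annotations are ranked A (highest confidence) to E (lowest)
#' from homology-hit tables against KEGG, Uniref90 and InterPro:
#' A = reciprocal best hit (RBH) to KEGG with bitscore > 350;
#' B = RBH to Uniref90 with bitscore > 350;
#' C = one-way hit to Uniref90 (or, as a gap rule, a one-way KEGG hit) with
#' bitscore >= 60; D = hits only to InterPro; E = hits whose best bitscore to
#' any scored database is < 60. Rules apply in order A to E, first match
#' wins; a query with no hits is unranked.
#'
#' @name annotation_ranking
NULL

VALID_DBS <- c("KEGG", "Uniref90", "InterPro")

#' Assign an annotation confidence rank to one query
#'
#' @param hits Data.frame of homology hits for a single query: columns `db`
#'   (KEGG, Uniref90 or InterPro), `bitscore` (NA for InterPro),
#'   `reciprocal` (logical).
#' @return One-row data.frame: `rank` in A-E or "unranked", and `basis`, the
#'   tag of the rule that fired.
#' @export
assign_rank <- function(hits) {
  hits <- as.data.frame(hits)
  if (nrow(hits) == 0) {
    return(data.frame(rank = "unranked", basis = "no-hits",
                      stringsAsFactors = FALSE))
  }
  bad <- setdiff(unique(hits$db), VALID_DBS)
  if (length(bad)) stop("unknown database tag: ", paste(bad, collapse = ", "))
  if (!"reciprocal" %in% names(hits)) hits$reciprocal <- FALSE
  hits$reciprocal[is.na(hits$reciprocal)] <- FALSE
  scored <- hits[hits$db != "InterPro" & !is.na(hits$bitscore), , drop = FALSE]
  if (any(scored$bitscore < 0)) stop("negative bitscore")
  res <- function(rank, basis) data.frame(rank = rank, basis = basis,
                                          stringsAsFactors = FALSE)
  if (any(scored$db == "KEGG" & scored$reciprocal & scored$bitscore > 350)) {
    return(res("A", "kegg-rbh-gt350"))
  }
  if (any(scored$db == "Uniref90" & scored$reciprocal & scored$bitscore > 350)) {
    return(res("B", "uniref90-rbh-gt350"))
  }
  if (any(scored$db == "Uniref90" & scored$bitscore >= 60)) {
    return(res("C", "uniref90-oneway"))
  }
  if (any(scored$db == "KEGG" & scored$bitscore >= 60)) {
    # the source rules leave mid-score KEGG-only hits unstated; treated as
    # one-way database evidence
    return(res("C", "gap-rule"))
  }
  if (nrow(scored) == 0 && any(hits$db == "InterPro")) {
    return(res("D", "interpro-only"))
  }
  res("E", "bitscore-lt60")
}

#' Rank every query in a homology-hit table
#'
#' @param hits_table Data.frame with a `query_id` column plus the columns of
#'   [assign_rank()].
#' @return Data.frame: query_id, rank, basis (one row per query).
#' @export
rank_annotations <- function(hits_table) {
  parts <- split(hits_table, hits_table$query_id)
  out <- do.call(rbind, lapply(names(parts), function(q) {
    cbind(query_id = q, assign_rank(parts[[q]]), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Flag nitrogen-cycle genes among annotated queries
#'
#' Codifies manual curation: a query is flagged for a catalog symbol when its
#' KEGG ortholog identifier matches the symbol's KO, or its annotation text
#' matches the symbol's case-insensitive keyword pattern.
#'
#' @param annotations Data.frame with columns `query_id`, `annotation_text`,
#'   and optionally `ko`.
#' @param catalog N-cycle catalog, see [ncycle_catalog()].
#' @return Sorted, deduplicated data.frame: query_id, symbol.
#' @export
flag_n_cycle <- function(annotations, catalog = ncycle_catalog()) {
  annotations <- as.data.frame(annotations)
  if (!"ko" %in% names(annotations)) annotations$ko <- NA_character_
  out <- list()
  for (i in seq_len(nrow(catalog))) {
    hit <- grepl(catalog$keywords[i], annotations$annotation_text,
                 ignore.case = TRUE, perl = TRUE) |
      (!is.na(annotations$ko) & annotations$ko == catalog$ko[i])
    if (any(hit)) {
      out[[length(out) + 1L]] <- data.frame(
        query_id = annotations$query_id[hit], symbol = catalog$symbol[i],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(query_id = character(0), symbol = character(0)))
  }
  res <- unique(do.call(rbind, out))
  res <- res[order(res$query_id, res$symbol), , drop = FALSE]
  rownames(res) <- NULL
  res
}
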