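#' Viral triage decision rules
#'
#' Scaffolds are called viral from external classifier outputs (VirSorter
#' categories, VirFinder score and p-value) under size-eligibility gates, and
#' gated again at 10 kbp before being reportable for AMG analysis. Classifier
#' internals are never recomputed here; their scores are consumed as tables.
#'
#' @name viral_triage
NULL

#' Detect circularity by terminal direct repeat
#'
#' A scaffold is considered circular when a terminal direct repeat of at
#' least `min_repeat` exact bases joins its ends, i.e. some prefix of length
#' r >= `min_repeat` equals the suffix of the same length.
#'
#' @param sequence Nucleotide string.
#' @param min_repeat Minimum repeat length in bases.
#' @return Logical flag.
#' @export
detect_circularity <- function(sequence, min_repeat = 20) {
  sequence <- as_sequence_vector(sequence)[[1]]
  L <- nchar(sequence)
  if (L < 2 * min_repeat) {
    stop("sequence shorter than twice min_repeat (", min_repeat, ")")
  }
  r <- min_repeat:(L %/% 2)
  any(substring(sequence, 1, r) == substring(sequence, L - r + 1, L))
}

#' Rate of coding-strand switching between consecutive genes
#'
#' Genes are ordered by start coordinate; the rate is the fraction of
#' adjacent gene pairs whose strands differ. A low rate is typical of phage
#' genome architecture and is reported as supporting evidence (no hard
#' cutoff is applied).
#'
#' @param gene_table Data.frame with columns `start` and `strand`.
#' @return Proportion in \[0, 1\]; `NA` (with a warning) for < 2 genes.
#' @export
strand_switch_rate <- function(gene_table) {
  if (nrow(gene_table) < 2) {
    warning("strand switch rate undefined for fewer than 2 genes")
    return(NA_real_)
  }
  s <- gene_table$strand[order(gene_table$start)]
  mean(s[-1] != s[-length(s)])
}

#' Classify scaffolds as viral and gate reportability
#'
#' A scaffold is size-eligible if longer than `size_gate` bases, or circular
#' and longer than `circular_gate` bases. An eligible scaffold is viral if
#' its VirSorter category is 1 or 2, or its VirFinder score exceeds 0.9 with
#' p < 0.05. Viral scaffolds of at least `report_min` bases are reportable
#' for AMG analysis.
#'
#' @param features Data.frame with columns `scaffold_id`, `length`,
#'   `circular`, and optionally `virsorter_category`, `virfinder_score`,
#'   `virfinder_p` (NA when a classifier made no call).
#' @param size_gate Linear size-eligibility gate (strictly greater than).
#' @param circular_gate Circular size-eligibility gate (strictly greater
#'   than).
#' @param report_min Final reporting threshold (at least).
#' @param vf_score_min,vf_p_max VirFinder thresholds (score strictly greater,
#'   p strictly less).
#' @return Data.frame: scaffold_id, is_viral, reportable, reasons (comma-
#'   separated tags of every rule that fired).
#' @export
classify_viral <- function(features, size_gate = 5000, circular_gate = 1500,
                           report_min = 10000, vf_score_min = 0.9,
                           vf_p_max = 0.05) {
  f <- as.data.frame(features)
  for (col in c("virsorter_category", "virfinder_score", "virfinder_p")) {
    if (!col %in% names(f)) f[[col]] <- NA_real_
  }
  ok_cat <- !is.na(f$virsorter_category) & f$virsorter_category %in% c(1, 2)
  ok_vf <- !is.na(f$virfinder_score) & !is.na(f$virfinder_p) &
    f$virfinder_score > vf_score_min & f$virfinder_p < vf_p_max
  size_ok <- f$length > size_gate
  circ_ok <- f$circular & f$length > circular_gate
  eligible <- size_ok | circ_ok
  is_viral <- eligible & (ok_cat | ok_vf)
  reportable <- is_viral & f$length >= report_min
  reasons <- vapply(seq_len(nrow(f)), function(i) {
    tags <- c(
      if (size_ok[i]) "size_gate",
      if (circ_ok[i]) "circular_gate",
      if (!eligible[i]) "too_small",
      if (ok_cat[i]) "virsorter_cat_1_2",
      if (ok_vf[i]) "virfinder_score_p",
      if (eligible[i] && !ok_cat[i] && !ok_vf[i]) "no_classifier_support",
      if (is_viral[i] && !reportable[i]) "below_report_min"
    )
    paste(tags, collapse = ",")
  }, character(1))
  data.frame(scaffold_id = f$scaffold_id, is_viral = is_viral,
             reportable = reportable, reasons = reasons,
             stringsAsFactors = FALSE)
}
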