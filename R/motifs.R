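#' Regulatory motif scanning and positional filters
#'
#' Scans scaffolds for NtcA-binding sites using the consensus adapted for
#' marine cyanobacteria (5'-GTA-N8-TAC-3'), and applies the positional
#' constraint that motif, promoter and terminator calls be intergenic or
#' within 10 bp of an ORF boundary. External promoter (BPROM-style LDF) and
#' terminator (TransTermHP-style percent confidence) calls are consumed as
#' tables and filtered at LDF > 2.75 and confidence > 90.
#'
#' @name regulatory_motifs
NULL

#' Define a fixed-length IUPAC consensus motif
#'
#' @param name Motif name.
#' @param consensus IUPAC nucleotide pattern; `N` matches any base. The
#'   default is the NtcA-binding consensus GTA-N8-TAC.
#' @return An object of class `motif_definition`.
#' @export
motif_definition <- function(name = "NtcA",
                             consensus = "GTANNNNNNNNTAC") {
  consensus <- toupper(consensus)
  valid <- names(Biostrings::IUPAC_CODE_MAP)
  if (!all(seq_chars(consensus) %in% valid)) {
    stop("consensus must be IUPAC nucleotide codes")
  }
  structure(list(name = name, consensus = consensus,
                 width = nchar(consensus)),
            class = "motif_definition")
}

#' Scan a sequence for all (possibly overlapping) motif matches
#'
#' Every window matching the consensus is reported, including overlapping
#' windows. The default NtcA consensus is reverse-complement symmetric, so a
#' forward-strand scan already finds every double-stranded site; scanning
#' `strand = "-"` reports matches on the reverse complement mapped back to
#' forward coordinates.
#'
#' @param sequence Nucleotide string.
#' @param motif A [motif_definition()].
#' @param scaffold_id Identifier recorded in the hits.
#' @param strand `"+"`, `"-"`, or `"both"`.
#' @return Data.frame of hits: scaffold_id, start, end (1-based inclusive),
#'   strand, matched_sequence.
#' @export
scan_motif <- function(sequence, motif = motif_definition(),
                       scaffold_id = "scaffold", strand = "+") {
  stopifnot(inherits(motif, "motif_definition"))
  strand <- match.arg(strand, c("+", "-", "both"))
  sequence <- toupper(as_sequence_vector(sequence)[[1]])
  if (!nzchar(sequence)) stop("sequence must be non-empty")
  if (strand == "both") {
    return(rbind(
      scan_motif(sequence, motif, scaffold_id, "+"),
      scan_motif(sequence, motif, scaffold_id, "-")
    ))
  }
  target <- if (strand == "+") sequence else revcomp(sequence)
  L <- nchar(target)
  w <- motif$width
  empty <- data.frame(scaffold_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      matched_sequence = character(0))
  if (L < w) return(empty)
  ch <- seq_chars(target)
  pat <- seq_chars(motif$consensus)
  ok <- rep(TRUE, L - w + 1L)
  for (j in seq_len(w)) {
    if (pat[j] == "N") next
    allowed <- seq_chars(Biostrings::IUPAC_CODE_MAP[[pat[j]]])
    ok <- ok & ch[seq_len(L - w + 1L) + j - 1L] %in% allowed
  }
  starts <- which(ok)
  if (!length(starts)) return(empty)
  ends <- starts + w - 1L
  matched <- substring(target, starts, ends)
  if (strand == "-") {
    fwd_start <- L - ends + 1L
    fwd_end <- L - starts + 1L
    o <- order(fwd_start)
    starts <- fwd_start[o]; ends <- fwd_end[o]; matched <- matched[o]
  }
  data.frame(scaffold_id = scaffold_id, start = starts, end = ends,
             strand = strand, matched_sequence = matched,
             stringsAsFactors = FALSE)
}

# distance from either end of [s, e] to the nearest boundary of gene [gs, ge]
edge_distance <- function(s, e, gs, ge) {
  pmin(abs(s - gs), abs(s - ge), abs(e - gs), abs(e - ge))
}

#' Flag hits as intergenic or boundary-proximal
#'
#' A hit passes the positional constraint when it lies wholly outside all
#' genes, or, for every gene it overlaps, one of its ends lies within `slack`
#' bases of that gene's start or stop boundary.
#'
#' @param hits Data.frame with `start`, `end` (and optionally `scaffold_id`)
#'   columns, e.g. from [scan_motif()].
#' @param gene_table Data.frame with `start`, `end` (1-based inclusive) and,
#'   when hits span several scaffolds, `scaffold_id`.
#' @param slack Distance in bases (inclusive) from an ORF boundary.
#' @return `hits` with a logical `positional_ok` column added.
#' @export
apply_positional_filter <- function(hits, gene_table, slack = 10) {
  hits <- as.data.frame(hits)
  genes <- as.data.frame(gene_table)
  by_scaffold <- "scaffold_id" %in% names(hits) &&
    "scaffold_id" %in% names(genes)
  hits$positional_ok <- vapply(seq_len(nrow(hits)), function(i) {
    g <- if (by_scaffold) {
      genes[genes$scaffold_id == hits$scaffold_id[i], , drop = FALSE]
    } else genes
    ov <- g$start <= hits$end[i] & g$end >= hits$start[i]
    if (!any(ov)) return(TRUE)
    all(edge_distance(hits$start[i], hits$end[i],
                      g$start[ov], g$end[ov]) <= slack)
  }, logical(1))
  hits
}

#' Filter external promoter and terminator calls
#'
#' Promoters are kept when their linear discriminant score exceeds `ldf_min`;
#' terminators when their percent confidence exceeds `conf_min` (both strict).
#' Surviving calls are then subjected to the positional constraint. A
#' promoter score that looks percent-scaled, or a terminator score that looks
#' LDF-scaled, triggers a unit-mismatch warning.
#'
#' @param calls Data.frame with columns `kind` ("promoter"/"terminator"),
#'   `position` (1-based), `score`, and optionally `scaffold_id`, `source`.
#' @param gene_table Gene table for the positional filter.
#' @param ldf_min Promoter LDF threshold.
#' @param conf_min Terminator percent-confidence threshold.
#' @param slack Positional slack in bases.
#' @return The calls that pass both filters, with `positional_ok` set.
#' @export
filter_external_calls <- function(calls, gene_table, ldf_min = 2.75,
                                  conf_min = 90, slack = 10) {
  calls <- as.data.frame(calls)
  stopifnot(all(calls$kind %in% c("promoter", "terminator")),
            !anyNA(calls$score))
  prom <- calls$kind == "promoter"
  if (any(prom & calls$score > 30)) {
    warning("promoter score(s) look percent-scaled, expected LDF units")
  }
  if (any(!prom & calls$score <= 30)) {
    warning("terminator score(s) look LDF-scaled, expected percent confidence")
  }
  keep <- (prom & calls$score > ldf_min) | (!prom & calls$score > conf_min)
  kept <- calls[keep, , drop = FALSE]
  if (nrow(kept) == 0) {
    kept$positional_ok <- logical(0)
    return(kept)
  }
  kept$start <- kept$position
  kept$end <- kept$position
  kept <- apply_positional_filter(kept, gene_table, slack)
  kept <- kept[kept$positional_ok, , drop = FALSE]
  kept$start <- NULL
  kept$end <- NULL
  rownames(kept) <- NULL
  kept
}
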