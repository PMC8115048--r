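#' Abundance profiling from read alignments
#'
#' Per-scaffold coverage is summarized by the trimmed ("tp") mean of per-base
#' depths, normalized for metagenome size, and reported only for populations
#' detected at >= 80% breadth and >= 5x trimmed-mean depth.
#'
#' @name abundance_profiling
NULL

#' Per-base depth profiles from alignment placements
#'
#' Depth at each base is the number of reads whose aligned span covers it.
#' Input is either a placement table (`scaffold_id`, `start`, `end`) such as
#' the simulator emits, or a path to a plain-text SAM file (see
#' [read_sam_placements()]); secondary and supplementary SAM alignments are
#' excluded.
#'
#' @param alignments Placement data.frame or path to a SAM file.
#' @param scaffold_lengths Named vector of scaffold lengths.
#' @return Named list of integer depth vectors, one per scaffold (scaffolds
#'   without any alignment get all-zero profiles).
#' @export
depth_from_alignments <- function(alignments, scaffold_lengths) {
  if (is.character(alignments) && length(alignments) == 1) {
    alignments <- read_sam_placements(alignments)
  }
  stopifnot(all(c("scaffold_id", "start", "end") %in% names(alignments)))
  unknown <- setdiff(unique(alignments$scaffold_id), names(scaffold_lengths))
  if (length(unknown)) {
    stop("alignments reference unknown scaffolds: ",
         paste(unknown, collapse = ", "))
  }
  out <- lapply(names(scaffold_lengths), function(scf) {
    L <- scaffold_lengths[[scf]]
    al <- alignments[alignments$scaffold_id == scf, , drop = FALSE]
    if (any(al$start < 1 | al$end > L)) {
      stop("alignment beyond scaffold end on ", scf)
    }
    delta <- integer(L + 1L)
    inc <- tabulate(al$start, nbins = L)
    dec <- tabulate(al$end + 1L, nbins = L + 1L)
    cumsum(inc - dec[seq_len(L)])
  })
  setNames(out, names(scaffold_lengths))
}

#' Read alignment placements from a plain-text SAM file
#'
#' Minimal SAM support for computing coverage: unmapped (0x4), secondary
#' (0x100) and supplementary (0x800) records are dropped and the reference
#' span is derived from the CIGAR string (M/D/N/=/X consume reference).
#'
#' @param path Path to a SAM file.
#' @return Placement data.frame: read_id, scaffold_id, start, end, strand.
#' @export
read_sam_placements <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  rows <- lapply(fields, function(f) {
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 0x4L) || bitwAnd(flag, 0x100L) || bitwAnd(flag, 0x800L)) {
      return(NULL)
    }
    cig <- f[6]
    ops <- regmatches(cig, gregexpr("[0-9]+[MIDNSHP=X]", cig))[[1]]
    n <- as.integer(sub("[A-Z=]$", "", ops))
    op <- sub("^[0-9]+", "", ops)
    span <- sum(n[op %in% c("M", "D", "N", "=", "X")])
    start <- as.integer(f[4])
    data.frame(read_id = f[1], scaffold_id = f[3], start = start,
               end = start + span - 1L,
               strand = if (bitwAnd(flag, 0x10L)) "-" else "+",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(read_id = character(0), scaffold_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0))
  }
  out
}

#' Trimmed-mean depth ("tpmean")
#'
#' The mean of per-base depths after removing the `trim_fraction` lowest and
#' `trim_fraction` highest positions (by sorted depth; the trim count is
#' rounded down).
#'
#' @param depths Integer/numeric vector of per-base depths.
#' @param trim_fraction Fraction trimmed from each end (default 0.10).
#' @return Trimmed mean fold-coverage.
#' @export
tpmean <- function(depths, trim_fraction = 0.10) {
  stopifnot(length(depths) > 0, trim_fraction >= 0, trim_fraction < 0.5)
  k <- floor(length(depths) * trim_fraction)
  s <- sort(depths)
  if (k > 0) s <- s[(k + 1):(length(s) - k)]
  mean(s)
}

#' Detection rule and metagenome-size normalization
#'
#' Breadth is the fraction of positions covered by at least one read. A
#' scaffold is detected in a sample when breadth >= `min_breadth` and trimmed
#' mean depth >= `min_tpmean`. Normalized coverage is tpmean per gigabase of
#' sample sequencing: tpmean x 1e9 / `sample_total_bases`.
#'
#' @param depths Per-base depth vector for one scaffold in one sample.
#' @param sample_total_bases Total sequenced bases in the sample (> 0).
#' @param scaffold_id,sample_id Identifiers for the output record.
#' @param min_breadth,min_tpmean Detection thresholds (defaults 0.80 and 5).
#' @param trim_fraction Passed to [tpmean()].
#' @param norm_constant Normalization constant (default 1e9, i.e. per Gb).
#' @return One-row data.frame: scaffold_id, sample_id, tpmean_depth, breadth,
#'   normalized_coverage, detected.
#' @export
detect_and_normalize <- function(depths, sample_total_bases,
                                 scaffold_id = "scaffold",
                                 sample_id = "sample",
                                 min_breadth = 0.80, min_tpmean = 5,
                                 trim_fraction = 0.10, norm_constant = 1e9) {
  stopifnot(sample_total_bases > 0)
  tp <- tpmean(depths, trim_fraction)
  breadth <- mean(depths >= 1)
  data.frame(scaffold_id = scaffold_id, sample_id = sample_id,
             tpmean_depth = tp, breadth = breadth,
             normalized_coverage = tp * norm_constant / sample_total_bases,
             detected = breadth >= min_breadth && tp >= min_tpmean,
             stringsAsFactors = FALSE)
}

#' Scaffold-by-sample abundance matrix
#'
#' Long-format records from [detect_and_normalize()] are reshaped into a
#' matrix (rows scaffolds, columns samples); non-detected entries carry 0.
#'
#' @param records Data.frame of abundance records.
#' @return Numeric matrix of normalized coverages.
#' @export
abundance_matrix <- function(records) {
  scf <- sort(unique(records$scaffold_id))
  smp <- sort(unique(records$sample_id))
  m <- matrix(0, length(scf), length(smp), dimnames = list(scf, smp))
  kept <- records[records$detected, , drop = FALSE]
  m[cbind(match(kept$scaffold_id, scf), match(kept$sample_id, smp))] <-
    kept$normalized_coverage
  m
}
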