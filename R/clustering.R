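#' Viral population clustering
#'
#' Average nucleotide identity (ANI) between scaffolds is estimated from
#' consolidated ungapped local alignments found by seed-and-extend: exact
#' k-mer anchors shared by the two sequences (both strands) are grouped by
#' alignment diagonal, extended with an X-drop rule, and the resulting
#' segments are consolidated so each position of the shorter sequence is
#' counted once. Populations are then formed by greedy longest-first centroid
#' clustering at >= 95% ANI over >= 80% of the shorter sequence.
#'
#' @name population_clustering
NULL

# X-drop extension: how far into `eqv` (logical match vector, walking outward)
# the alignment should extend. Match +1, mismatch -3; stop when the running
# score drops `xdrop` below its maximum; extend to the best-scoring prefix.
xdrop_extent <- function(eqv, xdrop) {
  if (!length(eqv)) return(0L)
  sc <- cumsum(ifelse(eqv, 1L, -3L))
  drop_at <- which(sc - cummax(sc) <= -xdrop)[1]
  lim <- if (is.na(drop_at)) length(eqv) else drop_at - 1L
  if (lim == 0L) return(0L)
  best <- which.max(sc[seq_len(lim)])
  if (sc[best] <= 0L) 0L else best
}

# ungapped local segments between character vectors `ach` and `bch` (already
# oriented); returns a matrix with a-coordinates, the diagonal offset
# d = a_pos - b_pos, and match counts. N never counts as a match.
diagonal_segments <- function(ach, bch, k, min_match, xdrop, max_gap = 200L) {
  La <- length(ach); Lb <- length(bch)
  if (La < k || Lb < k) return(NULL)
  kA <- kmerize(paste(ach, collapse = ""), k)
  kB <- kmerize(paste(bch, collapse = ""), k)
  kA[grepl("N", kA, fixed = TRUE)] <- NA
  kB[grepl("N", kB, fixed = TRUE)] <- NA
  m <- match(kA, kB, incomparables = NA)
  ia <- which(!is.na(m)); ib <- m[ia]
  if (!length(ia)) return(NULL)
  segs <- list()
  for (d in unique(ia - ib)) {
    pa <- sort(ia[ia - ib == d])
    a0 <- max(1L, 1L + d); a1 <- min(La, Lb + d)
    eq <- ach[a0:a1] == bch[(a0:a1) - d] & ach[a0:a1] != "N"
    grp <- cumsum(c(1L, diff(pa) > max_gap))
    for (g in split(pa, grp)) {
      s <- min(g) - a0 + 1L
      e <- max(g) + k - 1L - a0 + 1L
      extl <- xdrop_extent(rev(eq[seq_len(s - 1L)]), xdrop)
      extr <- if (e < length(eq)) xdrop_extent(eq[(e + 1L):length(eq)], xdrop)
              else 0L
      span_s <- s - extl; span_e <- e + extr
      if (span_e - span_s + 1L < min_match) next
      segs[[length(segs) + 1L]] <- c(a_start = a0 + span_s - 1L,
                                     a_end = a0 + span_e - 1L,
                                     d = d,
                                     matches = sum(eq[span_s:span_e]))
    }
  }
  if (!length(segs)) NULL else do.call(rbind, segs)
}

# count each position of the consolidation axis once; overlapping segments
# are trimmed and their matches scaled by the fraction kept
consolidate_segments <- function(segs) {
  segs <- segs[order(segs[, "start"]), , drop = FALSE]
  covered_end <- 0; cols <- 0; matches <- 0
  for (i in seq_len(nrow(segs))) {
    s <- max(unname(segs[i, "start"]), covered_end + 1)
    e <- unname(segs[i, "end"])
    if (s > e) next
    frac <- (e - s + 1) / (e - unname(segs[i, "start"]) + 1)
    cols <- cols + (e - s + 1)
    matches <- matches + unname(segs[i, "matches"]) * frac
    covered_end <- e
  }
  c(cols = unname(cols), matches = unname(matches))
}

#' Pairwise average nucleotide identity between two scaffolds
#'
#' @param seq_a,seq_b Nucleotide strings (or length-1 DNAStringSet).
#' @param id_a,id_b Optional scaffold identifiers for the output record.
#' @param k Anchor k-mer size.
#' @param min_match Minimum aligned segment length kept; spurious short
#'   anchor hits between unrelated sequences fall below this.
#' @param xdrop X-drop threshold for ungapped extension.
#' @return A one-row data.frame: `id_a`, `id_b`, `ani` (percent identity over
#'   aligned columns, `NA` when nothing aligns), `aligned_length`,
#'   `shorter_length`, `aligned_fraction_shorter`.
#' @export
pairwise_ani <- function(seq_a, seq_b, id_a = "a", id_b = "b",
                         k = 13, min_match = 65, xdrop = 20) {
  a <- toupper(as_sequence_vector(seq_a)[[1]])
  b <- toupper(as_sequence_vector(seq_b)[[1]])
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  if (grepl("^N*$", a) || grepl("^N*$", b)) {
    stop("undefined ANI: sequence contains only N characters")
  }
  La <- nchar(a); Lb <- nchar(b)
  shorter <- min(La, Lb)
  ach <- seq_chars(a)
  proj <- list()
  for (strand in c("+", "-")) {
    bo <- if (strand == "+") b else revcomp(b)
    segs <- diagonal_segments(ach, seq_chars(bo), k, min_match, xdrop)
    if (is.null(segs)) next
    for (i in seq_len(nrow(segs))) {
      as_ <- unname(segs[i, "a_start"]); ae <- unname(segs[i, "a_end"])
      d <- unname(segs[i, "d"])
      if (La <= Lb) {
        s <- as_; e <- ae
      } else {
        bs <- as_ - d; be <- ae - d          # coords on oriented b
        if (strand == "-") { tmp <- bs; bs <- Lb - be + 1L; be <- Lb - tmp + 1L }
        s <- bs; e <- be
      }
      proj[[length(proj) + 1L]] <- c(start = s, end = e,
                                     matches = unname(segs[i, "matches"]))
    }
  }
  if (!length(proj)) {
    res <- c(cols = 0, matches = 0)
  } else {
    res <- consolidate_segments(do.call(rbind, proj))
  }
  data.frame(id_a = id_a, id_b = id_b,
             ani = if (res[["cols"]] > 0)
               100 * res[["matches"]] / res[["cols"]] else NA_real_,
             aligned_length = unname(res[["cols"]]),
             shorter_length = shorter,
             aligned_fraction_shorter = unname(res[["cols"]]) / shorter,
             stringsAsFactors = FALSE)
}

greedy_clusters <- function(ids, lengths, edge_fun, ani_min, cov_min) {
  ord <- order(-lengths[ids], ids)
  reps <- character(0)
  assignment <- character(0)
  for (x in ids[ord]) {
    joined <- NA_character_
    for (r in reps) {
      e <- edge_fun(x, r)
      if (!is.null(e) && !is.na(e$ani) && e$ani >= ani_min &&
          e$aligned_fraction_shorter >= cov_min) {
        joined <- r
        break
      }
    }
    if (is.na(joined)) {
      reps <- c(reps, x)
      assignment[x] <- x
    } else {
      assignment[x] <- joined
    }
  }
  cluster_id <- setNames(sprintf("pop_%03d", seq_along(reps)), reps)
  data.frame(scaffold_id = names(assignment),
             cluster_id = unname(cluster_id[assignment]),
             representative_id = unname(assignment),
             is_representative = names(assignment) == assignment,
             length = unname(lengths[names(assignment)]),
             stringsAsFactors = FALSE)
}

#' Cluster scaffolds into populations from precomputed alignment summaries
#'
#' Greedy longest-first centroid clustering: scaffolds are visited in order of
#' decreasing length (ties broken lexicographically by id); each joins the
#' first existing cluster whose representative it matches at `ani >= ani_min`
#' and `aligned_fraction_shorter >= cov_min`, otherwise it founds a new
#' cluster. The representative is always the longest member.
#'
#' @param summaries Data.frame of pairwise summaries as produced by
#'   [pairwise_ani()] (a sparse edge list is fine; absent pairs are treated
#'   as non-matching).
#' @param lengths Named vector of scaffold lengths (defines the scaffold set).
#' @param ani_min Minimum percent identity (default 95).
#' @param cov_min Minimum aligned fraction of the shorter sequence (0.80).
#' @return Data.frame: scaffold_id, cluster_id, representative_id,
#'   is_representative, length.
#' @export
cluster_populations <- function(summaries, lengths, ani_min = 95,
                                cov_min = 0.80) {
  if (anyDuplicated(names(lengths))) stop("duplicate scaffold ids")
  key <- function(x, y) paste(pmin(x, y), pmax(x, y), sep = "\r")
  edges <- split(summaries, key(summaries$id_a, summaries$id_b))
  edge_fun <- function(x, r) {
    e <- edges[[key(x, r)]]
    if (is.null(e)) NULL else e[1, ]
  }
  greedy_clusters(names(lengths), lengths, edge_fun, ani_min, cov_min)
}

#' Cluster scaffolds into populations directly from sequences
#'
#' Convenience wrapper computing [pairwise_ani()] on demand (only against
#' current cluster representatives, as the greedy pass requires).
#'
#' @param sequences Named character vector or DNAStringSet.
#' @inheritParams cluster_populations
#' @param ... Passed to [pairwise_ani()].
#' @return See [cluster_populations()].
#' @export
cluster_scaffolds <- function(sequences, ani_min = 95, cov_min = 0.80, ...) {
  sequences <- as_sequence_vector(sequences)
  if (anyDuplicated(names(sequences))) stop("duplicate scaffold ids")
  lengths <- setNames(nchar(sequences), names(sequences))
  edge_fun <- function(x, r) {
    pairwise_ani(sequences[[x]], sequences[[r]], id_a = x, id_b = r, ...)
  }
  greedy_clusters(names(sequences), lengths, edge_fun, ani_min, cov_min)
}

#' Retention rule for density-gradient (CsCl) purified scaffolds
#'
#' A scaffold derived from a CsCl-purified sample is retained only if it is
#' the longest representative sequence of its population cluster; scaffolds
#' from other samples are always retained.
#'
#' @param clusters Clustering table from [cluster_populations()].
#' @param cscl_ids Character vector of scaffold ids that came from
#'   CsCl-purified samples.
#' @return Character vector of retained scaffold ids.
#' @export
apply_cscl_retention <- function(clusters, cscl_ids) {
  keep <- !(clusters$scaffold_id %in% cscl_ids) | clusters$is_representative
  clusters$scaffold_id[keep]
}

# best single diagonal between two oriented sequences (most anchor support);
# Ns are wildcards here because overlap merging fills them from the partner
best_overlap_diagonal <- function(a, b, k = 13) {
  kA <- kmerize(a, k); kB <- kmerize(b, k)
  kA[grepl("N", kA, fixed = TRUE)] <- NA
  kB[grepl("N", kB, fixed = TRUE)] <- NA
  m <- match(kA, kB, incomparables = NA)
  ia <- which(!is.na(m))
  if (!length(ia)) return(NULL)
  d_tab <- table(ia - m[ia])
  list(d = as.integer(names(d_tab)[which.max(d_tab)]),
       support = max(d_tab))
}

#' Merge scaffolds that share an AMG over a long, near-identical overlap
#'
#' Scaffold pairs assigned the same AMG symbol are merged when they share an
#' overlapping region longer than `min_overlap` bases at `>= min_identity`
#' percent identity (N positions are treated as fillable, not mismatches).
#' The merged sequence is the overlap-consistent union; N gaps in the overlap
#' are replaced by the partner's base where available. Merged sequences carry
#' a terminal "E" in their identifier.
#'
#' @param sequences Named character vector or DNAStringSet of scaffolds.
#' @param amg_assignments Data.frame with columns `scaffold_id`, `amg_symbol`.
#' @param min_overlap Minimum overlap length in bases (merge requires
#'   overlap strictly greater than this).
#' @param min_identity Minimum percent identity over the overlap.
#' @return A list: `sequences` (merged entries replace their sources) and
#'   `records` (one row per attempted merge: merged_id, source_ids,
#'   overlap_length, overlap_identity, n_gap_filled, merged, reason).
#' @export
merge_amg_scaffolds <- function(sequences, amg_assignments,
                                min_overlap = 1000, min_identity = 99) {
  sequences <- as_sequence_vector(sequences)
  out <- sequences
  records <- list()
  for (sym in unique(amg_assignments$amg_symbol)) {
    ids <- amg_assignments$scaffold_id[amg_assignments$amg_symbol == sym]
    ids <- ids[ids %in% names(out)]
    if (length(ids) < 2) next
    cur_id <- ids[1]
    for (nxt in ids[-1]) {
      res <- try_merge(out[[cur_id]], out[[nxt]], cur_id, nxt,
                       min_overlap, min_identity)
      records[[length(records) + 1L]] <- res$record
      if (res$merged) {
        out <- out[setdiff(names(out), c(cur_id, nxt))]
        out[res$record$merged_id] <- res$sequence
        cur_id <- res$record$merged_id
      }
    }
  }
  list(sequences = out,
       records = if (length(records)) do.call(rbind, records) else NULL)
}

try_merge <- function(a, b, id_a, id_b, min_overlap, min_identity) {
  rec <- function(merged, overlap_len = 0, ident = NA_real_, filled = 0,
                  reason = "", merged_id = NA_character_) {
    data.frame(merged_id = merged_id,
               source_ids = paste(id_a, id_b, sep = ","),
               overlap_length = overlap_len, overlap_identity = ident,
               n_gap_filled = filled, merged = merged, reason = reason,
               stringsAsFactors = FALSE)
  }
  La <- nchar(a); Lb <- nchar(b)
  best <- NULL
  for (strand in c("+", "-")) {
    bo <- if (strand == "+") b else revcomp(b)
    diag <- best_overlap_diagonal(a, bo)
    if (is.null(diag)) next
    d <- diag$d
    a0 <- max(1L, 1L + d); a1 <- min(La, Lb + d)
    if (is.null(best) || diag$support > best$support) {
      best <- list(strand = strand, bo = bo, d = d, a0 = a0, a1 = a1,
                   support = diag$support)
    }
  }
  if (is.null(best)) {
    return(list(merged = FALSE, record = rec(FALSE, reason = "no shared anchors")))
  }
  ach <- seq_chars(a); bch <- seq_chars(best$bo)
  ia <- best$a0:best$a1; ib <- ia - best$d
  an <- ach[ia] == "N"; bn <- bch[ib] == "N"
  eq <- ach[ia] == bch[ib] | an | bn
  overlap_len <- length(ia)
  ident <- 100 * sum(eq) / overlap_len
  if (overlap_len <= min_overlap) {
    return(list(merged = FALSE,
                record = rec(FALSE, overlap_len, ident,
                             reason = sprintf("overlap %d <= %d bases",
                                              overlap_len, min_overlap))))
  }
  if (ident < min_identity) {
    return(list(merged = FALSE,
                record = rec(FALSE, overlap_len, ident,
                             reason = sprintf("overlap identity %.2f%% < %s%%",
                                              ident, min_identity))))
  }
  # gap-fill the overlap: take the partner's base wherever one side has N
  fill_a <- an & !bn
  ach[ia[fill_a]] <- bch[ib[fill_a]]
  n_filled <- sum(fill_a)
  fill_b <- bn & !an
  bch[ib[fill_b]] <- ach[ia[fill_b]]
  n_filled <- n_filled + sum(fill_b)
  # overlap-consistent union
  d <- best$d
  merged <- if (d >= 0) {
    if (Lb + d > La) c(ach, bch[(La - d + 1L):Lb]) else ach
  } else {
    if (La - d < Lb) c(bch[seq_len(-d)], ach, bch[(La - d + 1L):Lb])
    else c(bch[seq_len(-d)], ach)
  }
  merged_id <- paste0(sub("E$", "", id_a), "E")
  list(merged = TRUE, sequence = paste(merged, collapse = ""),
       record = rec(TRUE, overlap_len, ident, n_filled,
                    reason = "merged", merged_id = merged_id))
}
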