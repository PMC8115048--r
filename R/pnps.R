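#' Selection analysis: pN/pS from pileups over coding sequences
#'
#' Population-level polymorphism rates are computed per gene from read
#' pileups: observed synonymous and non-synonymous SNPs are normalized by the
#' expected numbers of synonymous and non-synonymous sites in the reference
#' coding sequence (per codon position, the synonymous fraction is the number
#' of the 3 alternative bases preserving the amino acid divided by 3). A
#' defined ratio below 0.3 is interpreted as strong purifying selection, and
#' results are suppressed for genes whose minimum per-site coverage is not
#' above the coverage gate (default 10x). No coverage downsampling is
#' performed.
#'
#' @name selection_pnps
NULL

# per-codon synonymous site fractions at each codon position, computed once
codon_site_fractions <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    gc <- Biostrings::GENETIC_CODE
    sense <- names(gc)[gc != "*"]
    tab <- matrix(0, length(sense), 3, dimnames = list(sense, NULL))
    for (cod in sense) {
      for (p in 1:3) {
        ref_b <- substr(cod, p, p)
        n_syn <- 0L
        for (alt in setdiff(DNA_BASES, ref_b)) {
          alt_cod <- cod
          substr(alt_cod, p, p) <- alt
          if (gc[[alt_cod]] == gc[[cod]]) n_syn <- n_syn + 1L
        }
        tab[cod, p] <- n_syn / 3
      }
    }
    cache <<- tab
    cache
  }
})

split_codons <- function(cds) {
  substring(cds, seq(1, nchar(cds) - 2, by = 3), seq(3, nchar(cds), by = 3))
}

#' Expected synonymous and non-synonymous site counts of a CDS
#'
#' @param cds Reference coding sequence; length must be divisible by 3 with
#'   no internal stop codon. A terminal stop codon is allowed but excluded
#'   from the totals.
#' @param gene_id Identifier attached to the result.
#' @return A list of class `codon_site_table`: `gene_id`, `per_codon`
#'   (data.frame codon, N_sites, S_sites) and totals `N_sites`, `S_sites`
#'   (N + S = 3 per sense codon).
#' @export
expected_sites <- function(cds, gene_id = "gene") {
  cds <- toupper(as_sequence_vector(cds)[[1]])
  if (nchar(cds) %% 3 != 0) stop("CDS length not divisible by 3")
  codons <- split_codons(cds)
  gc <- Biostrings::GENETIC_CODE
  if (!all(codons %in% names(gc))) stop("CDS contains ambiguous codons")
  aa <- gc[codons]
  if (any(aa[-length(aa)] == "*")) stop("internal stop codon in CDS")
  keep <- aa != "*"
  frac <- codon_site_fractions()
  s_per <- rowSums(frac[codons[keep], , drop = FALSE])
  per_codon <- data.frame(codon_index = which(keep), codon = codons[keep],
                          S_sites = unname(s_per),
                          N_sites = 3 - unname(s_per),
                          stringsAsFactors = FALSE)
  structure(list(gene_id = gene_id, per_codon = per_codon,
                 S_sites = sum(per_codon$S_sites),
                 N_sites = sum(per_codon$N_sites)),
            class = "codon_site_table")
}

complement_pileup <- function(p) {
  out <- p[rev(seq_len(nrow(p))), , drop = FALSE]
  tmp <- out$A; out$A <- out$T; out$T <- tmp
  tmp <- out$C; out$C <- out$G; out$G <- tmp
  out$ref <- unname(COMPLEMENT[out$ref])
  out$pos <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Base-count pileup over a scaffold from simulated or placed reads
#'
#' @param reads Data.frame with `start`, `end`, `seq` (reference-oriented)
#'   and `scaffold_id` columns, as produced by [simulate_reads()].
#' @param scaffold_id Scaffold to pile up.
#' @param reference Scaffold reference sequence (for the `ref` column).
#' @return Pileup data.frame: pos, ref, A, C, G, T.
#' @export
pileup_from_reads <- function(reads, scaffold_id, reference) {
  reference <- as_sequence_vector(reference)[[1]]
  L <- nchar(reference)
  rd <- reads[reads$scaffold_id == scaffold_id, , drop = FALSE]
  if (any(rd$end > L | rd$start < 1)) stop("read beyond scaffold end")
  counts <- matrix(0L, L, 4, dimnames = list(NULL, DNA_BASES))
  if (nrow(rd)) {
    pos <- unlist(Map(seq.int, rd$start, rd$end), use.names = FALSE)
    base <- unlist(strsplit(rd$seq, "", fixed = TRUE), use.names = FALSE)
    ok <- base %in% DNA_BASES
    idx <- cbind(pos[ok], match(base[ok], DNA_BASES))
    for (b in 1:4) {
      sel <- idx[idx[, 2] == b, 1]
      counts[, b] <- tabulate(sel, nbins = L)
    }
  }
  data.frame(pos = seq_len(L), ref = seq_chars(reference),
             A = counts[, "A"], C = counts[, "C"], G = counts[, "G"],
             T = counts[, "T"], stringsAsFactors = FALSE)
}

#' Extract a gene's pileup in CDS coordinates
#'
#' Subsets a scaffold pileup to a gene's span; for minus-strand genes the
#' rows are reversed and base counts complemented so positions and alleles
#' are reported on the coding strand.
#'
#' @param pileup Scaffold pileup from [pileup_from_reads()].
#' @param start,end Gene span (1-based inclusive, genomic).
#' @param strand `"+"` or `"-"`.
#' @return Pileup data.frame in CDS coordinates.
#' @export
gene_pileup <- function(pileup, start, end, strand = "+") {
  if (end > max(pileup$pos) || start < 1) stop("gene outside pileup range")
  p <- pileup[pileup$pos >= start & pileup$pos <= end, , drop = FALSE]
  p <- p[order(p$pos), , drop = FALSE]
  p$pos <- seq_len(nrow(p))
  rownames(p) <- NULL
  if (strand == "-") complement_pileup(p) else p
}

#' Call population SNPs from a CDS pileup
#'
#' A site is a SNP when its depth is at least `min_site_depth` and some
#' alternate allele reaches both `min_alt_fraction` of the depth and
#' `min_alt_reads` supporting reads. Every qualifying alternate allele is
#' reported (multi-allelic sites yield one call per allele, majority allele
#' first). Classification translates the reference codon with only that
#' substitution applied; substitutions creating a stop codon count as
#' non-synonymous.
#'
#' @param pileup CDS-coordinate pileup (see [gene_pileup()]).
#' @param cds Reference coding sequence the pileup is aligned to.
#' @param gene_id Identifier for the calls.
#' @param min_site_depth,min_alt_fraction,min_alt_reads SNP-calling
#'   thresholds.
#' @return Data.frame of variant calls: gene_id, cds_position, ref_base,
#'   alt_base, depth, alt_fraction, classification.
#' @export
call_variants <- function(pileup, cds, gene_id = "gene",
                          min_site_depth = 10, min_alt_fraction = 0.01,
                          min_alt_reads = 2) {
  cds <- toupper(as_sequence_vector(cds)[[1]])
  if (max(pileup$pos) > nchar(cds)) stop("pileup column beyond CDS")
  gc <- Biostrings::GENETIC_CODE
  out <- list()
  counts <- as.matrix(pileup[, DNA_BASES])
  depth <- rowSums(counts)
  for (i in seq_len(nrow(pileup))) {
    if (depth[i] < min_site_depth) next
    cpos <- pileup$pos[i]
    ref_b <- substr(cds, cpos, cpos)
    alts <- setdiff(DNA_BASES, ref_b)
    ac <- counts[i, alts]
    qual <- ac >= min_alt_reads & ac / depth[i] >= min_alt_fraction
    if (!any(qual)) next
    for (alt in alts[qual][order(-ac[qual])]) {
      ci <- (cpos - 1L) %/% 3L
      cod <- substr(cds, ci * 3L + 1L, ci * 3L + 3L)
      alt_cod <- cod
      substr(alt_cod, (cpos - 1L) %% 3L + 1L, (cpos - 1L) %% 3L + 1L) <- alt
      cls <- if (gc[[alt_cod]] == gc[[cod]]) "synonymous" else "nonsynonymous"
      out[[length(out) + 1L]] <- data.frame(
        gene_id = gene_id, cds_position = cpos, ref_base = ref_b,
        alt_base = alt, depth = unname(depth[i]),
        alt_fraction = unname(counts[i, alt] / depth[i]),
        classification = cls, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(gene_id = character(0), cds_position = integer(0),
                      ref_base = character(0), alt_base = character(0),
                      depth = integer(0), alt_fraction = numeric(0),
                      classification = character(0)))
  }
  do.call(rbind, out)
}

#' pN/pS from variant calls and expected site counts
#'
#' pN = observed non-synonymous SNPs / expected non-synonymous sites;
#' pS likewise for synonymous. The ratio pN/pS is 0 when no non-synonymous
#' SNP is observed but synonymous ones are; it is undefined (NA, flagged)
#' when no synonymous SNP is observed. A defined ratio below
#' `purifying_threshold` flags strong purifying selection.
#'
#' @param gene_id Gene identifier.
#' @param variants Variant calls from [call_variants()].
#' @param site_table Expected site counts from [expected_sites()].
#' @param min_gene_coverage Minimum per-site depth across the CDS, if known
#'   (reported; results should be gated at > 10x upstream).
#' @param purifying_threshold Ratio below which purifying selection is
#'   flagged.
#' @return One-row data.frame: gene_id, n_obs, s_obs, N_sites, S_sites, pN,
#'   pS, ratio, n_snps, min_gene_coverage, ratio_defined, purifying.
#' @export
pnps <- function(gene_id, variants, site_table,
                 min_gene_coverage = NA_real_, purifying_threshold = 0.3) {
  stopifnot(inherits(site_table, "codon_site_table"))
  n_obs <- sum(variants$classification == "nonsynonymous")
  s_obs <- sum(variants$classification == "synonymous")
  pN <- n_obs / site_table$N_sites
  pS <- s_obs / site_table$S_sites
  ratio <- if (s_obs == 0) NA_real_ else pN / pS
  data.frame(gene_id = gene_id, n_obs = n_obs, s_obs = s_obs,
             N_sites = site_table$N_sites, S_sites = site_table$S_sites,
             pN = pN, pS = pS, ratio = ratio, n_snps = n_obs + s_obs,
             min_gene_coverage = min_gene_coverage,
             ratio_defined = !is.na(ratio),
             purifying = !is.na(ratio) && ratio < purifying_threshold,
             stringsAsFactors = FALSE)
}

#' End-to-end pN/pS for one gene from a CDS pileup
#'
#' Runs [call_variants()] and [pnps()] and reports the minimum per-site depth
#' across the CDS. When that minimum is not above `coverage_gate`, the
#' statistics are suppressed (returned as NA, not zero), mirroring the
#' requirement that pN/pS be computed only from samples with minimal gene
#' coverage above 10x.
#'
#' @inheritParams call_variants
#' @param coverage_gate Minimum-coverage gate (strictly greater than).
#' @param purifying_threshold See [pnps()].
#' @return One-row data.frame as in [pnps()] plus a `suppressed` flag.
#' @export
pnps_from_pileup <- function(pileup, cds, gene_id = "gene",
                             min_site_depth = 10, min_alt_fraction = 0.01,
                             min_alt_reads = 2, coverage_gate = 10,
                             purifying_threshold = 0.3) {
  st <- expected_sites(cds, gene_id)
  min_cov <- min(rowSums(pileup[, DNA_BASES]))
  res <- pnps(gene_id,
              call_variants(pileup, cds, gene_id, min_site_depth,
                            min_alt_fraction, min_alt_reads),
              st, min_gene_coverage = min_cov,
              purifying_threshold = purifying_threshold)
  res$suppressed <- min_cov <= coverage_gate
  if (res$suppressed) {
    res[c("n_obs", "s_obs", "pN", "pS", "ratio", "n_snps")] <- NA
    res$ratio_defined <- FALSE
    res$purifying <- FALSE
  }
  res
}
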