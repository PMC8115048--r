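#' Synthetic virome generation
#'
#' Generators for phage-like scaffolds with annotated gene layouts, inserted
#' AMG cassettes, population variants at controlled nucleotide identity, and
#' strain-resolved reads with controlled synonymous/non-synonymous SNP
#' composition. Every emitted object carries a ground-truth record so each
#' pipeline stage can be tested without external data.
#'
#' @name synthetic_virome
NULL

GENE_CATEGORIES <- c("viral_hallmark", "viral_like", "host_like", "amg",
                     "unknown")

SENSE_CODONS <- local({
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
})

STOP_CODONS <- local({
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc == "*"]
})

codons_for_aa <- function(aa) {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc == aa]
}

# terminal direct repeat length used to mark circular scaffolds
CIRCULAR_REPEAT <- 30L

#' Describe one synthetic scaffold
#'
#' @param scaffold_id Scaffold name.
#' @param length Scaffold length in bases (>= 1000).
#' @param genes A data.frame with columns `start`, `end` (1-based inclusive),
#'   `strand` (`+`/`-`), `category` (one of viral_hallmark, viral_like,
#'   host_like, amg, unknown) and optionally `amg_symbol` for AMG rows.
#' @param circular Logical; circular scaffolds are emitted with a terminal
#'   direct repeat of `r CIRCULAR_REPEAT` bases.
#' @param gc_fraction Target GC content.
#' @return A validated object of class `genome_spec`.
#' @export
genome_spec <- function(scaffold_id, length, genes, circular = FALSE,
                        gc_fraction = 0.45) {
  stopifnot(is.character(scaffold_id), length >= 1000,
            gc_fraction >= 0, gc_fraction <= 1)
  genes <- as.data.frame(genes)
  need <- c("start", "end", "strand", "category")
  if (!all(need %in% names(genes))) {
    stop("gene layout needs columns: ", paste(need, collapse = ", "))
  }
  if (!"amg_symbol" %in% names(genes)) genes$amg_symbol <- NA_character_
  if (any(genes$start > genes$end)) stop("gene layout error: start > end")
  if (any(genes$start < 1 | genes$end > length)) {
    stop("gene layout error: gene outside [1, length]")
  }
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be + or -")
  if (!all(genes$category %in% GENE_CATEGORIES)) {
    stop("unknown gene category; valid: ", paste(GENE_CATEGORIES, collapse = ", "))
  }
  o <- order(genes$start)
  genes <- genes[o, , drop = FALSE]
  if (nrow(genes) > 1 && any(genes$start[-1] <= genes$end[-nrow(genes)])) {
    stop("gene layout error: overlapping genes")
  }
  amg <- genes$category == "amg"
  if (any(amg & (is.na(genes$amg_symbol) |
                 !genes$amg_symbol %in% ncycle_catalog()$symbol))) {
    stop("amg genes must carry a symbol from the N-cycle catalog")
  }
  if (circular) {
    clash <- genes$start <= CIRCULAR_REPEAT |
      genes$end > length - CIRCULAR_REPEAT
    if (any(clash)) {
      stop("gene layout error: genes may not overlap the ", CIRCULAR_REPEAT,
           "-bp terminal repeat of a circular scaffold")
    }
  }
  structure(list(scaffold_id = scaffold_id, length = as.integer(length),
                 circular = isTRUE(circular), gc_fraction = gc_fraction,
                 genes = genes),
            class = "genome_spec")
}

back_translate <- function(protein) {
  aas <- seq_chars(protein)
  bad <- setdiff(aas, unique(Biostrings::GENETIC_CODE))
  if (length(bad)) stop("invalid amino acid(s): ", paste(bad, collapse = ""))
  paste(vapply(aas, function(a) {
    cods <- codons_for_aa(a)
    cods[sample.int(length(cods), 1)]
  }, character(1)), collapse = "")
}

# ATG + (optional back-translated protein) + random sense codons + stop
make_orf <- function(len, protein = NULL) {
  stopifnot(len %% 3 == 0, len >= 9)
  n_body <- len / 3 - 2
  core <- ""
  if (!is.null(protein)) {
    if (nchar(protein) > n_body) {
      stop("gene span too short for AMG protein (needs ",
           3 * (nchar(protein) + 2), " nt)")
    }
    core <- back_translate(protein)
    n_body <- n_body - nchar(protein)
  }
  filler <- if (n_body > 0) {
    paste(SENSE_CODONS[sample.int(length(SENSE_CODONS), n_body, replace = TRUE)],
          collapse = "")
  } else ""
  paste0("ATG", core, filler, STOP_CODONS[sample.int(3, 1)])
}

#' Generate scaffold sequences, a gene table and ground truth
#'
#' Each scaffold is a random background sequence at the requested GC content
#' with genes inserted as real open reading frames (ATG start, in-frame, no
#' internal stop on the annotated strand). AMG genes embed the back-translated
#' reference protein for their symbol; their span must therefore be a multiple
#' of 3 and long enough for the protein plus start and stop codons.
#'
#' @param specs A list of [genome_spec()] objects.
#' @param seed Integer seed; identical specs and seed give byte-identical
#'   output.
#' @return A list: `sequences` (named character vector), `genes` (data.frame
#'   with scaffold_id, gene_id, start, end, strand, category, amg_symbol) and
#'   `truth` (per-scaffold records).
#' @export
generate_scaffolds <- function(specs, seed = 1) {
  if (inherits(specs, "genome_spec")) specs <- list(specs)
  stopifnot(all(vapply(specs, inherits, logical(1), "genome_spec")))
  ids <- vapply(specs, `[[`, character(1), "scaffold_id")
  if (anyDuplicated(ids)) stop("duplicate scaffold ids")
  set.seed(seed)
  proteins <- amg_proteins()
  seqs <- character(0)
  gene_rows <- list()
  truth_rows <- list()
  for (sp in specs) {
    s <- random_dna(sp$length, sp$gc_fraction)
    if (sp$circular) {
      substr(s, sp$length - CIRCULAR_REPEAT + 1L, sp$length) <-
        substr(s, 1L, CIRCULAR_REPEAT)
    }
    g <- sp$genes
    g$gene_id <- sprintf("%s_g%02d", sp$scaffold_id, seq_len(nrow(g)))
    for (i in seq_len(nrow(g))) {
      len <- g$end[i] - g$start[i] + 1L
      if (g$category[i] == "amg") {
        orf <- make_orf(len, proteins[[g$amg_symbol[i]]])
      } else if (len %% 3 == 0 && len >= 9) {
        orf <- make_orf(len)
      } else {
        next  # non-coding filler span stays random background
      }
      if (g$strand[i] == "-") orf <- revcomp(orf)
      substr(s, g$start[i], g$end[i]) <- orf
    }
    seqs[sp$scaffold_id] <- s
    gene_rows[[sp$scaffold_id]] <- data.frame(
      scaffold_id = sp$scaffold_id, gene_id = g$gene_id,
      start = g$start, end = g$end, strand = g$strand,
      category = g$category, amg_symbol = g$amg_symbol,
      stringsAsFactors = FALSE)
    truth_rows[[sp$scaffold_id]] <- data.frame(
      scaffold_id = sp$scaffold_id, length = sp$length,
      circular = sp$circular, gc_fraction = sp$gc_fraction,
      n_genes = nrow(g),
      amg_symbols = paste(stats::na.omit(g$amg_symbol), collapse = ","),
      stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, unname(gene_rows))
  list(sequences = seqs, genes = genes,
       truth = list(scaffolds = do.call(rbind, unname(truth_rows)),
                    genes = genes))
}

#' Mutate a sequence to a target average nucleotide identity
#'
#' Introduces substitutions only (no indels) at positions sampled uniformly,
#' so identity to the input has an exact Hamming-distance oracle.
#'
#' @param sequence Input nucleotide string.
#' @param target_ani Target identity as a proportion in \[0.80, 1\].
#' @param seed Integer seed.
#' @return A mutated sequence of the same length.
#' @export
mutate_to_ani <- function(sequence, target_ani, seed = 1) {
  sequence <- as_sequence_vector(sequence)
  stopifnot(length(sequence) == 1, target_ani >= 0.80, target_ani <= 1)
  L <- nchar(sequence)
  n_sub <- round((1 - target_ani) * L)
  if (n_sub == 0) return(sequence)
  set.seed(seed)
  pos <- sample.int(L, n_sub)
  ch <- seq_chars(sequence)
  ch[pos] <- vapply(ch[pos], function(b) {
    alt <- setdiff(DNA_BASES, b)
    alt[sample.int(length(alt), 1)]
  }, character(1))
  paste(ch, collapse = "")
}

#' Split and rearrange a sequence into fragments
#'
#' Produces a rearranged variant whose homology to the input lies on several
#' alignment diagonals, exercising multi-segment identity estimation without
#' introducing indels within segments.
#'
#' @param sequence Input nucleotide string.
#' @param n_pieces Number of fragments (>= 2).
#' @param seed Integer seed.
#' @return A list: `sequence` (rearranged concatenation), `pieces`, `order`.
#' @export
fragment_sequence <- function(sequence, n_pieces = 3, seed = 1) {
  sequence <- as_sequence_vector(sequence)
  L <- nchar(sequence)
  stopifnot(n_pieces >= 2, L >= 2 * n_pieces)
  set.seed(seed)
  cuts <- sort(sample(seq(100, L - 100), n_pieces - 1))
  starts <- c(1, cuts + 1)
  ends <- c(cuts, L)
  pieces <- substring(sequence, starts, ends)
  ord <- sample.int(n_pieces)
  list(sequence = paste(pieces[ord], collapse = ""), pieces = pieces,
       order = ord)
}

#' Describe a read-simulation experiment
#'
#' @param depth_target Fold coverage per scaffold (> 0).
#' @param read_length Read length in bases.
#' @param error_rate Uniform per-base sequencing error probability.
#' @param snp_spec Optional data.frame (`gene_id`, `n_syn`, `n_nonsyn`,
#'   `allele_freq`) of strain-level biallelic SNPs to inject into named genes.
#' @param seed Integer seed.
#' @return An object of class `read_sim_spec`.
#' @export
read_sim_spec <- function(depth_target, read_length = 150, error_rate = 0,
                          snp_spec = NULL, seed = 1) {
  stopifnot(depth_target > 0, read_length >= 20,
            error_rate >= 0, error_rate < 1)
  if (!is.null(snp_spec)) {
    snp_spec <- as.data.frame(snp_spec)
    stopifnot(all(c("gene_id", "n_syn", "n_nonsyn", "allele_freq") %in%
                    names(snp_spec)))
    if (any(snp_spec$allele_freq <= 0 | snp_spec$allele_freq > 1)) {
      stop("allele_freq must be in (0, 1]")
    }
  }
  structure(list(depth_target = depth_target, read_length = as.integer(read_length),
                 error_rate = error_rate, snp_spec = snp_spec,
                 seed = as.integer(seed)),
            class = "read_sim_spec")
}

# enumerate single-base substitutions in a CDS, classified syn/nonsyn.
# start and stop codons are excluded so injected variants keep the ORF intact.
snp_candidates <- function(cds) {
  gc <- Biostrings::GENETIC_CODE
  n_cod <- nchar(cds) / 3
  out <- list()
  for (ci in seq(2, n_cod - 1)) {
    ref_cod <- substr(cds, (ci - 1) * 3 + 1, ci * 3)
    if (!ref_cod %in% names(gc) || gc[[ref_cod]] == "*") next
    for (p in 1:3) {
      ref_b <- substr(ref_cod, p, p)
      for (alt in setdiff(DNA_BASES, ref_b)) {
        alt_cod <- ref_cod
        substr(alt_cod, p, p) <- alt
        if (gc[[alt_cod]] == "*") next
        out[[length(out) + 1]] <- data.frame(
          cds_pos = (ci - 1L) * 3L + p, ref = ref_b, alt = alt,
          class = if (gc[[alt_cod]] == gc[[ref_cod]]) "synonymous"
                  else "nonsynonymous",
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

extract_cds <- function(sequence, start, end, strand) {
  s <- substr(sequence, start, end)
  if (strand == "-") s <- revcomp(s) else s
}

pick_snp_sites <- function(cds, n_syn, n_nonsyn) {
  cand <- snp_candidates(cds)
  pick <- function(cls, n, used) {
    cc <- cand[cand$class == cls & !cand$cds_pos %in% used, , drop = FALSE]
    pos <- unique(cc$cds_pos)
    if (length(pos) < n) stop("not enough ", cls, " candidate sites in gene")
    sel <- pos[sample.int(length(pos), n)]
    do.call(rbind, lapply(sel, function(p) {
      rows <- cc[cc$cds_pos == p, , drop = FALSE]
      rows[sample.int(nrow(rows), 1), , drop = FALSE]
    }))
  }
  syn <- if (n_syn > 0) pick("synonymous", n_syn, integer(0)) else NULL
  non <- if (n_nonsyn > 0) pick("nonsynonymous", n_nonsyn,
                                syn$cds_pos %||% integer(0)) else NULL
  rbind(syn, non)
}

#' Simulate shotgun reads with strain-level SNPs and full ground truth
#'
#' Reads are placed uniformly along each scaffold at the requested fold
#' coverage. Injected SNPs are strain-level biallelic sites: each read draws a
#' single latent haplotype coordinate, so sites with equal allele frequency
#' are perfectly linked (a two-haplotype mixture). Sequencing errors are
#' uniform per base. Read sequences are stored in reference orientation; the
#' FASTQ writer reverse-complements minus-strand reads.
#'
#' @param sequences Named character vector (or DNAStringSet) of scaffolds.
#' @param genes Gene table as produced by [generate_scaffolds()]; required
#'   when `spec$snp_spec` names genes.
#' @param spec A [read_sim_spec()].
#' @return A list: `reads` (data.frame read_id, scaffold_id, start, end,
#'   strand, seq), `placements` (the same, without seq), and `truth`
#'   (`snps` with genomic and CDS coordinates and classes, `depths` realized
#'   per scaffold).
#' @export
simulate_reads <- function(sequences, genes = NULL, spec) {
  sequences <- as_sequence_vector(sequences)
  stopifnot(inherits(spec, "read_sim_spec"), !is.null(names(sequences)))
  set.seed(spec$seed)
  rl <- spec$read_length

  snps <- NULL
  if (!is.null(spec$snp_spec) && nrow(spec$snp_spec) > 0) {
    if (is.null(genes)) stop("snp_spec given but no gene table supplied")
    snps <- do.call(rbind, lapply(seq_len(nrow(spec$snp_spec)), function(i) {
      req <- spec$snp_spec[i, ]
      g <- genes[genes$gene_id == req$gene_id, , drop = FALSE]
      if (nrow(g) != 1) stop("gene not found in gene table: ", req$gene_id)
      cds <- extract_cds(sequences[[g$scaffold_id]], g$start, g$end, g$strand)
      sites <- pick_snp_sites(cds, req$n_syn, req$n_nonsyn)
      if (is.null(sites)) return(NULL)
      gpos <- if (g$strand == "+") g$start + sites$cds_pos - 1L
              else g$end - sites$cds_pos + 1L
      galt <- if (g$strand == "+") sites$alt else unname(COMPLEMENT[sites$alt])
      gref <- if (g$strand == "+") sites$ref else unname(COMPLEMENT[sites$ref])
      data.frame(scaffold_id = g$scaffold_id, gene_id = req$gene_id,
                 cds_pos = sites$cds_pos, genomic_pos = gpos,
                 ref_cds = sites$ref, alt_cds = sites$alt,
                 ref_genomic = gref, alt_genomic = galt,
                 class = sites$class, allele_freq = req$allele_freq,
                 stringsAsFactors = FALSE)
    }))
  }

  read_list <- list()
  depth_rows <- list()
  for (scf in names(sequences)) {
    L <- nchar(sequences[[scf]])
    if (L < rl) {
      warning("scaffold ", scf, " shorter than read length; no reads emitted")
      next
    }
    n_reads <- round(spec$depth_target * L / rl)
    if (n_reads == 0) {
      warning("depth target too low for ", scf, "; no reads emitted")
      next
    }
    starts <- sample.int(L - rl + 1L, n_reads, replace = TRUE)
    ends <- starts + rl - 1L
    u <- runif(n_reads)  # latent haplotype coordinate per read
    rd <- substring(sequences[[scf]], starts, ends)
    if (!is.null(snps)) {
      here <- snps[snps$scaffold_id == scf, , drop = FALSE]
      for (j in seq_len(nrow(here))) {
        gp <- here$genomic_pos[j]
        hit <- which(starts <= gp & gp <= ends & u < here$allele_freq[j])
        if (length(hit)) {
          off <- gp - starts[hit] + 1L
          substr(rd[hit], off, off) <- here$alt_genomic[j]
        }
      }
    }
    if (spec$error_rate > 0) {
      n_err <- rbinom(n_reads, rl, spec$error_rate)
      for (i in which(n_err > 0)) {
        ep <- sample.int(rl, n_err[i])
        ch <- seq_chars(rd[i])
        ch[ep] <- vapply(ch[ep], function(b) {
          alt <- setdiff(DNA_BASES, b); alt[sample.int(3, 1)]
        }, character(1))
        rd[i] <- paste(ch, collapse = "")
      }
    }
    read_list[[scf]] <- data.frame(
      read_id = sprintf("%s_r%06d", scf, seq_len(n_reads)),
      scaffold_id = scf, start = starts, end = ends,
      strand = sample(c("+", "-"), n_reads, replace = TRUE),
      seq = rd, stringsAsFactors = FALSE)
    depth_rows[[scf]] <- data.frame(
      scaffold_id = scf, n_reads = n_reads,
      realized_depth = n_reads * rl / L, stringsAsFactors = FALSE)
  }
  reads <- do.call(rbind, unname(read_list))
  if (is.null(reads)) {
    reads <- data.frame(read_id = character(0), scaffold_id = character(0),
                        start = integer(0), end = integer(0),
                        strand = character(0), seq = character(0))
  }
  list(reads = reads,
       placements = reads[, c("read_id", "scaffold_id", "start", "end",
                              "strand")],
       truth = list(snps = snps, depths = do.call(rbind, unname(depth_rows))))
}
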