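#' Write sequences to FASTA
#'
#' @param sequences Named character vector or DNAStringSet.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  sequences <- as_sequence_vector(sequences)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sequences), filepath = path)
  invisible(path)
}

#' Read scaffolds from FASTA
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  as_sequence_vector(Biostrings::readDNAStringSet(path))
}

#' Write simulated reads to FASTQ
#'
#' Reads are stored reference-oriented by the simulator; minus-strand reads
#' are reverse-complemented on output. Qualities are constant (the simulator
#' has no quality model).
#'
#' @param reads Read table from [simulate_reads()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  seqs <- ifelse(reads$strand == "-",
                 vapply(reads$seq, revcomp, character(1), USE.NAMES = FALSE),
                 reads$seq)
  qual <- strrep("I", nchar(seqs))
  writeLines(paste0("@", reads$read_id, "\n", seqs, "\n+\n", qual), path)
  invisible(path)
}

#' Write alignment placements as a plain-text SAM file
#'
#' Emits one primary ungapped alignment per read (CIGAR `<len>M`), with SEQ
#' in reference orientation as SAM requires.
#'
#' @param reads Read table from [simulate_reads()].
#' @param scaffold_lengths Named vector of reference lengths for the header.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, scaffold_lengths, path) {
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(scaffold_lengths),
                      as.integer(scaffold_lengths)))
  flag <- ifelse(reads$strand == "-", 16L, 0L)
  body <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
                  reads$read_id, flag, reads$scaffold_id, reads$start,
                  nchar(reads$seq), reads$seq)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write all simulator outputs to a directory
#'
#' Emits scaffolds.fasta, genes.tsv, reads.fastq, placements.sam,
#' placements.tsv and truth/*.tsv, the inputs the downstream pipeline stages
#' consume.
#'
#' @param scaffolds Output of [generate_scaffolds()].
#' @param sim Output of [simulate_reads()] (optional).
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(scaffolds, sim = NULL, outdir) {
  dir.create(file.path(outdir, "truth"), recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, f) write.table(x, file.path(outdir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
  write_fasta(scaffolds$sequences, file.path(outdir, "scaffolds.fasta"))
  tsv(scaffolds$genes, "genes.tsv")
  tsv(scaffolds$truth$scaffolds, file.path("truth", "scaffolds.tsv"))
  if (!is.null(sim)) {
    write_fastq(sim$reads, file.path(outdir, "reads.fastq"))
    lens <- setNames(nchar(scaffolds$sequences), names(scaffolds$sequences))
    write_sam(sim$reads, lens, file.path(outdir, "placements.sam"))
    tsv(sim$placements, "placements.tsv")
    if (!is.null(sim$truth$snps)) tsv(sim$truth$snps, file.path("truth", "snps.tsv"))
    if (!is.null(sim$truth$depths)) {
      tsv(sim$truth$depths, file.path("truth", "depths.tsv"))
    }
  }
  invisible(outdir)
}
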