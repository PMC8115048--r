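# Shared fixture builders. Everything is generated in code at test time.

# a small scaffold with one AMG (glnK, shortest catalog protein), one
# minus-strand hallmark gene and one plus-strand gene
demo_scaffolds <- function(seed = 11) {
  genes <- data.frame(start = c(501, 2001, 4001), end = c(1499, 3800, 5200),
                      strand = c("+", "-", "+"),
                      category = c("amg", "viral_hallmark", "viral_like"),
                      amg_symbol = c("glnK", NA, NA))
  generate_scaffolds(list(genome_spec("scfA", 6000, genes)), seed = seed)
}

# scaffold carrying a single 999-nt plus-strand gene, for SNP recovery runs
snp_test_scaffold <- function(seed = 21) {
  genes <- data.frame(start = 1501, end = 2499, strand = "+",
                      category = "viral_like", amg_symbol = NA)
  generate_scaffolds(list(genome_spec("scfS", 4000, genes)), seed = seed)
}

hamming_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  100 * mean(ca == cb)
}

extract_cds_chr <- function(sequence, start, end, strand) {
  s <- substr(sequence, start, end)
  if (strand == "-") {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  } else s
}

rc <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# brute-force oracle: enumerate all 9 single-base substitutions of a codon
brute_sites <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  syn <- 0
  for (p in 1:3) {
    for (alt in setdiff(c("A", "C", "G", "T"), substr(codon, p, p))) {
      alt_cod <- codon
      substr(alt_cod, p, p) <- alt
      if (gc[[alt_cod]] == gc[[codon]]) syn <- syn + 1
    }
  }
  c(S = syn / 3, N = 3 - syn / 3)
}
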