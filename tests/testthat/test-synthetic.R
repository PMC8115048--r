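test_that("generated scaffolds honor the spec: lengths, gene table, real ORFs", {
  sc <- demo_scaffolds()
  expect_equal(nchar(sc$sequences[["scfA"]]), 6000)
  expect_equal(nrow(sc$genes), 3)
  # every coding gene, on its annotated strand, is a clean ORF
  for (i in seq_len(nrow(sc$genes))) {
    g <- sc$genes[i, ]
    cds <- extract_cds_chr(sc$sequences[[g$scaffold_id]], g$start, g$end,
                           g$strand)
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
    expect_equal(substr(aa, 1, 1), "M")
    expect_false(grepl("*", substr(aa, 1, nchar(aa) - 1), fixed = TRUE))
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
  }
  # the AMG really embeds its catalog protein
  g <- sc$genes[sc$genes$category == "amg", ]
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(
    extract_cds_chr(sc$sequences[[g$scaffold_id]], g$start, g$end, g$strand))))
  expect_true(grepl(amg_proteins()[["glnK"]], aa, fixed = TRUE))
})

test_that("generation is deterministic and rejects bad layouts", {
  a <- demo_scaffolds(seed = 5)
  b <- demo_scaffolds(seed = 5)
  expect_identical(a$sequences, b$sequences)
  expect_identical(a$genes, b$genes)
  expect_false(identical(a$sequences, demo_scaffolds(seed = 6)$sequences))

  overlapping <- data.frame(start = c(100, 150), end = c(200, 250),
                            strand = "+", category = "unknown")
  expect_error(genome_spec("x", 2000, overlapping), "overlapping")
  outside <- data.frame(start = 100, end = 3000, strand = "+",
                        category = "unknown")
  expect_error(genome_spec("x", 2000, outside), "outside")
  bad_amg <- data.frame(start = 99, end = 1097, strand = "+",
                        category = "amg", amg_symbol = "notagene")
  expect_error(genome_spec("x", 2000, bad_amg), "catalog")
})

test_that("mutate_to_ani hits the target identity exactly by Hamming count", {
  set.seed(31)
  s <- random_dna(10000)
  expect_identical(mutate_to_ani(s, 1.0), s)
  for (ani in c(0.95, 0.90)) {
    v <- mutate_to_ani(s, ani, seed = 13)
    expect_equal(nchar(v), nchar(s))
    mm <- sum(strsplit(s, "")[[1]] != strsplit(v, "")[[1]])
    expect_equal(mm, round((1 - ani) * 10000))
  }
  expect_error(mutate_to_ani(s, 0.5), "target_ani")
})

test_that("simulated reads hit the depth target and respect allele freqs", {
  set.seed(7)
  scf <- c(big = random_dna(50000))
  sim <- simulate_reads(scf, spec = read_sim_spec(20, 150, 0, seed = 2))
  expected <- 20 * 50000 / 150
  expect_lt(abs(nrow(sim$reads) - expected) / expected, 0.10)
  expect_true(all(sim$reads$end <= 50000 & sim$reads$start >= 1))

  # error-free, SNP-free reads match the reference exactly
  ok <- vapply(seq_len(200), function(i) {
    r <- sim$reads[i, ]
    r$seq == substr(scf[["big"]], r$start, r$end)
  }, logical(1))
  expect_true(all(ok))

  # injected synonymous SNPs sit at their stated allele frequency
  sc <- snp_test_scaffold()
  ss <- data.frame(gene_id = sc$genes$gene_id[1], n_syn = 7, n_nonsyn = 0,
                   allele_freq = 0.5)
  sim2 <- simulate_reads(sc$sequences, sc$genes,
                         read_sim_spec(50, 150, 0, ss, seed = 3))
  expect_equal(nrow(sim2$truth$snps), 7)
  expect_true(all(sim2$truth$snps$class == "synonymous"))
  pu <- pileup_from_reads(sim2$reads, "scfS", sc$sequences[[1]])
  for (j in seq_len(7)) {
    snp <- sim2$truth$snps[j, ]
    row <- pu[pu$pos == snp$genomic_pos, ]
    depth <- sum(row[c("A", "C", "G", "T")])
    alt_frac <- row[[snp$alt_genomic]] / depth
    # binomial 3-sigma band around the target frequency
    expect_lt(abs(alt_frac - 0.5), 3 * sqrt(0.25 / depth) + 1e-9)
  }
})

test_that("read simulation truth closure: every read maps to one scaffold", {
  set.seed(8)
  scf <- c(s1 = random_dna(5000), s2 = random_dna(7000))
  sim <- simulate_reads(scf, spec = read_sim_spec(5, 100, 0.001, seed = 9))
  expect_equal(nrow(sim$placements), nrow(sim$reads))
  expect_true(all(sim$placements$scaffold_id %in% names(scf)))
  expect_false(anyDuplicated(sim$placements$read_id) > 0)
})

test_that("fragmented variants keep full homology across diagonals", {
  set.seed(12)
  s <- random_dna(8000)
  fr <- fragment_sequence(s, 4, seed = 3)
  expect_equal(nchar(fr$sequence), nchar(s))
  expect_equal(sort(unlist(strsplit(fr$pieces, ""))),
               sort(strsplit(s, "")[[1]]))
  ani <- pairwise_ani(s, fr$sequence)
  expect_gt(ani$aligned_fraction_shorter, 0.95)
  expect_gt(ani$ani, 99.5)
})
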