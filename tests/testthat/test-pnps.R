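
test_that("expected site counts match the 9-substitution enumerator exactly", {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  expect_length(sense, 61)
  for (cod in sense) {
    st <- expected_sites(cod)
    oracle <- brute_sites(cod)
    expect_equal(st$S_sites, unname(oracle["S"]), info = cod)
    expect_equal(st$N_sites, unname(oracle["N"]), info = cod)
    expect_equal(st$N_sites + st$S_sites, 3, info = cod)
  }
  # worked examples
  atg <- expected_sites("ATG")
  expect_equal(c(atg$N_sites, atg$S_sites), c(3, 0))
  ttt <- expected_sites("TTT")
  expect_equal(c(ttt$N_sites, ttt$S_sites), c(8 / 3, 1 / 3))
  both <- expected_sites("ATGTTT")
  expect_equal(both$N_sites, 17 / 3)
  expect_equal(both$S_sites, 1 / 3)
})

test_that("expected_sites validates the reading frame", {
  expect_error(expected_sites("ATGTT"), "divisible by 3")
  expect_error(expected_sites("ATGTAAGGG"), "internal stop")
  # a terminal stop codon is tolerated and excluded from totals
  st <- expected_sites("ATGTTTTAA")
  expect_equal(st$N_sites + st$S_sites, 6)
})

test_that("variant calls respect depth, fraction and support thresholds", {
  cds <- "ATGTTTAAATAG"
  mk <- function(pos, counts) {
    p <- data.frame(pos = 1:12, ref = strsplit(cds, "")[[1]],
                    A = 0L, C = 0L, G = 0L, T = 0L)
    # reference support everywhere
    for (i in 1:12) p[i, p$ref[i]] <- 30L
    for (b in names(counts)) p[pos, b] <- counts[[b]]
    p
  }
  # clear site: depth 50, alt 25
  p <- mk(6, list(C = 25L))  # TTT -> TTC, synonymous third position
  v <- call_variants(p, cds)
  expect_equal(nrow(v), 1)
  expect_equal(v$classification, "synonymous")
  expect_equal(v$alt_fraction, 25 / 55)
  # below the depth gate: no call
  p2 <- mk(6, list(C = 4L))
  p2[, c("A", "C", "G", "T")] <- p2[, c("A", "C", "G", "T")] * 0L
  p2[6, "T"] <- 4L; p2[6, "C"] <- 4L
  for (i in setdiff(1:12, 6)) p2[i, p2$ref[i]] <- 30L
  expect_equal(nrow(call_variants(p2, cds)), 0)
  # single supporting read is not enough
  p3 <- mk(6, list(C = 1L))
  expect_equal(nrow(call_variants(p3, cds)), 0)
  # nonsynonymous second-position change
  p4 <- mk(5, list(C = 20L))  # TTT -> TCT
  expect_equal(call_variants(p4, cds)$classification, "nonsynonymous")
  # multi-allelic site: one call per qualifying allele, majority first
  p5 <- mk(6, list(C = 20L, G = 10L))
  v5 <- call_variants(p5, cds)
  expect_equal(nrow(v5), 2)
  expect_equal(v5$alt_base, c("C", "G"))
})

test_that("pnps arithmetic follows the worked examples", {
  st <- expected_sites("ATGTTT")
  syn <- data.frame(classification = "synonymous")
  r1 <- pnps("g", syn, st)
  expect_equal(r1$pS, 3)
  expect_equal(r1$ratio, 0)
  expect_true(r1$purifying)

  both <- data.frame(classification = c("nonsynonymous", "synonymous"))
  r2 <- pnps("g", both, st)
  expect_equal(r2$pN, 3 / 17)
  expect_equal(r2$ratio, (3 / 17) / 3, tolerance = 1e-12)
  expect_true(r2$purifying)

  # undefined when no synonymous SNPs
  non <- data.frame(classification = "nonsynonymous")
  r3 <- pnps("g", non, st)
  expect_true(is.na(r3$ratio))
  expect_false(r3$purifying)
  r4 <- pnps("g", both[0, , drop = FALSE], st)
  expect_true(is.na(r4$ratio))
})

test_that("pN/pS recovery from simulated strain variation", {
  sc <- snp_test_scaffold()
  g <- sc$genes[1, ]
  cds <- extract_cds_chr(sc$sequences[[1]], g$start, g$end, g$strand)

  run <- function(n_syn, n_nonsyn, seed) {
    ss <- data.frame(gene_id = g$gene_id, n_syn = n_syn, n_nonsyn = n_nonsyn,
                     allele_freq = 0.5)
    sim <- simulate_reads(sc$sequences, sc$genes,
                          read_sim_spec(50, 150, 0, ss, seed = seed))
    pu <- pileup_from_reads(sim$reads, g$scaffold_id, sc$sequences[[1]])
    gp <- gene_pileup(pu, g$start, g$end, g$strand)
    pnps_from_pileup(gp, cds, g$gene_id)
  }
  # all-synonymous variation: ratio exactly 0
  r <- run(7, 0, seed = 3)
  expect_equal(r$n_snps, 7)
  expect_equal(r$ratio, 0)
  expect_true(r$purifying)
  # mixed variation recovers the analytic truth ratio
  r2 <- run(12, 1, seed = 4)
  st <- expected_sites(cds)
  analytic <- (1 / st$N_sites) / (12 / st$S_sites)
  expect_equal(r2$ratio, analytic, tolerance = 0.15)
})

test_that("ratio is invariant under uniform depth scaling", {
  cds <- "ATGTTTAAACCCGGGTAG"
  p <- data.frame(pos = 1:18, ref = strsplit(cds, "")[[1]],
                  A = 0L, C = 0L, G = 0L, T = 0L)
  for (i in 1:18) p[i, p$ref[i]] <- 40L
  p[6, "C"] <- 12L   # synonymous
  p[5, "C"] <- 10L   # nonsynonymous
  r1 <- pnps_from_pileup(p, cds)
  p2 <- p
  p2[, c("A", "C", "G", "T")] <- 2L * as.matrix(p[, c("A", "C", "G", "T")])
  r2 <- pnps_from_pileup(p2, cds)
  expect_equal(r2$ratio, r1$ratio)
  expect_equal(r2$n_snps, r1$n_snps)
})

test_that("low-coverage genes are suppressed, not zeroed", {
  cds <- "ATGTTTAAATAG"
  p <- data.frame(pos = 1:12, ref = strsplit(cds, "")[[1]],
                  A = 0L, C = 0L, G = 0L, T = 0L)
  for (i in 1:12) p[i, p$ref[i]] <- 8L
  r <- pnps_from_pileup(p, cds)
  expect_true(r$suppressed)
  expect_true(is.na(r$ratio))
  expect_equal(r$min_gene_coverage, 8)
})

test_that("minus-strand gene pileups are complemented into CDS coordinates", {
  sc <- demo_scaffolds()
  g <- sc$genes[2, ]  # minus strand
  expect_equal(g$strand, "-")
  sim <- simulate_reads(sc$sequences, sc$genes,
                        read_sim_spec(30, 150, 0, seed = 6))
  pu <- pileup_from_reads(sim$reads, g$scaffold_id, sc$sequences[[1]])
  gp <- gene_pileup(pu, g$start, g$end, g$strand)
  cds <- extract_cds_chr(sc$sequences[[1]], g$start, g$end, g$strand)
  ref_chars <- strsplit(cds, "")[[1]]
  expect_equal(gp$ref, ref_chars)
  # with no variation the consensus base equals the CDS base at each position
  counts <- as.matrix(gp[, c("A", "C", "G", "T")])
  covered <- rowSums(counts) > 0
  maj <- c("A", "C", "G", "T")[max.col(counts[covered, ])]
  expect_equal(maj, ref_chars[covered])
})
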