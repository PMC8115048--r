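test_that("pairwise_ani recovers constructed identities and coverage", {
  set.seed(42)
  a <- random_dna(10000)
  expect_equal(pairwise_ani(a, a)$ani, 100)
  expect_equal(pairwise_ani(a, a)$aligned_fraction_shorter, 1.0)

  # 300 substitutions inside a 9-kb homologous region, unrelated 1-kb tails
  core <- substr(a, 1, 9000)
  b <- paste0(mutate_to_ani(core, 1 - 300 / 9000, seed = 3), random_dna(1000))
  res <- pairwise_ani(a, b)
  expect_equal(res$ani, 100 * 8700 / 9000, tolerance = 0.003)
  expect_equal(res$aligned_fraction_shorter, 0.90, tolerance = 0.01)

  # unrelated sequences share no long alignment
  expect_lt(pairwise_ani(random_dna(10000), random_dna(10000))
            $aligned_fraction_shorter, 0.10)

  expect_error(pairwise_ani(strrep("N", 500), a), "only N")
})

test_that("pairwise_ani matches the Hamming oracle on substitution-only pairs", {
  set.seed(19)
  for (i in 1:6) {
    s <- random_dna(8000 + 500 * i)
    ani_target <- c(0.96, 0.97, 0.98, 0.99, 0.95, 0.92)[i]
    v <- mutate_to_ani(s, ani_target, seed = i)
    est <- pairwise_ani(s, v)$ani
    expect_lt(abs(est - hamming_identity(s, v)), 0.3)
  }
})

test_that("reverse-complement variants align as well as forward ones", {
  set.seed(23)
  s <- random_dna(9000)
  v <- mutate_to_ani(s, 0.97, seed = 4)
  fwd <- pairwise_ani(s, v)
  rev <- pairwise_ani(s, rc(v))
  expect_equal(rev$ani, fwd$ani, tolerance = 0.003)
  expect_equal(rev$aligned_fraction_shorter, fwd$aligned_fraction_shorter,
               tolerance = 0.01)
})

test_that("pairwise_ani agrees with Biostrings local alignment on small pairs", {
  set.seed(29)
  s <- random_dna(2000)
  v <- mutate_to_ani(s, 0.95, seed = 5)
  aln <- Biostrings::pairwiseAlignment(s, v, type = "local")
  oracle <- 100 * Biostrings::nmatch(aln) / Biostrings::nchar(aln)
  expect_lt(abs(pairwise_ani(s, v)$ani - oracle), 0.5)
})

test_that("greedy clustering applies both thresholds and picks longest reps", {
  set.seed(33)
  anc <- random_dna(12000)
  seqs <- c(anc = anc,
            near = mutate_to_ani(anc, 0.96, seed = 1),
            far = mutate_to_ani(anc, 0.90, seed = 2))
  cl <- cluster_scaffolds(seqs)
  expect_equal(cl$cluster_id[cl$scaffold_id == "near"],
               cl$cluster_id[cl$scaffold_id == "anc"])
  expect_false(cl$cluster_id[cl$scaffold_id == "far"] ==
                 cl$cluster_id[cl$scaffold_id == "anc"])
  expect_true(cl$is_representative[cl$scaffold_id == "anc"])

  # identical triple collapses to one cluster
  tri <- c(x = anc, y = anc, z = anc)
  expect_equal(length(unique(cluster_scaffolds(tri)$cluster_id)), 1)

  # high identity but low coverage fails the 80% criterion
  half <- paste0(substr(anc, 1, 6000), random_dna(6000))
  cl2 <- cluster_scaffolds(c(a = anc, b = half))
  expect_equal(length(unique(cl2$cluster_id)), 2)
})

test_that("clustering from an edge list is a partition and handles sparsity", {
  lengths <- c(s1 = 9000, s2 = 8000, s3 = 7000, s4 = 6500)
  edges <- data.frame(id_a = c("s1", "s1"), id_b = c("s2", "s3"),
                      ani = c(97, 91),
                      aligned_length = c(7800, 6900),
                      shorter_length = c(8000, 7000),
                      aligned_fraction_shorter = c(0.975, 0.985))
  cl <- cluster_populations(edges, lengths)
  expect_setequal(cl$scaffold_id, names(lengths))
  expect_equal(anyDuplicated(cl$scaffold_id), 0)
  expect_equal(cl$representative_id[cl$scaffold_id == "s2"], "s1")
  # s3 fails ANI, s4 has no edge: both found their own clusters
  expect_true(cl$is_representative[cl$scaffold_id == "s3"])
  expect_true(cl$is_representative[cl$scaffold_id == "s4"])
  expect_error(cluster_populations(edges, c(s1 = 1, s1 = 2)), "duplicate")
})

test_that("CsCl scaffolds are retained only as cluster representatives", {
  cl <- data.frame(scaffold_id = c("r", "m", "o"),
                   cluster_id = c("p1", "p1", "p2"),
                   representative_id = c("r", "r", "o"),
                   is_representative = c(TRUE, FALSE, TRUE))
  expect_setequal(apply_cscl_retention(cl, "r"), c("r", "m", "o"))
  expect_setequal(apply_cscl_retention(cl, "m"), c("r", "o"))
  expect_setequal(apply_cscl_retention(cl, character(0)), c("r", "m", "o"))
})

test_that("AMG scaffold merging requires >1 kb overlap at >=99% identity", {
  set.seed(44)
  base <- random_dna(14000)
  a <- substr(base, 1, 8000)
  b <- substr(base, 6001, 14000)
  asgn <- data.frame(scaffold_id = c("s1", "s2"), amg_symbol = "nirA")
  mg <- merge_amg_scaffolds(c(s1 = a, s2 = b), asgn)
  expect_true(mg$records$merged)
  expect_equal(mg$records$overlap_length, 2000)
  expect_match(mg$records$merged_id, "E$")
  expect_identical(mg$sequences[["s1E"]], base)

  # 900-bp overlap: below the >1 kb rule
  b2 <- substr(base, 7101, 14000)
  mg2 <- merge_amg_scaffolds(c(s1 = a, s2 = b2), asgn)
  expect_false(mg2$records$merged)

  # identity below 99% over the overlap blocks the merge
  b3 <- paste0(mutate_to_ani(substr(base, 6001, 8000), 0.97, seed = 1),
               substr(base, 8001, 14000))
  mg3 <- merge_amg_scaffolds(c(s1 = a, s2 = b3), asgn)
  expect_false(mg3$records$merged)
})

test_that("merging fills N gaps from the partner and never loses AMG bases", {
  set.seed(45)
  base <- random_dna(12000)
  a <- substr(base, 1, 7000)
  substr(a, 6200, 6220) <- strrep("N", 21)
  b <- substr(base, 5001, 12000)
  asgn <- data.frame(scaffold_id = c("s1", "s2"), amg_symbol = "norB")
  mg <- merge_amg_scaffolds(c(s1 = a, s2 = b), asgn)
  expect_true(mg$records$merged)
  expect_equal(mg$records$n_gap_filled, 21)
  merged <- mg$sequences[[1]]
  expect_false(grepl("N", merged, fixed = TRUE))
  # never fewer non-N bases than the best source scaffold
  non_n <- function(x) sum(strsplit(x, "")[[1]] != "N")
  expect_gte(non_n(merged), max(non_n(a), non_n(b)))
  expect_identical(merged, base)
})
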