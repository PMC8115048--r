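test_that("terminal direct repeats mark circular scaffolds", {
  set.seed(3)
  s <- random_dna(3000)
  circ <- paste0(s, substr(s, 1, 30))
  expect_true(detect_circularity(circ))
  expect_true(detect_circularity(circ, min_repeat = 30))
  expect_false(detect_circularity(circ, min_repeat = 31))
  # brute-force check that no terminal repeat exists in a random sequence
  L <- nchar(s)
  reps <- vapply(20:(L %/% 2), function(r) {
    substr(s, 1, r) == substr(s, L - r + 1, L)
  }, logical(1))
  expect_false(any(reps))
  expect_equal(detect_circularity(s), any(reps))
  expect_error(detect_circularity("ACGTACGT", min_repeat = 5), "min_repeat")
})

test_that("strand switch rate counts adjacent-pair changes and is order-stable", {
  gt <- function(strands) data.frame(start = seq_along(strands) * 100,
                                     strand = strands)
  expect_equal(strand_switch_rate(gt(c("+", "+", "+", "+"))), 0)
  expect_equal(strand_switch_rate(gt(c("+", "+", "-", "-", "+"))), 0.5)
  expect_equal(strand_switch_rate(gt(c("+", "-", "+", "-"))), 1)
  expect_warning(r <- strand_switch_rate(gt("+")), "fewer than 2")
  expect_true(is.na(r))
  # invariant under reversing the table rows (ordering is by start)
  tab <- gt(c("+", "-", "-", "+", "+"))
  expect_equal(strand_switch_rate(tab[rev(seq_len(nrow(tab))), ]),
               strand_switch_rate(tab))
})

test_that("viral classification follows the published decision rules", {
  f <- data.frame(
    scaffold_id = c("a", "b", "c", "d"),
    length = c(12400, 8000, 1800, 12000),
    circular = c(FALSE, FALSE, TRUE, FALSE),
    virsorter_category = c(2, NA, NA, NA),
    virfinder_score = c(NA, 0.95, 0.92, 0.85),
    virfinder_p = c(NA, 0.01, 0.03, 0.01))
  d <- classify_viral(f)
  expect_equal(d$is_viral, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(d$reportable, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("the full rule truth table matches a hand-enumerated oracle", {
  lengths <- c(1200, 1800, 5000, 5001, 9999, 10000, 15000)
  circular <- c(TRUE, FALSE)
  classifier <- list(
    cat1 = list(vs = 1, score = NA, p = NA),
    cat3 = list(vs = 3, score = NA, p = NA),
    vf_strong = list(vs = NA, score = 0.95, p = 0.01),
    vf_exact_score = list(vs = NA, score = 0.9, p = 0.01),
    vf_bad_p = list(vs = NA, score = 0.95, p = 0.05),
    none = list(vs = NA, score = NA, p = NA))
  grid <- expand.grid(len = lengths, circ = circular,
                      cls = names(classifier), stringsAsFactors = FALSE)
  f <- data.frame(
    scaffold_id = sprintf("s%03d", seq_len(nrow(grid))),
    length = grid$len, circular = grid$circ,
    virsorter_category = vapply(grid$cls, function(x) classifier[[x]]$vs,
                                numeric(1)),
    virfinder_score = vapply(grid$cls, function(x) classifier[[x]]$score,
                             numeric(1)),
    virfinder_p = vapply(grid$cls, function(x) classifier[[x]]$p, numeric(1)))
  got <- classify_viral(f)
  for (i in seq_len(nrow(f))) {
    # independent literal reading of the rules
    eligible <- f$length[i] > 5000 || (f$circular[i] && f$length[i] > 1500)
    classifier_ok <-
      (!is.na(f$virsorter_category[i]) && f$virsorter_category[i] <= 2) ||
      (!is.na(f$virfinder_score[i]) && f$virfinder_score[i] > 0.9 &&
         f$virfinder_p[i] < 0.05)
    viral <- eligible && classifier_ok
    expect_equal(got$is_viral[i], viral, info = paste("row", i))
    expect_equal(got$reportable[i], viral && f$length[i] >= 10000,
                 info = paste("row", i))
  }
})

test_that("raising the VirFinder score never un-calls a viral scaffold", {
  base <- data.frame(scaffold_id = "s", length = 8000, circular = FALSE,
                     virsorter_category = NA, virfinder_p = 0.01)
  scores <- seq(0, 1, by = 0.05)
  calls <- vapply(scores, function(sc) {
    classify_viral(cbind(base, virfinder_score = sc))$is_viral
  }, logical(1))
  expect_true(all(diff(calls) >= 0))
})
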