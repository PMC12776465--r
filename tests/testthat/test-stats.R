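test_that("TMD randomization preserves counts, lengths and bounds", {
  tmds <- data.frame(transcript_id = rep(c("A", "B"), c(2, 1)),
                     aa_start = c(10L, 60L, 5L), aa_end = c(28L, 80L, 24L))
  plen <- c(A = 150L, B = 90L)
  r1 <- randomizeTmdPositions(tmds, plen, seed = 5)
  r2 <- randomizeTmdPositions(tmds, plen, seed = 5)
  expect_identical(r1, r2)  # determinism under seed
  set.seed(1)
  for (rep in 1:50) {
    r <- randomizeTmdPositions(tmds, plen)
    expect_identical(r$aa_end - r$aa_start, tmds$aa_end - tmds$aa_start)
    expect_true(all(r$aa_start >= 1L))
    for (tid in c("A", "B")) {
      j <- which(r$transcript_id == tid)
      expect_true(all(r$aa_end[j] <= plen[[tid]]))
      o <- order(r$aa_start[j])
      if (length(j) > 1)
        expect_true(all(r$aa_start[j][o][-1] > r$aa_end[j][o][-length(j)]))
    }
  }
  short <- data.frame(transcript_id = "S", aa_start = 1L, aa_end = 19L)
  expect_warning(randomizeTmdPositions(short, c(S = 10L), seed = 1),
                 "too short")
})

test_that("a single randomized TMD start is uniform on its feasible range", {
  tmds <- data.frame(transcript_id = "A", aa_start = 40L, aa_end = 58L)
  plen <- c(A = 100L)
  set.seed(8)
  starts <- replicate(10000, randomizeTmdPositions(tmds, plen)$aa_start)
  expect_setequal(sort(unique(starts)), 1:82)
  gof <- suppressWarnings(stats::chisq.test(table(factor(starts, 1:82))))
  expect_gt(gof$p.value, 0.01)
})

test_that("random heptamer sets are distinct, sized, and unbiased", {
  sets <- sampleRandomHeptamerSets(20, 465, seed = 3)
  expect_length(sets, 20L)
  expect_true(all(vapply(sets, function(s)
    length(s) == 465L && !anyDuplicated(s), TRUE)))
  expect_identical(anyDuplicated(vapply(sets, paste, "", collapse = "")), 0L)
  full <- sampleRandomHeptamerSets(1, 16384, seed = 1)
  expect_length(full[[1]], 16384L)
  expect_error(sampleRandomHeptamerSets(2, 16384), "distinct")
  # inclusion frequency of a fixed heptamer ~ Binomial(n, 465/16384)
  big <- sampleRandomHeptamerSets(400, 465, seed = 9)
  freq <- mean(vapply(big, function(s) "AAAAAAG" %in% s, TRUE))
  p0 <- 465 / 16384
  expect_lt(abs(freq - p0), 4 * sqrt(p0 * (1 - p0) / 400))
})

test_that("Mann-Whitney agrees with exact references and handles ties", {
  expect_equal(mannWhitneyU(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1)
  same <- mannWhitneyU(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 4.5)
  expect_equal(same$p_value, 1)
  expect_equal(mannWhitneyU(rep(0, 40), rep(0, 35))$p_value, 1)
  expect_error(mannWhitneyU(numeric(0), 1), "non-empty")
  set.seed(6)
  # tie-free small samples against wilcox.test's exact distribution
  for (rep in 1:20) {
    x <- sample(1:100, sample(3:8, 1))
    y <- sample(1:100, sample(3:8, 1)) + 0.5  # offset grid: no ties
    expect_equal(mannWhitneyU(x, y)$p_value,
                 stats::wilcox.test(x, y, exact = TRUE)$p.value)
  }
  # tied small samples against the pairwise-comparison oracle
  for (rep in 1:20) {
    x <- sample(1:4, sample(3:8, 1), replace = TRUE)
    y <- sample(2:5, sample(3:8, 1), replace = TRUE)
    expect_equal(mannWhitneyU(x, y)$p_value, oracle_mw_p(x, y))
  }
  # large-sample path tracks wilcox.test's normal approximation
  x <- rnorm(60); y <- rnorm(55, 0.3)
  expect_equal(mannWhitneyU(x, y)$p_value,
               stats::wilcox.test(x, y, exact = FALSE)$p.value)
})

test_that("Fisher test matches hypergeometric enumeration and sample OR", {
  expect_equal(fisherExact(matrix(c(10, 10, 10, 10), 2))$odds_ratio, 1)
  expect_equal(fisherExact(matrix(c(5, 0, 0, 5), 2, byrow = TRUE))$p_value,
               2 / 252)
  expect_equal(fisherExact(matrix(c(0, 0, 5, 5), 2))$p_value, 1)
  set.seed(14)
  for (rep in 1:30) {
    tb <- matrix(sample(0:6, 4, replace = TRUE), 2)
    if (any(rowSums(tb) == 0) || any(colSums(tb) == 0)) next
    expect_equal(fisherExact(tb)$p_value,
                 oracle_fisher_p(tb[1, 1], tb[1, 2], tb[2, 1], tb[2, 2]),
                 tolerance = 1e-12)
    expect_equal(fisherExact(tb)$odds_ratio,
                 tb[1, 1] * tb[2, 2] / (tb[1, 2] * tb[2, 1]))
  }
})

test_that("chi-squared association matches the textbook formula", {
  tb <- matrix(c(20, 10, 10, 20), 2)
  n <- sum(tb)
  want <- n * (tb[1, 1] * tb[2, 2] - tb[1, 2] * tb[2, 1])^2 /
    prod(rowSums(tb), colSums(tb))
  got <- chi2Association(tb)
  expect_equal(got$statistic, want)
  prop <- matrix(c(10, 20, 20, 40), 2)
  expect_equal(chi2Association(prop)$statistic, 0)
  expect_equal(chi2Association(prop)$p_value, 1)
  expect_error(chi2Association(matrix(c(0, 0, 5, 5), 2)), "fisherExact")
})

test_that("positional null test flags planted ideal spacing", {
  # ~30% of transcripts carry an ideal-spacing motif; the rest have a TMD
  # with their planted heptamer out of range, over a natural slippery
  # background. A point mass at L = 45 sits at the centre of the null
  # distance distribution, so the ideal-spacing odds ratio (not the rank
  # test) is the sensitive detector here.
  tab <- slip_tab()
  pm <- data.frame(L = c(45L, 72L, 72L), heptamer = "AAAAAAG",
                   tmd_len = 19L, isoform_only = FALSE, canonical_L = 90L)
  g <- generateTranscriptome(simConfig(n_genes = 60, planted_motifs = pm,
                                       cds_length_range = c(300L, 380L),
                                       background_slippery_rate = 1,
                                       seed = 44), tab)
  tmds <- findTmds(g$transcripts)
  r <- positionalNullTest(g$transcripts, tmds, tab, n_iterations = 200,
                          seed = 2)
  expect_gt(r$ideal_test$odds_ratio, 1)
  expect_lt(r$ideal_test$p_value, 0.01)
  expect_identical(sum(r$histogram$observed), length(r$observed_L))
  # a single iteration still returns a well-formed result
  r1 <- positionalNullTest(g$transcripts, tmds, tab, n_iterations = 1,
                           seed = 2)
  expect_identical(r1$n_iterations, 1L)
  expect_true(is.numeric(r1$null_L))
})

test_that("NMD association detects a planted shift and respects nulls", {
  up <- generateUpf1Table(300, 300, effect_log2fc = 0.4, noise_sd = 0.5,
                          seed = 21)
  r <- nmdAssociation(up)
  expect_lt(r$mw$p_value, 0.001)
  expect_gt(r$fisher_up$odds_ratio, 1)
  expect_lt(r$fisher_down$odds_ratio, 1)
  flat <- data.frame(log2_fold_change = rep(0, 40),
                     has_motif = rep(c(TRUE, FALSE), 20))
  expect_equal(nmdAssociation(flat)$mw$p_value, 1)
  expect_error(nmdAssociation(data.frame(log2_fold_change = 1:3,
                                         has_motif = rep(TRUE, 3))),
               "both motif classes")
})

test_that("term enrichment applies Fisher tests and the retention filters", {
  bg <- sprintf("g%03d", 1:60)
  hits <- bg[1:20]
  ann <- rbind(
    data.frame(term = "hit_only", gene = hits, depth = 4L),
    data.frame(term = "everything", gene = bg, depth = 4L),
    data.frame(term = "too_shallow", gene = hits, depth = 2L))
  res <- termEnrichment(hits, bg, ann, min_genes = 10L, min_fold = 1.4,
                        depth_range = c(3L, 8L))
  expect_identical(res$term, "hit_only")
  expect_identical(res$odds_ratio, Inf)
  # hand-computed Fisher for the retained term
  expect_equal(res$p_value, oracle_fisher_p(20, 0, 0, 40), tolerance = 1e-12)
  # min_genes exclusion
  res2 <- termEnrichment(hits, bg, ann, min_genes = 21L)
  expect_identical(nrow(res2), 0L)
  expect_identical(nrow(termEnrichment(hits, bg, ann[0, ])), 0L)
})
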