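test_that("generation is byte-deterministic under a fixed seed", {
  tab <- slip_tab()
  cfg <- simConfig(n_genes = 4, seed = 77)
  g1 <- generateTranscriptome(cfg, tab)
  g2 <- generateTranscriptome(cfg, tab)
  expect_identical(as.character(cdsSequences(g1$transcripts)),
                   as.character(cdsSequences(g2$transcripts)))
  expect_identical(g1$truth, g2$truth)
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  writeCdsFasta(g1$transcripts, f1)
  writeCdsFasta(g2$transcripts, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("generator output is valid input for the FASTA reader", {
  tab <- slip_tab()
  g <- generateTranscriptome(simConfig(n_genes = 3, isoforms_per_gene = 2,
                                       seed = 55), tab)
  f <- withr::local_tempfile(fileext = ".fa")
  writeCdsFasta(g$transcripts, f)
  back <- readCdsFasta(f)
  expect_identical(as.character(cdsSequences(back)),
                   as.character(cdsSequences(g$transcripts)))
  expect_identical(isoformClass(back), isoformClass(g$transcripts))
})

test_that("truth tables are consistent with the emitted sequences", {
  tab <- slip_tab()
  pm <- data.frame(L = c(45L, 39L), heptamer = "AAAAAAG", tmd_len = 19L,
                   isoform_only = c(FALSE, TRUE), canonical_L = 67L)
  g <- generateTranscriptome(simConfig(n_genes = 4, isoforms_per_gene = 2,
                                       planted_motifs = pm, seed = 61), tab)
  cds <- as.character(cdsSequences(g$transcripts))
  names(cds) <- transcriptIds(g$transcripts)
  for (i in seq_len(nrow(g$truth))) {
    tr <- g$truth[i, ]
    expect_identical(substr(cds[[tr$transcript_id]], tr$heptamer_nt_start,
                            tr$heptamer_nt_start + 6L), tr$heptamer)
    expect_identical(tr$heptamer_nt_start %/% 3L + 1L - tr$tmd_aa_end, tr$L)
  }
})

test_that("motif-free scrubbed transcriptomes yield no motifs at all", {
  tab <- slip_tab()
  g <- generateTranscriptome(simConfig(n_genes = 5, planted_motifs = NULL,
                                       seed = 83), tab)
  expect_identical(nrow(g$truth), 0L)
  # scrubbing removed every phase-aligned slippery heptamer
  for (s in as.character(cdsSequences(g$transcripts)))
    expect_identical(nrow(tmdslip:::.scan_slippery(s, tab)), 0L)
  tmds <- findTmds(g$transcripts)
  expect_identical(nrow(findMotifs(g$transcripts, tmds, tab)), 0L)
})

test_that("infeasible planted geometry is a clean error", {
  cfg <- simConfig(n_genes = 1, cds_length_range = c(60L, 60L),
                   planted_motifs = data.frame(L = 200L,
                                               heptamer = "AAAAAAG",
                                               tmd_len = 19L,
                                               isoform_only = FALSE,
                                               canonical_L = 250L))
  expect_error(generateTranscriptome(cfg, slip_tab()), "infeasible")
})

test_that("UPF1 tables are seeded and carry the planted shift", {
  t1 <- generateUpf1Table(50, 60, seed = 4)
  t2 <- generateUpf1Table(50, 60, seed = 4)
  expect_identical(t1, t2)
  expect_identical(sum(t1$has_motif), 50L)
  big <- generateUpf1Table(5000, 5000, effect_log2fc = 0.3, noise_sd = 0.5,
                           seed = 10)
  expect_equal(mean(big$log2_fold_change[big$has_motif]) -
                 mean(big$log2_fold_change[!big$has_motif]), 0.3,
               tolerance = 0.05)
  expect_error(generateUpf1Table(10, 10, noise_sd = 0), "positive")
})

test_that("fixture classes cover the feasible set and skip the rest", {
  tab <- slip_tab()
  pm <- data.frame(L = 45L, heptamer = "UUUUAAA", tmd_len = 19L,
                   isoform_only = FALSE, canonical_L = 67L)
  g <- generateTranscriptome(simConfig(n_genes = 2, planted_motifs = pm,
                                       seed = 91), tab)
  # UUUUAAA shifts straight into a -1 stop: frameshift class unrealizable
  msgs <- capture_messages(fx <- generatePeptideFixtures(g$transcripts,
                                                         g$truth))
  expect_true(any(grepl("frameshift unrealizable", msgs)))
  expect_true(all(c("zero_frame", "premature_termination") %in% fx$label))
  expect_false("frameshift" %in% fx$label)
})
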