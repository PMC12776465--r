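# CDS with a slip site whose -1 frame behaviour is fully controlled:
# background GCU codons, heptamer at P-site codon k, and optionally a -1
# frame stop planted n_ext codons after the shifted A-site.
shifted_cds <- function(n_codons, k, heptamer = "AAAAAAG", ext_stop = NULL) {
  cds <- paste0(paste(rep("GCU", n_codons - 1), collapse = ""), "UAA")
  h <- 3L * k - 3L
  substr(cds, h, h + 6L) <- heptamer
  if (!is.null(ext_stop)) {
    p <- (h + 3L) + 3L * ext_stop      # -1 frame codon ext_stop+1 start
    substr(cds, p, p + 2L) <- "UAA"
  }
  cds
}

test_that("an immediate shifted-frame stop gives a premature-termination product", {
  cds <- shifted_cds(60, 20, "UUUUAAA")  # shifted A-site codon is UAA
  pr <- predictFrameshiftProduct(cds, list(heptamer_nt_start = 3L * 20 - 3L))
  expect_identical(pr$extension_len, 0L)
  expect_true(pr$terminated)
  expect_identical(nchar(pr$prefix), 20L)  # through the P-site residue
})

test_that("extension length counts -1 codons to the planted stop", {
  # prompt termination after eight -1 codons (HSP90B1-like geometry)
  pr8 <- predictFrameshiftProduct(
    shifted_cds(80, 20, ext_stop = 8L),
    list(heptamer_nt_start = 57L))
  expect_identical(pr8$extension_len, 8L)
  expect_true(pr8$terminated)
  # an uninterrupted 121-codon -1 open stretch (LPCAT1-like geometry)
  pr121 <- predictFrameshiftProduct(
    shifted_cds(180, 20, ext_stop = 121L),
    list(heptamer_nt_start = 57L))
  expect_identical(pr121$extension_len, 121L)
  expect_true(pr121$terminated)
})

test_that("extension equals translation of the shifted suffix", {
  set.seed(23)
  for (rep in 1:20) {
    cds <- paste0(random_rna(150 * 3))
    k <- sample(10:30, 1)
    h <- 3L * k - 3L
    substr(cds, h, h + 6L) <- "AAAAAAG"
    for (fr in c(-1L, -2L, 1L)) {
      pr <- predictFrameshiftProduct(cds, list(heptamer_nt_start = h), fr)
      expect_identical(pr$extension, translateCds(cds, 3L * k + 1L, fr))
      expect_identical(pr$prefix, translateCds(substr(cds, 1, 3 * k)))
      expect_false(grepl("\\*", paste0(pr$prefix, pr$extension)))
    }
  }
})

test_that("running off the sequence end leaves the product unterminated", {
  cds <- paste0(paste(rep("GCU", 29), collapse = ""), "UAA")
  h <- 3L * 10 - 3L
  substr(cds, h, h + 6L) <- "AAAAAAG"
  pr <- predictFrameshiftProduct(cds, list(heptamer_nt_start = h), -1L)
  expect_false(pr$terminated)
})

test_that("digestion obeys protease rules and reconstructs the input", {
  expect_identical(digestProtein("MKRGLK", proteaseRule("trypsin", 0))$peptide,
                   c("MK", "R", "GLK"))
  # proline blocks tryptic cleavage
  expect_identical(digestProtein("MKPGLR", proteaseRule("trypsin", 0))$peptide,
                   c("MKPGLR"))
  expect_identical(digestProtein("AAAA", proteaseRule("trypsin", 0))$peptide,
                   "AAAA")
  set.seed(31)
  for (nm in c("trypsin", "lysC", "lysN", "gluC", "aspN", "chymotrypsin")) {
    p <- random_protein(60)
    d0 <- digestProtein(p, proteaseRule(nm, 0))
    expect_identical(paste(d0$peptide, collapse = ""), p)
    d1 <- digestProtein(p, proteaseRule(nm, 1))
    expect_true(all(d0$peptide %in% d1$peptide))
    d2 <- digestProtein(p, proteaseRule(nm, 2))
    expect_true(all(d1$peptide %in% d2$peptide))
  }
})

test_that("the second-pass database is disjoint from 0-frame peptides", {
  tab <- slip_tab()
  g <- generateTranscriptome(simConfig(n_genes = 4, seed = 19), tab)
  tmds <- findTmds(g$transcripts)
  m <- findMotifs(g$transcripts, tmds, tab)
  db <- buildFrameshiftPeptideDb(g$transcripts, m)
  expect_gt(nrow(db), 0L)
  zf <- tmdslip:::.zero_frame_peptides(translateSet(g$transcripts),
                                       list(proteaseRule("trypsin")),
                                       c(7L, 50L))
  expect_false(any(db$peptide %in% zf))
  # every emitted peptide maps back to its transition or extension
  cds <- as.character(cdsSequences(g$transcripts))
  names(cds) <- transcriptIds(g$transcripts)
  for (i in seq_len(nrow(db))) {
    pr <- predictFrameshiftProduct(
      cds[[db$transcript_id[i]]],
      list(heptamer_nt_start = db$heptamer_nt_start[i]), db$frame[i])
    prod <- paste0(pr$prefix, pr$extension)
    at <- regexpr(db$peptide[i], prod, fixed = TRUE)
    expect_gt(at, 0L)
    expect_gt(at + nchar(db$peptide[i]) - 1L, nchar(pr$prefix))
  }
  # empty motif table -> empty database
  expect_identical(nrow(buildFrameshiftPeptideDb(g$transcripts, m[0, ])), 0L)
})

test_that("peptide classification recovers every fixture label", {
  tab <- slip_tab()
  pm <- data.frame(L = c(45L, 45L), heptamer = c("AAAAAAG", "UUUUAAA"),
                   tmd_len = 19L, isoform_only = FALSE, canonical_L = 67L)
  g <- generateTranscriptome(simConfig(n_genes = 6, planted_motifs = pm,
                                       seed = 29), tab)
  tmds <- findTmds(g$transcripts)
  m <- findMotifs(g$transcripts, tmds, tab)
  fx <- suppressMessages(generatePeptideFixtures(g$transcripts, g$truth))
  expect_setequal(unique(fx$label),
                  c("zero_frame", "transitional", "frameshift",
                    "premature_termination"))
  calls <- vapply(seq_len(nrow(fx)), function(i)
    classifyPeptide(fx$peptide[i], g$transcripts, m)$call, "")
  expect_identical(calls, fx$label)
  # classification is invariant to transcript order
  rev_ts <- g$transcripts[rev(seq_len(length(g$transcripts)))]
  calls_rev <- vapply(seq_len(nrow(fx)), function(i)
    classifyPeptide(fx$peptide[i], rev_ts, m)$call, "")
  expect_identical(calls_rev, calls)
})

test_that("every 0-frame digest peptide classifies as zero_frame", {
  tab <- slip_tab()
  g <- generateTranscriptome(simConfig(n_genes = 3, seed = 37), tab)
  tmds <- findTmds(g$transcripts)
  m <- findMotifs(g$transcripts, tmds, tab)
  prot <- translateSet(g$transcripts)[1]
  d <- digestProtein(prot, proteaseRule("trypsin", 0))
  peps <- d$peptide[nchar(d$peptide) >= 7]
  for (p in utils::head(peps, 10)) {
    cl <- classifyPeptide(p, g$transcripts, m)
    expect_identical(cl$call, "zero_frame")
  }
})
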