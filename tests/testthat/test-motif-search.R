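# Hand-built transcript: background of GCU (Ala) codons, a fake TMD entry
# supplied directly, and slippery heptamers planted at chosen P-site codons.
plant_transcript <- function(n_codons, p_sites, heptamer = "AAAAAAG") {
  cds <- paste(rep("GCU", n_codons - 1), collapse = "")
  cds <- paste0(cds, "UAA")
  for (k in p_sites) {
    h <- 3L * k - 3L
    substr(cds, h, h + 6L) <- heptamer
  }
  cds
}

fake_tmds <- function(tid, ends) {
  data.frame(transcript_id = tid, region_start = ends - 18L,
             region_end = ends, aa_start = ends - 18L, aa_end = ends,
             length = 19L, dg_app = -5, source = "builtin_scan")
}

test_that("computeDistance implements the spacing definition", {
  expect_identical(computeDistance(100L, ntPos(145L) - 1L), 45L)
  expect_identical(computeDistance(10L, 30L), 1L)  # P-site = aa_end + 1
  expect_identical(computeDistance(100L, 300L, "c_term_to_heptamer_start"),
                   0L + NA)  # codon 100 itself: not downstream
  expect_true(is.na(computeDistance(50L, 60L)))    # heptamer upstream
  expect_error(computeDistance(10L, 31L), "phase")
})

test_that("nearest-to-ideal dedup keeps the motif closest to 45 codons", {
  cds <- plant_transcript(200, c(140, 146))  # L = 40 and 46 from aa_end 100
  ts <- TranscriptSet(cds, "T1")
  m <- findMotifs(ts, fake_tmds("T1", 100L), slip_tab())
  expect_identical(nrow(m), 1L)
  expect_identical(m$distance_L, 46L)
  expect_false(m$is_ideal)
  m2 <- findMotifs(TranscriptSet(plant_transcript(200, 145), "T1"),
                   fake_tmds("T1", 100L), slip_tab())
  expect_true(m2$is_ideal)
})

test_that("tie in |L - 45| resolves to the smaller distance", {
  # adjacent heptamers overlap by one base, so pick a compatible pair
  # (first ends in G, second starts with G) that does not chain into
  # further slippery phase heptamers
  cds <- plant_transcript(200, 144)                 # AAAAAAG, L = 44
  substr(cds, 435, 441) <- "GCAAAAA"                # L = 46
  m <- findMotifs(TranscriptSet(cds, "T1"), fake_tmds("T1", 100L), slip_tab())
  expect_identical(m$distance_L, 44L)
  expect_identical(m$heptamer, "AAAAAAG")
})

test_that("no motifs are reported without in-range slippery heptamers", {
  cds <- plant_transcript(200, 170)  # L = 70: out of range
  m <- findMotifs(TranscriptSet(cds, "T1"), fake_tmds("T1", 100L), slip_tab())
  expect_identical(nrow(m), 0L)
  m2 <- findMotifs(TranscriptSet(plant_transcript(200, integer(0)), "T1"),
                   fake_tmds("T1", 100L), slip_tab())
  expect_identical(nrow(m2), 0L)
})

test_that("assignment and dedup match the brute-force pairing oracle", {
  set.seed(17)
  for (rep in 1:50) {
    psite <- sort(sample(1:300, sample(0:8, 1)))
    ends <- sort(sample(1:250, sample(0:4, 1)))
    got <- tmdslip:::.assign_motifs(psite, ends, c(35L, 55L), 45L)
    want <- brute_assign(psite, ends, c(35L, 55L), 45L)
    expect_identical(got$h, want$h)
    expect_identical(got$t, want$t)
    expect_identical(got$L, want$L)
    # dedup correctness: no TMD or heptamer used twice
    expect_false(anyDuplicated(got$t) > 0)
    expect_false(anyDuplicated(got$h) > 0)
  }
})

test_that("motif output is invariant to transcript order", {
  cds1 <- plant_transcript(200, 145)
  cds2 <- plant_transcript(220, 150, "AAAAAAC")
  tmds <- rbind(fake_tmds("A", 100L), fake_tmds("B", 110L))
  tsa <- TranscriptSet(c(cds1, cds2), c("A", "B"))
  tsb <- TranscriptSet(c(cds2, cds1), c("B", "A"))
  ma <- findMotifs(tsa, tmds, slip_tab())
  mb <- findMotifs(tsb, tmds, slip_tab())
  expect_identical(ma, mb)
})

test_that("splicing dependence follows the canonical-distance rule", {
  # same heptamer: canonical at L = 67 (out of range), isoform at L = 39
  can <- plant_transcript(220, 167)
  iso <- plant_transcript(192, 139)
  ts <- TranscriptSet(c(can, iso), c("C1", "I1"), gene_id = c("G", "G"),
                      isoform_class = c("canonical", "alternative"))
  tmds <- rbind(fake_tmds("C1", 100L), fake_tmds("I1", 100L))
  m <- classifySplicingDependence(findMotifs(ts, tmds, slip_tab()), ts)
  expect_identical(m$transcript_id, "I1")
  expect_identical(m$splicing_class, "splicing_dependent")
  # identical motif in canonical and isoform: not splicing-dependent
  ts2 <- TranscriptSet(c(plant_transcript(220, 145),
                         plant_transcript(220, 145)),
                       c("C1", "I1"), gene_id = c("G", "G"),
                       isoform_class = c("canonical", "alternative"))
  m2 <- classifySplicingDependence(findMotifs(ts2, tmds, slip_tab()), ts2)
  expect_setequal(m2$splicing_class, c("canonical", "shared_with_canonical"))
  # gene with no canonical transcript
  ts3 <- TranscriptSet(plant_transcript(192, 139), "I1", gene_id = "G",
                       isoform_class = "alternative")
  m3 <- classifySplicingDependence(
    findMotifs(ts3, fake_tmds("I1", 100L), slip_tab()), ts3)
  expect_identical(m3$splicing_class, "not_applicable")
  # two canonical transcripts for one gene is a data problem
  ts4 <- TranscriptSet(c(can, can), c("C1", "C2"), gene_id = c("G", "G"),
                       isoform_class = c("canonical", "canonical"))
  expect_error(classifySplicingDependence(m, ts4), "multiple canonical")
})
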