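.STOP_CODONS <- c("UAA", "UAG", "UGA")

.sense_codons <- function() {
  all <- as.vector(outer(as.vector(outer(c("A", "C", "G", "U"),
                                         c("A", "C", "G", "U"), paste0)),
                         c("A", "C", "G", "U"), paste0))
  setdiff(all, .STOP_CODONS)
}

# codons per amino acid (standard code), stops excluded; cached
.codon_env <- new.env(parent = emptyenv())
.codons_for <- function(aa) {
  if (is.null(.codon_env$map)) {
    sc <- .sense_codons()
    tr <- vapply(sc, function(cc)
      as.character(Biostrings::translate(Biostrings::RNAString(cc))), "")
    .codon_env$map <- split(sc, tr)
  }
  .codon_env$map[[aa]]
}

#' Simulation configuration for synthetic transcriptomes
#'
#' Bundles the knobs of [generateTranscriptome()]. Planted motifs are
#' recycled across genes; set `planted_motifs = NULL` for motif-free
#' transcriptomes. `isoform_only = TRUE` plants the heptamer at
#' `canonical_L` codons (outside the search range) in the canonical
#' transcript and derives an alternative isoform by deleting spacer codons
#' so the same heptamer falls at `L` — the splicing-dependent geometry.
#'
#' @param n_genes Number of genes.
#' @param isoforms_per_gene Transcripts per gene (>= 1; the first is
#'   canonical).
#' @param cds_length_range Range of CDS lengths in codons (stop codon
#'   included).
#' @param planted_motifs `NULL`, or a data.frame (recycled over genes) with
#'   columns `L`, `heptamer`, `tmd_len`, `isoform_only`, `canonical_L`.
#' @param background_slippery_rate 0 (default) scrubs accidental
#'   phase-aligned slippery heptamers near TMDs; any positive value leaves
#'   the natural background in place.
#' @param codon_usage Optional named weights over sense codons (default
#'   uniform).
#' @param seed Integer seed.
#' @return A `SimConfig` list.
#' @export
simConfig <- function(n_genes = 10L, isoforms_per_gene = 1L,
                      cds_length_range = c(250L, 350L),
                      planted_motifs = data.frame(
                        L = 45L, heptamer = "AAAAAAG", tmd_len = 19L,
                        isoform_only = FALSE, canonical_L = 67L),
                      background_slippery_rate = 0,
                      codon_usage = NULL, seed = 1L) {
  if (!is.null(planted_motifs)) {
    stopifnot(all(planted_motifs$L > 0L))
    if (is.null(planted_motifs$isoform_only))
      planted_motifs$isoform_only <- FALSE
    if (is.null(planted_motifs$canonical_L))
      planted_motifs$canonical_L <- 67L
  }
  structure(list(n_genes = as.integer(n_genes),
                 isoforms_per_gene = as.integer(isoforms_per_gene),
                 cds_length_range = as.integer(cds_length_range),
                 planted_motifs = planted_motifs,
                 background_slippery_rate = background_slippery_rate,
                 codon_usage = codon_usage, seed = as.integer(seed)),
            class = "SimConfig")
}

.sample_codons <- function(n, cfg) {
  sc <- .sense_codons()
  w <- if (is.null(cfg$codon_usage)) NULL else cfg$codon_usage[sc]
  sample(sc, n, replace = TRUE, prob = w)
}

# Replace codon `k` (1-based) of a codon-string CDS.
.set_codon <- function(cds, k, codon) {
  substr(cds, 3L * k - 2L, 3L * k) <- codon
  cds
}

# Mutate one free position of an accidental slippery heptamer so that the
# heptamer itself stops being slippery, without creating a 0-frame stop.
# Free positions are those outside every protected span.
.break_heptamer <- function(cds, h, protected, table) {
  span <- h:(h + 6L)
  free <- span[!span %in% protected]
  for (pos in free) {
    cur <- substr(cds, pos, pos)
    for (b in c("C", "G", "A", "U")) {
      if (b == cur) next
      cand <- cds
      substr(cand, pos, pos) <- b
      k <- codonIndex(pos)
      if (substr(cand, 3L * k - 2L, 3L * k) %in% .STOP_CODONS) next
      if (isSlippery(table, substr(cand, h, h + 6L))) next
      return(cand)
    }
  }
  cds  # nothing mutable; caller will regenerate
}

# Bounded mutate-and-rescan loop removing accidental phase-aligned slippery
# heptamers whose P-site falls in the guard window around the TMD end.
# Returns the scrubbed CDS, or NULL when stuck (caller regenerates/errors).
.scrub_cds <- function(cds, tmd_end, hept_nt, protected, table, l_range) {
  for (pass in 1:50) {
    hits <- .scan_slippery(cds, table)
    if (!is.null(hept_nt))
      hits <- hits[hits$nt_start != hept_nt, , drop = FALSE]
    if (!is.null(tmd_end) && nrow(hits)) {
      Lh <- hits$nt_start %/% 3L + 1L - tmd_end
      hits <- hits[Lh >= l_range[1] - 5L & Lh <= l_range[2] + 5L, ,
                   drop = FALSE]
    }
    if (nrow(hits) == 0L) return(cds)
    cds2 <- .break_heptamer(cds, hits$nt_start[1L], protected, table)
    if (identical(cds2, cds)) return(NULL)
    cds <- cds2
  }
  NULL
}

.build_transcript <- function(n_codons, motif, cfg, table, l_range) {
  hydro <- c("L", "I", "V", "F")
  polar <- c("D", "E", "N", "Q", "K", "R")
  for (attempt in 1:25) {
    cod <- .sample_codons(n_codons - 1L, cfg)
    cds <- paste0(paste(cod, collapse = ""), sample(.STOP_CODONS, 1L))
    planted <- NULL
    protected <- integer(0)
    if (!is.null(motif)) {
      tlen <- motif$tmd_len
      Lp <- if (isTRUE(motif$isoform_only)) motif$canonical_L else motif$L
      # geometry: [flank2][TMD tlen][flank2] ... P-site codon at tmd_end+Lp
      t0_max <- n_codons - 2L - (Lp + 1L) - tlen - 2L
      if (t0_max < 13L)
        stop("planted motif infeasible: L=", Lp, " needs a longer CDS (",
             n_codons, " codons)")
      t0 <- sample(13L:min(30L, t0_max), 1L)
      aa <- sample(hydro, tlen, replace = TRUE)
      for (i in seq_len(tlen))
        cds <- .set_codon(cds, t0 + i - 1L, sample(.codons_for(aa[i]), 1L))
      for (d in 1:2) {  # hydrophilic flanks pin the refined segment edges
        cds <- .set_codon(cds, t0 - d, sample(.codons_for(sample(polar, 1L)), 1L))
        cds <- .set_codon(cds, t0 + tlen - 1L + d,
                          sample(.codons_for(sample(polar, 1L)), 1L))
      }
      tmd_end <- t0 + tlen - 1L
      k <- tmd_end + Lp                   # P-site codon index
      h <- 3L * k - 3L                    # heptamer nt start (phase 0 mod 3)
      cds <- .set_codon(cds, k - 1L, paste0("GC", substr(motif$heptamer, 1L, 1L)))
      substr(cds, h, h + 6L) <- motif$heptamer
      if (substr(cds, 3L * k - 2L, 3L * k) %in% .STOP_CODONS ||
          substr(cds, 3L * k + 1L, 3L * k + 3L) %in% .STOP_CODONS)
        stop("planted heptamer ", motif$heptamer,
             " would introduce a 0-frame stop codon")
      planted <- list(tmd_start = t0, tmd_end = tmd_end, hept_nt = h,
                      p_site = k)
      protected <- c((3L * t0 - 2L):(3L * tmd_end), h:(h + 6L))
    }
    if (cfg$background_slippery_rate > 0)
      return(list(cds = cds, planted = planted, protected = protected))
    cds <- .scrub_cds(cds, if (is.null(planted)) NULL else planted$tmd_end,
                      if (is.null(planted)) NULL else planted$hept_nt,
                      protected, table, l_range)
    if (!is.null(cds))
      return(list(cds = cds, planted = planted, protected = protected))
  }
  stop("failed to generate a clean transcript after bounded retries")
}

# Derive an isoform by deleting `drop` codons starting at codon `at`
# (1-based), then re-scrub around the (possibly shifted) planted motif.
.derive_isoform <- function(bt, at, drop, cfg, table, l_range) {
  cds <- bt$cds
  from <- 3L * (at - 1L) + 1L
  iso <- paste0(substr(cds, 1L, from - 1L),
                substr(cds, from + 3L * drop, nchar(cds)))
  shift <- function(p) ifelse(p >= from, p - 3L * drop, p)
  planted <- bt$planted
  if (!is.null(planted)) {
    planted$hept_nt <- shift(planted$hept_nt)
    planted$p_site <- planted$hept_nt %/% 3L + 1L
  }
  protected <- unique(shift(bt$protected))
  if (cfg$background_slippery_rate == 0) {
    iso <- .scrub_cds(iso, if (is.null(planted)) NULL else planted$tmd_end,
                      if (is.null(planted)) NULL else planted$hept_nt,
                      protected, table, l_range)
    if (is.null(iso)) stop("could not scrub derived isoform")
  }
  list(cds = iso, planted = planted)
}

#' Generate a synthetic transcriptome with known motif ground truth
#'
#' Emulates a coding transcriptome for end-to-end pipeline validation:
#' random sense-codon background, codon-randomized strongly hydrophobic
#' TMD blocks (L/I/V/F) with hydrophilic flanks so the built-in scanner and
#' segment refinement recover them unambiguously, and slippery heptamers
#' planted phase-aligned at configured codon distances. With
#' `background_slippery_rate = 0` the neighbourhood of every TMD is
#' scrubbed of accidental phase-aligned slippery heptamers (bounded
#' mutate-and-rescan passes, then regeneration). Splicing-dependent motifs
#' are realized by spacer-codon deletion in an alternative isoform (same
#' heptamer, shorter TMD distance). Deterministic under `cfg$seed`.
#'
#' @param cfg A [simConfig()].
#' @param table [SlipperyTable-class] used for planting/scrubbing
#'   (default: the calibrated census).
#' @param l_range Motif search range the truth refers to.
#' @return List: `transcripts` ([TranscriptSet-class]), `truth`
#'   (data.frame, one row per planted in-range motif: `transcript_id`,
#'   `gene_id`, `tmd_aa_start`, `tmd_aa_end`, `heptamer`,
#'   `heptamer_nt_start`, `L`, `splicing_dependent`), and
#'   `transcript_truth` (`transcript_id`, `has_motif`).
#' @export
generateTranscriptome <- function(cfg, table = enumerateSlipperyHeptamers(),
                                  l_range = c(35L, 55L)) {
  set.seed(cfg$seed)
  seqs <- character(0); tid <- character(0); gid <- character(0)
  cls <- character(0); truth <- list(); has_motif <- logical(0)
  pm <- cfg$planted_motifs
  for (g in seq_len(cfg$n_genes)) {
    motif <- if (is.null(pm)) NULL else
      as.list(pm[(g - 1L) %% nrow(pm) + 1L, ])
    n_codons <- sample(seq(cfg$cds_length_range[1], cfg$cds_length_range[2]),
                       1L)
    bt <- .build_transcript(n_codons, motif, cfg, table, l_range)
    gene <- sprintf("SIMG%04d", g)
    can_id <- sprintf("SIMT%04d.1", g)
    seqs <- c(seqs, bt$cds); tid <- c(tid, can_id); gid <- c(gid, gene)
    cls <- c(cls, "canonical")
    iso_only <- !is.null(motif) && isTRUE(motif$isoform_only)
    can_has <- !is.null(motif) && !iso_only &&
      motif$L >= l_range[1] && motif$L <= l_range[2]
    has_motif <- c(has_motif, can_has)
    if (can_has)
      truth[[length(truth) + 1L]] <- data.frame(
        transcript_id = can_id, gene_id = gene,
        tmd_aa_start = bt$planted$tmd_start, tmd_aa_end = bt$planted$tmd_end,
        heptamer = motif$heptamer, heptamer_nt_start = bt$planted$hept_nt,
        L = motif$L, splicing_dependent = FALSE)
    n_iso <- cfg$isoforms_per_gene - 1L
    for (j in seq_len(max(0L, n_iso))) {
      iso_id <- sprintf("SIMT%04d.%d", g, j + 1L)
      if (iso_only && j == 1L && !is.null(bt$planted)) {
        drop <- motif$canonical_L - motif$L
        if (drop <= 0L || bt$planted$tmd_end + 2L + drop >= bt$planted$p_site)
          stop("isoform_only motif infeasible: canonical_L=",
               motif$canonical_L, " L=", motif$L)
        dv <- .derive_isoform(bt, bt$planted$tmd_end + 3L, drop, cfg, table,
                              l_range)
        seqs <- c(seqs, dv$cds); tid <- c(tid, iso_id); gid <- c(gid, gene)
        cls <- c(cls, "alternative"); has_motif <- c(has_motif, TRUE)
        truth[[length(truth) + 1L]] <- data.frame(
          transcript_id = iso_id, gene_id = gene,
          tmd_aa_start = dv$planted$tmd_start,
          tmd_aa_end = dv$planted$tmd_end, heptamer = motif$heptamer,
          heptamer_nt_start = dv$planted$hept_nt,
          L = motif$L, splicing_dependent = TRUE)
      } else {
        # plain isoform: drop three codons just before the stop codon
        # (a motif, if any, keeps its geometry)
        n_cod <- nchar(bt$cds) %/% 3L
        dv <- .derive_isoform(bt, n_cod - 3L, 3L, cfg, table, l_range)
        seqs <- c(seqs, dv$cds); tid <- c(tid, iso_id); gid <- c(gid, gene)
        cls <- c(cls, "alternative"); has_motif <- c(has_motif, can_has)
        if (can_has)
          truth[[length(truth) + 1L]] <- data.frame(
            transcript_id = iso_id, gene_id = gene,
            tmd_aa_start = dv$planted$tmd_start,
            tmd_aa_end = dv$planted$tmd_end, heptamer = motif$heptamer,
            heptamer_nt_start = dv$planted$hept_nt, L = motif$L,
            splicing_dependent = FALSE)
      }
    }
  }
  ts <- TranscriptSet(seqs, transcript_id = tid, gene_id = gid,
                      gene_name = sub("SIMG", "simgene", gid),
                      isoform_class = cls)
  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(transcript_id = character(0), gene_id = character(0),
               tmd_aa_start = integer(0), tmd_aa_end = integer(0),
               heptamer = character(0), heptamer_nt_start = integer(0),
               L = integer(0), splicing_dependent = logical(0))
  list(transcripts = ts, truth = truth_df,
       transcript_truth = data.frame(transcript_id = tid,
                                     has_motif = has_motif))
}

#' Generate a synthetic UPF1-depletion fold-change table
#'
#' Non-motif transcripts draw `log2_fold_change ~ Normal(0, noise_sd)`;
#' motif-bearing transcripts draw from `Normal(effect_log2fc, noise_sd)`.
#'
#' @param n_with_motif,n_without Group sizes (> 0).
#' @param effect_log2fc Planted abundance shift for motif transcripts.
#' @param noise_sd Noise standard deviation (> 0).
#' @param seed Integer seed.
#' @return data.frame: `transcript_id`, `log2_fold_change`, `has_motif`.
#' @export
generateUpf1Table <- function(n_with_motif, n_without, effect_log2fc = 0.263,
                              noise_sd = 0.5, seed = NULL) {
  stopifnot(n_with_motif > 0L, n_without > 0L)
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (!is.null(seed)) set.seed(seed)
  data.frame(
    transcript_id = sprintf("UPF1T%05d", seq_len(n_with_motif + n_without)),
    log2_fold_change = c(stats::rnorm(n_with_motif, effect_log2fc, noise_sd),
                         stats::rnorm(n_without, 0, noise_sd)),
    has_motif = rep(c(TRUE, FALSE), c(n_with_motif, n_without)))
}

#' Generate labeled peptide fixtures from planted motifs
#'
#' Emits, per planted motif and requested class, a peptide whose label is
#' known by construction: a 0-frame peptide upstream of the TMD, a
#' transitional 7-mer (six prefix residues plus the first alternative-frame
#' residue), a frameshift 8-mer from inside the extension, and (for motifs
#' whose shifted frame immediately presents a stop) a premature-termination
#' peptide ending at the P-site residue. Classes unrealizable for a motif
#' (e.g. a too-short extension) are skipped with a message.
#'
#' @param x A [TranscriptSet-class].
#' @param truth Truth table from [generateTranscriptome()].
#' @param classes Classes to emit.
#' @param frame Alternative frame (default -1).
#' @return data.frame: `peptide`, `label`, `transcript_id`, `frame`.
#' @export
generatePeptideFixtures <- function(x, truth,
                                    classes = c("zero_frame", "transitional",
                                                "frameshift",
                                                "premature_termination"),
                                    frame = -1L) {
  out <- list()
  cds <- as.character(cdsSequences(x))
  names(cds) <- transcriptIds(x)
  for (i in seq_len(nrow(truth))) {
    tid <- truth$transcript_id[i]
    pr <- predictFrameshiftProduct(
      cds[[tid]], list(heptamer_nt_start = truth$heptamer_nt_start[i]),
      frame)
    if ("zero_frame" %in% classes) {
      pep <- substr(pr$prefix, 2L, 11L)
      if (nchar(pep) >= 7L)
        out[[length(out) + 1L]] <- data.frame(
          peptide = pep, label = "zero_frame", transcript_id = tid,
          frame = frame)
    }
    if ("transitional" %in% classes) {
      # the alt-frame tail must diverge from the 0-frame continuation, or
      # the peptide is indistinguishable from a 0-frame peptide (slippery
      # sites often decode the same residue in both frames at the shift)
      zf_cont <- translateCds(cds[[tid]],
                              3L * pr$p_site_codon + 1L, 0L)
      j <- NA_integer_
      for (jj in seq_len(min(pr$extension_len, 6L))) {
        if (substr(pr$extension, 1L, jj) != substr(zf_cont, 1L, jj)) {
          j <- jj; break
        }
      }
      if (!is.na(j) && nchar(pr$prefix) >= 6L)
        out[[length(out) + 1L]] <- data.frame(
          peptide = paste0(substr(pr$prefix, nchar(pr$prefix) - 5L,
                                  nchar(pr$prefix)),
                           substr(pr$extension, 1L, j)),
          label = "transitional", transcript_id = tid, frame = frame)
      else message("transitional unrealizable for ", tid, "; skipped")
    }
    if ("frameshift" %in% classes) {
      if (pr$extension_len >= 9L)
        out[[length(out) + 1L]] <- data.frame(
          peptide = substr(pr$extension, 2L, 9L), label = "frameshift",
          transcript_id = tid, frame = frame)
      else message("frameshift unrealizable for ", tid,
                   " (extension too short); skipped")
    }
    if ("premature_termination" %in% classes) {
      if (pr$terminated && pr$extension_len == 0L && nchar(pr$prefix) >= 8L)
        out[[length(out) + 1L]] <- data.frame(
          peptide = substr(pr$prefix, nchar(pr$prefix) - 7L,
                           nchar(pr$prefix)),
          label = "premature_termination", transcript_id = tid,
          frame = frame)
      else message("premature_termination unrealizable for ", tid,
                   "; skipped")
    }
  }
  if (!length(out))
    return(data.frame(peptide = character(0), label = character(0),
                      transcript_id = character(0), frame = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
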