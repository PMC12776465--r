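#' Predict the alternative-frame translation product of a motif
#'
#' The nascent chain up to and including the slip-site P-site residue is
#' decoded in the 0-frame (`prefix`). At the shift, the P-site and A-site
#' tRNAs re-pair, so the first residue decoded in the alternative frame is
#' the shifted A-site codon: translation of the `extension` starts at the
#' codon beginning `frame` nucleotides from the 0-frame A-site and runs to
#' the first alternative-frame stop codon. An immediate shifted-frame stop
#' yields a zero-length extension (a premature-termination product); a
#' shift running off the sequence end yields `terminated = FALSE`.
#'
#' @param record A single-transcript [TranscriptSet-class] or an RNA/
#'   character CDS.
#' @param motif One row of the [findMotifs()] table (needs
#'   `heptamer_nt_start`).
#' @param frame Frame offset: -1 (default), -2 or +1.
#' @return List with `prefix`, `extension`, `extension_len`, `terminated`,
#'   `frame`, and `p_site_codon` (codon index of the last 0-frame residue).
#' @export
predictFrameshiftProduct <- function(record, motif, frame = -1L) {
  stopifnot(frame %in% c(-1L, -2L, 1L))
  cds <- if (is(record, "TranscriptSet"))
    as.character(cdsSequences(record))[[1]] else as.character(record)
  h <- as.integer(motif$heptamer_nt_start)
  if (h %% 3L != 0L || h + 6L > nchar(cds))
    stop("motif heptamer_nt_start does not fit this record")
  k <- h %/% 3L + 1L                  # P-site codon index
  prefix <- translateCds(substr(cds, 1L, 3L * k))
  a_site_nt <- 3L * k + 1L            # 0-frame A-site codon start
  ext_from <- a_site_nt + frame       # shifted A-site codon start
  ext <- translateCds(cds, start_nt = ext_from)
  # terminated iff a stop codon (not the sequence end) ended the extension
  stop_nt <- ext_from + 3L * nchar(ext)
  terminated <- stop_nt + 2L <= nchar(cds) &&
    as.character(Biostrings::translate(
      Biostrings::RNAString(substr(cds, stop_nt, stop_nt + 2L)),
      if.fuzzy.codon = "X")) == "*"
  list(prefix = prefix, extension = ext, extension_len = nchar(ext),
       terminated = terminated, frame = as.integer(frame), p_site_codon = k)
}

#' Protease cleavage rules for in-silico digestion
#'
#' Standard specificities: trypsin (after K/R, not before P), LysC (after
#' K), LysN (before K), GluC (after E), AspN (before D), chymotrypsin
#' (after F/W/Y/L, not before P).
#'
#' @param name Protease name.
#' @param max_missed Maximum number of missed cleavages (>= 0).
#' @return A `ProteaseRule` list: `name`, `residues`, `side`
#'   (`"C"`/`"N"`), `exception` (residue that blocks cleavage when
#'   following the site, or `NA`), `max_missed`.
#' @export
proteaseRule <- function(name = c("trypsin", "lysC", "lysN", "gluC",
                                  "aspN", "chymotrypsin"),
                         max_missed = 2L) {
  name <- match.arg(name)
  stopifnot(max_missed >= 0L)
  spec <- switch(name,
    trypsin = list(residues = c("K", "R"), side = "C", exception = "P"),
    lysC = list(residues = "K", side = "C", exception = NA_character_),
    lysN = list(residues = "K", side = "N", exception = NA_character_),
    gluC = list(residues = "E", side = "C", exception = NA_character_),
    aspN = list(residues = "D", side = "N", exception = NA_character_),
    chymotrypsin = list(residues = c("F", "W", "Y", "L"), side = "C",
                        exception = "P"))
  structure(c(list(name = name), spec, list(max_missed = as.integer(max_missed))),
            class = "ProteaseRule")
}

# Cleavage points (positions after which the chain is cut) for a rule.
.cleavage_sites <- function(aa, rule) {
  n <- length(aa)
  if (n < 2L) return(integer(0))
  if (rule$side == "C") {
    pos <- which(aa[-n] %in% rule$residues)
    if (!is.na(rule$exception))
      pos <- pos[aa[pos + 1L] != rule$exception]
  } else {
    pos <- which(aa[-1L] %in% rule$residues)  # cut before the residue
  }
  pos
}

#' Digest a protein in silico
#'
#' Fully deterministic digestion under a [proteaseRule()]: base fragments
#' between consecutive cleavage sites, plus every concatenation of up to
#' `max_missed` additional consecutive fragments. Peptides are returned in
#' positional order (with `start` coordinates); concatenating the 0-missed
#' set reconstructs the protein exactly. No length filter is applied here.
#'
#' @param protein Amino-acid string.
#' @param rule A `ProteaseRule`.
#' @return data.frame with `peptide`, `start`, `end`, `missed`.
#' @examples
#' digestProtein("MKRGLK", proteaseRule("trypsin", 0))$peptide
#' # "MK" "R" "GLK"
#' @export
digestProtein <- function(protein, rule = proteaseRule()) {
  stopifnot(nchar(protein) > 0L)
  aa <- strsplit(protein, "")[[1]]
  cuts <- .cleavage_sites(aa, rule)
  bounds <- c(0L, cuts, length(aa))
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1L]
  nfrag <- length(starts)
  out <- list()
  for (m in 0:min(rule$max_missed, nfrag - 1L)) {
    i <- seq_len(nfrag - m)
    out[[m + 1L]] <- data.frame(
      peptide = substring(protein, starts[i], ends[i + m]),
      start = starts[i], end = ends[i + m], missed = m)
  }
  do.call(rbind, out)
}

.zero_frame_peptides <- function(proteome, rules, length_range) {
  peps <- unlist(lapply(proteome, function(p) {
    if (!nzchar(p)) return(character(0))
    unlist(lapply(rules, function(r) digestProtein(p, r)$peptide))
  }), use.names = FALSE)
  w <- nchar(peps)
  unique(peps[w >= length_range[1] & w <= length_range[2]])
}

#' Build a two-pass frameshift peptide search database
#'
#' For every motif and requested frame, the predicted frameshift product
#' (`prefix + extension`) is digested with each protease rule. Peptides
#' that overlap the frameshift transition point or lie within the
#' alternative-frame extension are kept; any peptide identical to a
#' 0-frame peptide of the same transcriptome is removed, so the second-pass
#' database is disjoint from the first-pass (0-frame) database by
#' construction. For terminated products with an empty extension the
#' C-terminal prefix peptide (ending at the P-site residue) is emitted as a
#' premature-termination candidate.
#'
#' @param x A [TranscriptSet-class].
#' @param motifs Motif table from [findMotifs()].
#' @param frames Integer vector of frames (default -1).
#' @param rules List of [proteaseRule()] objects (default trypsin).
#' @param length_range Peptide length filter (default 7-50 residues).
#' @return data.frame: `peptide`, `transcript_id`, `frame`, `class`
#'   (`"transitional"`, `"frameshift"` or `"premature_termination"`),
#'   `heptamer_nt_start`.
#' @export
buildFrameshiftPeptideDb <- function(x, motifs, frames = -1L,
                                     rules = list(proteaseRule("trypsin")),
                                     length_range = c(7L, 50L)) {
  empty <- data.frame(peptide = character(0), transcript_id = character(0),
                      frame = integer(0), class = character(0),
                      heptamer_nt_start = integer(0))
  if (nrow(motifs) == 0L) return(empty)
  zf <- .zero_frame_peptides(translateSet(x), rules, length_range)
  cds <- as.character(cdsSequences(x))
  names(cds) <- transcriptIds(x)
  out <- list()
  for (i in seq_len(nrow(motifs))) for (fr in frames) {
    pr <- predictFrameshiftProduct(cds[[motifs$transcript_id[i]]],
                                   motifs[i, ], fr)
    np <- nchar(pr$prefix)
    if (pr$extension_len == 0L) {
      if (!pr$terminated || np < length_range[1]) next
      for (r in rules) {
        dg <- digestProtein(pr$prefix, r)
        dg <- dg[dg$end == np &
                 nchar(dg$peptide) >= length_range[1] &
                 nchar(dg$peptide) <= length_range[2], , drop = FALSE]
        if (nrow(dg)) out[[length(out) + 1L]] <- data.frame(
          peptide = dg$peptide, transcript_id = motifs$transcript_id[i],
          frame = fr, class = "premature_termination",
          heptamer_nt_start = motifs$heptamer_nt_start[i])
      }
      next
    }
    product <- paste0(pr$prefix, pr$extension)
    for (r in rules) {
      dg <- digestProtein(product, r)
      dg <- dg[dg$end > np &
               nchar(dg$peptide) >= length_range[1] &
               nchar(dg$peptide) <= length_range[2], , drop = FALSE]
      if (!nrow(dg)) next
      out[[length(out) + 1L]] <- data.frame(
        peptide = dg$peptide, transcript_id = motifs$transcript_id[i],
        frame = fr,
        class = ifelse(dg$start <= np, "transitional", "frameshift"),
        heptamer_nt_start = motifs$heptamer_nt_start[i])
    }
  }
  if (!length(out)) return(empty)
  db <- unique(do.call(rbind, out))
  db <- db[!db$peptide %in% zf, , drop = FALSE]  # disjoint from pass one
  rownames(db) <- NULL
  db
}

#' Classify an observed peptide against predicted frameshift products
#'
#' Exact-substring search against the 0-frame proteome and all predicted
#' frameshift products of the supplied motifs. Calls follow the product
#' geometry: `"zero_frame"` (substring of a 0-frame protein only),
#' `"transitional"` (0-frame residues followed by at least one
#' alternative-frame residue), `"frameshift"` (wholly inside an
#' alternative-frame extension), `"premature_termination"` (0-frame
#' sequence whose C-terminus is the slip-site P-site residue of a product
#' whose shifted frame immediately presents a stop codon; this more
#' specific call takes precedence over the zero-frame substring match it
#' necessarily also satisfies), and `"ambiguous"` (matching several
#' classes, or alternative-frame evidence at several distinct motifs; a
#' peptide matching nothing at all is also reported `"ambiguous"`).
#'
#' @param peptide Amino-acid string, length >= 7.
#' @param x A [TranscriptSet-class].
#' @param motifs Motif table from [findMotifs()].
#' @param frames Frames to consider (default -1).
#' @param collapse_il If `TRUE`, isoleucine and leucine are treated as
#'   equivalent (they are isobaric in mass spectrometry); default `FALSE`.
#' @return List: `sequence`, `call`, `frame` (or `NA`),
#'   `source_transcript` (or `NA`).
#' @export
classifyPeptide <- function(peptide, x, motifs, frames = -1L,
                            collapse_il = FALSE) {
  stopifnot(nchar(peptide) >= 7L)
  eq <- function(s) if (collapse_il) chartr("I", "L", s) else s
  pep <- eq(peptide)
  proteome <- translateSet(x)
  zero_hit <- vapply(proteome, function(p)
    grepl(pep, eq(p), fixed = TRUE), TRUE)
  alt <- list()  # per-match records from predicted products
  cds <- as.character(cdsSequences(x))
  names(cds) <- transcriptIds(x)
  pt_hit <- character(0)
  for (i in seq_len(nrow(motifs))) for (fr in frames) {
    pr <- predictFrameshiftProduct(cds[[motifs$transcript_id[i]]],
                                   motifs[i, ], fr)
    np <- nchar(pr$prefix)
    if (pr$terminated && pr$extension_len == 0L &&
        endsWith(eq(pr$prefix), pep))
      pt_hit <- c(pt_hit, motifs$transcript_id[i])
    if (pr$extension_len == 0L) next
    product <- eq(paste0(pr$prefix, pr$extension))
    at <- gregexpr(pep, product, fixed = TRUE)[[1]]
    for (s in at[at > 0L]) {
      e <- s + nchar(pep) - 1L
      if (e <= np) next  # wholly 0-frame occurrence inside the prefix
      gene <- if (!is.null(motifs$gene_id)) motifs$gene_id[i] else
        motifs$transcript_id[i]
      alt[[length(alt) + 1L]] <- list(
        class = if (s <= np) "transitional" else "frameshift",
        frame = fr, tid = motifs$transcript_id[i],
        # locus = gene x heptamer: isoforms of one gene share the motif
        motif = paste(gene, if (!is.null(motifs$heptamer))
          motifs$heptamer[i] else motifs$heptamer_nt_start[i]))
    }
  }
  classes <- unique(vapply(alt, `[[`, "", "class"))
  if (length(pt_hit)) classes <- c(classes, "premature_termination")
  if (any(zero_hit) && !length(classes)) classes <- "zero_frame"
  else if (any(zero_hit) && !"premature_termination" %in% classes)
    classes <- unique(c(classes, "zero_frame"))
  if (length(classes) == 0L)
    return(list(sequence = peptide, call = "ambiguous", frame = NA_integer_,
                source_transcript = NA_character_))
  if (length(classes) > 1L)
    return(list(sequence = peptide, call = "ambiguous", frame = NA_integer_,
                source_transcript = NA_character_))
  cls <- classes
  if (cls %in% c("transitional", "frameshift")) {
    loci <- unique(vapply(alt, `[[`, "", "motif"))
    if (length(loci) > 1L)
      return(list(sequence = peptide, call = "ambiguous",
                  frame = NA_integer_, source_transcript = NA_character_))
    fr <- unique(vapply(alt, `[[`, 0L, "frame"))
    return(list(sequence = peptide, call = cls, frame = fr,
                source_transcript = alt[[1L]]$tid))
  }
  if (cls == "premature_termination")
    return(list(sequence = peptide, call = cls, frame = NA_integer_,
                source_transcript = pt_hit[1L]))
  list(sequence = peptide, call = "zero_frame", frame = NA_integer_,
       source_transcript = names(proteome)[which(zero_hit)[1L]])
}
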