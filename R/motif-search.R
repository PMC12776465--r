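#' Codon distance between a TMD and a downstream slip site
#'
#' The distance `L` runs from the C-terminal residue of the refined TMD
#' segment to the 0-frame P-site codon of the heptamer (codon holding
#' heptamer nucleotides 2-4); with
#' `anchor = "c_term_to_heptamer_start"` it runs to the codon holding the
#' heptamer's first nucleotide instead (one codon less).
#'
#' @param tmd_aa_end C-terminal residue index of the refined TMD segment.
#' @param heptamer_nt_start 1-based CDS position of the heptamer's first
#'   nucleotide; must be phase-aligned (`heptamer_nt_start %% 3 == 0`).
#' @param anchor Distance convention (see above).
#' @return `L` in codons, or `NA` when the heptamer does not lie downstream
#'   of the TMD.
#' @examples
#' computeDistance(100, ntPos(145) - 1)  # heptamer P-site codon 145 -> L = 45
#' @export
computeDistance <- function(tmd_aa_end, heptamer_nt_start,
                            anchor = c("c_term_to_p_site",
                                       "c_term_to_heptamer_start")) {
  anchor <- match.arg(anchor)
  if (any(heptamer_nt_start %% 3L != 0L))
    stop("heptamer_nt_start must be phase-aligned (multiple of 3)")
  ref <- heptamer_nt_start %/% 3L +
    (if (anchor == "c_term_to_p_site") 1L else 0L)
  L <- ref - tmd_aa_end
  L[L <= 0L] <- NA_integer_
  as.integer(L)
}

# Assignment + dedup on one transcript.
# psite: anchor codon index per slippery heptamer occurrence;
# tmd_end: C-terminal residue per refined TMD.
# (1) each heptamer -> TMD minimizing |L - l_ideal| (L > 0 only; ties ->
#     smaller L); (2) per TMD keep the single best heptamer (same rule);
# (3) restrict to l_range.
.assign_motifs <- function(psite, tmd_end, l_range, l_ideal) {
  if (length(psite) == 0L || length(tmd_end) == 0L)
    return(data.frame(h = integer(0), t = integer(0), L = integer(0)))
  pick <- function(L) {
    ok <- which(!is.na(L) & L > 0L)
    if (!length(ok)) return(NA_integer_)
    d <- abs(L[ok] - l_ideal)
    cand <- ok[d == min(d)]
    cand[which.min(L[cand])]
  }
  tsel <- vapply(psite, function(p) pick(p - tmd_end), 0L)
  keep <- !is.na(tsel)
  if (!any(keep))
    return(data.frame(h = integer(0), t = integer(0), L = integer(0)))
  h <- which(keep); t <- tsel[keep]; L <- psite[keep] - tmd_end[t]
  res <- lapply(unique(t), function(tt) {
    j <- which(t == tt)
    d <- abs(L[j] - l_ideal)
    jj <- j[d == min(d)]
    jj <- jj[which.min(L[jj])]
    c(h = h[jj], t = tt, L = L[jj])
  })
  res <- as.data.frame(do.call(rbind, res))
  res <- res[res$L >= l_range[1] & res$L <= l_range[2], , drop = FALSE]
  res[order(res$h), , drop = FALSE]
}

# Phase-aligned heptamer scan of one CDS: positions h = 3, 6, ... with the
# heptamer ending before the final (stop) codon. Returns slippery hits.
.scan_slippery <- function(cds, table) {
  n <- nchar(cds)
  h <- seq.int(3L, by = 3L, length.out = max(0L, (n - 3L - 6L) %/% 3L))
  if (!length(h))
    return(data.frame(nt_start = integer(0), heptamer = character(0)))
  hept <- substring(cds, h, h + 6L)
  ok <- !grepl("N", hept, fixed = TRUE) & isSlippery(table, hept)
  data.frame(nt_start = h[ok], heptamer = hept[ok])
}

#' Find TMD-slip motifs in a transcriptome
#'
#' Pairs slippery heptamers with refined TMD segments at translation-coupled
#' distances. Per transcript: every phase-aligned heptamer (the classical
#' X XXY YYZ register, nucleotides 2-4 and 5-7 in frame) is looked up in the
#' slippery table; each slippery heptamer is assigned to the TMD minimizing
#' `|L - l_ideal|`; per TMD only the heptamer closest to the ideal spacing
#' is retained (double-counting guard); the output is restricted to motifs
#' with `L` inside `l_range`. Ties in `|L - l_ideal|` resolve to the
#' smaller `L`. Heptamers overlapping the stop codon or within 7 nt of the
#' CDS end, heptamers containing `N`, and transcripts flagged as not a
#' multiple of three are skipped. Output ordering is deterministic
#' (by transcript, then heptamer position) and invariant to input order.
#'
#' @param x A [TranscriptSet-class].
#' @param tmds Refined TMD table from [findTmds()].
#' @param table A [SlipperyTable-class].
#' @param l_range Admissible distance range in codons (default 35-55).
#' @param l_ideal Ideal spacing in codons (default 45).
#' @param anchor Distance convention, see [computeDistance()].
#' @return data.frame: `transcript_id`, `gene_id`, `gene_name`,
#'   `isoform_class`, `tmd_start`, `tmd_end`, `dg_app`, `heptamer`,
#'   `heptamer_nt_start`, `distance_L`, `is_ideal`, `in_range`,
#'   `splicing_class` (initialized `"not_applicable"`; see
#'   [classifySplicingDependence()]).
#' @export
findMotifs <- function(x, tmds, table, l_range = c(35L, 55L), l_ideal = 45L,
                       anchor = c("c_term_to_p_site",
                                  "c_term_to_heptamer_start")) {
  anchor <- match.arg(anchor)
  off <- if (anchor == "c_term_to_p_site") 1L else 0L
  mc <- S4Vectors::mcols(cdsSequences(x))
  cds <- as.character(cdsSequences(x))
  out <- list()
  ord <- order(mc$transcript_id)
  for (i in ord) {
    if (!mc$multiple_of_three[i]) next
    tt <- tmds[tmds$transcript_id == mc$transcript_id[i], , drop = FALSE]
    if (nrow(tt) == 0L) next
    hits <- .scan_slippery(cds[[i]], table)
    if (nrow(hits) == 0L) next
    asg <- .assign_motifs(hits$nt_start %/% 3L + off, tt$aa_end,
                          l_range, l_ideal)
    if (nrow(asg) == 0L) next
    out[[length(out) + 1L]] <- data.frame(
      transcript_id = mc$transcript_id[i], gene_id = mc$gene_id[i],
      gene_name = mc$gene_name[i], isoform_class = mc$isoform_class[i],
      tmd_start = tt$aa_start[asg$t], tmd_end = tt$aa_end[asg$t],
      dg_app = tt$dg_app[asg$t], heptamer = hits$heptamer[asg$h],
      heptamer_nt_start = hits$nt_start[asg$h], distance_L = asg$L,
      is_ideal = asg$L == l_ideal, in_range = TRUE,
      splicing_class = "not_applicable")
  }
  if (length(out) == 0L)
    return(data.frame(transcript_id = character(0), gene_id = character(0),
                      gene_name = character(0), isoform_class = character(0),
                      tmd_start = integer(0), tmd_end = integer(0),
                      dg_app = numeric(0), heptamer = character(0),
                      heptamer_nt_start = integer(0), distance_L = integer(0),
                      is_ideal = logical(0), in_range = logical(0),
                      splicing_class = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify motifs as canonical or splicing-dependent
#'
#' Motifs found in a gene's canonical transcript are class `"canonical"`.
#' A motif in an alternative isoform is `"splicing_dependent"` when no
#' in-range motif involving a heptamer of the same sequence exists in the
#' gene's canonical transcript, and `"shared_with_canonical"` when such a
#' motif does exist; `"not_applicable"` marks motifs of genes without any
#' canonical transcript in the input. Supplying `transcripts`
#' lets genes whose canonical transcript simply has no motifs be
#' distinguished from genes without any canonical transcript.
#'
#' @param motifs Motif table from [findMotifs()].
#' @param transcripts Optional [TranscriptSet-class] used to determine
#'   which genes have a canonical transcript and to reject genes annotated
#'   with more than one.
#' @return `motifs` with `splicing_class` filled in.
#' @export
classifySplicingDependence <- function(motifs, transcripts = NULL) {
  if (nrow(motifs) == 0L) return(motifs)
  if (!is.null(transcripts)) {
    can_per_gene <- tapply(isoformClass(transcripts) == "canonical",
                           geneIds(transcripts), sum)
    if (any(can_per_gene > 1L))
      stop("gene(s) with multiple canonical transcripts: ",
           paste(names(can_per_gene)[can_per_gene > 1L], collapse = ", "))
    has_can <- can_per_gene > 0L
  } else {
    cn <- unique(motifs[motifs$isoform_class == "canonical",
                        c("gene_id", "transcript_id")])
    dup <- table(cn$gene_id)
    if (any(dup > 1L))
      stop("gene(s) with multiple canonical transcripts: ",
           paste(names(dup)[dup > 1L], collapse = ", "))
    has_can <- stats::setNames(rep(TRUE, length(unique(motifs$gene_id))),
                               unique(motifs$gene_id))
  }
  can_key <- with(motifs[motifs$isoform_class == "canonical", , drop = FALSE],
                  paste(gene_id, heptamer))
  cls <- character(nrow(motifs))
  for (i in seq_len(nrow(motifs))) {
    if (motifs$isoform_class[i] == "canonical") {
      cls[i] <- "canonical"
    } else if (!isTRUE(unname(has_can[motifs$gene_id[i]]))) {
      cls[i] <- "not_applicable"
    } else {
      cls[i] <- if (paste(motifs$gene_id[i], motifs$heptamer[i]) %in% can_key)
        "shared_with_canonical" else "splicing_dependent"
    }
  }
  motifs$splicing_class <- cls
  motifs
}
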