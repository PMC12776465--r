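#' Default biological hydrophobicity scale
#'
#' Reads the bundled per-residue center coefficients and assembles a
#' [DgScale-class]. In `"positional"` mode each residue's contribution is
#' modulated by a Gaussian profile over the normalized segment coordinate
#' (full weight at the membrane center, decaying toward the edges), plus a
#' quadratic length correction centered on 19 residues; `"center_only"`
#' drops the position profile (flat contributions) and is the simplified
#' mode used in tests where exact profile shape is irrelevant.
#'
#' @param mode `"positional"` or `"center_only"`.
#' @param sigma Gaussian profile width (normalized coordinate units).
#' @param lengthCoef Coefficient of the quadratic length correction
#'   (kcal/mol per residue^2).
#' @param momentCoef Hydrophobic moment coefficient; 0 (default) disables
#'   the term.
#' @return A `DgScale`.
#' @export
dgScale <- function(mode = c("positional", "center_only"), sigma = 0.6,
                    lengthCoef = 0.033, momentCoef = 0) {
  mode <- match.arg(mode)
  tab <- utils::read.delim(system.file("extdata", "dg_scale_center.tsv",
                                       package = "tmdslip"),
                           stringsAsFactors = FALSE)
  new("DgScale", center = stats::setNames(tab$dg_center, tab$aa),
      sigma = sigma, lengthCoef = lengthCoef, lengthOpt = 19,
      momentCoef = momentCoef, mode = mode)
}

setMethod("show", "DgScale", function(object) {
  cat("DgScale (", object@mode, "): sigma", object@sigma,
      "| length corr", object@lengthCoef, "* (L -", object@lengthOpt, ")^2",
      if (object@momentCoef > 0) "| moment term on" else "", "\n")
})

#' Apparent free energy of translocon-mediated membrane insertion
#'
#' Scores a candidate transmembrane segment of 16-25 residues: lower values
#' mark segments the translocon partitions into the membrane more readily.
#'
#' @param segment Amino-acid string, 16-25 residues, no `X`.
#' @param scale A [DgScale-class].
#' @return \eqn{\Delta G_{app}} in kcal/mol.
#' @examples
#' sc <- dgScale()
#' dgApp(strrep("L", 19), sc) < dgApp(strrep("A", 19), sc)  # TRUE
#' @export
dgApp <- function(segment, scale = dgScale()) {
  L <- nchar(segment)
  if (L < 16L || L > 25L) stop("segment length must be in [16, 25], got ", L)
  aa <- strsplit(segment, "")[[1]]
  if (any(!aa %in% names(scale@center)))
    stop("unknown residue in segment: ",
         paste(unique(aa[!aa %in% names(scale@center)]), collapse = ""))
  cc <- scale@center[aa]
  if (scale@mode == "positional") {
    x <- (2 * seq_len(L) - L - 1) / (L - 1)
    cc <- cc * exp(-x^2 / (2 * scale@sigma^2))
  }
  dg <- sum(cc) + scale@lengthCoef * (L - scale@lengthOpt)^2
  if (scale@momentCoef > 0) {
    ang <- seq_len(L) * 100 * pi / 180  # alpha-helical periodicity
    mu <- sqrt(sum(scale@center[aa] * sin(ang))^2 +
               sum(scale@center[aa] * cos(ang))^2)
    dg <- dg + scale@momentCoef * mu / L
  }
  unname(dg)
}

#' Propose candidate TMD regions in a protein
#'
#' Two modes. `"topcons_file"` ingests an external per-residue topology
#' string (states `i`/`o`/`M` etc.) and extracts maximal runs of `M`;
#' runs shorter than 10 residues are dropped (region invariant).
#' `"builtin_scan"` is the self-contained fallback: it slides a 19-residue
#' \eqn{\Delta G_{app}} window along the protein, marks windows below
#' `dgCutoff`, converts maximal runs of marked window starts into residue
#' regions, and merges regions separated by fewer than 5 residues.
#'
#' @param protein Amino-acid string.
#' @param mode `"builtin_scan"` or `"topcons_file"`.
#' @param topology Per-residue topology string (required for
#'   `"topcons_file"`); must have the same length as `protein`.
#' @param dgCutoff Window cutoff in kcal/mol for the builtin scan.
#' @param scale A [DgScale-class].
#' @return data.frame with columns `aa_start`, `aa_end`, `source`;
#'   non-overlapping regions sorted by `aa_start`.
#' @export
proposeTmdRegions <- function(protein,
                              mode = c("builtin_scan", "topcons_file"),
                              topology = NULL, dgCutoff = 1.0,
                              scale = dgScale()) {
  mode <- match.arg(mode)
  stopifnot(nchar(protein) > 0L)
  empty <- data.frame(aa_start = integer(0), aa_end = integer(0),
                      source = character(0))
  if (mode == "topcons_file") {
    if (is.null(topology)) stop("topcons_file mode requires a topology string")
    if (nchar(topology) != nchar(protein))
      stop("topology string length (", nchar(topology),
           ") != protein length (", nchar(protein), ")")
    r <- rle(strsplit(topology, "")[[1]] == "M")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= 10L
    if (!any(keep)) return(empty)
    return(data.frame(aa_start = starts[keep], aa_end = ends[keep],
                      source = "topcons_file"))
  }
  n <- nchar(protein)
  win <- 19L
  if (n < win) return(empty)
  starts <- seq_len(n - win + 1L)
  dg <- vapply(starts, function(i)
    tryCatch(dgApp(substr(protein, i, i + win - 1L), scale),
             error = function(e) Inf),  # windows containing X never qualify
    0)
  hit <- dg < dgCutoff
  if (!any(hit)) return(empty)
  r <- IRanges::reduce(IRanges::IRanges(start = starts[hit],
                                        width = win), min.gapwidth = 5L)
  data.frame(aa_start = IRanges::start(r), aa_end = IRanges::end(r),
             source = "builtin_scan")
}

#' Refine a TMD region to its minimum-dG translocon segment
#'
#' Exhaustively enumerates every 16-25 residue segment fully contained in
#' the window from 10 residues upstream of the region to 10 residues
#' downstream (clipped to the protein bounds) and returns the segment with
#' minimal \eqn{\Delta G_{app}}. Ties are broken toward the shortest
#' segment, then the smallest start. Segments containing `X` are skipped.
#'
#' @param protein Amino-acid string.
#' @param region A single-row region (list or data.frame row with
#'   `aa_start`, `aa_end`).
#' @param scale A [DgScale-class].
#' @return data.frame row with `aa_start`, `aa_end`, `length`, `dg_app`.
#' @export
refineTmdSegment <- function(protein, region, scale = dgScale()) {
  n <- nchar(protein)
  a <- max(1L, as.integer(region$aa_start) - 10L)
  b <- min(n, as.integer(region$aa_end) + 10L)
  if (b - a + 1L < 16L)
    stop("refinement window [", a, ",", b, "] shorter than 16 residues ",
         "for region ", region$aa_start, "-", region$aa_end)
  best <- NULL
  for (len in 16:25) {
    if (b - a + 1L < len) break
    for (s in a:(b - len + 1L)) {
      seg <- substr(protein, s, s + len - 1L)
      if (grepl("X", seg, fixed = TRUE)) next
      dg <- dgApp(seg, scale)
      if (is.null(best) || dg < best$dg_app ||
          (dg == best$dg_app && (len < best$length ||
                                 (len == best$length && s < best$aa_start))))
        best <- list(aa_start = s, aa_end = s + len - 1L, length = len,
                     dg_app = dg)
    }
  }
  if (is.null(best)) stop("no admissible segment in window (all contain X)")
  as.data.frame(best)
}

#' Detect and refine TMD segments across a TranscriptSet
#'
#' Translates each in-frame transcript (frame 0, to the first stop), runs
#' [proposeTmdRegions()] and [refineTmdSegment()] per region, and returns
#' one row per refined segment. Transcripts flagged as not a multiple of
#' three, or whose protein is shorter than 16 residues, are skipped.
#'
#' @param x A [TranscriptSet-class].
#' @param mode,dgCutoff,scale Passed to [proposeTmdRegions()].
#' @param topologies Optional named list/character of topology strings per
#'   transcript id (for `mode = "topcons_file"`).
#' @return data.frame: `transcript_id`, `region_start`, `region_end`,
#'   `aa_start`, `aa_end`, `length`, `dg_app`, `source`.
#' @export
findTmds <- function(x, mode = c("builtin_scan", "topcons_file"),
                     topologies = NULL, dgCutoff = 1.0, scale = dgScale()) {
  mode <- match.arg(mode)
  prot <- translateSet(x)
  keep <- isMultipleOfThree(x) & nchar(prot) >= 16L
  out <- list()
  for (tid in transcriptIds(x)[keep]) {
    p <- prot[[tid]]
    reg <- proposeTmdRegions(p, mode = mode,
                             topology = if (!is.null(topologies))
                               topologies[[tid]] else NULL,
                             dgCutoff = dgCutoff, scale = scale)
    if (nrow(reg) == 0L) next
    for (i in seq_len(nrow(reg))) {
      seg <- refineTmdSegment(p, reg[i, ], scale)
      out[[length(out) + 1L]] <- cbind(
        data.frame(transcript_id = tid, region_start = reg$aa_start[i],
                   region_end = reg$aa_end[i]),
        seg, data.frame(source = reg$source[i]))
    }
  }
  if (length(out) == 0L)
    return(data.frame(transcript_id = character(0), region_start = integer(0),
                      region_end = integer(0), aa_start = integer(0),
                      aa_end = integer(0), length = integer(0),
                      dg_app = numeric(0), source = character(0)))
  do.call(rbind, out)
}
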