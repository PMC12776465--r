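#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<-
#' @importClassesFrom Biostrings RNAStringSet
#' @importClassesFrom S4Vectors DataFrame
NULL

#' A set of coding sequences with isoform annotations
#'
#' `TranscriptSet` wraps a [Biostrings::RNAStringSet] of coding sequences
#' (CDS) together with per-transcript metadata: transcript/gene identifiers,
#' a gene symbol, whether the record is the gene's canonical transcript or an
#' alternative isoform, and whether its length is a multiple of three.
#' Records whose length is not a multiple of three are kept but flagged, and
#' every motif-level operation skips them.
#'
#' Sequences are stored in the RNA alphabet; `T` is converted to `U` on
#' input. `N` is the only ambiguity code admitted.
#'
#' @slot sequences An `RNAStringSet`; its `mcols()` carry `transcript_id`,
#'   `gene_id`, `gene_name`, `isoform_class` (`"canonical"` or
#'   `"alternative"`) and `multiple_of_three` (logical).
#'
#' @seealso [TranscriptSet()], [readCdsFasta()], [writeCdsFasta()]
#' @exportClass TranscriptSet
setClass("TranscriptSet", representation(sequences = "RNAStringSet"))

setValidity("TranscriptSet", function(object) {
  sq <- object@sequences
  mc <- S4Vectors::mcols(sq)
  need <- c("transcript_id", "gene_id", "gene_name", "isoform_class",
            "multiple_of_three")
  if (!all(need %in% colnames(mc)))
    return(paste("mcols must contain:", paste(need, collapse = ", ")))
  if (length(sq) == 0L)
    return(TRUE)
  if (any(!nzchar(mc$transcript_id)) || any(!nzchar(mc$gene_id)))
    return("transcript_id and gene_id must be non-empty")
  if (anyDuplicated(mc$transcript_id))
    return("duplicated transcript_id")
  if (!all(mc$isoform_class %in% c("canonical", "alternative")))
    return("isoform_class must be 'canonical' or 'alternative'")
  if (any(Biostrings::width(sq) < 21L))
    return("all CDS must be at least 21 nt (one codon beyond a heptamer)")
  bad <- Biostrings::alphabetFrequency(sq)[, setdiff(colnames(Biostrings::alphabetFrequency(sq)),
                                                     c("A", "C", "G", "U", "N")), drop = FALSE]
  if (any(rowSums(bad) > 0))
    return("sequences may only contain A, C, G, U, N")
  ok3 <- Biostrings::width(sq) %% 3L == 0L
  if (!identical(unname(as.logical(mc$multiple_of_three)), unname(ok3)))
    return("multiple_of_three flag inconsistent with sequence widths")
  TRUE
})

#' Codon-anticodon pairing energy model
#'
#' Holds the constants behind the frameshift propensity score \eqn{\Delta
#' G_{FS}}: Turner-style nearest-neighbor stack free energies for
#' Watson-Crick steps, a stack value for steps flanked by a G-U wobble pair,
#' a per-wobble-pair term, and a per-mismatch penalty. A mismatched position
#' voids both adjacent stacking steps. The `stackWeight` scales all stack
#' contributions; together with the wobble and mismatch terms it is the
#' knowledge-based calibration knob of the model (see
#' [pairingEnergyModel()] for the calibrated defaults).
#'
#' @slot wcStacks Named numeric of length 16: stack free energy (kcal/mol)
#'   for each 5'->3' dinucleotide step of a Watson-Crick helix.
#' @slot guStack Single stack value (kcal/mol) used for any step in which at
#'   least one flanking pair is a G-U wobble.
#' @slot wobblePair Additive term (kcal/mol) per G-U pair.
#' @slot mismatchPenalty Additive term (kcal/mol) per mismatched pair;
#'   must be non-negative.
#' @slot stackWeight Multiplier applied to all stack terms.
#'
#' @exportClass PairingEnergyModel
setClass("PairingEnergyModel",
         representation(wcStacks = "numeric", guStack = "numeric",
                        wobblePair = "numeric", mismatchPenalty = "numeric",
                        stackWeight = "numeric"))

setValidity("PairingEnergyModel", function(object) {
  steps <- as.vector(outer(c("A", "C", "G", "U"), c("A", "C", "G", "U"), paste0))
  if (!all(steps %in% names(object@wcStacks)))
    return("wcStacks must name all 16 dinucleotide steps")
  if (length(object@mismatchPenalty) != 1L || object@mismatchPenalty < 0)
    return("mismatchPenalty must be a single non-negative value")
  if (length(object@guStack) != 1L || length(object@wobblePair) != 1L ||
      length(object@stackWeight) != 1L)
    return("guStack, wobblePair and stackWeight must be scalars")
  TRUE
})

#' Census of slippery heptanucleotides
#'
#' The result of scoring the full 4^7 = 16384 heptamer space with a
#' [PairingEnergyModel]: every heptamer with its \eqn{\Delta G_{FS}} and its
#' slippery classification under a strict `<` threshold comparison.
#'
#' @slot threshold The slippery cutoff in kcal/mol.
#' @slot census `DataFrame` with columns `heptamer`, `dg_fs`, `is_slippery`,
#'   one row per heptamer, in canonical (base-4) order.
#'
#' @seealso [enumerateSlipperyHeptamers()], [slipperyHeptamers()]
#' @exportClass SlipperyTable
setClass("SlipperyTable",
         representation(threshold = "numeric", census = "DataFrame"))

setValidity("SlipperyTable", function(object) {
  cs <- object@census
  if (!all(c("heptamer", "dg_fs", "is_slippery") %in% colnames(cs)))
    return("census must have heptamer, dg_fs, is_slippery")
  if (nrow(cs) != 16384L)
    return("census must cover all 16384 heptamers")
  if (!isTRUE(all(cs$is_slippery == (cs$dg_fs < object@threshold))))
    return("is_slippery must equal dg_fs < threshold")
  homo <- paste0(strrep(c("A", "C", "G", "U"), 7L))
  if (!isTRUE(all(cs$dg_fs[match(homo, cs$heptamer)] == 0)))
    return("homopolymer heptamers must score exactly 0")
  TRUE
})

#' Biological hydrophobicity scale for translocon-mediated insertion
#'
#' Parameters of the apparent free energy of membrane insertion
#' (\eqn{\Delta G_{app}}) of a 16-25 residue segment: per-residue center
#' coefficients, a Gaussian position profile, a quadratic length correction
#' centered on the optimal 19-residue span, and an optional hydrophobic
#' moment term.
#'
#' @slot center Named numeric of length 20: per-residue contribution at the
#'   membrane center (kcal/mol).
#' @slot sigma Width of the Gaussian position profile on the normalized
#'   segment coordinate in `[-1, 1]`.
#' @slot lengthCoef Coefficient of the `(L - lengthOpt)^2` length correction.
#' @slot lengthOpt Optimal segment length in residues.
#' @slot momentCoef Coefficient of the helical hydrophobic moment term
#'   (0 disables it).
#' @slot mode `"positional"` (full profile) or `"center_only"` (flat
#'   profile; simplified mode for tests).
#'
#' @exportClass DgScale
setClass("DgScale",
         representation(center = "numeric", sigma = "numeric",
                        lengthCoef = "numeric", lengthOpt = "numeric",
                        momentCoef = "numeric", mode = "character"))

setValidity("DgScale", function(object) {
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (!all(aas %in% names(object@center)))
    return("center must name all 20 amino acids")
  if (object@center[["L"]] >= object@center[["A"]])
    return("leucine must be more favorable than alanine at the center")
  if (!object@mode %in% c("positional", "center_only"))
    return("mode must be 'positional' or 'center_only'")
  if (object@sigma <= 0)
    return("sigma must be positive")
  TRUE
})
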