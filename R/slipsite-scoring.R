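.RNA_BASES <- c("A", "C", "G", "U")
.RNA_COMP <- c(A = "U", C = "G", G = "C", U = "A")

#' Default codon-anticodon pairing energy model
#'
#' Builds the [PairingEnergyModel-class] used to score heptamers for
#' frameshift propensity. Watson-Crick stack energies are read from the
#' bundled Turner nearest-neighbor table; the wobble stack, per-wobble-pair
#' term, per-mismatch penalty and stack weight default to the calibrated
#' values under which the 24 classical slippery reference motifs all score
#' below +2.9 kcal/mol and the slippery census at that cutoff contains 465
#' of the 16384 possible heptamers.
#'
#' @param wcStacks Named numeric of the 16 dinucleotide stack energies;
#'   defaults to the bundled Turner table.
#' @param guStack Stack value for steps flanked by a G-U wobble pair.
#' @param wobblePair Additive term per G-U pair.
#' @param mismatchPenalty Additive penalty per mismatched pair (>= 0); a
#'   mismatch also voids both adjacent stacking steps.
#' @param stackWeight Multiplier on all stack terms.
#' @return A `PairingEnergyModel`.
#' @export
pairingEnergyModel <- function(wcStacks = NULL, guStack = -1.00,
                               wobblePair = 0.56, mismatchPenalty = 0.32,
                               stackWeight = 0.5) {
  if (is.null(wcStacks)) {
    tab <- utils::read.delim(system.file("extdata", "turner_wc_stacks.tsv",
                                         package = "tmdslip"),
                             comment.char = "#", stringsAsFactors = FALSE)
    wcStacks <- stats::setNames(tab$dg_kcal_mol, tab$step)
  }
  new("PairingEnergyModel", wcStacks = wcStacks, guStack = guStack,
      wobblePair = wobblePair, mismatchPenalty = mismatchPenalty,
      stackWeight = stackWeight)
}

setMethod("show", "PairingEnergyModel", function(object) {
  cat("PairingEnergyModel: stackWeight", object@stackWeight,
      "| guStack", object@guStack, "| wobblePair", object@wobblePair,
      "| mismatchPenalty", object@mismatchPenalty, "kcal/mol\n")
})

.check_codon <- function(x) {
  if (length(x) != 1L || nchar(x) != 3L || grepl("[^ACGU]", x))
    stop("invalid codon: ", x)
  x
}

# Pair class of (target base : anticodon base complementary to codon base).
# WC when target == codon base; G-U wobble when the physical pair is {G,U}.
.pair_class <- function(target, codon) {
  a <- .RNA_COMP[codon]
  ifelse(target == codon, "WC",
         ifelse((target == "G" & a == "U") | (target == "U" & a == "G"),
                "GU", "MM"))
}

#' Energy of an anticodon paired against a codon
#'
#' Forms the perfect Watson-Crick anticodon of `anticodon_of` and pairs it,
#' in register, against `against`: a 3-bp minihelix whose energy is the sum
#' of the two nearest-neighbor stacking steps. A step is scored with the
#' Turner Watson-Crick stack when both flanking pairs are Watson-Crick, and
#' with the model's wobble stack when either flanking pair is G-U; a
#' mismatched position voids both adjacent steps. Each G-U pair adds the
#' per-wobble term and each mismatch adds the mismatch penalty.
#'
#' @param anticodon_of Codon whose cognate anticodon is formed.
#' @param against Codon the anticodon is paired against.
#' @param model A [PairingEnergyModel-class].
#' @return Energy in kcal/mol; the cognate case
#'   (`against == anticodon_of`) is minimal by construction.
#' @export
anticodonPairingEnergy <- function(anticodon_of, against,
                                   model = pairingEnergyModel()) {
  .check_codon(anticodon_of); .check_codon(against)
  tb <- strsplit(against, "")[[1]]
  cb <- strsplit(anticodon_of, "")[[1]]
  cls <- .pair_class(tb, cb)
  e <- sum(cls == "MM") * model@mismatchPenalty +
       sum(cls == "GU") * model@wobblePair
  for (i in 1:2) {
    if (any(cls[i:(i + 1L)] == "MM")) next
    e <- e + model@stackWeight *
      (if (all(cls[i:(i + 1L)] == "WC"))
         model@wcStacks[[paste0(tb[i], tb[i + 1L])]]
       else model@guStack)
  }
  e
}

# Per-codon-slip penalty table: delta[prev_base, codon] is the energy cost of
# re-pairing the cognate anticodon of `codon` one nucleotide upstream
# (against prev_base + codon[1:2]) relative to cognate pairing.
.delta_table <- function(model) {
  codons <- as.vector(outer(as.vector(outer(.RNA_BASES, .RNA_BASES, paste0)),
                            .RNA_BASES, paste0))
  codons <- sort(codons)
  d <- matrix(NA_real_, 4L, 64L, dimnames = list(.RNA_BASES, codons))
  for (b in .RNA_BASES) for (cc in codons) {
    shifted <- paste0(b, substr(cc, 1L, 2L))
    d[b, cc] <- anticodonPairingEnergy(cc, shifted, model) -
      anticodonPairingEnergy(cc, cc, model)
  }
  d
}

.model_cache <- new.env(parent = emptyenv())

.delta_table_cached <- function(model) {
  key <- paste(c(model@wcStacks[sort(names(model@wcStacks))], model@guStack,
                 model@wobblePair, model@mismatchPenalty, model@stackWeight),
               collapse = "|")
  if (is.null(.model_cache[[key]]))
    .model_cache[[key]] <- .delta_table(model)
  .model_cache[[key]]
}

#' Frameshift propensity of a heptanucleotide
#'
#' \eqn{\Delta G_{FS}} is the free-energy penalty of re-pairing the two
#' 0-frame tRNA anticodons against the -1-frame codons. For a heptamer
#' N1..N7 the 0-frame P- and A-site codons are N2N3N4 and N5N6N7; the -1
#' frame presents N1N2N3 and N4N5N6 to the same anticodons. Scores are
#' rounded to 0.01 kcal/mol; they are 0 exactly when the -1-frame codons
#' equal the 0-frame ones (the four homopolymers) and non-negative
#' otherwise, since cognate pairing is minimal by construction.
#'
#' @param heptamer Character vector of 7-mers over `A,C,G,U` (strict: `N`
#'   is never scored).
#' @param model A [PairingEnergyModel-class].
#' @return Numeric vector of \eqn{\Delta G_{FS}} in kcal/mol.
#' @examples
#' m <- pairingEnergyModel()
#' dgFs("UUUUUUU", m)  # 0
#' dgFs("AAAAAAG", m)  # slippery: well below +2.9
#' @export
dgFs <- function(heptamer, model = pairingEnergyModel()) {
  bad <- nchar(heptamer) != 7L | grepl("[^ACGU]", heptamer)
  if (any(bad)) stop("invalid heptamer(s): ",
                     paste(heptamer[bad], collapse = ", "))
  d <- .delta_table_cached(model)
  .round_dg(d[cbind(substr(heptamer, 1L, 1L), substr(heptamer, 2L, 4L))] +
            d[cbind(substr(heptamer, 4L, 4L), substr(heptamer, 5L, 7L))])
}

# Scores are exact multiples of 0.001 kcal/mol (table entries have two
# decimals, the stack weight adds at most one more); snap to milli-kcal
# integers first, then round half-up to 0.01 so the strict threshold
# comparison is stable across summation orders.
.round_dg <- function(x) {
  milli <- round(x * 1000)
  (milli %/% 10L + as.integer(milli %% 10L >= 5L)) / 100
}

#' The 24 classical slippery reference heptamers
#'
#' The known X XXY YYZ slippery alphabet (X any base, Y in `{A,U}`, Z in
#' `{A,C,U}`) bundled as the calibration reference set.
#'
#' @return Character vector of 24 heptamers.
#' @export
referenceSlipperyMotifs <- function() {
  x <- readLines(system.file("extdata", "reference_slippery_heptamers.txt",
                             package = "tmdslip"))
  x[!startsWith(x, "#") & nzchar(x)]
}

#' Calibrate the slippery threshold from reference motifs
#'
#' Scores a reference list of known slippery heptamers and returns the
#' cutoff below which all of them classify as slippery under the strict
#' `<` comparison used by [enumerateSlipperyHeptamers()]: the smallest
#' multiple of `grid` strictly greater than the maximum reference score.
#' With `grid = 0` the raw maximum (the inclusive upper bound of the
#' reference score range) is returned instead.
#'
#' @param reference_motifs Non-empty character vector of heptamers;
#'   defaults to the bundled 24-motif set.
#' @param model A [PairingEnergyModel-class].
#' @param grid Rounding grid for the published-style cutoff (default 0.1
#'   kcal/mol).
#' @return Threshold in kcal/mol (2.9 for the bundled references under the
#'   default model).
#' @export
calibrateThreshold <- function(reference_motifs = referenceSlipperyMotifs(),
                               model = pairingEnergyModel(), grid = 0.1) {
  if (length(reference_motifs) == 0L) stop("empty reference list")
  mx <- max(dgFs(reference_motifs, model))
  if (grid <= 0) return(mx)
  round(grid * (floor(mx / grid + 1e-9) + 1L), 10L)
}

#' Score the full heptamer space and tabulate slippery sequences
#'
#' Enumerates all 4^7 = 16384 heptanucleotides, scores each with [dgFs()]
#' and classifies as slippery those with \eqn{\Delta G_{FS}} strictly below
#' the threshold. The full census (all scores) is retained for auditing.
#'
#' @param model A [PairingEnergyModel-class].
#' @param threshold Slippery cutoff in kcal/mol (default +2.9, the
#'   calibrated published-style value).
#' @return A [SlipperyTable-class].
#' @examples
#' tab <- enumerateSlipperyHeptamers()
#' sum(censusTable(tab)$is_slippery)  # 465
#' @export
enumerateSlipperyHeptamers <- function(model = pairingEnergyModel(),
                                       threshold = 2.9) {
  stopifnot(is.finite(threshold))
  d <- .delta_table_cached(model)
  codons <- colnames(d)
  grid <- expand.grid(cA = codons, cP = codons, n1 = .RNA_BASES,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  hept <- paste0(grid$n1, grid$cP, grid$cA)
  dg <- .round_dg(d[cbind(grid$n1, grid$cP)] +
                  d[cbind(substr(grid$cP, 3L, 3L), grid$cA)])
  o <- order(hept)
  census <- S4Vectors::DataFrame(heptamer = hept[o], dg_fs = dg[o],
                                 is_slippery = dg[o] < threshold)
  new("SlipperyTable", threshold = threshold, census = census)
}

setMethod("show", "SlipperyTable", function(object) {
  cat("SlipperyTable:", sum(object@census$is_slippery), "of",
      nrow(object@census), "heptamers slippery at dG_FS <",
      object@threshold, "kcal/mol\n")
})

#' Accessors for SlipperyTable
#'
#' @param x A [SlipperyTable-class].
#' @return `slipperyHeptamers()`: character vector of slippery heptamers;
#'   `censusTable()`: the full census as a data frame;
#'   `slipThreshold()`: the cutoff.
#' @name slippery-accessors
NULL

#' @rdname slippery-accessors
#' @export
slipperyHeptamers <- function(x) x@census$heptamer[x@census$is_slippery]

#' @rdname slippery-accessors
#' @export
censusTable <- function(x) as.data.frame(x@census)

#' @rdname slippery-accessors
#' @export
slipThreshold <- function(x) x@threshold

#' @rdname slippery-accessors
#' @param heptamer Heptamer(s) to look up.
#' @export
isSlippery <- function(x, heptamer) {
  out <- x@census$is_slippery[match(heptamer, x@census$heptamer)]
  out[is.na(out)] <- FALSE
  out
}
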