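#' Construct a TranscriptSet
#'
#' @param cds Character vector, `DNAStringSet` or `RNAStringSet` of coding
#'   sequences. `T` is converted to `U`.
#' @param transcript_id,gene_id,gene_name Character vectors recycled to the
#'   number of sequences.
#' @param isoform_class `"canonical"` or `"alternative"`, recycled.
#'
#' @return A [TranscriptSet-class] object.
#' @examples
#' ts <- TranscriptSet("AUG AAA UUU UUU AAA CCC UAA" |> gsub(" ", "", x = _),
#'                     transcript_id = "T1", gene_id = "G1", gene_name = "g1")
#' ts
#' @export
TranscriptSet <- function(cds, transcript_id, gene_id = transcript_id,
                          gene_name = gene_id,
                          isoform_class = "canonical") {
  if (is(cds, "XStringSet")) cds <- as.character(cds)
  cds <- chartr("Tt", "Uu", toupper(cds))
  n <- length(cds)
  sq <- Biostrings::RNAStringSet(cds)
  names(sq) <- rep_len(as.character(transcript_id), n)
  S4Vectors::mcols(sq) <- S4Vectors::DataFrame(
    transcript_id = rep_len(as.character(transcript_id), n),
    gene_id = rep_len(as.character(gene_id), n),
    gene_name = rep_len(as.character(gene_name), n),
    isoform_class = rep_len(isoform_class, n),
    multiple_of_three = Biostrings::width(sq) %% 3L == 0L)
  new("TranscriptSet", sequences = sq)
}

#' @describeIn TranscriptSet Number of transcripts.
#' @param x,object A `TranscriptSet`.
#' @export
setMethod("length", "TranscriptSet", function(x) length(x@sequences))

#' @describeIn TranscriptSet Subset by index or transcript id.
#' @param i Index vector.
#' @param j,drop,... Ignored.
#' @export
setMethod("[", "TranscriptSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, transcriptIds(x))
  initialize(x, sequences = x@sequences[i])
})

setMethod("show", "TranscriptSet", function(object) {
  mc <- S4Vectors::mcols(object@sequences)
  cat("TranscriptSet with", length(object), "transcripts (",
      sum(mc$isoform_class == "canonical"), "canonical /",
      sum(mc$isoform_class == "alternative"), "alternative )\n")
  if (any(!mc$multiple_of_three))
    cat("  ", sum(!mc$multiple_of_three),
        "record(s) flagged: length not a multiple of 3\n")
})

#' Accessors for TranscriptSet metadata
#'
#' @param x A [TranscriptSet-class].
#' @return `cdsSequences()` returns the underlying `RNAStringSet`; the other
#'   accessors return per-transcript vectors.
#' @name transcript-accessors
NULL

#' @rdname transcript-accessors
#' @export
cdsSequences <- function(x) x@sequences

#' @rdname transcript-accessors
#' @export
transcriptIds <- function(x) S4Vectors::mcols(x@sequences)$transcript_id

#' @rdname transcript-accessors
#' @export
geneIds <- function(x) S4Vectors::mcols(x@sequences)$gene_id

#' @rdname transcript-accessors
#' @export
geneNames <- function(x) S4Vectors::mcols(x@sequences)$gene_name

#' @rdname transcript-accessors
#' @export
isoformClass <- function(x) S4Vectors::mcols(x@sequences)$isoform_class

#' @rdname transcript-accessors
#' @export
isMultipleOfThree <- function(x) S4Vectors::mcols(x@sequences)$multiple_of_three

.parse_header <- function(h) {
  # Ensembl CDS dialect: ">ENST... cds ... gene:ENSG... gene_symbol:SYM ...
  #  [tag:Ensembl_canonical]" -- tolerant: any missing field falls back.
  tid <- sub("\\s.*$", "", h)
  grab <- function(key) {
    m <- regmatches(h, regexpr(paste0(key, ":[^\\s]+"), h, perl = TRUE))
    if (length(m)) sub(paste0(key, ":"), "", m) else NA_character_
  }
  list(transcript_id = tid, gene_id = grab("gene"),
       gene_name = grab("gene_symbol"),
       canonical = grepl("Ensembl_canonical", h, fixed = TRUE))
}

#' Read a CDS FASTA with Ensembl-style headers
#'
#' Parses one record per FASTA entry. Headers are expected in the Ensembl
#' CDS dialect (`>ENST... cds ... gene:ENSG... gene_symbol:SYM
#' tag:Ensembl_canonical`), but any whitespace-delimited first token is
#' accepted as the transcript id and missing fields fall back to generic
#' values with a warning. `T` is normalized to `U`. Records shorter than 21
#' nt, or containing IUPAC ambiguity codes other than `N`, are skipped with
#' a warning; records whose length is not a multiple of three are kept but
#' flagged and excluded from motif search.
#'
#' @param path Path to a FASTA file of coding sequences (DNA or RNA).
#' @param canonical_map Optional sidecar: a data frame with columns
#'   `transcript_id` and `canonical` (logical), or a path to such a TSV.
#'   Used for records whose header lacks an `Ensembl_canonical` tag.
#'
#' @return A [TranscriptSet-class].
#' @seealso [writeCdsFasta()]
#' @export
readCdsFasta <- function(path, canonical_map = NULL) {
  if (!file.exists(path)) stop("cannot read FASTA: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L)
    return(TranscriptSet(character(0), character(0)))
  if (is.character(canonical_map))
    canonical_map <- utils::read.delim(canonical_map, stringsAsFactors = FALSE)
  hdr <- lapply(names(raw), .parse_header)
  seqs <- chartr("Tt", "Uu", toupper(as.character(raw)))
  keep <- rep(TRUE, length(raw))
  for (i in seq_along(raw)) {
    s <- seqs[[i]]
    if (grepl("[^ACGUN]", s)) {
      warning("skipping ", hdr[[i]]$transcript_id,
              ": ambiguity codes other than N are not accepted")
      keep[i] <- FALSE
    } else if (nchar(s) < 21L) {
      warning("skipping ", hdr[[i]]$transcript_id, ": CDS shorter than 21 nt")
      keep[i] <- FALSE
    }
  }
  hdr <- hdr[keep]; seqs <- seqs[keep]
  tid <- vapply(hdr, `[[`, "", "transcript_id")
  blank <- !nzchar(tid)
  if (any(blank)) {
    warning(sum(blank), " record(s) with malformed headers; generic ids assigned")
    tid[blank] <- paste0("transcript_", which(blank))
  }
  gid <- vapply(hdr, `[[`, "", "gene_id")
  gnm <- vapply(hdr, `[[`, "", "gene_name")
  can <- vapply(hdr, `[[`, NA, "canonical")
  if (!is.null(canonical_map)) {
    m <- match(tid, canonical_map$transcript_id)
    side <- !can & !is.na(m)
    can[side] <- as.logical(canonical_map$canonical[m[side]])
  }
  gid[is.na(gid)] <- tid[is.na(gid)]
  gnm[is.na(gnm)] <- gid[is.na(gnm)]
  TranscriptSet(seqs, transcript_id = tid, gene_id = gid, gene_name = gnm,
                isoform_class = ifelse(can, "canonical", "alternative"))
}

#' Write a TranscriptSet as CDS FASTA
#'
#' Emits Ensembl-dialect headers so that [readCdsFasta()] round-trips the
#' records (ids, annotations and sequence) exactly.
#'
#' @param x A [TranscriptSet-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeCdsFasta <- function(x, path) {
  sq <- x@sequences
  mc <- S4Vectors::mcols(sq)
  tag <- ifelse(mc$isoform_class == "canonical", " tag:Ensembl_canonical", "")
  names(sq) <- paste0(mc$transcript_id, " cds gene:", mc$gene_id,
                      " gene_symbol:", mc$gene_name, tag)
  Biostrings::writeXStringSet(sq, path)
  invisible(path)
}

#' Codon/frame arithmetic
#'
#' 1-based coordinate conventions used throughout: nucleotide position
#' `nt_pos` lies in codon `ceiling(nt_pos / 3)` with phase
#' `(nt_pos - 1) %% 3`.
#'
#' @param nt_pos 1-based nucleotide position(s).
#' @param codon_index 1-based codon index(es).
#' @return Integer vector.
#' @examples
#' codonIndex(7)   # 3
#' ntPos(3)        # 7
#' codonPhase(7)   # 0
#' @export
codonIndex <- function(nt_pos) as.integer(ceiling(nt_pos / 3))

#' @rdname codonIndex
#' @export
ntPos <- function(codon_index) as.integer(3L * codon_index - 2L)

#' @rdname codonIndex
#' @export
codonPhase <- function(nt_pos) as.integer((nt_pos - 1L) %% 3L)

#' Translate a CDS from an arbitrary start and frame offset
#'
#' Translation uses the standard genetic code, starts at
#' `start_nt + frame_offset`, and stops at (not including) the first stop
#' codon, or at the sequence end if no stop occurs. Codons containing `N`
#' translate to `X`. A start beyond the sequence end yields the empty
#' string.
#'
#' @param cds RNA sequence (character or `RNAString`).
#' @param start_nt 1-based start position.
#' @param frame_offset One of 0, -1, -2, +1; `start_nt + frame_offset` must
#'   be at least 1.
#' @return Amino-acid string.
#' @examples
#' translateCds("AUGAAAUAA")            # "MK"
#' translateCds("AAUGAAAUAA", 2, -1)    # "MK"
#' @export
translateCds <- function(cds, start_nt = 1L, frame_offset = 0L) {
  stopifnot(frame_offset %in% c(0L, -1L, -2L, 1L))
  from <- as.integer(start_nt + frame_offset)
  if (from < 1L) stop("start_nt + frame_offset must be >= 1")
  s <- as.character(cds)
  n <- nchar(s)
  if (from > n) return("")
  len <- (n - from + 1L) %/% 3L
  if (len == 0L) return("")
  # vectorized standard-genetic-code lookup (Biostrings' table); codons
  # with N or any other non-ACGU character translate to X
  starts <- seq.int(from, by = 3L, length.out = len)
  cods <- chartr("U", "T", substring(s, starts, starts + 2L))
  aa <- .GC_TABLE[cods]
  aa[is.na(aa)] <- "X"
  stop_at <- which(aa == "*")
  if (length(stop_at)) aa <- aa[seq_len(stop_at[1L] - 1L)]
  paste(aa, collapse = "")
}

.GC_TABLE <- Biostrings::GENETIC_CODE

#' Full 0-frame protein sequences of a TranscriptSet
#'
#' Translates each CDS from position 1 in frame 0 to the first stop codon.
#'
#' @param x A [TranscriptSet-class].
#' @return Named character vector of proteins (names are transcript ids).
#' @export
translateSet <- function(x) {
  p <- vapply(as.character(cdsSequences(x)), translateCds, "",
              USE.NAMES = FALSE)
  names(p) <- transcriptIds(x)
  p
}
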