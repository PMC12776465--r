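#' Run the full TMD-slip motif search
#'
#' Orchestrates the pipeline: read (or accept) a transcriptome, build the
#' slippery census, detect and refine TMDs, pair heptamers with TMDs,
#' classify splicing dependence, optionally predict frameshift products,
#' and write every stage output plus a run manifest (config echo, seed,
#' per-stage record counts) to `out_dir`. Re-running with an identical
#' configuration and seed reproduces the outputs byte for byte.
#'
#' @param input A [TranscriptSet-class] or a path to a CDS FASTA.
#' @param out_dir Output directory (created if needed); `NULL` skips all
#'   file output.
#' @param threshold Slippery cutoff in kcal/mol (default 2.9).
#' @param l_range,l_ideal Motif distance parameters (defaults 35-55, 45).
#' @param tmd_mode,topologies,dg_cutoff TMD detection options, see
#'   [findTmds()].
#' @param frames Frames for product prediction; `NULL` skips prediction.
#' @param seed Integer seed recorded in the manifest (the search itself is
#'   deterministic; the seed feeds any downstream randomization).
#' @return List: `census` ([SlipperyTable-class]), `tmds`, `motifs`,
#'   `products` (or `NULL`), `manifest`.
#' @export
runFullSearch <- function(input, out_dir = NULL, threshold = 2.9,
                          l_range = c(35L, 55L), l_ideal = 45L,
                          tmd_mode = "builtin_scan", topologies = NULL,
                          dg_cutoff = 1.0, frames = -1L, seed = 1L) {
  x <- if (is(input, "TranscriptSet")) input else readCdsFasta(input)
  table <- enumerateSlipperyHeptamers(threshold = threshold)
  tmds <- findTmds(x, mode = tmd_mode, topologies = topologies,
                   dgCutoff = dg_cutoff)
  motifs <- findMotifs(x, tmds, table, l_range = l_range, l_ideal = l_ideal)
  motifs <- classifySplicingDependence(motifs, transcripts = x)
  products <- NULL
  if (!is.null(frames) && nrow(motifs) > 0L) {
    cds <- as.character(cdsSequences(x))
    names(cds) <- transcriptIds(x)
    rows <- list()
    for (i in seq_len(nrow(motifs))) for (fr in frames) {
      pr <- predictFrameshiftProduct(cds[[motifs$transcript_id[i]]],
                                     motifs[i, ], fr)
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = motifs$transcript_id[i],
        heptamer_nt_start = motifs$heptamer_nt_start[i], frame = fr,
        extension_len = pr$extension_len, terminated = pr$terminated)
    }
    products <- do.call(rbind, rows)
  }
  manifest <- list(
    seed = seed, threshold = threshold, l_range = l_range,
    l_ideal = l_ideal, tmd_mode = tmd_mode, dg_cutoff = dg_cutoff,
    frames = frames,
    counts = list(transcripts = length(x),
                  transcripts_in_frame = sum(isMultipleOfThree(x)),
                  slippery_heptamers = length(slipperyHeptamers(table)),
                  tmds = nrow(tmds), motifs = nrow(motifs),
                  ideal_motifs = sum(motifs$is_ideal)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(censusTable(table),
                       file.path(out_dir, "heptamer_census.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(tmds, file.path(out_dir, "tmds.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(motifs, file.path(out_dir, "motifs.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    if (!is.null(products))
      utils::write.table(products, file.path(out_dir, "products.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(census = table, tmds = tmds, motifs = motifs, products = products,
       manifest = manifest)
}
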