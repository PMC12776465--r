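#' Randomize TMD positions within each protein
#'
#' Null-model re-placement of refined TMD segments: per transcript, the
#' segments keep their count and lengths and are re-placed uniformly at
#' random (order-preserving, non-overlapping, within the protein bounds);
#' slip-site positions are untouched. Placement is uniform over all
#' non-overlapping arrangements of the length-ordered segments (stars-and-
#' bars gap sampling). Transcripts whose protein is too short to host their
#' segments without overlap keep their original placement with a warning.
#'
#' @param tmds Refined TMD table ([findTmds()] columns `transcript_id`,
#'   `aa_start`, `aa_end`).
#' @param protein_lengths Named integer vector of protein lengths.
#' @param seed Integer seed; placements are reproducible.
#' @return `tmds` with re-placed `aa_start`/`aa_end`.
#' @export
randomizeTmdPositions <- function(tmds, protein_lengths, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- tmds
  for (tid in unique(tmds$transcript_id)) {
    j <- which(tmds$transcript_id == tid)
    lens <- tmds$aa_end[j] - tmds$aa_start[j] + 1L
    plen <- protein_lengths[[tid]]
    free <- plen - sum(lens)
    k <- length(lens)
    if (free < 0L) {
      warning("transcript ", tid, " too short to re-place its TMDs; ",
              "original placement kept")
      next
    }
    # gap sampling: choose k of (free + k) slots; gaps are the leftovers
    u <- sort(sample.int(free + k, k))
    gaps <- c(u[1L] - 1L, diff(u) - 1L)
    starts <- cumsum(gaps) + c(0L, cumsum(lens[-k])) + 1L
    o <- j[order(tmds$aa_start[j])]
    out$aa_start[o] <- starts
    out$aa_end[o] <- starts + lens[order(tmds$aa_start[j])] - 1L
  }
  out
}

#' Sample random heptamer sets
#'
#' Each set is drawn uniformly without replacement from the full
#' 16384-heptamer space; returned sets are mutually distinct.
#'
#' @param n_sets Number of sets.
#' @param set_size Members per set (<= 16384).
#' @param seed Integer seed.
#' @return List of character vectors.
#' @export
sampleRandomHeptamerSets <- function(n_sets, set_size, seed = NULL) {
  stopifnot(set_size <= 16384L)
  if (set_size == 16384L && n_sets > 1L)
    stop("only one distinct set of size 16384 exists")
  if (!is.null(seed)) set.seed(seed)
  space <- enumerateSlipperyHeptamers()@census$heptamer
  seen <- character(0)
  out <- vector("list", n_sets)
  for (i in seq_len(n_sets)) {
    for (try in 1:100) {
      s <- sort(sample(space, set_size))
      key <- paste(s, collapse = "")
      if (!key %in% seen) break
      if (try == 100L) stop("could not draw ", n_sets, " distinct sets")
    }
    seen <- c(seen, key)
    out[[i]] <- s
  }
  out
}

#' Mann-Whitney U test
#'
#' Rank-sum test with tie correction. For small samples
#' (`n1 + n2 <= 20`) the two-sided p-value is computed by exact, tie-aware
#' enumeration of all rank arrangements
#' (`P(|U - n1 n2 / 2| >= |u_obs - n1 n2 / 2|)`); larger samples use the
#' normal approximation with tie correction via [stats::wilcox.test()].
#'
#' @param x,y Non-empty numeric samples.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return List: `statistic` (U for `x`), `p_value`, `method`.
#' @export
mannWhitneyU <- function(x, y, alternative = "two.sided") {
  if (length(x) == 0L || length(y) == 0L) stop("samples must be non-empty")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 + n2 <= 20L) {
    combs <- utils::combn(n1 + n2, n1)
    u_all <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    mid <- n1 * n2 / 2
    p <- switch(alternative,
      two.sided = mean(abs(u_all - mid) >= abs(u_obs - mid) - 1e-9),
      greater = mean(u_all >= u_obs - 1e-9),
      less = mean(u_all <= u_obs + 1e-9),
      stop("unknown alternative"))
    return(list(statistic = u_obs, p_value = p, method = "exact enumeration"))
  }
  if (length(unique(c(x, y))) == 1L)  # fully tied: no evidence either way
    return(list(statistic = u_obs, p_value = 1,
                method = "degenerate (all values tied)"))
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = alternative,
                                            exact = FALSE, correct = TRUE))
  list(statistic = u_obs, p_value = wt$p.value,
       method = "normal approximation with tie correction")
}

#' Fisher's exact test on a 2x2 table
#'
#' Conditional hypergeometric p-value (two-sided by the point-probability
#' rule, via [stats::fisher.test()]) together with the sample odds ratio
#' `ad/bc` (infinite when `bc = 0`, `NaN` on degenerate tables).
#'
#' @param tab 2x2 matrix of non-negative counts.
#' @param alternative Test direction.
#' @return List: `p_value`, `odds_ratio`, `method`.
#' @export
fisherExact <- function(tab, alternative = "two.sided") {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2L), all(tab >= 0))
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  if (sum(tab) == 0L || any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(p_value = 1, odds_ratio = or, method = "degenerate margins"))
  ft <- stats::fisher.test(tab, alternative = alternative)
  list(p_value = ft$p.value, odds_ratio = unname(or),
       method = "Fisher's exact test")
}

#' Pearson chi-squared association test on a 2x2 table
#'
#' Without continuity correction, df = 1, plus the sample odds ratio.
#' Tables with a zero expected count are refused (use [fisherExact()]).
#'
#' @param tab 2x2 matrix of counts.
#' @return List: `statistic`, `p_value`, `odds_ratio`.
#' @export
chi2Association <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2L))
  expct <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(!is.finite(expct)) || any(expct == 0))
    stop("zero expected count; use fisherExact() instead")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p_value = ct$p.value,
       odds_ratio = unname((tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])))
}

# Distances retained by the motif assignment for fixed slip-site positions
# and one TMD-end configuration (fast path shared with findMotifs through
# .assign_motifs).
.distances_for <- function(psites, tmd_ends, l_range, l_ideal) {
  unlist(lapply(seq_along(psites), function(i)
    .assign_motifs(psites[[i]], tmd_ends[[i]], l_range, l_ideal)$L),
    use.names = FALSE)
}

#' Positional randomization null test for motif spacing
#'
#' Compares the observed distribution of TMD-to-slip-site distances to the
#' distances obtained across an ensemble of null transcriptomes: per
#' iteration either the TMD segments are re-placed uniformly at random
#' (`mode = "randomize_tmd_positions"`) or the slippery set is replaced by
#' a random heptamer set of equal size
#' (`mode = "randomize_heptamer_sets"`), and the motif assignment is
#' re-run. The observed distances are tested against the pooled null
#' distances with a two-tailed Mann-Whitney test; the per-distance count
#' table and a 2x2 chi-squared comparison of ideal-spacing counts
#' (observed vs null mean) are also returned.
#'
#' @param x A [TranscriptSet-class].
#' @param tmds Refined TMD table ([findTmds()]).
#' @param table A [SlipperyTable-class].
#' @param n_iterations Ensemble size (the full-scale analysis uses 16384;
#'   use a few hundred for calibration work).
#' @param seed Integer seed.
#' @param mode Randomization scheme (see above).
#' @param l_range,l_ideal Distance parameters as in [findMotifs()].
#' @return List: `observed_L`, `null_L` (pooled), `mw` (Mann-Whitney
#'   result), `histogram` (per-L observed count and null mean),
#'   `ideal_test` (chi-squared on ideal-spacing counts, or `NULL` when a
#'   margin is empty), `n_iterations`, `mode`, `seed`.
#' @export
positionalNullTest <- function(x, tmds, table, n_iterations = 200L,
                               seed = NULL,
                               mode = c("randomize_tmd_positions",
                                        "randomize_heptamer_sets"),
                               l_range = c(35L, 55L), l_ideal = 45L) {
  mode <- match.arg(mode)
  n_iterations <- as.integer(n_iterations)
  stopifnot(n_iterations >= 1L)
  if (!is.null(seed)) set.seed(seed)
  mc <- S4Vectors::mcols(cdsSequences(x))
  keep <- mc$multiple_of_three & mc$transcript_id %in% tmds$transcript_id
  tids <- mc$transcript_id[keep]
  cds <- as.character(cdsSequences(x))[keep]
  prot_len <- stats::setNames(nchar(vapply(cds, translateCds, "")), tids)
  hits <- lapply(cds, .scan_slippery, table = table)
  psites <- lapply(hits, function(h) h$nt_start %/% 3L + 1L)
  tmd_ends <- lapply(tids, function(t)
    tmds$aa_end[tmds$transcript_id == t])
  tmd_lens <- lapply(tids, function(t)
    tmds$aa_end[tmds$transcript_id == t] -
      tmds$aa_start[tmds$transcript_id == t] + 1L)
  observed <- .distances_for(psites, tmd_ends, l_range, l_ideal)
  null_L <- vector("list", n_iterations)
  if (mode == "randomize_tmd_positions") {
    for (it in seq_len(n_iterations)) {
      ends <- lapply(seq_along(tids), function(i) {
        lens <- tmd_lens[[i]]
        free <- prot_len[[i]] - sum(lens)
        if (free < 0L) return(tmd_ends[[i]])
        k <- length(lens)
        u <- sort(sample.int(free + k, k))
        gaps <- c(u[1L] - 1L, diff(u) - 1L)
        cumsum(gaps) + cumsum(lens)
      })
      null_L[[it]] <- .distances_for(psites, ends, l_range, l_ideal)
    }
  } else {
    n_slip <- length(slipperyHeptamers(table))
    space <- table@census$heptamer
    all_hepts <- lapply(cds, function(s) {
      n <- nchar(s)
      h <- seq.int(3L, by = 3L, length.out = max(0L, (n - 9L) %/% 3L))
      data.frame(nt_start = h, heptamer = substring(s, h, h + 6L))
    })
    for (it in seq_len(n_iterations)) {
      rset <- sample(space, n_slip)
      ps <- lapply(all_hepts, function(h)
        h$nt_start[h$heptamer %in% rset] %/% 3L + 1L)
      null_L[[it]] <- .distances_for(ps, tmd_ends, l_range, l_ideal)
    }
  }
  pooled <- unlist(null_L, use.names = FALSE)
  mw <- if (length(observed) && length(pooled))
    mannWhitneyU(observed, pooled) else NULL
  lvals <- seq.int(l_range[1], l_range[2])
  hist <- data.frame(
    L = lvals,
    observed = vapply(lvals, function(l) sum(observed == l), 0L),
    null_mean = vapply(lvals, function(l) sum(pooled == l), 0) /
      n_iterations)
  obs_tab <- rbind(c(sum(observed == l_ideal), sum(observed != l_ideal)),
                   round(c(sum(pooled == l_ideal),
                           sum(pooled != l_ideal)) / n_iterations))
  ideal <- if (all(rowSums(obs_tab) > 0) && all(colSums(obs_tab) > 0))
    chi2Association(obs_tab) else NULL
  list(observed_L = observed, null_L = pooled, mw = mw, histogram = hist,
       ideal_test = ideal, n_iterations = n_iterations, mode = mode,
       seed = seed)
}

#' Association between motifs and UPF1-sensitive transcript abundance
#'
#' Tests whether motif-bearing transcripts are enriched among transcripts
#' up-regulated on UPF1 depletion and depleted among down-regulated ones
#' (two Fisher tests), plus a two-tailed Mann-Whitney test on the log2
#' fold-changes of motif vs non-motif transcripts.
#'
#' @param records data.frame with columns `log2_fold_change` and
#'   `has_motif` (logical).
#' @param up_threshold,down_threshold Log2 fold-change cutoffs defining
#'   up-/down-regulation (defaults +/-0.263, i.e. +/-20%).
#' @return List: `fisher_up`, `fisher_down`, `mw`, `n_with`, `n_without`.
#' @export
nmdAssociation <- function(records, up_threshold = 0.263,
                           down_threshold = -0.263) {
  stopifnot(nrow(records) > 0L, all(is.finite(records$log2_fold_change)))
  if (length(unique(records$has_motif)) < 2L)
    stop("both motif classes must be represented")
  up <- records$log2_fold_change > up_threshold
  dn <- records$log2_fold_change < down_threshold
  mk <- function(flag) {
    tab <- matrix(c(sum(records$has_motif & flag),
                    sum(records$has_motif & !flag),
                    sum(!records$has_motif & flag),
                    sum(!records$has_motif & !flag)), 2L, byrow = TRUE)
    fisherExact(tab)
  }
  list(fisher_up = mk(up), fisher_down = mk(dn),
       mw = mannWhitneyU(records$log2_fold_change[records$has_motif],
                         records$log2_fold_change[!records$has_motif]),
       n_with = sum(records$has_motif), n_without = sum(!records$has_motif))
}

#' Annotation-term enrichment among hit genes
#'
#' Per-term 2x2 Fisher test of hit genes against the background, with
#' Benjamini-Hochberg adjustment across all tested terms. Retained terms
#' must have at least `min_genes` hit-set members, an odds ratio above
#' `min_fold`, and an annotation depth inside `depth_range`.
#'
#' @param hit_genes,background_genes Character vectors (hits must be a
#'   subset of the background).
#' @param annotation data.frame with columns `term`, `gene`, `depth`.
#' @param min_genes Minimum number of hit genes per retained term.
#' @param min_fold Minimum odds ratio per retained term.
#' @param depth_range Admissible annotation depths.
#' @return data.frame: `term`, `depth`, `n_hit`, `n_background`,
#'   `odds_ratio`, `p_value`, `p_adjusted`, filtered and sorted by
#'   adjusted p.
#' @export
termEnrichment <- function(hit_genes, background_genes, annotation,
                           min_genes = 100L, min_fold = 1.4,
                           depth_range = c(3L, 8L)) {
  stopifnot(all(hit_genes %in% background_genes))
  empty <- data.frame(term = character(0), depth = integer(0),
                      n_hit = integer(0), n_background = integer(0),
                      odds_ratio = numeric(0), p_value = numeric(0),
                      p_adjusted = numeric(0))
  if (nrow(annotation) == 0L) return(empty)
  terms <- unique(annotation$term)
  rows <- lapply(terms, function(tm) {
    genes <- unique(annotation$gene[annotation$term == tm])
    genes <- genes[genes %in% background_genes]
    a <- sum(hit_genes %in% genes)
    b <- length(hit_genes) - a
    cc <- sum(!background_genes %in% hit_genes & background_genes %in% genes)
    d <- length(background_genes) - length(hit_genes) - cc
    ft <- fisherExact(matrix(c(a, b, cc, d), 2L, byrow = TRUE))
    data.frame(term = tm,
               depth = annotation$depth[annotation$term == tm][1L],
               n_hit = a, n_background = length(genes),
               odds_ratio = ft$odds_ratio, p_value = ft$p_value)
  })
  res <- do.call(rbind, rows)
  res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
  keep <- !is.na(res$odds_ratio) & res$odds_ratio > min_fold &
    res$n_hit >= min_genes &
    res$depth >= depth_range[1] & res$depth <= depth_range[2]
  res <- res[keep, , drop = FALSE]
  res[order(res$p_adjusted), , drop = FALSE]
}
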