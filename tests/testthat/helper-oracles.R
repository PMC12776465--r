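# Shared fixtures and independent oracles for the suite.

# One slippery census per test run (deterministic; ~1 s to build).
slip_tab <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- enumerateSlipperyHeptamers()
    tab
  }
})

# --- independent dG_FS oracle -----------------------------------------------
# Naive per-heptamer scorer written directly from the pairing rules, sharing
# no code with the package path (no delta table, explicit pair walk).
oracle_wc <- c(AA = -0.93, UU = -0.93, AU = -1.10, UA = -1.33, CU = -2.08,
               AG = -2.08, CA = -2.11, UG = -2.11, GU = -2.24, AC = -2.24,
               GA = -2.35, UC = -2.35, CG = -2.36, GC = -3.42, GG = -3.26,
               CC = -3.26)

oracle_energy <- function(target, codon, s = 0.5, g = -1.0, w = 0.56,
                          p = 0.32) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  tb <- strsplit(target, "")[[1]]
  cb <- strsplit(codon, "")[[1]]
  cls <- character(3)
  for (i in 1:3) {
    anti <- comp[[cb[i]]]
    cls[i] <- if (tb[i] == cb[i]) "WC"
      else if ((tb[i] == "G" && anti == "U") ||
               (tb[i] == "U" && anti == "G")) "GU" else "MM"
  }
  e <- p * sum(cls == "MM") + w * sum(cls == "GU")
  for (i in 1:2) {
    if (cls[i] == "MM" || cls[i + 1] == "MM") next
    e <- e + s * (if (cls[i] == "WC" && cls[i + 1] == "WC")
      oracle_wc[[paste0(tb[i], tb[i + 1])]] else g)
  }
  e
}

oracle_dg_fs <- function(h) {
  cP <- substr(h, 2, 4); cA <- substr(h, 5, 7)
  mP <- paste0(substr(h, 1, 1), substr(h, 2, 3))
  mA <- paste0(substr(h, 4, 4), substr(h, 5, 6))
  raw <- oracle_energy(mP, cP) + oracle_energy(mA, cA) -
    oracle_energy(cP, cP) - oracle_energy(cA, cA)
  # the model's stated convention: snap to milli-kcal, round half-up to 0.01
  milli <- round(raw * 1000)
  (milli %/% 10 + (milli %% 10 >= 5)) / 100
}

# --- brute-force TMD refinement oracle --------------------------------------
brute_refine <- function(protein, aa_start, aa_end, scale = dgScale()) {
  n <- nchar(protein)
  a <- max(1L, aa_start - 10L); b <- min(n, aa_end + 10L)
  best <- NULL
  for (s in a:b) for (e in s:b) {
    len <- e - s + 1L
    if (len < 16L || len > 25L) next
    seg <- substr(protein, s, e)
    if (grepl("X", seg, fixed = TRUE)) next
    dg <- dgApp(seg, scale)
    if (is.null(best) || dg < best$dg_app ||
        (dg == best$dg_app && (len < best$length ||
          (len == best$length && s < best$aa_start))))
      best <- list(aa_start = s, aa_end = e, length = len, dg_app = dg)
  }
  best
}

# --- brute-force motif assignment oracle ------------------------------------
# Pair every slippery-heptamer P-site with every TMD end, then apply the
# two assignment rules literally.
brute_assign <- function(psite, tmd_end, l_range, l_ideal) {
  if (!length(psite) || !length(tmd_end))
    return(data.frame(h = integer(0), t = integer(0), L = integer(0)))
  rows <- expand.grid(h = seq_along(psite), t = seq_along(tmd_end))
  rows$L <- psite[rows$h] - tmd_end[rows$t]
  rows <- rows[rows$L > 0, , drop = FALSE]
  if (!nrow(rows)) return(data.frame(h = integer(0), t = integer(0),
                                     L = integer(0)))
  # step 1: each heptamer keeps its best TMD
  keep1 <- unlist(lapply(split(seq_len(nrow(rows)), rows$h), function(j) {
    d <- abs(rows$L[j] - l_ideal)
    j <- j[d == min(d)]
    j[which.min(rows$L[j])]
  }))
  rows <- rows[keep1, , drop = FALSE]
  # step 2: each TMD keeps its best heptamer
  keep2 <- unlist(lapply(split(seq_len(nrow(rows)), rows$t), function(j) {
    d <- abs(rows$L[j] - l_ideal)
    j <- j[d == min(d)]
    j[which.min(rows$L[j])]
  }))
  rows <- rows[keep2, , drop = FALSE]
  rows <- rows[rows$L >= l_range[1] & rows$L <= l_range[2], , drop = FALSE]
  rows <- rows[order(rows$h), c("h", "t", "L")]
  rownames(rows) <- NULL
  rows
}

# --- exact test oracles ------------------------------------------------------
# Two-sided Fisher p by direct hypergeometric point-mass summation.
oracle_fisher_p <- function(a, b, cc, d) {
  m <- a + b; n <- cc + d; k <- a + cc
  lo <- max(0L, k - n); hi <- min(k, m)
  pm <- vapply(lo:hi, function(x)
    exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)), 0)
  obs <- pm[a - lo + 1L]
  sum(pm[pm <= obs * (1 + 1e-7)])
}

# Exact two-sided Mann-Whitney p via pairwise-comparison U over all group
# relabelings (different computation path from the package's rank-based one).
oracle_mw_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  z <- c(x, y)
  uval <- function(idx) {
    xs <- z[idx]; ys <- z[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  combs <- utils::combn(n1 + n2, n1)
  u_all <- apply(combs, 2, uval)
  u_obs <- uval(seq_len(n1))
  mid <- n1 * n2 / 2
  mean(abs(u_all - mid) >= abs(u_obs - mid) - 1e-9)
}

# --- misc --------------------------------------------------------------------
random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n,
                                       replace = TRUE), collapse = "")

random_protein <- function(n)
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
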