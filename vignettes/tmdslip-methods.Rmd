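---
title: "Methods: finding TMD-slip motifs in coding transcriptomes"
author: "tmdslip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: finding TMD-slip motifs in coding transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmdslip)
```

## The model

During −1 programmed ribosomal frameshifting (−1PRF) the P- and A-site
tRNAs detach from their 0-frame codons and re-pair one nucleotide
upstream. Classical slippery heptamers (X XXY YYZ) permit this because the
−1-frame codons offer near-isoenergetic base pairing to the same
anticodons. Separately, when a hydrophobic transmembrane segment (TMD) of
the nascent chain engages the translocon, it exerts mechanical tension on
the ribosome; because roughly 45 codons of nascent chain span the exit
tunnel and the translocon, that tension peaks while the ribosome decodes
sequence ~45 codons downstream of the TMD-encoding region. A *TMD-slip
motif* is the conjunction of the two signals: a slippery heptamer placed
35–55 codons (ideally 45) downstream of a TMD, so that translocation
coincides with the decoding of the slip site.

`tmdslip` implements the full discovery pipeline: score all heptamers for
frameshift propensity, locate and refine translocon-engaged TMD segments,
pair the two at translation-coupled distances, predict the resulting
frameshift products and their proteolytic peptides, and assess the
statistical context with randomization nulls and exact tests.

## Slip-site energetics (ΔG~FS~)

For a heptamer N1…N7 the 0-frame P- and A-site codons are N2N3N4 and
N5N6N7; after a −1 shift the same anticodons face N1N2N3 and N4N5N6.
`dgFs()` scores

ΔG~FS~ = [E(ac(N2N3N4) : N1N2N3) + E(ac(N5N6N7) : N4N5N6)] −
[E(ac(N2N3N4) : N2N3N4) + E(ac(N5N6N7) : N5N6N7)],

where ac(·) is the perfect Watson–Crick anticodon and E(·) is the energy of
the three-base-pair minihelix: the sum of the two nearest-neighbor stacking
steps. The anticodon is the strict reverse complement of the 0-frame codon
(one cognate tRNA per codon; isoacceptor and wobble-decoder choice is not
modeled), and the same anticodon is re-paired against the −1-frame codon.

The energy bookkeeping is knowledge-based, with four constants on top of
the bundled Turner Watson–Crick stack table
(`inst/extdata/turner_wc_stacks.tsv`, read bit-exact):

| parameter | default | meaning |
|---|---|---|
| `stackWeight` | 0.5 | multiplier on all stack terms |
| `guStack` | −1.00 kcal/mol | stack value of any step flanked by a G·U pair |
| `wobblePair` | +0.56 kcal/mol | additive term per G·U pair |
| `mismatchPenalty` | +0.32 kcal/mol | additive term per mismatch; a mismatch also voids both adjacent stacks |

These defaults are a calibration, chosen once so that (i) the 24 classical
X XXY YYZ reference motifs (X any base, Y ∈ {A,U}, Z ∈ {A,C,U}) all score
at or below the +2.9 kcal/mol cutoff, and (ii) the census of the full
4^7 = 16,384 heptamer space at that cutoff contains 465 slippery
sequences. With the defaults the reference maximum is 2.82 kcal/mol and
`calibrateThreshold()` publishes the cutoff as the next 0.1 grid value,
2.9; `grid = 0` returns the raw maximum instead. Cognate pairing is
minimal under this bookkeeping, so ΔG~FS~ ≥ 0 always, with equality
exactly for the four homopolymers.

Scores are exact multiples of 0.001 kcal/mol; `dgFs()` snaps to
milli-kcal integers and rounds half-up to 0.01 so the strict `<`
threshold comparison is stable regardless of summation order.

## TMD detection and refinement (ΔG~app~)

The segment a translocon integrates is found in two stages. Candidate
regions come either from an ingested per-residue topology string (runs of
`M`, minimum 10 residues) or from the built-in fallback scanner, which
slides a 19-residue ΔG~app~ window and marks maximal runs below a cutoff
(default +1.0 kcal/mol), merging regions separated by fewer than 5
residues. The fallback is a stand-in for a dedicated topology predictor;
synthetic tests use unambiguous hydrophobic blocks so the stand-in never
decides a result.

`refineTmdSegment()` then enumerates every 16–25 residue segment inside
the window from 10 residues upstream to 10 downstream of the region
(clipped at the protein termini) and returns the minimum-ΔG~app~ segment;
ties break to the shortest segment, then the smallest start, making the
result unique and deterministic. The segment's C-terminal residue anchors
all distance computations.

The bundled scale uses per-residue center coefficients of the biological
hydrophobicity scale (leucine −0.55, alanine +0.11, aspartate +3.49
kcal/mol, …) with a Gaussian position profile exp(−x²/2σ²) on the
normalized coordinate x ∈ [−1, 1] (σ = 0.6), a quadratic length
correction 0.033·(L − 19)² kcal/mol, and an optional helical hydrophobic
moment term (coefficient 0 by default, as the published variant choice is
open). A `center_only` mode drops the position profile for tests where
profile shape is irrelevant. Segment refinement is validated against
exhaustive brute-force enumeration rather than against an external tool.

## Motif assignment

Only phase-aligned heptamers are scanned in transcripts — start position
≡ 0 (mod 3), so that nucleotides 2–4 and 5–7 are 0-frame codons (the
classical register); the 16,384 census is position-free. Heptamers
overlapping the stop codon, within 7 nt of the CDS end, or containing `N`
are skipped, as are transcripts whose length is not a multiple of three.

The distance L runs from the refined TMD's C-terminal residue to the
heptamer's 0-frame P-site codon (`anchor = "c_term_to_heptamer_start"`
selects the one-codon-shorter convention). Assignment is two-stage to
avoid double counting: each slippery heptamer goes to the TMD minimizing
|L − 45| (L > 0 only), then each TMD retains the single heptamer
minimizing |L − 45|. Ties in |L − 45| resolve to the smaller L — a
deterministic choice; the biology offers no guidance. Output is
restricted to L ∈ [35, 55] and is invariant to input transcript order.

A motif in an alternative isoform is *splicing-dependent* when the gene's
canonical transcript has no in-range motif with the same heptamer
sequence; when it does, the motif is labeled `shared_with_canonical` (an
extra class the enum needs to be total); genes without a canonical
transcript give `not_applicable`. A gene annotated with two canonical
transcripts is rejected as a data problem.

## Frameshift products and peptides

At the shift the P-site residue is the last 0-frame residue; the first
alternative-frame residue is decoded from the shifted A-site codon
(offset `frame` from the 0-frame A-site). The extension runs to the first
alternative-frame stop; an immediate stop is a premature-termination
product, and running off the sequence end leaves `terminated = FALSE`.
Frames −1 (default), −2 and +1 are supported.

`digestProtein()` applies standard protease specificities (trypsin, LysC,
LysN, GluC, AspN, chymotrypsin) with up to 2 missed cleavages; a 7–50
residue length filter is applied at database construction (common search
defaults; the source values are unstated upstream, so both are exposed).
The two-pass database emits, per motif × frame, digested peptides that
overlap the transition point or extension and removes any peptide
identical to a 0-frame peptide of the same transcriptome, so the
second-pass database is disjoint from pass one by construction.

`classifyPeptide()` does exact substring search against the 0-frame
proteome and all predicted products: `zero_frame`, `transitional` (0-frame
residues then ≥ 1 alternative-frame residue), `frameshift` (wholly inside
an extension), `premature_termination` (0-frame sequence ending at the
P-site residue of a product whose shifted frame presents an immediate
stop; this specific call outranks the zero-frame substring match it
necessarily also satisfies), and `ambiguous` for combinations. Isoforms
of one gene share sequence, so multi-locus ambiguity is assessed at the
gene level, and zero-frame matches in several transcripts stay
`zero_frame`. Isoleucine/leucine are kept distinct by default;
`collapse_il = TRUE` merges them (they are isobaric in MS).

## Statistics

Two randomization nulls mirror the two published ensembles: per-transcript
TMD re-placement (count- and length-preserving, order-preserving, uniform
over non-overlapping arrangements by stars-and-bars gap sampling) and
random heptamer sets of equal size drawn without replacement from the full
space. `positionalNullTest()` re-runs the motif assignment per iteration
and compares the observed distances against the pooled null with a
two-tailed Mann–Whitney test (pooling matches the single reported p per
analysis), and also returns the per-distance histogram plus a 2×2
chi-squared odds ratio for ideal-spacing counts. Note that an excess
point mass at L = 45 sits at the center of the null distance
distribution, where a rank test is insensitive — the ideal-spacing odds
ratio is the right detector for that signal.

`mannWhitneyU()` uses exact tie-aware enumeration of rank arrangements
for n1 + n2 ≤ 20 and the tie-corrected normal approximation otherwise
(full enumeration much beyond that total — e.g. two samples of 20 —
would mean ~10^11 arrangements and is not computable). `fisherExact()` reports the
conditional two-sided p (point-probability rule) with the sample odds
ratio ad/bc; `chi2Association()` is Pearson's χ² without continuity
correction. `nmdAssociation()` runs motif × up and motif × down Fisher
tests plus a Mann–Whitney on log2 fold-changes; the ±20% regulation
cutoffs (|log2FC| > 0.263) are config parameters, as the upstream source
does not print them. `termEnrichment()` filters per-term Fisher results
by odds ratio (> 1.4 — the "fold enrichment" the captions plot),
annotation depth (3–8) and hit-set size (≥ 100 at full scale), with
Benjamini–Hochberg adjustment across all tested terms.

## The synthetic transcriptome generator

`generateTranscriptome()` emulates exactly the features the pipeline
consumes: Ensembl-style CDS records grouped into genes with one canonical
transcript; codon-randomized, strongly hydrophobic (L/I/V/F) TMD blocks
with hydrophilic flanks that pin the refined segment to the planted
boundaries; phase-aligned slippery heptamers planted at configured codon
distances; and splicing-dependent geometries realized by spacer-codon
deletion (same heptamer, shorter distance, as in the published KCNQ1
example where the canonical spacing is 67 codons and an isoform brings it
to 39). With `background_slippery_rate = 0` a bounded mutate-and-rescan
pass scrubs accidental phase-aligned slippery heptamers in a ±5-codon
guard band around the search range (single-nucleotide substitutions that
never introduce 0-frame stops), so planted motifs are the only in-range
signal and closed-loop recovery is exact.

What the generator does **not** emulate: real codon-usage bias (uniform
over sense codons by default; a usage table can be supplied), UTRs and
splice-graph structure (isoforms are simple codon deletions), RNA
secondary structure near slip sites, signal peptides, and realistic TMD
hydrophobicity gradations. Passing closed-loop tests therefore
demonstrates the correctness of the search machinery, not the biological
error rate on real transcriptomes, where TMD prediction and annotation
quality dominate.

`generateUpf1Table()` draws motif-bearing transcripts from
Normal(effect, σ) and the rest from Normal(0, σ), mirroring the fold-change
comparison at the published group sizes (730 with motifs, 425 without,
effect +0.263 ≈ +20%, σ = 0.5 chosen as a realistic fold-change spread).

## Numerical choices and problem sizes

* ΔG~FS~ rounding: half-up at 0.01 kcal/mol after snapping to exact
  milli-kcal; strict `<` at the threshold.
* All randomized operations take explicit seeds; identical seeds give
  byte-identical outputs.
* Refinement windows are clipped at protein termini (regions near the
  ends are refined, not discarded); windows shorter than 16 residues are
  an error carrying the region coordinates.
* Degenerate inputs: empty motif tables propagate to empty outputs;
  fully tied Mann–Whitney samples give p = 1; degenerate Fisher margins
  give p = 1 with the odds ratio flagged undefined.
* Test-suite problem sizes (chosen as the package's own validation
  scale): brute-force refinement on 200 random windows; planted-motif
  recovery on a 100-gene genome; exact-test agreement on every 2×2 table
  of total ≤ 20 and Mann–Whitney samples of total ≤ 20; type-I
  calibration of the positional null with 100 replicates of 200
  iterations; NMD power at the published 730/425 group sizes with 100
  replicates. The full-scale analysis settings (16,384 iterations,
  transcriptome-wide search) are reachable through the same functions.

## Known limitations

* The ΔG~FS~ bookkeeping is one defensible reading of a knowledge-based
  pairing score; per-motif published scores were not available to match,
  so only the reference-range and census-size constraints pin the
  calibration.
* The built-in TMD scanner is deliberately simple; for real
  transcriptomes an external topology predictor's output should be
  ingested via `mode = "topcons_file"`.
* `classifyPeptide()` is sequence-level only: it does not model
  semi-specific termini, modifications, or spectral evidence.
* Worked examples on real human transcripts (KCNQ1, HSP90B1, LPCAT1)
  require downloading those CDS records; the package validates the same
  geometries on synthetic stand-ins.
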