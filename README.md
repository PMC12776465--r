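# tmdslip

Discovery of **TMD-slip motifs** — ribosomal frameshift sites created by
the mechanical coupling between nascent-chain membrane translocation and
the decoding of slippery heptanucleotides.

## The problem

−1 programmed ribosomal frameshifting (−1PRF) happens when the P- and
A-site tRNAs re-pair one nucleotide upstream during the decoding of a
"slippery" heptamer (classically X XXY YYZ). Most known sites rely on a
downstream RNA structure to stall the ribosome; an alternative trigger is
mechanical: when a transmembrane domain (TMD) of the nascent chain is
pulled into the membrane by the translocon, tension on the ribosome peaks
while it decodes sequence ~45 codons downstream of the TMD-encoding
region. A slippery heptamer placed 35–55 codons (ideally 45) downstream
of a TMD is therefore a candidate frameshift site — a TMD-slip motif.
Because these frameshifts usually run into premature stop codons, such
motifs also mark transcripts for nonsense-mediated decay (NMD), and
alternative splicing can create or destroy them by re-spacing TMDs and
slip sites.

`tmdslip` is for computational biologists who want to search coding
transcriptomes for these motifs and quantify their statistical context.

## What it computes

* **ΔG_FS** (`dgFs`, `enumerateSlipperyHeptamers`): the free-energy
  penalty of re-pairing both tRNA anticodons against the −1-frame codons,
  from Turner-style nearest-neighbor stacks. Scoring all 4^7 = 16,384
  heptamers at the calibrated cutoff (ΔG_FS < +2.9 kcal/mol, the upper
  bound of the 24 classical slippery motifs) yields 465 slippery
  sequences.
* **ΔG_app** (`dgApp`, `findTmds`, `refineTmdSegment`): apparent
  translocon insertion free energy of 16–25 residue segments from a
  biological hydrophobicity scale; each candidate TMD region is refined
  to its minimum-ΔG segment by exhaustive window enumeration.
* **Motif search** (`findMotifs`, `classifySplicingDependence`):
  phase-aligned slippery heptamers paired to TMDs by nearest-to-45-codon
  assignment with per-TMD dedup, restricted to L ∈ [35, 55], and
  classified as canonical, splicing-dependent, or shared.
* **Frameshift products** (`predictFrameshiftProduct`, `digestProtein`,
  `buildFrameshiftPeptideDb`, `classifyPeptide`): alternative-frame
  extensions to the first −1/−2/+1 stop, two-pass proteomic search
  databases disjoint from the 0-frame digest, and peptide calls
  (zero-frame / transitional / frameshift / premature termination).
* **Statistics** (`positionalNullTest`, `nmdAssociation`,
  `termEnrichment`, `mannWhitneyU`, `fisherExact`, `chi2Association`):
  randomized-TMD and randomized-heptamer-set null ensembles, exact rank
  and contingency tests, and annotation-term enrichment.
* **Synthetic truth** (`simConfig`, `generateTranscriptome`,
  `generateUpf1Table`, `generatePeptideFixtures`): transcriptomes with
  planted motifs and known ground truth for end-to-end validation.

## Worked example

```r
library(tmdslip)

tab <- enumerateSlipperyHeptamers()
tab
#> SlipperyTable: 465 of 16384 heptamers slippery at dG_FS < 2.9 kcal/mol

dgFs("AAAAAAG")        # the KCNQ1-style slip site
#> [1] 1.36             # well below the +2.9 kcal/mol cutoff

# a 5-gene synthetic transcriptome with one ideal-spacing motif per gene
g <- generateTranscriptome(simConfig(n_genes = 5, seed = 42), tab)
res <- runFullSearch(g$transcripts)
res$motifs[, c("transcript_id", "tmd_end", "heptamer", "distance_L", "is_ideal")]
#>   transcript_id tmd_end heptamer distance_L is_ideal
#> 1    SIMT0001.1      43  AAAAAAG         45     TRUE
#> 2    SIMT0002.1      38  AAAAAAG         45     TRUE
#> 3    SIMT0003.1      36  AAAAAAG         45     TRUE
#> 4    SIMT0004.1      43  AAAAAAG         45     TRUE
#> 5    SIMT0005.1      42  AAAAAAG         45     TRUE
```

Each row is one motif: the refined TMD's C-terminal residue (`tmd_end`),
the slippery heptamer and its distance `L` in codons from the TMD end to
the heptamer's P-site codon; `is_ideal` flags L = 45, the spacing at
which translocation force and slip-site decoding coincide. Every planted
motif is recovered at its exact distance and nothing else is reported —
the generator's ground truth makes that checkable.

Real transcriptomes enter through `readCdsFasta()` (Ensembl-style CDS
headers, optional canonical-flag sidecar), and external topology
predictions through `findTmds(mode = "topcons_file")`.

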