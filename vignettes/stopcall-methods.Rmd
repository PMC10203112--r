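---
title: "stopcall: methods and design notes"
author: "stopcall authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{stopcall: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stopcall)
```

# Scope

Cytosine base editors (CBEs) fuse a Cas9 nickase to a cytosine deaminase so
that cytosines within a narrow protospacer window are converted to thymines
without a double-strand break.  Gene silencing by CBE exploits four sense
codons: editing the C of CAA, CAG or CGA on the coding strand yields the
stop codons TAA, TAG or TGA, and editing the G-complements of TGG on the
antisense strand yields TAG, TGA or (with both G's edited) TAA.  `stopcall`
covers the full computational workflow around such experiments:

1. guide design over whole gene models (`findGuides`), with bystander
   amino-acid prediction, a transparent efficiency heuristic and ranking;
2. mismatch-tolerant off-target search (`findOfftargets`);
3. editing-outcome quantification and clone-based genotyping from amplicon
   data (`quantifyEdits`, `classifyGenotype`, `aggregateGenotypes`);
4. a genome-wide off-target burden test on consensus de-novo variants
   (`consensusVariants`, `filterVariants`, `burdenTest`);
5. WGBS summaries: 1-kb tile methylation, min-max normalized sample
   similarity, element/promoter methylation and hypermethylated-element
   calls;
6. seeded simulators for every input, with known ground truth
   (`simulateToyGenome`, `simulateAmpliconReads`, `simulateCallsets`,
   `simulateMethylomes`).

Everything runs at desk scale on toy genomes; no external data or genome
index is required.

# Coordinate convention

All internal coordinates are 1-based and closed, the IRanges/GenomicRanges
convention, so GFF3 input needs no conversion and every interval operation
goes through `IRanges`.  BED input/output converts at the boundary
(`readElementsBED`, `writeGuidesBED`).  Protospacer window positions are
counted from the PAM-distal (5') end of the protospacer, position 1 being
the 5'-most base.

# Guide design

`enumerateStopCodons` scans the spliced CDS for CAA/CAG/CGA/TGG strictly
between the start codon and the native stop.  For TGG all three antisense
conversions are emitted (TAG and TGA by a single edit, TAA by the canonical
double edit) and flagged via `canonical`; users who want only the
one-codon-one-stop mapping can filter on it or pass `canonicalOnly = TRUE`.

`findGuides` reports every genomic placement where a PAM matches one of the
profile's IUPAC patterns immediately 3' of the protospacer on the rule's
strand and *all* edited bases fall inside the editing window.  Two
consequences worth noting:

* Codons spanning exon junctions are eligible.  Eligibility requires only
  that the edited bases are exonic; the protospacer itself is genomic DNA
  and may run into an intron.
* Candidates whose stop codon lands in the final 5% of the CDS are flagged
  `lateTruncation` rather than removed, since such truncations often fail
  to inactivate the protein.

Editing windows and PAMs are configuration, not inference: the shipped
profiles (`editorProfile`) use the canonical BE3-family window 4-8 of a
20-nt protospacer with NGG, a slightly widened window 3-8 for the hA3A
deaminases, and NG for xCas9.  N bases are tolerated in genomes but any
protospacer containing N is skipped with a warning.

When a gene has several transcripts the designer defaults to the one with
the longest CDS (`selectDesignTranscripts`), with a flag for per-transcript
design; annotation sources rarely agree on a canonical isoform, and the
longest CDS maximizes the editable codon space.

## Efficiency heuristic

Published editing-efficiency models are not available in a re-implementable
form, so `scoreGuide` is a deliberately transparent, versioned heuristic
rather than a learned model: the product over required edited positions of
a triangular position weight `1 - |p - c|/(h + 1)` (centre `c`, half-span
`h` of the window; 1.0 at the centre) and a 5'-dinucleotide context weight
(TC 1.0, CC 0.9, AC 0.8, GC 0.5 — the well-known APOBEC preference
ordering), times a multi-edit penalty `0.8^(k-1)`.  The score only ranks
candidates; it is not a calibrated probability.  `rankGuides` sorts by
fewest predicted off-targets at up to 2 mismatches first, then score, then
earlier truncation, then coordinate, with a stable tie-break.

# Off-target search

`findOfftargets` is a sliding-window Hamming scan of both strands with an
exact IUPAC PAM gate, mirroring the common local-search practice: mismatches
in the PAM are not permitted, bulges are not modelled, and windows containing
N are skipped.  The default ceiling of 3 mismatches is configurable.  On the
toy genomes this package targets, a linear scan is faster than building an
index and — more importantly — is simple enough to verify against an
independent brute-force oracle, which the test suite does exhaustively on a
100-kb genome.

# Amplicon quantification

Reads are aligned globally to the amplicon reference with affine gaps
(match +2, mismatch -3, gap open -6, gap extend -1 per position).  With
this scoring a mismatch always beats an insertion-deletion pair, so
equal-score alignments differ only in indel placement; `alignRead`
left-shifts every gap run to make the reported alignment deterministic.
Inside `quantifyEdits`, equal-length reads within a small Hamming distance
of the reference (default 8) take a gapless fast path, which is
score-optimal for such local variants; everything else is fully aligned in
one vectorized pass.  Insertion anchors follow the aligner's placement;
with the default 5-nt window padding this affects at most boundary cases.

The three reported metrics follow the usual definitions for
amplicon-sequencing figures:

* **conversion** — per target position, the fraction of non-indel reads
  carrying T;
* **indel rate** — the fraction of *all* reads with an insertion or
  deletion overlapping the quantification window (protospacer padded by 5
  nt); indels elsewhere in the amplicon are ignored as PCR/sequencing
  artifacts;
* **adjacent-site mutation** — the fraction of non-indel reads with at
  least one unintended substitution at a non-target window position.
  "Adjacent site mutation" is used in the field without a formula; this
  operationalization (any unintended window substitution on a non-indel
  read) is the package's declared definition, with the padding exposed as
  configuration.

Reads are assumed pre-merged; indel reads are excluded from the conversion
and adjacent-site denominators, and the four read classes (intended-only,
adjacent-mutated, indel, unedited) partition the read set exactly.

## Genotyping

Blunt-cloned allele sequences are called per clone: `intended_stop` (all
target positions T, nothing else changed in the window), `wildtype`
(window identical to reference) or `other`.  The embryo label is
`homozygous_stop` only when *every* clone is intended; `wildtype` when all
are wildtype; `heterozygous` when exactly two classes are present and each
holds at least 25% of clones; `mosaic` otherwise.  The all-clones rule and
the 0.25 fraction are the package's operationalization of Sanger/blunting
practice and are exposed as configuration; the 13-clone minimum reflects
the sequencing depth the thresholds were designed for, and fewer clones
produce a low-confidence flag rather than an error.  Multi-locus
experiments count an embryo as homozygous only when homozygous at every
locus, and `aggregateGenotypes` rounds the percentage half-up to one
decimal, the convention used for printed rates.

# Off-target burden (GOIT-style)

De-novo variants are trusted only when all three callers agree
(`consensusVariants`; SNVs and indels intersected separately on contig,
position, ref and alt after left-normalizing the indel representation —
callers disagree on padding more often than on events).  Filtering keeps
variants with allele frequency strictly above 10% and drops anything in the
supplied known-variant lists (dbSNP/MGP-style exclusion).

`burdenTest` classifies each variant by overlap with transcript spans
("transcribed region" is read as the transcript span, configurable by
supplying any interval set), then simulates the same number of loci
uniformly over the non-N genome positions, without replacement within a
simulation, 10,000 times by default.  Significance is a two-sided Fisher's
exact test of the observed transcribed/untranscribed counts against the
*pooled* simulated counts (all `nSim * n` simulated loci).  An earlier
design compared against the simulation mean collapsed to `n` loci; that
construction treats a quantity known almost exactly as one more n-sized
sample, doubles the null variance, and measurably breaks calibration (a
~0.25% null rejection rate at the 5% level in 400-replicate experiments,
versus ~3.8% for the pooled form), so the pooled construction is used.
The test is seeded and fully reproducible.

`overlapPredicted` intersects the consensus variants with predicted
off-target protospacer intervals (optionally padded), the comparison used
to ask whether observed de-novo variants coincide with sequence-predicted
sites.

# WGBS summaries

Per-CpG levels are `methylated / (methylated + unmethylated)` and are used
only at 3X coverage or more.  Tiles are the fixed 1-kb grid; a tile or
element needs at least 3 usable CpGs for a defined level, and levels are
unweighted means of per-CpG levels (the "mean methylation level" convention;
read-count weighting would let a single deep CpG dominate an element).

Sample similarity is `1 - (d - d_min)/(d_max - d_min)` over the
off-diagonal pairwise Euclidean distances of tile-level vectors (tiles
undefined in any sample dropped listwise), so the closest pair scores 1,
the most distant pair scores exactly 0, and the diagonal is fixed at 1.
When every pairwise distance is equal the normalization is degenerate and
all similarities are defined as 1, with a warning.

Promoters are TSS ± 2 kb, strand-aware.  Hypermethylated elements require
a group-mean difference strictly greater than 0.30 *and* a raw Welch
t-test p-value strictly below 0.05; the difference is the difference of
replicate means (not of pooled counts).  A Benjamini-Hochberg column is
reported alongside, but the raw p is the calling criterion — the procedure
this mirrors applies no multiplicity correction, and the BH column lets
users apply one.  Degenerate elements (zero variance in both groups) get
p = 1 for equal means and p = 0 otherwise; elements with fewer than two
defined replicates per group are skipped with a warning.

# Simulators

Each generator draws from an RNG stream keyed on `(seed, generator name)`,
so adding a generator never shifts another's output and identical seeds are
byte-reproducible across sessions.

* `simulateToyGenome` builds one contig per gene: a stop-free CDS with
  CAA/CAG/CGA codons planted at spaced positions, split across 1-3 exons,
  with an NGG PAM engineered 16-17 nt 3' of each planted C so the C sits at
  protospacer position 6 — the centre of the BE3 window — guaranteeing
  recoverability; about half the genes are mirrored onto the minus strand.
  Plants are sense-strand only; TGG/antisense candidates still arise by
  chance and are checked against the brute-force oracle.  Default sizes
  (60-120 codons, 150-nt flanks, 60-150-nt introns) keep a gene cassette
  around 0.5-1.5 kb, which is large enough to contain realistic placement
  ambiguity and small enough for exhaustive oracle comparison.
* `simulateAmpliconReads` applies, per read: a 1-10-nt indel inside the
  protospacer with probability `indelRate`; otherwise the intended edit
  with probability `convRate` and one extra window substitution with
  probability `adjRate`; then uniform per-base sequencing errors.  Truth is
  recorded with conversion/adjacent counted over non-indel reads, matching
  the quantifier's denominators.
* `simulateCallsets` plants true variants in all three caller tables with
  per-caller allele-frequency jitter and adds caller-private false
  positives.  True variants are never dropped — consensus recovery is the
  property under test, and dropout would make it vacuous.
* `simulateMethylomes` draws per-replicate element levels (group mean +
  Normal noise), per-CpG levels around them, and binomial methylated counts
  at coverages drawn uniformly above the 3X floor.  The default planted
  difference of 0.45 with replicate noise 0.05 and 3 replicates per group
  emulates a strong, clean group contrast.

What the simulators do *not* emulate: sequencer-specific error profiles,
PCR duplicates, bisulfite non-conversion, mapping artifacts, and caller
error correlation.  Tests passing on these simulations therefore
demonstrate the correctness of the implemented statistics and algorithms on
inputs that satisfy their assumptions, not robustness of upstream wet-lab
or alignment pipelines.

# Verification scale

The test suite verifies designer exhaustiveness against a brute-force
oracle over 200 simulated genes, off-target equivalence on a 100-kb genome
for 20 guides at up to 3 mismatches, amplicon-rate recovery over 100 seeds
of 5,000 reads at true rates (0.30, 0.10, 0.05), burden-test calibration
over 100 replicates of 500 simulations, and hypermethylation recovery over
300 elements; the rate-recovery check counts each of the 300 estimates
against its 3-standard-error band.  `scripts/acceptance.R` recomputes the
same quantities at moderately reduced replicate counts, sized so a full run
completes in about a minute on one core.

# Known limitations

* No bulge (DNA/RNA) modelling and no CFD/MIT specificity scores in the
  off-target search.
* The efficiency score is an uncalibrated ranking heuristic.
* ABE (A-to-G) design, splice-site disruption design and chromatogram
  deconvolution are out of scope.
* Linear scans assume desk-scale genomes; whole-mammalian-genome use would
  need an indexed search.
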