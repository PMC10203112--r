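#' @import methods
#' @importFrom S4Vectors isSingleString
NULL

#' Transcript model: exon/CDS structure of one transcript on one contig
#'
#' Holds the genomic structure needed to assemble a spliced coding sequence:
#' ordered exon and CDS intervals (1-based, closed, genomic coordinates) plus
#' the strand.  CDS intervals must lie inside exon space and their total
#' length must be a multiple of 3; start/stop codon content is checked against
#' the genome by [splicedCDS()] (strict mode).
#'
#' @slot transcriptId single transcript identifier
#' @slot geneId gene the transcript belongs to
#' @slot contig name of the contig the transcript lies on
#' @slot strand `"+"` or `"-"`
#' @slot exons [IRanges::IRanges] of exon intervals, sorted, non-overlapping
#' @slot cds [IRanges::IRanges] of CDS intervals, sorted, non-overlapping,
#'   each contained in some exon
#'
#' @seealso [TranscriptModel()], [readGFF3()], [splicedCDS()]
#' @exportClass TranscriptModel
setClass("TranscriptModel",
  representation(
    transcriptId = "character",
    geneId       = "character",
    contig       = "character",
    strand       = "character",
    exons        = "IRanges",
    cds          = "IRanges"
  )
)

.validIntervalList <- function(x, what) {
  if (length(x) == 0L) return(sprintf("%s intervals must be non-empty", what))
  if (any(IRanges::width(x) < 1L)) return(sprintf("%s contains an empty interval", what))
  if (is.unsorted(IRanges::start(x))) return(sprintf("%s intervals not sorted by start", what))
  if (length(x) > 1L &&
      any(IRanges::start(x)[-1L] <= IRanges::end(x)[-length(x)]))
    return(sprintf("%s intervals overlap", what))
  NULL
}

setValidity("TranscriptModel", function(object) {
  msgs <- character()
  for (s in c("transcriptId", "geneId", "contig")) {
    v <- slot(object, s)
    if (!isSingleString(v) || !nzchar(v)) msgs <- c(msgs, sprintf("%s must be a non-empty string", s))
  }
  if (!identical(object@strand, "+") && !identical(object@strand, "-"))
    msgs <- c(msgs, "strand must be '+' or '-'")
  m <- .validIntervalList(object@exons, "exons"); if (!is.null(m)) msgs <- c(msgs, m)
  m <- .validIntervalList(object@cds, "cds");     if (!is.null(m)) msgs <- c(msgs, m)
  if (length(msgs) == 0L) {
    ov <- IRanges::findOverlaps(object@cds, object@exons, type = "within")
    if (length(unique(S4Vectors::queryHits(ov))) != length(object@cds))
      msgs <- c(msgs, "every CDS interval must lie within an exon")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a TranscriptModel
#'
#' @param transcriptId,geneId,contig,strand see the class slots
#' @param exons,cds `IRanges` or a 2-column matrix/data.frame of
#'   (start, end), 1-based closed genomic coordinates
#' @param permissive logical; if `FALSE` (default) a CDS whose total length is
#'   not a multiple of 3 is an error, otherwise a warning
#' @return a validated [TranscriptModel-class] object
#' @examples
#' t <- TranscriptModel("t1", "g1", "chr1", "+",
#'                      exons = cbind(1, 9), cds = cbind(1, 9))
#' cdsWidth(t)
#' @export
TranscriptModel <- function(transcriptId, geneId, contig, strand,
                            exons, cds, permissive = FALSE) {
  asIR <- function(x) {
    if (is(x, "IRanges")) return(x)
    x <- as.matrix(x)
    IRanges::IRanges(start = as.integer(x[, 1L]), end = as.integer(x[, 2L]))
  }
  obj <- new("TranscriptModel",
             transcriptId = transcriptId, geneId = geneId,
             contig = contig, strand = strand,
             exons = asIR(exons), cds = asIR(cds))
  w <- sum(IRanges::width(obj@cds))
  if (w %% 3L != 0L) {
    msg <- sprintf("CDS length %d of transcript '%s' is not a multiple of 3",
                   w, transcriptId)
    if (permissive) warning(msg) else stop(msg)
  }
  obj
}

#' Spliced coding sequence with a bidirectional genomic coordinate map
#'
#' The CDS in sense orientation together with, for every CDS base, the contig,
#' genomic position and strand it came from.  The map is a bijection: CDS
#' index i maps to `coordMap` row i, and [genomicToCds()] inverts it.  For
#' minus-strand transcripts genomic positions decrease along the CDS.
#'
#' @slot seq [Biostrings::DNAString] spliced CDS, sense orientation
#' @slot coordMap data.frame with columns `contig`, `pos`, `strand`, one row
#'   per CDS base
#' @slot transcriptId,geneId provenance
#' @seealso [splicedCDS()], [cdsToGenomic()], [genomicToCds()]
#' @exportClass CodingSequence
setClass("CodingSequence",
  representation(
    seq          = "DNAString",
    coordMap     = "data.frame",
    transcriptId = "character",
    geneId       = "character"
  )
)

setValidity("CodingSequence", function(object) {
  msgs <- character()
  if (length(object@seq) != nrow(object@coordMap))
    msgs <- c(msgs, "length(seq) must equal nrow(coordMap)")
  if (!all(c("contig", "pos", "strand") %in% colnames(object@coordMap)))
    msgs <- c(msgs, "coordMap must have columns contig, pos, strand")
  else {
    key <- paste0(object@coordMap$contig, ":", object@coordMap$pos)
    if (anyDuplicated(key)) msgs <- c(msgs, "coordMap is not a bijection")
  }
  if (length(msgs)) msgs else TRUE
})

#' Base-editor profile: protospacer length, PAM patterns, editing window
#'
#' The editing window is given in protospacer coordinates counted from the
#' PAM-distal (5') end, position 1 = 5'-most base; the deaminase converts C to
#' T on the protospacer strand within `window[1]..window[2]` (inclusive).
#'
#' @slot name profile name
#' @slot guideLength protospacer length in nt
#' @slot pamPatterns IUPAC patterns matched immediately 3' of the protospacer
#' @slot window integer vector `c(lo, hi)`, inclusive window bounds
#' @seealso [editorProfile()] for the shipped named profiles
#' @exportClass BaseEditorProfile
setClass("BaseEditorProfile",
  representation(
    name        = "character",
    guideLength = "integer",
    pamPatterns = "character",
    window      = "integer"
  )
)

setValidity("BaseEditorProfile", function(object) {
  msgs <- character()
  if (length(object@guideLength) != 1L || object@guideLength < 10L)
    msgs <- c(msgs, "guideLength must be a single integer >= 10")
  if (length(object@window) != 2L ||
      object@window[1L] < 1L || object@window[1L] > object@window[2L] ||
      object@window[2L] > object@guideLength)
    msgs <- c(msgs, "window must satisfy 1 <= lo <= hi <= guideLength")
  if (length(object@pamPatterns) == 0L)
    msgs <- c(msgs, "pamPatterns must be non-empty")
  else if (!all(grepl("^[ACGTRYSWKMBDHVN]+$", object@pamPatterns)))
    msgs <- c(msgs, "pamPatterns must use the IUPAC alphabet")
  if (length(msgs)) msgs else TRUE
})

#' Amplicon reference for editing-outcome quantification
#'
#' @slot seq [Biostrings::DNAString] amplicon reference, protospacer-strand
#'   orientation
#' @slot protospacer integer `c(start, end)` of the protospacer within the
#'   amplicon (1-based, closed)
#' @slot targetPositions amplicon coordinates of the intended edited C(s);
#'   the reference base at each must be `C`
#' @slot contig,offset optional genomic provenance (`NA` if unknown)
#' @seealso [AmpliconReference()], [quantifyEdits()], [classifyGenotype()]
#' @exportClass AmpliconReference
setClass("AmpliconReference",
  representation(
    seq             = "DNAString",
    protospacer     = "integer",
    targetPositions = "integer",
    contig          = "character",
    offset          = "integer"
  )
)

setValidity("AmpliconReference", function(object) {
  msgs <- character()
  n <- length(object@seq)
  p <- object@protospacer
  if (length(p) != 2L || p[1L] < 1L || p[2L] > n || p[1L] > p[2L])
    msgs <- c(msgs, "protospacer interval must lie inside the amplicon")
  tp <- object@targetPositions
  if (length(tp) == 0L) msgs <- c(msgs, "at least one target position required")
  else if (length(p) == 2L && (any(tp < p[1L]) || any(tp > p[2L])))
    msgs <- c(msgs, "target positions must lie inside the protospacer interval")
  else {
    bases <- strsplit(as.character(object@seq), "")[[1L]][tp]
    if (!all(bases == "C"))
      msgs <- c(msgs, "reference base at every target position must be 'C'")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an AmpliconReference
#'
#' @param seq amplicon reference sequence (character or `DNAString`),
#'   protospacer-strand orientation
#' @param protospacer `c(start, end)` of the protospacer, 1-based closed
#' @param targetPositions positions of the intended edited C(s)
#' @param contig,offset optional genomic provenance
#' @return an [AmpliconReference-class] object
#' @export
AmpliconReference <- function(seq, protospacer, targetPositions,
                              contig = NA_character_, offset = NA_integer_) {
  new("AmpliconReference",
      seq = as(Biostrings::DNAString(toupper(as.character(seq))), "DNAString"),
      protospacer = as.integer(protospacer),
      targetPositions = as.integer(targetPositions),
      contig = contig, offset = as.integer(offset))
}

#' Editing outcome of one amplicon sample
#'
#' Per-sample metrics over a quantification window (protospacer padded by
#' `windowPad`): C-to-T conversion per target position (fraction of non-indel
#' reads), indel rate (fraction of all reads with an insertion or deletion
#' overlapping the window), and adjacent-site mutation rate (fraction of
#' non-indel reads with at least one unintended substitution at a non-target
#' window position).
#'
#' @slot nReads total reads
#' @slot conversionRate named numeric, one entry per target position
#' @slot indelRate,adjacentRate single rates in \[0,1\]
#' @slot classCounts integer counts of the read classes `intended_only`,
#'   `adjacent_mutated`, `indel`, `unedited` (a partition of the reads)
#' @slot perPosition base-count matrix (rows A/C/G/T/other, columns window
#'   positions) over non-indel reads
#' @slot window integer `c(start, end)` quantification window in amplicon
#'   coordinates
#' @seealso [quantifyEdits()]
#' @exportClass EditOutcome
setClass("EditOutcome",
  representation(
    nReads         = "integer",
    conversionRate = "numeric",
    indelRate      = "numeric",
    adjacentRate   = "numeric",
    classCounts    = "integer",
    perPosition    = "matrix",
    window         = "integer"
  )
)

setValidity("EditOutcome", function(object) {
  msgs <- character()
  rates <- c(object@conversionRate, object@indelRate, object@adjacentRate)
  if (any(rates < 0 | rates > 1)) msgs <- c(msgs, "all rates must lie in [0,1]")
  if (sum(object@classCounts) != object@nReads)
    msgs <- c(msgs, "read classes must partition the read set")
  if (length(msgs)) msgs else TRUE
})

#' Clone-based genotype of one embryo
#'
#' @slot nClones number of sequenced clones
#' @slot calls character vector of per-clone calls (`intended_stop`,
#'   `wildtype`, `other`)
#' @slot label one of `homozygous_stop`, `heterozygous`, `mosaic`, `wildtype`
#' @slot lowConfidence `TRUE` when fewer than `minClones` clones were supplied
#' @seealso [classifyGenotype()], [aggregateGenotypes()]
#' @exportClass EmbryoGenotype
setClass("EmbryoGenotype",
  representation(
    nClones       = "integer",
    calls         = "character",
    label         = "character",
    lowConfidence = "logical"
  )
)

setValidity("EmbryoGenotype", function(object) {
  ok <- object@label %in% c("homozygous_stop", "heterozygous", "mosaic", "wildtype") &&
    all(object@calls %in% c("intended_stop", "wildtype", "other")) &&
    object@nClones == length(object@calls)
  if (ok) TRUE else "inconsistent genotype object"
})

#' Consensus de-novo variant set
#'
#' Variants called concordantly by all contributing callers (matched on
#' contig, position, ref, alt; SNVs and indels intersected separately).
#'
#' @slot variants data.frame with columns `contig`, `pos` (1-based), `ref`,
#'   `alt`, `af`, `type` (`SNV`/`indel`)
#' @slot provenance names of the contributing callers
#' @seealso [consensusVariants()], [filterVariants()], [burdenTest()]
#' @exportClass ConsensusVariantSet
setClass("ConsensusVariantSet",
  representation(variants = "data.frame", provenance = "character")
)

setValidity("ConsensusVariantSet", function(object) {
  need <- c("contig", "pos", "ref", "alt", "af", "type")
  msgs <- character()
  if (!all(need %in% colnames(object@variants)))
    msgs <- c(msgs, paste("variants must have columns", paste(need, collapse = ", ")))
  else {
    v <- object@variants
    if (nrow(v)) {
      if (any(v$ref == v$alt)) msgs <- c(msgs, "ref must differ from alt")
      if (any(v$af < 0 | v$af > 1)) msgs <- c(msgs, "allele frequencies must lie in [0,1]")
      if (!all(v$type %in% c("SNV", "indel"))) msgs <- c(msgs, "type must be SNV or indel")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Result of the transcribed-region variant-burden test
#'
#' @slot nVariants,nTranscribed observed counts
#' @slot observedProportion `nTranscribed / nVariants`
#' @slot expectedProportions per-simulation transcribed proportions of
#'   random loci (length `nSim`)
#' @slot fisherP two-sided Fisher's exact p-value of observed vs expected
#'   counts at equal n
#' @slot seed RNG seed used for the simulations
#' @seealso [burdenTest()]
#' @exportClass BurdenTestResult
setClass("BurdenTestResult",
  representation(
    nVariants           = "integer",
    nTranscribed        = "integer",
    observedProportion  = "numeric",
    expectedProportions = "numeric",
    fisherP             = "numeric",
    seed                = "integer"
  )
)

setValidity("BurdenTestResult", function(object) {
  msgs <- character()
  if (object@nVariants < 1L) msgs <- c(msgs, "nVariants must be positive")
  if (abs(object@observedProportion -
          object@nTranscribed / object@nVariants) > 1e-12)
    msgs <- c(msgs, "observedProportion must equal nTranscribed/nVariants")
  if (any(object@expectedProportions < 0 | object@expectedProportions > 1))
    msgs <- c(msgs, "expected proportions must lie in [0,1]")
  if (object@fisherP <= 0 || object@fisherP > 1)
    msgs <- c(msgs, "fisherP must lie in (0,1]")
  if (length(msgs)) msgs else TRUE
})
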