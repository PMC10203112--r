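#' @include AllClasses.R
NULL

#' Accessors for stopcall classes
#'
#' Small read-only accessors so user code never touches slots directly.
#'
#' @param x an object of the documented class
#' @return the corresponding slot value
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("transcriptId", function(x) standardGeneric("transcriptId"))
#' @rdname accessors
#' @export
setMethod("transcriptId", "TranscriptModel", function(x) x@transcriptId)
#' @rdname accessors
#' @export
setMethod("transcriptId", "CodingSequence", function(x) x@transcriptId)

#' @rdname accessors
#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))
#' @rdname accessors
#' @export
setMethod("geneId", "TranscriptModel", function(x) x@geneId)
#' @rdname accessors
#' @export
setMethod("geneId", "CodingSequence", function(x) x@geneId)

#' @rdname accessors
#' @export
setGeneric("contigName", function(x) standardGeneric("contigName"))
#' @rdname accessors
#' @export
setMethod("contigName", "TranscriptModel", function(x) x@contig)

#' @rdname accessors
#' @export
setGeneric("transcriptStrand", function(x) standardGeneric("transcriptStrand"))
#' @rdname accessors
#' @export
setMethod("transcriptStrand", "TranscriptModel", function(x) x@strand)

#' @rdname accessors
#' @export
setGeneric("exonRanges", function(x) standardGeneric("exonRanges"))
#' @rdname accessors
#' @export
setMethod("exonRanges", "TranscriptModel", function(x) x@exons)

#' @rdname accessors
#' @export
setGeneric("cdsRanges", function(x) standardGeneric("cdsRanges"))
#' @rdname accessors
#' @export
setMethod("cdsRanges", "TranscriptModel", function(x) x@cds)

#' @rdname accessors
#' @export
setGeneric("cdsWidth", function(x) standardGeneric("cdsWidth"))
#' @rdname accessors
#' @export
setMethod("cdsWidth", "TranscriptModel", function(x) sum(IRanges::width(x@cds)))

#' @rdname accessors
#' @export
setGeneric("cdsSeq", function(x) standardGeneric("cdsSeq"))
#' @rdname accessors
#' @export
setMethod("cdsSeq", "CodingSequence", function(x) x@seq)

#' @rdname accessors
#' @export
setGeneric("coordMap", function(x) standardGeneric("coordMap"))
#' @rdname accessors
#' @export
setMethod("coordMap", "CodingSequence", function(x) x@coordMap)

#' @rdname accessors
#' @export
setGeneric("guideLength", function(x) standardGeneric("guideLength"))
#' @rdname accessors
#' @export
setMethod("guideLength", "BaseEditorProfile", function(x) x@guideLength)

#' @rdname accessors
#' @export
setGeneric("pamPatterns", function(x) standardGeneric("pamPatterns"))
#' @rdname accessors
#' @export
setMethod("pamPatterns", "BaseEditorProfile", function(x) x@pamPatterns)

#' @rdname accessors
#' @export
setGeneric("editWindow", function(x) standardGeneric("editWindow"))
#' @rdname accessors
#' @export
setMethod("editWindow", "BaseEditorProfile", function(x) x@window)

#' @rdname accessors
#' @export
setGeneric("ampliconSeq", function(x) standardGeneric("ampliconSeq"))
#' @rdname accessors
#' @export
setMethod("ampliconSeq", "AmpliconReference", function(x) x@seq)

#' @rdname accessors
#' @export
setGeneric("protospacerRange", function(x) standardGeneric("protospacerRange"))
#' @rdname accessors
#' @export
setMethod("protospacerRange", "AmpliconReference", function(x) x@protospacer)

#' @rdname accessors
#' @export
setGeneric("targetPositions", function(x) standardGeneric("targetPositions"))
#' @rdname accessors
#' @export
setMethod("targetPositions", "AmpliconReference", function(x) x@targetPositions)

#' @rdname accessors
#' @export
setGeneric("conversionRate", function(x) standardGeneric("conversionRate"))
#' @rdname accessors
#' @export
setMethod("conversionRate", "EditOutcome", function(x) x@conversionRate)

#' @rdname accessors
#' @export
setGeneric("indelRate", function(x) standardGeneric("indelRate"))
#' @rdname accessors
#' @export
setMethod("indelRate", "EditOutcome", function(x) x@indelRate)

#' @rdname accessors
#' @export
setGeneric("adjacentRate", function(x) standardGeneric("adjacentRate"))
#' @rdname accessors
#' @export
setMethod("adjacentRate", "EditOutcome", function(x) x@adjacentRate)

#' @rdname accessors
#' @export
setGeneric("classCounts", function(x) standardGeneric("classCounts"))
#' @rdname accessors
#' @export
setMethod("classCounts", "EditOutcome", function(x) x@classCounts)

#' @rdname accessors
#' @export
setGeneric("perPositionCounts", function(x) standardGeneric("perPositionCounts"))
#' @rdname accessors
#' @export
setMethod("perPositionCounts", "EditOutcome", function(x) x@perPosition)

#' @rdname accessors
#' @export
setGeneric("genotypeLabel", function(x) standardGeneric("genotypeLabel"))
#' @rdname accessors
#' @export
setMethod("genotypeLabel", "EmbryoGenotype", function(x) x@label)

#' @rdname accessors
#' @export
setGeneric("cloneCalls", function(x) standardGeneric("cloneCalls"))
#' @rdname accessors
#' @export
setMethod("cloneCalls", "EmbryoGenotype", function(x) x@calls)

#' @rdname accessors
#' @export
setGeneric("variantTable", function(x) standardGeneric("variantTable"))
#' @rdname accessors
#' @export
setMethod("variantTable", "ConsensusVariantSet", function(x) x@variants)

#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setMethod("provenance", "ConsensusVariantSet", function(x) x@provenance)

#' @rdname accessors
#' @export
setGeneric("observedProportion", function(x) standardGeneric("observedProportion"))
#' @rdname accessors
#' @export
setMethod("observedProportion", "BurdenTestResult", function(x) x@observedProportion)

#' @rdname accessors
#' @export
setGeneric("expectedProportions", function(x) standardGeneric("expectedProportions"))
#' @rdname accessors
#' @export
setMethod("expectedProportions", "BurdenTestResult", function(x) x@expectedProportions)

#' @rdname accessors
#' @export
setGeneric("fisherP", function(x) standardGeneric("fisherP"))
#' @rdname accessors
#' @export
setMethod("fisherP", "BurdenTestResult", function(x) x@fisherP)

setMethod("show", "TranscriptModel", function(object) {
  cat(sprintf("TranscriptModel %s (gene %s) %s%s  exons: %d  CDS: %d nt\n",
              object@transcriptId, object@geneId, object@contig,
              object@strand, length(object@exons),
              sum(IRanges::width(object@cds))))
})

setMethod("show", "CodingSequence", function(object) {
  cat(sprintf("CodingSequence %s: %d nt (%d codons)\n",
              object@transcriptId, length(object@seq),
              length(object@seq) %/% 3L))
})

setMethod("show", "BaseEditorProfile", function(object) {
  cat(sprintf("BaseEditorProfile %s: %d-nt protospacer, PAM %s, window [%d,%d]\n",
              object@name, object@guideLength,
              paste(object@pamPatterns, collapse = "/"),
              object@window[1L], object@window[2L]))
})

setMethod("show", "AmpliconReference", function(object) {
  cat(sprintf("AmpliconReference: %d nt, protospacer [%d,%d], targets %s\n",
              length(object@seq), object@protospacer[1L], object@protospacer[2L],
              paste(object@targetPositions, collapse = ",")))
})

setMethod("show", "EditOutcome", function(object) {
  cat(sprintf("EditOutcome: %d reads\n", object@nReads))
  cat(sprintf("  conversion: %s\n",
              paste(sprintf("pos %s %.3f", names(object@conversionRate),
                            object@conversionRate), collapse = ", ")))
  cat(sprintf("  indel: %.3f  adjacent: %.3f\n",
              object@indelRate, object@adjacentRate))
})

setMethod("show", "EmbryoGenotype", function(object) {
  cat(sprintf("EmbryoGenotype: %s (%d clones%s)\n", object@label,
              object@nClones,
              if (object@lowConfidence) ", low confidence" else ""))
})

setMethod("show", "ConsensusVariantSet", function(object) {
  cat(sprintf("ConsensusVariantSet: %d variants (%d SNV, %d indel) from %s\n",
              nrow(object@variants), sum(object@variants$type == "SNV"),
              sum(object@variants$type == "indel"),
              paste(object@provenance, collapse = " + ")))
})

setMethod("show", "BurdenTestResult", function(object) {
  cat(sprintf(
    "BurdenTestResult: %d/%d variants transcribed (%.3f), expected %.3f over %d simulations, Fisher p = %.4g\n",
    object@nTranscribed, object@nVariants, object@observedProportion,
    mean(object@expectedProportions), length(object@expectedProportions),
    object@fisherP))
})
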