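#' @include AllClasses.R
NULL

# left-shift every gap run in x (against partner y) while the alignment score
# is preserved: a gap run [a,b] in x may move one column left when the
# partner base entering the run equals the partner base leaving it
.leftShiftGaps <- function(x, y) {
  runs <- rle(x == "-")
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (r in which(runs$values)) {
    a <- starts[r]; b <- ends[r]
    while (a > 1L && x[a - 1L] != "-" && y[a - 1L] == y[b]) {
      x[b] <- x[a - 1L]
      x[a - 1L] <- "-"
      a <- a - 1L; b <- b - 1L
    }
  }
  x
}

# vectorized global alignment of many reads against one reference with the
# package scoring, gap runs left-shifted per read
.alignBatch <- function(reads, refStr) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = FALSE)
  al <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(reads), subject = refStr,
    type = "global", substitutionMatrix = mat,
    gapOpening = 6, gapExtension = 1)
  ap <- as.character(Biostrings::alignedPattern(al))
  as <- as.character(Biostrings::alignedSubject(al))
  out <- list(alignedRead = character(length(reads)),
              alignedRef = character(length(reads)),
              score = Biostrings::score(al))
  for (i in seq_along(reads)) {
    p <- strsplit(ap[i], "")[[1L]]
    s <- strsplit(as[i], "")[[1L]]
    p2 <- .leftShiftGaps(p, s)
    s2 <- .leftShiftGaps(s, p2)
    out$alignedRead[i] <- paste(p2, collapse = "")
    out$alignedRef[i] <- paste(s2, collapse = "")
  }
  out
}

#' Globally align one read against an amplicon reference
#'
#' Needleman-Wunsch global alignment with affine gaps (match +2, mismatch -3,
#' gap open -6, gap extend -1 per gapped position) computed by
#' [Biostrings::pairwiseAlignment()], followed by deterministic indel
#' normalization: every gap run is shifted as far left as possible without
#' changing the score.  With this scoring mismatches are always preferred
#' over gap pairs, so equivalent-score alignments differ only in indel
#' placement, which the left shift fixes.
#'
#' @param read read sequence (character or `DNAString`)
#' @param ref an [AmpliconReference-class]
#' @return list with `alignedRead` and `alignedRef` (gapped strings of equal
#'   length) and `score`
#' @export
alignRead <- function(read, ref) {
  read <- toupper(as.character(read))
  refStr <- as.character(ref@seq)
  if (!nzchar(read) || !nzchar(refStr)) stop("read and reference must be non-empty")
  b <- .alignBatch(read, refStr)
  list(alignedRead = b$alignedRead[1L], alignedRef = b$alignedRef[1L],
       score = b$score[1L])
}

# per-read window analysis from a gapped alignment: does any indel overlap
# the window, and which window reference positions carry substitutions?
.analyseAlignment <- function(alignedRead, alignedRef, wStart, wEnd) {
  p <- strsplit(alignedRead, "")[[1L]]
  s <- strsplit(alignedRef, "")[[1L]]
  refPos <- cumsum(s != "-")
  delHit <- any(p == "-" & s != "-" & refPos >= wStart & refPos <= wEnd)
  insHit <- any(s == "-" & refPos >= wStart - 1L & refPos <= wEnd)
  subCols <- which(p != "-" & s != "-" & p != s &
                   refPos >= wStart & refPos <= wEnd)
  baseAt <- rep(NA_character_, wEnd - wStart + 1L)
  cols <- which(s != "-" & refPos >= wStart & refPos <= wEnd)
  baseAt[refPos[cols] - wStart + 1L] <- p[cols]  # '-' where deleted
  list(indel = delHit || insHit,
       subPositions = refPos[subCols],
       windowBases = baseAt)
}

#' Quantify base-editing outcomes from amplicon reads
#'
#' Computes the three per-sample metrics over the quantification window (the
#' protospacer padded by `windowPad` nt on each side): C-to-T conversion per
#' target position (fraction of non-indel reads carrying T), indel rate
#' (fraction of all reads with an insertion or deletion overlapping the
#' window; indels elsewhere in the amplicon are ignored as PCR/sequencing
#' artifacts), and adjacent-site mutation rate (fraction of non-indel reads
#' with at least one unintended substitution at a non-target window
#' position).  Indel reads are excluded from the conversion and
#' adjacent-site denominators.
#'
#' Equal-length reads within `fastHammingMax` substitutions of the reference
#' take a gapless fast path (gapless alignment is score-optimal for such
#' local variants under the scoring of [alignRead()]); all other reads are
#' fully aligned.
#'
#' @param reads character vector or `DNAStringSet` of (pre-merged) reads
#' @param ref an [AmpliconReference-class]
#' @param windowPad padding of the protospacer interval, nt (default 5)
#' @param fastHammingMax fast-path threshold (default 8)
#' @return an [EditOutcome-class]
#' @seealso [simulateAmpliconReads()] for matched synthetic reads
#' @export
quantifyEdits <- function(reads, ref, windowPad = 5L, fastHammingMax = 8L) {
  reads <- toupper(as.character(reads))
  if (length(reads) == 0L) stop("no reads supplied")
  refStr <- as.character(ref@seq)
  n <- nchar(refStr)
  wStart <- max(1L, ref@protospacer[1L] - windowPad)
  wEnd <- min(n, ref@protospacer[2L] + windowPad)
  targets <- ref@targetPositions
  refChars <- strsplit(refStr, "")[[1L]]
  wIdx <- wStart:wEnd

  nR <- length(reads)
  isIndel <- logical(nR)
  windowBases <- matrix(NA_character_, nrow = nR, ncol = length(wIdx))
  hasAdj <- logical(nR)

  sameLen <- nchar(reads) == n
  fast <- logical(nR)
  if (any(sameLen)) {
    cand <- which(sameLen)
    rc <- strsplit(reads[cand], "")
    hd <- vapply(rc, function(ch) sum(ch != refChars), integer(1))
    ok <- hd <= fastHammingMax
    fast[cand[ok]] <- TRUE
    for (j in which(ok)) {
      i <- cand[j]
      windowBases[i, ] <- rc[[j]][wIdx]
    }
  }
  slow <- which(!fast)
  if (length(slow)) {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                    baseOnly = FALSE)
    als <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAStringSet(reads[slow]), subject = refStr,
      type = "global", substitutionMatrix = mat,
      gapOpening = 6, gapExtension = 1)
    # read projected onto reference coordinates: insertions dropped,
    # deletions as '-'; insertion anchors from the indel accessor
    alnStr <- as.character(Biostrings::aligned(als))
    insL <- Biostrings::insertion(Biostrings::indel(als))
    for (j in seq_along(slow)) {
      i <- slow[j]
      wb <- strsplit(alnStr[j], "")[[1L]][wIdx]
      ins <- insL[[j]]
      insHit <- any(IRanges::start(ins) >= wStart &
                    IRanges::start(ins) <= wEnd + 1L)
      isIndel[i] <- insHit || any(wb == "-")
      windowBases[i, ] <- wb
    }
  }
  nonIndel <- which(!isIndel)
  tIdx <- targets - wStart + 1L
  adjMask <- !(wIdx %in% targets)
  for (i in nonIndel) {
    wb <- windowBases[i, ]
    hasAdj[i] <- any(adjMask & !is.na(wb) & wb != "-" & wb != refChars[wIdx])
  }
  conv <- vapply(tIdx, function(j) {
    b <- windowBases[nonIndel, j]
    if (length(nonIndel) == 0L) return(NA_real_)
    mean(!is.na(b) & b == "T")
  }, numeric(1))
  names(conv) <- as.character(targets)

  intended <- rep(FALSE, nR)
  for (i in nonIndel)
    intended[i] <- all(windowBases[i, tIdx] == "T", na.rm = FALSE) &&
      !anyNA(windowBases[i, tIdx])
  classes <- ifelse(isIndel, "indel",
             ifelse(hasAdj, "adjacent_mutated",
             ifelse(intended, "intended_only", "unedited")))
  classCounts <- vapply(c("intended_only", "adjacent_mutated", "indel",
                          "unedited"),
                        function(cl) sum(classes == cl), integer(1))

  perPos <- matrix(0L, nrow = 5L, ncol = length(wIdx),
                   dimnames = list(c("A", "C", "G", "T", "other"),
                                   as.character(wIdx)))
  if (length(nonIndel)) {
    for (j in seq_along(wIdx)) {
      b <- windowBases[nonIndel, j]
      b[is.na(b)] <- "other"
      b[!b %in% c("A", "C", "G", "T")] <- "other"
      tb <- table(factor(b, levels = rownames(perPos)))
      perPos[, j] <- as.integer(tb)
    }
  }
  new("EditOutcome",
      nReads = nR,
      conversionRate = conv,
      indelRate = sum(isIndel) / nR,
      adjacentRate = if (length(nonIndel)) sum(hasAdj) / length(nonIndel) else 0,
      classCounts = classCounts,
      perPosition = perPos,
      window = c(wStart, wEnd))
}

#' Classify an embryo genotype from Sanger-sequenced clones
#'
#' Each subcloned allele sequence is called `intended_stop` (all target
#' positions converted to T and no other change inside the quantification
#' window), `wildtype` (window identical to the reference) or `other`
#' (indels, partial conversion, extra substitutions).  The embryo label is
#' `homozygous_stop` when every clone is intended, `wildtype` when every
#' clone is wildtype, `heterozygous` when exactly two call classes are
#' present and each holds at least `hetMinFrac` of the clones, and `mosaic`
#' otherwise.
#'
#' @param cloneSeqs character vector of clone sequences (one allele each)
#' @param ref an [AmpliconReference-class]
#' @param minClones minimum clones for a confident call (default 13, the
#'   sequencing practice the thresholds were designed for); fewer clones
#'   warn and set the low-confidence flag
#' @param hetMinFrac minimum class fraction for a heterozygous call
#'   (default 0.25)
#' @param windowPad window padding as in [quantifyEdits()]
#' @return an [EmbryoGenotype-class]
#' @export
classifyGenotype <- function(cloneSeqs, ref, minClones = 13L,
                             hetMinFrac = 0.25, windowPad = 5L) {
  cloneSeqs <- toupper(as.character(cloneSeqs))
  if (length(cloneSeqs) == 0L) stop("no clone sequences supplied")
  low <- length(cloneSeqs) < minClones
  if (low)
    warning("only ", length(cloneSeqs), " clones (minimum ", minClones,
            "); genotype flagged low-confidence")
  refStr <- as.character(ref@seq)
  n <- nchar(refStr)
  wStart <- max(1L, ref@protospacer[1L] - windowPad)
  wEnd <- min(n, ref@protospacer[2L] + windowPad)
  targets <- ref@targetPositions
  refChars <- strsplit(refStr, "")[[1L]]
  wIdx <- wStart:wEnd
  tIdx <- targets - wStart + 1L
  calls <- vapply(cloneSeqs, function(sq) {
    if (nchar(sq) == n) {
      wb <- strsplit(sq, "")[[1L]][wIdx]
      indel <- FALSE
    } else {
      al <- alignRead(sq, ref)
      an <- .analyseAlignment(al$alignedRead, al$alignedRef, wStart, wEnd)
      wb <- an$windowBases
      indel <- an$indel
    }
    if (indel || anyNA(wb) || any(wb == "-")) return("other")
    diffs <- which(wb != refChars[wIdx])
    if (length(diffs) == 0L) return("wildtype")
    if (setequal(diffs, tIdx) && all(wb[tIdx] == "T")) return("intended_stop")
    "other"
  }, character(1), USE.NAMES = FALSE)
  tab <- table(calls)
  label <- if (all(calls == "intended_stop")) "homozygous_stop"
    else if (all(calls == "wildtype")) "wildtype"
    else if (length(tab) == 2L && all(tab / length(calls) >= hetMinFrac))
      "heterozygous"
    else "mosaic"
  new("EmbryoGenotype", nClones = length(calls), calls = calls,
      label = label, lowConfidence = low)
}

# round half away from zero, the convention used for printed percentages
.roundHalfUp <- function(x, digits = 1L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Aggregate embryo genotypes into a homozygosity summary
#'
#' For a single locus, pass a list of [EmbryoGenotype-class] objects (or a
#' character vector of labels).  For multi-locus experiments, pass a matrix
#' of labels (rows = embryos, columns = loci): an embryo counts as
#' homozygous only when it is `homozygous_stop` at every locus.
#' `percentHomozygous` is rounded half-up to one decimal.
#'
#' @param genotypes see description
#' @return list with `nEmbryos`, `counts` (per label; per-embryo combined
#'   labels for the multi-locus case), `nHomozygous`, `percentHomozygous`
#' @examples
#' labels <- c(rep("homozygous_stop", 9), rep("mosaic", 7))
#' aggregateGenotypes(labels)$percentHomozygous  # 56.3
#' @export
aggregateGenotypes <- function(genotypes) {
  if (is.list(genotypes) && length(genotypes) &&
      is(genotypes[[1L]], "EmbryoGenotype"))
    genotypes <- vapply(genotypes, genotypeLabel, character(1))
  if (is.matrix(genotypes)) {
    labels <- apply(genotypes, 1L, function(r)
      if (all(r == "homozygous_stop")) "homozygous_stop" else "not_homozygous")
  } else {
    labels <- as.character(genotypes)
  }
  if (length(labels) == 0L) stop("no embryos supplied")
  nH <- sum(labels == "homozygous_stop")
  list(nEmbryos = length(labels),
       counts = table(labels),
       nHomozygous = nH,
       percentHomozygous = .roundHalfUp(100 * nH / length(labels), 1L))
}

#' Read amplicon reads or clone sequences
#'
#' FASTQ files (detected by a leading `@`) are read with Biostrings; plain
#' text files are read one sequence per line (Sanger clone lists).
#'
#' @param path input path
#' @return character vector of sequences
#' @export
readAmpliconReads <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) && startsWith(first, "@")) {
    as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
  } else {
    x <- readLines(path)
    toupper(x[nzchar(x)])
  }
}
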