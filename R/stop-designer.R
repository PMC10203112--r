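#' @include AllClasses.R editor-profiles.R
NULL

#' Codon-to-stop conversion rules for cytosine base editing
#'
#' The four editable sense codons and their stop conversions: CAA, CAG and
#' CGA are edited at codon position 1 on the sense strand (C-to-T), giving
#' TAA, TAG and TGA respectively; TGG is edited on the antisense strand
#' (G-to-A on the sense strand) at codon positions 2 and/or 3, giving TAG,
#' TGA, or the canonical double-edit TAA.  `canonical` marks the four
#' one-codon-one-stop mappings (CAA to TAA, CAG to TAG, CGA to TGA, TGG to
#' TAA); the single-edit TGG variants are chemically implied and can be
#' filtered on this flag.
#'
#' @return data.frame with columns `sourceCodon`, `editStrand`
#'   (`sense`/`antisense`), `codonPositions` (list column of 1-based
#'   positions within the codon), `resultCodon`, `canonical`
#' @export
stopConversionRules <- function() {
  df <- data.frame(
    sourceCodon = c("CAA", "CAG", "CGA", "TGG", "TGG", "TGG"),
    editStrand  = c("sense", "sense", "sense",
                    "antisense", "antisense", "antisense"),
    resultCodon = c("TAA", "TAG", "TGA", "TAG", "TGA", "TAA"),
    canonical   = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  df$codonPositions <- list(1L, 1L, 1L, 2L, 3L, c(2L, 3L))
  df
}

.applyRuleToCodon <- function(codon, editStrand, codonPositions) {
  b <- strsplit(codon, "")[[1L]]
  b[codonPositions] <- if (editStrand == "sense") "T" else "A"
  paste(b, collapse = "")
}

#' Enumerate CDS codons convertible to premature stop codons
#'
#' Scans the spliced CDS for CAA/CAG/CGA/TGG codons strictly between the
#' start codon and the native stop and pairs each with its conversion
#' rule(s).  Codons containing N are skipped with a warning.
#'
#' @param cds a [CodingSequence-class]
#' @param canonicalOnly if `TRUE`, drop the single-edit TGG variants
#' @return data.frame with columns `codonNumber` (1-based codon position in
#'   the CDS; the start codon is 1), `sourceCodon`, `editStrand`,
#'   `codonPositions` (list), `resultCodon`, `canonical`
#' @examples
#' g <- Biostrings::DNAStringSet(c(c1 = "ATGCAGAAATAA"))
#' t <- TranscriptModel("t1", "g1", "c1", "+", cbind(1, 12), cbind(1, 12))
#' enumerateStopCodons(splicedCDS(t, g))
#' @export
enumerateStopCodons <- function(cds, canonicalOnly = FALSE) {
  rules <- stopConversionRules()
  if (canonicalOnly) rules <- rules[rules$canonical, , drop = FALSE]
  seq <- as.character(cds@seq)
  nCodon <- nchar(seq) %/% 3L
  empty <- cbind(data.frame(codonNumber = integer()),
                 rules[0L, , drop = FALSE])
  if (nCodon < 2L) {
    warning("CDS of transcript '", cds@transcriptId,
            "' is shorter than 2 codons; no editable codons")
    return(empty)
  }
  if (nCodon < 3L) return(empty)  # only start + stop: nothing editable
  inner <- 2:(nCodon - 1L)
  codons <- substring(seq, (inner - 1L) * 3L + 1L, inner * 3L)
  hasN <- grepl("N", codons, fixed = TRUE)
  if (any(hasN))
    warning(sum(hasN), " codon(s) containing N skipped in transcript '",
            cds@transcriptId, "'")
  hit <- which(!hasN & codons %in% rules$sourceCodon)
  if (length(hit) == 0L) return(empty)
  out <- do.call(rbind, lapply(hit, function(i) {
    r <- rules[rules$sourceCodon == codons[i], , drop = FALSE]
    cbind(data.frame(codonNumber = rep(inner[i], nrow(r))), r)
  }))
  rownames(out) <- NULL
  out
}

#' Transparent efficiency heuristic for a guide candidate
#'
#' Deterministic, configuration-versioned score in \[0,1\]: the product over
#' the required edited positions of a triangular position weight (1.0 at the
#' window centre, decaying linearly towards and beyond the window edges) and
#' a dinucleotide-context weight for the base 5' of each edited C
#' (TC = 1.0, CC = 0.9, AC = 0.8, GC = 0.5), times a multi-edit penalty
#' `0.8^(k-1)` for k required edits.  An edited C at protospacer position 1
#' (no 5' neighbour inside the protospacer) receives the neutral context
#' weight 0.8.
#'
#' @param protospacer protospacer sequence (5' to 3')
#' @param requiredPositions protospacer positions (1-based from the 5' end)
#'   of the cytosines whose editing creates the stop codon
#' @param profile a [BaseEditorProfile-class]
#' @return numeric score in \[0,1\]
#' @examples
#' p <- editorProfile("BE3")  # window [4,8], centre 6
#' scoreGuide(paste(rep("A", 20), collapse = ""), 6, p)  # context 'AC' -> 0.8
#' @export
scoreGuide <- function(protospacer, requiredPositions, profile) {
  w <- profile@window
  centre <- (w[1L] + w[2L]) / 2
  halfspan <- (w[2L] - w[1L]) / 2
  posW <- pmax(0, 1 - abs(requiredPositions - centre) / (halfspan + 1))
  ctxW <- vapply(requiredPositions, function(p) {
    if (p <= 1L) return(0.8)
    switch(substr(protospacer, p - 1L, p - 1L),
           T = 1.0, C = 0.9, A = 0.8, G = 0.5, 0.8)
  }, numeric(1))
  k <- length(requiredPositions)
  unname(prod(posW * ctxW) * 0.8^(k - 1L))
}

# window index of genomic position p for a protospacer placed at genomic
# [s, s+L-1]: '+' counts from the left end, '-' from the right end
.windowIndex <- function(p, s, L, strand)
  if (strand == "+") p - s + 1L else (s + L - 1L) - p + 1L

#' Enumerate stop-introducing sgRNA candidates for a transcript
#'
#' For every editable codon and conversion rule, reports every genomic
#' protospacer placement such that (i) a PAM matching one of the profile's
#' patterns lies immediately 3' of a `guideLength` protospacer on the rule's
#' strand (sense rules place the protospacer on the coding strand, antisense
#' rules on the opposite strand), and (ii) all genomic positions of the
#' rule's edited bases fall inside the editing window.  The protospacer is
#' genomic DNA and may overlap intron sequence when the window spans an exon
#' junction; eligibility only requires the edited bases themselves to be
#' exonic (they are, by construction from the CDS).  Placements containing N
#' are skipped with a warning.  Candidates whose stop lands in the final 5%
#' of the CDS are flagged `lateTruncation` but kept.
#'
#' @param transcript a [TranscriptModel-class]
#' @param genome `DNAStringSet` from [readGenome()]
#' @param profile a [BaseEditorProfile-class]
#' @param canonicalOnly drop single-edit TGG variants (default `FALSE`)
#' @param permissive passed to [splicedCDS()]
#' @param bystanders compute per-candidate bystander predictions (default
#'   `TRUE`)
#' @return data.frame, one row per candidate: placement (`contig`, `start`,
#'   `end`, `strand`), `protospacer`, `pam`, rule fields, `codonNumber`,
#'   `requiredPositions` (list column of window positions),
#'   `truncationFraction`, `lateTruncation`, `efficiencyScore`, and (when
#'   requested) a `bystanders` list column of data.frames
#' @seealso [rankGuides()], [findOfftargets()], [applyGuideEdits()]
#' @export
findGuides <- function(transcript, genome, profile = editorProfile("BE3"),
                       canonicalOnly = FALSE, permissive = FALSE,
                       bystanders = TRUE) {
  cs <- splicedCDS(transcript, genome, permissive = permissive)
  enum <- enumerateStopCodons(cs, canonicalOnly = canonicalOnly)
  L <- profile@guideLength
  lo <- profile@window[1L]; hi <- profile@window[2L]
  ts <- transcript@strand
  nCodon <- length(cs@seq) %/% 3L
  rows <- list()
  nSkipped <- 0L
  for (k in seq_len(nrow(enum))) {
    e <- enum[k, ]
    cdsIdx <- (e$codonNumber - 1L) * 3L + e$codonPositions[[1L]]
    gm <- cdsToGenomic(cs, cdsIdx)
    P <- gm$pos
    protoStrand <- if (e$editStrand == "sense") ts else setdiff(c("+", "-"), ts)
    if (protoStrand == "+") {
      starts <- seq.int(max(P) - hi + 1L, min(P) - lo + 1L)
    } else {
      ends <- seq.int(max(P) + lo - 1L, min(P) + hi - 1L)
      starts <- ends - L + 1L
    }
    for (s in starts) {
      if (protoStrand == "+") {
        wIdx <- P - s + 1L
      } else {
        wIdx <- (s + L - 1L) - P + 1L
      }
      if (any(wIdx < lo | wIdx > hi)) next
      protoRaw <- .contigSub(genome, transcript@contig, s, s + L - 1L)
      if (is.na(protoRaw)) next
      proto <- if (protoStrand == "+") protoRaw else .revcomp(protoRaw)
      if (grepl("N", proto, fixed = TRUE)) { nSkipped <- nSkipped + 1L; next }
      protoB <- strsplit(proto, "")[[1L]]
      if (!all(protoB[wIdx] == "C")) next  # defensive; true by construction
      pamHit <- NA_character_
      for (pat in profile@pamPatterns) {
        plen <- nchar(pat)
        pamRaw <- if (protoStrand == "+")
          .contigSub(genome, transcript@contig, s + L, s + L + plen - 1L)
        else
          .contigSub(genome, transcript@contig, s - plen, s - 1L)
        if (is.na(pamRaw)) next
        pamObs <- if (protoStrand == "+") pamRaw else .revcomp(pamRaw)
        if (grepl("N", pamObs, fixed = TRUE)) next
        if (.iupacMatch(pamObs, pat)) { pamHit <- pamObs; break }
      }
      if (is.na(pamHit)) next
      rows[[length(rows) + 1L]] <- data.frame(
        transcriptId = transcript@transcriptId,
        geneId       = transcript@geneId,
        contig       = transcript@contig,
        start        = s, end = s + L - 1L,
        strand       = protoStrand,
        protospacer  = proto, pam = pamHit,
        sourceCodon  = e$sourceCodon, editStrand = e$editStrand,
        resultCodon  = e$resultCodon, canonical = e$canonical,
        codonNumber  = e$codonNumber,
        nCodons      = nCodon,
        truncationFraction = (e$codonNumber - 1L) / (nCodon - 1L),
        lateTruncation = (e$codonNumber - 1L) / (nCodon - 1L) >= 0.95,
        stringsAsFactors = FALSE)
      rows[[length(rows)]]$requiredPositions <- list(sort(wIdx))
      rows[[length(rows)]]$codonPositions <- list(e$codonPositions[[1L]])
    }
  }
  if (nSkipped > 0L)
    warning(nSkipped, " protospacer placement(s) containing N skipped")
  if (length(rows) == 0L) {
    out <- data.frame(transcriptId = character(), geneId = character(),
                      contig = character(), start = integer(), end = integer(),
                      strand = character(), protospacer = character(),
                      pam = character(), sourceCodon = character(),
                      editStrand = character(), resultCodon = character(),
                      canonical = logical(), codonNumber = integer(),
                      nCodons = integer(), truncationFraction = numeric(),
                      lateTruncation = logical(), stringsAsFactors = FALSE)
    out$requiredPositions <- list(); out$codonPositions <- list()
    out$efficiencyScore <- numeric()
    if (bystanders) out$bystanders <- list()
    return(out)
  }
  out <- do.call(rbind, rows)
  key <- paste(out$contig, out$start, out$strand, out$sourceCodon,
               out$resultCodon,
               vapply(out$requiredPositions, paste, character(1), collapse = ","),
               sep = "|")
  out <- out[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out$efficiencyScore <- vapply(seq_len(nrow(out)), function(i)
    scoreGuide(out$protospacer[i], out$requiredPositions[[i]], profile),
    numeric(1))
  if (bystanders)
    out$bystanders <- lapply(seq_len(nrow(out)), function(i)
      predictBystanders(out[i, ], cs, genome, profile))
  out
}

#' Predict bystander effects of the window cytosines of a candidate
#'
#' One entry per editing-window cytosine (protospacer strand) other than the
#' required positions.  Coding positions are evaluated by substituting the
#' edit into the mapped CDS codon and translating (silent / missense /
#' nonsense); exonic non-CDS positions are labelled `UTR` and everything
#' else `splice/intronic`.
#'
#' @param cand single-row candidate data.frame from [findGuides()]
#' @param cds the transcript's [CodingSequence-class]
#' @param genome `DNAStringSet`
#' @param profile the [BaseEditorProfile-class] used for the design
#' @param exons optional `IRanges` of the transcript's exons, used to
#'   distinguish `UTR` from `splice/intronic` (omitted: all non-CDS
#'   positions are labelled `splice/intronic`)
#' @return data.frame with columns `windowPosition`, `pos` (genomic),
#'   `cdsIndex`, `refCodon`, `altCodon`, `refAA`, `altAA`, `consequence`
#' @export
predictBystanders <- function(cand, cds, genome, profile, exons = NULL) {
  lo <- profile@window[1L]; hi <- profile@window[2L]
  protoB <- strsplit(cand$protospacer, "")[[1L]]
  req <- cand$requiredPositions[[1L]]
  wpos <- setdiff(seq.int(lo, hi), req)
  wpos <- wpos[protoB[wpos] == "C"]
  out <- data.frame(windowPosition = integer(), pos = integer(),
                    cdsIndex = integer(), refCodon = character(),
                    altCodon = character(), refAA = character(),
                    altAA = character(), consequence = character(),
                    stringsAsFactors = FALSE)
  if (length(wpos) == 0L) return(out)
  L <- profile@guideLength
  seqStr <- as.character(cds@seq)
  ts <- cds@coordMap$strand[1L]
  for (w in wpos) {
    gp <- if (cand$strand == "+") cand$start + w - 1L else cand$end - w + 1L
    ci <- genomicToCds(cds, cand$contig, gp)
    if (is.na(ci)) {
      csq <- "splice/intronic"
      if (!is.null(exons)) {
        inExon <- any(gp >= IRanges::start(exons) & gp <= IRanges::end(exons))
        if (inExon) csq <- "UTR"
      }
      out <- rbind(out, data.frame(
        windowPosition = w, pos = gp, cdsIndex = NA_integer_,
        refCodon = NA_character_, altCodon = NA_character_,
        refAA = NA_character_, altAA = NA_character_, consequence = csq,
        stringsAsFactors = FALSE))
      next
    }
    codonNo <- (ci - 1L) %/% 3L + 1L
    cStart <- (codonNo - 1L) * 3L + 1L
    refCodon <- substr(seqStr, cStart, cStart + 2L)
    # C on the protospacer strand: same strand as the transcript means the
    # CDS base is C (edit C>T); opposite strand means the CDS base is G (G>A)
    alt <- if (cand$strand == ts) "T" else "A"
    b <- strsplit(refCodon, "")[[1L]]
    b[ci - cStart + 1L] <- alt
    altCodon <- paste(b, collapse = "")
    refAA <- as.character(Biostrings::translate(Biostrings::DNAString(refCodon),
                                                no.init.codon = TRUE))
    altAA <- as.character(Biostrings::translate(Biostrings::DNAString(altCodon),
                                                no.init.codon = TRUE))
    csq <- if (refAA == altAA) "silent"
           else if (altAA == "*") "nonsense" else "missense"
    out <- rbind(out, data.frame(
      windowPosition = w, pos = gp, cdsIndex = ci, refCodon = refCodon,
      altCodon = altCodon, refAA = refAA, altAA = altAA, consequence = csq,
      stringsAsFactors = FALSE))
  }
  out
}

#' Apply a candidate's edits to the spliced CDS
#'
#' Substitutes the rule's base changes (C-to-T on the sense strand for sense
#' rules, G-to-A for antisense rules) into the spliced CDS; used to verify
#' that every emitted candidate truncates the protein at the reported codon.
#'
#' @param cand single-row candidate data.frame from [findGuides()]
#' @param cds the transcript's [CodingSequence-class]
#' @return edited CDS as a character string
#' @export
applyGuideEdits <- function(cand, cds) {
  b <- strsplit(as.character(cds@seq), "")[[1L]]
  idx <- (cand$codonNumber - 1L) * 3L + cand$codonPositions[[1L]]
  b[idx] <- if (cand$editStrand == "sense") "T" else "A"
  paste(b, collapse = "")
}

#' Rank guide candidates
#'
#' Stable sort by (1) fewer predicted off-target sites at up to 2 mismatches,
#' (2) higher efficiency score, (3) smaller truncation fraction (earlier
#' stop), (4) genomic coordinate.  Requires [addOfftargetCounts()] (or a
#' manually supplied `offtargets2mm` column).
#'
#' @param cands candidate data.frame with columns `efficiencyScore`,
#'   `truncationFraction` and `offtargets2mm`
#' @return the same data.frame, reordered
#' @export
rankGuides <- function(cands) {
  if (!"offtargets2mm" %in% colnames(cands))
    stop("rank requires an 'offtargets2mm' column; run addOfftargetCounts()")
  ord <- order(cands$offtargets2mm, -cands$efficiencyScore,
               cands$truncationFraction, cands$contig, cands$start,
               method = "radix")
  out <- cands[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write guide candidates to TSV / BED6
#'
#' The BED score is `round(1000 * efficiencyScore)`; list columns are
#' flattened to comma-separated strings in the TSV.
#'
#' @param cands candidate data.frame from [findGuides()]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeGuidesTSV <- function(cands, path) {
  flat <- cands
  flat$requiredPositions <- vapply(cands$requiredPositions, paste,
                                   character(1), collapse = ",")
  flat$codonPositions <- vapply(cands$codonPositions, paste,
                                character(1), collapse = ",")
  if ("bystanders" %in% colnames(flat))
    flat$bystanders <- vapply(cands$bystanders, function(b)
      if (nrow(b) == 0L) "" else paste(b$windowPosition, b$consequence,
                                       sep = ":", collapse = ","),
      character(1))
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGuidesTSV
#' @export
writeGuidesBED <- function(cands, path) {
  bed <- data.frame(
    chrom = cands$contig,
    start = cands$start - 1L,  # BED is 0-based half-open
    end   = cands$end,
    name  = sprintf("%s_codon%d_%s>%s", cands$transcriptId, cands$codonNumber,
                    cands$sourceCodon, cands$resultCodon),
    score = round(1000 * cands$efficiencyScore),
    strand = cands$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
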