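# Independent oracles used by the unit and acceptance tests.  These
# deliberately use different mechanics from the package implementation:
# regex PAM scans instead of codon-anchored placement, integer-matrix
# Hamming counts instead of character-vector accumulation, and a direct
# Gotoh dynamic program for alignment scores.

oracleRevcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1L]]), collapse = "")
}

oracleTranslate <- function(x) {
  code <- Biostrings::GENETIC_CODE
  n <- nchar(x) %/% 3L
  paste(vapply(seq_len(n), function(i)
    code[[substr(x, (i - 1L) * 3L + 1L, i * 3L)]], character(1)),
    collapse = "")
}

# IUPAC pattern -> regex character classes
iupacToRegex <- function(pat) {
  map <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
           S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]", B = "[CGT]",
           D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  paste(map[strsplit(pat, "")[[1L]]], collapse = "")
}

# spliced CDS + per-base genomic positions built by direct string surgery
oracleSplicedCDS <- function(transcript, genome) {
  ct <- as.character(genome[[contigName(transcript)]])
  cds <- cdsRanges(transcript)
  seq <- ""
  pos <- integer(0)
  for (i in seq_along(cds)) {
    a <- IRanges::start(cds)[i]; b <- IRanges::end(cds)[i]
    seq <- paste0(seq, substr(ct, a, b))
    pos <- c(pos, a:b)
  }
  if (transcriptStrand(transcript) == "-") {
    seq <- oracleRevcomp(seq)
    pos <- rev(pos)
  }
  list(seq = seq, pos = pos)
}

# brute-force guide oracle: genome-wide regex PAM scan on both strands, then
# for every editable codon instance test containment of its edited genomic
# positions in each placement's window
oracleGuides <- function(transcript, genome, profile) {
  cs <- oracleSplicedCDS(transcript, genome)
  L <- guideLength(profile)
  w <- editWindow(profile)
  ts <- transcriptStrand(transcript)
  ctName <- contigName(transcript)
  ctSeq <- as.character(genome[[ctName]])
  n <- nchar(ctSeq)
  # all protospacer starts with a matching PAM, per genomic strand
  pamStarts <- function(strand) {
    hits <- integer(0)
    for (pat in pamPatterns(profile)) {
      rx <- iupacToRegex(pat)
      plen <- nchar(pat)
      if (strand == "+") {
        m <- gregexpr(sprintf("(?=%s)", rx), ctSeq, perl = TRUE)[[1L]]
        if (m[1L] != -1L) hits <- c(hits, m - L)  # PAM at s+L
      } else {
        rcrx <- iupacToRegex(oracleRevcomp(pat))  # PAM revcomp on fwd strand
        m <- gregexpr(sprintf("(?=%s)", rcrx), ctSeq, perl = TRUE)[[1L]]
        if (m[1L] != -1L) hits <- c(hits, m + plen)  # protospacer starts after
      }
    }
    sort(unique(hits[hits >= 1L & hits + L - 1L <= n]))
  }
  starts <- list("+" = pamStarts("+"), "-" = pamStarts("-"))
  rules <- stopConversionRules()
  nCodon <- nchar(cs$seq) %/% 3L
  keys <- character(0)
  for (k in 2:(nCodon - 1L)) {
    codon <- substr(cs$seq, (k - 1L) * 3L + 1L, k * 3L)
    for (r in which(rules$sourceCodon == codon)) {
      cp <- rules$codonPositions[[r]]
      P <- cs$pos[(k - 1L) * 3L + cp]
      protoStrand <- if (rules$editStrand[r] == "sense") ts
                     else setdiff(c("+", "-"), ts)
      for (s in starts[[protoStrand]]) {
        wIdx <- if (protoStrand == "+") P - s + 1L else (s + L - 1L) - P + 1L
        if (all(wIdx >= w[1L] & wIdx <= w[2L])) {
          proto <- substr(ctSeq, s, s + L - 1L)
          if (protoStrand == "-") proto <- oracleRevcomp(proto)
          if (grepl("N", proto, fixed = TRUE)) next
          keys <- c(keys, paste(ctName, s, protoStrand, codon,
                                rules$resultCodon[r],
                                paste(sort(wIdx), collapse = ","), sep = "|"))
        }
      }
    }
  }
  sort(unique(keys))
}

guideKeys <- function(cands) {
  sort(paste(cands$contig, cands$start, cands$strand, cands$sourceCodon,
             cands$resultCodon,
             vapply(cands$requiredPositions, paste, character(1),
                    collapse = ","), sep = "|"))
}

# integer-matrix Hamming scan over all windows of both strands
oracleOfftargets <- function(guide, genome, maxMM, pamPattern = "NGG") {
  L <- nchar(guide)
  plen <- nchar(pamPattern)
  rx <- paste0("^", iupacToRegex(pamPattern), "$")
  gInt <- utf8ToInt(guide)
  res <- list()
  for (ct in names(genome)) {
    for (strand in c("+", "-")) {
      seq <- as.character(genome[[ct]])
      if (strand == "-") seq <- oracleRevcomp(seq)
      s <- utf8ToInt(seq)
      n <- length(s)
      nPos <- n - L - plen + 1L
      if (nPos < 1L) next
      idx <- seq_len(nPos)
      m <- matrix(s[outer(idx, 0:(L - 1L), "+")], ncol = L)
      mm <- rowSums(m != matrix(gInt, nrow = nPos, ncol = L, byrow = TRUE))
      hasN <- rowSums(m == utf8ToInt("N")) > 0L
      pam <- substring(seq, idx + L, idx + L + plen - 1L)
      keep <- which(mm <= maxMM & !hasN & grepl(rx, pam))
      if (length(keep)) {
        start <- if (strand == "+") keep else n - (keep + L - 1L) + 1L
        res[[length(res) + 1L]] <- data.frame(
          contig = ct, start = start, strand = strand,
          mismatches = mm[keep], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(res) == 0L)
    return(data.frame(contig = character(), start = integer(),
                      strand = character(), mismatches = integer()))
  out <- do.call(rbind, res)
  out[order(out$contig, out$start, out$strand), ]
}

# Gotoh affine-gap global alignment score: gap of length k costs open + k*ext
oracleAlignScore <- function(a, b, match = 2, mismatch = -3,
                             open = 6, ext = 1) {
  a <- strsplit(a, "")[[1L]]; b <- strsplit(b, "")[[1L]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1L, m + 1L)  # ends in match/mismatch
  X <- matrix(NEG, n + 1L, m + 1L)  # ends in gap in b (a consumed)
  Y <- matrix(NEG, n + 1L, m + 1L)  # ends in gap in a (b consumed)
  M[1L, 1L] <- 0
  for (i in seq_len(n) + 1L) X[i, 1L] <- -(open + ext * (i - 1L))
  for (j in seq_len(m) + 1L) Y[1L, j] <- -(open + ext * (j - 1L))
  for (i in seq_len(n) + 1L) {
    for (j in seq_len(m) + 1L) {
      sc <- if (a[i - 1L] == b[j - 1L]) match else mismatch
      M[i, j] <- max(M[i - 1L, j - 1L], X[i - 1L, j - 1L],
                     Y[i - 1L, j - 1L]) + sc
      X[i, j] <- max(M[i - 1L, j] - open - ext, X[i - 1L, j] - ext)
      Y[i, j] <- max(M[i, j - 1L] - open - ext, Y[i, j - 1L] - ext)
    }
  }
  max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
}

# mirror a genome + annotation (reverse-complement every contig and map the
# transcript intervals), used by the strand-symmetry property tests
mirrorAssembly <- function(genome, transcripts) {
  widths <- Biostrings::width(genome)
  names(widths) <- names(genome)
  g2 <- Biostrings::reverseComplement(genome)
  names(g2) <- names(genome)
  t2 <- lapply(transcripts, function(t) {
    W <- widths[[contigName(t)]]
    flip <- function(ir) {
      m <- cbind(W - IRanges::end(ir) + 1L, W - IRanges::start(ir) + 1L)
      m[order(m[, 1L]), , drop = FALSE]
    }
    TranscriptModel(transcriptId(t), geneId(t), contigName(t),
                    if (transcriptStrand(t) == "+") "-" else "+",
                    exons = flip(exonRanges(t)), cds = flip(cdsRanges(t)))
  })
  list(genome = g2, transcripts = t2)
}
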