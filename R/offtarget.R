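#' @include AllClasses.R editor-profiles.R
NULL

# forward scan of one character vector: all windows [i, i+L-1] whose adjacent
# 3' PAM matches one of the patterns and whose Hamming distance to the guide
# is <= maxMM; windows (or PAMs) containing N are skipped
.scanForward <- function(x, gChars, pamPatterns, maxMM) {
  L <- length(gChars)
  n <- length(x)
  plens <- nchar(pamPatterns)
  nPos <- n - L - min(plens) + 1L
  if (nPos < 1L)
    return(data.frame(start = integer(), site = character(),
                      pam = character(), mismatches = integer(),
                      stringsAsFactors = FALSE))
  idx <- seq_len(nPos)
  mm <- integer(nPos)
  for (j in seq_len(L)) mm <- mm + (x[idx + j - 1L] != gChars[j])
  # windows containing N: every N mismatches all of ACGT, but such windows
  # are excluded rather than counted
  isN <- x == "N"
  cn <- cumsum(isN)
  hasN <- (cn[idx + L - 1L] - c(0L, cn)[idx]) > 0L
  pamOK <- rep(FALSE, nPos)
  pamStr <- rep(NA_character_, nPos)
  for (pat in pamPatterns) {
    plen <- nchar(pat)
    ok <- idx + L + plen - 1L <= n
    cur <- ok
    for (k in seq_len(plen)) {
      allowed <- .IUPAC[[substr(pat, k, k)]]
      ck <- x[pmin(idx + L + k - 1L, n)]
      cur <- cur & ck %in% allowed  # N never in allowed sets
    }
    new <- cur & !pamOK
    if (any(new)) {
      starts <- idx[new]
      pamStr[new] <- vapply(starts, function(s)
        paste(x[(s + L):(s + L + plen - 1L)], collapse = ""), character(1))
      pamOK <- pamOK | cur
    }
  }
  keep <- which(mm <= maxMM & !hasN & pamOK)
  if (length(keep) == 0L)
    return(data.frame(start = integer(), site = character(),
                      pam = character(), mismatches = integer(),
                      stringsAsFactors = FALSE))
  data.frame(
    start = keep,
    site  = vapply(keep, function(s) paste(x[s:(s + L - 1L)], collapse = ""),
                   character(1)),
    pam = pamStr[keep],
    mismatches = mm[keep],
    stringsAsFactors = FALSE)
}

#' Mismatch-tolerant off-target search for one guide
#'
#' Cas-OFFinder-style sliding-window scan of the whole genome, both strands:
#' every window whose adjacent 3' PAM matches one of the IUPAC patterns and
#' whose Hamming distance to the guide (PAM excluded) is at most
#' `maxMismatches` is reported exactly once.  Mismatches in the PAM are not
#' permitted; bulges are not modelled; windows containing N are skipped.
#'
#' @param guide protospacer sequence over A/C/G/T (5' to 3')
#' @param genome `DNAStringSet` from [readGenome()]
#' @param maxMismatches maximum Hamming distance (default 3, common
#'   Cas-OFFinder practice)
#' @param pamPatterns IUPAC PAM patterns (default `"NGG"`)
#' @param profile optional [BaseEditorProfile-class]; when given, supplies
#'   `pamPatterns` and the guide length is checked against it
#' @return data.frame with columns `guide`, `contig`, `start` (1-based
#'   leftmost genomic position of the protospacer), `strand`, `site`
#'   (protospacer-strand orientation), `pam`, `mismatches`,
#'   `mismatchPositions` (list column of guide positions)
#' @seealso [offtargetSummary()], [addOfftargetCounts()]
#' @export
findOfftargets <- function(guide, genome, maxMismatches = 3L,
                           pamPatterns = "NGG", profile = NULL) {
  guide <- toupper(guide)
  if (!grepl("^[ACGT]+$", guide)) stop("guide must be over {A,C,G,T}")
  if (!is.null(profile)) {
    if (nchar(guide) != profile@guideLength)
      stop("guide length ", nchar(guide), " does not match profile guide length ",
           profile@guideLength)
    pamPatterns <- profile@pamPatterns
  }
  if (maxMismatches < 0L) stop("maxMismatches must be >= 0")
  gChars <- strsplit(guide, "")[[1L]]
  L <- length(gChars)
  rows <- list()
  for (ct in names(genome)) {
    fwd <- strsplit(as.character(genome[[ct]]), "")[[1L]]
    n <- length(fwd)
    h <- .scanForward(fwd, gChars, pamPatterns, maxMismatches)
    if (nrow(h)) {
      h$contig <- ct; h$strand <- "+"
      rows[[length(rows) + 1L]] <- h
    }
    rev <- strsplit(.revcomp(as.character(genome[[ct]])), "")[[1L]]
    h <- .scanForward(rev, gChars, pamPatterns, maxMismatches)
    if (nrow(h)) {
      # map reverse-complement coordinates back to the forward strand:
      # window [i, i+L-1] on the revcomp corresponds to forward-strand
      # leftmost position n - (i + L - 1) + 1
      h$start <- n - (h$start + L - 1L) + 1L
      h$contig <- ct; h$strand <- "-"
      rows[[length(rows) + 1L]] <- h
    }
  }
  if (length(rows) == 0L) {
    out <- data.frame(guide = character(), contig = character(),
                      start = integer(), strand = character(),
                      site = character(), pam = character(),
                      mismatches = integer(), stringsAsFactors = FALSE)
    out$mismatchPositions <- list()
    return(out)
  }
  out <- do.call(rbind, rows)
  out$guide <- guide
  out <- out[order(out$contig, out$start, out$strand),
             c("guide", "contig", "start", "strand", "site", "pam",
               "mismatches")]
  rownames(out) <- NULL
  out$mismatchPositions <- lapply(out$site, function(s)
    which(strsplit(s, "")[[1L]] != gChars))
  out
}

#' Summarize off-target hits by mismatch count
#'
#' Counts sites per mismatch count, excluding the on-target self-hit: when
#' `onTarget` (a list/row with `contig`, `start`, `strand`) is given, only
#' the 0-mismatch hit at that locus is excluded; otherwise every 0-mismatch
#' hit is treated as the design locus and excluded.
#'
#' @param hits data.frame from [findOfftargets()] for a single guide
#' @param onTarget optional design locus
#' @return named integer vector, names = mismatch counts
#' @export
offtargetSummary <- function(hits, onTarget = NULL) {
  if (nrow(hits) == 0L) return(integer(0))
  key <- paste(hits$contig, hits$start, hits$strand)
  if (anyDuplicated(key)) stop("duplicate off-target hit records")
  drop <- if (is.null(onTarget)) hits$mismatches == 0L
          else hits$mismatches == 0L & hits$contig == onTarget$contig &
               hits$start == onTarget$start & hits$strand == onTarget$strand
  h <- hits[!drop, , drop = FALSE]
  if (nrow(h) == 0L) return(integer(0))
  tab <- table(h$mismatches)
  stats::setNames(as.integer(tab), names(tab))
}

#' Attach off-target counts to guide candidates
#'
#' Runs [findOfftargets()] for every candidate and records the per-mismatch
#' summary plus `offtargets2mm`, the number of predicted sites at up to 2
#' mismatches excluding the candidate's own design locus — the primary
#' ranking key of [rankGuides()].
#'
#' @param cands candidate data.frame from [findGuides()]
#' @param genome `DNAStringSet`
#' @param maxMismatches search ceiling (default 3)
#' @param profile [BaseEditorProfile-class] supplying the PAM patterns
#' @return `cands` with list column `offtargetCounts` and integer column
#'   `offtargets2mm`
#' @export
addOfftargetCounts <- function(cands, genome, maxMismatches = 3L,
                               profile = editorProfile("BE3")) {
  if (nrow(cands) == 0L) {
    cands$offtargetCounts <- list()
    cands$offtargets2mm <- integer()
    return(cands)
  }
  counts <- vector("list", nrow(cands))
  mm2 <- integer(nrow(cands))
  cache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(cands))) {
    g <- cands$protospacer[i]
    hits <- if (!is.null(cache[[g]])) cache[[g]]
            else cache[[g]] <- findOfftargets(g, genome, maxMismatches,
                                              profile = profile)
    self <- list(contig = cands$contig[i], start = cands$start[i],
                 strand = cands$strand[i])
    summ <- offtargetSummary(hits, onTarget = self)
    counts[[i]] <- summ
    mm2[i] <- sum(summ[as.integer(names(summ)) <= 2L])
  }
  cands$offtargetCounts <- counts
  cands$offtargets2mm <- mm2
  cands
}

#' Write off-target hits as a Cas-OFFinder-style TSV
#'
#' Column order mirrors Cas-OFFinder output: guide, contig, position, site,
#' strand, mismatches.
#'
#' @param hits data.frame from [findOfftargets()]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeOfftargetsTSV <- function(hits, path) {
  utils::write.table(
    hits[, c("guide", "contig", "start", "site", "strand", "mismatches")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
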