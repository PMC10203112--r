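#' @include AllClasses.R
NULL

#' Read a per-CpG methylation table
#'
#' bedGraph/MethylKit-style TSV with one row per CpG: contig, position
#' (1-based), methylated read count, unmethylated read count.  Column
#' indices are configurable for other dialects.
#'
#' @param path input path
#' @param columns integer positions of (contig, pos, methylated,
#'   unmethylated) in the file (default 1:4)
#' @param header does the file carry a header line (default `TRUE`)
#' @return data.frame with columns `contig`, `pos`, `meth`, `unmeth`
#' @export
readCpGTable <- function(path, columns = 1:4, header = TRUE) {
  df <- utils::read.table(path, header = header, sep = "\t",
                          stringsAsFactors = FALSE)
  out <- df[, columns]
  names(out) <- c("contig", "pos", "meth", "unmeth")
  out$pos <- as.integer(out$pos)
  out$meth <- as.integer(out$meth)
  out$unmeth <- as.integer(out$unmeth)
  if (any(out$meth < 0L | out$unmeth < 0L))
    stop("negative methylation counts")
  out
}

# per-CpG levels restricted to usable coverage
.usableCpGs <- function(cpgs, minCov) {
  if (any(cpgs$meth < 0L | cpgs$unmeth < 0L)) stop("negative methylation counts")
  cov <- cpgs$meth + cpgs$unmeth
  keep <- cov >= minCov
  data.frame(contig = cpgs$contig[keep], pos = cpgs$pos[keep],
             level = cpgs$meth[keep] / cov[keep], stringsAsFactors = FALSE)
}

#' Tile methylation on the fixed 1-kb grid
#'
#' CpGs with coverage below `minCov` are excluded, the genome is divided
#' into fixed tiles (`[k*tileSize+1, (k+1)*tileSize]` in 1-based
#' coordinates), and each tile's level is the unweighted mean of its usable
#' per-CpG levels.  Tiles with fewer than `minCpg` usable CpGs are reported
#' with `level = NA` (undefined); tiles with no usable CpGs at all are not
#' reported.  Output is invariant to input record order.
#'
#' @param cpgs data.frame from [readCpGTable()]
#' @param tileSize tile width in bp (default 1000)
#' @param minCpg minimum usable CpGs per tile (default 3)
#' @param minCov minimum per-CpG coverage (default 3)
#' @return data.frame with `contig`, `tileStart`, `tileEnd`, `nCpg`, `level`
#' @export
tileMethylation <- function(cpgs, tileSize = 1000L, minCpg = 3L, minCov = 3L) {
  u <- .usableCpGs(cpgs, minCov)
  if (nrow(u) == 0L)
    return(data.frame(contig = character(), tileStart = integer(),
                      tileEnd = integer(), nCpg = integer(), level = numeric(),
                      stringsAsFactors = FALSE))
  tile <- (u$pos - 1L) %/% tileSize
  key <- paste(u$contig, tile)
  agg <- tapply(u$level, key, mean)
  n <- tapply(u$level, key, length)
  firstIdx <- !duplicated(key)
  info <- data.frame(contig = u$contig[firstIdx], tile = tile[firstIdx],
                     key = key[firstIdx], stringsAsFactors = FALSE)
  info <- info[order(info$contig, info$tile), ]
  out <- data.frame(
    contig = info$contig,
    tileStart = info$tile * tileSize + 1L,
    tileEnd = (info$tile + 1L) * tileSize,
    nCpg = as.integer(n[info$key]),
    level = as.numeric(agg[info$key]),
    stringsAsFactors = FALSE)
  out$level[out$nCpg < minCpg] <- NA_real_
  rownames(out) <- NULL
  out
}

#' Min-max-normalized sample similarity
#'
#' Pairwise Euclidean distances between per-sample tile-level vectors
#' (tiles undefined in any sample are dropped listwise), min-max normalized
#' over the off-diagonal pairs and subtracted from 1, so the closest pair
#' scores 1 and the most distant pair scores exactly 0; the diagonal is
#' fixed at 1.  When all pairwise distances are equal the normalization is
#' degenerate and every off-diagonal similarity is defined as 1, with a
#' warning.
#'
#' @param levels numeric matrix, rows = samples, columns = tiles (NA =
#'   undefined tile)
#' @return symmetric similarity matrix with unit diagonal
#' @export
sampleSimilarity <- function(levels) {
  if (nrow(levels) < 2L) stop("at least two samples required")
  keep <- colSums(is.na(levels)) == 0L
  m <- levels[, keep, drop = FALSE]
  if (ncol(m) == 0L) stop("no tiles defined in every sample")
  d <- as.matrix(stats::dist(m))
  off <- d[upper.tri(d)]
  dmin <- min(off); dmax <- max(off)
  if (dmax == dmin) {
    warning("all pairwise distances equal; off-diagonal similarities set to 1")
    s <- matrix(1, nrow(d), ncol(d))
  } else {
    s <- 1 - (d - dmin) / (dmax - dmin)
  }
  diag(s) <- 1
  dimnames(s) <- dimnames(d)
  s
}

#' Promoter intervals from transcript models
#'
#' Promoters are the 2 kb upstream to 2 kb downstream of the transcription
#' start site (TSS), honoring strand: the TSS of a minus-strand transcript
#' is its rightmost exon coordinate.  Intervals are clipped at position 1.
#'
#' @param transcripts list of [TranscriptModel-class]
#' @param upstream,downstream flank sizes in bp (default 2000 each)
#' @return data.frame with `id`, `contig`, `start`, `end`, `class`
#' @export
promoterRegions <- function(transcripts, upstream = 2000L, downstream = 2000L) {
  rows <- lapply(transcripts, function(t) {
    tss <- if (t@strand == "+") min(IRanges::start(t@exons))
           else max(IRanges::end(t@exons))
    if (t@strand == "+") {
      start <- tss - upstream; end <- tss + downstream
    } else {
      start <- tss - downstream; end <- tss + upstream
    }
    data.frame(id = paste0(t@transcriptId, "_promoter"), contig = t@contig,
               start = max(1L, start), end = end, class = "promoter",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mean methylation level of genomic elements
#'
#' Per-element unweighted mean of the usable per-CpG levels (coverage >=
#' `minCov`); elements covering fewer than `minCpg` usable CpGs are
#' undefined (`level = NA`).
#'
#' @param cpgs data.frame from [readCpGTable()]
#' @param elements data.frame with `id`, `contig`, `start`, `end` and
#'   optionally `class` (e.g. from [promoterRegions()] or a BED reader)
#' @param minCpg minimum usable CpGs per element (default 3)
#' @param minCov minimum per-CpG coverage (default 3)
#' @return `elements` with added columns `nCpg` and `level`
#' @export
elementMethylation <- function(cpgs, elements, minCpg = 3L, minCov = 3L) {
  u <- .usableCpGs(cpgs, minCov)
  out <- elements
  out$nCpg <- 0L
  out$level <- NA_real_
  if (nrow(u)) {
    gr <- GenomicRanges::GRanges(u$contig, IRanges::IRanges(u$pos, u$pos))
    el <- GenomicRanges::GRanges(elements$contig,
                                 IRanges::IRanges(elements$start, elements$end))
    ov <- GenomicRanges::findOverlaps(el, gr)
    if (length(ov)) {
      lev <- split(u$level[S4Vectors::subjectHits(ov)],
                   S4Vectors::queryHits(ov))
      idx <- as.integer(names(lev))
      out$nCpg[idx] <- lengths(lev)
      out$level[idx] <- vapply(lev, mean, numeric(1))
    }
  }
  out$level[out$nCpg < minCpg] <- NA_real_
  out
}

#' Call hypermethylated elements between two replicate groups
#'
#' Per element, a two-sided Welch t-test on the replicate element levels of
#' group A versus group B; an element is called hypermethylated (in A) when
#' the difference of group means exceeds `diffMin` (strictly) and the raw
#' p-value is below `alpha` (strictly).  A Benjamini-Hochberg adjusted
#' p-value is reported alongside but the raw p is the calling criterion.
#' Elements with fewer than two defined replicate levels in either group are
#' skipped with a warning.  When both groups have zero variance the p-value
#' is 1 for equal means and 0 otherwise.
#'
#' @param groupA,groupB lists of replicate element tables (each a data.frame
#'   from [elementMethylation()], same elements in the same order)
#' @param diffMin minimum methylation difference, strict `>` (default 0.30)
#' @param alpha significance level, strict `<` (default 0.05)
#' @return data.frame with `id`, `meanA`, `meanB`, `difference`, `pValue`,
#'   `pAdjBH`, `isHyper`
#' @export
callHypermethylated <- function(groupA, groupB, diffMin = 0.30, alpha = 0.05) {
  ids <- groupA[[1L]]$id
  levA <- vapply(groupA, function(d) d$level, numeric(length(ids)))
  levB <- vapply(groupB, function(d) d$level, numeric(length(ids)))
  levA <- matrix(levA, nrow = length(ids))
  levB <- matrix(levB, nrow = length(ids))
  nA <- rowSums(!is.na(levA)); nB <- rowSums(!is.na(levB))
  usable <- nA >= 2L & nB >= 2L
  if (any(!usable))
    warning(sum(!usable), " element(s) with fewer than 2 defined replicates ",
            "per group skipped")
  idx <- which(usable)
  meanA <- rowMeans(levA, na.rm = TRUE)
  meanB <- rowMeans(levB, na.rm = TRUE)
  p <- rep(NA_real_, length(ids))
  for (i in idx) {
    a <- levA[i, !is.na(levA[i, ])]
    b <- levB[i, !is.na(levB[i, ])]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      p[i] <- if (mean(a) == mean(b)) 1 else 0
    } else {
      p[i] <- stats::t.test(a, b, var.equal = FALSE)$p.value
    }
  }
  out <- data.frame(
    id = ids,
    meanA = meanA, meanB = meanB,
    difference = meanA - meanB,
    pValue = p,
    stringsAsFactors = FALSE)
  out$pAdjBH <- NA_real_
  out$pAdjBH[idx] <- stats::p.adjust(p[idx], method = "BH")
  out$isHyper <- !is.na(p) & out$difference > diffMin & p < alpha
  out[!usable, c("meanA", "meanB", "difference")] <-
    out[!usable, c("meanA", "meanB", "difference")]  # kept as computed, p NA
  out
}

#' Read a BED file of genomic elements
#'
#' BED intervals (0-based half-open) are converted to the package's 1-based
#' closed convention.
#'
#' @param path BED path (3+ columns; column 4, when present, is the id)
#' @param class element class label (default `"custom"`)
#' @return data.frame with `id`, `contig`, `start`, `end`, `class`
#' @export
readElementsBED <- function(path, class = "custom") {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  data.frame(
    id = if (ncol(df) >= 4L) as.character(df[[4L]])
         else sprintf("%s:%d-%d", df[[1L]], df[[2L]] + 1L, df[[3L]]),
    contig = as.character(df[[1L]]),
    start = as.integer(df[[2L]]) + 1L,
    end = as.integer(df[[3L]]),
    class = class,
    stringsAsFactors = FALSE)
}
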