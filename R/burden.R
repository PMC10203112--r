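#' @include AllClasses.R
NULL

#' Read a variant call table (minimal VCF or TSV)
#'
#' Accepts either minimal VCF text (`##` headers, `#CHROM POS ID REF ALT ...`
#' with `AF=` in INFO or an `AF` column) or a headered TSV with columns
#' `contig`/`chrom`, `pos`, `ref`, `alt`, `af`.  Positions are 1-based in
#' both dialects.  Variants are typed `SNV` when ref and alt are single
#' bases, `indel` otherwise.
#'
#' @param path input path
#' @return data.frame with columns `contig`, `pos`, `ref`, `alt`, `af`,
#'   `type`
#' @export
readVariantTable <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty variant table: ", path)
  if (startsWith(lines[1L], "##") || startsWith(lines[1L], "#CHROM")) {
    body <- lines[!startsWith(lines, "##")]
    header <- strsplit(sub("^#", "", body[1L]), "\t")[[1L]]
    body <- body[-1L]
    if (length(body) == 0L)
      return(data.frame(contig = character(), pos = integer(),
                        ref = character(), alt = character(), af = numeric(),
                        type = character(), stringsAsFactors = FALSE))
    f <- do.call(rbind, strsplit(body, "\t"))
    colnames(f) <- header[seq_len(ncol(f))]
    af <- if ("AF" %in% header && !"INFO" %in% header) as.numeric(f[, "AF"])
      else {
        info <- f[, "INFO"]
        m <- regmatches(info, regexpr("AF=[0-9.eE+-]+", info))
        found <- grepl("AF=", info)
        out <- rep(NA_real_, length(info))
        out[found] <- as.numeric(sub("AF=", "", m))
        out
      }
    df <- data.frame(contig = f[, "CHROM"], pos = as.integer(f[, "POS"]),
                     ref = f[, "REF"], alt = f[, "ALT"], af = af,
                     stringsAsFactors = FALSE)
  } else {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    names(df) <- tolower(names(df))
    if ("chrom" %in% names(df)) names(df)[names(df) == "chrom"] <- "contig"
    need <- c("contig", "pos", "ref", "alt", "af")
    if (!all(need %in% names(df)))
      stop("variant TSV must have columns ", paste(need, collapse = ", "))
    df <- df[, need]
  }
  df$type <- ifelse(nchar(df$ref) == 1L & nchar(df$alt) == 1L, "SNV", "indel")
  df
}

#' Write a variant table as minimal VCF
#'
#' @param variants data.frame with `contig`, `pos`, `ref`, `alt`, `af`
#' @param path output path
#' @return `path`, invisibly
#' @export
writeVariantVCF <- function(variants, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Allele frequency\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(variants))
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tAF=%g",
                       variants$contig, variants$pos, variants$ref,
                       variants$alt, variants$af), con)
  invisible(path)
}

# normalize the (pos, ref, alt) representation of an indel: trim the common
# suffix, then the common prefix (advancing pos), keeping at least one base
# on each side
.normalizeVariant <- function(pos, ref, alt) {
  r <- strsplit(ref, "")[[1L]]; a <- strsplit(alt, "")[[1L]]
  while (length(r) > 1L && length(a) > 1L && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]; a <- a[-length(a)]
  }
  while (length(r) > 1L && length(a) > 1L && r[1L] == a[1L]) {
    r <- r[-1L]; a <- a[-1L]; pos <- pos + 1L
  }
  list(pos = pos, ref = paste(r, collapse = ""), alt = paste(a, collapse = ""))
}

.normalizeTable <- function(df) {
  if (nrow(df) == 0L) return(df)
  idx <- which(df$type == "indel" | nchar(df$ref) > 1L | nchar(df$alt) > 1L)
  for (i in idx) {
    nv <- .normalizeVariant(df$pos[i], df$ref[i], df$alt[i])
    df$pos[i] <- nv$pos; df$ref[i] <- nv$ref; df$alt[i] <- nv$alt
  }
  df$type <- ifelse(nchar(df$ref) == 1L & nchar(df$alt) == 1L, "SNV", "indel")
  df
}

#' Consensus variants across three callers
#'
#' The variants called concordantly by all three callers are treated as true
#' de-novo events.  SNVs and indels are intersected separately on
#' (contig, pos, ref, alt) after left-normalization of the indel
#' representation; the allele frequency of a consensus variant is the mean
#' across callers.  The operation is commutative and idempotent over
#' call-set order.
#'
#' @param callsets named list of exactly three variant data.frames (from
#'   [readVariantTable()] or [simulateCallsets()])
#' @return a [ConsensusVariantSet-class]
#' @export
consensusVariants <- function(callsets) {
  if (length(callsets) != 3L)
    stop("exactly three call sets are required, got ", length(callsets))
  if (is.null(names(callsets)))
    names(callsets) <- paste0("caller", seq_along(callsets))
  callsets <- lapply(callsets, .normalizeTable)
  keyOf <- function(df) paste(df$contig, df$pos, df$ref, df$alt, sep = ":")
  keys <- lapply(callsets, keyOf)
  common <- Reduce(intersect, keys)
  first <- callsets[[1L]]
  sel <- first[match(common, keys[[1L]]), , drop = FALSE]
  if (nrow(sel)) {
    afMat <- vapply(seq_along(callsets), function(j)
      callsets[[j]]$af[match(common, keys[[j]])], numeric(length(common)))
    sel$af <- rowMeans(matrix(afMat, nrow = length(common)))
  }
  rownames(sel) <- NULL
  new("ConsensusVariantSet", variants = sel, provenance = names(callsets))
}

#' Filter a consensus variant set
#'
#' Keeps variants with allele frequency strictly greater than `afMin`
#' (the reliability threshold; the default 0.10 drops everything at or below
#' 10%) that do not match any known site (dbSNP/MGP-style exclusion lists:
#' a `GRanges`, a BED-like data.frame with `contig`/`start`/`end`, or a site
#' table with `contig`/`pos`).
#'
#' @param cvs a [ConsensusVariantSet-class]
#' @param afMin allele-frequency threshold, strict `>` (default 0.10)
#' @param knownSites optional exclusion list(s); a list applies each in turn
#' @return the filtered [ConsensusVariantSet-class]
#' @export
filterVariants <- function(cvs, afMin = 0.10, knownSites = NULL) {
  v <- cvs@variants
  keep <- v$af > afMin
  if (!is.null(knownSites)) {
    sites <- if (is.data.frame(knownSites) || is(knownSites, "GRanges"))
      list(knownSites) else knownSites
    for (ks in sites) {
      if (is(ks, "GRanges")) {
        ks <- data.frame(contig = as.character(GenomicRanges::seqnames(ks)),
                         start = GenomicRanges::start(ks),
                         end = GenomicRanges::end(ks))
      }
      if (all(c("start", "end") %in% names(ks))) {
        for (i in which(keep)) {
          hit <- ks$contig == v$contig[i] & ks$start <= v$pos[i] &
                 ks$end >= v$pos[i]
          if (any(hit)) keep[i] <- FALSE
        }
      } else if ("pos" %in% names(ks)) {
        known <- paste(ks$contig, ks$pos)
        keep <- keep & !(paste(v$contig, v$pos) %in% known)
      } else stop("knownSites must have contig+start/end or contig+pos")
    }
  }
  out <- v[keep, , drop = FALSE]
  rownames(out) <- NULL
  new("ConsensusVariantSet", variants = out, provenance = cvs@provenance)
}

# membership lookup: one logical vector per contig marking transcribed and
# non-N positions
.genomeMasks <- function(genome, transcribed) {
  if (is(transcribed, "GRanges")) {
    transcribed <- data.frame(
      contig = as.character(GenomicRanges::seqnames(transcribed)),
      start = GenomicRanges::start(transcribed),
      end = GenomicRanges::end(transcribed))
  }
  masks <- list()
  for (ct in names(genome)) {
    w <- Biostrings::width(genome)[match(ct, names(genome))]
    tx <- rep(FALSE, w)
    sub <- transcribed[transcribed$contig == ct, , drop = FALSE]
    for (i in seq_len(nrow(sub)))
      tx[max(1L, sub$start[i]):min(w, sub$end[i])] <- TRUE
    nonN <- strsplit(as.character(genome[[ct]]), "")[[1L]] != "N"
    masks[[ct]] <- list(tx = tx, nonN = nonN)
  }
  masks
}

#' Transcribed-region burden test for de-novo variants
#'
#' Classifies each consensus variant as transcribed or untranscribed, then
#' simulates `nSim` draws of the same number of loci uniformly over the
#' non-N positions of the genome (without replacement within a draw) and
#' records the transcribed proportion of each.  The expected proportion is
#' the mean over simulations; significance is a two-sided Fisher's exact
#' test of the observed counts against the pooled simulated counts:
#' `[[obs_tx, obs_untx], [sim_tx, nSim*n - sim_tx]]` where `sim_tx` is the
#' total number of transcribed loci over all simulations.  Pooling keeps the
#' expected row at the precision the simulations actually provide; testing
#' against expected counts collapsed to n loci would double the null
#' variance and make the test severely conservative.
#'
#' @param cvs a non-empty [ConsensusVariantSet-class]
#' @param transcribed transcribed regions (`GRanges` or BED-like data.frame
#'   with `contig`, `start`, `end`; transcript spans, not exons)
#' @param genome `DNAStringSet`
#' @param nSim number of random-loci simulations (default 10000)
#' @param seed RNG seed (stored in the result; identical seeds give
#'   identical simulations)
#' @return a [BurdenTestResult-class]
#' @export
burdenTest <- function(cvs, transcribed, genome, nSim = 10000L, seed = 1L) {
  v <- cvs@variants
  if (nrow(v) == 0L) stop("empty variant set: transcribed proportion undefined")
  masks <- .genomeMasks(genome, transcribed)
  inTx <- vapply(seq_len(nrow(v)), function(i) {
    m <- masks[[v$contig[i]]]
    if (is.null(m)) stop("variant contig '", v$contig[i], "' not in genome")
    m$tx[v$pos[i]]
  }, logical(1))
  nV <- nrow(v)
  nT <- sum(inTx)
  # flatten non-N positions across contigs once; draws index into this pool
  txFlat <- unlist(lapply(masks, function(m) m$tx[m$nonN]), use.names = FALSE)
  nPool <- length(txFlat)
  if (nPool < nV) stop("genome has fewer non-N positions than variants")
  expProp <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(nSim), function(s)
      mean(txFlat[sample.int(nPool, nV)]), numeric(1))
  })
  simT <- round(sum(expProp) * nV)
  tab <- matrix(c(nT, nV - nT, simT, nSim * nV - simT),
                nrow = 2L, byrow = TRUE)
  p <- stats::fisher.test(tab)$p.value
  new("BurdenTestResult", nVariants = as.integer(nV),
      nTranscribed = as.integer(nT),
      observedProportion = nT / nV,
      expectedProportions = expProp,
      fisherP = min(p, 1),
      seed = as.integer(seed))
}

#' Overlap consensus variants with predicted off-target sites
#'
#' A variant overlaps a predicted site when its position falls within the
#' site's protospacer interval padded by `pad` nt.
#'
#' @param cvs a [ConsensusVariantSet-class]
#' @param predicted data.frame from [findOfftargets()] (needs `contig`,
#'   `start`, `site`) or any table with `contig`, `start`, `end`
#' @param pad padding in nt (default 0)
#' @return list with `count` (number of overlapping variants) and `pairs`
#'   (data.frame of matched variant/site indices)
#' @export
overlapPredicted <- function(cvs, predicted, pad = 0L) {
  v <- cvs@variants
  if (!"end" %in% names(predicted) && "site" %in% names(predicted))
    predicted$end <- predicted$start + nchar(predicted$site) - 1L
  pairs <- data.frame(variant = integer(), site = integer())
  for (i in seq_len(nrow(v))) {
    hit <- which(predicted$contig == v$contig[i] &
                 predicted$start - pad <= v$pos[i] &
                 predicted$end + pad >= v$pos[i])
    if (length(hit))
      pairs <- rbind(pairs, data.frame(variant = i, site = hit))
  }
  list(count = length(unique(pairs$variant)), pairs = pairs)
}
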