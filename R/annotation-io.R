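#' @include AllClasses.R
NULL

#' Read a genome assembly from FASTA
#'
#' Reads a multi-record FASTA into a [Biostrings::DNAStringSet], normalizing
#' lowercase to uppercase and validating that contig names are unique and
#' non-empty, sequences are non-empty and the alphabet is restricted to
#' A, C, G, T, N.  Record order is preserved.
#'
#' @param path path to a FASTA file
#' @return a `DNAStringSet`, one entry per contig
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "acgt"), fa)
#' readGenome(fa)
#' @export
readGenome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  g <- Biostrings::readDNAStringSet(path)
  if (length(g) == 0L) stop("FASTA format error: no records in ", path)
  # drop any description after the first whitespace, FASTA-header style
  names(g) <- sub("\\s.*$", "", names(g))
  validateGenome(Biostrings::DNAStringSet(toupper(g)))
}

#' Validate a genome assembly
#'
#' @param genome a `DNAStringSet` (or named character vector)
#' @return the validated `DNAStringSet`, invisibly usable downstream
#' @export
validateGenome <- function(genome) {
  if (!is(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(toupper(genome))
  nm <- names(genome)
  if (is.null(nm) || any(!nzchar(nm)))
    stop("FASTA format error: contig names must be non-empty")
  if (anyDuplicated(nm))
    stop("FASTA format error: duplicate contig name '",
         nm[duplicated(nm)][1L], "'")
  if (any(Biostrings::width(genome) == 0L))
    stop("FASTA format error: empty sequence for contig '",
         nm[Biostrings::width(genome) == 0L][1L], "'")
  freq <- Biostrings::alphabetFrequency(genome)
  bad <- rowSums(freq[, !colnames(freq) %in% c("A", "C", "G", "T", "N"),
                      drop = FALSE])
  if (any(bad > 0L))
    stop("genome alphabet must be {A,C,G,T,N}; offending contig: '",
         nm[bad > 0L][1L], "'")
  genome
}

#' Write a genome assembly to FASTA
#'
#' @param genome a `DNAStringSet`
#' @param path output path
#' @return `path`, invisibly
#' @export
writeGenome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read transcript models from GFF3
#'
#' Parses a GFF3 with gene/mRNA/exon/CDS features linked by `Parent`
#' attributes into a list of [TranscriptModel-class] objects.  GFF3
#' coordinates are 1-based closed, matching the package's internal
#' convention, so no conversion is applied.  Exon and CDS intervals are
#' grouped per transcript and sorted by genomic start.
#'
#' @param path path to a GFF3 file
#' @param permissive logical; if `FALSE` (default) validation failures
#'   (CDS length not a multiple of 3) are errors
#' @return named list of `TranscriptModel`, names = transcript ids
#' @seealso [writeGFF3()], [splicedCDS()]
#' @export
readGFF3 <- function(path, permissive = FALSE) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  firstParent <- function(p) vapply(p, function(x)
    if (length(x)) x[[1L]] else NA_character_, character(1))
  mrna <- gr[type == "mRNA" | type == "transcript"]
  if (length(mrna) == 0L) stop("GFF3 format error: no mRNA features in ", path)
  mrnaId <- as.character(S4Vectors::mcols(mrna)$ID)
  mrnaGene <- firstParent(S4Vectors::mcols(mrna)$Parent)
  mrnaGene[is.na(mrnaGene)] <- mrnaId[is.na(mrnaGene)]
  out <- list()
  for (i in seq_along(mrna)) {
    tid <- mrnaId[i]
    kids <- gr[!is.na(firstParent(md$Parent)) & firstParent(md$Parent) == tid]
    ktype <- as.character(S4Vectors::mcols(kids)$type)
    ex <- kids[ktype == "exon"]
    cd <- kids[ktype == "CDS"]
    if (length(cd) == 0L) next
    if (length(ex) == 0L) ex <- cd  # CDS-only annotation: exons = CDS
    ord <- order(GenomicRanges::start(ex))
    exI <- IRanges::IRanges(GenomicRanges::start(ex)[ord],
                            GenomicRanges::end(ex)[ord])
    ord <- order(GenomicRanges::start(cd))
    cdI <- IRanges::IRanges(GenomicRanges::start(cd)[ord],
                            GenomicRanges::end(cd)[ord])
    out[[tid]] <- TranscriptModel(
      transcriptId = tid,
      geneId       = mrnaGene[i],
      contig       = as.character(GenomicRanges::seqnames(mrna))[i],
      strand       = as.character(GenomicRanges::strand(mrna))[i],
      exons        = exI, cds = cdI,
      permissive   = permissive)
  }
  orphan <- gr[type == "CDS" & is.na(firstParent(md$Parent))]
  if (length(orphan) > 0L)
    stop("GFF3 format error: CDS feature without a parent mRNA")
  if (length(out) == 0L) stop("GFF3 format error: no transcript with CDS in ", path)
  out
}

#' Write transcript models to GFF3
#'
#' Inverse of [readGFF3()]: emits gene, mRNA, exon and CDS features with
#' `ID`/`Parent` attributes such that re-reading reproduces the same models.
#'
#' @param transcripts list of [TranscriptModel-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeGFF3 <- function(transcripts, path) {
  rows <- list()
  genesSeen <- character()
  for (t in transcripts) {
    gid <- t@geneId; tid <- t@transcriptId
    span <- c(min(IRanges::start(t@exons)), max(IRanges::end(t@exons)))
    if (!gid %in% genesSeen) {
      rows[[length(rows) + 1L]] <- data.frame(
        seqid = t@contig, source = "stopcall", type = "gene",
        start = span[1L], end = span[2L], score = ".", strand = t@strand,
        phase = ".", attributes = sprintf("ID=%s", gid))
      genesSeen <- c(genesSeen, gid)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      seqid = t@contig, source = "stopcall", type = "mRNA",
      start = span[1L], end = span[2L], score = ".", strand = t@strand,
      phase = ".", attributes = sprintf("ID=%s;Parent=%s", tid, gid))
    for (i in seq_along(t@exons))
      rows[[length(rows) + 1L]] <- data.frame(
        seqid = t@contig, source = "stopcall", type = "exon",
        start = IRanges::start(t@exons)[i], end = IRanges::end(t@exons)[i],
        score = ".", strand = t@strand, phase = ".",
        attributes = sprintf("ID=%s.exon%d;Parent=%s", tid, i, tid))
    # CDS phase: bases of the current codon already emitted before this piece
    cdsW <- IRanges::width(t@cds)
    if (t@strand == "+") {
      before <- cumsum(c(0L, cdsW))[seq_along(cdsW)]
    } else {
      before <- rev(cumsum(c(0L, rev(cdsW)))[seq_along(cdsW)])
    }
    phase <- (3L - before %% 3L) %% 3L
    for (i in seq_along(t@cds))
      rows[[length(rows) + 1L]] <- data.frame(
        seqid = t@contig, source = "stopcall", type = "CDS",
        start = IRanges::start(t@cds)[i], end = IRanges::end(t@cds)[i],
        score = ".", strand = t@strand, phase = phase[i],
        attributes = sprintf("ID=%s.cds;Parent=%s", tid, tid))
  }
  df <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Assemble the spliced coding sequence of a transcript
#'
#' Extracts the CDS pieces from the genome, splices them and (for
#' minus-strand transcripts) reverse-complements, producing the CDS in sense
#' orientation together with a per-base coordinate map back to the genome.
#' Under strict validation the translated CDS must begin with a start codon
#' and contain exactly one stop codon, at its end.
#'
#' @param transcript a [TranscriptModel-class]
#' @param genome a `DNAStringSet` from [readGenome()]
#' @param permissive logical; if `TRUE`, start/stop violations warn instead
#'   of erroring
#' @return a [CodingSequence-class]
#' @examples
#' g <- Biostrings::DNAStringSet(c(c1 = "ATGAAATAA"))
#' t <- TranscriptModel("t1", "g1", "c1", "+", cbind(1, 9), cbind(1, 9))
#' as.character(cdsSeq(splicedCDS(t, g)))
#' @export
splicedCDS <- function(transcript, genome, permissive = FALSE) {
  t <- transcript
  if (!t@contig %in% names(genome))
    stop("contig '", t@contig, "' not present in the genome")
  clen <- Biostrings::width(genome)[match(t@contig, names(genome))]
  if (max(IRanges::end(t@exons)) > clen || min(IRanges::start(t@exons)) < 1L)
    stop("transcript '", t@transcriptId, "' extends beyond contig bounds")
  contigSeq <- genome[[t@contig]]
  pieces <- lapply(seq_along(t@cds), function(i)
    as.character(Biostrings::subseq(contigSeq,
                                    IRanges::start(t@cds)[i],
                                    IRanges::end(t@cds)[i])))
  seq <- paste(unlist(pieces), collapse = "")
  pos <- unlist(lapply(seq_along(t@cds), function(i)
    seq.int(IRanges::start(t@cds)[i], IRanges::end(t@cds)[i])))
  if (t@strand == "-") {
    seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    pos <- rev(pos)
  }
  cmap <- data.frame(contig = t@contig, pos = pos, strand = t@strand,
                     stringsAsFactors = FALSE)
  cs <- new("CodingSequence", seq = Biostrings::DNAString(seq),
            coordMap = cmap, transcriptId = t@transcriptId, geneId = t@geneId)
  n <- length(cs@seq)
  if (n %% 3L == 0L && n >= 6L) {
    aa <- as.character(Biostrings::translate(cs@seq, no.init.codon = TRUE))
    bad <- character()
    if (substr(aa, 1L, 1L) != "M")
      bad <- c(bad, "CDS does not begin with a start codon")
    stops <- gregexpr("\\*", aa)[[1L]]
    if (length(stops) != 1L || stops[1L] != nchar(aa))
      bad <- c(bad, "CDS must contain exactly one stop codon, at its end")
    if (length(bad)) {
      msg <- paste0("transcript '", t@transcriptId, "': ",
                    paste(bad, collapse = "; "))
      if (permissive) warning(msg) else stop(msg)
    }
  }
  cs
}

#' Map CDS indices to genomic coordinates and back
#'
#' `cdsToGenomic` returns the (contig, pos, strand) rows for CDS indices;
#' `genomicToCds` returns the CDS index for genomic positions (`NA` when the
#' position is not part of the CDS, e.g. intronic).
#'
#' @param cds a [CodingSequence-class]
#' @param i integer CDS indices (1-based)
#' @param contig,pos genomic coordinates to look up
#' @return see description
#' @export
cdsToGenomic <- function(cds, i) {
  stopifnot(all(i >= 1L & i <= nrow(cds@coordMap)))
  cds@coordMap[i, , drop = FALSE]
}

#' @rdname cdsToGenomic
#' @export
genomicToCds <- function(cds, contig, pos) {
  key <- paste0(cds@coordMap$contig, ":", cds@coordMap$pos)
  match(paste0(contig, ":", pos), key)
}

#' Pick the design transcript for each gene
#'
#' The designer defaults to one transcript per gene, the one with the longest
#' CDS (ties broken by transcript id for determinism); `perTranscript = TRUE`
#' keeps all.
#'
#' @param transcripts list of [TranscriptModel-class]
#' @param perTranscript keep every transcript rather than one per gene
#' @return filtered list of transcripts
#' @export
selectDesignTranscripts <- function(transcripts, perTranscript = FALSE) {
  if (perTranscript) return(transcripts)
  genes <- vapply(transcripts, geneId, character(1))
  widths <- vapply(transcripts, cdsWidth, integer(1))
  tids <- vapply(transcripts, transcriptId, character(1))
  keep <- unlist(lapply(split(seq_along(transcripts), genes), function(idx) {
    idx[order(-widths[idx], tids[idx])][1L]
  }))
  transcripts[sort(keep)]
}
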