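#' @include AllClasses.R editor-profiles.R
NULL

# independent RNG stream per generator: the sub-seed depends on (seed, name)
# only, so adding a generator never shifts another generator's stream
.simSeed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer(((as.integer(seed) %% 46337L) * 46337L + h) %% 2147117569L)
}

.randomDNA <- function(n, gc = 0.45) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

.randomNonStopCodon <- function(gc = 0.45) {
  repeat {
    c3 <- paste(.randomDNA(3L, gc), collapse = "")
    if (!c3 %in% c("TAA", "TAG", "TGA")) return(c3)
  }
}

#' Simulate a toy genome with planted editable codons
#'
#' Generates one contig per gene: a coding sequence of random non-stop
#' codons with `plantsPerGene` editable codons (CAA/CAG/CGA) planted at
#' spaced positions, optionally split across exons by introns, embedded in
#' random flanks.  For every planted codon an NGG PAM is engineered at the
#' genomic distance that places the editable C at protospacer position
#' `plantWindowPos` of the default 20-nt protospacer, so each plant is
#' guaranteed reachable by at least one guide under [editorProfile()]
#' defaults; codons broken by the PAM engineering are repaired so the CDS
#' stays stop-free inside.  A fraction of genes is placed on the minus
#' strand by mirroring the whole cassette.
#'
#' @param seed integer seed; fixed seed gives byte-identical output
#' @param nGenes number of genes (= contigs)
#' @param nExonsRange inclusive range of exon counts per gene
#' @param cdsCodonsRange inclusive range of CDS length in codons
#' @param plantsPerGene editable codons planted per gene
#' @param gcFraction genome GC content; 0 leaves no C to plant and is an
#'   error when `plantsPerGene > 0`
#' @param flank flank length around each gene (nt)
#' @param intronRange inclusive range of intron lengths (nt)
#' @param minusStrandFraction probability a gene is placed on the minus
#'   strand
#' @param plantWindowPos protospacer window position of the planted C
#'   (default 6, centre of the BE3 window)
#' @return list with `genome` (`DNAStringSet`), `transcripts` (list of
#'   [TranscriptModel-class]) and `truth` (data.frame of planted codons
#'   with their expected guide placements: `contig`, `transcriptId`,
#'   `codonNumber`, `sourceCodon`, `strand`, `protoStart`, `windowPos`)
#' @export
simulateToyGenome <- function(seed = 1L, nGenes = 5L, nExonsRange = c(1L, 3L),
                              cdsCodonsRange = c(60L, 120L),
                              plantsPerGene = 2L, gcFraction = 0.45,
                              flank = 150L, intronRange = c(60L, 150L),
                              minusStrandFraction = 0.5,
                              plantWindowPos = 6L) {
  if (plantsPerGene > 0L && gcFraction == 0) {
    stop("gcFraction 0 leaves a genome over {A,T}: zero plantable codons")
  }
  L <- 20L; w <- as.integer(plantWindowPos)
  withr::with_seed(.simSeed(seed, "genome"), {
    contigs <- character(nGenes)
    names(contigs) <- sprintf("chr%d", seq_len(nGenes))
    transcripts <- list()
    truthRows <- list()
    for (gi in seq_len(nGenes)) {
      nCodon <- sample(seq.int(cdsCodonsRange[1L], cdsCodonsRange[2L]), 1L)
      if ((nCodon - 9L) < plantsPerGene * 8L)
        stop("infeasible config: CDS of ", nCodon,
             " codons too short for ", plantsPerGene, " planted codons")
      codons <- c("ATG",
                  vapply(seq_len(nCodon - 2L), function(i)
                    .randomNonStopCodon(gcFraction), character(1)),
                  "TAA")
      # plant positions spaced >= 8 codons apart, away from both ends
      avail <- seq.int(3L, nCodon - 8L)
      plantAt <- integer(0)
      for (k in seq_len(plantsPerGene)) {
        ok <- avail[vapply(avail, function(a)
          all(abs(a - plantAt) >= 8L), logical(1))]
        plantAt <- c(plantAt, sample(ok, 1L))
      }
      plantAt <- sort(plantAt)
      plantCodon <- sample(c("CAA", "CAG", "CGA"), plantsPerGene,
                           replace = TRUE)
      codons[plantAt] <- plantCodon
      cdsStr <- paste(codons, collapse = "")
      cdsLen <- nchar(cdsStr)
      # exon structure: split at codon boundaries clear of plant cassettes
      nExons <- sample(seq.int(nExonsRange[1L], nExonsRange[2L]), 1L)
      cutsOK <- setdiff(seq_len(nCodon - 1L),
                        unlist(lapply(plantAt, function(a) (a - 2L):(a + 7L))))
      nCuts <- min(nExons - 1L, length(cutsOK))
      cuts <- sort(sample(cutsOK, nCuts)) * 3L  # CDS nucleotide offsets
      bounds <- c(0L, cuts, cdsLen)
      # assemble the genomic gene region (plus-strand cassette)
      region <- character(0)
      exonReg <- matrix(0L, nrow = length(bounds) - 1L, ncol = 2L)
      cds2reg <- integer(cdsLen)
      for (e in seq_len(length(bounds) - 1L)) {
        piece <- substr(cdsStr, bounds[e] + 1L, bounds[e + 1L])
        exonReg[e, 1L] <- length(region) + 1L
        region <- c(region, strsplit(piece, "")[[1L]])
        exonReg[e, 2L] <- length(region)
        cds2reg[(bounds[e] + 1L):bounds[e + 1L]] <-
          exonReg[e, 1L]:exonReg[e, 2L]
        if (e < length(bounds) - 1L) {
          ilen <- sample(seq.int(intronRange[1L], intronRange[2L]), 1L)
          intron <- .randomDNA(ilen, gcFraction)
          intron[1:2] <- c("G", "T"); intron[(ilen - 1L):ilen] <- c("A", "G")
          region <- c(region, intron)
        }
      }
      # engineer the PAM for each plant in genomic space: the editable C sits
      # at protospacer position w, so GG goes 16..17 nt 3' of it
      for (k in seq_len(plantsPerGene)) {
        p <- cds2reg[(plantAt[k] - 1L) * 3L + 1L]
        gg <- p + (L - w) + c(2L, 3L)
        if (max(gg) > length(region))
          region <- c(region, .randomDNA(max(gg) - length(region), gcFraction))
        region[gg] <- "G"
      }
      # repair exonic codons broken into stops by the PAM engineering
      repeat {
        cdsNow <- paste(region[cds2reg], collapse = "")
        inner <- 2:(nCodon - 1L)
        cNow <- substring(cdsNow, (inner - 1L) * 3L + 1L, inner * 3L)
        bad <- which(cNow %in% c("TAA", "TAG", "TGA"))
        if (length(bad) == 0L) break
        for (b in bad) region[cds2reg[(inner[b] - 1L) * 3L + 1L]] <- "C"
      }
      # embed in flanks
      pre <- .randomDNA(flank, gcFraction)
      post <- .randomDNA(flank, gcFraction)
      contigSeq <- c(pre, region, post)
      exonG <- exonReg + flank
      plantG <- vapply(plantAt, function(a)
        cds2reg[(a - 1L) * 3L + 1L] + flank, integer(1))
      W <- length(contigSeq)
      strand <- if (stats::runif(1) < minusStrandFraction) "-" else "+"
      if (strand == "-") {
        contigSeq <- rev(chartr("ACGT", "TGCA", contigSeq))
        exonG <- cbind(W - exonG[, 2L] + 1L, W - exonG[, 1L] + 1L)
        exonG <- exonG[order(exonG[, 1L]), , drop = FALSE]
        plantG <- W - plantG + 1L
      }
      ct <- names(contigs)[gi]
      contigs[gi] <- paste(contigSeq, collapse = "")
      tid <- sprintf("tx%d", gi)
      transcripts[[tid]] <- TranscriptModel(
        transcriptId = tid, geneId = sprintf("gene%d", gi),
        contig = ct, strand = strand, exons = exonG, cds = exonG)
      protoStrand <- strand  # sense rules: protospacer on the coding strand
      protoStart <- if (protoStrand == "+") plantG - w + 1L
                    else plantG + w - L
      truthRows[[gi]] <- data.frame(
        contig = ct, transcriptId = tid, codonNumber = plantAt,
        sourceCodon = plantCodon, strand = protoStrand,
        protoStart = protoStart, windowPos = w, stringsAsFactors = FALSE)
    }
    list(genome = Biostrings::DNAStringSet(contigs),
         transcripts = transcripts,
         truth = do.call(rbind, truthRows))
  })
}

#' Simulate edited amplicon reads with known truth
#'
#' Each read independently: with probability `indelRate` it receives one
#' random 1-10 nt insertion or deletion inside the protospacer; otherwise,
#' with probability `convRate` the intended C-to-T edit(s) at the target
#' position(s), and with probability `adjRate` one extra substitution at a
#' random non-target protospacer position.  Uniform sequencing errors are
#' then applied at `errRate` per base.  The realized per-read assignments
#' are returned as truth.
#'
#' @param ref an [AmpliconReference-class]
#' @param nReads number of reads
#' @param convRate,indelRate,adjRate,errRate rates in \[0,1\]
#' @param seed integer seed
#' @return list with `reads` (character vector) and `truth` (list:
#'   requested rates plus realized counts `nIndel`, `nConverted`,
#'   `nAdjacent` — conversion/adjacent counts are over non-indel reads,
#'   matching the quantifier's denominators)
#' @export
simulateAmpliconReads <- function(ref, nReads = 5000L, convRate = 0.3,
                                  indelRate = 0.1, adjRate = 0.05,
                                  errRate = 0, seed = 1L) {
  stopifnot(all(c(convRate, indelRate, adjRate, errRate) >= 0),
            all(c(convRate, indelRate, adjRate, errRate) <= 1))
  refStr <- as.character(ref@seq)
  n <- nchar(refStr)
  ps <- ref@protospacer[1L]; pe <- ref@protospacer[2L]
  targets <- ref@targetPositions
  nonTarget <- setdiff(ps:pe, targets)
  bases <- c("A", "C", "G", "T")
  withr::with_seed(.simSeed(seed, "amplicon"), {
    isIndel <- stats::runif(nReads) < indelRate
    isConv <- !isIndel & stats::runif(nReads) < convRate
    isAdj <- !isIndel & stats::runif(nReads) < adjRate
    reads <- character(nReads)
    for (i in seq_len(nReads)) {
      b <- strsplit(refStr, "")[[1L]]
      if (isIndel[i]) {
        len <- sample(1:10, 1L)
        at <- sample(ps:pe, 1L)
        if (stats::runif(1) < 0.5) {
          b <- b[-(at:min(n, at + len - 1L))]                 # deletion
        } else {
          b <- append(b, sample(bases, len, replace = TRUE), after = at)
        }
      } else {
        if (isConv[i]) b[targets] <- "T"
        if (isAdj[i]) {
          at <- sample(nonTarget, 1L)
          b[at] <- sample(setdiff(bases, b[at]), 1L)
        }
      }
      if (errRate > 0) {
        hit <- which(stats::runif(length(b)) < errRate)
        for (h in hit) b[h] <- sample(setdiff(bases, b[h]), 1L)
      }
      reads[i] <- paste(b, collapse = "")
    }
    list(reads = reads,
         truth = list(convRate = convRate, indelRate = indelRate,
                      adjRate = adjRate, errRate = errRate,
                      nIndel = sum(isIndel), nConverted = sum(isConv),
                      nAdjacent = sum(isAdj), nReads = nReads))
  })
}

#' Simulate three variant-caller tables with planted truth
#'
#' Planted true variants appear in all three caller tables (with per-caller
#' allele-frequency jitter); each caller additionally reports private false
#' positives at positions disjoint from the truth and from the other
#' callers.
#'
#' @param genome `DNAStringSet`
#' @param nPlanted number of true variants
#' @param indelFraction fraction of true variants that are indels
#' @param afRange uniform range the true allele frequencies are drawn from
#' @param fpPerCaller private false positives per caller
#' @param afJitterSd per-caller AF jitter s.d. (clamped to \[0,1\])
#' @param seed integer seed
#' @return list with `callsets` (named list of three data.frames) and
#'   `truth` (data.frame of planted variants with their mean AF)
#' @export
simulateCallsets <- function(genome, nPlanted = 50L, indelFraction = 0.2,
                             afRange = c(0.15, 0.9), fpPerCaller = 10L,
                             afJitterSd = 0.02, seed = 1L) {
  widths <- Biostrings::width(genome)
  cum <- cumsum(widths)
  bases <- c("A", "C", "G", "T")
  flatToVar <- function(flat, af, indel) {
    ci <- findInterval(flat - 1L, c(0L, cum)) # contig index
    pos <- flat - c(0L, cum)[ci]
    ct <- names(genome)[ci]
    refB <- substr(as.character(genome[[ci]]), pos, pos)
    if (refB == "N") refB <- "A"
    if (!indel) {
      alt <- sample(setdiff(bases, refB), 1L)
      data.frame(contig = ct, pos = pos, ref = refB, alt = alt, af = af,
                 stringsAsFactors = FALSE)
    } else if (stats::runif(1) < 0.5) {
      ins <- paste(sample(bases, sample(1:3, 1L), replace = TRUE),
                   collapse = "")
      data.frame(contig = ct, pos = pos, ref = refB,
                 alt = paste0(refB, ins), af = af, stringsAsFactors = FALSE)
    } else {
      dlen <- sample(1:3, 1L)
      dend <- min(pos + dlen, widths[ci])
      refD <- substr(as.character(genome[[ci]]), pos, dend)
      data.frame(contig = ct, pos = pos, ref = refD,
                 alt = substr(refD, 1L, 1L), af = af, stringsAsFactors = FALSE)
    }
  }
  withr::with_seed(.simSeed(seed, "callsets"), {
    total <- nPlanted + 3L * fpPerCaller
    flat <- sample.int(sum(widths) - 5L, total)
    trueFlat <- flat[seq_len(nPlanted)]
    trueIndel <- stats::runif(nPlanted) < indelFraction
    trueAF <- stats::runif(nPlanted, afRange[1L], afRange[2L])
    truth <- if (nPlanted > 0L)
      do.call(rbind, lapply(seq_len(nPlanted), function(i)
        flatToVar(trueFlat[i], trueAF[i], trueIndel[i])))
    else
      data.frame(contig = character(), pos = integer(), ref = character(),
                 alt = character(), af = numeric(), stringsAsFactors = FALSE)
    truth$type <- ifelse(nchar(truth$ref) == 1L & nchar(truth$alt) == 1L,
                         "SNV", "indel")
    if (nrow(truth) == 0L) truth$type <- character(0)
    callsets <- list()
    for (j in 1:3) {
      tab <- truth[, c("contig", "pos", "ref", "alt", "af")]
      tab$af <- pmin(1, pmax(0, tab$af + stats::rnorm(nPlanted, 0, afJitterSd)))
      if (fpPerCaller > 0L) {
        fpFlat <- flat[nPlanted + (j - 1L) * fpPerCaller + seq_len(fpPerCaller)]
        fp <- do.call(rbind, lapply(fpFlat, function(fl)
          flatToVar(fl, stats::runif(1, 0.05, 0.6), FALSE)))
        tab <- rbind(tab, fp[, c("contig", "pos", "ref", "alt", "af")])
      }
      tab <- tab[order(tab$contig, tab$pos), ]
      rownames(tab) <- NULL
      tab$type <- ifelse(nchar(tab$ref) == 1L & nchar(tab$alt) == 1L,
                         "SNV", "indel")
      callsets[[sprintf("caller%d", j)]] <- tab
    }
    list(callsets = callsets, truth = truth)
  })
}

#' Simulate replicate methylomes with planted hypermethylated elements
#'
#' For each element, CpG positions are placed uniformly inside the element;
#' each replicate draws an element-level methylation mean (group mean plus
#' Normal noise `repSd`, clamped to \[0,1\]), per-CpG levels around it, and
#' binomial methylated counts at a coverage drawn uniformly from
#' `covRange` (so the configured coverage floor is always respected).
#' Elements listed in `hyperIds` get `baseLevel + delta` in group A.
#'
#' @param elements data.frame with `id`, `contig`, `start`, `end`
#' @param hyperIds element ids planted as hypermethylated in group A
#' @param delta planted group-mean difference (default 0.45)
#' @param baseLevel group-B (and null group-A) mean level (default 0.2)
#' @param repSd replicate-level noise s.d. (default 0.05)
#' @param cpgSd per-CpG level noise s.d. (default 0.02)
#' @param nReps replicates per group (default 3)
#' @param nCpgRange CpGs per element, uniform range
#' @param covRange per-CpG coverage, uniform range (floor >= 3 keeps every
#'   CpG usable at the 3X threshold)
#' @param seed integer seed
#' @return list with `groupA`, `groupB` (lists of per-replicate CpG tables)
#'   and `truth` (data.frame `id`, `hyper`)
#' @export
simulateMethylomes <- function(elements, hyperIds = character(),
                               delta = 0.45, baseLevel = 0.2, repSd = 0.05,
                               cpgSd = 0.02, nReps = 3L,
                               nCpgRange = c(6L, 14L), covRange = c(5L, 30L),
                               seed = 1L) {
  clamp <- function(x) pmin(1, pmax(0, x))
  withr::with_seed(.simSeed(seed, "methylome"), {
    nEl <- nrow(elements)
    nCpg <- sample(seq.int(nCpgRange[1L], nCpgRange[2L]), nEl, replace = TRUE)
    cpgPos <- lapply(seq_len(nEl), function(i)
      sort(sample(seq.int(elements$start[i], elements$end[i]),
                  nCpg[i])))
    isHyper <- elements$id %in% hyperIds
    mkRep <- function(groupMeans) {
      rows <- lapply(seq_len(nEl), function(i) {
        lev <- clamp(groupMeans[i] + stats::rnorm(1, 0, repSd))
        cl <- clamp(lev + stats::rnorm(nCpg[i], 0, cpgSd))
        cov <- sample(seq.int(covRange[1L], covRange[2L]), nCpg[i],
                      replace = TRUE)
        meth <- stats::rbinom(nCpg[i], cov, cl)
        data.frame(contig = elements$contig[i], pos = cpgPos[[i]],
                   meth = meth, unmeth = cov - meth, stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    }
    meansA <- ifelse(isHyper, clamp(baseLevel + delta), baseLevel)
    meansB <- rep(baseLevel, nEl)
    list(groupA = lapply(seq_len(nReps), function(r) mkRep(meansA)),
         groupB = lapply(seq_len(nReps), function(r) mkRep(meansB)),
         truth = data.frame(id = elements$id, hyper = isHyper,
                            stringsAsFactors = FALSE))
  })
}

#' Write simulated inputs for an end-to-end run
#'
#' Writes the standard file formats for one of four presets so every
#' command-line workflow can run offline: `design` (FASTA + GFF3 + truth
#' TSV), `amplicon` (reference FASTA + FASTQ reads), `goit` (genome FASTA,
#' three VCFs, transcribed-region BED, known-sites BED), `meth` (per-replicate
#' CpG TSVs + elements BED).
#'
#' @param preset one of `"design"`, `"amplicon"`, `"goit"`, `"meth"`
#' @param seed integer seed
#' @param dir output directory (created if needed)
#' @return character vector of written paths, invisibly
#' @export
simulatePreset <- function(preset = c("design", "amplicon", "goit", "meth"),
                           seed = 1L, dir = ".") {
  preset <- match.arg(preset)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(dir, f)
  written <- character()
  if (preset == "design") {
    sim <- simulateToyGenome(seed)
    writeGenome(sim$genome, pth("genome.fa"))
    writeGFF3(sim$transcripts, pth("annotation.gff3"))
    utils::write.table(sim$truth, pth("planted_truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    written <- pth(c("genome.fa", "annotation.gff3", "planted_truth.tsv"))
  } else if (preset == "amplicon") {
    ref <- .presetAmpliconRef(seed)
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(stats::setNames(as.character(ref@seq),
                                               "amplicon")),
      pth("amplicon.fa"))
    sim <- simulateAmpliconReads(ref, seed = seed)
    con <- file(pth("reads.fastq"), "w")
    for (i in seq_along(sim$reads))
      writeLines(c(sprintf("@read%d", i), sim$reads[i], "+",
                   strrep("I", nchar(sim$reads[i]))), con)
    close(con)
    written <- pth(c("amplicon.fa", "reads.fastq"))
  } else if (preset == "goit") {
    sim <- simulateToyGenome(seed, nGenes = 3L)
    writeGenome(sim$genome, pth("genome.fa"))
    tx <- do.call(rbind, lapply(sim$transcripts, function(t) data.frame(
      contig = t@contig, start = min(IRanges::start(t@exons)) - 1L,
      end = max(IRanges::end(t@exons)), id = t@transcriptId)))
    utils::write.table(tx, pth("transcribed.bed"), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    cs <- simulateCallsets(sim$genome, seed = seed)
    for (j in 1:3)
      writeVariantVCF(cs$callsets[[j]], pth(sprintf("caller%d.vcf", j)))
    utils::write.table(
      data.frame(contig = cs$truth$contig[1L],
                 start = cs$truth$pos[1L] - 1L, end = cs$truth$pos[1L]),
      pth("known.bed"), sep = "\t", quote = FALSE, row.names = FALSE,
      col.names = FALSE)
    written <- pth(c("genome.fa", "transcribed.bed", "caller1.vcf",
                     "caller2.vcf", "caller3.vcf", "known.bed"))
  } else {
    elements <- data.frame(
      id = sprintf("el%d", 1:40), contig = "chr1",
      start = seq(1L, by = 2000L, length.out = 40L),
      end = seq(1500L, by = 2000L, length.out = 40L))
    sim <- simulateMethylomes(elements, hyperIds = sprintf("el%d", 1:10),
                              seed = seed)
    for (g in c("groupA", "groupB"))
      for (r in seq_along(sim[[g]])) {
        f <- pth(sprintf("%s_rep%d.tsv", g, r))
        utils::write.table(sim[[g]][[r]], f, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        written <- c(written, f)
      }
    utils::write.table(
      data.frame(elements$contig, elements$start - 1L, elements$end,
                 elements$id),
      pth("elements.bed"), sep = "\t", quote = FALSE, row.names = FALSE,
      col.names = FALSE)
    written <- c(written, pth("elements.bed"))
  }
  invisible(written)
}

# fixed-layout amplicon used by the amplicon preset: protospacer at 51-70
# with the target C at protospacer position 6
.presetAmpliconRef <- function(seed) {
  withr::with_seed(.simSeed(seed, "ampliconRef"), {
    b <- .randomDNA(120L, 0.45)
    b[56L] <- "C"           # target
    b[71:73] <- c("A", "G", "G")  # PAM
    AmpliconReference(paste(b, collapse = ""), c(51L, 70L), 56L)
  })
}
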