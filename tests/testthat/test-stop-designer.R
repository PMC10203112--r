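test_that("editable codons are enumerated with the correct conversion rules", {
  mg <- miniGene("ATGCAGAAATAA")
  e <- enumerateStopCodons(splicedCDS(mg$transcript, mg$genome))
  expect_equal(nrow(e), 1L)
  expect_equal(e$codonNumber, 2L)
  expect_equal(e$sourceCodon, "CAG")
  expect_equal(e$resultCodon, "TAG")
  expect_equal(e$editStrand, "sense")
  expect_equal(e$codonPositions[[1L]], 1L)

  mg <- miniGene("ATGTGGAAATAA")
  e <- enumerateStopCodons(splicedCDS(mg$transcript, mg$genome))
  expect_equal(nrow(e), 3L)  # TAG, TGA single edits + canonical TAA double
  expect_setequal(e$resultCodon, c("TAG", "TGA", "TAA"))
  taa <- e[e$resultCodon == "TAA", ]
  expect_equal(taa$codonPositions[[1L]], c(2L, 3L))
  expect_true(taa$canonical)
  expect_true(all(e$editStrand == "antisense"))
  e2 <- enumerateStopCodons(splicedCDS(mg$transcript, mg$genome),
                            canonicalOnly = TRUE)
  expect_equal(e2$resultCodon, "TAA")

  mg <- miniGene("ATGAAATAA")
  e <- enumerateStopCodons(splicedCDS(mg$transcript, mg$genome))
  expect_equal(nrow(e), 0L)

  # start codon and native stop are never editable: CAA at codon 1 cannot
  # exist (start is ATG) and the terminal TAA stays untouched by design
  expect_true(all(e$codonNumber > 1L))
})

test_that("applying each rule to its source codon yields the stated stop codon", {
  r <- stopConversionRules()
  for (i in seq_len(nrow(r))) {
    got <- stopcall:::.applyRuleToCodon(r$sourceCodon[i], r$editStrand[i],
                                        r$codonPositions[[i]])
    expect_equal(got, r$resultCodon[i])
    expect_true(got %in% c("TAA", "TAG", "TGA"))
  }
})

# hand-built gene: flank of 30 T's, then ATG CAG AAA AAA AAA AAA AAG GAA TAA;
# the editable C sits at contig position 34, 16 nt 5' of an AGG PAM at 50-52,
# i.e. protospacer window position 5 of the single valid placement
.pamGene <- function(codon7 = "AAG", codon8 = "GAA", codon6 = "AAA") {
  cds <- paste0("ATGCAG", "AAAAAAAAA", codon6, codon7, codon8, "TAA")
  contig <- paste0(strrep("T", 30), cds, strrep("T", 20))
  genome <- Biostrings::DNAStringSet(c(c1 = contig))
  t <- TranscriptModel("t1", "g1", "c1", "+",
                       exons = cbind(31L, 30L + nchar(cds)),
                       cds = cbind(31L, 30L + nchar(cds)))
  list(genome = genome, transcript = t)
}

test_that("guide placement requires a PAM and an in-window editable C", {
  g <- .pamGene()
  expect_equal(substr(as.character(g$genome[[1]]), 50, 52), "AGG")
  cand <- findGuides(g$transcript, g$genome, editorProfile("BE3"))
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$start, 30L)
  expect_equal(cand$strand, "+")
  expect_equal(cand$pam, "AGG")
  expect_equal(cand$requiredPositions[[1L]], 5L)
  expect_equal(cand$codonNumber, 2L)
  expect_equal(cand$resultCodon, "TAG")
  expect_equal(nrow(cand$bystanders[[1L]]), 0L)  # no extra window C

  # PAM destroyed (AGG -> ATG via the middle base) -> no candidate
  g2 <- .pamGene(codon7 = "AAT")
  cand2 <- findGuides(g2$transcript, g2$genome, editorProfile("BE3"))
  expect_equal(nrow(cand2), 0L)

  # PAM placed so the C falls at window position 9 -> no candidate
  g3 <- .pamGene(codon6 = "AGG", codon7 = "AAA", codon8 = "AAA")
  cand3 <- findGuides(g3$transcript, g3$genome, editorProfile("BE3"))
  expect_equal(nrow(cand3), 0L)
})

test_that("bystander cytosines are classified by their codon consequence", {
  # missense: extra window C's of a CCA codon (CCA->CTA, Pro->Leu)
  cds <- paste0("ATG", "AAA", "CAG", "CCA", "AAA", "AAA", "AAA", "AAA",
                "GGA", "TAA")
  contig <- paste0(strrep("T", 30), cds, strrep("T", 20))
  genome <- Biostrings::DNAStringSet(c(c1 = contig))
  t <- TranscriptModel("t1", "g1", "c1", "+",
                       exons = cbind(31L, 30L + nchar(cds)),
                       cds = cbind(31L, 30L + nchar(cds)))
  cand <- findGuides(t, genome, editorProfile("BE3"))
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$requiredPositions[[1L]], 4L)
  by <- cand$bystanders[[1L]]
  expect_equal(nrow(by), 2L)
  leu <- by[by$altCodon == "CTA", ]
  expect_equal(leu$refCodon, "CCA")
  expect_equal(leu$consequence, "missense")
  expect_equal(leu$refAA, "P")
  expect_equal(leu$altAA, "L")
  expect_true(all(by$consequence == "missense"))

  # silent: extra window C in the third position of GGC (GGC->GGT)
  cds <- paste0("ATG", "GGC", "CAG", "AAA", "AAA", "AAA", "AAG", "GAA", "TAA")
  contig <- paste0(strrep("T", 30), cds, strrep("T", 20))
  genome <- Biostrings::DNAStringSet(c(c1 = contig))
  t <- TranscriptModel("t1", "g1", "c1", "+",
                       exons = cbind(31L, 30L + nchar(cds)),
                       cds = cbind(31L, 30L + nchar(cds)))
  cand <- findGuides(t, genome, editorProfile("BE3"))
  expect_equal(nrow(cand), 1L)
  by <- cand$bystanders[[1L]]
  expect_equal(nrow(by), 1L)
  expect_equal(by$refCodon, "GGC")
  expect_equal(by$altCodon, "GGT")
  expect_equal(by$consequence, "silent")
})

test_that("the efficiency heuristic evaluates its documented formula", {
  p <- editorProfile("BE3")  # window [4,8], centre 6
  proto <- function(ctx5) {
    b <- rep("A", 20); b[6] <- "C"; b[5] <- ctx5
    paste(b, collapse = "")
  }
  expect_equal(scoreGuide(proto("T"), 6L, p), 1.0)
  expect_equal(scoreGuide(proto("G"), 6L, p), 0.5)
  expect_equal(scoreGuide(proto("C"), 6L, p), 0.9)
  # two required edits at 6 and 7: pos weights 1 and 2/3, contexts T and C,
  # multi-edit penalty 0.8
  b <- rep("A", 20); b[5] <- "T"; b[6] <- "C"; b[7] <- "C"
  expect_equal(scoreGuide(paste(b, collapse = ""), c(6L, 7L), p),
               1 * 1.0 * (2 / 3) * 0.9 * 0.8)
  # bounded in [0,1] over arbitrary cases
  set.seed(99)
  for (i in 1:20) {
    pr <- paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = "")
    rp <- sort(sample(4:8, sample(1:2, 1)))
    s <- scoreGuide(pr, rp, p)
    expect_gte(s, 0); expect_lte(s, 1)
  }
})

test_that("ranking sorts by off-targets, then score, truncation, coordinate, stably", {
  base <- data.frame(
    transcriptId = "t", contig = "c1", start = c(10L, 20L, 30L, 40L),
    efficiencyScore = c(0.5, 0.9, 0.9, 0.2),
    truncationFraction = c(0.1, 0.5, 0.2, 0.1),
    offtargets2mm = c(3L, 0L, 0L, 0L))
  r <- rankGuides(base)
  # fewest 2-mismatch off-targets first; among ties higher score; among those
  # smaller truncation fraction
  expect_equal(r$start, c(30L, 20L, 40L, 10L))
  # stable: identical keys preserve input order
  same <- data.frame(contig = "c1", start = c(5L, 5L, 5L),
                     efficiencyScore = 0.5, truncationFraction = 0.5,
                     offtargets2mm = 1L, tag = c("a", "b", "c"))
  expect_equal(rankGuides(same)$tag, c("a", "b", "c"))
  expect_error(rankGuides(base[, -6]), "offtargets2mm")
})

test_that("every emitted candidate truncates the protein at the reported codon", {
  for (seed in c(101, 202)) {
    sim <- simulateToyGenome(seed = seed, nGenes = 4)
    for (t in sim$transcripts) {
      cs <- splicedCDS(t, sim$genome)
      cand <- findGuides(t, sim$genome, editorProfile("BE3"))
      expect_gt(nrow(cand), 0L)
      for (i in seq_len(nrow(cand))) {
        edited <- applyGuideEdits(cand[i, ], cs)
        aa <- oracleTranslate(edited)
        firstStop <- regexpr("*", aa, fixed = TRUE)[1L]
        expect_equal(firstStop, cand$codonNumber[i])
        expect_equal(substr(edited, (cand$codonNumber[i] - 1L) * 3L + 1L,
                            cand$codonNumber[i] * 3L),
                     cand$resultCodon[i])
        expect_lt(cand$codonNumber[i], cand$nCodons[i])
        expect_gte(cand$truncationFraction[i], 0)
        expect_lt(cand$truncationFraction[i], 1)
      }
    }
  }
})

test_that("candidate sets equal the brute-force all-window oracle", {
  sim <- simulateToyGenome(seed = 303, nGenes = 5)
  for (t in sim$transcripts) {
    cand <- findGuides(t, sim$genome, editorProfile("BE3"), bystanders = FALSE)
    expect_equal(guideKeys(cand),
                 oracleGuides(t, sim$genome, editorProfile("BE3")))
  }
})

test_that("design is symmetric under genome mirroring", {
  sim <- simulateToyGenome(seed = 404, nGenes = 3)
  mir <- mirrorAssembly(sim$genome, sim$transcripts)
  for (tid in names(sim$transcripts)) {
    a <- findGuides(sim$transcripts[[tid]], sim$genome,
                    editorProfile("BE3"), bystanders = FALSE)
    b <- findGuides(mir$transcripts[[tid]], mir$genome,
                    editorProfile("BE3"), bystanders = FALSE)
    expect_equal(nrow(a), nrow(b))
    W <- Biostrings::width(sim$genome)[match(tid, names(sim$transcripts))]
    W <- Biostrings::width(sim$genome)[[match(contigName(sim$transcripts[[tid]]),
                                              names(sim$genome))]]
    # map mirrored placements back: start' = W - end + 1, strand flipped
    bMapped <- b
    bMapped$start <- W - (b$start + 19L) + 1L
    bMapped$strand <- ifelse(b$strand == "+", "-", "+")
    expect_setequal(guideKeys(bMapped), guideKeys(a))
  }
})

test_that("guide tables export to TSV and BED6", {
  sim <- simulateToyGenome(seed = 7, nGenes = 1)
  t <- sim$transcripts[[1L]]
  cand <- findGuides(t, sim$genome, editorProfile("BE3"))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  bed <- withr::local_tempfile(fileext = ".bed")
  writeGuidesTSV(cand, tsv)
  back <- read.table(tsv, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(nrow(back), nrow(cand))
  writeGuidesBED(cand, bed)
  bb <- read.table(bed, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(nrow(bb), nrow(cand))
  expect_equal(bb$V2, cand$start - 1L)  # BED 0-based starts
  expect_equal(bb$V5, round(1000 * cand$efficiencyScore))
})
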