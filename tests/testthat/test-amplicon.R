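test_that("read alignment is exact for identity and substitution reads", {
  ref <- testAmplicon()
  refStr <- as.character(ampliconSeq(ref))
  al <- alignRead(refStr, ref)
  expect_equal(al$alignedRead, refStr)
  expect_equal(al$alignedRef, refStr)
  expect_equal(al$score, 2 * nchar(refStr))

  edited <- mutateAt(refStr, 56, "T")
  al <- alignRead(edited, ref)
  expect_equal(nchar(al$alignedRead), nchar(refStr))  # gapless
  diffs <- which(strsplit(al$alignedRead, "")[[1L]] !=
                 strsplit(al$alignedRef, "")[[1L]])
  expect_equal(diffs, 56L)
})

test_that("alignment scores match the Gotoh oracle and deletions left-shift", {
  # toy pair exercised against a full dynamic program
  refStr <- "ATGCCGGTTAACCGGATCGATCGAATT"
  ref <- AmpliconReference(mutateAt(refStr, 5, "C"), c(3L, 22L), 5L)
  rs <- as.character(ampliconSeq(ref))
  set.seed(11)
  for (i in 1:8) {
    b <- strsplit(rs, "")[[1L]]
    op <- sample(c("del", "ins", "sub"), 1L)
    at <- sample(5:20, 1L)
    rd <- switch(op,
      del = paste(b[-(at:(at + sample(1:3, 1L) - 1L))], collapse = ""),
      ins = paste(append(b, sample(c("A", "C", "G", "T"), 2L, TRUE), at),
                  collapse = ""),
      sub = mutateAt(rs, at, setdiff(c("A", "C", "G", "T"), b[at])[1L]))
    al <- alignRead(rd, ref)
    expect_equal(al$score, oracleAlignScore(rd, rs))
  }

  # a deletion inside a repeat is reported at its leftmost placement
  rep4 <- "ATGAAAACCCCGGGGTTTTACGCAT"
  refR <- AmpliconReference(mutateAt(rep4, 8, "C"), c(2L, 21L), 8L)
  rrs <- as.character(ampliconSeq(refR))
  rd <- deleteAt(rrs, 13, 3)  # delete 3 of the G run (positions 12-15)
  al <- alignRead(rd, refR)
  gapCols <- which(strsplit(al$alignedRead, "")[[1L]] == "-")
  expect_equal(length(gapCols), 3L)
  refCols <- cumsum(strsplit(al$alignedRef, "")[[1L]] != "-")
  # leftmost equivalent placement of the G-run deletion starts at ref pos 12
  expect_equal(min(refCols[gapCols]), 12L)
  expect_equal(al$score, oracleAlignScore(rd, rrs))
})

test_that("editing metrics match hand counts on constructed read sets", {
  ref <- testAmplicon()
  refStr <- as.character(ampliconSeq(ref))
  intended <- mutateAt(refStr, 56, "T")

  out <- quantifyEdits(rep(intended, 100), ref)
  expect_equal(unname(conversionRate(out)), 1.0)
  expect_equal(indelRate(out), 0.0)
  expect_equal(adjacentRate(out), 0.0)
  expect_equal(unname(classCounts(out)["intended_only"]), 100L)

  # 6 intended + 2 adjacent-mutated (also intended) + 2 in-window deletions:
  # conversion 8/8, indel 2/10, adjacent 2/8
  adj <- mutateAt(intended, 60, "A")
  del <- deleteAt(refStr, 58, 3)
  reads <- c(rep(intended, 6), rep(adj, 2), rep(del, 2))
  out <- quantifyEdits(reads, ref)
  expect_equal(unname(conversionRate(out)), 1.0)
  expect_equal(indelRate(out), 0.2)
  expect_equal(adjacentRate(out), 0.25)
  expect_equal(unname(classCounts(out)),
               c(6L, 2L, 2L, 0L))  # intended, adjacent, indel, unedited

  # read classes always partition the read set
  expect_equal(sum(classCounts(out)), out@nReads)

  # indels outside the quantification window are ignored
  farDel <- deleteAt(refStr, 5, 2)
  out2 <- quantifyEdits(c(rep(intended, 5), farDel), ref)
  expect_equal(indelRate(out2), 0.0)
  expect_equal(unname(conversionRate(out2)), 5 / 6)

  expect_error(quantifyEdits(character(0), ref), "no reads")
})

test_that("per-position base counts cover non-indel reads only", {
  ref <- testAmplicon()
  refStr <- as.character(ampliconSeq(ref))
  intended <- mutateAt(refStr, 56, "T")
  del <- deleteAt(refStr, 58, 3)
  out <- quantifyEdits(c(rep(intended, 4), del), ref)
  pp <- perPositionCounts(out)
  expect_equal(sum(pp[, "56"]), 4L)  # indel read excluded
  expect_equal(unname(pp["T", "56"]), 4L)
})

test_that("simulated reads recover the programmed rates", {
  ref <- testAmplicon()
  sim <- simulateAmpliconReads(ref, nReads = 5000, convRate = 0.30,
                               indelRate = 0.10, adjRate = 0.05, seed = 31)
  out <- quantifyEdits(sim$reads, ref)
  nNon <- 5000 - sim$truth$nIndel
  # the quantifier reproduces the realized assignments exactly at zero
  # sequencing error
  expect_equal(unname(conversionRate(out)), sim$truth$nConverted / nNon)
  expect_equal(indelRate(out), sim$truth$nIndel / 5000)
  expect_equal(adjacentRate(out), sim$truth$nAdjacent / nNon)
  # and the realized rates sit within 3 binomial s.e. of the programmed ones
  expect_lt(abs(unname(conversionRate(out)) - 0.30),
            3 * sqrt(0.30 * 0.70 / nNon))
  expect_lt(abs(indelRate(out) - 0.10), 3 * sqrt(0.10 * 0.90 / 5000))
  expect_lt(abs(adjacentRate(out) - 0.05), 3 * sqrt(0.05 * 0.95 / nNon))
})

test_that("identical inputs give identical outcome tables", {
  ref <- testAmplicon()
  sim <- simulateAmpliconReads(ref, nReads = 300, seed = 5)
  a <- quantifyEdits(sim$reads, ref)
  b <- quantifyEdits(sim$reads, ref)
  expect_identical(conversionRate(a), conversionRate(b))
  expect_identical(perPositionCounts(a), perPositionCounts(b))
  expect_identical(classCounts(a), classCounts(b))
})

test_that("clone-based genotype labels follow the classification rule", {
  ref <- testAmplicon()
  refStr <- as.character(ampliconSeq(ref))
  intended <- mutateAt(refStr, 56, "T")
  other <- deleteAt(refStr, 55, 2)

  g <- classifyGenotype(rep(intended, 14), ref)
  expect_equal(genotypeLabel(g), "homozygous_stop")
  expect_false(g@lowConfidence)

  expect_equal(genotypeLabel(classifyGenotype(rep(refStr, 14), ref)),
               "wildtype")

  g <- classifyGenotype(c(rep(intended, 7), rep(refStr, 7)), ref)
  expect_equal(genotypeLabel(g), "heterozygous")

  g <- classifyGenotype(c(rep(intended, 10), rep(other, 3), refStr), ref)
  expect_equal(genotypeLabel(g), "mosaic")

  # two classes but one below the 25% fraction: mosaic, not heterozygous
  g <- classifyGenotype(c(rep(intended, 13), refStr), ref)
  expect_equal(genotypeLabel(g), "mosaic")

  expect_warning(g <- classifyGenotype(rep(intended, 5), ref), "low-confidence")
  expect_true(g@lowConfidence)
  expect_equal(genotypeLabel(g), "homozygous_stop")

  # a clone with an extra window substitution is 'other', not intended
  extra <- mutateAt(intended, 60, "A")
  calls <- cloneCalls(classifyGenotype(c(rep(intended, 12), extra), ref))
  expect_equal(sum(calls == "other"), 1L)
})

test_that("genotype aggregation reproduces printed homozygosity percentages", {
  expect_equal(aggregateGenotypes(c(rep("homozygous_stop", 9),
                                    rep("mosaic", 7)))$percentHomozygous,
               56.3)
  expect_equal(aggregateGenotypes(rep("homozygous_stop", 16))$percentHomozygous,
               100.0)
  expect_equal(aggregateGenotypes(c(rep("homozygous_stop", 11),
                                    rep("heterozygous", 5)))$percentHomozygous,
               68.8)
  # multi-locus: an embryo counts only when homozygous at every locus
  m <- rbind(c("homozygous_stop", "homozygous_stop"),
             c("homozygous_stop", "mosaic"),
             c("wildtype", "homozygous_stop"))
  expect_equal(aggregateGenotypes(m)$nHomozygous, 1L)
  expect_error(aggregateGenotypes(character(0)), "no embryos")
})

test_that("amplicon reads load from FASTQ and plain text", {
  fq <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "GGTT", "+", "IIII"), fq)
  expect_equal(readAmpliconReads(fq), c(r1 = "ACGT", r2 = "GGTT"),
               ignore_attr = TRUE)
  txt <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("acgt", "", "GGTT"), txt)
  expect_equal(readAmpliconReads(txt), c("ACGT", "GGTT"))
})
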