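.cpg <- function(contig, pos, meth, unmeth) {
  data.frame(contig = contig, pos = as.integer(pos), meth = as.integer(meth),
             unmeth = as.integer(unmeth), stringsAsFactors = FALSE)
}

test_that("tile methylation applies the coverage and CpG-count gates", {
  # 3 CpGs in one tile at levels 1.0, 0.5, 0.0, each at >= 3X
  cpgs <- .cpg("c1", c(100, 200, 300), c(4, 2, 0), c(0, 2, 5))
  t <- tileMethylation(cpgs)
  expect_equal(nrow(t), 1L)
  expect_equal(t$tileStart, 1L)
  expect_equal(t$tileEnd, 1000L)
  expect_equal(t$nCpg, 3L)
  expect_equal(t$level, 0.5)

  # 2 usable CpGs: tile reported but undefined
  t <- tileMethylation(.cpg("c1", c(100, 200), c(3, 3), c(0, 0)))
  expect_true(is.na(t$level))
  expect_equal(t$nCpg, 2L)

  # a CpG at 2X is excluded before tiling
  cpgs <- .cpg("c1", c(100, 200, 300, 400), c(4, 2, 0, 1), c(0, 2, 5, 1))
  t <- tileMethylation(cpgs)
  expect_equal(t$nCpg, 3L)
  expect_equal(t$level, 0.5)

  # fixed grid: position 1000 belongs to tile [1,1000], 1001 to [1001,2000]
  t <- tileMethylation(.cpg("c1", c(998, 999, 1000, 1001), 3, 0))
  expect_equal(t$tileStart, c(1L, 1001L))
  expect_equal(t$nCpg, c(3L, 1L))

  expect_error(tileMethylation(.cpg("c1", 1, -1, 5)), "negative")
})

test_that("tile methylation is invariant to record order", {
  set.seed(4)
  cpgs <- .cpg(sample(c("c1", "c2"), 60, TRUE),
               sample(1:5000, 60), sample(0:9, 60, TRUE),
               sample(0:9, 60, TRUE))
  a <- tileMethylation(cpgs)
  b <- tileMethylation(cpgs[sample(nrow(cpgs)), ])
  expect_equal(a, b)
})

test_that("sample similarity is the min-max normalized distance complement", {
  # hand-computed 3-sample example: distances d12 = 0.1, d13 ~ 1.7349,
  # d23 ~ 1.6763; s = 1 - (d - dmin)/(dmax - dmin)
  m <- rbind(s1 = c(0, 0, 0), s2 = c(0, 0, 0.1), s3 = c(1, 1, 1))
  s <- sampleSimilarity(m)
  d12 <- 0.1; d13 <- sqrt(3); d23 <- sqrt(1 + 1 + 0.81)
  expect_equal(s["s1", "s2"], 1.0)                     # closest pair
  expect_equal(s["s1", "s3"], 0.0)                     # most distant pair
  expect_equal(s["s2", "s3"], 1 - (d23 - d12) / (d13 - d12))
  expect_equal(s, t(s))
  expect_equal(unname(diag(s)), rep(1, 3))
  expect_true(all(s >= 0 & s <= 1))

  # duplicate samples among >= 3 score exactly 1
  m2 <- rbind(a = c(0.2, 0.4), b = c(0.2, 0.4), c = c(0.9, 0.9))
  s2 <- sampleSimilarity(m2)
  expect_equal(s2["a", "b"], 1.0)

  # tiles undefined in any sample are dropped listwise
  m3 <- cbind(m, c(NA, 0.5, 0.5))
  expect_equal(sampleSimilarity(m3), s)

  # degenerate: all pairwise distances equal (single pair)
  m4 <- rbind(a = c(0, 0), b = c(1, 0))
  expect_warning(s4 <- sampleSimilarity(m4), "equal")
  expect_true(all(s4 == 1))

  expect_error(sampleSimilarity(m[1, , drop = FALSE]), "two samples")
})

test_that("promoters are TSS +/- 2 kb honoring strand", {
  g <- Biostrings::DNAStringSet(c(c1 = strrep("A", 20000)))
  tp <- TranscriptModel("tp", "g1", "c1", "+", cbind(10000L, 12000L),
                        cbind(10000L, 12000L), permissive = TRUE)
  tm <- TranscriptModel("tm", "g2", "c1", "-", cbind(10000L, 12000L),
                        cbind(10000L, 12000L), permissive = TRUE)
  pr <- promoterRegions(list(tp, tm))
  plus <- pr[pr$id == "tp_promoter", ]
  expect_equal(c(plus$start, plus$end), c(8000L, 12000L))    # TSS at 10000
  minus <- pr[pr$id == "tm_promoter", ]
  expect_equal(c(minus$start, minus$end), c(10000L, 14000L)) # TSS at 12000
  # clipping at the contig origin
  t0 <- TranscriptModel("t0", "g3", "c1", "+", cbind(500L, 1000L),
                        cbind(500L, 1000L), permissive = TRUE)
  p0 <- promoterRegions(list(t0))
  expect_equal(p0$start, 1L)
})

test_that("element methylation averages usable CpGs within the element", {
  el <- data.frame(id = c("e1", "e2"), contig = "c1",
                   start = c(100L, 1000L), end = c(500L, 1200L))
  cpgs <- .cpg("c1", c(150, 200, 300, 400, 1100), c(0, 0, 5, 5, 2),
               c(5, 5, 0, 0, 1))
  em <- elementMethylation(cpgs, el)
  expect_equal(em$level[em$id == "e1"], 0.5)   # {0,0,1,1}
  expect_equal(em$nCpg[em$id == "e1"], 4L)
  expect_true(is.na(em$level[em$id == "e2"]))  # single usable CpG < 3
})

test_that("hypermethylated elements require a >30% difference at p<0.05, strictly", {
  el <- data.frame(id = c("hyper", "boundary", "null"), contig = "c1",
                   start = c(1L, 1000L, 2000L), end = c(500L, 1500L, 2500L))
  mkRep <- function(levels) {
    el2 <- el
    el2$nCpg <- 5L
    el2$level <- levels
    el2
  }
  gA <- list(mkRep(c(0.80, 0.50, 0.20)), mkRep(c(0.83, 0.50, 0.22)),
             mkRep(c(0.77, 0.50, 0.18)))
  gB <- list(mkRep(c(0.10, 0.20, 0.20)), mkRep(c(0.13, 0.20, 0.22)),
             mkRep(c(0.07, 0.20, 0.18)))
  hc <- callHypermethylated(gA, gB)
  expect_true(hc$isHyper[hc$id == "hyper"])
  # the boundary element differs by exactly 0.30 with zero variance: the
  # strict '>' keeps it out even at p = 0
  expect_equal(hc$difference[hc$id == "boundary"], 0.30)
  expect_equal(hc$pValue[hc$id == "boundary"], 0)
  expect_false(hc$isHyper[hc$id == "boundary"])
  expect_false(hc$isHyper[hc$id == "null"])

  # identical groups: zero-variance equal means give p = 1, no calls
  hc2 <- callHypermethylated(gA, gA)
  expect_false(any(hc2$isHyper))
  expect_equal(hc2$pValue[hc2$id == "boundary"], 1)

  # elements without two defined replicates per group are skipped
  gA2 <- gA
  gA2[[1]]$level[3] <- NA; gA2[[2]]$level[3] <- NA; gA2[[3]]$level[3] <- NA
  expect_warning(hc3 <- callHypermethylated(gA2, gB), "skipped")
  expect_true(is.na(hc3$pValue[hc3$id == "null"]))
})

test_that("planted hypermethylated elements are recovered from simulated methylomes", {
  el <- data.frame(id = sprintf("el%d", 1:40), contig = "chr1",
                   start = seq(1L, by = 2000L, length.out = 40),
                   end = seq(1500L, by = 2000L, length.out = 40))
  hyper <- sprintf("el%d", 1:10)
  sim <- simulateMethylomes(el, hyperIds = hyper, delta = 0.45, repSd = 0.05,
                            seed = 19)
  gA <- lapply(sim$groupA, elementMethylation, elements = el)
  gB <- lapply(sim$groupB, elementMethylation, elements = el)
  hc <- callHypermethylated(gA, gB)
  expect_gte(mean(hc$isHyper[sim$truth$hyper]), 0.9)
  expect_lte(mean(hc$isHyper[!sim$truth$hyper]), 0.07)
})

test_that("CpG tables and element BEDs load with coordinate conversion", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("contig\tpos\tmeth\tunmeth", "c1\t100\t3\t1"), f)
  cp <- readCpGTable(f)
  expect_equal(cp$meth, 3L)
  writeLines(c("c1\t100\t3\t-1"), f)
  expect_error(readCpGTable(f, header = FALSE), "negative")

  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("c1\t99\t200\tmyel", bed)
  el <- readElementsBED(bed)
  expect_equal(el$start, 100L)  # BED 0-based start converted
  expect_equal(el$end, 200L)
  expect_equal(el$id, "myel")
})
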