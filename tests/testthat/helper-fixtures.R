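# shared fixture builders (everything is generated in code)

# single-contig plus-strand gene whose CDS is the whole contig
miniGene <- function(cdsStr, contig = "c1", tid = "t1", gid = "g1",
                     strand = "+") {
  genome <- Biostrings::DNAStringSet(stats::setNames(cdsStr, contig))
  t <- TranscriptModel(tid, gid, contig, strand,
                       exons = cbind(1L, nchar(cdsStr)),
                       cds = cbind(1L, nchar(cdsStr)))
  list(genome = genome, transcript = t)
}

# deterministic amplicon reference: 120 nt, protospacer 51-70, target C at
# amplicon position 56 (protospacer position 6), PAM AGG at 71-73
testAmplicon <- function() {
  set.seed(424242)
  b <- sample(c("A", "C", "G", "T"), 120, replace = TRUE)
  b[56] <- "C"
  b[71:73] <- c("A", "G", "G")
  AmpliconReference(paste(b, collapse = ""), c(51L, 70L), 56L)
}

mutateAt <- function(seq, pos, base) {
  b <- strsplit(seq, "")[[1L]]
  b[pos] <- base
  paste(b, collapse = "")
}

deleteAt <- function(seq, pos, len) {
  b <- strsplit(seq, "")[[1L]]
  paste(b[-(pos:(pos + len - 1L))], collapse = "")
}
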