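Package: stopcall
Title: Guide Design and Outcome Analysis for Stop-Codon-Introducing Cytosine Base Editing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for CRISPR cytosine-base-editor experiments that silence
    genes by converting sense codons (CAA, CAG, CGA on the sense strand; TGG
    via antisense editing) into premature stop codons. Enumerates and ranks
    candidate sgRNAs over whole gene models with bystander amino-acid
    prediction, performs mismatch-tolerant genome-wide off-target search,
    quantifies editing outcomes (C-to-T conversion, indels, adjacent-site
    mutations) and clone-based embryo genotypes from amplicon data, tests
    de-novo variant burden in transcribed regions against random-locus
    simulations with Fisher's exact test, and computes whole-genome
    bisulfite sequencing summaries (1-kb tile methylation, min-max
    normalized sample similarity, element and promoter methylation,
    hypermethylated-element calls). Seeded simulators generate every input
    format with known ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'amplicon.R'
    'annotation-io.R'
    'burden.R'
    'editor-profiles.R'
    'methylation.R'
    'offtarget.R'
    'sim-data.R'
    'stop-designer.R'
    'stopcall-package.R'
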