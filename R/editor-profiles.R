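#' @include AllClasses.R
NULL

#' Construct a base-editor profile
#'
#' @param name profile name
#' @param guideLength protospacer length (nt)
#' @param pamPatterns IUPAC patterns matched immediately 3' of the
#'   protospacer
#' @param window inclusive editing-window bounds `c(lo, hi)` counted from the
#'   PAM-distal (5') end of the protospacer (position 1 = 5'-most)
#' @return a [BaseEditorProfile-class]
#' @export
BaseEditorProfile <- function(name, guideLength = 20L, pamPatterns = "NGG",
                              window = c(4L, 8L)) {
  new("BaseEditorProfile", name = name, guideLength = as.integer(guideLength),
      pamPatterns = toupper(pamPatterns), window = as.integer(window))
}

#' Named base-editor profiles
#'
#' Shipped configurations for common cytosine base editors.  The editing
#' windows and PAM sets are package defaults, declared and versioned here so
#' that designs are reproducible; the canonical BE3-family window is
#' protospacer positions 4-8, the engineered hA3A deaminases use a slightly
#' wider window, and xCas9 relaxes the PAM to NG.
#'
#' @param name one of `"BE3"`, `"BE4"`, `"hA3A-BE3-Y130F"`,
#'   `"hA3A-eBE3-Y130F"`, `"xCas9-BE"`
#' @return a [BaseEditorProfile-class]
#' @examples
#' editorProfile("hA3A-eBE3-Y130F")
#' @export
editorProfile <- function(name = c("BE3", "BE4", "hA3A-BE3-Y130F",
                                   "hA3A-eBE3-Y130F", "xCas9-BE")) {
  name <- match.arg(name)
  switch(name,
    "BE3"             = BaseEditorProfile("BE3", 20L, "NGG", c(4L, 8L)),
    "BE4"             = BaseEditorProfile("BE4", 20L, "NGG", c(4L, 8L)),
    "hA3A-BE3-Y130F"  = BaseEditorProfile("hA3A-BE3-Y130F", 20L, "NGG", c(3L, 8L)),
    "hA3A-eBE3-Y130F" = BaseEditorProfile("hA3A-eBE3-Y130F", 20L, "NGG", c(3L, 8L)),
    "xCas9-BE"        = BaseEditorProfile("xCas9-BE", 20L, "NG", c(4L, 8L)))
}

# IUPAC degenerate-base match of equal-length strings; N in the subject never
# matches (sites containing N are skipped upstream)
.IUPAC <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))

.iupacMatch <- function(seq, pattern) {
  if (nchar(seq) != nchar(pattern)) return(FALSE)
  s <- strsplit(seq, "")[[1L]]
  p <- strsplit(pattern, "")[[1L]]
  all(vapply(seq_along(s), function(i) s[i] %in% .IUPAC[[p[i]]], logical(1)))
}

.revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

# substring of a contig with bounds check; NA when out of bounds
.contigSub <- function(genome, contig, start, end) {
  w <- Biostrings::width(genome)[match(contig, names(genome))]
  if (is.na(w) || start < 1L || end > w || start > end) return(NA_character_)
  as.character(Biostrings::subseq(genome[[contig]], start, end))
}
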