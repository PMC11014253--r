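# Shared nucleotide alphabet helpers.
#
# Two encodings are used throughout:
#   * characters "A","C","G","T","N" for user-facing sequences;
#   * integer codes for the FM-index / DP kernels:
#       0 '$' terminal sentinel, 1 '!' inter-strand sentinel,
#       2 A, 3 C, 4 G, 5 T, 6 X (reference N / contig junction; never
#       matches), 7 read-N (pattern-only, never matches).

.CODE_OF <- c("$" = 0L, "!" = 1L, "A" = 2L, "C" = 3L, "G" = 4L, "T" = 5L,
              "X" = 6L, "N" = 6L)
.CHAR_OF <- c("$", "!", "A", "C", "G", "T", "X", "N")

#' Reverse complement of a DNA string
#'
#' Ns (and the internal junction symbol X) are self-complementary.
#'
#' @param x a character vector of DNA strings over A,C,G,T,N,X.
#' @return the reverse complement of each element.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTNXacgtnx", "TGCANXtgcanx", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# character string -> integer codes (text encoding; N -> X code 6)
dna_to_codes <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  codes <- unname(.CODE_OF[chars])
  if (anyNA(codes)) {
    bad <- which(is.na(codes))[1]
    stop("invalid character '", chars[bad], "' at position ", bad)
  }
  codes
}

# read sequence -> pattern codes (N -> 7, never matches anything)
read_to_codes <- function(s) {
  chars <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  codes <- unname(.CODE_OF[chars])
  codes[is.na(codes) | chars == "N"] <- 7L
  codes
}

codes_to_dna <- function(codes) {
  paste(.CHAR_OF[codes + 1L], collapse = "")
}

# in-silico conversion of a sequence (C->T or G->A)
convert_seq <- function(s, kind = c("C_LESS", "G_LESS")) {
  kind <- match.arg(kind)
  if (kind == "C_LESS") chartr("Cc", "Tt", s) else chartr("Gg", "Aa", s)
}

# bisulfite-strand bookkeeping -------------------------------------------------
# Tags and their conversion class as seen in forward-reference coordinates:
#   OT   (+ strand alignment, ref C / read T tolerated)   class "C2T"
#   CTOT (- strand alignment, ref C / read T tolerated)   class "C2T"
#   OB   (- strand alignment, ref G / read A tolerated)   class "G2A"
#   CTOB (+ strand alignment, ref G / read A tolerated)   class "G2A"
.TAG_CLASS <- c(OT = "C2T", CTOT = "C2T", OB = "G2A", CTOB = "G2A")
.TAG_ZS    <- c(OT = "++", CTOT = "+-", OB = "-+", CTOB = "--")

tag_class <- function(tag) unname(.TAG_CLASS[tag])
tag_zs <- function(tag) unname(.TAG_ZS[tag])

# (alignment orientation, conversion class) -> bisulfite strand tag
strand_class_tag <- function(strand, cls) {
  ifelse(strand == "+",
         ifelse(cls == "C2T", "OT", "CTOB"),
         ifelse(cls == "C2T", "CTOT", "OB"))
}
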