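# Small sequence helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")
IUPAC_CHARS <- c("A", "C", "G", "T", "N", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "U")
AA_CHARS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
              "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Reverse complement of a nucleotide string
#'
#' @param x character vector of nucleotide strings (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    comp <- chartr("ACGTN", "TGCAN", s)
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Translate a nucleotide string in frame 0
#'
#' Uses the standard genetic code (via [Biostrings::GENETIC_CODE]). Codons
#' containing N or incomplete trailing codons translate to "X".
#'
#' @param nt nucleotide string.
#' @return amino-acid string; stop codons appear as `*`.
#' @export
translate_nt <- function(nt) {
  n <- nchar(nt)
  if (n < 3) return("")
  n_codons <- n %/% 3
  starts <- seq(1, by = 3, length.out = n_codons)
  codons <- substring(nt, starts, starts + 2)
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# Phred+33 encode/decode
phred_decode <- function(qual_string) {
  if (nchar(qual_string) == 0) return(integer(0))
  utf8ToInt(qual_string) - 33L
}

phred_encode <- function(q) {
  intToUtf8(pmin(q, 93L) + 33L)
}

# fraction of identical positions between two equal-length strings
hamming_identity <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  1 - cpp_hamming(a, b) / nchar(a)
}

# gene-level call: allele suffix "*NN" stripped
gene_of <- function(call) sub("\\*.*$", "", call)

# family label from a segment name, e.g. "TVH3-1*01" -> "VH3"
family_of <- function(name) {
  sub("^T", "", sub("[-*].*$", "", name))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic 31-bit child seed for a pipeline stage
derive_seed <- function(seed, stage) {
  h <- cpp_fnv1a(paste0(seed, "::", stage))
  as.integer(strtoi(substr(h, 1, 7), base = 16L))
}
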