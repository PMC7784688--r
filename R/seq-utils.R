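#' @importFrom Biostrings DNAString DNAStringSet AAStringSet BStringSet
#'   readBStringSet writeXStringSet reverseComplement alphabetFrequency
#'   matchPattern pairwiseAlignment alignedPattern alignedSubject
#' @importFrom IRanges start width
NULL

IUPAC_CODES <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

# residues a degenerate base stands for, used by the motif scanner
IUPAC_EXPANSION <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.checkIupac <- function(motif) {
  chars <- strsplit(toupper(motif), "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), IUPAC_CODES)
  if (length(bad))
    stop("non-IUPAC character(s) in motif: ", paste(bad, collapse = ", "))
  paste(chars, collapse = "")
}

#' GC content of a DNA sequence
#'
#' Fraction of unambiguous bases that are G or C. Ambiguous bases (`N`) are
#' excluded from both numerator and denominator, so the value is the GC
#' fraction of the informative positions only.
#'
#' @param sequence a single DNA string over `A,C,G,T,N` (case-insensitive),
#'   or a [Biostrings::DNAString].
#' @return GC fraction in `[0, 1]`.
#' @examples
#' gcContent("ATGC")  # 0.5
#' gcContent("AANT")  # 0, denominator 3
#' @export
gcContent <- function(sequence) {
  s <- toupper(as.character(sequence))
  if (length(s) != 1L || nchar(s) == 0L)
    stop("sequence must be a single non-empty DNA string")
  if (grepl("[^ACGTN]", s))
    stop("sequence contains characters outside {A,C,G,T,N}")
  freq <- alphabetFrequency(DNAString(s))
  denom <- sum(freq[c("A", "C", "G", "T")])
  if (denom == 0L)
    stop("no informative bases (sequence is all N)")
  unname(sum(freq[c("G", "C")]) / denom)
}

#' Reverse complement of an IUPAC motif
#'
#' Complements degenerate bases with the standard IUPAC pairing
#' (A-T, C-G, R-Y, K-M, B-V, D-H; S, W and N are self-complementary)
#' and reverses the string. Used to decide whether a restriction-site motif
#' is palindromic and to scan the complementary strand when it is not.
#'
#' @param motif IUPAC DNA string.
#' @return The reverse-complemented IUPAC string (uppercase).
#' @examples
#' revCompIupac("GAATTC")  # palindrome: unchanged
#' revCompIupac("ACCGT")   # "ACGGT"
#' @export
revCompIupac <- function(motif) {
  m <- .checkIupac(motif)
  as.character(reverseComplement(DNAString(m)))
}

#' Is a motif its own reverse complement?
#'
#' @param motif IUPAC DNA string.
#' @return `TRUE` for palindromic motifs (including degenerate palindromes
#'   such as `GANTC`).
#' @export
isPalindromicMotif <- function(motif) {
  m <- .checkIupac(motif)
  identical(m, revCompIupac(m))
}
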