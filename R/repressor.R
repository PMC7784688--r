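#' Repressor sequence similarity
#'
#' Similarity between two (repressor) protein sequences, defined as the
#' number of identically matched positions under a global alignment with zero
#' mismatch and gap costs — i.e. the length of the longest common
#' subsequence — divided by the length of the smaller sequence. Symmetric,
#' in `[0, 1]`, and 1 exactly when the shorter sequence is a subsequence of
#' the longer.
#'
#' @param seqA,seqB non-empty protein sequences (character or AAString).
#' @return similarity fraction in `[0, 1]`.
#' @examples
#' repressorSimilarity("ACDEF", "AXCXDXEXF")  # 1
#' repressorSimilarity("AAAA", "CCCC")        # 0
#' @export
repressorSimilarity <- function(seqA, seqB) {
  a <- toupper(as.character(seqA)); b <- toupper(as.character(seqB))
  if (nchar(a) == 0L || nchar(b) == 0L) stop("empty sequence")
  letters <- unique(c(strsplit(a, "")[[1L]], strsplit(b, "")[[1L]]))
  subst <- diag(1L, length(letters))
  dimnames(subst) <- list(letters, letters)
  score <- pairwiseAlignment(BStringSet(a), BStringSet(b),
                             substitutionMatrix = subst,
                             gapOpening = 0, gapExtension = 0,
                             type = "global", scoreOnly = TRUE)
  score / min(nchar(a), nchar(b))
}

#' Select repressor candidate profile hits
#'
#' Filters one-row-per-(protein, profile) hit tables to profiles that are
#' virus-specific and annotated as immunity functions: viral quotient
#' strictly above 0.8, best-domain e-value at most `1e-4`, profile coverage
#' at least 60%, and a description containing at least one of the keywords
#' immunity, superinfection, repressor, exclusion (case-insensitive).
#'
#' @param profileHits data.frame with columns `vq`, `best_domain_evalue`,
#'   `coverage`, `description` (other columns pass through).
#' @param keywords keyword set to match in descriptions.
#' @return the filtered data.frame.
#' @export
selectRepressorCandidates <- function(profileHits,
    keywords = c("immunity", "superinfection", "repressor", "exclusion")) {
  need <- c("vq", "best_domain_evalue", "coverage", "description")
  miss <- setdiff(need, names(profileHits))
  if (length(miss))
    stop("profile hits missing column(s): ", paste(miss, collapse = ", "))
  pat <- paste(keywords, collapse = "|")
  keep <- profileHits$vq > 0.8 &
    profileHits$best_domain_evalue <= 1e-4 &
    profileHits$coverage >= 0.6 &
    grepl(pat, profileHits$description, ignore.case = TRUE)
  profileHits[keep, , drop = FALSE]
}
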