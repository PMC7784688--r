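.RM_THRESHOLDS <- list(
  REase = c(I = 0.80, II = 0.50, IIG = 0.55, III = 0.80, IV = 0.50),
  MTase = c(I = 0.80, II = 0.60, IIG = 0.55, III = 0.80))

#' Per-type identity threshold for R-M protein equivalence
#'
#' Type II and IV REases: 50%; type IIG: 55%; type II MTases: 60%; type I
#' and III MTases and REases: 80%.
#'
#' @param role `"MTase"` or `"REase"`.
#' @param rmType one of `"I", "II", "IIG", "III", "IV"`.
#' @return identity threshold as a fraction.
#' @export
rmIdentityThreshold <- function(role, rmType) {
  tab <- .RM_THRESHOLDS[[role]]
  if (is.null(tab) || is.na(tab[rmType]))
    stop(sprintf("no equivalence threshold for role '%s' of type '%s'",
                 role, rmType))
  unname(tab[rmType])
}

#' Global-alignment identity of two protein sequences
#'
#' Needleman-Wunsch global alignment (BLOSUM62, affine gaps); identity is
#' the number of identical columns divided by the number of aligned columns
#' after excluding terminal-gap columns.
#'
#' @param seqA,seqB protein sequences.
#' @return identity fraction in `[0, 1]`.
#' @export
proteinIdentity <- function(seqA, seqB) {
  a <- toupper(as.character(seqA)); b <- toupper(as.character(seqB))
  if (nchar(a) == 0L || nchar(b) == 0L) stop("empty sequence")
  aln <- pairwiseAlignment(AAStringSet(a), AAStringSet(b),
                           substitutionMatrix = "BLOSUM62",
                           gapOpening = 10, gapExtension = 0.5,
                           type = "global")
  pa <- strsplit(as.character(alignedPattern(aln)), "")[[1L]]
  ps <- strsplit(as.character(alignedSubject(aln)), "")[[1L]]
  gap <- pa == "-" | ps == "-"
  inner <- which(!gap)
  if (length(inner) == 0L) return(0)
  keep <- seq(min(inner), max(inner))  # drop terminal-gap columns
  sum(pa[keep] == ps[keep]) / length(keep)
}

#' Can two R-M proteins target similar recognition sites?
#'
#' Compares two proteins of the same role (MTase or REase) and system type
#' and returns whether their global-alignment identity reaches the per-type
#' threshold of [rmIdentityThreshold()].
#'
#' @param seqA,seqB protein sequences.
#' @param role `"MTase"` or `"REase"`.
#' @param rmType R-M system type.
#' @return logical.
#' @export
rmProteinEquivalent <- function(seqA, seqB, role, rmType) {
  thr <- rmIdentityThreshold(role, rmType)
  proteinIdentity(seqA, seqB) >= thr
}

#' Find occurrences of an IUPAC recognition motif
#'
#' Scans the forward strand for all windows compatible with the motif under
#' IUPAC expansion. When the motif is not palindromic (its reverse
#' complement differs), the complementary strand is scanned as well;
#' palindromic motifs report forward-strand sites only, since each site
#' would otherwise be reported twice. Positions are 1-based starts on the
#' forward strand.
#'
#' @param motif IUPAC DNA motif, length >= 4.
#' @param sequence DNA sequence to scan.
#' @return data.frame with columns `position`, `strand`.
#' @examples
#' findMotifSites("GAATTC", "AAGAATTCAA")  # one site, position 3, strand +
#' @export
findMotifSites <- function(motif, sequence) {
  m <- .checkIupac(motif)
  if (nchar(m) < 4L) stop("motif shorter than 4 bases")
  sq <- DNAString(toupper(as.character(sequence)))
  fwd <- start(matchPattern(DNAString(m), sq, fixed = "subject"))
  out <- data.frame(position = as.integer(fwd),
                    strand = rep("+", length(fwd)),
                    stringsAsFactors = FALSE)
  if (!isPalindromicMotif(m)) {
    rev <- start(matchPattern(DNAString(revCompIupac(m)), sq,
                              fixed = "subject"))
    out <- rbind(out, data.frame(position = as.integer(rev),
                                 strand = rep("-", length(rev)),
                                 stringsAsFactors = FALSE))
  }
  out <- out[order(out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# does system sysB (rows of the R-M table) have an equivalent counterpart in
# strain A? TRUE when any MTase/REase component of sysB matches a protein of
# the same role and type in A at the per-type identity threshold.
.rmSystemPresentIn <- function(sysB, rmA, proteinSeqs) {
  comp <- sysB[sysB$role %in% c("MTase", "REase"), , drop = FALSE]
  for (i in seq_len(nrow(comp))) {
    cand <- rmA[rmA$role == comp$role[i] & rmA$rm_type == comp$rm_type[i], ,
                drop = FALSE]
    for (j in seq_len(nrow(cand))) {
      if (rmProteinEquivalent(proteinSeqs[[comp$protein_fasta_id[i]]],
                              proteinSeqs[[cand$protein_fasta_id[j]]],
                              comp$role[i], comp$rm_type[i]))
        return(TRUE)
    }
  }
  FALSE
}

#' R-M targeting calls across a strain panel
#'
#' For each ordered strain pair (A producer, B target): collect the R-M
#' systems of B that have no equivalent counterpart (same type, same role,
#' per-type identity threshold) in A — the systems whose methylation pattern
#' A's phage DNA will not carry. For each such system with a known
#' recognition motif, count motif sites in every intact prophage of A. A
#' prophage is called targeted when some system finds at least one site
#' (`twoSiteMode = FALSE`) or at least two sites (`twoSiteMode = TRUE`, for
#' systems requiring two recognition sites to cleave); the pair-level call
#' is positive when any prophage is targeted. Systems without motifs are
#' skipped with a message.
#'
#' @param rmTable R-M data.frame (`system_id, strain_id, rm_type, role,
#'   protein_fasta_id, motif`), one row per component.
#' @param proteinSeqs named [Biostrings::AAStringSet] (or named character)
#'   holding the component protein sequences.
#' @param prophageTable data.frame with `prophage_id, strain_id,
#'   completeness`.
#' @param prophageSeqs named [Biostrings::DNAStringSet] (or named
#'   character) of prophage sequences.
#' @param strains panel strain identifiers; defaults to those in the input
#'   tables.
#' @param twoSiteMode require two sites per prophage per motif (default
#'   `FALSE`).
#' @return data.frame of calls: `producer, target, mechanism, targeted,
#'   evidence` (total motif sites found over absent systems and intact
#'   prophages).
#' @export
rmTargeting <- function(rmTable, proteinSeqs, prophageTable, prophageSeqs,
                        strains = NULL, twoSiteMode = FALSE) {
  minSites <- if (twoSiteMode) 2L else 1L
  pseqs <- setNames(toupper(as.character(proteinSeqs)), names(proteinSeqs))
  gseqs <- setNames(toupper(as.character(prophageSeqs)), names(prophageSeqs))
  if (is.null(strains))
    strains <- sort(unique(c(prophageTable$strain_id, rmTable$strain_id)))
  intact <- prophageTable[prophageTable$completeness == "intact", ,
                          drop = FALSE]
  sysMotif <- tapply(rmTable$motif, rmTable$system_id,
                     function(m) m[!is.na(m)][1])
  noMotif <- names(sysMotif)[is.na(sysMotif)]
  if (length(noMotif))
    message("skipping R-M system(s) without recognition motif: ",
            paste(noMotif, collapse = ", "))
  calls <- expand.grid(producer = strains, target = strains,
                       stringsAsFactors = FALSE)
  calls <- calls[calls$producer != calls$target, , drop = FALSE]
  calls$mechanism <- "rm"
  calls$targeted <- FALSE
  calls$evidence <- 0L
  for (i in seq_len(nrow(calls))) {
    A <- calls$producer[i]; B <- calls$target[i]
    phA <- intact$prophage_id[intact$strain_id == A]
    rmB <- rmTable[rmTable$strain_id == B, , drop = FALSE]
    rmA <- rmTable[rmTable$strain_id == A, , drop = FALSE]
    if (length(phA) == 0L || nrow(rmB) == 0L) next
    ev <- 0L; hit <- FALSE
    for (sid in unique(rmB$system_id)) {
      motif <- sysMotif[[sid]]
      if (is.na(motif)) next
      sysB <- rmB[rmB$system_id == sid, , drop = FALSE]
      if (.rmSystemPresentIn(sysB, rmA, pseqs)) next  # not absent from A
      for (ph in phA) {
        nSites <- nrow(findMotifSites(motif, gseqs[[ph]]))
        ev <- ev + nSites
        if (nSites >= minSites) hit <- TRUE
      }
    }
    calls$targeted[i] <- hit
    calls$evidence[i] <- ev
  }
  rownames(calls) <- NULL
  calls
}
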