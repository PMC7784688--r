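#' Drop CRISPR arrays with fewer than three spacers
#'
#' Arrays with less than three spacers are unreliable array calls and are
#' excluded from targeting inference.
#'
#' @param spacerTable data.frame with columns `array_id, strain_id,
#'   spacer_seq` (one row per spacer).
#' @return the table restricted to arrays with >= 3 spacers.
#' @export
filterCrisprArrays <- function(spacerTable) {
  if (nrow(spacerTable) == 0L) return(spacerTable)
  sizes <- table(spacerTable$array_id)
  keep <- names(sizes)[sizes >= 3L]
  spacerTable[spacerTable$array_id %in% keep, , drop = FALSE]
}

#' Match a CRISPR spacer against a prophage sequence
#'
#' Ungapped scan of both strands. Contiguous truncations of the spacer
#' (prefix and/or suffix removed) down to a coverage of `minCoverage` are
#' allowed, and a window is reported when its nucleotide identity over the
#' matched length is at least `minIdentity`. Overlapping reports on the same
#' strand are collapsed to the best one (fewest mismatches, then longest,
#' then leftmost). Defaults correspond to 90% identity and 90% spacer
#' coverage.
#'
#' @param spacer spacer sequence (>= 10 nt, `A,C,G,T,N`).
#' @param prophageSeq prophage nucleotide sequence to scan.
#' @param minIdentity minimum identity over the matched window (default 0.9).
#' @param minCoverage minimum fraction of the spacer length that must be
#'   matched (default 0.9).
#' @return data.frame with columns `position` (1-based start on the forward
#'   strand), `strand` (`"+"`/`"-"`), `matched_length`, `n_mismatches`,
#'   `identity`, `coverage`. Zero rows when no match.
#' @export
matchSpacer <- function(spacer, prophageSeq, minIdentity = 0.9,
                        minCoverage = 0.9) {
  sp <- toupper(as.character(spacer))
  sq <- toupper(as.character(prophageSeq))
  L <- nchar(sp)
  if (L < 10L) stop("spacer shorter than 10 nt")
  empty <- data.frame(position = integer(), strand = character(),
                      matched_length = integer(), n_mismatches = integer(),
                      identity = numeric(), coverage = numeric(),
                      stringsAsFactors = FALSE)
  # epsilon guards keep threshold arithmetic exact at representable
  # boundaries such as 0.9 * 20
  minLen <- as.integer(ceiling(minCoverage * L - 1e-9))
  n <- nchar(sq)
  if (n < minLen) return(empty)
  seqInt <- utf8ToInt(sq)
  scanOne <- function(query, strand) {
    qInt <- utf8ToInt(query)
    rows <- vector("list", 0L)
    for (Lp in seq(minLen, min(L, n))) {
      nSub <- nchar(query) - Lp + 1L
      maxMm <- floor((1 - minIdentity) * Lp + 1e-9)
      for (s0 in seq_len(nSub)) {
        sub <- qInt[s0:(s0 + Lp - 1L)]
        starts <- seq_len(n - Lp + 1L)
        mm <- integer(length(starts))
        for (k in seq_len(Lp))
          mm <- mm + (seqInt[starts + k - 1L] != sub[k])
        hit <- which(mm <= maxMm)
        if (length(hit))
          rows[[length(rows) + 1L]] <- data.frame(
            position = starts[hit], strand = strand,
            matched_length = Lp, n_mismatches = mm[hit],
            stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) do.call(rbind, rows) else NULL
  }
  cand <- rbind(scanOne(sp, "+"),
                scanOne(revCompIupac(sp), "-"))
  if (is.null(cand) || nrow(cand) == 0L) return(empty)
  # collapse overlapping same-strand windows to the best report
  cand <- cand[order(cand$n_mismatches, -cand$matched_length, cand$position), ,
               drop = FALSE]
  kept <- empty[, c("position", "strand", "matched_length", "n_mismatches")]
  for (i in seq_len(nrow(cand))) {
    ci <- cand[i, ]
    same <- kept[kept$strand == ci$strand, , drop = FALSE]
    overlaps <- nrow(same) > 0L &&
      any(ci$position <= same$position + same$matched_length - 1L &
          same$position <= ci$position + ci$matched_length - 1L)
    if (!overlaps) kept <- rbind(kept, ci)
  }
  kept$identity <- (kept$matched_length - kept$n_mismatches) /
    kept$matched_length
  kept$coverage <- kept$matched_length / L
  kept <- kept[order(kept$position, kept$strand), , drop = FALSE]
  rownames(kept) <- NULL
  kept
}

#' CRISPR targeting calls across a strain panel
#'
#' For every ordered strain pair (A producer, B target), the pair is called
#' targeted when any spacer of B (in arrays with >= 3 spacers) matches any
#' intact prophage of A under [matchSpacer()]. The interpretation: B stores
#' immunity against the phages the lysate of A may carry.
#'
#' @param spacerTable spacer data.frame (`array_id, strain_id, spacer_seq`);
#'   arrays with < 3 spacers are dropped internally.
#' @param prophageTable data.frame with `prophage_id, strain_id,
#'   completeness`.
#' @param prophageSeqs named [Biostrings::DNAStringSet] (or named character)
#'   of prophage sequences.
#' @param strains panel strain identifiers; defaults to those appearing in
#'   either table.
#' @param minIdentity,minCoverage passed to [matchSpacer()].
#' @return data.frame of calls: `producer, target, mechanism, targeted,
#'   evidence` (number of spacer-prophage matches).
#' @export
crisprTargeting <- function(spacerTable, prophageTable, prophageSeqs,
                            strains = NULL, minIdentity = 0.9,
                            minCoverage = 0.9) {
  spacerTable <- filterCrisprArrays(spacerTable)
  seqs <- setNames(toupper(as.character(prophageSeqs)), names(prophageSeqs))
  if (is.null(strains))
    strains <- sort(unique(c(prophageTable$strain_id, spacerTable$strain_id)))
  intact <- prophageTable[prophageTable$completeness == "intact", ,
                          drop = FALSE]
  calls <- expand.grid(producer = strains, target = strains,
                       stringsAsFactors = FALSE)
  calls <- calls[calls$producer != calls$target, , drop = FALSE]
  calls$mechanism <- "crispr"
  calls$targeted <- FALSE
  calls$evidence <- 0L
  for (i in seq_len(nrow(calls))) {
    phA <- intact$prophage_id[intact$strain_id == calls$producer[i]]
    spB <- spacerTable$spacer_seq[spacerTable$strain_id == calls$target[i]]
    if (length(phA) == 0L || length(spB) == 0L) next
    ev <- 0L
    for (ph in phA) for (sp in spB)
      if (nrow(matchSpacer(sp, seqs[[ph]], minIdentity, minCoverage)) > 0L)
        ev <- ev + 1L
    calls$targeted[i] <- ev >= 1L
    calls$evidence[i] <- ev
  }
  rownames(calls) <- NULL
  calls
}
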