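#' Filter homology hits for BBH computation
#'
#' Keeps hits with `evalue < maxEvalue` (strict), `pct_identity >=
#' minIdentityPct` and coverage `>= minCoverage` (inclusive). By default the
#' coverage requirement applies to both query and subject protein
#' (`coverageMode = "both"`); `"query"` restricts it to the query side.
#'
#' @param hits data.frame from [readHitsTable()].
#' @param maxEvalue strict upper bound on evalue (default `1e-4`).
#' @param minIdentityPct minimum percent identity (default 35).
#' @param minCoverage minimum alignment coverage as a fraction (default 0.5).
#' @param coverageMode `"both"` (default) or `"query"`.
#' @return The filtered hits data.frame.
#' @export
filterHits <- function(hits, maxEvalue = 1e-4, minIdentityPct = 35,
                       minCoverage = 0.5, coverageMode = c("both", "query")) {
  coverageMode <- match.arg(coverageMode)
  keep <- hits$evalue < maxEvalue & hits$pct_identity >= minIdentityPct &
    hits$query_coverage >= minCoverage
  if (coverageMode == "both")
    keep <- keep & hits$subject_coverage >= minCoverage
  hits[keep, , drop = FALSE]
}

.assignProphage <- function(ids, proteinsByProphage, what) {
  map <- rep(names(proteinsByProphage), lengths(proteinsByProphage))
  names(map) <- unlist(proteinsByProphage, use.names = FALSE)
  out <- unname(map[ids])
  if (anyNA(out))
    stop(what, " protein(s) not assigned to any proteome: ",
         paste(unique(ids[is.na(out)]), collapse = ", "))
  out
}

#' Best hit of each protein into each other proteome
#'
#' For every (query protein, subject proteome) combination, retains the single
#' best filtered hit, ranked by higher bitscore, then lower evalue, then
#' higher identity, then lexicographically smaller subject identifier.
#'
#' @param filtered filtered hits data.frame (see [filterHits()]).
#' @param proteinsByProphage named list mapping each prophage identifier to
#'   its vector of protein identifiers.
#' @return data.frame of best hits with added columns `query_prophage` and
#'   `subject_prophage`.
#' @export
bestHits <- function(filtered, proteinsByProphage) {
  h <- filtered
  if (nrow(h) == 0L) {
    h$query_prophage <- character()
    h$subject_prophage <- character()
    return(h)
  }
  h$query_prophage <- .assignProphage(h$query_id, proteinsByProphage, "query")
  h$subject_prophage <- .assignProphage(h$subject_id, proteinsByProphage,
                                        "subject")
  h <- h[h$query_prophage != h$subject_prophage, , drop = FALSE]
  if (nrow(h) == 0L) return(h)
  o <- order(h$query_id, h$subject_prophage, -h$bitscore, h$evalue,
             -h$pct_identity, h$subject_id)
  h <- h[o, , drop = FALSE]
  keep <- !duplicated(h[, c("query_id", "subject_prophage")])
  h[keep, , drop = FALSE]
}

#' Bidirectional best hits between two prophages
#'
#' A protein pair (x in A, y in B) is a BBH iff x's best hit into B is y and
#' y's best hit into A is x. The pair identity is the arithmetic mean of the
#' two directional percent identities (they can differ when the underlying
#' alignments differ).
#'
#' @param best data.frame from [bestHits()].
#' @param prophageA,prophageB prophage identifiers.
#' @return data.frame with columns `protein_a, protein_b, identity`
#'   (percent).
#' @export
bidirectionalBestHits <- function(best, prophageA, prophageB) {
  ab <- best[best$query_prophage == prophageA &
             best$subject_prophage == prophageB, , drop = FALSE]
  ba <- best[best$query_prophage == prophageB &
             best$subject_prophage == prophageA, , drop = FALSE]
  empty <- data.frame(protein_a = character(), protein_b = character(),
                      identity = numeric(), stringsAsFactors = FALSE)
  if (nrow(ab) == 0L || nrow(ba) == 0L) return(empty)
  back <- setNames(ba$subject_id, ba$query_id)    # y -> best(y -> A)
  backId <- setNames(ba$pct_identity, ba$query_id)
  recip <- !is.na(back[ab$subject_id]) & back[ab$subject_id] == ab$query_id
  ab <- ab[recip, , drop = FALSE]
  if (nrow(ab) == 0L) return(empty)
  data.frame(protein_a = ab$query_id, protein_b = ab$subject_id,
             identity = (ab$pct_identity +
                         unname(backId[ab$subject_id])) / 2,
             stringsAsFactors = FALSE)
}

#' Weighted gene repertoire relatedness of one prophage pair
#'
#' Computes `wGRR = sum_i id(A_i, B_i) / min(#A, #B)` over the bidirectional
#' best-hit pairs, with identities as fractions. The score is 0 with no
#' homologs and 1 when every protein of the smaller proteome has a
#' 100%-identical reciprocal best hit: three homolog pairs at 100% identity
#' against a smaller proteome of 100 proteins give 0.03, as do six pairs at
#' 50%.
#'
#' @param pairs data.frame of BBH pairs with percent `identity` column
#'   (see [bidirectionalBestHits()]).
#' @param nA,nB protein counts of the two proteomes (both >= 1).
#' @return list with `wgrr` (fraction), `n_bbh_pairs`.
#' @examples
#' pairs <- data.frame(protein_a = paste0("a", 1:3),
#'                     protein_b = paste0("b", 1:3), identity = 100)
#' wgrr(pairs, 100, 120)$wgrr  # 0.03
#' @export
wgrr <- function(pairs, nA, nB) {
  if (nA < 1L || nB < 1L) stop("proteome sizes must be >= 1")
  p <- nrow(pairs)
  if (p > min(nA, nB))
    stop(sprintf("%d BBH pairs exceed min proteome size %d", p, min(nA, nB)))
  if (p > 0 && (anyDuplicated(pairs$protein_a) || anyDuplicated(pairs$protein_b)))
    stop("a protein participates in more than one BBH pair")
  list(wgrr = if (p == 0L) 0 else sum(pairs$identity / 100) / min(nA, nB),
       n_bbh_pairs = p)
}

#' All-against-all wGRR matrix
#'
#' @param proteinsByProphage named list mapping prophage identifiers to
#'   protein identifier vectors (each of length >= 1).
#' @param hits homology hits data.frame; filtered internally with the
#'   supplied thresholds.
#' @param maxEvalue,minIdentityPct,minCoverage,coverageMode passed to
#'   [filterHits()].
#' @return list with `wgrr` (symmetric matrix, diagonal 1 by convention) and
#'   `n_bbh` (matrix of BBH pair counts).
#' @export
wgrrMatrix <- function(proteinsByProphage, hits, maxEvalue = 1e-4,
                       minIdentityPct = 35, minCoverage = 0.5,
                       coverageMode = "both") {
  ids <- names(proteinsByProphage)
  if (is.null(ids) || anyDuplicated(ids))
    stop("proteinsByProphage must be uniquely named")
  if (any(lengths(proteinsByProphage) < 1L))
    stop("every proteome must contain at least one protein")
  filtered <- filterHits(hits, maxEvalue, minIdentityPct, minCoverage,
                         coverageMode)
  best <- bestHits(filtered, proteinsByProphage)
  n <- length(ids)
  w <- matrix(0, n, n, dimnames = list(ids, ids))
  nb <- matrix(0L, n, n, dimnames = list(ids, ids))
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
      pairs <- bidirectionalBestHits(best, ids[i], ids[j])
      res <- wgrr(pairs, length(proteinsByProphage[[i]]),
                  length(proteinsByProphage[[j]]))
      w[i, j] <- w[j, i] <- res$wgrr
      nb[i, j] <- nb[j, i] <- res$n_bbh_pairs
    }
  }
  diag(w) <- 1
  list(wgrr = w, n_bbh = nb)
}

#' Threshold similarity network from a wGRR matrix
#'
#' Undirected edges connect prophage pairs whose wGRR strictly exceeds the
#' threshold (the study's network uses "higher than 50%").
#'
#' @param wgrrMat symmetric wGRR matrix.
#' @param threshold edge threshold in `[0, 1]` (default 0.5, strict).
#' @return data.frame with columns `prophage_a, prophage_b, wgrr`, one row
#'   per edge, `prophage_a < prophage_b` lexicographically.
#' @export
similarityNetwork <- function(wgrrMat, threshold = 0.5) {
  ids <- rownames(wgrrMat)
  edges <- which(upper.tri(wgrrMat) & wgrrMat > threshold, arr.ind = TRUE)
  if (nrow(edges) == 0L)
    return(data.frame(prophage_a = character(), prophage_b = character(),
                      wgrr = numeric(), stringsAsFactors = FALSE))
  out <- data.frame(prophage_a = ids[edges[, 1L]],
                    prophage_b = ids[edges[, 2L]],
                    wgrr = wgrrMat[edges], stringsAsFactors = FALSE)
  swap <- out$prophage_a > out$prophage_b
  tmp <- out$prophage_a[swap]
  out$prophage_a[swap] <- out$prophage_b[swap]
  out$prophage_b[swap] <- tmp
  out[order(out$prophage_a, out$prophage_b), , drop = FALSE]
}
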