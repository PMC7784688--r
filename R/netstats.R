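#' @importFrom stats dhyper cor wilcox.test rbinom runif median
NULL

#' Exact test for a 2x2 contingency table
#'
#' Two-sided Fisher exact p value by the point-probability rule: the sum of
#' hypergeometric probabilities of all tables with the observed margins whose
#' point probability does not exceed that of the observed table (a relative
#' tolerance of `1e-7` guards floating-point ties). The odds ratio is the
#' sample odds ratio `a*d / (b*c)`: `Inf` when `b*c == 0` with `a*d > 0`,
#' `NA` when both products are zero. No continuity or Haldane correction is
#' applied.
#'
#' @param table 2x2 matrix of non-negative integer counts
#'   `rbind(c(a, b), c(c, d))`.
#' @param testName label stored in the result.
#' @return A [ContingencyResult-class].
#' @examples
#' res <- fisherExact2x2(rbind(c(35, 70), c(40, 1080)))
#' oddsRatio(res)  # 13.5
#' pValue(res) < 1e-4
#' @export
fisherExact2x2 <- function(table, testName = "Fisher's exact test") {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L))) stop("table must be 2x2")
  if (any(is.na(tab)) || any(tab < 0) || any(tab != round(tab)))
    stop("table cells must be non-negative integers")
  if (is.null(dimnames(tab)))
    dimnames(tab) <- list(c("row1", "row2"), c("col1", "col2"))
  a <- tab[1L, 1L]; b <- tab[1L, 2L]; cc <- tab[2L, 1L]; d <- tab[2L, 2L]
  ad <- a * d; bc <- b * cc
  or <- if (bc > 0) ad / bc else if (ad > 0) Inf else NA_real_
  r1 <- a + b; c1 <- a + cc; N <- a + b + cc + d
  if (N == 0L || r1 == 0L || r1 == N || c1 == 0L || c1 == N) {
    p <- if (N == 0L) NA_real_ else 1  # degenerate margin: only one table
  } else {
    support <- max(0L, r1 + c1 - N):min(r1, c1)
    probs <- dhyper(support, c1, N - c1, r1)
    pObs <- dhyper(a, c1, N - c1, r1)
    p <- min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
  }
  new("ContingencyResult", table = tab, oddsRatio = or, pValue = p,
      testName = testName)
}

#' Per-producer infection score
#'
#' The average frequency at which a strain's lysate infects the strains of
#' the panel: the mean over all targets (self included) of the fraction of
#' replicates showing clearing.
#'
#' @param im an [InfectionMatrix-class].
#' @param producer producer strain identifier.
#' @return fraction in `[0, 1]`.
#' @export
infectionScore <- function(im, producer) {
  cts <- counts(im)
  if (!producer %in% rownames(cts)) stop("unknown producer: ", producer)
  mean(cts[producer, ] / nReplicates(im))
}

#' Infected producer-target combinations
#'
#' A combination is infected when clearing was observed in at least one
#' replicate (configurable to all replicates).
#'
#' @param im an [InfectionMatrix-class].
#' @param rule `"any"` (>= 1 replicate, default) or `"all"` (every
#'   replicate).
#' @return logical producer x target matrix.
#' @export
infectedPairs <- function(im, rule = c("any", "all")) {
  rule <- match.arg(rule)
  if (rule == "any") counts(im) >= 1L else counts(im) == nReplicates(im)
}

#' Replicate reproducibility of infections
#'
#' Among infected combinations (>= 1 positive replicate), the fraction
#' positive in every replicate. With CLT labels supplied, the fraction is
#' also stratified into same-CLT and cross-CLT pairs.
#'
#' @param im an [InfectionMatrix-class] with `nReplicates >= 2`.
#' @param cltByStrain optional named vector of capsule locus types.
#' @return list with `overall`, `nInfected`, and (when labels are given)
#'   `sameClt`, `crossClt`. Values are `NA` when no pair is infected in the
#'   stratum.
#' @export
replicateReproducibility <- function(im, cltByStrain = NULL) {
  if (nReplicates(im) < 2L) stop("need at least 2 replicates")
  cts <- counts(im)
  frac <- function(sel) {
    inf <- cts >= 1L & sel
    if (!any(inf)) return(NA_real_)
    sum(cts == nReplicates(im) & sel) / sum(inf)
  }
  out <- list(overall = frac(TRUE), nInfected = sum(cts >= 1L))
  if (!is.null(cltByStrain)) {
    same <- outer(cltByStrain[rownames(cts)], cltByStrain[colnames(cts)], "==")
    out$sameClt <- frac(same)
    out$crossClt <- frac(!same)
  }
  out
}

.labelContingency <- function(im, labels, includeSelf, rowLabel) {
  cts <- counts(im)
  miss <- setdiff(c(rownames(cts), colnames(cts)), names(labels))
  if (length(miss))
    stop("missing label for strain(s): ", paste(miss, collapse = ", "))
  same <- outer(labels[rownames(cts)], labels[colnames(cts)], "==")
  inf <- cts >= 1L
  sel <- matrix(TRUE, nrow(cts), ncol(cts))
  if (!includeSelf && !is.null(rownames(cts)))
    sel <- outer(rownames(cts), colnames(cts), "!=")
  tab <- rbind(c(sum(inf & same & sel), sum(!inf & same & sel)),
               c(sum(inf & !same & sel), sum(!inf & !same & sel)))
  dimnames(tab) <- list(paste0(c("same_", "cross_"), rowLabel),
                        c("infected", "not_infected"))
  tab
}

#' Capsule-serotype contingency table of an infection matrix
#'
#' Counts ordered (producer, target) combinations cross-tabulated by
#' same-CLT vs cross-CLT and infected (>= 1 replicate) vs not. With
#' `includeSelf = TRUE` (default) self-pairs are counted among the same-CLT
#' combinations, which is what makes the combination totals sum to the
#' square of the panel size.
#'
#' @param im an [InfectionMatrix-class].
#' @param cltByStrain named vector of capsule locus type labels covering
#'   every strain.
#' @param includeSelf count producer == target pairs (default `TRUE`).
#' @return 2x2 integer matrix (rows same/cross CLT, columns
#'   infected/not_infected).
#' @export
cltContingency <- function(im, cltByStrain, includeSelf = TRUE) {
  .labelContingency(im, cltByStrain, includeSelf, "clt")
}

#' CLT modularity test
#'
#' [cltContingency()] followed by [fisherExact2x2()].
#'
#' @inheritParams cltContingency
#' @return A [ContingencyResult-class].
#' @export
cltModularityTest <- function(im, cltByStrain, includeSelf = TRUE) {
  fisherExact2x2(cltContingency(im, cltByStrain, includeSelf),
                 testName = "Fisher's exact test (CLT modularity)")
}

#' LPS-serotype contingency test
#'
#' Same construction as [cltModularityTest()] with LPS O-locus labels, the
#' tested alternative surface determinant.
#'
#' @param im an [InfectionMatrix-class].
#' @param lpsByStrain named vector of LPS serotype labels.
#' @param includeSelf count self-pairs (default `TRUE`).
#' @return A [ContingencyResult-class].
#' @export
lpsContingency <- function(im, lpsByStrain, includeSelf = TRUE) {
  fisherExact2x2(.labelContingency(im, lpsByStrain, includeSelf, "lps"),
                 testName = "Fisher's exact test (LPS serotype)")
}

#' Association between prophage similarity and infection
#'
#' For each ordered strain pair, the exposure is whether any prophage of the
#' target shares wGRR strictly above `threshold` with any prophage of the
#' producer (a proxy for superinfection immunity through a similar resident
#' prophage); exposure is cross-tabulated against infection (>= 1 replicate)
#' and tested exactly.
#'
#' @param im an [InfectionMatrix-class].
#' @param wgrrMat symmetric prophage x prophage wGRR matrix.
#' @param prophagesByStrain named list mapping strains to their prophage
#'   identifiers (may be empty vectors).
#' @param threshold wGRR exposure threshold (default 0.5, strict).
#' @param includeSelf count self-pairs (default `FALSE`: immunity of a
#'   strain to its own lysate is trivially confounded).
#' @return A [ContingencyResult-class].
#' @export
prophageSimilarityAssociation <- function(im, wgrrMat, prophagesByStrain,
                                          threshold = 0.5,
                                          includeSelf = FALSE) {
  cts <- counts(im)
  tab <- matrix(0L, 2L, 2L,
                dimnames = list(c("similar_prophage", "no_similar_prophage"),
                                c("infected", "not_infected")))
  for (A in rownames(cts)) for (B in colnames(cts)) {
    if (!includeSelf && A == B) next
    phA <- prophagesByStrain[[A]]; phB <- prophagesByStrain[[B]]
    exposed <- length(phA) > 0L && length(phB) > 0L &&
      any(wgrrMat[phB, phA, drop = FALSE] > threshold)
    infected <- cts[A, B] >= 1L
    i <- if (exposed) 1L else 2L
    j <- if (infected) 1L else 2L
    tab[i, j] <- tab[i, j] + 1L
  }
  fisherExact2x2(tab, testName = "Fisher's exact test (prophage similarity)")
}

#' Fraction of dissimilar prophage pairs with similar repressors
#'
#' Among all unordered prophage pairs, the fraction with `wGRR < wgrrMax`
#' but repressor similarity `> repMin` — the pairs that could confer
#' superinfection immunity without overall genomic similarity.
#'
#' @param wgrrMat symmetric prophage x prophage wGRR matrix.
#' @param repressorSim symmetric matrix of repressor similarities with `NA`
#'   where either prophage lacks a repressor candidate (or a long-format
#'   data.frame `prophage_a, prophage_b, similarity`).
#' @param wgrrMax wGRR ceiling (default 0.5, strict `<`).
#' @param repMin repressor similarity floor (default 0.8, strict `>`).
#' @return fraction of all unordered pairs.
#' @export
repressorPairFraction <- function(wgrrMat, repressorSim, wgrrMax = 0.5,
                                  repMin = 0.8) {
  ids <- rownames(wgrrMat)
  n <- length(ids)
  if (n < 2L) return(0)
  if (is.data.frame(repressorSim)) {
    m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
    for (k in seq_len(nrow(repressorSim))) {
      i <- repressorSim$prophage_a[k]; j <- repressorSim$prophage_b[k]
      m[i, j] <- m[j, i] <- repressorSim$similarity[k]
    }
    repressorSim <- m
  }
  ut <- upper.tri(wgrrMat)
  qualifying <- ut & wgrrMat < wgrrMax &
    !is.na(repressorSim[ids, ids]) & repressorSim[ids, ids] > repMin
  sum(qualifying) / sum(ut)
}

#' Pair-level defense-targeting vs infection association
#'
#' Aggregates per-mechanism targeting calls to ordered strain pairs and
#' cross-tabulates the pair-level targeted flag against infection (>= 1
#' replicate), restricted to non-self pairs whose producer carries at least
#' one intact prophage.
#'
#' @param im an [InfectionMatrix-class].
#' @param calls data.frame of targeting calls from [rmTargeting()] or
#'   [crisprTargeting()].
#' @param prophageStrains strains carrying at least one intact prophage;
#'   defaults to every producer present in `calls`.
#' @return A [ContingencyResult-class].
#' @export
defenseAssociation <- function(im, calls, prophageStrains = NULL) {
  cts <- counts(im)
  if (is.null(prophageStrains)) prophageStrains <- unique(calls$producer)
  panel <- intersect(rownames(cts), colnames(cts))
  if (!all(unique(calls$producer) %in% rownames(cts)) ||
      !all(unique(calls$target) %in% colnames(cts)))
    stop("targeting calls involve strains absent from the infection matrix")
  key <- paste(calls$producer, calls$target, sep = "\r")
  targetedByPair <- tapply(calls$targeted, key, any)
  tab <- matrix(0L, 2L, 2L,
                dimnames = list(c("targeted", "not_targeted"),
                                c("infected", "not_infected")))
  for (A in intersect(rownames(cts), prophageStrains)) for (B in colnames(cts)) {
    if (A == B) next
    tgt <- targetedByPair[paste(A, B, sep = "\r")]
    tgt <- !is.na(tgt) && tgt
    infected <- cts[A, B] >= 1L
    tab[if (tgt) 1L else 2L, if (infected) 1L else 2L] <-
      tab[if (tgt) 1L else 2L, if (infected) 1L else 2L] + 1L
  }
  fisherExact2x2(tab, testName = "Fisher's exact test (defense targeting)")
}

#' Spearman rank correlation with a seeded permutation test
#'
#' `rho` is the Pearson correlation of mid-ranks (average ranks on ties);
#' the two-sided p value is a permutation test with `(k + 1)/(n + 1)`
#' correction, appropriate at panel scale where the t approximation is
#' doubtful.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param nPermutations number of permutations (default 10000).
#' @param seed RNG seed for the permutation test.
#' @return list with `rho` and `p` (`rho = NA` for constant input).
#' @export
spearmanRho <- function(x, y, nPermutations = 10000L, seed = 1L) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("x and y must have equal length >= 3")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    return(list(rho = NA_real_, p = NA_real_, note = "constant input"))
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  cnt <- 0L
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
         else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  for (i in seq_len(nPermutations)) {
    if (abs(cor(rx, sample(ry))) >= abs(rho) - 1e-12) cnt <- cnt + 1L
  }
  list(rho = rho, p = (cnt + 1) / (nPermutations + 1))
}

#' Prophage vs chromosome GC comparison
#'
#' Paired differences (prophage GC minus host chromosome GC) tested with the
#' two-sided Wilcoxon signed-rank test: exact for n <= 25, normal
#' approximation with continuity correction otherwise. The median difference
#' is reported in percentage points, the scale on which horizontally
#' acquired elements are usually described (prophages running about 5 points
#' below their host chromosome).
#'
#' @param prophageGc numeric vector of prophage GC fractions.
#' @param hostGc numeric vector of the matching host chromosome GC
#'   fractions (same length, >= 5 pairs).
#' @return list with `median_difference_points`, `p`, `n`.
#' @export
gcComparison <- function(prophageGc, hostGc) {
  if (length(prophageGc) != length(hostGc))
    stop("prophage and host GC vectors must be paired")
  ok <- !is.na(prophageGc) & !is.na(hostGc)
  d <- prophageGc[ok] - hostGc[ok]
  n <- length(d)
  if (n < 5L) stop("insufficient pairs (need >= 5)")
  p <- if (all(d == 0)) 1 else  # signed-rank is undefined on all-zero diffs
    suppressWarnings(
      wilcox.test(d, mu = 0, exact = n <= 25L, correct = TRUE)$p.value)
  list(median_difference_points = 100 * median(d), p = p, n = n)
}
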