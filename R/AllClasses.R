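#' @import methods
#' @importFrom stats setNames
NULL

#' InfectionMatrix: all-against-all lysate clearing outcomes
#'
#' Container for the result of spotting induced, PEG-precipitated lysates of
#' every strain on bacterial overlays of every strain, repeated over
#' independent replicates. Rows are lysate producers, columns target strains;
#' each cell counts the replicates in which a clearing (or plaques) was
#' observed, so values lie in `[0, nReplicates]`.
#'
#' @slot counts integer matrix, producers x targets, with dimnames carrying
#'   the strain identifiers.
#' @slot nReplicates single integer, number of independently produced lysates
#'   (3 in the study design this emulates).
#'
#' @seealso [readInfectionMatrix()], [infectionScore()], [cltContingency()]
#' @export
setClass("InfectionMatrix",
  representation(counts = "matrix", nReplicates = "integer"))

setValidity("InfectionMatrix", function(object) {
  cts <- object@counts
  msgs <- character()
  if (is.null(rownames(cts)) || is.null(colnames(cts)))
    msgs <- c(msgs, "counts must have producer rownames and target colnames")
  if (anyDuplicated(rownames(cts)) || anyDuplicated(colnames(cts)))
    msgs <- c(msgs, "duplicated strain identifiers in dimnames")
  if (length(object@nReplicates) != 1L || is.na(object@nReplicates) ||
      object@nReplicates < 1L)
    msgs <- c(msgs, "nReplicates must be a single positive integer")
  if (any(is.na(cts)))
    msgs <- c(msgs, "counts must not contain NA")
  else if (any(cts < 0L) || any(cts > object@nReplicates))
    msgs <- c(msgs, sprintf("counts must lie in [0, %d]", object@nReplicates))
  else if (any(cts != as.integer(cts)))
    msgs <- c(msgs, "counts must be integers")
  if (length(msgs)) msgs else TRUE
})

#' Construct an InfectionMatrix
#'
#' @param counts numeric matrix of replicate-positive counts with producer
#'   rownames and target colnames.
#' @param nReplicates number of replicates per producer-target combination.
#' @return An [InfectionMatrix-class] object.
#' @examples
#' m <- matrix(c(3L, 0L, 1L, 2L), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("s1", "s2")))
#' InfectionMatrix(m, nReplicates = 3)
#' @export
InfectionMatrix <- function(counts, nReplicates = 3L) {
  storage.mode(counts) <- "integer"
  new("InfectionMatrix", counts = counts, nReplicates = as.integer(nReplicates))
}

#' ContingencyResult: a 2x2 table with its exact test
#'
#' Holds a 2x2 contingency table together with the sample odds ratio
#' (`a*d / (b*c)`) and the two-sided exact p value computed by
#' [fisherExact2x2()]. The odds ratio is `Inf` when `b*c == 0` with
#' `a*d > 0`, and `NA` when both products vanish (degenerate margins).
#'
#' @slot table 2x2 integer matrix with dimnames.
#' @slot oddsRatio sample odds ratio (may be `Inf` or `NA`).
#' @slot pValue two-sided exact p value in `[0, 1]` (`NA` when degenerate).
#' @slot testName label of the test performed.
#' @export
setClass("ContingencyResult",
  representation(table = "matrix", oddsRatio = "numeric",
                 pValue = "numeric", testName = "character"))

setValidity("ContingencyResult", function(object) {
  msgs <- character()
  if (!all(dim(object@table) == c(2L, 2L)))
    msgs <- c(msgs, "table must be 2x2")
  if (any(object@table < 0))
    msgs <- c(msgs, "table cells must be non-negative")
  p <- object@pValue
  if (length(p) != 1L || (!is.na(p) && (p < 0 || p > 1)))
    msgs <- c(msgs, "pValue must be a single value in [0,1] or NA")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "InfectionMatrix", function(object) {
  cts <- object@counts
  cat(sprintf("InfectionMatrix: %d producers x %d targets, %d replicates\n",
              nrow(cts), ncol(cts), object@nReplicates))
  inf <- sum(cts >= 1L)
  cat(sprintf("  %d of %d combinations infected (>=1 replicate)\n",
              inf, length(cts)))
  if (inf > 0L)
    cat(sprintf("  %d (%.0f%%) infected in all replicates\n",
                sum(cts == object@nReplicates),
                100 * sum(cts == object@nReplicates) / inf))
  invisible(NULL)
})

setMethod("show", "ContingencyResult", function(object) {
  cat(sprintf("ContingencyResult (%s)\n", object@testName))
  print(object@table)
  cat(sprintf("  odds ratio = %s, two-sided p = %s\n",
              format(object@oddsRatio, digits = 4),
              format(object@pValue, digits = 4)))
  invisible(NULL)
})
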