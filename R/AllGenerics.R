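#' Accessors for InfectionMatrix and ContingencyResult
#'
#' @param object an [InfectionMatrix-class] or [ContingencyResult-class].
#' @return `counts()` the integer producer x target matrix; `producers()`
#'   and `targets()` the strain identifier vectors; `nReplicates()` the
#'   replicate count; `oddsRatio()` and `pValue()` the statistics of a
#'   contingency result; `contingencyTable()` its 2x2 table.
#' @name accessors
#' @examples
#' m <- InfectionMatrix(matrix(0L, 2, 2,
#'        dimnames = list(c("a", "b"), c("a", "b"))))
#' producers(m)
#' nReplicates(m)
NULL

#' @rdname accessors
#' @export
setGeneric("counts", function(object) standardGeneric("counts"))

#' @rdname accessors
#' @export
setGeneric("producers", function(object) standardGeneric("producers"))

#' @rdname accessors
#' @export
setGeneric("targets", function(object) standardGeneric("targets"))

#' @rdname accessors
#' @export
setGeneric("nReplicates", function(object) standardGeneric("nReplicates"))

#' @rdname accessors
#' @export
setGeneric("oddsRatio", function(object) standardGeneric("oddsRatio"))

#' @rdname accessors
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))

#' @rdname accessors
#' @export
setGeneric("contingencyTable", function(object) standardGeneric("contingencyTable"))

#' @rdname accessors
#' @export
setMethod("counts", "InfectionMatrix", function(object) object@counts)

#' @rdname accessors
#' @export
setMethod("producers", "InfectionMatrix", function(object) rownames(object@counts))

#' @rdname accessors
#' @export
setMethod("targets", "InfectionMatrix", function(object) colnames(object@counts))

#' @rdname accessors
#' @export
setMethod("nReplicates", "InfectionMatrix", function(object) object@nReplicates)

#' @rdname accessors
#' @export
setMethod("oddsRatio", "ContingencyResult", function(object) object@oddsRatio)

#' @rdname accessors
#' @export
setMethod("pValue", "ContingencyResult", function(object) object@pValue)

#' @rdname accessors
#' @export
setMethod("contingencyTable", "ContingencyResult", function(object) object@table)
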