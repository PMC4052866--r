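# Generics and accessors for the S4 containers.

#' @rdname accessors
#' @export
setGeneric("patterns", function(x) standardGeneric("patterns"))

#' @rdname accessors
#' @export
setGeneric("referenceIntensities",
           function(x) standardGeneric("referenceIntensities"))

#' @rdname accessors
#' @export
setGeneric("observations", function(x) standardGeneric("observations"))

#' @rdname accessors
#' @export
setGeneric("basisMatrix", function(x) standardGeneric("basisMatrix"))

#' @rdname accessors
#' @export
setGeneric("trueBasis", function(x) standardGeneric("trueBasis"))

#' @rdname accessors
#' @export
setGeneric("mergedTable", function(x, cycle) standardGeneric("mergedTable"))

#' @rdname accessors
#' @export
setGeneric("scaleFactors", function(x, cycle) standardGeneric("scaleFactors"))

#' @rdname accessors
#' @export
setGeneric("rFactorHistory", function(x) standardGeneric("rFactorHistory"))

#' @rdname accessors
#' @export
setGeneric("refinementSummary",
           function(x, cycle) standardGeneric("refinementSummary"))

#' Accessors for snapshot datasets, patterns and refinement runs
#'
#' \code{patterns} returns the list of patterns of a dataset;
#' \code{referenceIntensities} the reference table; \code{observations} the
#' observation data.frame of a pattern (or the pooled table of a dataset);
#' \code{basisMatrix}/\code{trueBasis} the working and generating reciprocal
#' bases; \code{mergedTable}, \code{scaleFactors}, \code{rFactorHistory} and
#' \code{refinementSummary} the per-cycle outputs of a
#' \linkS4class{PostRefinementRun} (\code{cycle} is the refinement cycle
#' number, 0 = initial scaling and merging).
#'
#' @param x the object.
#' @param cycle cycle number (0-based; default: last).
#' @name accessors
NULL

#' @rdname accessors
setMethod("patterns", "SnapshotDataset", function(x) x@patterns)

#' @rdname accessors
setMethod("referenceIntensities", "SnapshotDataset",
          function(x) x@reference)

#' @rdname accessors
setMethod("observations", "SnapshotPattern", function(x) x@obs)

#' @rdname accessors
setMethod("observations", "SnapshotDataset",
          function(x) poolObservations(x@patterns))

#' @rdname accessors
setMethod("basisMatrix", "SnapshotPattern", function(x) x@basis)

#' @rdname accessors
setMethod("trueBasis", "SnapshotPattern", function(x) x@trueBasis)

#' @rdname accessors
setMethod("mergedTable", "PostRefinementRun", function(x, cycle) {
  if (missing(cycle)) cycle <- x@nCycles
  x@mergedTables[[cycle + 1]]
})

#' @rdname accessors
setMethod("scaleFactors", "PostRefinementRun", function(x, cycle) {
  if (missing(cycle)) cycle <- x@nCycles
  x@scales[[cycle + 1]]
})

#' @rdname accessors
setMethod("rFactorHistory", "PostRefinementRun", function(x) {
  stats::setNames(x@rHistory, paste0("cycle", seq_along(x@rHistory) - 1))
})

#' @rdname accessors
setMethod("refinementSummary", "PostRefinementRun", function(x, cycle) {
  if (missing(cycle)) cycle <- x@nCycles
  stopifnot(cycle >= 1, cycle <= length(x@refinement))
  x@refinement[[cycle]]
})

#' @rdname accessors
#' @export
setGeneric("symmetryOps", function(x) standardGeneric("symmetryOps"))

#' @rdname accessors
setMethod("symmetryOps", "SymmetryGroup", function(x) x@ops)
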