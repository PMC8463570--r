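## Accessor generics and methods. Slots are never accessed with `@` by users.

#' @rdname IncidenceExperiment-class
#' @param x an object.
#' @export
setGeneric("incidence", function(x) standardGeneric("incidence"))

#' @rdname IncidenceExperiment-class
#' @export
setMethod("incidence", "IncidenceExperiment", function(x)
  SummarizedExperiment::assay(x, "incidence"))

#' @rdname IncidenceExperiment-class
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))

#' @rdname IncidenceExperiment-class
#' @export
setMethod("sampleData", "IncidenceExperiment", function(x)
  SummarizedExperiment::colData(x))

#' @rdname CladeSet-class
#' @export
setGeneric("cladeTable", function(x) standardGeneric("cladeTable"))

#' @rdname CladeSet-class
#' @export
setMethod("cladeTable", "CladeSet", function(x) {
  tab <- x@clades
  if (nrow(tab) && ncol(x@prevalence)) {
    prev <- x@prevalence
    colnames(prev) <- paste0("prev_", colnames(prev))
    tab <- cbind(tab, as.data.frame(prev, optional = TRUE))
  }
  rownames(tab) <- NULL
  tab
})

#' @rdname CladeSet-class
#' @export
setGeneric("cladeMembers", function(x) standardGeneric("cladeMembers"))

#' @rdname CladeSet-class
#' @export
setMethod("cladeMembers", "CladeSet", function(x) x@members)

#' @rdname CladeSet-class
#' @export
setGeneric("cladePrevalences", function(x) standardGeneric("cladePrevalences"))

#' @rdname CladeSet-class
#' @export
setMethod("cladePrevalences", "CladeSet", function(x) x@prevalence)

#' @rdname CospeciationResult-class
#' @param object,x a `CospeciationResult`.
#' @export
setGeneric("statistic", function(x) standardGeneric("statistic"))

#' @rdname CospeciationResult-class
#' @export
setMethod("statistic", "CospeciationResult", function(x) x@statistic)

#' @rdname CospeciationResult-class
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname CospeciationResult-class
#' @export
setMethod("pValue", "CospeciationResult", function(x) x@p)

#' @rdname CladeSizeNull-class
#' @param x an object with a permutation null distribution.
#' @export
setGeneric("nullValues", function(x) standardGeneric("nullValues"))

#' @rdname CospeciationResult-class
#' @export
setMethod("nullValues", "CospeciationResult", function(x) x@nullValues)

#' @rdname CladeSizeNull-class
#' @export
setMethod("nullValues", "CladeSizeNull", function(x) x@permMaxSize)

#' @rdname CladeSizeNull-class
#' @export
setGeneric("empiricalP", function(x) standardGeneric("empiricalP"))

#' @rdname CladeSizeNull-class
#' @export
setMethod("empiricalP", "CladeSizeNull", function(x) x@empiricalP)

#' @rdname CospeciationResult-class
#' @export
setGeneric("isDegenerate", function(x) standardGeneric("isDegenerate"))

#' @rdname CospeciationResult-class
#' @export
setMethod("isDegenerate", "CospeciationResult", function(x) x@degenerate)
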