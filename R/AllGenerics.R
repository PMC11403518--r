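#' @include AllGenerics.R
NULL

#' Accessor generics
#'
#' Small family of accessors used across the container classes: per-window
#' metadata, strength matrices, module membership and state labels.
#'
#' @param object a dynstates S4 object
#' @param ... further arguments for methods
#' @return the slot content documented in the class the method belongs to
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("windowMeta", function(object, ...) standardGeneric("windowMeta"))

#' @rdname accessors
#' @export
setGeneric("roiIds", function(object, ...) standardGeneric("roiIds"))

#' @rdname accessors
#' @export
setGeneric("strengthRaw", function(object, ...) standardGeneric("strengthRaw"))

#' @rdname accessors
#' @export
setGeneric("strengthZ", function(object, ...) standardGeneric("strengthZ"))

#' @rdname accessors
#' @export
setGeneric("referenceStats", function(object, ...) standardGeneric("referenceStats"))

#' @rdname accessors
#' @export
setGeneric("membership", function(object, ...) standardGeneric("membership"))

#' @rdname accessors
#' @export
setGeneric("stateLabels", function(object, ...) standardGeneric("stateLabels"))

#' @rdname accessors
#' @export
setGeneric("clusterSummary", function(object, ...) standardGeneric("clusterSummary"))

#' @rdname accessors
#' @export
setGeneric("subjectSummary", function(object, ...) standardGeneric("subjectSummary"))
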