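#' @rdname accessors
#' @export
setGeneric("nodes", function(x) standardGeneric("nodes"))

#' @rdname accessors
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' @rdname accessors
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' @rdname accessors
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' @rdname accessors
#' @export
setGeneric("degrees", function(x) standardGeneric("degrees"))

#' @rdname accessors
#' @export
setGeneric("pathways", function(x) standardGeneric("pathways"))

#' @rdname accessors
#' @export
setGeneric("targets", function(x) standardGeneric("targets"))

#' @rdname accessors
#' @export
setGeneric("compounds", function(x) standardGeneric("compounds"))

#' @rdname accessors
#' @export
setGeneric("links", function(x) standardGeneric("links"))
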