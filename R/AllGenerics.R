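#' @name FCSelect-generics
#' @title Accessor generics
#' @description Accessors for the containers in this package.
#' @param x an object.
#' @keywords internal
NULL

#' @rdname FCSelect-generics
#' @export
setGeneric("repetitionTime", function(x) standardGeneric("repetitionTime"))

#' @rdname FCSelect-generics
#' @export
setGeneric("roiNames", function(x) standardGeneric("roiNames"))

#' @rdname FCSelect-generics
#' @export
setGeneric("seriesValues", function(x) standardGeneric("seriesValues"))

#' @rdname FCSelect-generics
#' @export
setGeneric("confoundRoles", function(x) standardGeneric("confoundRoles"))

#' @rdname FCSelect-generics
#' @export
setGeneric("edgeMatrix", function(x) standardGeneric("edgeMatrix"))

#' @rdname FCSelect-generics
#' @export
setGeneric("edgeMap", function(x) standardGeneric("edgeMap"))

#' @rdname FCSelect-generics
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))

#' @rdname FCSelect-generics
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @rdname FCSelect-generics
#' @export
setGeneric("signalEdges", function(x) standardGeneric("signalEdges"))

#' @rdname FCSelect-generics
#' @export
setGeneric("foldResults", function(x) standardGeneric("foldResults"))

#' @rdname FCSelect-generics
#' @export
setGeneric("pipelineParams", function(x) standardGeneric("pipelineParams"))

#' @rdname FCSelect-generics
#' @export
setGeneric("stableEdges", function(x) standardGeneric("stableEdges"))
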