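#' Accessors for ppifam classes
#'
#' @param object A ppifam object.
#' @return `networkName`: the network label; `nodeIds`: character vector
#'   of node identifiers; `edgeMatrix`: canonical two-column edge matrix;
#'   `foAnnotation`: named character vector of FO-group labels (`NA` =
#'   null function); `nodeCount`/`edgeCount`: integers.
#' @name ppifam-accessors
#' @aliases networkName nodeIds edgeMatrix foAnnotation nodeCount edgeCount
NULL

#' @rdname ppifam-accessors
#' @export
setGeneric("networkName", function(object) standardGeneric("networkName"))

#' @rdname ppifam-accessors
#' @export
setGeneric("nodeIds", function(object) standardGeneric("nodeIds"))

#' @rdname ppifam-accessors
#' @export
setGeneric("edgeMatrix", function(object) standardGeneric("edgeMatrix"))

#' @rdname ppifam-accessors
#' @export
setGeneric("foAnnotation", function(object) standardGeneric("foAnnotation"))

#' @rdname ppifam-accessors
#' @export
setGeneric("nodeCount", function(object) standardGeneric("nodeCount"))

#' @rdname ppifam-accessors
#' @export
setGeneric("edgeCount", function(object) standardGeneric("edgeCount"))

#' @rdname asIgraph
#' @export
setGeneric("asIgraph", function(object, ...) standardGeneric("asIgraph"))
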