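#' Construct a PPINetwork
#'
#' Builds the canonical representation: edge endpoints are sorted within
#' each pair, duplicate pairs collapse to one, and rows are sorted, so
#' two equal networks have byte-identical serializations.
#'
#' @param name Network label.
#' @param nodes Character vector of node identifiers. Endpoints appearing
#'   in `edges` are added automatically.
#' @param edges Two-column character matrix (or `NULL` for an edgeless
#'   network). Self-loops are rejected.
#' @param fo Named character vector of FO-group labels; missing nodes are
#'   filled with `NA` (the null-function sentinel).
#' @return A [PPINetwork-class] object.
#' @examples
#' net <- PPINetwork("toy", edges = cbind(c("a", "b"), c("b", "c")))
#' nodeCount(net)
#' @export
PPINetwork <- function(name, nodes = character(), edges = NULL, fo = NULL) {
  if (is.null(edges)) edges <- matrix(character(), ncol = 2L)
  edges <- as.matrix(edges)
  storage.mode(edges) <- "character"
  if (nrow(edges)) {
    if (any(edges[, 1L] == edges[, 2L]))
      stop("self-loops are not allowed in a PPINetwork")
    a <- pmin(edges[, 1L], edges[, 2L])
    b <- pmax(edges[, 1L], edges[, 2L])
    o <- !duplicated(paste(a, b, sep = "\r"))
    edges <- cbind(a[o], b[o])
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  }
  nodes <- unique(c(as.character(nodes), c(t(edges))))
  ann <- rep(NA_character_, length(nodes))
  names(ann) <- nodes
  if (!is.null(fo)) {
    fo <- fo[names(fo) %in% nodes]
    ann[names(fo)] <- unname(fo)
  }
  colnames(edges) <- c("from", "to")
  new("PPINetwork", name = as.character(name), nodes = nodes,
      edges = edges, fo = ann)
}

#' @rdname ppifam-accessors
#' @export
setMethod("networkName", "PPINetwork", function(object) object@name)

#' @rdname ppifam-accessors
#' @export
setMethod("nodeIds", "PPINetwork", function(object) object@nodes)

#' @rdname ppifam-accessors
#' @export
setMethod("edgeMatrix", "PPINetwork", function(object) object@edges)

#' @rdname ppifam-accessors
#' @export
setMethod("foAnnotation", "PPINetwork", function(object) object@fo)

#' @rdname ppifam-accessors
#' @export
setMethod("nodeCount", "PPINetwork", function(object) length(object@nodes))

#' @rdname ppifam-accessors
#' @export
setMethod("edgeCount", "PPINetwork", function(object) nrow(object@edges))

setMethod("show", "PPINetwork", function(object) {
  nann <- sum(!is.na(object@fo))
  cat(sprintf("PPINetwork '%s': %d nodes, %d edges (%d FO-annotated)\n",
              object@name, nodeCount(object), edgeCount(object), nann))
})

setMethod("show", "FamilyBundle", function(object) {
  cat(sprintf("FamilyBundle: %d networks, %d FO groups, %d similarity records\n",
              length(object@networks),
              length(unique(object@groups$group)),
              nrow(object@similarities)))
  for (net in object@networks)
    cat(sprintf("  %-12s %6d nodes %7d edges\n",
                net@name, nodeCount(net), edgeCount(net)))
})

setMethod("show", "ModelParams", function(object) {
  p <- switch(object@model,
    dmc    = sprintf("q_con=%g, q_mod=%g", object@q_con, object@q_mod),
    dmr    = sprintf("q_new=%g, q_del=%g", object@q_new, object@q_del),
    cg     = sprintf("delta=%d", object@delta),
    sticky = sprintf("f_del=%g, gamma_deg=%g, d_max=%d",
                     object@f_del, object@gamma_deg, object@d_max))
  cat(sprintf("ModelParams [%s]: %s\n", toupper(object@model), p))
})

setMethod("show", "GammaFit", function(object) {
  cat(sprintf("GammaFit: shape=%.4f scale=%.4f (logLik %.1f, n=%d)\n",
              object@shape, object@scale, object@logLik, object@n))
})

setMethod("show", "GraphletStats", function(object) {
  cat(sprintf("GraphletStats for '%s': %d nodes x 73 orbits\n",
              object@network, nrow(object@counts)))
})

setMethod("show", "PhylogenyNode", function(object) {
  rec <- function(nd, depth) {
    cat(strrep("  ", depth), nd@name, " [", nd@size, "]\n", sep = "")
    for (ch in nd@children) rec(ch, depth + 1L)
  }
  rec(object, 0L)
})

#' Convert a PPINetwork to an igraph object
#'
#' @param object A [PPINetwork-class].
#' @param ... Ignored.
#' @return An undirected `igraph` graph with a vertex per node (isolated
#'   nodes included) and the FO annotation in vertex attribute `fo`.
#' @rdname asIgraph
#' @export
setMethod("asIgraph", "PPINetwork", function(object, ...) {
  g <- igraph::make_empty_graph(n = length(object@nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = object@nodes)
  if (nrow(object@edges))
    g <- igraph::add_edges(g, t(matrix(match(object@edges, object@nodes),
                                       ncol = 2L)))
  igraph::set_vertex_attr(g, "fo", value = unname(object@fo))
})

#' Read an undirected edge list
#'
#' Parses a two-column whitespace-separated edge-list file (`.net`).
#' Lines starting with `#` and blank lines are ignored. Repeated lines
#' and reversed duplicates collapse to a single undirected edge; FO
#' annotations are initialized to the null-function sentinel (`NA`).
#'
#' @param path Path to the file.
#' @param name Network label; defaults to the file name without extension.
#' @return A [PPINetwork-class].
#' @examples
#' f <- tempfile(fileext = ".net")
#' writeLines(c("a\tb", "b\ta", "b\tc"), f)
#' readEdgeList(f)
#' @export
readEdgeList <- function(path, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  nt <- lengths(toks)
  if (any(nt != 2L))
    stop(sprintf("malformed edge-list line %d: expected two fields, found %d",
                 keep[which(nt != 2L)[1L]], nt[nt != 2L][1L]))
  if (length(toks)) {
    m <- matrix(unlist(toks), ncol = 2L, byrow = TRUE)
    if (any(m[, 1L] == m[, 2L]))
      stop(sprintf("self-loop at line %d: '%s'",
                   keep[which(m[, 1L] == m[, 2L])[1L]],
                   m[m[, 1L] == m[, 2L], 1L][1L]))
  } else {
    m <- NULL
  }
  PPINetwork(name, edges = m)
}

#' Node degree
#'
#' Number of edges incident to a node (or to every node).
#'
#' @param network A [PPINetwork-class].
#' @param node A node identifier, or `NULL` for all nodes.
#' @return Integer degree, or a named integer vector over all nodes.
#' @examples
#' star <- PPINetwork("star", edges = cbind("c", c("l1", "l2", "l3", "l4")))
#' nodeDegree(star, "c")
#' @export
nodeDegree <- function(network, node = NULL) {
  stopifnot(is(network, "PPINetwork"))
  deg <- integer(length(network@nodes))
  names(deg) <- network@nodes
  if (nrow(network@edges)) {
    t1 <- table(factor(network@edges[, 1L], levels = network@nodes))
    t2 <- table(factor(network@edges[, 2L], levels = network@nodes))
    deg <- as.integer(t1 + t2)
    names(deg) <- network@nodes
  }
  if (is.null(node)) return(deg)
  if (!node %in% network@nodes)
    stop("unknown node '", node, "' in network '", network@name, "'")
  deg[[node]]
}

# Internal: replace a network's FO annotation (names must match nodes).
setFO <- function(network, fo) {
  ann <- rep(NA_character_, length(network@nodes))
  names(ann) <- network@nodes
  fo <- fo[!is.na(fo)]
  ann[names(fo)] <- unname(fo)
  initialize(network, fo = ann)
}
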