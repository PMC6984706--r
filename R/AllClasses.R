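#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib ppifam, .registration = TRUE
NULL

# Sentinel for nodes carrying no functional-orthology annotation.
# Encoded as NA_character_ in `fo` slots and absent from orthology files.

#' PPINetwork: an undirected simple protein-interaction network
#'
#' Nodes are opaque string identifiers, edges are unordered pairs stored
#' once with lexicographically sorted endpoints, and every node carries a
#' functional-orthology (FO) group label or `NA` (the null-function
#' sentinel).
#'
#' @slot name Single string, the network label.
#' @slot nodes Character vector of unique node identifiers.
#' @slot edges Two-column character matrix; each row an edge with
#'   endpoints sorted, rows sorted lexicographically (canonical storage,
#'   so equal networks serialize to identical bytes).
#' @slot fo Named character vector (one entry per node): FO-group
#'   identifier or `NA` for the null function.
#'
#' @seealso [PPINetwork()], [readEdgeList()], [nodeDegree()]
#' @export
setClass("PPINetwork",
  representation(
    name  = "character",
    nodes = "character",
    edges = "matrix",
    fo    = "character"
  )
)

setValidity("PPINetwork", function(object) {
  msg <- character()
  if (length(object@name) != 1L) msg <- c(msg, "name must be a single string")
  if (anyDuplicated(object@nodes)) msg <- c(msg, "duplicated node identifiers")
  e <- object@edges
  if (ncol(e) != 2L) msg <- c(msg, "edges must have two columns")
  if (nrow(e) > 0L) {
    if (any(e[, 1L] == e[, 2L])) msg <- c(msg, "self-loops are not allowed")
    if (!all(c(e) %in% object@nodes))
      msg <- c(msg, "edge endpoint not among nodes")
    if (any(e[, 1L] > e[, 2L]))
      msg <- c(msg, "edge endpoints must be stored in sorted order")
    key <- paste(e[, 1L], e[, 2L], sep = "\r")
    if (anyDuplicated(key)) msg <- c(msg, "duplicate edges")
  }
  if (length(object@fo) != length(object@nodes) ||
      !identical(names(object@fo), object@nodes))
    msg <- c(msg, "fo must be named by nodes, one entry per node")
  if (length(msg)) msg else TRUE
})

#' PhylogenyNode: a binary phylogeny with target network sizes
#'
#' Each node carries a label and the number of proteins the network at
#' that node must reach; internal nodes have exactly two children
#' (bifurcation), leaves none. Sizes are non-decreasing from root to
#' leaves because networks only grow along a lineage.
#'
#' @slot name Node label.
#' @slot size Target node count (positive integer).
#' @slot children List of 0 or 2 `PhylogenyNode` objects.
#'
#' @seealso [parsePhylogeny()], [presetTree()]
#' @export
setClass("PhylogenyNode",
  representation(
    name     = "character",
    size     = "integer",
    children = "list"
  )
)

setValidity("PhylogenyNode", function(object) {
  msg <- character()
  if (length(object@size) != 1L || is.na(object@size) || object@size < 1L)
    msg <- c(msg, "size must be a positive integer")
  nc <- length(object@children)
  if (!nc %in% c(0L, 2L))
    msg <- c(msg, sprintf("node '%s' has %d children; bifurcating trees need 0 or 2",
                          object@name, nc))
  for (ch in object@children) {
    if (!is(ch, "PhylogenyNode")) {
      msg <- c(msg, "children must be PhylogenyNode objects")
    } else if (ch@size < object@size) {
      msg <- c(msg, sprintf("child '%s' (size %d) smaller than parent '%s' (size %d)",
                            ch@name, ch@size, object@name, object@size))
    }
  }
  if (length(msg)) msg else TRUE
})

#' ModelParams: parameters of a network growth model
#'
#' Holds the model choice and its intra-network parameters. Only the
#' slots relevant to `model` are used:
#' \describe{
#'   \item{DMC}{`q_con` (complementation edge probability), `q_mod`
#'     (per-neighbour mutation probability).}
#'   \item{DMR}{`q_new` (random-attachment intensity; each non-neighbour
#'     gains an edge with probability `q_new/N`), `q_del` (per-copied-edge
#'     deletion probability).}
#'   \item{CG}{`delta` (number of edges every new node brings).}
#'   \item{STICKY}{`f_del` (probability that one randomly chosen edge of
#'     the freshly inserted node is removed again), `gamma_deg` (degree
#'     exponent of the power-law sampler for the assigned degree),
#'     `d_max` (truncation of the sampler support).}
#' }
#'
#' @slot model One of `"dmc"`, `"dmr"`, `"cg"`, `"sticky"`.
#' @slot q_con,q_mod,q_new,q_del,f_del Probabilities in \[0, 1\].
#' @slot delta Positive integer (CG).
#' @slot gamma_deg Power-law exponent, > 1 (STICKY).
#' @slot d_max Positive integer truncation (STICKY).
#'
#' @seealso [modelParams()], [legacyModelParams()]
#' @export
setClass("ModelParams",
  representation(
    model     = "character",
    q_con     = "numeric",
    q_mod     = "numeric",
    q_new     = "numeric",
    q_del     = "numeric",
    delta     = "integer",
    f_del     = "numeric",
    gamma_deg = "numeric",
    d_max     = "integer"
  )
)

setValidity("ModelParams", function(object) {
  msg <- character()
  if (!object@model %in% c("dmc", "dmr", "cg", "sticky"))
    msg <- c(msg, "model must be one of dmc, dmr, cg, sticky")
  pr <- c(q_con = object@q_con, q_mod = object@q_mod,
          q_new = object@q_new, q_del = object@q_del, f_del = object@f_del)
  bad <- names(pr)[is.na(pr) | pr < 0 | pr > 1]
  if (length(bad)) msg <- c(msg, paste0(bad, " must lie in [0, 1]", collapse = "; "))
  if (is.na(object@delta) || object@delta < 1L) msg <- c(msg, "delta must be >= 1")
  if (is.na(object@gamma_deg) || object@gamma_deg <= 1)
    msg <- c(msg, "gamma_deg must be > 1")
  if (is.na(object@d_max) || object@d_max < 1L) msg <- c(msg, "d_max must be >= 1")
  if (length(msg)) msg else TRUE
})

#' CrossNetParams: cross-network score and annotation parameters
#'
#' Parameters governing the biological correspondence between nodes of
#' different networks in a family: the Gamma laws of emulated sequence
#' similarity (BLAST bit) scores for orthologous and non-orthologous
#' pairs, the probability of carrying a non-null functional annotation,
#' the half-width of the per-node multiplicative score jitter, and the
#' truncated power law of spurious (non-orthologous) partner counts.
#'
#' @slot k_o,theta_o Gamma shape/scale for orthologous pair scores.
#' @slot k_n,theta_n Gamma shape/scale for non-orthologous pair scores.
#' @slot p_fo Probability that a newly added node keeps a (non-null)
#'   functional annotation.
#' @slot lambda_max Per-node score scale factors are drawn uniformly from
#'   \[1 - lambda_max, 1 + lambda_max\].
#' @slot beta_spur Exponent of the truncated power law of per-node
#'   spurious partner counts.
#' @slot l_max_spur Truncation of the spurious partner count support.
#'
#' @seealso [crossNetParams()], [emitSimilarities()]
#' @export
setClass("CrossNetParams",
  representation(
    k_o        = "numeric",
    theta_o    = "numeric",
    k_n        = "numeric",
    theta_n    = "numeric",
    p_fo       = "numeric",
    lambda_max = "numeric",
    beta_spur  = "numeric",
    l_max_spur = "integer"
  )
)

setValidity("CrossNetParams", function(object) {
  msg <- character()
  if (any(c(object@k_o, object@theta_o, object@k_n, object@theta_n) <= 0))
    msg <- c(msg, "Gamma shapes and scales must be positive")
  if (object@p_fo < 0 || object@p_fo > 1) msg <- c(msg, "p_fo must lie in [0, 1]")
  if (object@lambda_max < 0 || object@lambda_max > 1)
    msg <- c(msg, "lambda_max must lie in [0, 1]")
  if (object@beta_spur <= 1) msg <- c(msg, "beta_spur must be > 1")
  if (object@l_max_spur < 0L) msg <- c(msg, "l_max_spur must be >= 0")
  if (length(msg)) msg else TRUE
})

#' GraphletStats: per-orbit graphlet degree distributions of one network
#'
#' For each of the 73 automorphism orbits of the 2-5-node graphlet
#' catalogue, records how many times each node touches the orbit. The
#' graphlet degree distribution of orbit j is the histogram, over k, of
#' nodes touching orbit j exactly k times; orbit 0 (edge endpoint)
#' reproduces the ordinary degree distribution.
#'
#' @slot counts Numeric matrix, nodes x 73; `counts[v, j+1]` is the
#'   number of times node v touches orbit j (orbits numbered 0-72).
#' @slot network Name of the summarized network.
#'
#' @seealso [graphletDegreeDistributions()], [gdda()], [graphletCatalogue()]
#' @export
setClass("GraphletStats",
  representation(
    counts  = "matrix",
    network = "character"
  )
)

setValidity("GraphletStats", function(object) {
  if (ncol(object@counts) != 73L)
    return("counts must have 73 columns (one per automorphism orbit)")
  if (any(object@counts < 0)) return("orbit touch counts must be non-negative")
  TRUE
})

#' GammaFit: maximum-likelihood Gamma fit of similarity scores
#'
#' @slot shape,scale Positive Gamma parameters (shape kappa, scale theta).
#' @slot logLik Log-likelihood at the optimum.
#' @slot n Number of samples fitted.
#'
#' @seealso [fitGamma()]
#' @export
setClass("GammaFit",
  representation(
    shape  = "numeric",
    scale  = "numeric",
    logLik = "numeric",
    n      = "integer"
  )
)

setValidity("GammaFit", function(object) {
  if (object@shape <= 0 || object@scale <= 0)
    return("shape and scale must be positive")
  TRUE
})

#' FamilyBundle: a synthesized family of related PPI networks
#'
#' The output of [synthesizeFamily()]: the leaf networks of the
#' phylogeny, the ground-truth functional-orthology groups, the emulated
#' cross-network similarity records, and a manifest of the generation
#' parameters.
#'
#' @slot networks Named list of [PPINetwork-class] leaves.
#' @slot groups `data.frame` with columns `group`, `network`, `node`:
#'   the FO-group membership of every annotated node.
#' @slot similarities `data.frame` with columns `net_a`, `node_a`,
#'   `net_b`, `node_b`, `score`, `orthologous`.
#' @slot internal Named list of retained internal-node networks
#'   (empty unless requested).
#' @slot manifest List: model, parameters, seed, phylogeny, per-network
#'   node and edge counts.
#'
#' @seealso [synthesizeFamily()], [writeFamily()]
#' @export
setClass("FamilyBundle",
  representation(
    networks     = "list",
    groups       = "data.frame",
    similarities = "data.frame",
    internal     = "list",
    manifest     = "list"
  )
)

setValidity("FamilyBundle", function(object) {
  msg <- character()
  nm <- vapply(object@networks, function(x) x@name, character(1))
  if (anyDuplicated(nm)) msg <- c(msg, "network names must be unique")
  if (!identical(names(object@networks), unname(nm)))
    msg <- c(msg, "networks list must be named by network names")
  g <- object@groups
  if (!all(c("group", "network", "node") %in% names(g)))
    msg <- c(msg, "groups must have columns group, network, node")
  if (nrow(g) && anyDuplicated(paste(g$network, g$node, sep = "\r")))
    msg <- c(msg, "a node may belong to at most one FO group")
  if (length(msg)) msg else TRUE
})
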