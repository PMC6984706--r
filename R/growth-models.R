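#' Growth-model parameter sets
#'
#' `modelParams()` builds a [ModelParams-class] with the package's
#' default parameterization for each model; `legacyModelParams()` returns
#' the sparse first-generation parameterization (subcritical duplication
#' regime with asymptotic density of about two edges per node), kept for
#' comparative studies of benchmark realism.
#'
#' Defaults: DMC `q_con = 0.5`, `q_mod = 0.4`; DMR `q_new = 0.85`,
#' `q_del = 0.4`; CG `delta = 4`; STICKY `f_del = 0.55`,
#' `gamma_deg = 1.6`, `d_max = 50`.
#'
#' @param model One of `"dmc"`, `"dmr"`, `"cg"`, `"sticky"`.
#' @param ... Named overrides of the slots listed in [ModelParams-class].
#' @return A validated [ModelParams-class] object.
#' @examples
#' modelParams("dmc")
#' modelParams("sticky", f_del = 0.3)
#' @export
modelParams <- function(model = c("dmc", "dmr", "cg", "sticky"), ...) {
  model <- match.arg(tolower(model), c("dmc", "dmr", "cg", "sticky"))
  p <- list(model = model,
            q_con = 0.5, q_mod = 0.4,
            q_new = 0.85, q_del = 0.4,
            delta = 4L,
            f_del = 0.55, gamma_deg = 1.6, d_max = 50L)
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  p[names(dots)] <- dots
  p$delta <- as.integer(p$delta)
  p$d_max <- as.integer(p$d_max)
  do.call(new, c(list("ModelParams"), p))
}

#' @rdname modelParams
#' @export
legacyModelParams <- function(model = c("dmc", "dmr", "cg")) {
  model <- match.arg(tolower(model), c("dmc", "dmr", "cg"))
  switch(model,
    dmc = modelParams("dmc", q_con = 0.4, q_mod = 0.6),
    dmr = modelParams("dmr", q_new = 0.4, q_del = 0.6),
    cg  = modelParams("cg"))
}

#' Stickiness indices
#'
#' Normalizes assigned node degrees into stickiness indices
#' `theta_i = d_i / sum_j d_j`, so the indices sum to one. These weights
#' drive the functional-annotation neighbour choice in the STICKY model;
#' the edge-insertion probability between two nodes is the product form
#' `min(1, d_i d_j / sum_j d_j)` (see Details).
#'
#' @details The edge rule divides the raw degree product by the total
#' degree mass once (equivalently, multiplies two square-root-normalized
#' indices), so that a node's expected number of insertions matches its
#' assigned degree. For weighting choices where only relative size
#' matters (neighbour selection), the sum-normalized indices returned
#' here are the natural representation.
#'
#' @param degrees Named non-negative numeric vector of assigned degrees;
#'   the total must be positive.
#' @return Named numeric vector summing to one.
#' @examples
#' stickinessIndices(c(a = 1, b = 2, c = 1))
#' @export
stickinessIndices <- function(degrees) {
  if (length(degrees) == 0L) stop("empty degree vector")
  if (any(degrees < 0)) stop("assigned degrees must be non-negative")
  s <- sum(degrees)
  if (s <= 0) stop("degenerate input: all assigned degrees are zero")
  degrees / s
}

#' Select a neighbour proportionally to stickiness
#'
#' Picks one element of `neighbors` with probability proportional to its
#' assigned degree (the normalization of stickiness indices cancels in
#' the categorical draw). Used to choose which adjacent node donates its
#' biological function to a newly inserted node.
#'
#' @param neighbors Vector of candidate node indices/identifiers.
#' @param stickyDegrees Assigned degrees, indexable by `neighbors`.
#' @return One element of `neighbors`.
#' @export
pickNeighborByStickiness <- function(neighbors, stickyDegrees) {
  if (length(neighbors) == 0L) stop("node has no neighbours to inherit from")
  w <- stickyDegrees[neighbors]
  if (any(is.na(w)) || any(w < 0)) stop("invalid assigned degrees for neighbours")
  if (sum(w) <= 0) w <- rep(1, length(w))
  neighbors[sample.int(length(neighbors), 1L, prob = w)]
}

# ---- internal growth state ------------------------------------------------
# Mutable environment holding the network under construction:
#   adj      list of integer neighbour vectors (1..n used)
#   deg      integer degrees
#   n        current node count
#   sticky_d assigned degrees (STICKY; realized degrees otherwise)
#   sumd     running sum of sticky_d[1..n]
#   lineage  integer FO lineage per node (0 = none)
#   labeled  logical: node carries a non-null annotation
#   groupNames character: lineage index -> FO group identifier

.newState <- function(capacity) {
  st <- new.env(parent = emptyenv())
  st$adj <- vector("list", capacity)
  st$deg <- integer(capacity)
  st$n <- 0L
  st$ids <- character(capacity)
  st$name <- "net"
  st$sticky_d <- numeric(capacity)
  st$sumd <- 0
  st$lineage <- integer(capacity)
  st$labeled <- logical(capacity)
  st$groupNames <- character()
  st
}

.copyState <- function(st, capacity) {
  s2 <- .newState(capacity)
  n <- st$n
  s2$adj[seq_len(n)] <- st$adj[seq_len(n)]
  s2$deg[seq_len(n)] <- st$deg[seq_len(n)]
  s2$ids[seq_len(n)] <- st$ids[seq_len(n)]
  s2$name <- st$name
  s2$idClash <- st$idClash
  s2$n <- n
  s2$sticky_d[seq_len(n)] <- st$sticky_d[seq_len(n)]
  s2$sumd <- st$sumd
  s2$lineage[seq_len(n)] <- st$lineage[seq_len(n)]
  s2$labeled[seq_len(n)] <- st$labeled[seq_len(n)]
  s2$groupNames <- st$groupNames
  s2
}

.stateFromNetwork <- function(network, capacity) {
  n <- length(network@nodes)
  capacity <- max(capacity, n)
  st <- .newState(capacity)
  st$n <- n
  st$ids[seq_len(n)] <- network@nodes
  st$name <- network@name
  st$idClash <- !identical(network@nodes, paste0(network@name, "_", seq_len(n)))
  if (nrow(network@edges)) {
    ij <- matrix(match(network@edges, network@nodes), ncol = 2L)
    for (r in seq_len(nrow(ij))) {
      a <- ij[r, 1L]; b <- ij[r, 2L]
      st$adj[[a]] <- c(st$adj[[a]], b)
      st$adj[[b]] <- c(st$adj[[b]], a)
    }
  }
  st$deg[seq_len(n)] <- lengths(st$adj[seq_len(n)])
  # assigned degrees default to realized degrees for externally supplied nets
  st$sticky_d[seq_len(n)] <- st$deg[seq_len(n)]
  st$sumd <- sum(st$sticky_d[seq_len(n)])
  fo <- network@fo
  grp <- unique(fo[!is.na(fo)])
  st$groupNames <- unname(grp)
  st$lineage[seq_len(n)] <- ifelse(is.na(fo), 0L, match(fo, grp))
  st$labeled[seq_len(n)] <- !is.na(fo)
  st
}

# rename = TRUE reassigns all ids to <name>_<creation index> (used when a
# bifurcation renames whole networks); rename = FALSE preserves pre-existing
# ids and names only the nodes added during growth.
.finalizeState <- function(st, name, rename = TRUE) {
  n <- st$n
  ids <- if (rename) paste0(name, "_", seq_len(n)) else st$ids[seq_len(n)]
  from <- integer(0); to <- integer(0)
  adj <- st$adj
  for (v in seq_len(n)) {
    nb <- adj[[v]]
    nb <- nb[nb > v]
    if (length(nb)) { from <- c(from, rep.int(v, length(nb))); to <- c(to, nb) }
  }
  fo <- rep(NA_character_, n)
  lab <- st$labeled[seq_len(n)] & st$lineage[seq_len(n)] > 0L
  fo[lab] <- st$groupNames[st$lineage[seq_len(n)][lab]]
  names(fo) <- ids
  net <- PPINetwork(name, nodes = ids,
                    edges = if (length(from)) cbind(ids[from], ids[to]) else NULL,
                    fo = fo)
  attr(net, "stickyDegrees") <- stats::setNames(st$sticky_d[seq_len(n)], ids)
  net
}

# Truncated discrete power-law sampler p(d) ~ d^-gamma on {1..d_max},
# exact inverse-CDF (no rejection).
.powerLawCdf <- function(gamma_deg, d_max) {
  w <- (seq_len(d_max))^(-gamma_deg)
  cumsum(w) / sum(w)
}

.sampleAssignedDegree <- function(cdf, nDraws = 1L) {
  findInterval(stats::runif(nDraws), cdf) + 1L
}

# ---- one add-node attempt per model ---------------------------------------
# Each attempt either commits the new node (returning its neighbour set and
# anchor) or signals failure without mutating the state.

.attemptDMC <- function(st, mp) {
  n <- st$n
  u <- sample.int(n, 1L)
  nb <- st$adj[[u]]
  d <- length(nb)
  if (d == 0L) return(NULL)     # should not occur under the no-singleton invariant
  mutated <- stats::runif(d) < mp@q_mod
  vSide <- stats::runif(d) < 0.5   # TRUE: the copy (v,w) is the deleted one
  keep_v <- nb[!(mutated & vSide)]
  drop_u <- nb[mutated & !vSide]
  conn <- stats::runif(1L) < mp@q_con
  newNb <- if (conn) c(keep_v, u) else keep_v
  if (length(newNb) == 0L) return(NULL)             # singleton new node
  if (st$deg[u] - length(drop_u) + as.integer(conn) == 0L)
    return(NULL)                                    # anchor would be orphaned
  v <- n + 1L
  if (length(drop_u)) {
    st$adj[[u]] <- setdiff(st$adj[[u]], drop_u)
    for (w in drop_u) st$adj[[w]] <- st$adj[[w]][st$adj[[w]] != u]
    st$deg[drop_u] <- st$deg[drop_u] - 1L
    st$deg[u] <- st$deg[u] - length(drop_u)
  }
  list(v = v, neighbors = newNb, anchor = u)
}

.attemptDMR <- function(st, mp) {
  n <- st$n
  u <- sample.int(n, 1L)
  nb <- st$adj[[u]]
  kept <- nb[stats::runif(length(nb)) >= mp@q_del]
  cand <- setdiff(seq_len(n), c(kept, u))
  if (length(cand)) {
    nAdd <- stats::rbinom(1L, length(cand), min(1, mp@q_new / n))
    if (nAdd > 0L) kept <- c(kept, cand[sample.int(length(cand), nAdd)])
  }
  if (length(kept) == 0L) return(NULL)
  list(v = n + 1L, neighbors = kept, anchor = u)
}

.attemptCG <- function(st, mp) {
  n <- st$n
  delta <- mp@delta
  if (n < delta) stop("CG growth needs at least delta = ", delta, " nodes")
  a <- sample.int(n, 1L)
  targets <- a
  while (length(targets) < delta) {
    pool <- setdiff(unique(unlist(st$adj[targets], use.names = FALSE)), targets)
    if (length(pool) == 0L) pool <- setdiff(seq_len(n), targets)
    targets <- c(targets, pool[sample.int(length(pool), 1L)])
  }
  list(v = n + 1L, neighbors = targets, anchor = a)
}

.attemptSTICKY <- function(st, mp, cdf) {
  n <- st$n
  d <- .sampleAssignedDegree(cdf)
  tot <- st$sumd + d
  p <- pmin(1, d * st$sticky_d[seq_len(n)] / tot)
  kept <- which(stats::runif(n) < p)
  # with probability f_del one randomly chosen inserted edge is removed
  if (length(kept) && stats::runif(1L) < mp@f_del)
    kept <- kept[-sample.int(length(kept), 1L)]
  if (length(kept) == 0L) return(NULL)
  anchor <- pickNeighborByStickiness(kept, st$sticky_d)
  list(v = n + 1L, neighbors = kept, anchor = anchor, assigned = d)
}

# Commit a successful attempt: insert node v with its neighbours, record
# lineage (anchor's, never erased by label dropout) and roll the
# annotation-dropout die with probability 1 - pFO of a null label.
.commitNode <- function(st, res, pFO) {
  v <- res$v
  id <- paste0(st$name, "_", v)
  if (isTRUE(st$idClash))
    while (id %in% st$ids[seq_len(v - 1L)]) id <- paste0(id, "b")
  st$ids[v] <- id
  st$adj[[v]] <- res$neighbors
  for (w in res$neighbors) st$adj[[w]] <- c(st$adj[[w]], v)
  st$deg[res$neighbors] <- st$deg[res$neighbors] + 1L
  st$deg[v] <- length(res$neighbors)
  st$n <- v
  d <- if (is.null(res$assigned)) length(res$neighbors) else res$assigned
  st$sticky_d[v] <- d
  st$sumd <- st$sumd + d
  st$lineage[v] <- st$lineage[res$anchor]
  st$labeled[v] <- st$lineage[v] > 0L && stats::runif(1L) < pFO
  invisible(st)
}

# One repaired add-node step: redraw until the new node (and, for DMC, the
# anchor) keeps at least one edge; capped to guard pathological parameters.
.addNodeRepaired <- function(st, mp, pFO, cdf = NULL, maxRetry = 1000L) {
  for (i in seq_len(maxRetry)) {
    res <- switch(mp@model,
      dmc    = .attemptDMC(st, mp),
      dmr    = .attemptDMR(st, mp),
      cg     = .attemptCG(st, mp),
      sticky = .attemptSTICKY(st, mp, cdf))
    if (!is.null(res)) return(.commitNode(st, res, pFO))
  }
  desc <- switch(mp@model,
    dmc    = sprintf("q_con=%g, q_mod=%g", mp@q_con, mp@q_mod),
    dmr    = sprintf("q_new=%g, q_del=%g", mp@q_new, mp@q_del),
    cg     = sprintf("delta=%d", mp@delta),
    sticky = sprintf("f_del=%g, gamma_deg=%g, d_max=%d",
                     mp@f_del, mp@gamma_deg, mp@d_max))
  stop(sprintf(
    "singleton repair failed after %d retries for model %s (%s): parameters leave no escape",
    maxRetry, toupper(mp@model), desc))
}

.growState <- function(st, targetN, mp, pFO, maxRetry = 1000L) {
  if (targetN < st$n) stop("target size smaller than current network")
  if (mp@model == "sticky") cdf <- .powerLawCdf(mp@gamma_deg, mp@d_max) else cdf <- NULL
  while (st$n < targetN) .addNodeRepaired(st, mp, pFO, cdf, maxRetry)
  invisible(st)
}

# ---- exported growth operations -------------------------------------------

#' Add one node to a network with a growth model
#'
#' Applies a single add-node step of the chosen model, including
#' singleton repair: if the stochastic edge-perturbation leaves the new
#' node with no edges (or, for DMC, would orphan the anchor), the step is
#' discarded and redrawn with fresh randomness, up to `maxRetry` times.
#'
#' @param network A [PPINetwork-class] with at least one edge (CG
#'   requires at least `delta` nodes).
#' @param params A [ModelParams-class].
#' @param pFO Probability that the new node keeps a non-null functional
#'   annotation (inherited from its anchor / stickiness-selected
#'   neighbour).
#' @param seed Optional integer seed.
#' @param maxRetry Retry cap for singleton repair.
#' @return A [PPINetwork-class] with one more node (named
#'   `<network>_<n+1>`), guaranteed non-singleton.
#' @examples
#' s <- makeSeedNetwork(10, seed = 1)
#' addNode(s, modelParams("dmc"), seed = 2)
#' @export
addNode <- function(network, params, pFO = 0.9, seed = NULL, maxRetry = 1000L) {
  if (!is.null(seed)) set.seed(seed)
  if (nodeCount(network) == 0L) stop("cannot grow an empty network")
  st <- .stateFromNetwork(network, nodeCount(network) + 1L)
  sd <- attr(network, "stickyDegrees")
  if (!is.null(sd)) {
    st$sticky_d[seq_len(st$n)] <- unname(sd[network@nodes])
    st$sumd <- sum(st$sticky_d[seq_len(st$n)])
  }
  cdf <- if (params@model == "sticky") .powerLawCdf(params@gamma_deg, params@d_max)
  .addNodeRepaired(st, params, pFO, cdf, maxRetry)
  .finalizeState(st, network@name, rename = FALSE)
}

#' Grow a network to a target size
#'
#' Repeatedly applies the model's add-node step (with singleton repair)
#' until the network has `targetN` nodes. Functional lineages are
#' inherited from the anchor node and annotation labels are dropped to
#' the null function independently with probability `1 - pFO`.
#'
#' @inheritParams addNode
#' @param targetN Target node count (at least the current size).
#' @return A [PPINetwork-class] with exactly `targetN` nodes.
#' @examples
#' net <- growToSize(makeSeedNetwork(20, seed = 1), 60,
#'                   modelParams("cg"), seed = 2)
#' edgeCount(net) - 20 * 2.2 # delta * grown nodes, within rounding of seed edges
#' @export
growToSize <- function(network, targetN, params, pFO = 0.9, seed = NULL,
                       maxRetry = 1000L) {
  if (!is.null(seed)) set.seed(seed)
  if (targetN < nodeCount(network))
    stop("targetN is smaller than the current node count")
  st <- .stateFromNetwork(network, targetN)
  sd <- attr(network, "stickyDegrees")
  if (!is.null(sd)) {
    st$sticky_d[seq_len(st$n)] <- unname(sd[network@nodes])
    st$sumd <- sum(st$sticky_d[seq_len(st$n)])
  }
  .growState(st, targetN, params, pFO, maxRetry)
  .finalizeState(st, network@name, rename = FALSE)
}

#' Static stickiness-model network
#'
#' Generates a network over `length(degreeSeq)` nodes in one pass: every
#' unordered pair (i, j) receives an edge independently with probability
#' `min(1, d_i d_j / sum(d))`, the stickiness product rule, so node i's
#' expected degree approximates its assigned degree `d_i`.
#'
#' @param degreeSeq Positive numeric vector of assigned degrees
#'   (length at least 2).
#' @param name Network label.
#' @param seed Optional integer seed.
#' @return A [PPINetwork-class].
#' @export
stickyStatic <- function(degreeSeq, name = "sticky", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(degreeSeq)
  if (n < 2L) stop("need at least two nodes")
  stickinessIndices(degreeSeq)   # validates non-degeneracy
  tot <- sum(degreeSeq)
  ij <- utils::combn(n, 2L)
  p <- pmin(1, degreeSeq[ij[1L, ]] * degreeSeq[ij[2L, ]] / tot)
  keep <- stats::runif(ncol(ij)) <= p
  ids <- paste0(name, "_", seq_len(n))
  edges <- if (any(keep)) cbind(ids[ij[1L, keep]], ids[ij[2L, keep]])
  net <- PPINetwork(name, nodes = ids, edges = edges)
  attr(net, "stickyDegrees") <- stats::setNames(as.numeric(degreeSeq), ids)
  net
}

#' Seed network for family synthesis
#'
#' Builds a sparse connected seed: a ring over `seedSize` nodes plus
#' uniformly sampled chords, totalling about `edgesPerNode` edges per
#' node (2.2 by default, the ancestral density consistent with the
#' densities the duplication models are tuned to reach at benchmark
#' scale). For very small sizes the rule saturates to the complete
#' graph (`seedSize = 5` gives the 5-clique). Every seed node founds its
#' own FO group (`F1`, `F2`, ...).
#'
#' @param seedSize Number of nodes (at least 5).
#' @param name Network label.
#' @param seed Optional integer seed.
#' @param edgesPerNode Target edge density of the seed.
#' @param model Ignored; the seed construction is model-independent and
#'   shared by all growth models. Kept so callers may record the model a
#'   seed is destined for.
#' @return A connected [PPINetwork-class], each node in its own FO group.
#' @examples
#' makeSeedNetwork(5)  # the 5-clique, 10 edges
#' @export
makeSeedNetwork <- function(seedSize = 50L, name = "seed", seed = NULL,
                            edgesPerNode = 2.2, model = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(seedSize)
  if (n < 5L) stop("seedSize must be at least 5")
  target <- min(choose(n, 2L), round(edgesPerNode * n))
  ring <- cbind(seq_len(n), c(seq_len(n - 1L) + 1L, 1L))
  nChords <- max(0L, target - n)
  if (nChords > 0L) {
    all <- utils::combn(n, 2L)
    key <- all[1L, ] * (n + 1L) + all[2L, ]
    ringKey <- pmin(ring[, 1L], ring[, 2L]) * (n + 1L) + pmax(ring[, 1L], ring[, 2L])
    cand <- which(!key %in% ringKey)
    pick <- cand[sample.int(length(cand), min(nChords, length(cand)))]
    ring <- rbind(ring, t(all[, pick, drop = FALSE]))
  }
  ids <- paste0(name, "_", seq_len(n))
  fo <- stats::setNames(paste0("F", seq_len(n)), ids)
  net <- PPINetwork(name, nodes = ids,
                    edges = cbind(ids[ring[, 1L]], ids[ring[, 2L]]), fo = fo)
  attr(net, "stickyDegrees") <- stats::setNames(as.numeric(nodeDegree(net)), ids)
  net
}
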