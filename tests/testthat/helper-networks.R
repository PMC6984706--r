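# Shared fixtures and independent oracles, built in code at test time.

triangleNet <- function(name = "tri") {
  PPINetwork(name, edges = cbind(c("a", "b", "c"), c("b", "c", "a")))
}

pathNet <- function(n = 3, name = "path") {
  ids <- paste0("p", seq_len(n))
  PPINetwork(name, edges = cbind(ids[-n], ids[-1]))
}

starNet <- function(leaves = 4, name = "star") {
  PPINetwork(name, edges = cbind("hub", paste0("leaf", seq_len(leaves))))
}

cycleNet <- function(n = 4, name = "cyc") {
  ids <- paste0("c", seq_len(n))
  PPINetwork(name, edges = cbind(ids, c(ids[-1], ids[1])))
}

cliqueNet <- function(n = 5, name = "clique") {
  prs <- utils::combn(n, 2)
  ids <- paste0("k", seq_len(n))
  PPINetwork(name, edges = cbind(ids[prs[1, ]], ids[prs[2, ]]))
}

# Erdos-Renyi test network via igraph (fixture generator, not an oracle)
rndNet <- function(n, p, seed, name = "rnd") {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  e <- igraph::as_edgelist(g)
  ids <- paste0("v", seq_len(n))
  PPINetwork(name, nodes = ids,
             edges = if (nrow(e)) cbind(ids[e[, 1]], ids[e[, 2]]))
}

# ---- independent graphlet oracle (igraph/VF2 + BLISS automorphisms) --------

.repIgraph <- function(mask, k) {
  prs <- utils::combn(k, 2)
  bits <- bitwAnd(mask, 2L^(seq_len(ncol(prs)) - 1L)) > 0L
  g <- igraph::make_empty_graph(k, directed = FALSE)
  if (any(bits)) g <- igraph::add_edges(g, c(prs[, bits]))
  g
}

# orbit partition via BLISS automorphism-group generators
.blissOrbits <- function(g) {
  gens <- igraph::automorphism_group(g)
  part <- seq_len(igraph::vcount(g))
  repeat {
    changed <- FALSE
    for (gen in gens) {
      img <- part[as.integer(gen)]
      mn <- pmin(part, img)
      if (!identical(mn, part)) { part <- mn; changed <- TRUE }
    }
    if (!changed) break
  }
  part
}

# Rebuild the vertex -> global-orbit-id map of every catalogue graphlet
# using igraph's automorphism machinery and the documented orbit ordering
# (degree, then sorted neighbour-degree profile, then canonical index).
.oracleOrbitMap <- function() {
  cat <- graphletCatalogue()
  out <- list()
  for (i in seq_len(nrow(cat$graphlets))) {
    gid <- cat$graphlets$id[i]
    k <- cat$graphlets$size[i]
    g <- .repIgraph(cat$graphlets$mask[i], k)
    part <- .blissOrbits(g)
    deg <- igraph::degree(g)
    prof <- vapply(seq_len(k), function(v) {
      paste(sort(deg[igraph::neighbors(g, v)]), collapse = ",")
    }, character(1))
    cls <- sort(unique(part))
    key <- data.frame(cls = cls, deg = deg[cls], prof = prof[cls])
    key <- key[order(key$deg, key$prof, key$cls), ]
    ids <- sort(cat$orbits$orbit[cat$orbits$graphlet == gid])
    stopifnot(length(ids) == nrow(key))
    vOrbit <- integer(k)
    for (ci in seq_len(nrow(key)))
      vOrbit[part == key$cls[ci]] <- ids[ci]
    out[[as.character(gid)]] <- list(graph = g, vOrbit = vOrbit, part = part)
  }
  out
}

# Brute-force per-node orbit counts: enumerate every vertex subset of size
# 2-5, keep connected induced subgraphs, identify the graphlet by VF2
# isomorphism and the focal vertex's orbit by colored VF2 against one
# representative vertex of each orbit.
bruteOrbitCounts <- function(net, orbitMap = .oracleOrbitMap()) {
  g <- asIgraph(net)
  n <- igraph::vcount(g)
  counts <- matrix(0, n, 73, dimnames = list(nodeIds(net), paste0("O", 0:72)))
  for (k in 2:5) {
    if (n < k) next
    subs <- utils::combn(n, k)
    for (ci in seq_len(ncol(subs))) {
      s <- subs[, ci]
      h <- igraph::induced_subgraph(g, s)
      if (!igraph::is_connected(h)) next
      hit <- NULL
      for (nmg in names(orbitMap)) {
        rep <- orbitMap[[nmg]]
        if (igraph::vcount(rep$graph) == k &&
            igraph::ecount(rep$graph) == igraph::ecount(h) &&
            igraph::isomorphic(h, rep$graph, method = "vf2")) {
          hit <- rep; break
        }
      }
      stopifnot(!is.null(hit))
      for (pos in seq_len(k)) {
        orb <- NA_integer_
        for (cls in unique(hit$part)) {
          u <- which(hit$part == cls)[1]
          ok <- igraph::isomorphic(
            h, hit$graph, method = "vf2",
            vertex.color1 = as.integer(seq_len(k) == pos) + 1L,
            vertex.color2 = as.integer(seq_len(k) == u) + 1L)
          if (ok) { orb <- hit$vOrbit[u]; break }
        }
        stopifnot(!is.na(orb))
        counts[s[pos], orb + 1L] <- counts[s[pos], orb + 1L] + 1
      }
    }
  }
  counts
}
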