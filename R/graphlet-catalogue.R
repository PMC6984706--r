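# Graphlet catalogue: all connected simple graphs on 2-5 nodes up to
# isomorphism (30 graphlets: 1 + 2 + 6 + 21 by size) and their 73
# automorphism orbits. Built once by exhaustive enumeration with
# brute-force isomorphism rejection over all vertex permutations, then
# cached for the session.

.pkgCache <- new.env(parent = emptyenv())

# all permutations of 1..k as a matrix (k! rows)
.permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(k - 1L)
  out <- matrix(0L, nrow = k * nrow(sub), ncol = k)
  r <- 1L
  for (pos in seq_len(k)) {
    for (i in seq_len(nrow(sub))) {
      row <- integer(k)
      row[pos] <- k
      row[-pos] <- sub[i, ]
      out[r, ] <- row
      r <- r + 1L
    }
  }
  out
}

# pair (i, j), i<j, -> bit position (1-based), in combn(k, 2) order
.pairPos <- function(k) {
  m <- matrix(0L, k, k)
  p <- 0L
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    p <- p + 1L
    m[i, j] <- p; m[j, i] <- p
  }
  m
}

.maskConnected <- function(mask, k, pairs) {
  if (k == 1L) return(TRUE)
  adj <- matrix(FALSE, k, k)
  bits <- bitwAnd(mask, 2L^(seq_len(ncol(pairs)) - 1L)) > 0L
  for (p in which(bits)) {
    i <- pairs[1L, p]; j <- pairs[2L, p]
    adj[i, j] <- adj[j, i] <- TRUE
  }
  seen <- logical(k); seen[1L] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nxt <- which(apply(adj[frontier, , drop = FALSE], 2L, any) & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

.buildCatalogue <- function() {
  graphlets <- list(); orbits <- list(); lookups <- list()
  gid <- -1L; oid <- -1L
  for (k in 2:5) {
    pairs <- utils::combn(k, 2L)
    np <- ncol(pairs)
    pp <- .pairPos(k)
    perms <- .permutations(k)
    nPerm <- nrow(perms)
    masks <- 0:(2L^np - 1L)
    bitsM <- sapply(seq_len(np), function(p) bitwAnd(masks, 2L^(p - 1L)) > 0L)
    # permuted[m+1, s]: mask of the graph relabelled by permutation s
    permuted <- matrix(0L, length(masks), nPerm)
    for (s in seq_len(nPerm)) {
      sig <- perms[s, ]
      # original pair p = (i, j) lands at position of (sig[i], sig[j])
      dest <- vapply(seq_len(np), function(p)
        pp[sig[pairs[1L, p]], sig[pairs[2L, p]]], integer(1))
      permuted[, s] <- as.integer(bitsM %*% 2L^(dest - 1L))
    }
    conn <- vapply(masks, .maskConnected, logical(1), k = k, pairs = pairs)
    canon <- apply(permuted, 1L, min)
    canonPermIdx <- apply(permuted, 1L, which.min)
    reps <- sort(unique(canon[conn]))
    # order classes by edge count, then canonical mask
    ec <- vapply(reps, function(m) sum(bitsM[m + 1L, ]), integer(1))
    reps <- reps[order(ec, reps)]
    repOrbitIds <- vector("list", length(reps))   # per-vertex global orbit id
    for (ri in seq_along(reps)) {
      m <- reps[ri]
      gid <- gid + 1L
      auto <- perms[permuted[m + 1L, ] == m, , drop = FALSE]
      # orbit partition: closure of v -> sigma(v)
      part <- seq_len(k)
      repeat {
        changed <- FALSE
        for (s in seq_len(nrow(auto))) {
          img <- part[auto[s, ]]
          mn <- pmin(part, img)
          if (!identical(mn, part)) { part <- mn; changed <- TRUE }
        }
        if (!changed) break
      }
      deg <- vapply(seq_len(k), function(v)
        sum(bitsM[m + 1L, pp[v, -v]]), integer(1))
      # deterministic orbit order: vertex degree, neighbour-degree profile,
      # smallest vertex index in the canonical labelling
      prof <- vapply(seq_len(k), function(v) {
        nb <- which(bitsM[m + 1L, pp[v, -v]])
        nbv <- (seq_len(k)[-v])[nb]
        paste(sort(deg[nbv]), collapse = ",")
      }, character(1))
      cls <- sort(unique(part))
      key <- data.frame(cls = cls,
                        deg = deg[cls],
                        prof = prof[cls],
                        stringsAsFactors = FALSE)
      key <- key[order(key$deg, key$prof, key$cls), ]
      vOrbit <- integer(k)
      for (ci in seq_len(nrow(key))) {
        oid <- oid + 1L
        members <- which(part == key$cls[ci])
        vOrbit[members] <- oid
        orbits[[length(orbits) + 1L]] <- data.frame(
          orbit = oid, graphlet = gid, size = k,
          degree = key$deg[ci], multiplicity = length(members))
      }
      repOrbitIds[[ri]] <- vOrbit
      graphlets[[length(graphlets) + 1L]] <- data.frame(
        id = gid, size = k, edges = sum(bitsM[m + 1L, ]), mask = m)
    }
    # labelled-mask -> per-position orbit lookup
    lk <- matrix(NA_integer_, length(masks), k)
    repMap <- stats::setNames(seq_along(reps), reps)
    for (m in masks[conn]) {
      c0 <- canon[m + 1L]
      sig <- perms[canonPermIdx[m + 1L], ]
      vo <- repOrbitIds[[repMap[[as.character(c0)]]]]
      lk[m + 1L, ] <- vo[sig]
    }
    lookups[[as.character(k)]] <- lk
  }
  graphlets <- do.call(rbind, graphlets)
  orbits <- do.call(rbind, orbits)
  stopifnot(nrow(graphlets) == 30L, nrow(orbits) == 73L,
            identical(as.integer(table(graphlets$size)), c(1L, 2L, 6L, 21L)))
  list(graphlets = graphlets, orbits = orbits, lookups = lookups)
}

.catalogue <- function() {
  if (is.null(.pkgCache$catalogue)) .pkgCache$catalogue <- .buildCatalogue()
  .pkgCache$catalogue
}

#' The 2-5-node graphlet catalogue
#'
#' Exhaustively enumerates all non-isomorphic connected simple graphs on
#' 2 to 5 nodes (isomorphism rejected by brute force over vertex
#' permutations) and partitions each graphlet's vertices into
#' automorphism orbits. There are 30 such graphlets in total - the
#' single-edge graphlet plus the 29 classic graphlets on 3-5 nodes - and
#' 73 automorphism orbits, numbered 0-72 with orbit 0 the edge endpoint.
#' Numbering is deterministic: graphlets ascend by size, then edge
#' count, then canonical adjacency encoding; orbits within a graphlet
#' ascend by vertex degree and neighbour-degree profile.
#'
#' @return A list with elements
#'   \item{graphlets}{`data.frame`: `id` (0-29), `size`, `edges`, `mask`
#'     (canonical adjacency bit mask).}
#'   \item{orbits}{`data.frame`: `orbit` (0-72), `graphlet`, `size`,
#'     `degree` (vertex degree on the orbit), `multiplicity` (orbit
#'     size).}
#' @examples
#' cat29 <- graphletCatalogue()
#' nrow(cat29$graphlets)                      # 30 including the edge
#' sum(cat29$graphlets$size >= 3)             # the 29 classic graphlets
#' nrow(cat29$orbits)                         # 73 orbits
#' @export
graphletCatalogue <- function() {
  cat <- .catalogue()
  list(graphlets = cat$graphlets, orbits = cat$orbits)
}
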