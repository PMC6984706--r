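#' Cross-network parameter set
#'
#' Defaults: orthologous scores `X ~ Gamma(k_o = 0.94, theta_o = 169.49)`,
#' non-orthologous scores `X ~ Gamma(k_n = 0.86, theta_n = 42.00)`,
#' annotation probability `p_fo = 0.9`, score jitter `lambda_max = 0.1`,
#' spurious-partner law exponent `beta_spur = 1.7` truncated at
#' `l_max_spur = 10`.
#'
#' @param ... Named overrides of the slots of [CrossNetParams-class].
#' @return A validated [CrossNetParams-class].
#' @examples
#' crossNetParams(lambda_max = 0)
#' @export
crossNetParams <- function(...) {
  p <- list(k_o = 0.94, theta_o = 169.49, k_n = 0.86, theta_n = 42.00,
            p_fo = 0.9, lambda_max = 0.1, beta_spur = 1.7, l_max_spur = 10L)
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  p[names(dots)] <- dots
  p$l_max_spur <- as.integer(p$l_max_spur)
  do.call(new, c(list("CrossNetParams"), p))
}

# ---- phylogeny -------------------------------------------------------------

.parseLabel <- function(label) {
  if (is.null(label) || is.na(label) || !nzchar(label) || !grepl("\\|", label))
    stop("phylogeny node label '", label,
         "' must have the form name|size (e.g. A|3000)")
  parts <- strsplit(label, "\\|")[[1L]]
  size <- suppressWarnings(as.integer(parts[2L]))
  if (length(parts) != 2L || is.na(size) || size < 1L)
    stop("invalid size in phylogeny label '", label, "'")
  list(name = parts[1L], size = size)
}

#' Parse a phylogeny specification
#'
#' Reads a Newick-like binary tree whose node labels have the form
#' `name|size`, where `size` is the target node count of the network at
#' that node, e.g. `(A|3000,B|4000)Root|2000;`. Sizes must be
#' non-decreasing from root to leaves (networks only grow) and every
#' internal node must have exactly two children.
#'
#' @param text Tree as a string (`;`-terminated).
#' @param file Alternatively, a path to a file containing the tree.
#' @return The root [PhylogenyNode-class].
#' @examples
#' parsePhylogeny("(A|3000,B|4000)Root|2000;")
#' @export
parsePhylogeny <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of 'text' or 'file'")
  if (!is.null(file)) {
    text <- paste(readLines(file, warn = FALSE), collapse = "")
    text <- gsub("#[^\n]*", "", text)
  }
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) stop("could not parse phylogeny: ",
                                           conditionMessage(e)))
  if (is.null(phy)) stop("could not parse phylogeny: empty tree")
  nTip <- length(phy$tip.label)
  if (is.null(phy$node.label) || length(phy$node.label) != phy$Nnode)
    stop("every internal node needs a name|size label")
  labelOf <- function(id) {
    if (id <= nTip) phy$tip.label[id] else phy$node.label[id - nTip]
  }
  build <- function(id) {
    lab <- .parseLabel(labelOf(id))
    kids <- phy$edge[phy$edge[, 1L] == id, 2L]
    children <- lapply(kids, build)
    node <- new("PhylogenyNode", name = lab$name, size = as.integer(lab$size),
                children = children)
    validObject(node)
    node
  }
  root <- build(nTip + 1L)
  if (length(phylogenyLeaves(root)) < 2L)
    stop("a phylogeny needs at least two leaves")
  root
}

#' Leaves of a phylogeny
#'
#' @param tree A [PhylogenyNode-class].
#' @return Named integer vector of leaf sizes, names = leaf labels.
#' @export
phylogenyLeaves <- function(tree) {
  if (length(tree@children) == 0L)
    return(stats::setNames(tree@size, tree@name))
  do.call(c, lapply(tree@children, phylogenyLeaves))
}

.phylogenyText <- function(tree) {
  rec <- function(nd) {
    lab <- paste0(nd@name, "|", nd@size)
    if (length(nd@children) == 0L) return(lab)
    paste0("(", paste(vapply(nd@children, rec, character(1)), collapse = ","),
           ")", lab)
  }
  paste0(rec(tree), ";")
}

# ---- function assignment ---------------------------------------------------

#' Finalize functional annotations with null-function dropout
#'
#' Each candidate FO-group label survives independently with probability
#' `p_fo` and is replaced by the null-function sentinel (`NA`) otherwise.
#' Entries that are already `NA` (no lineage) stay `NA`.
#'
#' @param candidates Character vector of candidate group identifiers
#'   (possibly `NA`).
#' @param p_fo Per-node probability of keeping the annotation.
#' @param seed Optional integer seed.
#' @return Character vector of final labels with `NA` for null function.
#' @examples
#' table(is.na(assignFunctions(rep("F1", 1000), 0.9, seed = 1)))
#' @export
assignFunctions <- function(candidates, p_fo, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (p_fo < 0 || p_fo > 1) stop("p_fo must lie in [0, 1]")
  drop <- stats::runif(length(candidates)) >= p_fo
  candidates[drop] <- NA_character_
  candidates
}

# ---- similarity scores -----------------------------------------------------

.sampleSpuriousCounts <- function(nDraws, beta, lMax) {
  support <- 0:lMax
  w <- (support + 1)^(-beta)
  sample(support, nDraws, replace = TRUE, prob = w)
}

#' Emulate cross-network sequence-similarity scores
#'
#' Every node receives a private scale factor drawn uniformly from
#' `[1 - lambda_max, 1 + lambda_max]`. Each orthologous cross-network
#' pair (same FO group, different networks) is scored
#' `lambda_u * lambda_v * X` with `X ~ Gamma(k_o, theta_o)`. Each node
#' additionally draws a spurious-partner count from a truncated power
#' law and that many uniformly chosen non-orthologous cross-network
#' partners, scored with `X ~ Gamma(k_n, theta_n)`.
#'
#' @param networks Named list of [PPINetwork-class] objects (at least 2).
#' @param groups `data.frame` with columns `group`, `network`, `node`.
#' @param params A [CrossNetParams-class].
#' @param seed Optional integer seed.
#' @return `data.frame` with columns `net_a`, `node_a`, `net_b`,
#'   `node_b`, `score`, `orthologous`; networks ordered so
#'   `net_a < net_b`, one record per scored pair.
#' @export
emitSimilarities <- function(networks, groups, params = crossNetParams(),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(networks) >= 2L)
  netNames <- vapply(networks, networkName, character(1))
  names(networks) <- netNames
  # per-node multiplicative jitter
  lambda <- lapply(networks, function(nw) {
    stats::setNames(stats::runif(nodeCount(nw), 1 - params@lambda_max,
                                 1 + params@lambda_max), nodeIds(nw))
  })
  # node universe with group labels
  uni <- do.call(rbind, lapply(networks, function(nw) {
    data.frame(network = nw@name, node = nodeIds(nw),
               group = unname(foAnnotation(nw)), stringsAsFactors = FALSE)
  }))
  rownames(uni) <- NULL

  recs <- vector("list", 0L)
  # (b) orthologous pairs: all cross-network same-group pairs
  if (nrow(groups)) {
    sp <- split(groups, groups$group)
    orth <- lapply(sp, function(g) {
      byNet <- split(g$node, g$network)
      if (length(byNet) < 2L) return(NULL)
      nets <- sort(names(byNet))
      prs <- utils::combn(nets, 2L)
      do.call(rbind, lapply(seq_len(ncol(prs)), function(i) {
        a <- prs[1L, i]; b <- prs[2L, i]
        eg <- expand.grid(node_a = byNet[[a]], node_b = byNet[[b]],
                          stringsAsFactors = FALSE)
        cbind(net_a = a, eg, net_b = b)
      }))
    })
    orth <- do.call(rbind, orth[!vapply(orth, is.null, logical(1))])
    if (!is.null(orth) && nrow(orth)) {
      x <- stats::rgamma(nrow(orth), shape = params@k_o, scale = params@theta_o)
      la <- mapply(function(nw, nd) lambda[[nw]][[nd]], orth$net_a, orth$node_a)
      lb <- mapply(function(nw, nd) lambda[[nw]][[nd]], orth$net_b, orth$node_b)
      recs[[length(recs) + 1L]] <- data.frame(
        net_a = orth$net_a, node_a = orth$node_a,
        net_b = orth$net_b, node_b = orth$node_b,
        score = la * lb * x, orthologous = TRUE, stringsAsFactors = FALSE)
    }
  }
  # (c) spurious partners, per node
  counts <- .sampleSpuriousCounts(nrow(uni), params@beta_spur, params@l_max_spur)
  spur <- vector("list", 0L)
  for (i in which(counts > 0L)) {
    v <- uni[i, ]
    cand <- which(uni$network != v$network &
                    (is.na(uni$group) | is.na(v$group) | uni$group != v$group))
    if (!length(cand)) next
    pick <- cand[sample.int(length(cand), min(counts[i], length(cand)))]
    spur[[length(spur) + 1L]] <- data.frame(
      net_a = v$network, node_a = v$node,
      net_b = uni$network[pick], node_b = uni$node[pick],
      stringsAsFactors = FALSE)
  }
  if (length(spur)) {
    spur <- do.call(rbind, spur)
    # canonical orientation, then drop duplicate draws
    flip <- spur$net_a > spur$net_b
    spur[flip, c("net_a", "node_a", "net_b", "node_b")] <-
      spur[flip, c("net_b", "node_b", "net_a", "node_a")]
    spur <- spur[!duplicated(paste(spur$net_a, spur$node_a,
                                   spur$net_b, spur$node_b, sep = "\r")), ]
    x <- stats::rgamma(nrow(spur), shape = params@k_n, scale = params@theta_n)
    la <- mapply(function(nw, nd) lambda[[nw]][[nd]], spur$net_a, spur$node_a)
    lb <- mapply(function(nw, nd) lambda[[nw]][[nd]], spur$net_b, spur$node_b)
    recs[[length(recs) + 1L]] <- data.frame(
      net_a = spur$net_a, node_a = spur$node_a,
      net_b = spur$net_b, node_b = spur$node_b,
      score = la * lb * x, orthologous = FALSE, stringsAsFactors = FALSE)
  }
  if (!length(recs))
    return(data.frame(net_a = character(), node_a = character(),
                      net_b = character(), node_b = character(),
                      score = numeric(), orthologous = logical(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Potential-ortholog counts
#'
#' For each node appearing in the similarity records, counts the
#' cross-network partners whose similarity score strictly exceeds the
#' threshold (default 45, the bit-score cut-off separating plausible
#' orthologs from background).
#'
#' @param similarities `data.frame` as returned by [emitSimilarities()].
#' @param threshold Non-negative score threshold.
#' @return `data.frame` with columns `network`, `node`, `count`.
#' @export
potentialOrthologCounts <- function(similarities, threshold = 45) {
  if (threshold < 0) stop("threshold must be non-negative")
  if (nrow(similarities) == 0L)
    return(data.frame(network = character(), node = character(),
                      count = integer(), stringsAsFactors = FALSE))
  ends <- data.frame(
    network = c(similarities$net_a, similarities$net_b),
    node = c(similarities$node_a, similarities$node_b),
    above = rep(similarities$score > threshold, 2L),
    stringsAsFactors = FALSE)
  agg <- stats::aggregate(above ~ network + node, data = ends, FUN = sum)
  names(agg)[names(agg) == "above"] <- "count"
  agg$count <- as.integer(agg$count)
  agg[order(agg$network, agg$node), c("network", "node", "count")]
}

# ---- family synthesis ------------------------------------------------------

#' Synthesize a family of related PPI networks along a phylogeny
#'
#' Grows an ancestral network from a sparse seed to the root size, then
#' repeats a bifurcation process down the binary phylogeny: at each
#' internal node the network is duplicated (functional annotations
#' inherited) and each copy grows independently to its child's size with
#' the chosen growth model. The leaf networks form the family; internal
#' networks are discarded unless `keepInternal = TRUE`. Ground-truth
#' functional-orthology groups (founded by the seed nodes) and emulated
#' similarity scores are attached.
#'
#' @param tree A [PhylogenyNode-class] (see [parsePhylogeny()],
#'   [presetTree()]).
#' @param params A [ModelParams-class].
#' @param cross A [CrossNetParams-class].
#' @param seed Optional integer seed making the whole family
#'   reproducible.
#' @param seedSize Size of the ancestral seed network (capped at the
#'   root size).
#' @param seedNetwork Optional [PPINetwork-class] used instead of the
#'   internally generated seed; its FO labels found the orthology
#'   groups.
#' @param keepInternal Retain internal-node networks in the bundle.
#' @return A [FamilyBundle-class].
#' @examples
#' fam <- synthesizeFamily(parsePhylogeny("(A|120,B|150)R|100;"),
#'                         modelParams("dmc"), seed = 7, seedSize = 20)
#' fam
#' @export
synthesizeFamily <- function(tree, params, cross = crossNetParams(),
                             seed = NULL, seedSize = 50L, seedNetwork = NULL,
                             keepInternal = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(is(tree, "PhylogenyNode"), is(params, "ModelParams"))
  validObject(tree)
  leaves <- phylogenyLeaves(tree)
  if (anyDuplicated(names(leaves))) stop("leaf names must be unique")
  capacity <- max(leaves)
  if (is.null(seedNetwork))
    seedNetwork <- makeSeedNetwork(min(as.integer(seedSize), tree@size))
  st <- .stateFromNetwork(seedNetwork, capacity)
  .growState(st, tree@size, params, cross@p_fo)

  nets <- list(); internal <- list()
  walk <- function(node, state) {
    if (length(node@children) == 0L) {
      nets[[node@name]] <<- .finalizeState(state, node@name)
      return(invisible(NULL))
    }
    if (keepInternal)
      internal[[node@name]] <<- .finalizeState(state, node@name)
    for (ch in node@children) {
      stChild <- .copyState(state, capacity)
      .growState(stChild, ch@size, params, cross@p_fo)
      walk(ch, stChild)
    }
  }
  walk(tree, st)
  nets <- nets[names(leaves)[names(leaves) %in% names(nets)]]

  groups <- do.call(rbind, lapply(nets, function(nw) {
    fo <- foAnnotation(nw)
    keep <- !is.na(fo)
    data.frame(group = unname(fo[keep]), network = nw@name,
               node = names(fo)[keep], stringsAsFactors = FALSE)
  }))
  rownames(groups) <- NULL
  sims <- emitSimilarities(nets, groups, cross)
  manifest <- list(
    model = params@model,
    parameters = .paramList(params),
    cross_parameters = .crossParamList(cross),
    seed = if (is.null(seed)) NA else seed,
    phylogeny = .phylogenyText(tree),
    networks = lapply(nets, function(nw)
      list(nodes = nodeCount(nw), edges = edgeCount(nw))))
  new("FamilyBundle", networks = nets, groups = groups,
      similarities = sims, internal = internal, manifest = manifest)
}

.paramList <- function(mp) {
  switch(mp@model,
    dmc    = list(q_con = mp@q_con, q_mod = mp@q_mod),
    dmr    = list(q_new = mp@q_new, q_del = mp@q_del),
    cg     = list(delta = mp@delta),
    sticky = list(f_del = mp@f_del, gamma_deg = mp@gamma_deg, d_max = mp@d_max))
}

.crossParamList <- function(cp) {
  list(k_o = cp@k_o, theta_o = cp@theta_o, k_n = cp@k_n, theta_n = cp@theta_n,
       p_fo = cp@p_fo, lambda_max = cp@lambda_max,
       beta_spur = cp@beta_spur, l_max_spur = cp@l_max_spur)
}
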