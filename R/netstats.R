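#' Degree histogram
#'
#' @param network A [PPINetwork-class].
#' @return Named integer vector: degree value -> number of nodes with
#'   that degree; counts sum to the node count.
#' @export
degreeHistogram <- function(network) {
  deg <- nodeDegree(network)
  tab <- table(deg)
  stats::setNames(as.integer(tab), names(tab))
}

#' Local clustering coefficient
#'
#' `CC = 2 e / (k (k - 1))` for a node of degree `k` with `e` edges
#' among its neighbours; defined as 0 for `k < 2` (the formula is
#' otherwise undefined, and the zero convention keeps distribution
#' totals equal to the node count).
#'
#' @param network A [PPINetwork-class].
#' @param node A node identifier, or `NULL` for all nodes.
#' @return Value in \[0, 1\], or a named vector over all nodes.
#' @examples
#' tri <- PPINetwork("t", edges = cbind(c("a", "b", "c"), c("b", "c", "a")))
#' clusteringCoefficient(tri, "a")  # 1
#' @export
clusteringCoefficient <- function(network, node = NULL) {
  g <- asIgraph(network)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[is.nan(cc)] <- 0
  names(cc) <- network@nodes
  if (is.null(node)) return(cc)
  if (!node %in% network@nodes)
    stop("unknown node '", node, "' in network '", network@name, "'")
  unname(cc[node])
}

#' Fit the power-law degree exponent
#'
#' Estimates the exponent gamma of `P_d(k) ~ k^-gamma` by ordinary
#' least-squares regression of `log10(count)` on `log10(degree)` over
#' the degrees with positive counts (degree 0 excluded), mirroring the
#' unbinned polyfit-style procedure; returns the negated slope. Exact on
#' noiseless power-law histograms.
#'
#' @param histogram Named numeric vector (names = degree values, entries
#'   = node counts), e.g. from [degreeHistogram()].
#' @return The estimated degree exponent.
#' @examples
#' h <- stats::setNames((1:100)^-2 * 1e6, 1:100)
#' fitDegreeExponent(h)  # 2
#' @export
fitDegreeExponent <- function(histogram) {
  k <- suppressWarnings(as.numeric(names(histogram)))
  if (any(is.na(k))) stop("histogram names must be numeric degrees")
  keep <- k > 0 & histogram > 0
  if (sum(keep) < 2L)
    stop("need at least two degrees with positive counts to fit an exponent")
  fit <- stats::lm(y ~ x, data = data.frame(x = log10(k[keep]),
                                            y = log10(as.numeric(histogram[keep]))))
  -unname(stats::coef(fit)[2L])
}

#' Graphlet degree distributions of a network
#'
#' Counts, for every node, how many times it touches each of the 73
#' automorphism orbits over all connected induced subgraphs on 2-5
#' nodes containing it (ESU enumeration in compiled code; each subgraph
#' is visited exactly once). Orbit 0 counts reproduce node degrees.
#'
#' @param network A [PPINetwork-class] (simple, undirected).
#' @return A [GraphletStats-class].
#' @export
graphletDegreeDistributions <- function(network) {
  cat <- .catalogue()
  n <- nodeCount(network)
  if (n == 0L)
    return(new("GraphletStats",
               counts = matrix(0, 0L, 73L), network = network@name))
  adj <- rep(list(integer()), n)
  e <- edgeMatrix(network)
  if (nrow(e)) {
    ij <- matrix(match(e, network@nodes), ncol = 2L)
    for (r in seq_len(nrow(ij))) {
      a <- ij[r, 1L]; b <- ij[r, 2L]
      adj[[a]] <- c(adj[[a]], b - 1L)   # 0-based for the compiled counter
      adj[[b]] <- c(adj[[b]], a - 1L)
    }
  }
  flat <- function(k) {
    lk <- cat$lookups[[as.character(k)]]
    lk[is.na(lk)] <- -1L
    as.integer(t(lk))                   # row-major: mask * k + position
  }
  counts <- .countGraphletOrbits(adj, flat(2L), flat(3L), flat(4L), flat(5L))
  rownames(counts) <- network@nodes
  colnames(counts) <- paste0("O", 0:72)
  new("GraphletStats", counts = counts, network = network@name)
}

#' Graphlet degree distribution for one orbit
#'
#' @param stats A [GraphletStats-class].
#' @param orbit Orbit number, 0-72.
#' @return Named numeric vector: touch count k -> number of nodes
#'   touching the orbit exactly k times (k with zero nodes omitted).
#' @export
gddHistogram <- function(stats, orbit) {
  stopifnot(is(stats, "GraphletStats"), orbit >= 0L, orbit <= 72L)
  tab <- table(stats@counts[, orbit + 1L])
  stats::setNames(as.numeric(tab), names(tab))
}

#' Graphlet degree distribution agreement (GDDA)
#'
#' For each orbit j the distribution `D(k)` (nodes touching the orbit
#' exactly k times, k >= 1) is scaled by `S(k) = D(k)/k`, normalized to
#' total mass one, and the two networks are compared with the distance
#' `d_j = (1/sqrt(2)) * sqrt(sum_k (N_a(k) - N_b(k))^2)`; the per-orbit
#' agreement is `1 - d_j`, and the GDDA score is the arithmetic mean of
#' the agreements over orbits where at least one network has mass
#' (orbits empty in both networks are skipped).
#'
#' @param statsA,statsB [GraphletStats-class] objects computed with the
#'   same orbit numbering (always true within this package).
#' @return Agreement score in \[0, 1\]; `gdda(x, x)` is 1.
#' @export
gdda <- function(statsA, statsB) {
  stopifnot(is(statsA, "GraphletStats"), is(statsB, "GraphletStats"))
  if (ncol(statsA@counts) != ncol(statsB@counts))
    stop("orbit counts are incompatible")
  agree <- numeric(0)
  for (j in seq_len(73L)) {
    na <- .normalizedGdd(statsA@counts[, j])
    nb <- .normalizedGdd(statsB@counts[, j])
    if (is.null(na) && is.null(nb)) next
    ks <- sort(unique(c(names(na), names(nb))))
    va <- vb <- stats::setNames(numeric(length(ks)), ks)
    if (!is.null(na)) va[names(na)] <- na
    if (!is.null(nb)) vb[names(nb)] <- nb
    d <- sqrt(sum((va - vb)^2)) / sqrt(2)
    agree <- c(agree, 1 - d)
  }
  if (!length(agree)) return(1)
  mean(agree)
}

.normalizedGdd <- function(colCounts) {
  vals <- colCounts[colCounts > 0]
  if (!length(vals)) return(NULL)
  tab <- table(vals)
  k <- as.numeric(names(tab))
  s <- as.numeric(tab) / k
  stats::setNames(s / sum(s), names(tab))
}

#' Maximum-likelihood Gamma fit
#'
#' Fits shape and scale of a Gamma distribution to positive samples by
#' maximum likelihood (via `fitdistrplus`).
#'
#' @param samples Numeric vector of at least 10 positive values with
#'   positive variance.
#' @return A [GammaFit-class].
#' @examples
#' set.seed(1)
#' fitGamma(rgamma(5000, shape = 0.94, scale = 169.49))
#' @export
fitGamma <- function(samples) {
  if (length(samples) < 10L) stop("need at least 10 samples")
  if (any(samples <= 0)) stop("Gamma samples must be strictly positive")
  if (stats::var(samples) == 0) stop("degenerate input: constant samples")
  fit <- fitdistrplus::fitdist(as.numeric(samples), "gamma",
                               method = "mle", lower = c(1e-10, 1e-10))
  shp <- unname(fit$estimate[["shape"]])
  rate <- unname(fit$estimate[["rate"]])
  new("GammaFit", shape = shp, scale = 1 / rate,
      logLik = as.numeric(fit$loglik), n = length(samples))
}

#' Summary statistics of a network
#'
#' One summary row per network: node and edge counts, edges per node
#' (`|E|/|V|`), the fitted power-law degree exponent (NA when fewer than
#' two degree values carry mass), and the mean local clustering
#' coefficient.
#'
#' @param network A [PPINetwork-class].
#' @return A one-row `data.frame` with columns `name`, `nodes`, `edges`,
#'   `edgesPerNode`, `degreeExponent`, `meanClustering`.
#' @export
networkSummary <- function(network) {
  n <- nodeCount(network); m <- edgeCount(network)
  gam <- tryCatch(fitDegreeExponent(degreeHistogram(network)),
                  error = function(e) NA_real_)
  cc <- if (n) mean(clusteringCoefficient(network)) else 0
  data.frame(name = network@name, nodes = n, edges = m,
             edgesPerNode = if (n) m / n else 0,
             degreeExponent = gam, meanClustering = cc,
             stringsAsFactors = FALSE)
}
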