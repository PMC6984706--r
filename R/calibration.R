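#' Feature summary of a network for calibration
#'
#' Collects the features used to compare a synthetic network with a
#' reference: per-node degrees, per-node local clustering coefficients,
#' node and edge counts and, optionally, graphlet degree distributions
#' (the costly term, off by default).
#'
#' @param network A [PPINetwork-class].
#' @param includeGraphlets Also compute [graphletDegreeDistributions()].
#' @return A list of class `ppifamSummary` with elements `nodes`,
#'   `edges`, `degrees`, `cc`, and `gdd` (`NULL` unless requested).
#' @export
referenceSummary <- function(network, includeGraphlets = FALSE) {
  out <- list(nodes = nodeCount(network),
              edges = edgeCount(network),
              degrees = as.numeric(nodeDegree(network)),
              cc = as.numeric(clusteringCoefficient(network)),
              gdd = if (includeGraphlets) graphletDegreeDistributions(network))
  class(out) <- "ppifamSummary"
  out
}

# two-sample Kolmogorov-Smirnov distance (statistic only; ties are fine)
.ksDist <- function(x, y) {
  v <- sort(unique(c(x, y)))
  max(abs(stats::ecdf(x)(v) - stats::ecdf(y)(v)))
}

#' Discrepancy between two network feature summaries
#'
#' Weighted sum of four terms: relative edge-density difference
#' `|d_a - d_b| / mean(d_a, d_b)`, the Kolmogorov-Smirnov distance
#' between the degree distributions, the KS distance between the
#' clustering-coefficient distributions, and `1 - GDDA` when both
#' summaries carry graphlet statistics. Symmetric in its two arguments;
#' lower is better; zero for identical summaries.
#'
#' @param summaryA,summaryB Summaries from [referenceSummary()].
#' @param weights Named weights for `density`, `degree`, `cc`, `gdda`.
#' @return Non-negative scalar discrepancy.
#' @export
scoreCandidate <- function(summaryA, summaryB,
                           weights = c(density = 1, degree = 1,
                                       cc = 1, gdda = 1)) {
  if (summaryA$nodes == 0L || summaryB$nodes == 0L)
    stop("cannot score an empty summary")
  w <- c(density = 1, degree = 1, cc = 1, gdda = 1)
  w[names(weights)] <- weights
  da <- summaryA$edges / summaryA$nodes
  db <- summaryB$edges / summaryB$nodes
  dens <- if (da == 0 && db == 0) 0 else abs(da - db) / mean(c(da, db))
  s <- w[["density"]] * dens +
    w[["degree"]] * .ksDist(summaryA$degrees, summaryB$degrees) +
    w[["cc"]] * .ksDist(summaryA$cc, summaryB$cc)
  if (!is.null(summaryA$gdd) && !is.null(summaryB$gdd))
    s <- s + w[["gdda"]] * (1 - gdda(summaryA$gdd, summaryB$gdd))
  unname(s)
}

#' Grid-search calibration of growth-model parameters
#'
#' Replicates the estimation protocol: the ranges of the model's free
#' parameters are divided into an equal-width grid (0.05 steps by
#' default when built with [gridSpec()]), `replicates` networks are
#' generated at each grid point and their mean discrepancy
#' ([scoreCandidate()]) to the reference summary is recorded; the
#' parameter combination with the smallest mean discrepancy wins, ties
#' broken by the lexicographically smallest parameter tuple.
#'
#' @param model Growth model name (`"dmc"`, `"dmr"`, `"sticky"`; CG is
#'   excluded from calibration by default since its single parameter is
#'   kept fixed at `delta = 4`).
#' @param grid Named list of parameter value vectors, e.g.
#'   `list(q_con = seq(0.3, 0.7, 0.05), q_mod = seq(0.2, 0.6, 0.05))`.
#' @param reference A `ppifamSummary` from [referenceSummary()]; if it
#'   carries graphlet statistics, candidates are scored with the GDDA
#'   term as well.
#' @param size Node count of the candidate networks.
#' @param replicates Networks generated per grid point.
#' @param weights Passed to [scoreCandidate()].
#' @param seedSize Seed-network size for candidate growth.
#' @param seed Optional integer seed (whole search reproducible).
#' @return List with `best` (a [ModelParams-class]) and `table` (a
#'   `data.frame` of all grid points and mean scores).
#' @export
gridSearch <- function(model, grid, reference, size, replicates = 3L,
                       weights = c(density = 1, degree = 1, cc = 1, gdda = 1),
                       seedSize = 50L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  model <- match.arg(tolower(model), c("dmc", "dmr", "cg", "sticky"))
  stopifnot(length(grid) >= 1L, !is.null(names(grid)), replicates >= 1L)
  pts <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  useGdd <- !is.null(reference$gdd)
  scores <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    mp <- do.call(modelParams, c(list(model), as.list(pts[i, , drop = FALSE])))
    reps <- vapply(seq_len(replicates), function(r) {
      net <- growToSize(makeSeedNetwork(min(seedSize, size)), size, mp)
      scoreCandidate(referenceSummary(net, includeGraphlets = useGdd),
                     reference, weights)
    }, numeric(1))
    scores[i] <- mean(reps)
  }
  tab <- cbind(pts, score = scores)
  ord <- do.call(order, c(list(scores), as.list(pts)))
  best <- tab[ord[1L], , drop = FALSE]
  bestParams <- do.call(modelParams,
                        c(list(model),
                          as.list(best[, names(grid), drop = FALSE])))
  list(best = bestParams, table = tab)
}

#' Equal-width parameter grid
#'
#' @param min,max Range limits.
#' @param step Grid step (default 0.05).
#' @return Numeric vector of grid values.
#' @export
gridSpec <- function(min, max, step = 0.05) {
  if (min > max || step <= 0) stop("need min <= max and step > 0")
  seq(min, max, by = step)
}
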