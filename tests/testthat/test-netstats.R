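test_that("clustering coefficients follow 2e/(k(k-1)) with the k<2 convention", {
  expect_equal(clusteringCoefficient(triangleNet(), "a"), 1)
  expect_equal(clusteringCoefficient(pathNet(3), "p2"), 0)
  expect_equal(clusteringCoefficient(pathNet(2), "p1"), 0)  # degree 1
  # k = 3 with 2 neighbour edges -> 2/3
  net <- PPINetwork("m", edges = cbind(c("c", "c", "c", "a", "b"),
                                       c("a", "b", "d", "b", "d")))
  expect_equal(clusteringCoefficient(net, "c"), 2 / 3)
  expect_error(clusteringCoefficient(net, "zz"), "unknown node")
})

test_that("degree-exponent regression is exact on noiseless power laws", {
  k <- 1:100
  expect_equal(fitDegreeExponent(stats::setNames(k^-2 * 1e8, k)), 2,
               tolerance = 1e-9)
  expect_equal(fitDegreeExponent(stats::setNames(k^-1.6 * 1e8, k)), 1.6,
               tolerance = 1e-9)
  expect_equal(fitDegreeExponent(c(`1` = 10, `10` = 1)), 1, tolerance = 1e-12)
  expect_error(fitDegreeExponent(c(`3` = 5)), "at least two")
})

test_that("the graphlet catalogue enumerates 30 graphlets and 73 orbits", {
  cat29 <- graphletCatalogue()
  expect_equal(nrow(cat29$graphlets), 30L)
  expect_equal(as.integer(table(cat29$graphlets$size)), c(1L, 2L, 6L, 21L))
  expect_equal(sum(cat29$graphlets$size >= 3), 29L)  # the classic catalogue
  expect_equal(nrow(cat29$orbits), 73L)
  expect_equal(sort(cat29$orbits$orbit), 0:72)
  # graphlets on <= 3 nodes: edge (1 orbit), path (2), triangle (1)
  expect_equal(sum(cat29$orbits$size <= 3), 4L)
  expect_equal(cat29$orbits$orbit[cat29$orbits$size == 2], 0L)
  # orbit multiplicities within each graphlet sum to its node count
  ms <- tapply(cat29$orbits$multiplicity, cat29$orbits$graphlet, sum)
  expect_equal(as.integer(ms), cat29$graphlets$size)
})

test_that("catalogue representatives are connected and pairwise non-isomorphic", {
  cat29 <- graphletCatalogue()
  gs <- lapply(seq_len(nrow(cat29$graphlets)), function(i)
    .repIgraph(cat29$graphlets$mask[i], cat29$graphlets$size[i]))
  expect_true(all(vapply(gs, igraph::is_connected, logical(1))))
  for (i in seq_along(gs)) for (j in seq_len(i - 1L)) {
    if (igraph::vcount(gs[[i]]) != igraph::vcount(gs[[j]])) next
    expect_false(igraph::isomorphic(gs[[i]], gs[[j]]), info = paste(i, j))
  }
})

test_that("graphlet degree distributions match exhaustive expectations", {
  # triangle: orbit 0 twice, triangle orbit once per node
  gs <- graphletDegreeDistributions(triangleNet())
  expect_equal(unname(gs@counts[, 1]), c(2, 2, 2))
  expect_equal(unname(gs@counts[, 4]), c(1, 1, 1))  # orbit 3 = triangle
  expect_equal(sum(gs@counts), 3 * 2 + 3 * 1)
  # 4-cycle: each node is a path end twice, a path middle once, and
  # touches the single 4-node orbit (of the 4-edge cycle graphlet) once
  g4 <- graphletDegreeDistributions(cycleNet(4))
  expect_equal(unname(g4@counts[, 2]), rep(2, 4))   # orbit 1, path end
  expect_equal(unname(g4@counts[, 3]), rep(1, 4))   # orbit 2, path middle
  cat29 <- graphletCatalogue()
  four <- cat29$orbits[cat29$orbits$size == 4, ]
  touched <- which(colSums(g4@counts) > 0) - 1L
  o4 <- intersect(touched, four$orbit)
  expect_length(o4, 1L)
  cyc <- four[four$orbit == o4, ]
  expect_equal(cat29$graphlets$edges[cat29$graphlets$id == cyc$graphlet], 4L)
  expect_equal(unname(g4@counts[, o4 + 1L]), rep(1, 4))
  # empty network
  e <- graphletDegreeDistributions(PPINetwork("void"))
  expect_equal(nrow(e@counts), 0L)
})

test_that("orbit-0 distribution equals the degree histogram", {
  for (s in 1:10) {
    net <- rndNet(18, 0.2, seed = 100 + s)
    gs <- graphletDegreeDistributions(net)
    expect_equal(unname(gs@counts[, 1]), unname(as.numeric(nodeDegree(net))),
                 info = s)
  }
})

test_that("compiled orbit counts agree with the brute-force subset oracle", {
  om <- .oracleOrbitMap()
  for (s in 1:3) {
    net <- rndNet(11, 0.3, seed = 200 + s)
    fast <- graphletDegreeDistributions(net)@counts
    slow <- bruteOrbitCounts(net, om)
    expect_equal(unname(fast), unname(slow), info = s)
  }
  # denser case
  net <- rndNet(9, 0.5, seed = 300)
  expect_equal(unname(graphletDegreeDistributions(net)@counts),
               unname(bruteOrbitCounts(net, om)))
})

test_that("GDDA is symmetric, bounded, and separates disjoint distributions", {
  a <- graphletDegreeDistributions(rndNet(20, 0.2, seed = 7))
  b <- graphletDegreeDistributions(rndNet(20, 0.3, seed = 8))
  expect_equal(gdda(a, b), gdda(b, a))
  expect_gte(gdda(a, b), 0)
  expect_lte(gdda(a, b), 1)
  expect_equal(gdda(a, a), 1)
  # single-orbit mass at different k: orthogonal unit vectors -> agreement 0
  mk <- function(k) {
    m <- matrix(0, 5, 73)
    m[, 6] <- k
    new("GraphletStats", counts = m, network = "x")
  }
  expect_equal(gdda(mk(2), mk(3)), 0)
})

test_that("Gamma fits recover known parameters and reject bad input", {
  set.seed(5)
  x <- stats::rgamma(10000, shape = 2, scale = 3)
  fit <- fitGamma(x)
  expect_lt(abs(fit@shape - 2) / 2, 0.05)
  expect_lt(abs(fit@scale - 3) / 3, 0.05)
  expect_error(fitGamma(c(x[1:20], -1)), "positive")
  expect_error(fitGamma(rep(2, 100)), "degenerate|constant")
  expect_error(fitGamma(x[1:5]), "at least 10")
})

test_that("network summaries report the standard row", {
  s <- networkSummary(cliqueNet(5))
  expect_equal(s$nodes, 5L)
  expect_equal(s$edges, 10L)
  expect_equal(s$edgesPerNode, 2)
  expect_equal(s$meanClustering, 1)
  empty <- networkSummary(PPINetwork("void"))
  expect_equal(empty$nodes, 0L)
  expect_true(is.na(empty$degreeExponent))
})
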