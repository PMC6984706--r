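test_that("stickiness indices normalize assigned degrees", {
  expect_equal(stickinessIndices(c(a = 1, b = 2, c = 1)),
               c(a = 0.25, b = 0.5, c = 0.25))
  expect_equal(stickinessIndices(c(a = 5)), c(a = 1))
  expect_error(stickinessIndices(c(a = 0, b = 0)), "degenerate")
  for (s in 1:10) {
    set.seed(s)
    th <- stickinessIndices(stats::runif(20, 0.1, 9))
    expect_equal(sum(th), 1, tolerance = 1e-12)
  }
})

test_that("static stickiness model matches its closed-form edge expectation", {
  # equal assigned degrees d over n nodes: per-pair probability d/n,
  # expected edges C(n,2) * d / n = (n-1) d / 2
  n <- 20; d <- 4; reps <- 600
  set.seed(42)
  m <- vapply(seq_len(reps), function(i)
    edgeCount(stickyStatic(rep(d, n))), numeric(1))
  p <- d / n
  se <- sqrt(choose(n, 2) * p * (1 - p) / reps)
  expect_lt(abs(mean(m) - (n - 1) * d / 2), 3 * se)
  # determinism
  expect_identical(edgeMatrix(stickyStatic(rep(3, 15), seed = 9)),
                   edgeMatrix(stickyStatic(rep(3, 15), seed = 9)))
})

test_that("sticky add-node edge frequencies match the product rule with repair", {
  # frozen 10-node state; gamma large so the sampled degree is 1 almost
  # surely; per-pair insertion min(1, d * d_j / sum d), conditioned on
  # the new node keeping at least one edge (f_del = 0 isolates insertion)
  base <- cliqueNet(5)
  ring <- cycleNet(5, "r")
  net <- PPINetwork("frozen", edges = rbind(edgeMatrix(base),
                                            edgeMatrix(ring),
                                            cbind("k1", "r1")))
  mp <- modelParams("sticky", gamma_deg = 30, f_del = 0, d_max = 50)
  dvec <- as.numeric(nodeDegree(net))
  names(dvec) <- nodeIds(net)
  pIns <- pmin(1, 1 * dvec / (sum(dvec) + 1))
  pCond <- pIns / (1 - prod(1 - pIns))
  reps <- 4000
  set.seed(7)
  hits <- stats::setNames(numeric(length(dvec)), names(dvec))
  for (i in seq_len(reps)) {
    grown <- addNode(net, mp)
    nb <- edgeMatrix(grown)
    newId <- setdiff(nodeIds(grown), nodeIds(net))
    nbs <- c(nb[nb[, 1] == newId, 2], nb[nb[, 2] == newId, 1])
    hits[nbs] <- hits[nbs] + 1
  }
  freq <- hits / reps
  se <- sqrt(pCond * (1 - pCond) / reps)
  expect_true(all(abs(freq - pCond) <= 3 * se + 1e-9))
})

test_that("the sticky deletion step removes at most one inserted edge", {
  # two high-stickiness nodes: insertion to both is certain whenever the
  # sampled degree is >= 3; with f_del = 1 exactly one edge is removed,
  # so the committed node has degree 1 (degree-2 outcomes only from
  # low-degree draws); with f_del = 0 it has degree 2
  net <- PPINetwork("h", edges = cbind("a", "b"))
  attr(net, "stickyDegrees") <- c(a = 30, b = 30)
  set.seed(15)
  degDel <- vapply(1:300, function(i) {
    g <- addNode(net, modelParams("sticky", f_del = 1))
    nodeDegree(g, setdiff(nodeIds(g), c("a", "b")))
  }, numeric(1))
  expect_true(all(degDel <= 2))
  expect_gt(mean(degDel == 1), 0.8)
  keep <- t(vapply(1:150, function(i) {
    g <- addNode(net, modelParams("sticky", f_del = 0))
    newId <- setdiff(nodeIds(g), c("a", "b"))
    c(deg = nodeDegree(g, newId),
      assigned = unname(attr(g, "stickyDegrees")[newId]))
  }, numeric(2)))
  # insertion to both anchors is certain once the assigned degree is >= 3
  expect_true(all(keep[keep[, "assigned"] >= 3, "deg"] == 2))
})

test_that("sticky degree sampler concentrates at 1 for large exponents", {
  mp <- modelParams("sticky", gamma_deg = 6, f_del = 0)
  net <- cliqueNet(6)
  set.seed(3)
  draws <- vapply(1:400, function(i) {
    grown <- addNode(net, mp)
    sd <- attr(grown, "stickyDegrees")
    unname(sd[setdiff(names(sd), nodeIds(net))])
  }, numeric(1))
  cNorm <- 1 / sum((1:50)^(-6))
  se <- sqrt(cNorm * (1 - cNorm) / length(draws))
  expect_lt(abs(mean(draws == 1) - cNorm), 3 * se + 1e-9)
})

test_that("DMC parameter limits give exact duplication behaviour", {
  net <- rndNet(12, 0.3, seed = 2)
  # q_mod = 0, q_con = 0: the new node copies its anchor exactly
  set.seed(10)
  g0 <- addNode(net, modelParams("dmc", q_mod = 0, q_con = 0))
  newId <- setdiff(nodeIds(g0), nodeIds(net))
  e <- edgeMatrix(g0)
  nbs <- sort(c(e[e[, 1] == newId, 2], e[e[, 2] == newId, 1]))
  anchors <- Filter(function(v) {
    setequal(nbs, c(e[e[, 1] == v, 2], e[e[, 2] == v, 1]) |> setdiff(newId))
  }, nodeIds(net))
  expect_gt(length(anchors), 0)
  expect_false(newId %in% c(nbs))
  # q_mod = 0, q_con = 1: v duplicates u and links to it
  set.seed(11)
  g1 <- addNode(net, modelParams("dmc", q_mod = 0, q_con = 1))
  newId <- setdiff(nodeIds(g1), nodeIds(net))
  dNew <- nodeDegree(g1, newId)
  expect_equal(edgeCount(g1) - edgeCount(net), dNew)
  e1 <- edgeMatrix(g1)
  nbs1 <- sort(c(e1[e1[, 1] == newId, 2], e1[e1[, 2] == newId, 1]))
  # the anchor is among v's neighbours and donates the remaining ones
  anchors1 <- Filter(function(v) {
    setequal(setdiff(nbs1, v),
             setdiff(c(e1[e1[, 1] == v, 2], e1[e1[, 2] == v, 1]), newId))
  }, nbs1)
  expect_gt(length(anchors1), 0)
  # q_mod = 1: expected net degree change = q_con (one copy survives
  # per neighbour); Monte-Carlo on the edge-count increment
  set.seed(12)
  inc <- vapply(1:600, function(i)
    edgeCount(addNode(net, modelParams("dmc", q_mod = 1, q_con = 0.5))) -
      edgeCount(net), numeric(1))
  # each neighbour keeps exactly one of the two copies: increment = q_con
  expect_lt(abs(mean(inc) - 0.5), 3 * sqrt(0.25 / 600) + 0.05)
})

test_that("DMR parameter limits and random-attachment expectation hold", {
  net <- rndNet(50, 0.12, seed = 4)
  # q_del = 0, q_new = 0: exact neighbourhood duplication
  set.seed(20)
  g0 <- addNode(net, modelParams("dmr", q_del = 0, q_new = 0))
  newId <- setdiff(nodeIds(g0), nodeIds(net))
  e <- edgeMatrix(g0)
  nbs <- sort(c(e[e[, 1] == newId, 2], e[e[, 2] == newId, 1]))
  anchors <- Filter(function(v) {
    setequal(nbs, c(e[e[, 1] == v, 2], e[e[, 2] == v, 1]) |> setdiff(newId))
  }, nodeIds(net))
  expect_gt(length(anchors), 0)
  # q_del = 1, q_new = 0: no escape from the singleton -> retry cap error
  expect_error(addNode(net, modelParams("dmr", q_del = 1, q_new = 0),
                       maxRetry = 50),
               "singleton repair failed")
  # expected degree of the new node: E[deg(u)] + q_new (N-1-E[deg]) / N
  n <- nodeCount(net)
  mdeg <- mean(nodeDegree(net))
  expected <- mdeg + 0.85 * (n - 1 - mdeg) / n
  set.seed(21)
  degs <- vapply(1:800, function(i) {
    g <- addNode(net, modelParams("dmr", q_del = 0, q_new = 0.85))
    nodeDegree(g, setdiff(nodeIds(g), nodeIds(net)))
  }, numeric(1))
  expect_lt(abs(mean(degs) - expected), 3 * stats::sd(degs) / sqrt(800))
})

test_that("CG adds exactly delta edges per node and respects preconditions", {
  seedNet <- makeSeedNetwork(20, seed = 1)
  grown <- growToSize(seedNet, 120, modelParams("cg"), seed = 2)
  expect_equal(edgeCount(grown), edgeCount(seedNet) + 4L * 100L)
  expect_equal(nodeCount(grown), 120L)
  # delta = 1 grows a tree from a single edge
  pairNet <- PPINetwork("p2", edges = cbind("a", "b"))
  tree <- growToSize(pairNet, 30, modelParams("cg", delta = 1), seed = 3)
  expect_equal(edgeCount(tree), 29L)
  expect_true(igraph::is_connected(asIgraph(tree)))
  # network smaller than delta
  expect_error(addNode(pairNet, modelParams("cg", delta = 5)), "delta")
})

test_that("growth is deterministic under a fixed seed and size-exact", {
  for (model in c("dmc", "dmr", "cg", "sticky")) {
    s <- makeSeedNetwork(20, seed = 5)
    a <- growToSize(s, 80, modelParams(model), seed = 31)
    b <- growToSize(s, 80, modelParams(model), seed = 31)
    expect_identical(edgeMatrix(a), edgeMatrix(b), info = model)
    expect_identical(foAnnotation(a), foAnnotation(b), info = model)
    expect_equal(nodeCount(a), 80L, info = model)
    expect_true(min(nodeDegree(a)) >= 1L, info = model)
  }
  # identity growth
  s <- makeSeedNetwork(15, seed = 6)
  expect_identical(edgeMatrix(growToSize(s, 15, modelParams("dmc"))),
                   edgeMatrix(s))
})

test_that("sticky growth retains no singletons even under heavy deletion", {
  s <- makeSeedNetwork(15, seed = 8)
  net <- growToSize(s, 60, modelParams("sticky", f_del = 0.9), seed = 9)
  expect_true(min(nodeDegree(net)) >= 1L)
})

test_that("seed networks are connected with one founder FO group per node", {
  expect_equal(edgeCount(makeSeedNetwork(5)), 10L)  # saturates to the 5-clique
  for (s in 1:20) {
    seedNet <- makeSeedNetwork(30, seed = s)
    expect_true(igraph::is_connected(asIgraph(seedNet)))
  }
  seedNet <- makeSeedNetwork(40, seed = 3)
  fo <- foAnnotation(seedNet)
  expect_false(any(is.na(fo)))
  expect_equal(length(unique(fo)), 40L)
  expect_equal(edgeCount(seedNet), round(2.2 * 40))
})

test_that("neighbour selection follows stickiness weights", {
  set.seed(99)
  sd <- c(n1 = 3, n2 = 1)
  picks <- vapply(1:4000, function(i)
    pickNeighborByStickiness(c("n1", "n2"), sd), character(1))
  f <- mean(picks == "n1")
  expect_lt(abs(f - 0.75), 3 * sqrt(0.75 * 0.25 / 4000))
  expect_identical(pickNeighborByStickiness("only", c(only = 2)), "only")
  expect_error(pickNeighborByStickiness(character(), sd), "no neighbours")
})
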