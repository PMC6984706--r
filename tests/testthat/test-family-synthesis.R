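test_that("phylogeny parsing validates structure, sizes and monotonicity", {
  tr <- parsePhylogeny("(A|3000,B|4000)Root|2000;")
  expect_equal(tr@size, 2000L)
  expect_equal(sort(unname(phylogenyLeaves(tr))), c(3000L, 4000L))
  expect_error(parsePhylogeny("(A|100)R|50;"))
  expect_error(parsePhylogeny("(A|40,B|60)R|50;"), "smaller than parent")
  expect_error(parsePhylogeny("(A,B|60)R|50;"), "name\\|size")
  expect_error(parsePhylogeny("(A|10,B|20,C|30)R|5;"), "children")
})

test_that("leaf networks have exactly their tree-specified sizes", {
  fam <- synthesizeFamily(parsePhylogeny("(A|64,(B|90,C|75)I|70)R|55;"),
                          modelParams("cg"), seed = 13, seedSize = 20)
  expect_named(fam@networks, c("A", "B", "C"), ignore.order = TRUE)
  expect_equal(nodeCount(fam@networks$A), 64L)
  expect_equal(nodeCount(fam@networks$B), 90L)
  expect_equal(nodeCount(fam@networks$C), 75L)
  for (nw in fam@networks) expect_true(min(nodeDegree(nw)) >= 1L)
})

test_that("duplication without growth yields a perfect 1:1 ground truth", {
  fam <- synthesizeFamily(parsePhylogeny("(A|60,B|60)R|60;"),
                          modelParams("dmc"),
                          cross = crossNetParams(p_fo = 1),
                          seed = 17, seedSize = 20)
  a <- fam@networks$A; b <- fam@networks$B
  # identical topology modulo the name prefix
  expect_identical(gsub("^A", "B", edgeMatrix(a)), edgeMatrix(b))
  # every annotated A node pairs with the mirrored B node in the same group
  foA <- foAnnotation(a); foB <- foAnnotation(b)
  expect_identical(unname(foA), unname(foB))
  # with p_fo = 1 every node whose lineage exists is annotated
  g <- fam@groups
  byGroup <- split(g, g$group)
  for (gr in byGroup) {
    mA <- sort(gr$node[gr$network == "A"])
    mB <- sort(gr$node[gr$network == "B"])
    expect_identical(gsub("^A", "B", mA), mB)
  }
})

test_that("annotation dropout is per-node binomial", {
  expect_false(any(is.na(assignFunctions(rep("F1", 500), 1))))
  expect_true(all(is.na(assignFunctions(rep("F1", 500), 0))))
  set.seed(23)
  lab <- assignFunctions(rep("F1", 10000), 0.9)
  frac <- mean(is.na(lab))
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / 10000))
})

test_that("similarity scores follow the configured Gamma laws", {
  # two fully orthologous blocks, no jitter: scores are pure Gamma draws
  ids <- function(p, n) paste0(p, "_", seq_len(n))
  mkNet <- function(nm, n, nLab) {
    e <- cbind(ids(nm, n)[-n], ids(nm, n)[-1])
    PPINetwork(nm, edges = e,
               fo = stats::setNames(rep("F1", nLab), ids(nm, n)[1:nLab]))
  }
  nets <- list(A = mkNet("A", 220, 160), B = mkNet("B", 220, 160))
  groups <- do.call(rbind, lapply(nets, function(nw) {
    fo <- foAnnotation(nw)
    data.frame(group = "F1", network = networkName(nw),
               node = names(fo)[!is.na(fo)])
  }))
  cp <- crossNetParams(lambda_max = 0)
  sims <- emitSimilarities(nets, groups, cp, seed = 33)
  orth <- sims$score[sims$orthologous]
  expect_equal(length(orth), 160L * 160L)
  seO <- cp@theta_o * sqrt(cp@k_o) / sqrt(length(orth))
  expect_lt(abs(mean(orth) - cp@k_o * cp@theta_o), 3 * seO)
  spur <- sims$score[!sims$orthologous]
  expect_gt(length(spur), 100)
  seN <- cp@theta_n * sqrt(cp@k_n) / sqrt(length(spur))
  expect_lt(abs(mean(spur) - cp@k_n * cp@theta_n), 3 * seN)
  # spurious partners are never in the same FO group (here: none exist)
  expect_true(all(sims$orthologous == (sims$score %in% orth)))
  # determinism
  sims2 <- emitSimilarities(nets, groups, cp, seed = 33)
  expect_identical(sims, sims2)
})

test_that("orthologous pairs carry exactly one similarity record each", {
  fam <- synthesizeFamily(parsePhylogeny("(A|70,B|85)R|60;"),
                          modelParams("dmr"), seed = 37, seedSize = 20)
  g <- fam@groups
  sims <- fam@similarities
  orth <- sims[sims$orthologous, ]
  key <- paste(orth$net_a, orth$node_a, orth$net_b, orth$node_b)
  expect_false(anyDuplicated(key) > 0)
  expected <- sum(vapply(split(g, g$group), function(gr) {
    tab <- table(gr$network)
    if (length(tab) < 2) return(0)
    sum(utils::combn(as.integer(tab), 2, FUN = prod))
  }, numeric(1)))
  expect_equal(nrow(orth), expected)
})

test_that("potential-ortholog counts apply a strict threshold", {
  sims <- data.frame(net_a = "A", node_a = "v",
                     net_b = "B", node_b = c("u1", "u2"),
                     score = c(50, 40), orthologous = TRUE)
  pc <- potentialOrthologCounts(sims, 45)
  expect_equal(pc$count[pc$node == "v"], 1L)
  pc0 <- potentialOrthologCounts(sims, 0)
  expect_equal(pc0$count[pc0$node == "v"], 2L)
  pcInf <- potentialOrthologCounts(sims, 1e9)
  expect_true(all(pcInf$count == 0L))
})

test_that("family synthesis is reproducible for a fixed seed", {
  tr <- parsePhylogeny("(A|60,B|70)R|50;")
  f1 <- synthesizeFamily(tr, modelParams("sticky"), seed = 41, seedSize = 20)
  f2 <- synthesizeFamily(tr, modelParams("sticky"), seed = 41, seedSize = 20)
  expect_identical(lapply(f1@networks, edgeMatrix),
                   lapply(f2@networks, edgeMatrix))
  expect_identical(f1@similarities, f2@similarities)
  expect_identical(f1@groups, f2@groups)
})
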