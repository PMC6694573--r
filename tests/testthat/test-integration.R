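test_that("projection sums positive and negative neighbour weights", {
  expect_equal(projectNetwork(pathNetwork(), pathLabeling()),
               data.frame(id = c("a", "b", "c"), p1 = c(0, 1, 0),
                          p2 = c(1, 1, 1), label = c(1L, 0L, 0L)))

  edgeless <- weightedNetwork(vertices = c("a", "b", "c"))
  pts <- projectNetwork(edgeless, pathLabeling())
  expect_true(all(pts$p1 == 0 & pts$p2 == 0))

  star <- weightedNetwork(data.frame(from = "h", to = c("p", "n1", "n2"),
                                     weight = c(0.5, 0.25, 0.25)))
  lab <- termLabeling("GO:s", "p", vertexIds(star))
  h <- projectNetwork(star, lab)
  expect_equal(h[h$id == "h", c("p1", "p2")],
               data.frame(p1 = 0.5, p2 = 0.5, row.names = 1L))

  expect_error(projectNetwork(pathNetwork(),
                              termLabeling("GO:1", "a", c("a", "b"))),
               "aligned")
})

test_that("fMeasure follows the printed formula and its edge cases", {
  expect_identical(fMeasure(tp = 2, fp = 1, fn = 0), 0.8)
  expect_identical(fMeasure(tp = 0, fp = 5, fn = 3), 0)
  expect_identical(fMeasure(tp = 7, fp = 0, fn = 0), 1)
  expect_error(fMeasure(tp = 0, fp = 3, fn = 0), "undefined")
})

test_that("evaluateLine applies the strict half-plane rule", {
  pts <- data.frame(p1 = c(1, 0), p2 = c(0, 1), label = c(1L, 0L))
  expect_equal(evaluateLine(pts, pi / 4, 0),
               list(tp = 1L, fp = 0L, fn = 0L, tn = 1L))

  # q above every achievable score: nothing predicted positive
  high <- evaluateLine(pts, pi / 4, 10)
  expect_equal(high$tp + high$fp, 0L)

  # boundary points are predicted negative
  onLine <- data.frame(p1 = 1, p2 = 1, label = 1L)
  expect_equal(evaluateLine(onLine, pi / 4, 0)$tp, 0L)

  worked <- data.frame(p1 = c(1, 0, 1, 0), p2 = c(0, 1, 1, 0),
                       label = c(1L, 1L, 0L, 0L))
  counts <- evaluateLine(worked, pi / 4, -1)
  expect_equal(counts$tp, 2L)
  expect_equal(counts$fp, 2L)
})

test_that("learnOptimalLine finds separable optima and breaks ties", {
  sep <- data.frame(p1 = c(1, 2, 0, 0), p2 = c(0, 0, 1, 2),
                    label = c(1L, 1L, 0L, 0L))
  best <- learnOptimalLine(sep)
  expect_equal(best$f, 1)
  expect_equal(best$counts, list(tp = 2L, fp = 0L, fn = 0L, tn = 2L))

  tie <- data.frame(p1 = c(1, 0, 1, 0), p2 = c(0, 1, 1, 0),
                    label = c(1L, 1L, 0L, 0L))
  bestTie <- learnOptimalLine(tie)
  expect_equal(bestTie$f, 2 / 3)
  expect_equal(bestTie$counts$tp, 2L)

  degenerate <- data.frame(p1 = c(0, 0), p2 = c(0, 0), label = c(1L, 0L))
  bestDeg <- learnOptimalLine(degenerate)
  expect_equal(bestDeg$f, 2 / 3)

  expect_error(learnOptimalLine(data.frame(p1 = 1, p2 = 1, label = 0L)),
               "positive")

  # the learned line reproduces its own confusion counts
  counts <- evaluateLine(tie, bestTie$alpha, bestTie$q)
  expect_equal(counts, bestTie$counts)
})

test_that("relevance captures informativeness and its invariances", {
  # disjoint positive and negative cliques: perfectly separable
  cliq <- weightedNetwork(data.frame(
    from = c("a", "a", "b", "x", "x", "y"),
    to = c("b", "c", "c", "y", "z", "z"), weight = 1))
  lab <- termLabeling("GO:c", c("a", "b", "c"), vertexIds(cliq))
  expect_equal(networkRelevance(cliq, lab)$relevance, 1)

  # edgeless network: only the trivial all-positive line is available
  edgeless <- weightedNetwork(vertices = sprintf("v%d", 1:10))
  lab10 <- termLabeling("GO:e", "v1", vertexIds(edgeless))
  expect_equal(networkRelevance(edgeless, lab10)$relevance, 2 / 11)

  expect_error(
    networkRelevance(cliq, new("TermLabeling", term = "GO:none",
                               positives = character(),
                               universe = vertexIds(cliq))),
    "no positive")

  # global rescaling of the weights leaves relevance unchanged
  for (seed in 1:4) {
    net <- randomNetwork(n = 14, m = 28, seed = seed)
    labr <- termLabeling("GO:r", sample(vertexIds(net), 3), vertexIds(net))
    r1 <- networkRelevance(net, labr)$relevance
    scaled <- net
    adj <- adjacencyMatrix(net); adj@x <- adj@x * 37.5
    scaled@adjacency <- adj
    expect_equal(networkRelevance(scaled, labr)$relevance, r1,
                 tolerance = 1e-12)
  }
})

test_that("integrating one network returns its max-normalized self", {
  net <- randomNetwork(n = 12, m = 20, seed = 3)
  lab <- termLabeling("GO:x", vertexIds(net)[1:3], vertexIds(net))
  cons <- integrateNetworks(networkCollection(list(net)), lab)
  expect_equal(edgeTable(cons), edgeTable(maxNormalize(net)))

  # two identical networks: consensus identical to either
  net2 <- net; net2@name <- "copy"
  cons2 <- integrateNetworks(networkCollection(list(net, net2)), lab)
  expect_equal(edgeTable(cons2)$weight, edgeTable(maxNormalize(net))$weight)
})

test_that("consensus weights are the relevance-weighted mean", {
  fix <- sixNodeInstance()
  lab <- fix$labeling
  cons <- integrateNetworks(networkCollection(fix$nets), lab)
  rep <- relevanceReport(cons)
  r <- setNames(rep$relevance, rep$network)

  norm1 <- maxNormalize(alignToUniverse(fix$nets[[1]], fix$ids))
  norm2 <- maxNormalize(alignToUniverse(fix$nets[[2]], fix$ids))
  w1 <- adjacencyMatrix(norm1)["u1", "u2"]
  w2 <- adjacencyMatrix(norm2)["u1", "u2"]
  expected <- (r[["netA"]] * w1 + r[["netB"]] * w2) / sum(r)
  expect_equal(adjacencyMatrix(cons)["u1", "u2"], expected)

  # convexity: every consensus weight within the per-edge input range
  et <- edgeTable(cons)
  for (k in seq_len(nrow(et))) {
    inputs <- c(adjacencyMatrix(norm1)[et$from[k], et$to[k]],
                adjacencyMatrix(norm2)[et$from[k], et$to[k]])
    expect_lte(et$weight[k], max(inputs) + 1e-12)
    expect_gte(et$weight[k], 0)
  }

  # provenance: shared edge lists both networks, private edges one
  prov <- edgeProvenance(cons)
  key <- paste(prov$from, prov$to)
  expect_setequal(prov$sources[[match("u1 u2", key)]], c("netA", "netB"))
  expect_identical(prov$sources[[match("u5 u6", key)]], "netA")
  expect_identical(prov$sources[[match("u2 u4", key)]], "netB")
})

test_that("relevance reports and consensus files round-trip", {
  fix <- sixNodeInstance()
  cons <- integrateNetworks(networkCollection(fix$nets), fix$labeling)
  dir <- withr::local_tempdir()
  paths <- writeConsensus(cons, file.path(dir, "consensus.tsv"))
  relPath <- writeRelevanceReport(relevanceReport(cons),
                                  file.path(dir, "relevance.tsv"))

  back <- readConsensus(paths[["consensus"]], relevancePath = relPath,
                        term = termId(cons))
  expect_equal(edgeTable(back), edgeTable(cons))
  expect_equal(edgeProvenance(back)$sources, edgeProvenance(cons)$sources)
  expect_equal(relevanceReport(back)$relevance,
               relevanceReport(cons)$relevance)
})
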