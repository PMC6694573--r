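test_that("triplet networks parse, deduplicate and report malformed lines", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "", "a\tb\t1.0", "b\tc\t0.5"), f)
  net <- readTripletNetwork(f, name = "t")
  expect_identical(vertexIds(net), c("a", "b", "c"))
  expect_equal(edgeTable(net),
               data.frame(from = c("a", "b"), to = c("b", "c"),
                          weight = c(1, 0.5)))

  writeLines(c("a\tb\t1.0", "b\ta\t1.0"), f)
  expect_equal(numEdges(readTripletNetwork(f)), 1L)

  writeLines("a\tb", f)
  expect_error(readTripletNetwork(f), "line 1")
  writeLines(c("a\tb\t1", "c\td\tx"), f)
  expect_error(readTripletNetwork(f), "line 2")
  writeLines("a\tb\t-0.5", f)
  expect_error(readTripletNetwork(f), "negative")
  writeLines(c("# only", ""), f)
  expect_error(readTripletNetwork(f), "no data")
  writeLines("a\tb\t1e-3", f)
  expect_equal(edgeTable(readTripletNetwork(f))$weight, 0.001)
})

test_that("triplet write/read round-trips edges and weights exactly", {
  net <- randomNetwork(n = 25, m = 100, seed = 99)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeTripletNetwork(net, f)
  back <- readTripletNetwork(f, name = networkName(net))
  expect_identical(edgeTable(back), edgeTable(net))
  expect_setequal(vertexIds(back), setdiff(vertexIds(net),
    setdiff(vertexIds(net), c(edgeTable(net)$from, edgeTable(net)$to))))

  # gz round trip
  fz <- withr::local_tempfile(fileext = ".tsv.gz")
  writeTripletNetwork(net, fz)
  expect_identical(edgeTable(readTripletNetwork(fz)), edgeTable(net))

  # edgeless network writes a readable, data-free file
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeTripletNetwork(weightedNetwork(vertices = c("a", "b")), f2)
  expect_true(all(grepl("^#|^$", readLines(f2))))
})

test_that("protein lists preserve order, strip whitespace, drop duplicates", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("p2", "p1"), f)
  expect_identical(readProteinList(f), c("p2", "p1"))

  writeLines(c("p1", "", "p1"), f)
  expect_warning(ids <- readProteinList(f), "duplicate")
  expect_identical(ids, "p1")

  writeLines(c(" p1 ", "p2\t", "p3"), f)
  expect_identical(readProteinList(f), c("p1", "p2", "p3"))

  writeLines(character(), f)
  expect_error(readProteinList(f), "empty")
})

test_that("term annotation tables select exactly the requested term", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("p1\tGO:1", "p2\tGO:2", "p3\tGO:1", "p3\tGO:1"), f)
  expect_setequal(readTermAnnotations(f, "GO:1"), c("p1", "p3"))
  expect_length(readTermAnnotations(f, "GO:1"), 2)
  expect_error(readTermAnnotations(f, "GO:9"), "no annotated")
})

test_that("alias mapping is loss-free when complete, reported when not", {
  net <- weightedNetwork(data.frame(from = "g1", to = "g2", weight = 1))
  full <- applyAliasMap(net, c(g1 = "E1", g2 = "E2"))
  expect_equal(edgeTable(full$network),
               data.frame(from = "E1", to = "E2", weight = 1))
  expect_length(full$report$unmapped, 0)
  expect_equal(full$report$droppedEdges, 0)

  partial <- applyAliasMap(net, c(g1 = "E1"))
  expect_equal(numEdges(partial$network), 0L)
  expect_identical(partial$report$unmapped, "g2")
  expect_equal(partial$report$droppedEdges, 1)

  merged <- applyAliasMap(net, c(g1 = "E1", g2 = "E1"))
  expect_equal(numEdges(merged$network), 0L)
  expect_equal(merged$report$selfLoops, 1)

  # identity map is the identity
  ids <- vertexIds(net)
  ident <- applyAliasMap(net, setNames(ids, ids))
  expect_identical(edgeTable(ident$network), edgeTable(net))
  expect_length(ident$report$unmapped, 0)
})

test_that("alias map files reject conflicting mappings", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("g1\tE1", "g1\tE1", "g2\tE2"), f)
  expect_equal(readAliasMap(f), c(g1 = "E1", g2 = "E2"))
  writeLines(c("g1\tE1", "g1\tE9"), f)
  expect_error(readAliasMap(f), "multiple canonical")
})

test_that("JSON export/import round-trips a decorated subgraph", {
  cons <- toyConsensus()
  sg <- egoSubgraph(cons, "hub", depth = 2)
  lab <- termLabeling("GO:toy", "hub", vertexIds(cons))
  pred <- predictProteins(cons, lab, mode = "all")
  sg <- decorateSubgraph(sg, lab, pred, mode = "all")

  f <- withr::local_tempfile(fileext = ".json")
  exportSubgraph(sg, f, format = "json",
                 aliases = list(hub = c("HUB_ALIAS")))
  back <- importSubgraphJSON(f)

  expect_setequal(back$nodes$id, vertexIds(sg))
  expect_identical(back$nodes$aliases[[match("hub", back$nodes$id)]],
                   "HUB_ALIAS")
  et <- edgeTable(sg)
  expect_equal(nrow(back$edges), nrow(et))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  m <- match(key(et$from, et$to), key(back$edges$source, back$edges$target))
  expect_false(anyNA(m))
  expect_equal(back$edges$weight[m], et$weight)
  expect_true(all(vapply(back$edges$provenance, identical, logical(1),
                         "toy")))
  # scores survive the round trip
  nd <- sg@nodeData
  mm <- match(nd$id, back$nodes$id)
  expect_equal(back$nodes$score[mm], nd$phi)
  expect_equal(back$nodes$annotated[mm], nd$annotated)
})

test_that("CSV export writes edge and node tables with provenance", {
  cons <- toyConsensus()
  sg <- egoSubgraph(cons, "hub", depth = 1)
  f <- withr::local_tempfile(fileext = ".csv")
  paths <- exportSubgraph(sg, f, format = "csv")
  edges <- read.csv(paths[["edges"]])
  nodes <- read.csv(paths[["nodes"]])
  expect_named(edges, c("source", "target", "weight", "provenance"))
  expect_named(nodes, c("id", "annotated", "score", "predicted"))
  expect_true(all(edges$provenance == "toy"))
  expect_equal(nrow(nodes), numVertices(sg))
  expect_error(exportSubgraph(sg, f, format = "xml"))
})
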