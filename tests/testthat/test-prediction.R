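test_that("parameters are learned from the consensus projection", {
  # separable consensus: the learned line classifies every protein right
  cliq <- weightedNetwork(data.frame(
    from = c("a", "a", "b", "x", "x", "y"),
    to = c("b", "c", "c", "y", "z", "z"), weight = 1))
  lab <- termLabeling("GO:c", c("a", "b", "c"), vertexIds(cliq))
  cons <- integrateNetworks(networkCollection(list(cliq)), lab)
  config <- learnHopfieldParameters(cons, lab)
  counts <- evaluateLine(projectNetwork(cons, lab), config@alpha, config@q)
  expect_equal(fMeasure(counts$tp, counts$fp, counts$fn), 1)
  expect_gt(config@alpha, 0); expect_lt(config@alpha, pi / 2)

  expect_error(learnHopfieldParameters(cons,
    new("TermLabeling", term = "GO:0", positives = character(),
        universe = vertexIds(cons))), "no positive")

  # determinism on a seeded synthetic consensus
  sim <- generateCollection(plantedScenario(n = 60, nPos = 10, seed = 11))
  c1 <- integrateNetworks(sim$collection, sim$labeling)
  c2 <- integrateNetworks(sim$collection, sim$labeling)
  expect_identical(learnHopfieldParameters(c1, sim$labeling),
                   learnHopfieldParameters(c2, sim$labeling))
})

test_that("clamped dynamics follow the neuron update rule", {
  toy <- hopfieldToy()
  config <- hopfieldConfig(alpha = pi / 4, q = 0)

  # empty query set: clamped states returned unchanged after one sweep
  dyn0 <- runHopfieldDynamics(toy$net, toy$labeling, config, character())
  expect_equal(dyn0$sweeps, 1)
  expect_true(dyn0$converged)
  a <- sin(pi / 4); b <- -cos(pi / 4)
  expect_equal(unname(dyn0$state),
               ifelse(vertexIds(toy$net) %in% c("p1", "p2"), a, b))

  # one free vertex linked to 2 positives and 1 negative, unit weights:
  # input 2*sin(pi/4) - cos(pi/4) > 0, so it settles positive
  ids <- c("u", "P1", "P2", "N1")
  net <- weightedNetwork(data.frame(from = "u", to = c("P1", "P2", "N1"),
                                    weight = 1), vertices = ids)
  lab1 <- termLabeling("GO:u", c("P1", "P2"), ids)
  cons1 <- new("ConsensusNetwork", name = "c", adjacency =
               adjacencyMatrix(net), provenance = data.frame(),
               relevance = data.frame(), term = "GO:u")
  dyn1 <- runHopfieldDynamics(cons1, lab1, config, "u")
  expect_equal(unname(dyn1$state[["u"]]), sin(pi / 4))

  expect_error(runHopfieldDynamics(cons1, lab1, config, "P1"),
               "unlabeled")
  expect_error(runHopfieldDynamics(cons1, lab1, config, "ghost"),
               "outside")
})

test_that("dynamics agree with a plain-R oracle and reach a fixed point", {
  toy <- hopfieldToy()
  for (alpha in c(pi / 6, pi / 4, pi / 3)) {
    config <- hopfieldConfig(alpha = alpha, q = 0.1)
    a <- sin(alpha); b <- -cos(alpha)
    dyn <- runHopfieldDynamics(toy$net, toy$labeling, config, toy$free)

    ids <- vertexIds(toy$net)
    W <- as.matrix(adjacencyMatrix(toy$net))
    clamped <- !(ids %in% toy$free)
    state0 <- ifelse(ids %in% positiveIds(toy$labeling), a, b)
    ref <- refHopfield(W, state0, clamped, a, b, 0.1)
    expect_equal(unname(dyn$state), ref$state)
    expect_true(dyn$converged)

    # fixed point: no free neuron wants to change state
    for (v in which(!clamped)) {
      A <- sum(W[v, ] * ref$state) - 0.1
      expect_equal(ref$state[v], if (A > 0) a else b)
    }
    # energy trace never increases and matches the closed form
    expect_true(all(diff(dyn$energies) <= 1e-12))
    expect_equal(dyn$energies[length(dyn$energies)],
                 refEnergy(W, ref$state, 0.1))
  }
})

test_that("hopfieldEnergy matches the quadratic form", {
  config <- hopfieldConfig(alpha = pi / 4, q = 0)
  two <- weightedNetwork(vertices = c("a", "b"))
  consTwo <- new("ConsensusNetwork", name = "c", adjacency =
                 adjacencyMatrix(two), provenance = data.frame(),
                 relevance = data.frame(), term = "t")
  expect_equal(hopfieldEnergy(consTwo, config, c(1, -1)), 0)

  edge <- weightedNetwork(data.frame(from = "a", to = "b", weight = 1))
  consEdge <- new("ConsensusNetwork", name = "c", adjacency =
                  adjacencyMatrix(edge), provenance = data.frame(),
                  relevance = data.frame(), term = "t")
  s <- sin(pi / 4)
  expect_equal(hopfieldEnergy(consEdge, config, c(s, s)), -0.5)
})

test_that("scores normalise inputs into [-1, 1] with the boundary rule", {
  expect_equal(netintegrate:::.phiFromInput(c(2, -1, 1)), c(1, -0.5, 0.5))
  expect_equal(netintegrate:::.phiFromInput(c(0, 0)), c(0, 0))
  expect_equal(netintegrate:::.phiFromInput(-3), -1)

  toy <- hopfieldToy()
  config <- hopfieldConfig(alpha = pi / 4, q = 0)
  dyn <- runHopfieldDynamics(toy$net, toy$labeling, config, toy$free)
  sc <- scoreEquilibrium(toy$net, config, dyn$state, toy$free)
  expect_true(all(abs(sc$phi) <= 1))
  expect_equal(max(abs(sc$phi)), 1)
  expect_identical(sc$predicted, sc$input > 0)
  expect_error(scoreEquilibrium(toy$net, config, dyn$state, character()),
               "empty")
})

test_that("predictProteins composes the pipeline over both modes", {
  toy <- hopfieldToy()
  resAll <- predictProteins(toy$net, toy$labeling, mode = "all")
  expect_setequal(predictionScores(resAll)$protein,
                  setdiff(vertexIds(toy$net), c("p1", "p2")))
  expect_true(all(diff(predictionScores(resAll)$phi) <= 0))

  # selection containing an annotated positive: excluded but reported
  resSel <- predictProteins(toy$net, toy$labeling, mode = "selection",
                            targets = c("f1", "p1"))
  expect_identical(resSel@annotated, "p1")
  expect_identical(predictionScores(resSel)$protein, "f1")

  # a single queried protein is normalised to |phi| = 1 (or 0 input)
  phiSel <- predictionScores(resSel)$phi
  expect_true(abs(phiSel) %in% c(0, 1))

  expect_warning(
    resPart <- predictProteins(toy$net, toy$labeling, mode = "selection",
                               targets = c("f1", "ghost")),
    "outside")
  expect_identical(predictionScores(resPart)$protein, "f1")
  expect_error(predictProteins(toy$net, toy$labeling, mode = "selection",
                               targets = "ghost"), "none of")
  expect_error(predictProteins(toy$net, toy$labeling, mode = "selection",
                               targets = character()), "non-empty")
})

test_that("prediction TSV lists annotated first, scores to 6 decimals", {
  toy <- hopfieldToy()
  res <- predictProteins(toy$net, toy$labeling, mode = "selection",
                         targets = c("f1", "f2", "p1"))
  f <- withr::local_tempfile(fileext = ".tsv")
  writePredictions(res, f)
  tab <- read.delim(f, colClasses = c(phi = "character"))
  expect_identical(tab$protein_id[1], "p1")
  expect_equal(tab$annotated, c(1L, 0L, 0L))
  expect_true(all(grepl("^-?[01]\\.[0-9]{6}$",
                        tab$phi[tab$annotated == 0])))
})
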