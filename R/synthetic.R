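# Seeded generators of network collections with planted function-specific
# structure. A planted (informative) network connects the positives of a
# term preferentially and with heavier weights; noise networks are
# label-independent Erdos-Renyi graphs. This emulates the situation the
# integration engine is built for: a source can be informative for one
# function and uninformative for another.

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

.deriveSeed <- function(seed, k) (as.numeric(seed) * 7919 + k) %% 2147483647

#' Define a planted benchmark scenario
#'
#' Defaults describe the standard study conditions used throughout the
#' package's tests: a universe of 200 proteins with 30 positives, positive
#' pairs connected with probability 0.3 and heavier weights (uniform on
#' \[0.5, 1\]), all other pairs with probability 0.05 and background weights
#' (uniform on \[0, 0.5\]), plus two label-independent noise networks of
#' edge density 0.1 with weights uniform on \[0, 1\].
#'
#' @param n total number of proteins.
#' @param nPos number of planted positives (`nPos < n`).
#' @param pIn edge probability between positive pairs.
#' @param pOut edge probability for every other pair (`pOut <= pIn`).
#' @param nNoiseNetworks number of noise networks in a collection.
#' @param pNoise edge probability of the noise networks.
#' @param weightInformative,weightBackground length-2 numeric ranges of the
#'   uniform weight laws for positive-pair and other edges of the planted
#'   network.
#' @param term GO-term label attached to the generated labeling.
#' @param seed integer seed; identical seeds give identical output.
#' @return a `plantedScenario` list.
#' @export
plantedScenario <- function(n = 200, nPos = 30, pIn = 0.3, pOut = 0.05,
                            nNoiseNetworks = 2, pNoise = 0.1,
                            weightInformative = c(0.5, 1),
                            weightBackground = c(0, 0.5),
                            term = "GO:SYNTH", seed = 42) {
  stopifnot(nPos < n, nPos >= 1, pOut >= 0, pOut <= pIn, pIn <= 1,
            pNoise >= 0, pNoise <= 1, nNoiseNetworks >= 0,
            length(weightInformative) == 2, length(weightBackground) == 2)
  structure(list(n = n, nPos = nPos, pIn = pIn, pOut = pOut,
                 nNoiseNetworks = nNoiseNetworks, pNoise = pNoise,
                 weightInformative = weightInformative,
                 weightBackground = weightBackground,
                 term = term, seed = seed),
            class = "plantedScenario")
}

.syntheticUniverse <- function(n) sprintf("P%06d", seq_len(n))

#' Generate the planted (informative) network of a scenario
#'
#' Positives are sampled from the universe; every positive pair receives an
#' edge with probability `pIn` and a weight from the informative law, every
#' other pair with probability `pOut` and a background weight.
#'
#' @param scenario a [plantedScenario()].
#' @param name network name.
#' @return list with elements `network` ([WeightedNetwork]) and `labeling`
#'   ([TermLabeling]).
#' @export
generatePlantedNetwork <- function(scenario, name = "planted") {
  stopifnot(inherits(scenario, "plantedScenario"))
  .withSeed(scenario$seed, {
    ids <- .syntheticUniverse(scenario$n)
    positives <- sort(sample(ids, scenario$nPos))
    pairIdx <- which(upper.tri(matrix(0, scenario$n, scenario$n)),
                     arr.ind = TRUE)
    from <- ids[pairIdx[, 1]]; to <- ids[pairIdx[, 2]]
    posPair <- from %in% positives & to %in% positives
    p <- ifelse(posPair, scenario$pIn, scenario$pOut)
    present <- runif(length(p)) < p
    lo <- ifelse(posPair[present], scenario$weightInformative[1],
                 scenario$weightBackground[1])
    hi <- ifelse(posPair[present], scenario$weightInformative[2],
                 scenario$weightBackground[2])
    weight <- lo + runif(sum(present)) * (hi - lo)
    network <- weightedNetwork(
      data.frame(from = from[present], to = to[present], weight = weight,
                 stringsAsFactors = FALSE),
      vertices = ids, name = name)
    list(network = network,
         labeling = termLabeling(scenario$term, positives, ids))
  })
}

#' Generate a label-independent noise network
#'
#' Erdos-Renyi graph G(n, pNoise) over the scenario universe with weights
#' uniform on \[0, 1\].
#'
#' @param n number of proteins.
#' @param pNoise edge probability, in \[0, 1\].
#' @param seed integer seed.
#' @param name network name.
#' @return a [WeightedNetwork].
#' @export
generateNoiseNetwork <- function(n, pNoise, seed, name = "noise") {
  stopifnot(pNoise >= 0, pNoise <= 1)
  .withSeed(seed, {
    ids <- .syntheticUniverse(n)
    pairIdx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    present <- runif(nrow(pairIdx)) < pNoise
    weightedNetwork(
      data.frame(from = ids[pairIdx[present, 1]],
                 to = ids[pairIdx[present, 2]],
                 weight = runif(sum(present)), stringsAsFactors = FALSE),
      vertices = ids, name = name)
  })
}

#' Generate a full planted collection
#'
#' One planted network plus `nNoiseNetworks` noise networks over the same
#' universe, in shuffled order, with the shared labeling. All randomness is
#' driven by seeds derived from `scenario$seed`, so output is reproducible.
#'
#' @param scenario a [plantedScenario()].
#' @return list with elements `collection` ([NetworkCollection]) and
#'   `labeling` ([TermLabeling]).
#' @export
generateCollection <- function(scenario) {
  stopifnot(inherits(scenario, "plantedScenario"))
  planted <- generatePlantedNetwork(scenario)
  noise <- lapply(seq_len(scenario$nNoiseNetworks), function(k)
    generateNoiseNetwork(scenario$n, scenario$pNoise,
                         seed = .deriveSeed(scenario$seed, k),
                         name = paste0("noise", k)))
  nets <- c(list(planted$network), noise)
  ord <- .withSeed(.deriveSeed(scenario$seed, 999), sample(length(nets)))
  list(collection = networkCollection(nets[ord]),
       labeling = planted$labeling)
}
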