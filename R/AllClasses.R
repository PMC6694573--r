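#' Weighted undirected protein network
#'
#' An undirected, weighted graph over a set of protein identifiers, stored as
#' a sparse symmetric adjacency matrix with zero diagonal and nonnegative
#' weights. Symmetry is unrepresentable-by-construction: the class stores a
#' `Matrix::dsCMatrix`, so an asymmetric edge set cannot exist.
#'
#' @slot name single character, the network's name (unique within a
#'   [NetworkCollection]).
#' @slot adjacency symmetric sparse matrix (`dsCMatrix`) with protein IDs as
#'   dimnames, zero diagonal and nonnegative entries.
#'
#' @seealso [weightedNetwork()], [edgeTable()], [alignToUniverse()],
#'   [maxNormalize()]
#' @export
setClass("WeightedNetwork",
  slots = c(name = "character", adjacency = "dsCMatrix"))

setValidity("WeightedNetwork", function(object) {
  msg <- character()
  if (length(object@name) != 1L || is.na(object@name) || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  adj <- object@adjacency
  ids <- rownames(adj)
  if (nrow(adj) == 0 && is.null(ids)) ids <- character()
  if (nrow(adj) > 0 && (is.null(ids) || !identical(ids, colnames(adj))))
    msg <- c(msg, "adjacency must carry identical row and column protein IDs")
  else {
    if (anyDuplicated(ids)) msg <- c(msg, "protein IDs must be unique")
    if (any(!nzchar(ids)) || any(grepl("[\t\n]", ids)))
      msg <- c(msg, "protein IDs must be non-empty and free of tabs/newlines")
  }
  if (length(adj@x) && any(adj@x < 0))
    msg <- c(msg, "edge weights must be nonnegative")
  if (any(Matrix::diag(adj) != 0))
    msg <- c(msg, "self-interactions are not allowed (diagonal must be zero)")
  if (length(msg)) msg else TRUE
})

#' Ordered collection of networks over a shared protein universe
#'
#' @slot networks list of [WeightedNetwork] objects with unique names.
#' @slot universe character vector: the ordered union of all member vertex
#'   sets (plus any extra labeled proteins supplied at construction).
#'
#' @seealso [networkCollection()], [integrateNetworks()]
#' @export
setClass("NetworkCollection",
  slots = c(networks = "list", universe = "character"))

setValidity("NetworkCollection", function(object) {
  msg <- character()
  ok <- vapply(object@networks, is, logical(1), class2 = "WeightedNetwork")
  if (!all(ok)) msg <- c(msg, "all members must be WeightedNetwork objects")
  else {
    nms <- vapply(object@networks, function(x) x@name, character(1))
    if (anyDuplicated(nms)) msg <- c(msg, "network names must be unique")
    members <- unique(unlist(lapply(object@networks, function(x)
      rownames(x@adjacency))))
    if (!all(members %in% object@universe))
      msg <- c(msg, "universe must contain every member vertex")
  }
  if (anyDuplicated(object@universe))
    msg <- c(msg, "universe IDs must be unique")
  if (length(msg)) msg else TRUE
})

#' Binary labeling of a protein universe for one GO term
#'
#' Proteins annotated with the term are the positives (label 1); all other
#' proteins of the universe are negatives (label 0). GO annotations are
#' typically scarce, so the positive class is strongly under-represented —
#' the imbalance both the integration and the prediction engine are designed
#' around.
#'
#' @slot term single character, e.g. `"GO:0001837"`.
#' @slot positives character vector, subset of `universe`.
#' @slot universe ordered character vector of protein IDs.
#'
#' @seealso [termLabeling()], [labelVector()]
#' @export
setClass("TermLabeling",
  slots = c(term = "character", positives = "character",
            universe = "character"))

setValidity("TermLabeling", function(object) {
  msg <- character()
  if (length(object@term) != 1L || !nzchar(object@term))
    msg <- c(msg, "'term' must be a single non-empty string")
  if (anyDuplicated(object@universe))
    msg <- c(msg, "universe IDs must be unique")
  if (anyDuplicated(object@positives))
    msg <- c(msg, "positive IDs must be unique")
  if (!all(object@positives %in% object@universe))
    msg <- c(msg, "positives must be a subset of the universe")
  if (length(msg)) msg else TRUE
})

#' Consensus network with per-edge provenance and relevance report
#'
#' The relevance-weighted linear combination of a network collection for one
#' GO term. Extends [WeightedNetwork]; additionally records, for every
#' consensus edge, the set of source networks in which the edge is present
#' with positive weight, and the per-network relevance report (best
#' F-measure, optimal line parameters, confusion counts).
#'
#' @slot provenance data.frame with columns `from`, `to` and list-column
#'   `sources` (character vectors of source network names).
#' @slot relevance data.frame with one row per source network: `network`,
#'   `relevance`, `alpha`, `q`, `tp`, `fp`, `fn`, `tn`.
#' @slot term the GO term the consensus was built for.
#'
#' @seealso [integrateNetworks()], [relevanceReport()], [edgeProvenance()]
#' @export
setClass("ConsensusNetwork", contains = "WeightedNetwork",
  slots = c(provenance = "data.frame", relevance = "data.frame",
            term = "character"))

#' Hopfield prediction engine configuration
#'
#' Parameters of the two-state Hopfield network run on the consensus.
#' The neuron states are `sin(alpha)` (positive) and `-cos(alpha)`
#' (negative) and the common activation threshold is `q`, so that the
#' neuron update rule coincides with the classification rule of the learned
#' separating line.
#'
#' @slot alpha angle in radians, open interval (0, pi/2).
#' @slot q real activation threshold.
#' @slot maxSweeps positive integer, maximum number of full sweeps.
#' @slot initState `"negative"` (default; the majority class under label
#'   imbalance) or `"positive"` — initial state of unlabeled neurons.
#'
#' @seealso [hopfieldConfig()], [learnHopfieldParameters()]
#' @export
setClass("HopfieldConfig",
  slots = c(alpha = "numeric", q = "numeric", maxSweeps = "integer",
            initState = "character"))

setValidity("HopfieldConfig", function(object) {
  msg <- character()
  if (length(object@alpha) != 1L || is.na(object@alpha) ||
      object@alpha <= 0 || object@alpha >= pi / 2)
    msg <- c(msg, "'alpha' must lie in the open interval (0, pi/2)")
  if (length(object@q) != 1L || is.na(object@q))
    msg <- c(msg, "'q' must be a single finite number")
  if (length(object@maxSweeps) != 1L || object@maxSweeps < 1L)
    msg <- c(msg, "'maxSweeps' must be a positive integer")
  if (!object@initState %in% c("negative", "positive"))
    msg <- c(msg, "'initState' must be \"negative\" or \"positive\"")
  if (length(msg)) msg else TRUE
})

#' Result of a Hopfield prediction run
#'
#' Scores and binary calls for the queried proteins. For each queried protein
#' the raw internal input \eqn{A_i = \sum_j W_{ij} x_j - q} at equilibrium is
#' normalised by the maximum absolute input over the query set, giving
#' \eqn{\phi_i \in [-1, 1]}; the protein is predicted positive iff
#' \eqn{A_i > 0}. Scores near zero mark uncertain predictions.
#'
#' @slot scores data.frame sorted by decreasing `phi`, with columns
#'   `protein`, `input` (raw \eqn{A_i}), `phi`, `predicted` (logical).
#' @slot annotated character vector: queried proteins that were already
#'   labeled positive and hence excluded from scoring.
#' @slot converged logical: did the dynamics reach a fixed point within the
#'   sweep budget?
#' @slot sweeps number of full sweeps executed.
#' @slot config the [HopfieldConfig] used.
#'
#' @seealso [predictProteins()], [predictionScores()]
#' @export
setClass("PredictionResult",
  slots = c(scores = "data.frame", annotated = "character",
            converged = "logical", sweeps = "integer",
            config = "HopfieldConfig"))

#' Vertex-centric subgraph of a consensus network
#'
#' A subset of a [ConsensusNetwork]'s vertices with (a subset of) its induced
#' edges, optionally decorated with annotation flags and prediction scores
#' for rendering/export.
#'
#' @slot parent the [ConsensusNetwork] the subgraph was taken from.
#' @slot vertices character vector of member protein IDs.
#' @slot edges data.frame (`from`, `to`, `weight`), a subset of the parent's
#'   edges induced on `vertices`.
#' @slot nodeData data.frame with columns `id`, `annotated` (logical),
#'   `phi` (numeric, `NA` when absent), `predicted` (logical, `NA` when
#'   absent), `decorated` (logical).
#' @slot mode decoration mode: `"none"`, `"all"` or `"selection"`.
#'
#' @seealso [egoSubgraph()], [decorateSubgraph()], [exportSubgraph()]
#' @export
setClass("NetworkSubgraph",
  slots = c(parent = "ConsensusNetwork", vertices = "character",
            edges = "data.frame", nodeData = "data.frame",
            mode = "character"))

setValidity("NetworkSubgraph", function(object) {
  msg <- character()
  if (!all(c(object@edges$from, object@edges$to) %in% object@vertices))
    msg <- c(msg, "every edge endpoint must appear among the vertices")
  if (!identical(sort(object@nodeData$id), sort(object@vertices)))
    msg <- c(msg, "nodeData must have exactly one row per vertex")
  if (length(msg)) msg else TRUE
})
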