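#' @name accessors
#' @title Accessors for netintegrate objects
#'
#' @description
#' `vertexIds()` returns the ordered protein IDs of a network, collection,
#' labeling or subgraph; `networkName()` the name of a network;
#' `adjacencyMatrix()` the sparse symmetric adjacency; `edgeTable()` a
#' data.frame of edges (`from`, `to`, `weight`, endpoints in lexicographic
#' order within each row, rows sorted); `numVertices()`/`numEdges()` the
#' corresponding counts; `positiveIds()` and `termId()` the positives and the
#' GO term of a labeling; `labelVector()` the named 0/1 vector over the
#' universe; `relevanceReport()` and `edgeProvenance()` the per-network
#' relevance table and the per-edge source networks of a consensus;
#' `predictionScores()` the score table of a prediction result.
#'
#' @param x the object.
#' @return See description; accessors never expose slots for modification.
NULL

#' @rdname accessors
#' @export
setGeneric("vertexIds", function(x) standardGeneric("vertexIds"))

#' @rdname accessors
#' @export
setGeneric("networkName", function(x) standardGeneric("networkName"))

#' @rdname accessors
#' @export
setGeneric("adjacencyMatrix", function(x) standardGeneric("adjacencyMatrix"))

#' @rdname accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname accessors
#' @export
setGeneric("numVertices", function(x) standardGeneric("numVertices"))

#' @rdname accessors
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' @rdname accessors
#' @export
setGeneric("positiveIds", function(x) standardGeneric("positiveIds"))

#' @rdname accessors
#' @export
setGeneric("termId", function(x) standardGeneric("termId"))

#' @rdname accessors
#' @export
setGeneric("labelVector", function(x) standardGeneric("labelVector"))

#' @rdname accessors
#' @export
setGeneric("relevanceReport", function(x) standardGeneric("relevanceReport"))

#' @rdname accessors
#' @export
setGeneric("edgeProvenance", function(x) standardGeneric("edgeProvenance"))

#' @rdname accessors
#' @export
setGeneric("predictionScores", function(x) standardGeneric("predictionScores"))

#' Restrict or extend a network to a vertex universe
#'
#' Returns a network whose vertex set is exactly `universe`: edges with both
#' endpoints in `universe` are kept, all other edges are dropped, and
#' proteins absent from the original network become isolated vertices.
#' Idempotent.
#'
#' @param network a [WeightedNetwork].
#' @param universe ordered character vector of protein IDs.
#' @return a [WeightedNetwork] over `universe`.
#' @examples
#' net <- weightedNetwork(data.frame(from = "a", to = "b", weight = 1))
#' vertexIds(alignToUniverse(net, c("a", "b", "c")))
#' @export
setGeneric("alignToUniverse",
  function(network, universe) standardGeneric("alignToUniverse"))

#' Rescale a network's weights to a maximum of one
#'
#' Divides every edge weight by the network's maximum weight, so all weights
#' fall in \[0, 1\] with the maximum exactly 1 when edges exist. An edgeless
#' network is returned unchanged. Idempotent. Applied to every source before
#' integration so that heterogeneous weight scales are comparable.
#'
#' @param network a [WeightedNetwork].
#' @return the rescaled [WeightedNetwork].
#' @export
setGeneric("maxNormalize", function(network) standardGeneric("maxNormalize"))

#' Degree or strength of a vertex
#'
#' @param network a [WeightedNetwork].
#' @param vertex a protein ID present in the network.
#' @param mode `"count"` (number of incident positive-weight edges) or
#'   `"strength"` (sum of incident weights).
#' @return a single number.
#' @export
setGeneric("nodeDegree",
  function(network, vertex, mode = c("count", "strength"))
    standardGeneric("nodeDegree"))
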