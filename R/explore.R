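# Vertex-centric exploration of the consensus: ego subgraphs, one-step
# expansion, weight filtering, node/edge search, render decorations.

.subgraphFromVertices <- function(consensus, vertices) {
  et <- edgeTable(consensus)
  keep <- et$from %in% vertices & et$to %in% vertices
  edges <- et[keep, , drop = FALSE]
  rownames(edges) <- NULL
  nodeData <- data.frame(id = vertices, annotated = FALSE, phi = NA_real_,
                         predicted = NA, decorated = FALSE,
                         stringsAsFactors = FALSE)
  new("NetworkSubgraph", parent = consensus, vertices = vertices,
      edges = edges, nodeData = nodeData, mode = "none")
}

.consensusGraph <- function(consensus) {
  adj <- as(as(adjacencyMatrix(consensus), "generalMatrix"),
            "CsparseMatrix")
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                      weighted = TRUE)
}

#' Extract the ego subgraph around a target protein
#'
#' Returns the induced subgraph on all proteins within `depth` edge-hops of
#' the target (edges with positive weight). The default depth of 1 mirrors
#' the tool's default view, which shows only the proteins one edge away
#' from the target.
#'
#' @param consensus a [ConsensusNetwork].
#' @param target a protein ID of the consensus universe. An unknown ID
#'   raises an error listing case-insensitive substring near-misses.
#' @param depth positive number of hops (`Inf` for the whole connected
#'   component).
#' @return a [NetworkSubgraph].
#' @export
egoSubgraph <- function(consensus, target, depth = 1) {
  ids <- vertexIds(consensus)
  if (length(target) != 1L || !target %in% ids) {
    near <- ids[grepl(tolower(target), tolower(ids), fixed = TRUE)]
    stop("unknown target protein '", target, "'",
         if (length(near)) paste0("; did you mean: ",
                                  paste(utils::head(near, 10), collapse = ", "),
                                  "?") else "")
  }
  stopifnot(depth >= 1)
  g <- .consensusGraph(consensus)
  order <- if (is.finite(depth)) depth else length(ids)
  verts <- names(igraph::ego(g, order = order, nodes = target)[[1]])
  verts <- ids[ids %in% verts]  # keep universe order
  .subgraphFromVertices(consensus, verts)
}

#' Expand a subgraph one step from a node
#'
#' Adds all parent-network neighbours of `node` (and the induced edges) to
#' the subgraph. When no node can be added the subgraph is returned
#' unchanged and an `"emptyExpansion"` message is signalled, mirroring the
#' tool's alert.
#'
#' @param subgraph a [NetworkSubgraph].
#' @param node a protein ID already in the subgraph.
#' @return a [NetworkSubgraph]. Idempotent: expanding twice from the same
#'   node equals expanding once.
#' @export
expandOneStep <- function(subgraph, node) {
  if (length(node) != 1L || !node %in% subgraph@vertices)
    stop("node '", node, "' is not part of the subgraph")
  parent <- subgraph@parent
  col <- adjacencyMatrix(parent)[, node]
  neighbours <- names(col)[col > 0]
  newVerts <- setdiff(neighbours, subgraph@vertices)
  if (length(newVerts) == 0) {
    message("emptyExpansion: no new neighbours of '", node, "' to add")
    return(subgraph)
  }
  ids <- vertexIds(parent)
  verts <- ids[ids %in% c(subgraph@vertices, newVerts)]
  out <- .subgraphFromVertices(parent, verts)
  # carry existing decorations over; new vertices stay plain
  keep <- match(out@nodeData$id, subgraph@nodeData$id)
  has <- !is.na(keep)
  out@nodeData[has, ] <- subgraph@nodeData[keep[has], ]
  out@mode <- subgraph@mode
  out
}

#' Keep only edges at or above a weight threshold
#'
#' Vertices are retained even when they become isolated. Inclusive
#' threshold: an edge whose weight equals the threshold stays visible.
#' Monotone (a higher threshold keeps a subset of the edges) and idempotent.
#'
#' @param subgraph a [NetworkSubgraph].
#' @param threshold nonnegative weight threshold.
#' @return a [NetworkSubgraph].
#' @export
filterEdgesByWeight <- function(subgraph, threshold) {
  stopifnot(threshold >= 0)
  out <- subgraph
  out@edges <- subgraph@edges[subgraph@edges$weight >= threshold, ,
                              drop = FALSE]
  rownames(out@edges) <- NULL
  out
}

#' Search nodes by identifier substring
#'
#' Case-insensitive substring match over protein IDs and, when supplied,
#' their aliases. Results are sorted lexicographically.
#'
#' @param x a [ConsensusNetwork], [WeightedNetwork] or [NetworkSubgraph].
#' @param pattern non-empty search string (fixed, not a regular
#'   expression).
#' @param aliases optional named list mapping protein IDs to character
#'   vectors of aliases.
#' @return sorted character vector of matching protein IDs (possibly
#'   empty).
#' @export
searchNodes <- function(x, pattern, aliases = NULL) {
  stopifnot(nzchar(pattern))
  ids <- vertexIds(x)
  hit <- grepl(tolower(pattern), tolower(ids), fixed = TRUE)
  if (!is.null(aliases)) {
    aliasHit <- vapply(ids, function(id) {
      a <- aliases[[id]]
      !is.null(a) && any(grepl(tolower(pattern), tolower(a), fixed = TRUE))
    }, logical(1))
    hit <- hit | aliasHit
  }
  sort(ids[hit])
}

#' Search edges by endpoint and weight range
#'
#' Returns the edges with at least one endpoint matching the
#' case-insensitive substring pattern (an empty pattern matches every
#' edge) and weight within `[minWeight, maxWeight]`.
#'
#' @param x a [ConsensusNetwork], [WeightedNetwork] or [NetworkSubgraph].
#' @param pattern endpoint search string; `""` matches all.
#' @param minWeight,maxWeight inclusive weight bounds; `minWeight` must not
#'   exceed `maxWeight`.
#' @return data.frame of edges (`from`, `to`, `weight`).
#' @export
searchEdges <- function(x, pattern = "", minWeight = 0, maxWeight = Inf) {
  if (minWeight > maxWeight)
    stop("minWeight must not exceed maxWeight")
  et <- edgeTable(x)
  hit <- if (nzchar(pattern)) {
    grepl(tolower(pattern), tolower(et$from), fixed = TRUE) |
      grepl(tolower(pattern), tolower(et$to), fixed = TRUE)
  } else rep(TRUE, nrow(et))
  out <- et[hit & et$weight >= minWeight & et$weight <= maxWeight, ,
            drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Decorate a subgraph with annotation flags and prediction scores
#'
#' Prepares a subgraph for rendering/export. In mode `"none"` every vertex
#' is plain (white circle). In mode `"all"` every vertex carries its
#' annotated flag and, unless annotated, its score. In mode `"selection"`
#' only the queried vertices carry scores; all others are plain. Annotated
#' means labeled positive for the term (rendered as squares); annotated
#' proteins never carry a score — they are excluded from the query set.
#'
#' @param subgraph a [NetworkSubgraph].
#' @param labeling a [TermLabeling].
#' @param predictions a [PredictionResult]; required in modes `"all"` and
#'   `"selection"`.
#' @param mode `"none"`, `"all"` or `"selection"`.
#' @return the decorated [NetworkSubgraph].
#' @export
decorateSubgraph <- function(subgraph, labeling, predictions = NULL,
                             mode = c("none", "all", "selection")) {
  mode <- match.arg(mode)
  nd <- subgraph@nodeData
  nd$annotated <- FALSE; nd$phi <- NA_real_
  nd$predicted <- NA; nd$decorated <- FALSE
  if (mode != "none") {
    if (is.null(predictions))
      stop("mode '", mode, "' requires a PredictionResult")
    sc <- predictionScores(predictions)
    idx <- match(nd$id, sc$protein)
    pos <- nd$id %in% positiveIds(labeling)
    if (mode == "all") {
      nd$annotated <- pos
      nd$phi <- sc$phi[idx]
      nd$predicted <- sc$predicted[idx]
      nd$decorated <- TRUE
    } else {
      queried <- !is.na(idx)
      sel <- queried | nd$id %in% predictions@annotated
      nd$annotated[sel] <- pos[sel]
      nd$phi[queried] <- sc$phi[idx[queried]]
      nd$predicted[queried] <- sc$predicted[idx[queried]]
      nd$decorated <- sel
    }
  }
  out <- subgraph
  out@nodeData <- nd
  out@mode <- mode
  out
}
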