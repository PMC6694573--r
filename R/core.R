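# Constructors and basic graph algebra for the shared domain types.

#' Build a weighted undirected protein network
#'
#' Constructs a [WeightedNetwork] from an edge table. Edges are unordered
#' pairs; `from`/`to` order is irrelevant and duplicate listings of the same
#' pair are collapsed (identical weights silently, conflicting weights by
#' their arithmetic mean with a warning). Self-pairs are dropped with a
#' warning — the Hopfield dynamics requires a zero diagonal. Negative
#' weights are rejected: all supported sources are similarity-type networks.
#'
#' @param edges data.frame whose first three columns are interpreted as
#'   `from`, `to`, `weight`; may have zero rows.
#' @param vertices optional character vector of protein IDs to include even
#'   when isolated; edge endpoints are appended in order of appearance.
#' @param name network name.
#' @return a [WeightedNetwork].
#' @examples
#' weightedNetwork(data.frame(from = c("a", "b"), to = c("b", "c"),
#'                            weight = c(1, 0.5)))
#' @export
weightedNetwork <- function(edges = NULL, vertices = NULL, name = "network") {
  if (is.null(edges)) {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric())
  }
  stopifnot(is.data.frame(edges), ncol(edges) >= 3 || nrow(edges) == 0)
  if (nrow(edges)) {
    from <- as.character(edges[[1]])
    to <- as.character(edges[[2]])
    weight <- as.numeric(edges[[3]])
    if (anyNA(weight)) stop("edge weights must be numeric and non-missing")
    if (any(weight < 0)) stop("negative edge weights are not allowed")
    loops <- from == to
    if (any(loops)) {
      warning(sum(loops), " self-interaction(s) dropped (zero diagonal ",
              "is required)")
      from <- from[!loops]; to <- to[!loops]; weight <- weight[!loops]
    }
  } else {
    from <- to <- character(); weight <- numeric()
  }

  ids <- unique(c(as.character(vertices), from, to))
  if (length(from)) {
    a <- pmin(from, to); b <- pmax(from, to)
    key <- paste(a, b, sep = "\t")
    if (anyDuplicated(key)) {
      w <- tapply(weight, key, function(v) v, simplify = FALSE)
      conflicting <- vapply(w, function(v) length(unique(v)) > 1, logical(1))
      if (any(conflicting))
        warning(sum(conflicting), " duplicated edge(s) with conflicting ",
                "weights averaged")
      keys <- names(w)
      weight <- vapply(w, mean, numeric(1))
      parts <- strsplit(keys, "\t", fixed = TRUE)
      a <- vapply(parts, `[`, character(1), 1L)
      b <- vapply(parts, `[`, character(1), 2L)
    }
    keep <- weight > 0
    a <- a[keep]; b <- b[keep]; weight <- weight[keep]
  } else {
    a <- b <- character()
  }

  i0 <- match(a, ids); j0 <- match(b, ids)
  adj <- Matrix::sparseMatrix(
    i = pmin(i0, j0), j = pmax(i0, j0), x = weight,
    dims = c(length(ids), length(ids)), dimnames = list(ids, ids),
    symmetric = TRUE)
  new("WeightedNetwork", name = name, adjacency = as(adj, "dsCMatrix"))
}

#' Assemble a network collection over the union universe
#'
#' The collection's universe is the ordered union of all member vertex sets,
#' followed by any `extraVertices` (typically labeled proteins absent from
#' every network, which then remain isolated).
#'
#' @param networks list of [WeightedNetwork] objects (or a single one).
#' @param extraVertices character vector of additional protein IDs.
#' @return a [NetworkCollection].
#' @export
networkCollection <- function(networks, extraVertices = character()) {
  if (is(networks, "WeightedNetwork")) networks <- list(networks)
  universe <- unique(c(
    unlist(lapply(networks, function(x) rownames(x@adjacency))),
    as.character(extraVertices)))
  new("NetworkCollection", networks = networks, universe = universe)
}

#' Define the labeling of one GO term over a protein universe
#'
#' @param term GO term identifier (any non-empty token).
#' @param positives protein IDs annotated with the term.
#' @param universe ordered protein universe; must contain all positives.
#' @return a [TermLabeling].
#' @export
termLabeling <- function(term, positives, universe) {
  new("TermLabeling", term = as.character(term),
      positives = unique(as.character(positives)),
      universe = as.character(universe))
}

## ---- accessors ------------------------------------------------------------

#' @rdname accessors
setMethod("vertexIds", "WeightedNetwork",
  function(x) rownames(x@adjacency) %||% character())
#' @rdname accessors
setMethod("vertexIds", "NetworkCollection", function(x) x@universe)
#' @rdname accessors
setMethod("vertexIds", "TermLabeling", function(x) x@universe)
#' @rdname accessors
setMethod("vertexIds", "NetworkSubgraph", function(x) x@vertices)

#' @rdname accessors
setMethod("networkName", "WeightedNetwork", function(x) x@name)

#' @rdname accessors
setMethod("adjacencyMatrix", "WeightedNetwork", function(x) x@adjacency)

#' @rdname accessors
setMethod("edgeTable", "WeightedNetwork", function(x) {
  tm <- as(as(x@adjacency, "generalMatrix"), "TsparseMatrix")
  keep <- tm@i < tm@j & tm@x != 0
  ids <- rownames(x@adjacency)
  from0 <- ids[tm@i[keep] + 1L]
  to0 <- ids[tm@j[keep] + 1L]
  from <- pmin(from0, to0); to <- pmax(from0, to0)
  ord <- order(from, to)
  data.frame(from = from[ord], to = to[ord], weight = tm@x[keep][ord],
             stringsAsFactors = FALSE)
})

#' @rdname accessors
setMethod("edgeTable", "NetworkSubgraph", function(x) x@edges)

#' @rdname accessors
setMethod("numVertices", "WeightedNetwork",
  function(x) nrow(x@adjacency))
#' @rdname accessors
setMethod("numVertices", "NetworkSubgraph", function(x) length(x@vertices))
#' @rdname accessors
setMethod("numEdges", "WeightedNetwork", function(x) nrow(edgeTable(x)))
#' @rdname accessors
setMethod("numEdges", "NetworkSubgraph", function(x) nrow(x@edges))

#' @rdname accessors
setMethod("positiveIds", "TermLabeling", function(x) x@positives)
#' @rdname accessors
setMethod("termId", "TermLabeling", function(x) x@term)
#' @rdname accessors
setMethod("termId", "ConsensusNetwork", function(x) x@term)

#' @rdname accessors
setMethod("labelVector", "TermLabeling", function(x)
  setNames(as.numeric(x@universe %in% x@positives), x@universe))

#' @rdname accessors
setMethod("relevanceReport", "ConsensusNetwork", function(x) x@relevance)
#' @rdname accessors
setMethod("edgeProvenance", "ConsensusNetwork", function(x) x@provenance)

#' @rdname accessors
setMethod("predictionScores", "PredictionResult", function(x) x@scores)

#' @describeIn networkCollection number of member networks
#' @param x a [NetworkCollection].
#' @export
setMethod("length", "NetworkCollection", function(x) length(x@networks))

#' @describeIn networkCollection member network names
#' @export
setMethod("names", "NetworkCollection",
  function(x) vapply(x@networks, function(n) n@name, character(1)))

#' @describeIn networkCollection extract a member by index or name
#' @param i index or network name.
#' @export
setMethod("[[", "NetworkCollection", function(x, i) {
  if (is.character(i)) i <- match(i, names(x))
  x@networks[[i]]
})

## ---- graph algebra --------------------------------------------------------

#' @rdname alignToUniverse
setMethod("alignToUniverse", "WeightedNetwork", function(network, universe) {
  universe <- as.character(universe)
  if (anyDuplicated(universe)) stop("universe IDs must be unique")
  if (identical(rownames(network@adjacency), universe)) return(network)
  et <- edgeTable(network)
  et <- et[et$from %in% universe & et$to %in% universe, , drop = FALSE]
  weightedNetwork(et, vertices = universe, name = network@name)
})

#' @rdname maxNormalize
setMethod("maxNormalize", "WeightedNetwork", function(network) {
  adj <- network@adjacency
  if (length(adj@x) == 0 || max(adj@x) == 0) return(network)
  adj@x <- adj@x / max(adj@x)
  initialize(network, adjacency = adj)
})

#' @rdname nodeDegree
setMethod("nodeDegree", "WeightedNetwork",
  function(network, vertex, mode = c("count", "strength")) {
    mode <- match.arg(mode)
    if (length(vertex) != 1L || !vertex %in% rownames(network@adjacency))
      stop("unknown vertex: ", vertex)
    col <- network@adjacency[, vertex]
    if (mode == "count") sum(col > 0) else sum(col)
  })

## ---- show methods ---------------------------------------------------------

setMethod("show", "WeightedNetwork", function(object) {
  cat(class(object), sprintf("'%s': %d vertices, %d edges\n",
      object@name, numVertices(object), numEdges(object)))
})

setMethod("show", "NetworkCollection", function(object) {
  cat("NetworkCollection:", length(object), "network(s),",
      length(object@universe), "proteins in the universe\n")
  for (n in object@networks)
    cat(sprintf("  %s: %d vertices, %d edges\n", n@name,
                numVertices(n), numEdges(n)))
})

setMethod("show", "TermLabeling", function(object) {
  cat(sprintf("TermLabeling '%s': %d positives / %d proteins (%.2f%%)\n",
      object@term, length(object@positives), length(object@universe),
      100 * length(object@positives) / max(1L, length(object@universe))))
})

setMethod("show", "ConsensusNetwork", function(object) {
  cat(sprintf("ConsensusNetwork for '%s': %d vertices, %d edges, %d source network(s)\n",
      object@term, numVertices(object), numEdges(object),
      nrow(object@relevance)))
  if (nrow(object@relevance)) {
    cat("  relevances:\n")
    for (k in seq_len(nrow(object@relevance)))
      cat(sprintf("    %s: r = %.4f\n", object@relevance$network[k],
                  object@relevance$relevance[k]))
  }
})

setMethod("show", "HopfieldConfig", function(object) {
  cat(sprintf("HopfieldConfig: alpha = %.6f, q = %.6f, maxSweeps = %d, init = %s\n",
      object@alpha, object@q, object@maxSweeps, object@initState))
})

setMethod("show", "PredictionResult", function(object) {
  cat(sprintf("PredictionResult: %d scored protein(s), %d annotated, %s after %d sweep(s)\n",
      nrow(object@scores), length(object@annotated),
      if (object@converged) "converged" else "NOT converged", object@sweeps))
  if (nrow(object@scores))
    print(utils::head(object@scores, 5L), row.names = FALSE)
})

setMethod("show", "NetworkSubgraph", function(object) {
  cat(sprintf("NetworkSubgraph: %d vertices, %d edges (decoration mode '%s')\n",
      length(object@vertices), nrow(object@edges), object@mode))
})
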