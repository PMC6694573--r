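# Function-specific, imbalance-aware integration of weighted networks.
#
# For one GO term d, every network k is projected onto the plane: protein i
# becomes the point (P_i1, P_i2) with P_i1 the summed weight towards its
# positive neighbours and P_i2 towards its negative neighbours. A straight
# line with positive slope, parameterized as
#     p1 * sin(alpha) - p2 * cos(alpha) - q > 0  =>  positive,
# is fitted to maximize the F-measure 2TP/(2TP + FP + FN) of the known
# labels; the optimum F is the network's relevance r for the term. The
# consensus is the r-weighted mean of the max-normalized networks.

#' Project a network onto the plane for one term
#'
#' For every protein \eqn{i}, computes
#' \eqn{P_{i,1} = \sum_j W_{ij} y(j)} (weighted sum of positive neighbours)
#' and \eqn{P_{i,2} = \sum_j W_{ij} (1 - y(j))} (weighted sum of negative
#' neighbours). The protein's own label never enters its point — the
#' diagonal of \eqn{W} is zero by construction.
#'
#' @param network a [WeightedNetwork], aligned to the labeling's universe
#'   (same IDs, same order; see [alignToUniverse()]).
#' @param labeling a [TermLabeling].
#' @return data.frame with columns `id`, `p1`, `p2`, `label` (0/1), one row
#'   per protein of the universe.
#' @examples
#' net <- weightedNetwork(data.frame(from = c("a", "b"), to = c("b", "c"),
#'                                   weight = 1))
#' lab <- termLabeling("GO:1", "a", c("a", "b", "c"))
#' projectNetwork(net, lab)
#' @export
projectNetwork <- function(network, labeling) {
  stopifnot(is(network, "WeightedNetwork"), is(labeling, "TermLabeling"))
  ids <- vertexIds(network)
  if (!identical(ids, vertexIds(labeling)))
    stop("network is not aligned to the labeling's universe; ",
         "use alignToUniverse() first")
  y <- labelVector(labeling)
  adj <- adjacencyMatrix(network)
  p1 <- as.numeric(adj %*% y)
  p2 <- as.numeric(adj %*% (1 - y))
  data.frame(id = ids, p1 = p1, p2 = p2, label = as.integer(y),
             stringsAsFactors = FALSE)
}

#' F-measure from confusion counts
#'
#' \eqn{F = 2TP / (2TP + FP + FN)}. Ignores true negatives, which makes it
#' robust to the heavy class imbalance of GO annotations. Undefined (an
#' error) when there are no positive instances; returns 0 when `tp` is 0.
#'
#' @param tp,fp,fn nonnegative integer counts.
#' @return a number in \[0, 1\].
#' @examples
#' fMeasure(tp = 2, fp = 1, fn = 0) # 0.8
#' @export
fMeasure <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  if (tp + fn < 1) stop("F-measure is undefined without positive instances")
  if (tp == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Confusion counts of a separating line on projected points
#'
#' A point \eqn{(p_1, p_2)} is predicted positive iff
#' \eqn{p_1 \sin\alpha - p_2 \cos\alpha - q > 0} (strict: boundary points are
#' predicted negative).
#'
#' @param points projection data.frame as returned by [projectNetwork()]
#'   (columns `p1`, `p2`, `label`).
#' @param alpha line angle in radians, in (0, pi/2).
#' @param q line offset.
#' @return list with integer counts `tp`, `fp`, `fn`, `tn`.
#' @export
evaluateLine <- function(points, alpha, q) {
  stopifnot(alpha > 0, alpha < pi / 2)
  z <- points$p1 * sin(alpha) - points$p2 * cos(alpha) - q
  pred <- z > 0
  pos <- points$label == 1
  list(tp = sum(pred & pos), fp = sum(pred & !pos),
       fn = sum(!pred & pos), tn = sum(!pred & !pos))
}

#' Learn the F-measure-optimal separating line
#'
#' Searches the line \eqn{p_1 \sin\alpha - p_2 \cos\alpha - q = 0},
#' \eqn{\alpha \in (0, \pi/2)}, maximizing the F-measure of the labeled
#' projected points. Candidate angles are the pairwise coincidence angles
#' \eqn{\arctan(\Delta p_2 / \Delta p_1)} of all point pairs (kept when in
#' range), a uniform fallback grid of 64 angles, and \eqn{\pm 10^{-6}}
#' perturbations of every candidate; for each angle the offset is swept
#' exactly over midpoints between consecutive distinct projected scores plus
#' sentinels beyond both extremes. Ties are broken by maximum F, then
#' maximum TP, then minimum \eqn{\alpha}, then minimum \eqn{q}, making the
#' result deterministic.
#'
#' @param points projection data.frame (columns `p1`, `p2`, `label`) with at
#'   least one positive point.
#' @return list with elements `alpha`, `q`, `counts` (list `tp`,`fp`,`fn`,
#'   `tn`) and `f` (the maximal F-measure).
#' @export
learnOptimalLine <- function(points) {
  if (sum(points$label == 1) < 1)
    stop("no positive proteins: cannot learn a separating line")
  res <- cpp_best_line(points$p1, points$p2, as.integer(points$label))
  list(alpha = res$alpha, q = res$q,
       counts = list(tp = res$tp, fp = res$fp, fn = res$fn, tn = res$tn),
       f = res$f)
}

#' Relevance of one network for one term
#'
#' The best F-measure achievable by a separating line on the network's
#' projection — the coefficient with which the network enters the
#' consensus. The network is aligned to the labeling's universe first.
#' Relevance is invariant under a global rescaling of the network's weights
#' (the projection scales both coordinates and the optimal line rescales
#' with them).
#'
#' @param network a [WeightedNetwork].
#' @param labeling a [TermLabeling] with at least one positive.
#' @return one-row data.frame: `network`, `relevance`, `alpha`, `q`, `tp`,
#'   `fp`, `fn`, `tn`.
#' @export
networkRelevance <- function(network, labeling) {
  if (length(positiveIds(labeling)) < 1)
    stop("no positive proteins for term '", termId(labeling), "'")
  aligned <- alignToUniverse(network, vertexIds(labeling))
  best <- learnOptimalLine(projectNetwork(aligned, labeling))
  data.frame(network = networkName(network), relevance = best$f,
             alpha = best$alpha, q = best$q,
             tp = best$counts$tp, fp = best$counts$fp,
             fn = best$counts$fn, tn = best$counts$tn,
             stringsAsFactors = FALSE)
}

#' Integrate a network collection into a function-specific consensus
#'
#' Every network is aligned to the experiment universe (the union of the
#' collection's universe and the labeled proteins) and max-normalized; its
#' relevance \eqn{r_k} for the term is the best F-measure of a linear
#' separator of its projection. The consensus weight of an edge is the
#' relevance-weighted mean of the normalized input weights,
#' \eqn{W_{ij} = \sum_k r_k \hat W^{(k)}_{ij} / \sum_k r_k}, which keeps
#' consensus weights on the \[0, 1\] scale of the normalized inputs.
#' Per-edge provenance records the source networks in which the edge is
#' present with positive weight. Networks with \eqn{r_k = 0} contribute no
#' weight but are retained in provenance; a network whose optimum is the
#' trivial all-positive line is flagged with a message (its relevance only
#' reflects the class prior, not topology).
#'
#' @param collection a [NetworkCollection] (or a single [WeightedNetwork]).
#' @param labeling a [TermLabeling] with at least one positive protein.
#' @return a [ConsensusNetwork]; its relevance report is available via
#'   [relevanceReport()].
#' @export
integrateNetworks <- function(collection, labeling) {
  if (is(collection, "WeightedNetwork"))
    collection <- networkCollection(list(collection))
  stopifnot(is(collection, "NetworkCollection"), is(labeling, "TermLabeling"))
  if (length(collection) < 1) stop("at least one network is required")
  if (length(positiveIds(labeling)) < 1)
    stop("no positive proteins for term '", termId(labeling), "'")

  universe <- unique(c(vertexIds(collection), vertexIds(labeling)))
  lab <- termLabeling(termId(labeling), positiveIds(labeling), universe)

  nets <- lapply(collection@networks, function(nw)
    maxNormalize(alignToUniverse(nw, universe)))
  report <- do.call(rbind, lapply(nets, function(nw) {
    entry <- networkRelevance(nw, lab)
    nNeg <- length(universe) - length(positiveIds(lab))
    if (entry$fp == nNeg && entry$fn == 0)
      message("network '", entry$network, "': optimal line is the trivial ",
              "all-positive classifier; relevance reflects the class prior")
    entry
  }))

  r <- report$relevance
  if (sum(r) <= 0)
    stop("all networks have zero relevance for term '", termId(lab),
         "': uninformative collection")

  n <- length(universe)
  acc <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                              dims = c(n, n),
                              dimnames = list(universe, universe))
  for (k in seq_along(nets))
    acc <- acc + r[k] * adjacencyMatrix(nets[[k]])
  acc <- acc / sum(r)
  acc <- Matrix::drop0(as(forceSymmetric(acc), "dsCMatrix"))

  # provenance: per consensus edge, source networks carrying it
  keyList <- lapply(nets, function(nw) {
    et <- edgeTable(nw)
    paste(et$from, et$to, sep = "\t")
  })
  allKeys <- unlist(keyList, use.names = FALSE)
  allSrc <- rep(report$network, lengths(keyList))
  sets <- split(allSrc, allKeys)  # sorted by key
  parts <- strsplit(names(sets), "\t", fixed = TRUE)
  prov <- data.frame(
    from = vapply(parts, `[`, character(1), 1L),
    to = vapply(parts, `[`, character(1), 2L),
    stringsAsFactors = FALSE)
  prov$sources <- unname(sets)
  rownames(prov) <- NULL

  new("ConsensusNetwork",
      name = paste0("consensus:", termId(lab)),
      adjacency = acc, provenance = prov, relevance = report,
      term = termId(lab))
}

#' Write a relevance report as TSV
#'
#' Columns: `network`, `relevance` (the best F), `alpha`, `q`, `tp`, `fp`,
#' `fn`, `tn`.
#'
#' @param report data.frame from [relevanceReport()] or
#'   [networkRelevance()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRelevanceReport <- function(report, path) {
  write.table(report, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a consensus network with its provenance sidecar
#'
#' The consensus itself is written in triplet TSV format (see
#' [writeTripletNetwork()]); provenance goes to `<stem>-provenance.tsv`
#' with columns `source`, `target`, `networks` (semicolon-joined).
#'
#' @param consensus a [ConsensusNetwork].
#' @param path path for the triplet file; the provenance path is derived.
#' @return invisibly, the two paths written.
#' @export
writeConsensus <- function(consensus, path) {
  writeTripletNetwork(consensus, path)
  provPath <- paste0(sub("\\.tsv$", "", path), "-provenance.tsv")
  prov <- edgeProvenance(consensus)
  out <- data.frame(source = prov$from, target = prov$to,
                    networks = vapply(prov$sources, paste, character(1),
                                      collapse = ";"),
                    stringsAsFactors = FALSE)
  write.table(out, provPath, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(consensus = path, provenance = provPath))
}

#' Read a consensus network written by [writeConsensus()]
#'
#' Rebuilds a [ConsensusNetwork] from the triplet file and its provenance
#' sidecar (and, when present, the relevance report).
#'
#' @param path path to the consensus triplet TSV.
#' @param provenancePath path to the provenance sidecar; derived from
#'   `path` by default.
#' @param relevancePath optional path to a relevance report TSV.
#' @param term the GO term the consensus was built for.
#' @return a [ConsensusNetwork].
#' @export
readConsensus <- function(path,
                          provenancePath = paste0(sub("\\.tsv$", "", path),
                                                  "-provenance.tsv"),
                          relevancePath = NULL, term = "unknown") {
  net <- readTripletNetwork(path, name = paste0("consensus:", term))
  prov <- read.delim(provenancePath, colClasses = "character")
  provDf <- data.frame(from = pmin(prov$source, prov$target),
                       to = pmax(prov$source, prov$target),
                       stringsAsFactors = FALSE)
  provDf$sources <- strsplit(prov$networks, ";", fixed = TRUE)
  ord <- order(provDf$from, provDf$to)
  provDf <- provDf[ord, , drop = FALSE]
  rownames(provDf) <- NULL
  rel <- if (is.null(relevancePath)) {
    data.frame(network = character(), relevance = numeric(),
               alpha = numeric(), q = numeric(), tp = integer(),
               fp = integer(), fn = integer(), tn = integer())
  } else read.delim(relevancePath)
  new("ConsensusNetwork", name = paste0("consensus:", term),
      adjacency = adjacencyMatrix(net), provenance = provDf,
      relevance = rel, term = term)
}
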