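# Cost-sensitive Hopfield prediction on the consensus network.
#
# Neuron states are {sin(alpha), -cos(alpha)} with common threshold q, so
# the neuron update rule
#     x_i <- sin(alpha)  if  sum_j W_ij x_j - q > 0  else  -cos(alpha)
# is exactly the classification rule of the separating line learned on the
# consensus projection: maximizing F moves the known labeling towards an
# energy minimum of the same network. Labeled proteins are clamped; the
# asynchronous dynamics runs on the queried (unlabeled) proteins only, and
# the equilibrium internal inputs A_i = sum_j W_ij x_j - q, normalized to
# [-1, 1], are the prediction scores.

#' Construct a Hopfield configuration
#'
#' @param alpha neuron-state angle in radians, open interval (0, pi/2);
#'   positive state `sin(alpha)`, negative state `-cos(alpha)`.
#' @param q activation threshold.
#' @param maxSweeps maximum number of full asynchronous sweeps.
#' @param initState initial state of queried neurons: `"negative"` (default;
#'   the majority class under GO label imbalance) or `"positive"`.
#' @return a [HopfieldConfig].
#' @export
hopfieldConfig <- function(alpha, q, maxSweeps = 1000L,
                           initState = c("negative", "positive")) {
  new("HopfieldConfig", alpha = alpha, q = q,
      maxSweeps = as.integer(maxSweeps), initState = match.arg(initState))
}

#' Learn Hopfield parameters from the consensus projection
#'
#' `(alpha, q)` are taken from the F-measure-optimal separating line of the
#' consensus network's projection for the term (see [learnOptimalLine()]);
#' the remaining fields take their defaults.
#'
#' @param consensus a [ConsensusNetwork] (any [WeightedNetwork] works).
#' @param labeling a [TermLabeling] with at least one positive, aligned to
#'   the consensus universe (realigned internally otherwise).
#' @param maxSweeps,initState passed to [hopfieldConfig()].
#' @return a [HopfieldConfig].
#' @export
learnHopfieldParameters <- function(consensus, labeling, maxSweeps = 1000L,
                                    initState = "negative") {
  if (length(positiveIds(labeling)) < 1)
    stop("no positive proteins for term '", termId(labeling), "'")
  lab <- .alignLabeling(consensus, labeling)
  best <- learnOptimalLine(projectNetwork(consensus, lab))
  hopfieldConfig(best$alpha, best$q, maxSweeps = maxSweeps,
                 initState = initState)
}

.alignLabeling <- function(network, labeling) {
  ids <- vertexIds(network)
  if (identical(ids, vertexIds(labeling))) return(labeling)
  if (!all(positiveIds(labeling) %in% ids))
    stop("labeled positives missing from the network universe")
  termLabeling(termId(labeling), positiveIds(labeling), ids)
}

#' Run the clamped asynchronous Hopfield dynamics
#'
#' Labeled positive proteins are clamped at `sin(alpha)`, labeled negatives
#' at `-cos(alpha)`; the queried proteins start in the configured initial
#' state and are updated in ascending vertex order, one full sweep after
#' another, until a sweep produces zero flips or `maxSweeps` is reached.
#' The energy \eqn{E = -\tfrac12 \sum_{i \ne j} W_{ij} x_i x_j + q \sum_i
#' x_i} never increases across an accepted flip (symmetric weights, zero
#' diagonal); the trace after every flip is returned.
#'
#' @param consensus a [ConsensusNetwork] or [WeightedNetwork].
#' @param labeling a [TermLabeling] over the same universe.
#' @param config a [HopfieldConfig].
#' @param queried protein IDs to treat as unlabeled (must not contain
#'   labeled positives). Proteins outside `queried` and not positive are
#'   clamped as labeled negatives.
#' @return list: `state` (named numeric vector over the universe),
#'   `clamped` (named logical), `sweeps`, `converged`, `energies` (energy
#'   before dynamics and after every flip), `flips`.
#' @export
runHopfieldDynamics <- function(consensus, labeling, config, queried) {
  stopifnot(is(config, "HopfieldConfig"))
  ids <- vertexIds(consensus)
  lab <- .alignLabeling(consensus, labeling)
  queried <- as.character(queried)
  if (!all(queried %in% ids))
    stop("queried proteins outside the universe: ",
         paste(setdiff(queried, ids), collapse = ", "))
  if (any(queried %in% positiveIds(lab)))
    stop("queried set must contain only unlabeled proteins")

  a <- sin(config@alpha); b <- -cos(config@alpha)
  pos <- ids %in% positiveIds(lab)
  free <- ids %in% queried
  state <- ifelse(pos, a, b)
  if (config@initState == "positive") state[free] <- a
  clamped <- !free

  adj <- as(as(adjacencyMatrix(consensus), "generalMatrix"), "CsparseMatrix")
  res <- cpp_hopfield(length(ids), adj@p, adj@i, adj@x, state, clamped,
                      a, b, config@q, config@maxSweeps)
  if (!res$converged)
    warning("Hopfield dynamics did not converge within ", config@maxSweeps,
            " sweeps")
  list(state = setNames(res$state, ids), clamped = setNames(clamped, ids),
       sweeps = res$sweeps, converged = res$converged,
       energies = res$energies, flips = res$flips)
}

#' Hopfield energy of a state
#'
#' \eqn{E = -\tfrac12 \sum_{i \ne j} W_{ij} x_i x_j + q \sum_i x_i}, summed
#' over all vertices.
#'
#' @param consensus a [WeightedNetwork].
#' @param config a [HopfieldConfig] (supplies `q`).
#' @param state numeric vector of activations in universe order (or named).
#' @return a single number.
#' @export
hopfieldEnergy <- function(consensus, config, state) {
  ids <- vertexIds(consensus)
  if (!is.null(names(state))) state <- state[ids]
  x <- as.numeric(state)
  W <- adjacencyMatrix(consensus)
  as.numeric(-0.5 * crossprod(x, W %*% x) + config@q * sum(x))
}

.phiFromInput <- function(A) {
  m <- max(abs(A))
  if (m == 0) rep(0, length(A)) else A / m
}

#' Score queried proteins at equilibrium
#'
#' The raw internal input of protein \eqn{i} is \eqn{A_i = \sum_j W_{ij}
#' x_j - q}; the score is \eqn{\phi_i = A_i / \max_j |A_j|} over the queried
#' set (all-zero inputs give \eqn{\phi = 0}), so \eqn{\phi \in [-1, 1]}
#' with at least one \eqn{|\phi_i| = 1} whenever some \eqn{A_i \ne 0}.
#' Predicted positive iff \eqn{A_i > 0}; a zero input is predicted negative.
#' Scores near 0 mark uncertain predictions.
#'
#' @param consensus a [WeightedNetwork].
#' @param config a [HopfieldConfig].
#' @param state equilibrium state vector (named, over the universe).
#' @param queried non-empty character vector of queried protein IDs.
#' @return data.frame `protein`, `input`, `phi`, `predicted`, sorted by
#'   decreasing `phi`.
#' @export
scoreEquilibrium <- function(consensus, config, state, queried) {
  queried <- as.character(queried)
  if (length(queried) == 0) stop("empty queried set")
  ids <- vertexIds(consensus)
  if (!is.null(names(state))) state <- state[ids]
  W <- adjacencyMatrix(consensus)
  A <- as.numeric(W %*% as.numeric(state))[match(queried, ids)] - config@q
  phi <- .phiFromInput(A)
  out <- data.frame(protein = queried, input = A, phi = phi,
                    predicted = A > 0, stringsAsFactors = FALSE)
  out <- out[order(-out$phi, out$protein), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predict protein-term associations on a consensus network
#'
#' Full prediction pipeline: learn `(alpha, q)` on the consensus projection,
#' run the clamped asynchronous dynamics, and score the queried proteins
#' with the normalized equilibrium inputs. In `"all"` mode every unlabeled
#' protein is queried; in `"selection"` mode only the listed proteins are.
#' Listed proteins that are already labeled positive are excluded from the
#' query set and reported as annotated; listed proteins outside the universe
#' raise a warning (an error when none remain).
#'
#' @param consensus a [ConsensusNetwork] (see [integrateNetworks()]).
#' @param labeling a [TermLabeling].
#' @param mode `"all"` or `"selection"`.
#' @param targets protein IDs to predict in `"selection"` mode.
#' @param config optional [HopfieldConfig]; learned from the consensus when
#'   `NULL`.
#' @return a [PredictionResult].
#' @export
predictProteins <- function(consensus, labeling,
                            mode = c("all", "selection"), targets = NULL,
                            config = NULL) {
  mode <- match.arg(mode)
  lab <- .alignLabeling(consensus, labeling)
  ids <- vertexIds(consensus)
  if (mode == "all") {
    queried <- setdiff(ids, positiveIds(lab))
    annotated <- character()
  } else {
    targets <- unique(as.character(targets))
    if (length(targets) == 0)
      stop("selection mode requires a non-empty target list")
    unknown <- setdiff(targets, ids)
    if (length(unknown) == length(targets))
      stop("none of the selected proteins belong to the universe")
    if (length(unknown))
      warning("ignoring ", length(unknown), " selected protein(s) outside ",
              "the universe: ", paste(unknown, collapse = ", "))
    targets <- setdiff(targets, unknown)
    annotated <- intersect(targets, positiveIds(lab))
    queried <- setdiff(targets, annotated)
    if (length(queried) == 0)
      stop("all selected proteins are already annotated positives")
  }
  if (is.null(config))
    config <- learnHopfieldParameters(consensus, lab)
  dyn <- runHopfieldDynamics(consensus, lab, config, queried)
  scores <- scoreEquilibrium(consensus, config, dyn$state, queried)
  new("PredictionResult", scores = scores, annotated = annotated,
      converged = dyn$converged, sweeps = as.integer(dyn$sweeps),
      config = config)
}

#' Write predictions as TSV
#'
#' Columns `protein_id`, `phi` (6 decimal places; empty for annotated
#' proteins), `predicted` (1/0), `annotated` (1/0), `converged` (1/0),
#' sorted by decreasing score with the annotated proteins listed first.
#'
#' @param result a [PredictionResult].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePredictions <- function(result, path) {
  sc <- predictionScores(result)
  rows <- data.frame(
    protein_id = c(result@annotated, sc$protein),
    phi = c(rep(NA_character_, length(result@annotated)),
            sprintf("%.6f", sc$phi)),
    predicted = c(rep(1L, length(result@annotated)),
                  as.integer(sc$predicted)),
    annotated = c(rep(1L, length(result@annotated)),
                  rep(0L, nrow(sc))),
    converged = as.integer(result@converged),
    stringsAsFactors = FALSE)
  write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE,
              na = "")
  invisible(path)
}
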