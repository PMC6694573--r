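# Independent oracles and shared fixtures. These deliberately avoid the
# package's own search/dynamics code paths: the line oracle is a dense
# angle grid with an exact offset sweep, and the Hopfield oracle is a plain
# dense-matrix R re-statement of the update rule.

# Best F-measure of any separator p1*sin(a) - p2*cos(a) - q > 0 over a
# uniform grid of angles, sweeping q exactly for each angle. With k points
# predicted positive of which tp are true positives and P positives total,
# F = 2*tp / (k + P).
gridBestF <- function(p1, p2, y, nAngles = 10000) {
  P <- sum(y)
  n <- length(y)
  best <- 0
  for (alpha in (pi / 2) * seq_len(nAngles) / (nAngles + 1)) {
    z <- p1 * sin(alpha) - p2 * cos(alpha)
    o <- order(z, decreasing = TRUE)
    zs <- z[o]
    cum <- cumsum(y[o])
    valid <- c(zs[-n] > zs[-1], TRUE)
    best <- max(best, 2 * cum[valid] / (seq_len(n)[valid] + P))
  }
  best
}

# Plain-R asynchronous Hopfield dynamics on a dense matrix.
refHopfield <- function(W, state, clamped, a, b, q, maxSweeps = 1000) {
  n <- length(state)
  for (s in seq_len(maxSweeps)) {
    flips <- 0
    for (v in seq_len(n)) {
      if (clamped[v]) next
      A <- sum(W[v, ] * state) - q
      desired <- if (A > 0) a else b
      if (desired != state[v]) {
        state[v] <- desired
        flips <- flips + 1
      }
    }
    if (flips == 0)
      return(list(state = state, sweeps = s, converged = TRUE))
  }
  list(state = state, sweeps = maxSweeps, converged = FALSE)
}

refEnergy <- function(W, state, q) {
  -0.5 * as.numeric(t(state) %*% W %*% state) + q * sum(state)
}

# Wilcoxon rank-sum AUC of scores for positives vs negatives.
rankAUC <- function(pos, neg) {
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

## ---- fixtures -------------------------------------------------------------

pathNetwork <- function() {
  weightedNetwork(data.frame(from = c("a", "b"), to = c("b", "c"),
                             weight = 1), name = "path")
}

pathLabeling <- function() termLabeling("GO:1", "a", c("a", "b", "c"))

randomNetwork <- function(n = 20, m = 30, seed = 1, name = "random") {
  set.seed(seed)
  ids <- sprintf("v%03d", seq_len(n))
  pairs <- t(combn(ids, 2))
  pick <- sample(nrow(pairs), m)
  weightedNetwork(data.frame(from = pairs[pick, 1], to = pairs[pick, 2],
                             weight = round(runif(m), 6) + 1e-6),
                  vertices = ids, name = name)
}

# Single-network consensus over a 5-weight toy used by the exploration
# tests: star around "hub" plus a tail.
toyConsensus <- function() {
  net <- weightedNetwork(data.frame(
    from = c("hub", "hub", "hub", "a1", "b2"),
    to = c("a1", "b2", "c3", "d4", "e5"),
    weight = c(0.1, 0.3, 0.5, 0.7, 0.9)), name = "toy")
  suppressMessages(
    integrateNetworks(networkCollection(list(net)),
                      termLabeling("GO:toy", "hub", vertexIds(net))))
}

# Two 6-node networks sharing the edge (u1, u2), with labeled positives
# {u1, u2}; used to verify the relevance-weighted combination formula.
sixNodeInstance <- function() {
  ids <- paste0("u", 1:6)
  net1 <- weightedNetwork(data.frame(
    from = c("u1", "u1", "u5"), to = c("u2", "u3", "u6"),
    weight = c(2, 1, 4)), vertices = ids, name = "netA")
  net2 <- weightedNetwork(data.frame(
    from = c("u1", "u2", "u3"), to = c("u2", "u4", "u4"),
    weight = c(1, 0.5, 0.25)), vertices = ids, name = "netB")
  list(ids = ids, nets = list(net1, net2),
       labeling = termLabeling("GO:6", c("u1", "u2"), ids))
}

# 6-vertex Hopfield toy: two mutually-linked free vertices plus clamps.
hopfieldToy <- function() {
  ids <- c("p1", "p2", "n1", "n2", "f1", "f2")
  net <- weightedNetwork(data.frame(
    from = c("p1", "p2", "n1", "f1", "p1", "n2"),
    to = c("f1", "f1", "f2", "f2", "f2", "f1"),
    weight = c(1, 0.8, 0.6, 0.9, 0.4, 0.3)), vertices = ids,
    name = "hopfield-toy")
  list(net = integrateNetworks(networkCollection(list(net)),
                               termLabeling("GO:h", c("p1", "p2"), ids)),
       labeling = termLabeling("GO:h", c("p1", "p2"), ids),
       free = c("f1", "f2"))
}
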