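---
title: "Function-specific network integration and Hopfield prediction"
author: "netintegrate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Function-specific network integration and Hopfield prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netintegrate)
```

## The model

Protein function prediction from networks is a semi-supervised node
classification problem with two structural features that shape every design
choice in this package. First, evidence networks are *function-specific*:
a co-expression network may be highly informative for one GO term and pure
noise for another, so the weight a network receives in a consensus must be
learned per term. Second, GO annotations are *scarce*: for most terms well
under 5% of proteins are positives, so any criterion that rewards correct
negatives (accuracy, error rate) is dominated by the majority class.

For a term $d$ over the universe $V$ with labels $y_d(i) \in \{0, 1\}$,
each network $G^{(k)} = \langle V, W^{(k)} \rangle$ is collapsed to one
labeled planar point per protein:

$$P^{(k)}_{i,1} = \sum_{j \in V} W^{(k)}_{ij}\, y_d(j), \qquad
  P^{(k)}_{i,2} = \sum_{j \in V} W^{(k)}_{ij}\, (1 - y_d(j)),$$

the summed weight towards positive and negative neighbours respectively.
The diagonal of $W$ is zero by construction, so a protein's own label never
leaks into its point. In an informative network positives sit high on the
first coordinate; in an uninformative one the two coordinates mix.

A linear separator with positive slope, written in normal form

$$p_1 \sin\alpha - p_2 \cos\alpha - q > 0 \;\Rightarrow\; \text{positive},
  \qquad \alpha \in (0, \pi/2),$$

is fitted to maximize the F-measure $F = 2TP / (2TP + FP + FN)$, which
never credits true negatives and is therefore imbalance-aware. The optimum
$\bar F$ is the network's *relevance* $r^{(k)}_d \in [0, 1]$. The consensus
weight of each edge is the relevance-weighted mean of the max-normalized
inputs,
$$W_{ij} = \frac{\sum_k r_k \hat W^{(k)}_{ij}}{\sum_k r_k},$$
which keeps consensus weights on the same $[0,1]$ scale as the inputs and
makes a single-network integration the identity (after normalization).

Restricting $\alpha$ to $(0, \pi/2)$ admits only separators for which more
positive-neighbour mass can never argue *against* a positive call — and it
makes the line's decision rule identical to the activation rule of a
two-state Hopfield neuron with states $\{\sin\alpha, -\cos\alpha\}$ and
threshold $q$. That identification is the bridge to the prediction engine:
the parameters learned by F-maximization on the consensus *are* the
Hopfield parameters, and maximizing F moves the observed labeling towards a
minimum of the network energy
$$E = -\tfrac12 \sum_{i \ne j} W_{ij} x_i x_j + q \sum_i x_i.$$

Prediction clamps labeled proteins (positives at $\sin\alpha$, negatives at
$-\cos\alpha$) and relaxes the queried proteins by asynchronous sweeps of
the update rule until a fixed point. Because couplings are symmetric and
the diagonal is zero, every accepted flip strictly decreases $E$ except for
zero-field flips, so the dynamics terminates; the package asserts the
non-increasing energy trace on every test run. The equilibrium internal
input $A_i = \sum_j W_{ij} x_j - q$ is normalized by
$\max_{j \in U} |A_j|$ to a score $\phi_i \in [-1, 1]$; $A_i > 0$ gives the
binary call, and $|\phi|$ near 0 marks uncertain predictions.

## Parameters that matter

* **`alpha` (radians, open $(0, \pi/2)$)** and **`q`** — the separator /
  neuron parameters. Learned per term; only override them to probe the
  dynamics (as the tests do).
* **`maxSweeps` (default 1000)** — sweep budget for the dynamics. All test
  instances up to 500 vertices converge within a handful of sweeps; the
  budget exists as a guard, and exceeding it flags (not fails) the result.
* **`initState` (default `"negative"`)** — initial state of queried
  neurons. Negative is the majority class under annotation imbalance, so it
  is the conservative prior; a positive start biases towards the positive
  basin and is offered only as an option.
* **Weight scale** — none. Relevance is invariant under global rescaling of
  a network (both projection coordinates scale together, and the optimal
  line rescales with them; asserted numerically in the tests), and every
  network is max-normalized before combination.

## The optimal-line search

The F-landscape over $(\alpha, q)$ is piecewise constant, so the search is
combinatorial rather than numerical. Candidate angles are taken where the
ordering of projected scores $z_i = p_{1i}\sin\alpha - p_{2i}\cos\alpha$
can change — $\tan\alpha = \Delta p_2 / \Delta p_1$ for every pair of
distinct points, kept when inside $(0, \pi/2)$ — plus a uniform 64-angle
fallback grid (for degenerate point sets with no admissible pairwise
angle) and $\pm 10^{-6}$ perturbations of every candidate: an angle passing
exactly through two points leaves them tied on the boundary, and the two
perturbations realize both resolutions of the tie. For each angle, $q$ is
swept exactly over midpoints between consecutive distinct sorted scores
plus sentinels beyond both extremes; with $k$ points above the cut of which
$tp$ positive, $F = 2\,tp/(k + P)$. Ties are broken by maximum $F$, then
maximum $TP$ (prefer recall under imbalance), then minimum $\alpha$, then
minimum $q$ — a fixed hierarchy chosen purely for determinism. Boundary
points are classified negative (strict inequality): conservative under
imbalance, and consistent with the Hopfield rule where a zero field sends
the neuron to the negative state. The search is implemented in C++ (as is
the sweep dynamics); a 10,000-angle brute-force grid with the same exact
$q$-sweep serves as an independent oracle in the tests, and the two agree
to $10^{-9}$ on a hundred random instances.

Two degenerate behaviours are worth knowing. An edgeless (or zero-relevance
direction) network projects every protein to the origin, where the only
non-trivial cut is "predict everything positive"; its relevance is then the
class-prior baseline $2P/(n + P)$ rather than zero. The package keeps this
faithful value (no baseline subtraction) but emits a message when a
network's optimum is the trivial all-positive line. Second, relevance can
never be exactly zero (the all-positive cut always has $F > 0$), so the
weighted mean is always well defined; the all-zero guard in
`integrateNetworks()` is defensive only.

## Design choices where the design was open

* **Universe construction** — the experiment universe is the *union* of all
  selected networks' vertices plus all labeled proteins; labeled proteins
  absent from every network stay as isolated vertices rather than being
  dropped. Intersection would silently discard exactly the proteins a user
  asks about.
* **Hopfield parameters are learned on the consensus**, not recycled from
  any single network's line: the dynamics runs on the consensus, so its
  parameters should be fitted to the consensus geometry.
* **Update order** is a deterministic ascending-ID sweep, chosen for exact
  reproducibility of scores and ranks across runs and platforms.
* **Normalization of $\phi$** divides by the maximum absolute internal
  input over the queried set, so $\phi$ always spans to $\pm 1$ when any
  input is nonzero and an all-zero query set scores 0 everywhere.
* **Ego exploration** returns the *induced* subgraph on the vertices within
  the requested hop distance (not only target-incident edges), because
  neighbour–neighbour edges are what make local cliques visible. The edge
  weight filter is inclusive ($\ge$), so a user-typed exact weight stays
  visible; it is monotone and idempotent.
* **Duplicate and self edges** — duplicate listings of an unordered pair
  collapse to one edge (conflicting weights average, with a warning);
  self-pairs are dropped (the dynamics requires a zero diagonal). Negative
  weights are a format error, since all supported sources are
  similarity-type.

## What the synthetic generator emulates — and what it does not

`plantedScenario()` encodes the package's standard study conditions: 200
proteins, 30 positives, positive pairs connected with probability 0.3 and
weights uniform on $[0.5, 1]$, all other pairs with probability 0.05 and
weights uniform on $[0, 0.5]$, plus two label-independent Erdős–Rényi
noise networks ($p = 0.1$, weights uniform on $[0, 1]$). The informative
weight law is deliberately heavier than the background so that
max-normalization and weight filtering are exercised, and the positive rate
(15%) is imbalanced but not so extreme that 20-replicate tests become
noise-dominated. All randomness flows through seeds derived from the
scenario seed, so identical seeds give byte-identical files.

What passing tests on this generator show: the relevance machinery ranks a
function-informative network above label-independent noise (19/20 seeds or
better), and masked positives are recovered by $\phi$ with AUC > 0.8 in at
least 9/10 seeds. What they do not show: real protein networks have
heavy-tailed degree distributions, modular structure and correlated noise
across sources, none of which the generator models; GO terms overlap and
form a hierarchy, which the single-term labeling ignores. Results on
planted data bound the machinery's correctness, not its biological
performance.

## Problem sizes and tolerances

The test suite runs the full pipeline at $n = 200$ (the default scenario)
and the Hopfield property checks up to $n = 500$; line-search oracle
comparisons use up to 12 points, where the dense grid is provably close to
exhaustive. Energy monotonicity is asserted at $10^{-9}$ slack (floating
accumulation over a trace), oracle agreement at $10^{-9}$, and exact
formula examples (projection, F-measure, the combination identity) at
equality. F-measure comparisons inside the C++ search use exact rational
arithmetic in doubles ($2\,tp/(k+P)$ with small integers), so tie-breaking
is not tolerance-dependent.

## Known limitations

* Relevance of a topology-free network equals the class-prior baseline, so
  very sparse networks receive a small but nonzero combination weight;
  whether to subtract the baseline is left open deliberately, and the
  faithful $\bar F$ is used.
* The trivial all-positive optimum is reported by message, not by a
  relevance of zero.
* The per-edge combination divides by the total $\sum_k r_k$, not by the
  sum over networks containing that edge; edges present in few networks are
  therefore down-weighted relative to ubiquitous ones. This is the intended
  reading of a linear combination of whole networks.
* Prediction treats every unannotated protein as a (clamped or queried)
  negative; there is no negative-selection heuristic and no GO-hierarchy
  post-processing.
* The Hopfield model here is one concrete, self-consistent instantiation of
  the cost-sensitive lineage: two states coupled to the learned line, common
  threshold, deterministic sweeps. Variants with neuron-specific thresholds
  or regularized F are out of scope.
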