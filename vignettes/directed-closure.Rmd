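---
title: "Measuring directed triangle formation from the end-node: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring directed triangle formation from the end-node: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netclosure)
```

## The two views of triangle formation

An *open triad* is an unordered pair of edges sharing a node. The shared
node is the triad's *centre*; the other two nodes are its *ends*. A third
edge between the two end-nodes *closes* the triad into a triangle. The
clustering coefficient evaluates closure from the centre: of the
`d_i (d_i - 1) / 2` triads centred at node `i`, what fraction is closed?
The closure coefficient evaluates the same phenomenon from the end: of the
`sum_{j in N(i)} (d_j - 1)` triads with `i` at one end, what fraction is
closed? The two are not redundant — the closing edge in the end-node view
is *incident to the focal node*, which is exactly what makes the closure
coefficient informative for link prediction, and each triangle at `i`
contains `i` once as a centre and twice as an end (hence the factor 2 in
`E(i) = 2 T(i) / OTE(i)`).

## Directed definitions and the bidirectional convention

In a simple digraph each of a triangle's three edges can point either way,
giving eight directed triangle types. All counts in this package follow
the *bidirectional decomposition* convention: a reciprocated edge is
treated as two unidirectional edges, so an open triad with one
bidirectional edge counts as two unidirectional triads, and a triangle
with two bidirectional edges as four unidirectional triangles. A fully
reciprocal triangle therefore contributes 8 instances at each node, and on
a symmetric digraph every directed coefficient collapses to its
undirected counterpart (this reduction is tested).

Writing `b_ij = a_ij + a_ji` and `d_j` for the total degree, the local
directed closure coefficient is

    E^D(i) = [ sum_jk b_ij b_ik b_jk ] / [ 2 sum_{j in N(i)} b_ij (d_j - b_ij) ]

The denominator counts end-node directed open triads `OTE^D(i)` twice
because the closing edge may take either direction. When the neighbours of
`i` connect only to `i`, the denominator vanishes and the coefficient is
*undefined*; undefined values are kept as `NA` at node level and mapped to
0 only inside network averages (this averaging convention is applied
uniformly, including in the signature features).

Splitting the closing edge by direction gives the source and target
coefficients

    E_src(i) = T_src(i) / OTE^D(i),   E_tgt(i) = T_tgt(i) / OTE^D(i)

whose denominators are the *single*-direction triad count: each admissible
closing direction is a separate chance to close, so both lie in [0, 1] and
`E_src + E_tgt = 2 E^D` wherever defined. The denominator here is `OTE^D(i)`
computed from the *neighbours'* degrees `d_j`; writing it with the focal
degree `d_i` instead would break that identity, which the test suite
asserts exactly on hundreds of random digraphs. A triangle whose closing
edge is bidirectional contributes to both the source and the target count
after decomposition.

The four *patterns* classify the eight triangle types by the focal node's
transitive role — head of the length-2 path (`i→j`, `j→k` or the mirror),
middle, end, or cyclic — and each pattern coefficient divides twice its
triangle count by the two open-triad types it can close, e.g.

    E_head(i) = 2 T_head(i) / (OTE^{>>}(i) + OTE^{><}(i))
              = sum_jk a_ij a_ik b_jk / sum_{j in N(i)} a_ij (d_j - b_ij)

All pattern denominators are computable from the focal node's
neighbourhood and its neighbours' in/out-degrees. The head+end and
mid+cyc denominator pairs each partition `OTE^D(i)` (tested), and the four
pattern numerators partition the directed triangle count. The analogous
centre-node pattern denominators are `2 OTC^{>>} = d_out (d_out - 1)`,
`2 OTC^{<<} = d_in (d_in - 1)` and `OTC^{><} = d_in d_out - d_bi`.

## Weighted and signed graphs

For weighted graphs the potential closing edge is implicitly assigned the
maximum weight, so the denominator becomes a strength-based capacity:

    E^{W,D}(i) = sum_jk (w_ij+w_ji)(w_ik+w_ki)(w_jk+w_kj) /
                 [ 2 sum_{j in N(i)} (|w_ij|+|w_ji|) (s_j - (|w_ij|+|w_ji|)) ]

Weights must be normalised by the maximum absolute weight
(`normalize_weights()`, applied automatically by the CLI); zero-weight
edges are dropped at construction because every formula treats them as
absent. For signed graphs the strength uses absolute weights,
`s_j = sum_k |w_jk| + sum_k |w_kj|`. The denominator *factors* also use
magnitudes `|w_ij| + |w_ji|` — with raw signed sums the "capacity" could
be negative and the coefficient unbounded; with magnitudes the denominator
is the positive capacity of the surrounding triads, the numerator is odd
under a global sign flip (tested), and `E^{W,D}` stays in [-1, 1], negative
exactly when negative (distrustful) triangles outweigh positive ones.
This treatment of the denominator is a deliberate design choice of this
package: it is the minimal completion of the signed definition that
preserves the stated range.

The undirected weighted coefficient `E^W(i)` is defined for symmetric
weights; when a digraph is supplied, the weight of an unordered pair is
taken as the mean of its present directed weights (a symmetric input
keeps its shared weight, a single edge keeps its own). Binary weights
reduce both weighted coefficients exactly to their binary counterparts
(tested on random digraphs).

## Fast path, oracle, and numerical choices

Every coefficient is a ratio of integer counts. The fast path assembles
all numerators and denominators for all nodes at once from sparse 0/1
adjacency products (`Matrix`), e.g. `sum_jk b_ij b_jk a_ik` is
`rowSums((B %*% B) * A)` with `B = A + t(A)`. Sparse products visit one
entry per (neighbour, neighbour-of-neighbour) pair, so the cost tracks
`sum_j d_j^2` — the same `O(|V| k̄²)` budget as an explicit neighbourhood
iteration, while staying vectorised R. Counts are integer-valued doubles
(exact below 2^53) and each ratio is divided once at the end, so results
carry no accumulation error and agree *bit for bit* with the brute-force
oracle.

That oracle (`enumerate_triads()`, `enumerate_triangles()`) iterates over
all ordered node pairs `(j, k)` with explicit scalar arithmetic on a dense
adjacency matrix, decomposing bidirectional edges and classifying each
unidirectional instance before aggregation. It is deliberately naive
(`O(n²)` per node), shares no code with the fast path, and is also
reachable from the command line via `--method brute`. The test suite
checks exact equality of every local coefficient on 200 seeded random
digraphs (`n ≤ 40`, `p ∈ {0.05, 0.2, 0.5}`), plus the global
closure/clustering equivalences to 1e-12 — these hold with gap exactly 0
because both global ratios are formed from the same integer totals.

Degenerate inputs are handled explicitly: self-loops are dropped at
construction (all definitions assume their absence), duplicate ordered
pairs collapse with the last weight winning, empty denominators yield
`NA` (written as `NA` in CSV output), and an empty edge set makes
reciprocity and the global coefficients an error rather than a silent 0.

## Synthetic data and what the tests do and do not show

`sample_gnp_directed(n, p)` draws each ordered pair independently with
probability `p`, so reciprocity arises by chance at rate `p`; optional
weights are uniform on (0, 1] or, for signed graphs, uniform on [-1, 1]
excluding 0. Under this null model the expected local directed closure
coefficient is `p`, and the acceptance suite checks the node-averaged
coefficient on seeded G(300, p) graphs against `p` within three standard
errors for `p ∈ {0.05, 0.1, 0.2}`.

Two caveats are worth stating. First, the `E[E^D] = p` claim is
asymptotic: at `n = 300` we observe a small systematic deficit of about
0.001–0.002 (the closing edge of one triad is also a leg of other triads,
which correlates numerator and denominator and biases the ratio
downwards); the 3-standard-error band absorbs it at this size, but
replicate-averaged grand means would resolve the bias. Second, G(n, p)
graphs are homogeneous: they exercise correctness of the counting
machinery, not the heavy-tailed degree distributions, degree–closure
correlations or community structure of real directed networks, so passing
tests certify the *implementation*, not behaviour on any particular
empirical network class.

Problem sizes in the suite were chosen to keep the full run at desk
scale: 200 oracle-checked graphs up to `n = 40`, expectation checks at
`n = 300`, link-prediction protocols on graphs of 30–60 nodes, and
classification contracts on 10–20 row signature tables.

## Link prediction protocol

`evaluate_link_prediction()` follows a 50/50 protocol: edges are ordered
by timestamp (ties by input order) when a temporal split is requested,
otherwise sampled uniformly; the old graph is the selected edges plus
their incident nodes `V*`, and future edges are the remainder with both
endpoints in `V*`. Candidates are all ordered pairs over `V*` minus
existing edges *and minus self-pairs* — a simple digraph cannot gain a
self-loop, so including self-pairs would only pad the negatives (the
candidate count is therefore `|V*|² - |V*| - |E_old|`). Scores with
undefined source/target closure contribute 0. PR-AUC is computed as
non-interpolated average precision over the descending-score ranking with
stable tie-breaking; on graphs beyond 10,000 nodes each repetition scores
the pairs among 3,000 nodes sampled uniformly from the old graph's
non-isolated nodes. The natural logarithm is used in the Adamic–Adar
weight, the convention of the original undirected index.

## Classification harness

`loocv_classify()` and `feature_importance()` operate on signature tables
(one row per network, eight averaged pattern features). Signature tables
of real network collections are small — a few dozen rows — so the tree
models default to small-sample settings: CART grows with `minsplit = 2`,
`minbucket = 1`, `cp = 0` (the usual `minsplit = 20` would never split),
and the boosted model uses exact mid-gap splits with
`min_child_weight = 0` (histogram splitting places thresholds adjacent to
a class boundary, which misclassifies held-out margin points, and the
default hessian floor refuses any split on ~10-row training folds). The
random forest keeps its standard defaults. Accuracy is the mean over
repeated leave-one-out rounds (ensembles are stochastic; seeding makes
runs reproducible), and importances are normalised impurity decreases
averaged over repeats, summing to 1 by construction — with the documented
convention that a fit using no feature contributes a uniform vector.
Feature standardization for visual comparison uses the population
standard deviation, mapping a two-point column {0, 2} to {-1, +1}.

## Known limitations

- The published food-web and signed trust-network case studies are
  reproduced by acceptance tests only when the corresponding public edge
  lists are placed under `inst/extdata/realworld/`; they are not bundled.
- Weighted versions of the four patterns and of the source/target
  coefficients are not defined here (the weighted theory covers the
  general directed coefficient only).
- The link-prediction protocol scores all candidate pairs; on dense or
  large old graphs this is quadratic in `|V*|`, which is why node
  sampling kicks in beyond 10,000 nodes.
- Multigraphs are out of scope: duplicate edges collapse at construction.
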