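#' Local closure coefficient (undirected)
#'
#' Measures triangle formation from the end-node of an open triad: twice
#' the number of triangles at the focal node over the number of open triads
#' with the focal node at an end,
#' `E(i) = 2 T(i) / sum_{j in N(i)} (d_j - 1)`, on the undirected
#' projection. Each triangle contains the focal node as the end-node of two
#' open triads, hence the factor two. `NA` when every neighbour of `i` is
#' connected only to `i`.
#'
#' @param g a [digraph]; direction is ignored.
#' @return A named numeric vector over all nodes, `NA` where undefined.
#' @export
local_closure <- function(g) {
  uc <- undirected_counts(g)
  stats::setNames(safe_ratio(uc$num_2t, uc$ote_u), g$nodes)
}

#' Global closure coefficient (undirected)
#'
#' Network-level closure: six times the triangle count over twice the
#' number of end-node open triads. On any undirected network this equals
#' the global clustering coefficient, because globally the position of the
#' focal node in a triad does not matter.
#'
#' @inheritParams local_closure
#' @return A number in `[0, 1]`.
#' @export
global_closure <- function(g) {
  uc <- undirected_counts(g)
  den <- sum(uc$ote_u)
  if (den == 0) stop("no open triads: global closure is undefined")
  sum(uc$num_2t) / den
}

#' Local directed closure coefficient
#'
#' The core end-node measure for digraphs: twice the number of
#' unidirectional directed triangle instances at the focal node over twice
#' the number of directed open triads with the focal node at an end,
#' \deqn{E^D(i) = \frac{\sum_j \sum_k (a_{ij}+a_{ji})(a_{ik}+a_{ki})(a_{jk}+a_{kj})}
#'   {2 \sum_{j \in N(i)} (a_{ij}+a_{ji})\,(d_j - (a_{ij}+a_{ji}))}.}
#' Bidirectional edges are decomposed into unidirectional instances. The
#' denominator doubling reflects that the closing edge can take either
#' direction. On a symmetric digraph this reduces to the undirected
#' [local_closure()]. `NA` when the node's neighbours connect only to it.
#'
#' @param g a [digraph].
#' @return A named numeric vector over all nodes, `NA` where undefined.
#' @export
local_directed_closure <- function(g) {
  dc <- directed_counts(g)
  stats::setNames(safe_ratio(dc$num_t2d, 2 * dc$ote_d), g$nodes)
}

#' Source and target closure coefficients
#'
#' Splits the directed closure coefficient by the direction of the closing
#' edge: `E_src(i)` counts triangles where the focal node is the source of
#' the closing edge, `E_tgt(i)` those where it is the target, each over the
#' (single-direction) open-triad count `OTE^D(i)`. Because triangles are
#' counted from the end-node perspective, a triangle whose closing edge is
#' bidirectional contributes to both, giving the identity
#' `E_src(i) + E_tgt(i) = 2 E^D(i)` wherever defined.
#'
#' @param g a [digraph].
#' @return A data frame with columns `node`, `e_src`, `e_tgt` (`NA` where
#'   undefined).
#' @export
source_target_closure <- function(g) {
  dc <- directed_counts(g)
  data.frame(node = g$nodes,
             e_src = safe_ratio(dc$num_src, dc$ote_d),
             e_tgt = safe_ratio(dc$num_tgt, dc$ote_d),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Four directed closure patterns
#'
#' Splits the directed closure coefficient by the transitive role of the
#' focal (end) node: head-of-path (`e_head`), mid-of-path (`e_mid`),
#' end-of-path (`e_end`) and cyclic (`e_cyc`). Each pattern is twice its
#' triangle count over the sum of the two open-triad types it can close,
#' computable from the focal node's neighbourhood and its neighbours'
#' degrees. A pattern is `NA` where its open-triad denominator vanishes.
#'
#' @param g a [digraph].
#' @return A data frame with columns `node`, `e_head`, `e_mid`, `e_end`,
#'   `e_cyc`.
#' @export
closure_patterns <- function(g) {
  dc <- directed_counts(g)
  data.frame(node = g$nodes,
             e_head = safe_ratio(dc$num_head, dc$ote_head),
             e_mid = safe_ratio(dc$num_mid, dc$ote_mid),
             e_end = safe_ratio(dc$num_end, dc$ote_end),
             e_cyc = safe_ratio(dc$num_cyc, dc$ote_cyc),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Average directed closure coefficient
#'
#' Mean of the local directed closure coefficient over all nodes, with
#' undefined values treated as zero. On a directed Erdos-Renyi G(n, p)
#' graph its expectation is `p`.
#'
#' @param g a non-empty [digraph].
#' @return A number in `[0, 1]`.
#' @export
average_directed_closure <- function(g) {
  average_coefficient(local_directed_closure(g))
}

#' Global directed closure coefficient
#'
#' Network-level directed closure: six times the directed triangle count
#' over twice the number of end-node directed open triads. On any digraph
#' this equals the global directed clustering coefficient
#' ([global_directed_clustering()]); both are exposed so the identity can
#' be verified numerically.
#'
#' @param g a [digraph].
#' @return A number in `[0, 1]`.
#' @export
global_directed_closure <- function(g) {
  dc <- directed_counts(g)
  den <- sum(dc$ote_d)
  if (den == 0) stop("no directed open triads: global directed closure is undefined")
  sum(dc$num_t2d) / (2 * den)
}

#' Per-node closure profile
#'
#' Bundles the undirected, directed, source/target and four-pattern closure
#' coefficients for every node.
#'
#' @param g a [digraph].
#' @return A data frame with columns `node`, `e`, `e_d`, `e_src`, `e_tgt`,
#'   `e_head`, `e_mid`, `e_end`, `e_cyc` (`NA` where undefined).
#' @export
closure_profile <- function(g) {
  st <- source_target_closure(g)
  pat <- closure_patterns(g)
  data.frame(node = g$nodes,
             e = unname(local_closure(g)),
             e_d = unname(local_directed_closure(g)),
             st[, c("e_src", "e_tgt")],
             pat[, c("e_head", "e_mid", "e_end", "e_cyc")],
             stringsAsFactors = FALSE, row.names = NULL)
}
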