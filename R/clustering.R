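#' Local clustering coefficient (undirected)
#'
#' Fraction of centre-node open triads at each node that are closed:
#' `C(i) = T(i) / [d_i (d_i - 1) / 2]`, computed on the undirected
#' projection of the graph (an edge is present if either orientation
#' exists). Undefined (`NA`) when the node has fewer than two neighbours.
#'
#' @param g a [digraph]; direction is ignored.
#' @return A named numeric vector over all nodes, `NA` where undefined.
#' @export
local_clustering <- function(g) {
  uc <- undirected_counts(g)
  out <- safe_ratio(uc$num_2t, uc$du * (uc$du - 1))
  stats::setNames(out, g$nodes)
}

#' Global clustering coefficient (undirected)
#'
#' Fraction of open triads in the whole (projected) network that form
#' triangles: the triangle count is summed over nodes before dividing, so
#' this is not the average of the local coefficients.
#'
#' @inheritParams local_clustering
#' @return A number in `[0, 1]`.
#' @export
global_clustering <- function(g) {
  uc <- undirected_counts(g)
  den <- sum(uc$du * (uc$du - 1))
  if (den == 0) stop("no open triads: global clustering is undefined")
  sum(uc$num_2t) / den
}

#' Local directed clustering coefficient
#'
#' Fagiolo-style clustering for digraphs: the number of unidirectional
#' directed triangle instances at the focal node, over twice the number of
#' centre-node directed open triads,
#' `C^D(i) = T^D(i) / [d_i (d_i - 1) - 2 d_i^bi]`. Bidirectional edges are
#' decomposed into unidirectional instances throughout. `NA` when the
#' denominator is zero.
#'
#' @param g a [digraph].
#' @return A named numeric vector over all nodes, `NA` where undefined.
#' @export
local_directed_clustering <- function(g) {
  dc <- directed_counts(g)
  stats::setNames(safe_ratio(dc$num_t2d / 2, dc$otc_d2), g$nodes)
}

#' Global directed clustering coefficient
#'
#' Fraction of directed open triads in the entire network that form
#' directed triangles; the numerator equals three times the number of
#' directed triangles. Equals the global directed closure coefficient on
#' every digraph (see [global_directed_closure()]).
#'
#' @param g a [digraph].
#' @return A number in `[0, 1]`.
#' @export
global_directed_clustering <- function(g) {
  dc <- directed_counts(g)
  den <- sum(dc$otc_d2)
  if (den == 0) stop("no directed open triads: global directed clustering is undefined")
  (sum(dc$num_t2d) / 2) / den
}

#' Four directed clustering patterns
#'
#' Splits the directed clustering coefficient by the transitive role of the
#' focal (centre) node: head-of-path (`c_head`, two outgoing triad edges),
#' end-of-path (`c_end`, two incoming), mid-of-path (`c_mid`) and cyclic
#' (`c_cyc`, both on mixed triads). Pattern denominators are
#' `2 OTC^{->->} = d_out (d_out - 1)`, `2 OTC^{<-<-} = d_in (d_in - 1)` and
#' `OTC^{-><-} = d_in d_out - d_bi`; a pattern is `NA` where its
#' denominator vanishes.
#'
#' @param g a [digraph].
#' @return A data frame with columns `node`, `c_head`, `c_mid`, `c_end`,
#'   `c_cyc`.
#' @export
clustering_patterns <- function(g) {
  dc <- directed_counts(g)
  data.frame(node = g$nodes,
             c_head = safe_ratio(dc$num_head / 2, 2 * dc$otc_oo),
             c_mid = safe_ratio(dc$num_mid / 2, dc$otc_oi),
             c_end = safe_ratio(dc$num_end / 2, 2 * dc$otc_ii),
             c_cyc = safe_ratio(dc$num_cyc / 2, dc$otc_oi),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Average a per-node coefficient with the undefined-as-zero convention
#'
#' Network-level averages of local coefficients treat an undefined (`NA`)
#' local value as zero, so the mean always runs over all nodes.
#'
#' @param values numeric vector of per-node values, possibly `NA`.
#' @return The mean with `NA` replaced by 0.
#' @export
average_coefficient <- function(values) {
  if (!length(values)) stop("cannot average over an empty node set")
  values[is.na(values)] <- 0
  mean(values)
}

#' Per-node clustering profile
#'
#' Bundles the undirected, directed and four-pattern clustering
#' coefficients for every node.
#'
#' @param g a [digraph].
#' @return A data frame with columns `node`, `c`, `c_d`, `c_head`, `c_mid`,
#'   `c_end`, `c_cyc` (`NA` where undefined).
#' @export
clustering_profile <- function(g) {
  pat <- clustering_patterns(g)
  data.frame(node = g$nodes,
             c = unname(local_clustering(g)),
             c_d = unname(local_directed_clustering(g)),
             pat[, c("c_head", "c_mid", "c_end", "c_cyc")],
             stringsAsFactors = FALSE, row.names = NULL)
}
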