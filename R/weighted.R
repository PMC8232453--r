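# Weighted closure follows the strength-based construction: the potential
# closing edge is implicitly given the maximum (normalised) weight 1, so the
# denominator is a triad "capacity" computed from strengths.

check_normalized <- function(g) {
  if (!is_weighted(g)) stop("graph has no weights")
  if (max(abs(g$weight)) > 1 + 1e-9) {
    stop("weights must lie in [-1, 1]; call normalize_weights() first")
  }
}

#' Normalize edge weights by the maximum absolute weight
#'
#' Divides every weight by `max(|w|)` so that unsigned weights lie in
#' `(0, 1]` and signed weights in `[-1, 1]`, preserving signs. The weighted
#' closure coefficients assume weights on this scale. Idempotent.
#'
#' @param g a weighted [digraph].
#' @return A [digraph] with rescaled weights.
#' @export
normalize_weights <- function(g) {
  if (!is_weighted(g)) stop("graph has no weights")
  m <- max(abs(g$weight))
  if (m == 0) stop("all weights are zero")
  digraph(g$nodes[g$from], g$nodes[g$to], weight = g$weight / m,
          timestamp = g$timestamp, nodes = g$nodes, signed = g$signed)
}

# Undirected weight of {i, j}: mean of the weights of the present directed
# edges, as a symmetric sparse matrix.
undirected_weight_matrix <- function(g) {
  W <- g$W
  S <- W + Matrix::t(W)
  Cnt <- adj(g) + adj_t(g)                      # 1 or 2 orientations present
  Tc <- methods::as(Cnt, "TsparseMatrix")
  i <- Tc@i + 1L
  j <- Tc@j + 1L
  Matrix::sparseMatrix(i = i, j = j, x = S[cbind(i, j)] / Tc@x,
                       dims = dim(W))
}

#' Weighted closure coefficient (undirected)
#'
#' End-node triangle formation for weighted networks with weights in
#' `[0, 1]`:
#' \deqn{E^W(i) = \frac{\sum_j \sum_k w_{ij} w_{ik} w_{jk}}
#'   {\sum_{j \in N(i)} w_{ij} (s_j - w_{ij})},}
#' where `s_j` is the strength of `j`. The graph is treated as undirected;
#' for digraph input the weight of an unordered pair is the mean of its
#' present directed weights. With binary weights this reduces exactly to
#' [local_closure()]. `NA` where the denominator is zero.
#'
#' @param g a weighted, unsigned [digraph] with normalized weights.
#' @return A named numeric vector over all nodes, `NA` where undefined.
#' @export
weighted_closure <- function(g) {
  check_normalized(g)
  if (any(g$weight < 0)) {
    stop("the undirected weighted closure coefficient requires unsigned weights")
  }
  Uw <- undirected_weight_matrix(g)
  s <- Matrix::rowSums(Uw)
  num <- Matrix::rowSums((Uw %*% Uw) * Uw)
  den <- as.numeric(Uw %*% s) - Matrix::rowSums(Uw * Uw)
  stats::setNames(safe_ratio(num, den), g$nodes)
}

#' Weighted (and signed) directed closure coefficient
#'
#' Directed end-node triangle formation with weights:
#' \deqn{E^{W,D}(i) = \frac{\sum_j \sum_k (w_{ij}+w_{ji})(w_{ik}+w_{ki})(w_{jk}+w_{kj})}
#'   {2 \sum_{j \in N(i)} (|w_{ij}|+|w_{ji}|)\,(s_j - (|w_{ij}|+|w_{ji}|))}.}
#' For signed graphs the strength uses absolute weights,
#' `s_j = sum_k |w_jk| + sum_k |w_kj|`, and the denominator factors use the
#' magnitude `|w_ij| + |w_ji|` so that the denominator remains a positive
#' capacity; the coefficient then lies in `[-1, 1]`, negative exactly when
#' negative (distrustful) triangles outweigh positive ones around the focal
#' node. For unsigned graphs the magnitudes are a no-op and the value lies
#' in `[0, 1]`; with binary weights it reduces exactly to
#' [local_directed_closure()]. `NA` where the denominator is zero.
#'
#' @param g a weighted [digraph] with normalized weights (signed allowed).
#' @return A named numeric vector over all nodes, `NA` where undefined.
#' @export
weighted_directed_closure <- function(g) {
  check_normalized(g)
  W <- g$W
  Bw <- W + Matrix::t(W)
  Babs <- abs(W) + Matrix::t(abs(W))
  s <- Matrix::rowSums(Babs)
  num <- Matrix::rowSums((Bw %*% Bw) * Bw)
  den <- 2 * (as.numeric(Babs %*% s) - Matrix::rowSums(Babs * Babs))
  stats::setNames(safe_ratio(num, den), g$nodes)
}

#' Census of nodes with negative weighted directed closure
#'
#' In a signed network a strictly negative weighted directed closure
#' coefficient flags a node around which distrustful (negative) triangles
#' outweigh trustful ones. Balance theory predicts such nodes are rare in
#' trust networks. Undefined coefficients are excluded from the negative
#' count but included in the total.
#'
#' @param g a weighted [digraph] (normalized weights).
#' @return A list with elements `negative` (count of nodes with
#'   `E^{W,D}(i) < 0`) and `total` (node count).
#' @export
negative_closure_census <- function(g) {
  if (!is_weighted(g)) stop("graph has no weights")
  ewd <- weighted_directed_closure(g)
  list(negative = sum(ewd < 0, na.rm = TRUE), total = n_nodes(g))
}
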