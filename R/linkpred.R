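#' Split a graph into an old graph and future edges
#'
#' For temporal graphs, orders edges by timestamp (ties keep input order)
#' and takes the first `floor(fraction * |E|)` edges as the old graph; for
#' non-temporal graphs the old edges are a uniform random sample of the
#' same size (seed the RNG for reproducibility). The old node set `V*` is
#' the set of endpoints of old edges; future edges are the remaining edges
#' whose endpoints both lie in `V*`.
#'
#' @param g a [digraph].
#' @param fraction fraction of edges assigned to the old graph, in (0, 1).
#' @param temporal logical; use the timestamp ordering (requires
#'   timestamps).
#' @return A list with `g_old` (a [digraph] on `V*`) and `e_new` (a data
#'   frame of future edges with columns `from`, `to`).
#' @export
split_old_new <- function(g, fraction = 0.5, temporal = FALSE) {
  if (fraction <= 0 || fraction >= 1) stop("`fraction` must lie in (0, 1)")
  m <- n_edges(g)
  if (m < 2) stop("need at least 2 edges to split")
  n_old <- max(1L, floor(fraction * m))
  if (temporal) {
    if (is.null(g$timestamp)) {
      stop("temporal split requested but the graph has no timestamps")
    }
    sel <- order(g$timestamp)[seq_len(n_old)]
  } else {
    sel <- sample.int(m, n_old)
  }
  sel <- sort(sel)
  old_nodes <- g$nodes[unique(c(g$from[sel], g$to[sel]))]
  g_old <- digraph(g$nodes[g$from[sel]], g$nodes[g$to[sel]],
                   weight = g$weight[sel], timestamp = g$timestamp[sel],
                   nodes = old_nodes, signed = g$signed)
  rest <- setdiff(seq_len(m), sel)
  keep <- g$nodes[g$from[rest]] %in% old_nodes &
    g$nodes[g$to[rest]] %in% old_nodes
  e_new <- data.frame(from = g$nodes[g$from[rest]][keep],
                      to = g$nodes[g$to[rest]][keep],
                      stringsAsFactors = FALSE)
  list(g_old = g_old, e_new = e_new)
}

# index-level scores for ordered pairs (si, ti) on g_old
link_scores_idx <- function(g_old, si, ti, method) {
  A <- adj(g_old)
  switch(
    method,
    DiCN = as.numeric((A %*% A)[cbind(si, ti)]),
    DiAA = {
      du <- Matrix::rowSums(adj_undirected(g_old))
      w <- ifelse(du > 1, 1 / log(du), 0)
      as.numeric((A %*% Matrix::Diagonal(x = w) %*% A)[cbind(si, ti)])
    },
    DiRA = {
      du <- Matrix::rowSums(adj_undirected(g_old))
      w <- ifelse(du > 0, 1 / du, 0)
      as.numeric((A %*% Matrix::Diagonal(x = w) %*% A)[cbind(si, ti)])
    },
    CCI = ,
    ECCI = {
      st <- source_target_closure(g_old)
      e_src <- ifelse(is.na(st$e_src), 0, st$e_src)
      e_tgt <- ifelse(is.na(st$e_tgt), 0, st$e_tgt)
      M <- if (method == "CCI") A %*% A else {
        U <- adj_undirected(g_old)
        U %*% U
      }
      as.numeric(M[cbind(si, ti)]) * (e_src[si] + e_tgt[ti])
    },
    stop("unknown method: ", method)
  )
}

#' Similarity score of an ordered node pair
#'
#' Scores the likelihood of a future edge `s -> t` on the old graph using
#' one of five neighbourhood indices:
#' \describe{
#'   \item{DiCN}{directed common neighbours `|N_out(s) ∩ N_in(t)|`.}
#'   \item{DiAA}{directed Adamic-Adar, common neighbours `u` weighted by
#'     `1 / log |N(u)|` (natural log).}
#'   \item{DiRA}{directed resource allocation, weighted by `1 / |N(u)|`.}
#'   \item{CCI}{closure closeness `DiCN(s,t) * (E_src(s) + E_tgt(t))`.}
#'   \item{ECCI}{extra closure closeness
#'     `|N(s) ∩ N(t)| * (E_src(s) + E_tgt(t))`.}
#' }
#' Undefined source/target closure coefficients contribute 0.
#'
#' @param g_old the old [digraph].
#' @param s,t node identifiers, `s != t` (vectors allowed, recycled
#'   pairwise).
#' @param method one of `"DiCN"`, `"DiAA"`, `"DiRA"`, `"CCI"`, `"ECCI"`.
#' @return A nonnegative numeric vector of scores.
#' @export
score_pair <- function(g_old, s, t, method = c("DiCN", "DiAA", "DiRA", "CCI", "ECCI")) {
  method <- match.arg(method)
  si <- node_index(g_old, s)
  ti <- node_index(g_old, t)
  if (any(si == ti)) stop("self-pairs cannot be scored")
  link_scores_idx(g_old, si, ti, method)
}

#' Candidate ordered pairs for link prediction
#'
#' All ordered node pairs over the graph's node set excluding existing
#' edges and self-pairs (self-loops cannot occur in a simple digraph, so
#' they are never candidates).
#'
#' @param g a non-empty [digraph].
#' @return A data frame with character columns `from`, `to`.
#' @export
candidate_pairs <- function(g) {
  n <- n_nodes(g)
  if (n == 0L) stop("empty graph")
  si <- rep(seq_len(n), each = n)
  ti <- rep(seq_len(n), times = n)
  keep <- si != ti
  si <- si[keep]; ti <- ti[keep]
  existing <- (g$from - 1) * n + g$to
  keep <- !((si - 1) * n + ti) %in% existing
  data.frame(from = g$nodes[si[keep]], to = g$nodes[ti[keep]],
             stringsAsFactors = FALSE)
}

#' Area under the precision-recall curve (average precision)
#'
#' Non-interpolated average precision of a scored, labelled candidate
#' list: candidates are ranked by descending score (ties broken stably by
#' input order) and the precision at each positive's rank is averaged.
#'
#' @param scores numeric scores.
#' @param labels logical (or 0/1) labels; at least one positive required.
#' @return A number in `(0, 1]`.
#' @export
pr_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  if (anyNA(scores) || anyNA(labels)) stop("scores and labels must not contain NA")
  if (!any(labels)) stop("PR-AUC is undefined without positive labels")
  ord <- order(-scores, seq_along(scores))
  lab <- labels[ord]
  prec <- cumsum(lab) / seq_along(lab)
  mean(prec[lab])
}

#' Evaluate link-prediction methods on a network
#'
#' Runs the 50/50 old/new evaluation protocol: split the edges (temporally
#' when timestamps are present and `temporal = TRUE`, otherwise uniformly
#' at random, repeated `repeats` times), score every candidate ordered
#' pair on the old graph with each method, label it by membership in the
#' future edge set, and report the mean PR-AUC per method. For graphs with
#' more than `sample_threshold` nodes, each repetition instead scores the
#' candidate pairs among `sample_size` nodes sampled uniformly (without
#' replacement) from the old graph's non-isolated nodes.
#'
#' @param g a [digraph].
#' @param methods character vector of method names (see [score_pair()]).
#' @param fraction old-graph edge fraction.
#' @param repeats number of random splits (or node samples).
#' @param sample_size nodes to sample on large graphs.
#' @param sample_threshold node count above which sampling kicks in.
#' @param temporal logical; use timestamp ordering for the split.
#' @param seed optional integer seed for reproducibility.
#' @return A data frame with columns `method` and `pr_auc` (mean over
#'   repeats); per-repeat values are attached as attribute
#'   `"per_repeat"` (repeats x methods matrix).
#' @export
evaluate_link_prediction <- function(g,
                                     methods = c("DiCN", "DiAA", "DiRA", "CCI", "ECCI"),
                                     fraction = 0.5, repeats = 10,
                                     sample_size = 3000,
                                     sample_threshold = 10000,
                                     temporal = FALSE, seed = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (repeats < 1) stop("`repeats` must be >= 1")
  sampling <- n_nodes(g) > sample_threshold
  n_rep <- if (temporal && !sampling) 1L else as.integer(repeats)
  local_seed(seed, {
    per <- matrix(NA_real_, n_rep, length(methods),
                  dimnames = list(NULL, methods))
    split_fixed <- if (temporal) split_old_new(g, fraction, temporal = TRUE)
    for (r in seq_len(n_rep)) {
      sp <- if (temporal) split_fixed else split_old_new(g, fraction)
      g_old <- sp$g_old
      n <- n_nodes(g_old)
      if (sampling) {
        deg <- degrees(g_old)
        pool <- which(deg$d > 0)
        nodes_r <- sort(sample(pool, min(sample_size, length(pool))))
      } else {
        nodes_r <- seq_len(n)
      }
      si <- rep(nodes_r, each = length(nodes_r))
      ti <- rep(nodes_r, times = length(nodes_r))
      keep <- si != ti
      si <- si[keep]; ti <- ti[keep]
      existing <- (g_old$from - 1) * n + g_old$to
      key <- (si - 1) * n + ti
      keep <- !key %in% existing
      si <- si[keep]; ti <- ti[keep]; key <- key[keep]
      new_key <- (match(sp$e_new$from, g_old$nodes) - 1) * n +
        match(sp$e_new$to, g_old$nodes)
      labels <- key %in% new_key
      if (!any(labels)) {
        stop("no positive candidate pairs in repetition ", r,
             "; the graph is too small or too dense for this protocol")
      }
      for (mth in methods) {
        per[r, mth] <- pr_auc(link_scores_idx(g_old, si, ti, mth), labels)
      }
    }
    out <- data.frame(method = methods, pr_auc = colMeans(per),
                      stringsAsFactors = FALSE, row.names = NULL)
    attr(out, "per_repeat") <- per
    out
  })
}
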