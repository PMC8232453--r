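#' Brute-force enumeration of directed open triads at a node
#'
#' Exhaustively iterates over ordered node pairs `(j, k)` and counts open
#' triads containing the focal node, decomposing every bidirectional edge
#' into two unidirectional edges. This is the deliberately naive
#' `O(n^2)`-per-node ground truth against which the fast sparse-matrix
#' implementations are verified; it shares no code with them.
#'
#' End-node triads (focal node `i` at one end) are classified by the
#' directions of the `i`-`j` edge and the `j`-`k` edge: `oo` (`i->j`,
#' `j->k`), `oi` (`i->j`, `k->j`), `io` (`j->i`, `j->k`), `ii` (`j->i`,
#' `k->j`). Centre-node triads (focal node in the middle) come in three
#' types: `oo` (two outgoing), `ii` (two incoming), `oi` (one of each).
#'
#' @param g a [digraph].
#' @param i a single node identifier.
#' @return A list of counts: `ote_oo`, `ote_oi`, `ote_io`, `ote_ii`,
#'   `ote_total`, `otc_oo`, `otc_ii`, `otc_oi`, `otc_total`.
#' @seealso [enumerate_triangles()]
#' @export
enumerate_triads <- function(g, i) {
  idx <- node_index(g, i)
  if (length(idx) != 1L) stop("`i` must be a single node")
  A <- as.matrix(adj(g))
  n <- nrow(A)
  ote <- c(oo = 0, oi = 0, io = 0, ii = 0)
  otc_oo2 <- 0; otc_ii2 <- 0; otc_oi <- 0
  others <- setdiff(seq_len(n), idx)
  for (j in others) {
    for (k in others) {
      if (j == k) next
      ote[["oo"]] <- ote[["oo"]] + A[idx, j] * A[j, k]
      ote[["oi"]] <- ote[["oi"]] + A[idx, j] * A[k, j]
      ote[["io"]] <- ote[["io"]] + A[j, idx] * A[j, k]
      ote[["ii"]] <- ote[["ii"]] + A[j, idx] * A[k, j]
      otc_oo2 <- otc_oo2 + A[idx, j] * A[idx, k]
      otc_ii2 <- otc_ii2 + A[j, idx] * A[k, idx]
      otc_oi <- otc_oi + A[idx, j] * A[k, idx]
    }
  }
  list(ote_oo = ote[["oo"]], ote_oi = ote[["oi"]],
       ote_io = ote[["io"]], ote_ii = ote[["ii"]],
       ote_total = sum(ote),
       otc_oo = otc_oo2 / 2, otc_ii = otc_ii2 / 2, otc_oi = otc_oi,
       otc_total = otc_oo2 / 2 + otc_ii2 / 2 + otc_oi)
}

#' Brute-force enumeration of directed triangles at a node
#'
#' Exhaustively counts unidirectional triangle instances containing the
#' focal node `i`, after decomposing bidirectional edges (a triangle with
#' two bidirectional edges counts as four unidirectional triangles, etc.).
#' Each instance is classified first, so composites never carry a pattern
#' of their own.
#'
#' Reported counts:
#' \describe{
#'   \item{t_d}{unidirectional triangle instances containing `i`.}
#'   \item{t_src, t_tgt}{end-node-perspective instance counts split by the
#'     direction of the closing edge (leaving vs entering `i`); a triangle
#'     whose closing edge is bidirectional contributes to both, giving the
#'     identity `t_src + t_tgt = 2 t_d`.}
#'   \item{t_head, t_mid, t_end, t_cyc}{transitive-pattern counts (focal
#'     node at the head, middle or end of the length-2 path, or on a
#'     3-cycle); they partition `t_d`.}
#' }
#'
#' @inheritParams enumerate_triads
#' @return A list of counts: `t_d`, `t_src`, `t_tgt`, `t_head`, `t_mid`,
#'   `t_end`, `t_cyc`.
#' @export
enumerate_triangles <- function(g, i) {
  idx <- node_index(g, i)
  if (length(idx) != 1L) stop("`i` must be a single node")
  A <- as.matrix(adj(g))
  n <- nrow(A)
  t2_d <- 0; t_src <- 0; t_tgt <- 0
  head2 <- 0; mid2 <- 0; end2 <- 0; cyc2 <- 0
  others <- setdiff(seq_len(n), idx)
  for (j in others) {
    for (k in others) {
      if (j == k) next
      bij <- A[idx, j] + A[j, idx]
      bik <- A[idx, k] + A[k, idx]
      bjk <- A[j, k] + A[k, j]
      t2_d <- t2_d + bij * bik * bjk
      t_src <- t_src + bij * bjk * A[idx, k]
      t_tgt <- t_tgt + bij * bjk * A[k, idx]
      head2 <- head2 + A[idx, j] * A[idx, k] * bjk
      end2 <- end2 + A[j, idx] * A[k, idx] * bjk
      mid2 <- mid2 + A[j, idx] * A[idx, k] * A[j, k] +
        A[k, idx] * A[idx, j] * A[k, j]
      cyc2 <- cyc2 + A[j, idx] * A[idx, k] * A[k, j] +
        A[k, idx] * A[idx, j] * A[j, k]
    }
  }
  list(t_d = t2_d / 2, t_src = t_src, t_tgt = t_tgt,
       t_head = head2 / 2, t_mid = mid2 / 2, t_end = end2 / 2,
       t_cyc = cyc2 / 2)
}
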