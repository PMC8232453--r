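# Run `code` under `seed` without disturbing the caller's RNG stream.
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Random directed G(n, p) graph
#'
#' Draws each of the `n (n - 1)` ordered node pairs independently with
#' probability `p` (so reciprocal edges arise by chance at rate `p^2`).
#' This is the null model under which the expected local directed closure
#' coefficient equals `p`. Optionally attaches edge weights: `"uniform01"`
#' draws from `(0, 1]`, `"signed_uniform"` from `[-1, 1]` excluding 0.
#'
#' @param n node count.
#' @param p edge probability in `[0, 1]`.
#' @param weights weight model: `"none"`, `"uniform01"` or
#'   `"signed_uniform"`.
#' @param seed optional integer seed; the caller's RNG state is preserved.
#' @return A [digraph] with nodes `"1" ... "n"` (isolated nodes included).
#' @export
sample_gnp_directed <- function(n, p,
                                weights = c("none", "uniform01", "signed_uniform"),
                                seed = NULL) {
  weights <- match.arg(weights)
  if (n < 0) stop("`n` must be nonnegative")
  if (is.na(p) || p < 0 || p > 1) stop("`p` must lie in [0, 1]")
  signed <- weights == "signed_uniform"
  ids <- as.character(seq_len(n))
  if (n < 2) {
    return(digraph(character(), character(), nodes = ids, signed = signed))
  }
  local_seed(seed, {
    from_all <- rep(seq_len(n), each = n - 1L)
    to_all <- unlist(lapply(seq_len(n), function(i) seq_len(n)[-i]),
                     use.names = FALSE)
    pick <- stats::runif(n * (n - 1L)) < p
    from <- from_all[pick]
    to <- to_all[pick]
    m <- length(from)
    w <- NULL
    if (weights == "uniform01" && m > 0) {
      w <- 1 - stats::runif(m)                     # (0, 1]
    } else if (signed && m > 0) {
      w <- stats::runif(m, -1, 1)
      while (any(w == 0)) w[w == 0] <- stats::runif(sum(w == 0), -1, 1)
    }
    digraph(ids[from], ids[to], weight = w, nodes = ids, signed = signed)
  })
}

#' Canonical 3-node motif fixtures
#'
#' Returns the small digraphs used throughout the documentation and tests:
#' \describe{
#'   \item{FF3}{feed-forward triangle `{1->2, 2->3, 1->3}`.}
#'   \item{CY3}{3-cycle `{1->2, 2->3, 3->1}`.}
#'   \item{BI3}{one bidirectional pair plus a pendant edge
#'     `{1->2, 2->1, 1->3}`.}
#'   \item{tri_xyz}{the eight directed triangle types on nodes 1, 2, 3:
#'     the three letters give the orientation of the 1-2, 2-3 and 1-3
#'     edges (`o` = following node order, `i` = reversed), e.g.
#'     `tri_ooo` is the feed-forward triangle.}
#'   \item{ote_xy}{the four end-node open-triad types with focal node 1:
#'     letters give the 1-2 and 2-3 edge orientations.}
#'   \item{path3, star4}{an undirected-style 2-path and a 3-leaf out-star.}
#' }
#'
#' @return A named list of [digraph] objects.
#' @export
motif_fixtures <- function() {
  eg <- function(...) {
    e <- matrix(c(...), ncol = 2, byrow = TRUE)
    digraph(as.character(e[, 1]), as.character(e[, 2]))
  }
  out <- list(
    FF3 = eg(1, 2, 2, 3, 1, 3),
    CY3 = eg(1, 2, 2, 3, 3, 1),
    BI3 = eg(1, 2, 2, 1, 1, 3),
    ote_oo = eg(1, 2, 2, 3),
    ote_oi = eg(1, 2, 3, 2),
    ote_io = eg(2, 1, 2, 3),
    ote_ii = eg(2, 1, 3, 2),
    path3 = eg(1, 2, 2, 3),
    star4 = eg(1, 2, 1, 3, 1, 4)
  )
  for (d1 in c("o", "i")) {
    for (d2 in c("o", "i")) {
      for (d3 in c("o", "i")) {
        e12 <- if (d1 == "o") c(1, 2) else c(2, 1)
        e23 <- if (d2 == "o") c(2, 3) else c(3, 2)
        e13 <- if (d3 == "o") c(1, 3) else c(3, 1)
        out[[paste0("tri_", d1, d2, d3)]] <- eg(e12, e23, e13)
      }
    }
  }
  out
}
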