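#' Construct a simple directed graph
#'
#' Builds a simple digraph (no self-loops, no duplicate ordered pairs) from
#' parallel vectors of edge endpoints, with optional edge weights and
#' timestamps. Node identifiers are treated as opaque strings; no assumption
#' of integer-contiguity is made.
#'
#' Self-loops are dropped (with a message reporting the count), since every
#' coefficient implemented here assumes their absence. Duplicate ordered
#' pairs collapse to a single edge; for weighted graphs the last weight in
#' input order wins. Zero-weight edges are dropped: they are
#' indistinguishable from absent edges in every weighted formula.
#'
#' @param from,to vectors of node identifiers (coerced to character).
#' @param weight optional numeric edge weights; may be signed when
#'   `signed = TRUE`.
#' @param timestamp optional numeric edge timestamps.
#' @param nodes optional character vector of node identifiers; defaults to
#'   nodes appearing in `from`/`to`, in order of first appearance. Extra
#'   entries create isolated nodes.
#' @param signed logical; allow negative weights.
#' @return An object of class `digraph`.
#' @examples
#' g <- digraph(c("1", "2", "1"), c("2", "3", "3"))  # feed-forward triangle
#' g
#' @export
digraph <- function(from, to, weight = NULL, timestamp = NULL, nodes = NULL,
                    signed = FALSE) {
  from <- as.character(from)
  to <- as.character(to)
  if (length(from) != length(to)) {
    stop("`from` and `to` must have the same length")
  }
  m <- length(from)
  if (!is.null(weight)) {
    weight <- as.numeric(weight)
    if (length(weight) != m) stop("`weight` must match the number of edges")
    if (anyNA(weight)) stop("weights must not contain NA")
    if (!signed && any(weight < 0)) {
      stop("negative weight in an unsigned graph; use `signed = TRUE`")
    }
  }
  if (!is.null(timestamp)) {
    timestamp <- as.numeric(timestamp)
    if (length(timestamp) != m) stop("`timestamp` must match the number of edges")
  }

  loops <- from == to
  if (any(loops)) {
    message(sum(loops), " self-loop(s) dropped")
    from <- from[!loops]; to <- to[!loops]
    weight <- weight[!loops]; timestamp <- timestamp[!loops]
  }
  if (!is.null(weight)) {
    zero <- weight == 0
    if (any(zero)) {
      message(sum(zero), " zero-weight edge(s) dropped")
      from <- from[!zero]; to <- to[!zero]
      weight <- weight[!zero]; timestamp <- timestamp[!zero]
    }
  }
  key <- paste(from, to, sep = "\r")
  if (anyDuplicated(key)) {
    message(sum(duplicated(key)), " duplicate edge(s) collapsed (last kept)")
    keep <- !duplicated(key, fromLast = TRUE)
    # preserve first-occurrence order of the surviving edges
    keep_idx <- sort(which(keep))
    from <- from[keep_idx]; to <- to[keep_idx]
    weight <- weight[keep_idx]; timestamp <- timestamp[keep_idx]
  }

  if (is.null(nodes)) {
    nodes <- unique(c(rbind(from, to)))
  } else {
    nodes <- unique(as.character(nodes))
    missing <- setdiff(unique(c(from, to)), nodes)
    if (length(missing)) {
      stop("edge endpoints not in `nodes`: ", paste(missing, collapse = ", "))
    }
  }
  n <- length(nodes)
  fi <- match(from, nodes)
  ti <- match(to, nodes)

  A <- Matrix::sparseMatrix(i = fi, j = ti, x = rep(1, length(fi)),
                            dims = c(n, n))
  W <- NULL
  if (!is.null(weight)) {
    W <- Matrix::sparseMatrix(i = fi, j = ti, x = weight, dims = c(n, n))
  }

  structure(
    list(nodes = nodes, from = fi, to = ti,
         weight = weight, timestamp = timestamp,
         signed = isTRUE(signed), A = A, W = W),
    class = "digraph"
  )
}

#' @exportS3Method base::print
print.digraph <- function(x, ...) {
  cat(sprintf("digraph: %d nodes, %d edges%s%s%s\n",
              length(x$nodes), length(x$from),
              if (!is.null(x$weight)) ", weighted" else "",
              if (x$signed) " (signed)" else "",
              if (!is.null(x$timestamp)) ", timestamped" else ""))
  invisible(x)
}

n_nodes <- function(g) length(g$nodes)
n_edges <- function(g) length(g$from)

is_weighted <- function(g) !is.null(g$weight)

node_index <- function(g, i) {
  idx <- match(as.character(i), g$nodes)
  if (anyNA(idx)) stop("unknown node: ", paste(as.character(i)[is.na(idx)], collapse = ", "))
  idx
}

# Adjacency helpers (sparse, 0/1 pattern stored as numeric)
adj <- function(g) g$A
adj_t <- function(g) Matrix::t(g$A)
# b_ij = a_ij + a_ji
adj_both <- function(g) g$A + Matrix::t(g$A)
# undirected 0/1 projection: edge present if either orientation exists
adj_undirected <- function(g) {
  B <- adj_both(g)
  B@x <- rep(1, length(B@x))
  B
}

#' Read a directed graph from a plain-text edge list
#'
#' Parses files of the form `src dst [weight] [timestamp]`, one edge per
#' line. Lines starting with `#` or `%` and blank lines are skipped
#' (covering the common dialects of public network repositories).
#'
#' @param path path to the edge-list file.
#' @param delimiter field separator; `NULL` (default) splits on any
#'   whitespace run.
#' @param weighted,timestamped logical; expect a weight (3rd) and/or
#'   timestamp (4th, or 3rd if unweighted) field.
#' @param signed logical; allow negative weights.
#' @return A [digraph].
#' @seealso [write_edgelist()]
#' @export
read_edgelist <- function(path, delimiter = NULL, weighted = FALSE,
                          timestamped = FALSE, signed = FALSE) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*($|#|%)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("no edges in file: ", path)
  if (is.null(delimiter)) {
    fields <- strsplit(trimws(lines), "\\s+")
  } else {
    fields <- strsplit(lines, delimiter, fixed = TRUE)
    fields <- lapply(fields, trimws)
  }
  need <- 2L + as.integer(weighted) + as.integer(timestamped)
  nf <- lengths(fields)
  bad <- which(nf < need)
  if (length(bad)) {
    stop(sprintf("malformed line %d in %s: expected >= %d fields, got %d",
                 lineno[bad[1]], path, need, nf[bad[1]]))
  }
  from <- vapply(fields, `[[`, "", 1L)
  to <- vapply(fields, `[[`, "", 2L)
  weight <- NULL
  timestamp <- NULL
  col <- 3L
  if (weighted) {
    weight <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", col)))
    if (anyNA(weight)) {
      stop(sprintf("malformed line %d in %s: unparseable weight",
                   lineno[which(is.na(weight))[1]], path))
    }
    col <- col + 1L
  }
  if (timestamped) {
    timestamp <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", col)))
    if (anyNA(timestamp)) {
      stop(sprintf("malformed line %d in %s: unparseable timestamp",
                   lineno[which(is.na(timestamp))[1]], path))
    }
  }
  digraph(from, to, weight = weight, timestamp = timestamp, signed = signed)
}

#' Write a directed graph as a plain-text edge list
#'
#' Inverse of [read_edgelist()]: writes `src dst [weight] [timestamp]`,
#' one edge per line, in stored edge order.
#'
#' @param g a [digraph].
#' @param path output file path.
#' @param delimiter field separator (default single space).
#' @export
write_edgelist <- function(g, path, delimiter = " ") {
  cols <- list(g$nodes[g$from], g$nodes[g$to])
  if (!is.null(g$weight)) cols <- c(cols, list(format(g$weight, trim = TRUE, digits = 15)))
  if (!is.null(g$timestamp)) cols <- c(cols, list(format(g$timestamp, trim = TRUE, digits = 15)))
  writeLines(do.call(paste, c(cols, sep = delimiter)), path)
  invisible(path)
}

#' Node degrees, bidirectional degree and strength
#'
#' For each node reports the out-degree, in-degree, total degree
#' `d = d_out + d_in`, the bidirectional degree `d_bi` (number of mutual
#' neighbour pairs), and the strength `s`. For weighted graphs the strength
#' is the sum of absolute weights on incident edges, both directions (for
#' unsigned graphs the absolute value is a no-op); for unweighted graphs
#' `s = d`.
#'
#' @param g a [digraph].
#' @param v optional node identifiers to restrict to.
#' @return A data frame with columns `node`, `d_out`, `d_in`, `d`, `d_bi`, `s`.
#' @export
degrees <- function(g, v = NULL) {
  A <- adj(g)
  d_out <- Matrix::rowSums(A)
  d_in <- Matrix::colSums(A)
  d_bi <- Matrix::rowSums(A * Matrix::t(A))
  if (is_weighted(g)) {
    Wabs <- abs(g$W)
    s <- Matrix::rowSums(Wabs) + Matrix::colSums(Wabs)
  } else {
    s <- d_out + d_in
  }
  out <- data.frame(node = g$nodes, d_out = d_out, d_in = d_in,
                    d = d_out + d_in, d_bi = d_bi, s = s,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(v)) out <- out[node_index(g, v), , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Neighbour sets of a node
#'
#' Returns the out-neighbour set (successors), in-neighbour set
#' (predecessors) and their union for a single node. The focal node is
#' never its own neighbour.
#'
#' @param g a [digraph].
#' @param i a node identifier.
#' @return A list with character vectors `out`, `in` and `all`.
#' @export
node_neighbors <- function(g, i) {
  idx <- node_index(g, i)
  if (length(idx) != 1L) stop("`i` must be a single node")
  out <- g$to[g$from == idx]
  inn <- g$from[g$to == idx]
  list(out = g$nodes[sort(unique(out))],
       "in" = g$nodes[sort(unique(inn))],
       all = g$nodes[sort(unique(c(out, inn)))])
}

#' Edge reciprocity
#'
#' Fraction of directed edges `(i, j)` whose reverse `(j, i)` is also an
#' edge. A fully symmetrized graph has reciprocity 1.
#'
#' @param g a [digraph] with at least one edge.
#' @return A number in `[0, 1]`.
#' @export
reciprocity <- function(g) {
  if (n_edges(g) == 0L) stop("reciprocity is undefined on an empty edge set")
  A <- adj(g)
  sum(A * Matrix::t(A)) / n_edges(g)
}

#' Average degree
#'
#' Returns `|E| / |V|`, i.e. edges per node. Note this is the directed-edge
#' convention (not `2|E|/|V|`): each directed edge is counted once.
#'
#' @param g a non-empty [digraph].
#' @return A number.
#' @export
average_degree <- function(g) {
  if (n_nodes(g) == 0L) stop("average degree is undefined on an empty graph")
  n_edges(g) / n_nodes(g)
}
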