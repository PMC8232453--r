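# Shared fixtures and independent mini-oracles for the test suite.

motifs <- motif_fixtures()

# quiet constructor for ad-hoc edge lists given as a matrix-like vector
quick_graph <- function(..., weight = NULL, signed = FALSE, nodes = NULL) {
  e <- matrix(c(...), ncol = 2, byrow = TRUE)
  suppressMessages(digraph(as.character(e[, 1]), as.character(e[, 2]),
                           weight = weight, signed = signed, nodes = nodes))
}

# add every reverse edge (collapsing duplicates quietly)
symmetrize <- function(g) {
  suppressMessages(digraph(
    c(g$nodes[g$from], g$nodes[g$to]),
    c(g$nodes[g$to], g$nodes[g$from]),
    nodes = g$nodes
  ))
}

# Independent undirected triangle/triad oracle: dense-matrix loops built
# straight from the edge vectors, sharing nothing with the package's
# sparse fast path.
undirected_oracle <- function(g) {
  n <- length(g$nodes)
  M <- matrix(0L, n, n)
  M[cbind(g$from, g$to)] <- 1L
  M <- pmin(M + t(M), 1L)
  d <- rowSums(M)
  t_cnt <- numeric(n)
  ote <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(M[i, ] == 1)
    if (length(nb) >= 2) t_cnt[i] <- sum(M[nb, nb, drop = FALSE]) / 2
    ote[i] <- sum(d[nb] - 1)
  }
  list(t = t_cnt, d = d, ote = ote)
}

# Full per-node coefficient table derived only from the brute-force
# enumeration oracles, mirroring every ratio the fast path computes.
oracle_coefficients <- function(g) {
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  rows <- lapply(g$nodes, function(v) {
    tr <- enumerate_triangles(g, v)
    td <- enumerate_triads(g, v)
    data.frame(
      node = v,
      c_d = ratio(tr$t_d, 2 * td$otc_total),
      e_d = ratio(2 * tr$t_d, 2 * td$ote_total),
      e_src = ratio(tr$t_src, td$ote_total),
      e_tgt = ratio(tr$t_tgt, td$ote_total),
      c_head = ratio(tr$t_head, 2 * td$otc_oo),
      c_mid = ratio(tr$t_mid, td$otc_oi),
      c_end = ratio(tr$t_end, 2 * td$otc_ii),
      c_cyc = ratio(tr$t_cyc, td$otc_oi),
      e_head = ratio(2 * tr$t_head, td$ote_oo + td$ote_oi),
      e_mid = ratio(2 * tr$t_mid, td$ote_oi + td$ote_io),
      e_end = ratio(2 * tr$t_end, td$ote_io + td$ote_ii),
      e_cyc = ratio(2 * tr$t_cyc, td$ote_oo + td$ote_ii),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
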