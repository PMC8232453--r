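# Shared fast-path machinery for the clustering and closure coefficients.
#
# Every numerator/denominator below is an integer count obtained from sparse
# 0/1 adjacency products; division happens once, at the end, so fast values
# agree exactly with the brute-force oracle ratios. Notation: A is the
# adjacency matrix, B = A + t(A) holds bidirectional multiplicities
# (b_ij in {0,1,2}), U is the 0/1 undirected projection.

safe_ratio <- function(num, den) {
  out <- rep(NA_real_, length(num))
  ok <- den > 0
  out[ok] <- num[ok] / den[ok]
  out
}

# Per-node directed triangle/triad counts, all nodes at once.
# Cost is driven by the sparse products A %*% B etc., i.e. sum_j d_j^2 —
# the O(|V| * kbar^2) neighbourhood-iteration budget.
directed_counts <- function(g) {
  A <- adj(g)
  At <- Matrix::t(A)
  B <- A + At
  d_out <- Matrix::rowSums(A)
  d_in <- Matrix::colSums(A)
  d <- d_out + d_in
  d_bi <- Matrix::rowSums(A * At)

  BB <- B %*% B
  AB <- A %*% B
  AtB <- At %*% B
  AAt <- A %*% At
  AA <- A %*% A

  num_t2d <- Matrix::rowSums(BB * B)        # sum_jk b_ij b_ik b_jk = 2 T^D(i)
  num_src <- Matrix::rowSums(BB * A)        # T^src(i)
  num_tgt <- Matrix::rowSums(BB * At)       # T^tgt(i)
  num_head <- Matrix::rowSums(AB * A)       # 2 T^head(i)
  num_end <- Matrix::rowSums(AtB * At)      # 2 T^end(i)
  num_mid <- 2 * Matrix::rowSums(At * AAt)  # 2 T^mid(i)
  num_cyc <- 2 * Matrix::rowSums(At * AA)   # 2 T^cyc(i)

  # open-triad denominators
  ote_d <- as.numeric(B %*% d) - Matrix::rowSums(B * B)        # OTE^D(i)
  ote_head <- as.numeric(A %*% d) - Matrix::rowSums(A * B)     # OTE^>> + OTE^><
  ote_end <- as.numeric(At %*% d) - Matrix::rowSums(At * B)    # OTE^<< + OTE^<>
  ote_mid <- as.numeric(A %*% d_in) - d_out +
    as.numeric(At %*% d_out) - d_in                            # OTE^>< + OTE^<>
  ote_cyc <- as.numeric(At %*% d_in) + as.numeric(A %*% d_out) -
    2 * d_bi                                                   # OTE^>> + OTE^<<
  otc_d2 <- d * (d - 1) - 2 * d_bi                             # 2 OTC^D(i)
  otc_oo <- d_out * (d_out - 1) / 2                            # OTC^->->
  otc_ii <- d_in * (d_in - 1) / 2                              # OTC^<-<-
  otc_oi <- d_in * d_out - d_bi                                # OTC^-><-

  list(d_out = d_out, d_in = d_in, d = d, d_bi = d_bi,
       num_t2d = num_t2d, num_src = num_src, num_tgt = num_tgt,
       num_head = num_head, num_mid = num_mid, num_end = num_end,
       num_cyc = num_cyc,
       ote_d = ote_d, ote_head = ote_head, ote_mid = ote_mid,
       ote_end = ote_end, ote_cyc = ote_cyc,
       otc_d2 = otc_d2, otc_oo = otc_oo, otc_ii = otc_ii, otc_oi = otc_oi)
}

# Per-node undirected counts on the 0/1 projection.
undirected_counts <- function(g) {
  U <- adj_undirected(g)
  du <- Matrix::rowSums(U)
  num_2t <- Matrix::rowSums((U %*% U) * U)          # 2 T(i)
  ote_u <- as.numeric(U %*% du) - du                # sum_{j in N(i)} (d_j - 1)
  list(du = du, num_2t = num_2t, ote_u = ote_u)
}

# Work measure of the per-node neighbourhood iteration: the number of
# (neighbour, neighbour-of-neighbour) probes sum_i sum_{j in N(i)} d_j.
# Used for coarse empirical scaling checks.
triangle_work <- function(g) {
  U <- adj_undirected(g)
  du <- Matrix::rowSums(U)
  sum(as.numeric(U %*% du))
}
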