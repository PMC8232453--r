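test_that("undirected closure matches hand-worked values and its loop oracle", {
  tri <- motifs$FF3
  expect_equal(unname(local_closure(tri)), c(1, 1, 1))
  expect_equal(unname(local_closure(motifs$path3))[1], 0)

  # square 1-2-3-4-1 with chord 1-3: node 4 closes 1 of 4 end-node triads
  sq <- quick_graph(1, 2, 2, 3, 3, 4, 4, 1, 1, 3)
  expect_equal(unname(local_closure(sq))["4" == sq$nodes], 0.5)

  for (seed in 1:10) {
    g <- sample_gnp_directed(20, 0.2, seed = 600 + seed)
    orc <- undirected_oracle(g)
    expected <- ifelse(orc$ote > 0, 2 * orc$t / orc$ote, NA_real_)
    expect_equal(unname(local_closure(g)), expected)
  }
})

test_that("global closure equals global clustering on any network", {
  gp <- quick_graph(1, 2, 1, 3, 2, 3, 1, 4)
  expect_equal(global_closure(gp), 0.6)
  expect_equal(global_closure(gp), global_clustering(gp))
  for (seed in 1:10) {
    g <- sample_gnp_directed(25, 0.15, seed = 700 + seed)
    expect_equal(global_closure(g), global_clustering(g), tolerance = 1e-12)
  }
})

test_that("directed closure reproduces hand-worked motif values", {
  expect_equal(unname(local_directed_closure(motifs$FF3)), c(0.5, 0.5, 0.5))
  expect_equal(unname(local_directed_closure(motifs$CY3)), c(0.5, 0.5, 0.5))
  expect_equal(unname(local_directed_closure(symmetrize(motifs$FF3))), c(1, 1, 1))
  # hub whose neighbours connect only to it: undefined; leaves see open triads
  expect_equal(unname(local_directed_closure(motifs$star4)), c(NA, 0, 0, 0))

  st <- source_target_closure(motifs$FF3)
  expect_equal(st$e_src, c(1, 0.5, 0))
  expect_equal(st$e_tgt, c(0, 0.5, 1))
  st <- source_target_closure(motifs$CY3)
  expect_equal(st$e_src, c(0.5, 0.5, 0.5))
  expect_equal(st$e_tgt, c(0.5, 0.5, 0.5))

  p <- closure_patterns(motifs$FF3)
  expect_equal(p$e_head[1], 1)
  expect_equal(p$e_mid[2], 1)
  expect_equal(p$e_end[3], 1)
  expect_true(is.na(p$e_end[1]))
  expect_equal(p$e_cyc[1], 0)
  p <- closure_patterns(motifs$CY3)
  expect_equal(p$e_cyc, c(1, 1, 1))
  expect_equal(p$e_head, c(0, 0, 0))
})

test_that("average directed closure follows the undefined-as-zero convention", {
  expect_equal(average_directed_closure(motifs$FF3), 0.5)
  g <- quick_graph(1, 2, 2, 3, 1, 3, nodes = c("1", "2", "3", "iso"))
  expect_equal(average_directed_closure(g), 0.375)
})

test_that("source/target closure sums to twice the directed closure wherever defined", {
  for (seed in 1:20) {
    g <- sample_gnp_directed(sample(10:30, 1), sample(c(0.05, 0.2, 0.5), 1),
                             seed = 800 + seed)
    st <- source_target_closure(g)
    ed <- unname(local_directed_closure(g))
    ok <- !is.na(ed)
    expect_equal(st$e_src[ok] + st$e_tgt[ok], 2 * ed[ok], tolerance = 1e-15)
    expect_true(all(st$e_src[ok] >= 0 & st$e_src[ok] <= 1))
    expect_true(all(st$e_tgt[ok] >= 0 & st$e_tgt[ok] <= 1))
  }
})

test_that("pattern numerators and open-triad types partition the directed totals", {
  for (seed in 1:10) {
    g <- sample_gnp_directed(15, 0.3, seed = 900 + seed)
    for (v in g$nodes) {
      td <- enumerate_triads(g, v)
      tr <- enumerate_triangles(g, v)
      # OTE type partition: head+end groups and mid+cyc groups both cover OTE^D
      expect_equal((td$ote_oo + td$ote_oi) + (td$ote_io + td$ote_ii),
                   td$ote_total)
      expect_equal((td$ote_oi + td$ote_io) + (td$ote_oo + td$ote_ii),
                   td$ote_total)
      expect_equal(tr$t_head + tr$t_mid + tr$t_end + tr$t_cyc, tr$t_d)
    }
  }
})

test_that("fast closure values equal brute-force oracle ratios", {
  for (seed in 1:20) {
    g <- sample_gnp_directed(sample(8:20, 1), sample(c(0.1, 0.3), 1),
                             seed = 1000 + seed)
    orc <- oracle_coefficients(g)
    prof <- closure_profile(g)
    for (col in c("e_d", "e_src", "e_tgt", "e_head", "e_mid", "e_end", "e_cyc")) {
      expect_identical(prof[[col]], orc[[col]])
    }
  }
})

test_that("directed closure of a symmetric digraph equals undirected closure", {
  for (seed in 1:5) {
    gs <- symmetrize(sample_gnp_directed(20, 0.2, seed = 1100 + seed))
    expect_equal(local_directed_closure(gs), local_closure(gs))
  }
})

test_that("global directed closure equals global directed clustering (many random graphs)", {
  expect_equal(global_directed_closure(motifs$FF3), 0.5)
  expect_equal(global_directed_closure(motifs$CY3), 0.5)
  for (seed in 1:100) {
    g <- sample_gnp_directed(30, 0.2, seed = 1200 + seed)
    expect_equal(global_directed_closure(g), global_directed_clustering(g),
                 tolerance = 1e-15)
  }
})

test_that("mean directed closure on G(n, p) tracks p and work scales with density", {
  # coarse sanity check; the calibrated 3-standard-error version of this
  # claim lives in the acceptance suite
  g <- sample_gnp_directed(300, 0.1, seed = 1400)
  v <- unname(local_directed_closure(g))
  v[is.na(v)] <- 0
  expect_lt(abs(mean(v) - 0.1), 0.01)
  # doubling p roughly quadruples the neighbourhood-iteration work
  w1 <- netclosure:::triangle_work(sample_gnp_directed(200, 0.1, seed = 1))
  w2 <- netclosure:::triangle_work(sample_gnp_directed(200, 0.2, seed = 2))
  expect_gt(w2 / w1, 2.5)
  expect_lt(w2 / w1, 6)
})
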