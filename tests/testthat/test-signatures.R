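# builds a toy labelled signature table: `sep` controls how far apart the
# two class centroids sit in the closure-pattern features
toy_signatures <- function(n_per_class = 5, sep = 1, seed = 1) {
  withr::with_seed(seed, {
    base <- expand.grid(cls = c("foodweb", "word"), k = seq_len(n_per_class))
    feats <- c("c_head", "c_mid", "c_end", "c_cyc",
               "e_head", "e_mid", "e_end", "e_cyc")
    X <- matrix(runif(nrow(base) * 8, 0, 0.1), ncol = 8,
                dimnames = list(NULL, feats))
    X[base$cls == "foodweb", c("e_head", "e_mid")] <-
      X[base$cls == "foodweb", c("e_head", "e_mid")] + sep * 0.5
    data.frame(name = paste0("net", seq_len(nrow(base))),
               class_label = as.character(base$cls), X,
               stringsAsFactors = FALSE)
  })
}

test_that("network signatures average the node profiles with undefined as zero", {
  sig <- network_signature(motifs$FF3, "ff3", "toy")
  expect_equal(sig$n_nodes, 3)
  expect_equal(sig$n_edges, 3)
  expect_equal(sig$avg_degree, 1)
  expect_equal(sig$reciprocity, 0)
  expect_equal(sig$avg_c_d, 0.5)
  expect_equal(sig$avg_e_d, 0.5)
  expect_equal(unlist(sig[c("e_head", "e_mid", "e_end", "e_cyc")]),
               c(e_head = 1 / 3, e_mid = 1 / 3, e_end = 1 / 3, e_cyc = 0))
  expect_equal(unlist(sig[c("c_head", "c_mid", "c_end", "c_cyc")]),
               c(c_head = 1 / 6, c_mid = 1 / 3, c_end = 1 / 6, c_cyc = 0))

  sig <- network_signature(motifs$CY3, "cy3")
  expect_equal(sig$e_cyc, 1)
  expect_equal(sig$c_cyc, 1)
  expect_equal(sig$e_head + sig$e_mid + sig$e_end, 0)

  # averaged coefficients always stay in [0, 1]
  g <- sample_gnp_directed(40, 0.15, seed = 1800)
  sig <- network_signature(g)
  vals <- unlist(sig[c("avg_c_d", "avg_e_d", "c_head", "c_mid", "c_end",
                       "c_cyc", "e_head", "e_mid", "e_end", "e_cyc")])
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("feature standardization removes the mean and scales to unit variance", {
  expect_equal(unname(standardize_features(cbind(x = c(0, 2)))[, 1]), c(-1, 1))
  m <- cbind(a = c(1, 5, 9, 2), b = c(0, 1, 0, 1))
  z <- standardize_features(m)
  expect_equal(colMeans(z), c(a = 0, b = 0))
  expect_equal(apply(z, 2, function(x) mean(x^2)), c(a = 1, b = 1))
  expect_equal(standardize_features(z), z)
  expect_warning(z2 <- standardize_features(cbind(k = c(3, 3, 3))), "constant")
  expect_equal(unname(z2[, 1]), c(0, 0, 0))
  expect_error(standardize_features(cbind(1)), "two rows")
})

test_that("pearson correlation matches closed-form values", {
  expect_equal(pearson(1:5, 1:5), 1)
  expect_equal(pearson(1:5, -(1:5)), -1)
  expect_equal(pearson(c(1, 2, 3), c(1, 2, 4)), 1.5 / sqrt(7 / 3) / 1,
               tolerance = 1e-10)
  expect_equal(round(pearson(c(1, 2, 3), c(1, 2, 4)), 4), 0.982)
  expect_error(pearson(1:3, 1:4), "length")
  expect_error(pearson(c(1, 1, 1), 1:3), "zero-variance")
})

test_that("leave-one-out classification separates well-separated classes", {
  sigs <- toy_signatures(sep = 1)
  for (model in c("tree", "forest", "boosted")) {
    acc <- loocv_classify(sigs, features = "closure", model = model,
                          repeats = 2, seed = 5)
    expect_equal(acc, 1, info = model)
  }
  # identical runs under the same seed agree
  a <- loocv_classify(sigs, features = "both", model = "forest",
                      repeats = 2, seed = 9)
  b <- loocv_classify(sigs, features = "both", model = "forest",
                      repeats = 2, seed = 9)
  expect_identical(a, b)
})

test_that("permuted labels bring accuracy down to chance levels", {
  sigs <- toy_signatures(n_per_class = 10, sep = 0, seed = 3)
  acc <- loocv_classify(sigs, features = "both", model = "tree",
                        repeats = 1, seed = 2)
  expect_lt(acc, 0.85)
  expect_gte(acc, 0)
})

test_that("classification inputs are validated", {
  sigs <- toy_signatures()
  sigs$class_label[1] <- "lonely"
  expect_error(loocv_classify(sigs, model = "tree", repeats = 1),
               "at least two")
  expect_error(loocv_classify(toy_signatures()[, -3], features = "both",
                              model = "tree", repeats = 1),
               "feature column")
})

test_that("impurity importances are normalised and find a planted feature", {
  sigs <- toy_signatures(sep = 2, seed = 4)
  # make e_mid the single perfectly separating feature
  sigs$e_head <- withr::with_seed(8, runif(nrow(sigs)))
  for (model in c("tree", "forest", "boosted")) {
    imp <- feature_importance(sigs, features = "closure", model = model,
                              repeats = 3, seed = 6)
    expect_equal(sum(imp), 1, tolerance = 1e-9)
    expect_true(all(imp >= 0))
    expect_gt(imp[["e_mid"]], 0.4)
  }
})
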