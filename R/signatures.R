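sig_feature_sets <- list(
  clustering = c("c_head", "c_mid", "c_end", "c_cyc"),
  closure = c("e_head", "e_mid", "e_end", "e_cyc"),
  both = c("c_head", "c_mid", "c_end", "c_cyc",
           "e_head", "e_mid", "e_end", "e_cyc")
)

#' Network-level signature of a directed graph
#'
#' Summarises a digraph as one row of statistics: node and edge counts,
#' average degree (`|E|/|V|`), reciprocity, the average directed clustering
#' and closure coefficients, and the node-averaged four clustering patterns
#' and four closure patterns (undefined node values count as zero
#' throughout, per the averaging convention). The eight pattern averages
#' are the feature vector used for network classification.
#'
#' @param g a [digraph] with at least one edge.
#' @param name label for the network.
#' @param class_label optional class (e.g. `"trust"`, `"foodweb"`) used by
#'   the classification harness.
#' @return A one-row data frame.
#' @export
network_signature <- function(g, name = "network", class_label = NA_character_) {
  if (n_edges(g) == 0L) stop("signature requires a non-empty graph")
  cp <- clustering_patterns(g)
  ep <- closure_patterns(g)
  data.frame(
    name = name, class_label = as.character(class_label),
    n_nodes = n_nodes(g), n_edges = n_edges(g),
    avg_degree = average_degree(g), reciprocity = reciprocity(g),
    avg_c_d = average_coefficient(local_directed_clustering(g)),
    avg_e_d = average_directed_closure(g),
    c_head = average_coefficient(cp$c_head),
    c_mid = average_coefficient(cp$c_mid),
    c_end = average_coefficient(cp$c_end),
    c_cyc = average_coefficient(cp$c_cyc),
    e_head = average_coefficient(ep$e_head),
    e_mid = average_coefficient(ep$e_mid),
    e_end = average_coefficient(ep$e_end),
    e_cyc = average_coefficient(ep$e_cyc),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Standardize signature features
#'
#' Centres each feature column to zero mean and scales it to unit variance
#' (population standard deviation, i.e. dividing by `sqrt(mean((x - mean(x))^2))`,
#' so a two-point column `{0, 2}` maps to `{-1, +1}`). Constant columns are
#' mapped to zero with a warning.
#'
#' @param m a numeric matrix or data frame of signatures (rows) by
#'   features (columns), at least two rows.
#' @return A numeric matrix of the same shape.
#' @export
standardize_features <- function(m) {
  m <- as.matrix(m)
  if (!is.numeric(m)) stop("features must be numeric")
  if (nrow(m) < 2) stop("standardization needs at least two rows")
  out <- apply(m, 2, function(x) {
    s <- sqrt(mean((x - mean(x))^2))
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  })
  if (any(apply(m, 2, function(x) length(unique(x)) == 1))) {
    warning("constant feature column(s) mapped to 0")
  }
  dimnames(out) <- dimnames(m)
  out
}

#' Pearson correlation coefficient
#'
#' Sample Pearson correlation between two equal-length vectors, with
#' explicit checks that both have positive variance.
#'
#' @param x,y numeric vectors of equal length (>= 2).
#' @return A number in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` differ in length")
  if (length(x) < 2) stop("need at least two observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation is undefined for zero-variance input")
  }
  stats::cor(x, y)
}

fit_and_predict <- function(X, y, train, test, model) {
  switch(
    model,
    tree = {
      d <- data.frame(.y = y[train], X[train, , drop = FALSE],
                      check.names = FALSE)
      fit <- rpart::rpart(
        .y ~ ., data = d, method = "class",
        control = rpart::rpart.control(minsplit = 2, minbucket = 1,
                                       cp = 0, xval = 0))
      nd <- data.frame(X[test, , drop = FALSE], check.names = FALSE)
      as.character(predict(fit, nd, type = "class"))
    },
    forest = {
      fit <- randomForest::randomForest(X[train, , drop = FALSE],
                                        droplevels(y[train]), ntree = 300)
      as.character(predict(fit, X[test, , drop = FALSE]))
    },
    boosted = {
      fit <- xgboost::xgboost(x = X[train, , drop = FALSE], y = y[train],
                              nrounds = 30, max_depth = 3,
                              learning_rate = 0.3, min_child_weight = 0,
                              tree_method = "exact", nthreads = 1,
                              verbosity = 0)
      as.character(predict(fit, X[test, , drop = FALSE], type = "class"))
    },
    stop("unknown model: ", model)
  )
}

check_signature_table <- function(signatures, features) {
  cols <- sig_feature_sets[[match.arg(features, names(sig_feature_sets))]]
  missing <- setdiff(cols, names(signatures))
  if (length(missing)) {
    stop("signature table lacks feature column(s): ",
         paste(missing, collapse = ", "))
  }
  if (!"class_label" %in% names(signatures) ||
      anyNA(signatures$class_label)) {
    stop("signature table needs a complete `class_label` column")
  }
  X <- as.matrix(signatures[, cols, drop = FALSE])
  storage.mode(X) <- "double"
  y <- factor(signatures$class_label)
  if (any(table(y) < 2)) {
    stop("every class needs at least two networks for leave-one-out evaluation")
  }
  list(X = X, y = y)
}

#' Leave-one-out classification accuracy of network signatures
#'
#' Classifies network types from their averaged pattern features using a
#' tree-based model under leave-one-out cross-validation: each network is
#' predicted by a model trained on all others, and accuracy is the
#' fraction predicted correctly. Because tree ensembles are stochastic,
#' the procedure is repeated and the mean accuracy reported.
#'
#' @param signatures a data frame of [network_signature()] rows with a
#'   complete `class_label` column; every class needs >= 2 members.
#' @param features feature set: `"clustering"` (four clustering patterns),
#'   `"closure"` (four closure patterns) or `"both"`.
#' @param model `"tree"` (CART via rpart, grown with `minsplit = 2`,
#'   `minbucket = 1`, `cp = 0` so that small signature tables can split),
#'   `"forest"` (random forest) or `"boosted"` (gradient boosted trees,
#'   grown with exact mid-gap splits and `min_child_weight = 0` for the
#'   same small-sample reason).
#' @param repeats repetitions to average over.
#' @param seed optional integer seed.
#' @return Mean accuracy in `[0, 1]`.
#' @export
loocv_classify <- function(signatures, features = c("both", "clustering", "closure"),
                           model = c("tree", "forest", "boosted"),
                           repeats = 1000, seed = NULL) {
  model <- match.arg(model)
  dat <- check_signature_table(signatures, match.arg(features))
  X <- dat$X; y <- dat$y
  n <- nrow(X)
  local_seed(seed, {
    acc <- vapply(seq_len(repeats), function(r) {
      pred <- vapply(seq_len(n), function(i) {
        fit_and_predict(X, y, setdiff(seq_len(n), i), i, model)
      }, "")
      mean(pred == as.character(y))
    }, 0)
    mean(acc)
  })
}

#' Impurity-based feature importance for network classification
#'
#' Fits the chosen tree-based model to the full signature table and
#' reports the normalised total impurity decrease attributed to each
#' feature, averaged over repeated fits. Scores are nonnegative and sum
#' to one; features never used by the model score zero. If a fit uses no
#' feature at all, that repeat contributes a uniform score vector.
#'
#' @inheritParams loocv_classify
#' @return A named numeric vector (one score per feature) summing to 1.
#' @export
feature_importance <- function(signatures, features = c("both", "clustering", "closure"),
                               model = c("tree", "forest", "boosted"),
                               repeats = 100, seed = NULL) {
  model <- match.arg(model)
  dat <- check_signature_table(signatures, match.arg(features))
  X <- dat$X; y <- dat$y
  feat <- colnames(X)
  local_seed(seed, {
    total <- stats::setNames(rep(0, length(feat)), feat)
    for (r in seq_len(repeats)) {
      raw <- switch(
        model,
        tree = {
          d <- data.frame(.y = y, X, check.names = FALSE)
          fit <- rpart::rpart(
            .y ~ ., data = d, method = "class",
            control = rpart::rpart.control(minsplit = 2, minbucket = 1,
                                           cp = 0, xval = 0))
          imp <- fit$variable.importance
          if (is.null(imp)) stats::setNames(numeric(0), character(0)) else imp
        },
        forest = {
          fit <- randomForest::randomForest(X, y, ntree = 300)
          stats::setNames(fit$importance[, "MeanDecreaseGini"],
                          rownames(fit$importance))
        },
        boosted = {
          fit <- xgboost::xgboost(x = X, y = y, nrounds = 30, max_depth = 3,
                                  learning_rate = 0.3, min_child_weight = 0,
                                  tree_method = "exact", nthreads = 1,
                                  verbosity = 0)
          imp <- xgboost::xgb.importance(model = fit)
          stats::setNames(imp$Gain, imp$Feature)
        })
      sc <- stats::setNames(rep(0, length(feat)), feat)
      sc[names(raw)[names(raw) %in% feat]] <- raw[names(raw) %in% feat]
      total <- total + if (sum(sc) > 0) sc / sum(sc) else
        rep(1 / length(feat), length(feat))
    }
    total / repeats
  })
}
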