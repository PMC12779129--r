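# Regression-tree and gradient-boosting engine for 0/1 indicator features.
#
# The analysis design only ever contains binary dummy columns, so every
# split is "flag == 1"; the greedy variance-reduction splitter and the
# boosting loop live in src/boost.cpp. Trees come back as parallel vectors
# (feature, left, right, value) with feature == 0 marking a leaf. The same
# engine backs the decision-tree, random-forest and gradient-boosting
# learner families. mtry subsampling draws from R's RNG, so fits are
# reproducible under a fixed seed.

as_double_matrix <- function(x) {
  if (!is.matrix(x)) x <- as.matrix(x)
  storage.mode(x) <- "double"
  x
}

tree_grow <- function(x, y, max_depth = 6L, min_n = 10L, mtry = ncol(x)) {
  cpp_tree_grow(as_double_matrix(x), as.numeric(y), as.integer(max_depth),
                as.integer(min_n), as.integer(mtry))
}

tree_apply <- function(tree, x) cpp_tree_apply(tree, as_double_matrix(x))

tree_predict <- function(tree, x) tree$value[tree_apply(tree, x)]

forest_fit <- function(x, y, n_trees = 100L, mtry = max(1L, floor(sqrt(ncol(x)))),
                       max_depth = 8L, min_n = 10L) {
  x <- as_double_matrix(x)
  n <- nrow(x)
  trees <- vector("list", n_trees)
  for (b in seq_len(n_trees)) {
    rows <- sample.int(n, n, replace = TRUE)
    trees[[b]] <- tree_grow(x[rows, , drop = FALSE], y[rows],
                            max_depth = max_depth, min_n = min_n, mtry = mtry)
  }
  list(trees = trees)
}

forest_predict <- function(fit, x) {
  x <- as_double_matrix(x)
  preds <- vapply(fit$trees, tree_predict, numeric(nrow(x)), x = x)
  if (nrow(x) == 1L) mean(preds) else rowMeans(preds)
}

# Gradient boosting with Newton leaf updates (logistic loss for binary
# targets, squared loss otherwise).
boost_fit <- function(x, y, n_trees = 150L, learn_rate = 0.1, max_depth = 2L,
                      min_n = 10L, binary = TRUE) {
  cpp_boost_fit(as_double_matrix(x), as.numeric(y), as.integer(n_trees),
                learn_rate, as.integer(max_depth), as.integer(min_n),
                isTRUE(binary))
}

boost_predict <- function(fit, x) {
  as.numeric(cpp_boost_predict(fit, as_double_matrix(x)))
}
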