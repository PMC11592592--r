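# Latent decision tree: information gain, SVM split gating, Algorithm
# behavior on constructed configurations, prediction and descriptions.

test_that("information gain reproduces closed-form entropy arithmetic", {
  expect_identical(information_gain(c(1, 1, 0, 0), c(1, 1), c(0, 0)), 1)
  # split leaving both children at parent proportions gains nothing
  expect_equal(information_gain(c(1, 1, 0, 0), c(1, 0), c(1, 0)), 0)
  # counts (6,2) split into (4,0) and (2,2): closed form
  y <- c(rep(1, 6), rep(0, 2))
  left <- c(rep(1, 4)); right <- c(rep(1, 2), rep(0, 2))
  h <- function(p) ifelse(p %in% c(0, 1), 0, -p * log2(p) - (1 - p) * log2(1 - p))
  expected <- h(6 / 8) - (4 / 8) * h(1) - (4 / 8) * h(2 / 4)
  expect_equal(information_gain(y, left, right), expected, tolerance = 1e-12)
  expect_error(information_gain(integer(0), integer(0), integer(0)), "empty")
})

test_that("SVM splits separate separable features and gate unusable ones", {
  set.seed(31)
  z <- matrix(rnorm(200 * 2), 200, 2)
  feat <- as.integer(z[, 1] > 0)            # linearly separable by axis
  sv <- fit_split_svm(z, feat, tree_config())
  expect_identical(sv$accuracy, 1)
  expect_identical(sv$pred, feat)
  expect_null(fit_split_svm(z, rep(1L, 200), tree_config()))  # single-valued
  # conflicting duplicate points cannot be fit perfectly
  zdup <- matrix(0, 10, 2)
  ydup <- rep(c(0L, 1L), 5)
  svd <- fit_split_svm(zdup, ydup, tree_config())
  expect_true(is.null(svd) || svd$accuracy < 1)
})

test_that("features independent of the latent space are rejected", {
  set.seed(32)
  rejections <- 0L
  for (rep in 1:30) {
    z <- matrix(rnorm(200 * 2), 200, 2)
    feat <- sample(0:1, 200, replace = TRUE)   # no relation to z
    sv <- fit_split_svm(z, feat, tree_config())
    if (is.null(sv) || sv$accuracy <= 0.8) rejections <- rejections + 1L
  }
  expect_gte(rejections, 28L)  # min_acc = 0.8 gates noise features
})

test_that("stopping rules fire before any SVM is trained", {
  z <- matrix(rnorm(40), 20, 2)
  f <- cbind(a = rep(0:1, 10))
  pure <- make_split(z, rep(1L, 20), f, depth = 0L, tree_config())
  expect_null(pure$split)                     # pure node: immediate leaf
  small <- make_split(z[1:9, ], rep(c(0L, 1L), length.out = 9), f[1:9, , drop = FALSE],
                      depth = 0L, tree_config(min_samples = 10))
  expect_null(small$split)                    # below min_samples
  deep <- make_split(z, rep(c(0L, 1L), 10), f, depth = 5L,
                     tree_config(max_depth = 5))
  expect_null(deep$split)                     # depth limit
})

test_that("the tree splits on the informative feature, not the noise", {
  set.seed(33)
  z <- matrix(rnorm(300 * 2), 300, 2)
  z[, 1] <- z[, 1] + 0.3 * sign(z[, 1])        # margin around the boundary
  y <- as.integer(z[, 1] > 0)
  f <- cbind(signal = y,                       # perfectly separable, aligns with y
             noise = sample(0:1, 300, replace = TRUE))
  tree <- fit_latent_tree(z, y, f, tree_config())
  expect_identical(tree$root$feature, "signal")
  expect_identical(unname(predict(tree, z)), y)
  # gain at the root must be exhaustively maximal among eligible features
  for (j in 1:2) {
    sv <- fit_split_svm(z, f[, j], tree_config())
    if (is.null(sv) || sv$accuracy <= 0.8) next
    g <- information_gain(y, y[sv$pred == 0], y[sv$pred == 1])
    expect_lte(g, tree$root$split$gain + 1e-12)
  }
})

test_that("a depth-0 tree predicts the majority class everywhere", {
  z <- matrix(rnorm(20), 10, 2)
  y <- c(rep(1L, 7), rep(0L, 3))
  tree <- fit_latent_tree(z, y, cbind(f = rep(0L, 10)), tree_config())
  expect_null(tree$root$split)  # single-valued feature: no split possible
  expect_identical(unname(predict(tree, matrix(rnorm(10), 5, 2))), rep(1L, 5))
})

test_that("training-set predictions agree with leaf majorities", {
  set.seed(34)
  z <- matrix(rnorm(200 * 3), 200, 3)
  y <- as.integer(z[, 1] + 0.3 * z[, 2] > 0)
  f <- cbind(a = as.integer(z[, 1] > 0), b = as.integer(z[, 2] > 0))
  tree <- fit_latent_tree(z, y, f, tree_config())
  pred <- predict(tree, z, paths = TRUE)
  expect_gte(mean(pred$class == y), 0.8)
  expect_true(all(lengths(pred$path) <= 5))
})

test_that("descriptions cover exactly the positive-majority leaves", {
  z <- matrix(rnorm(40), 20, 2)
  # pure positive root: one description with no conditions
  t1 <- fit_latent_tree(z, rep(1L, 20), cbind(f = rep(0:1, 10)), tree_config())
  d1 <- extract_descriptions(t1)
  expect_length(d1, 1)
  expect_length(d1[[1]]$conditions, 0)
  expect_identical(d1[[1]]$purity, 1)
  # all-negative tree: no descriptions
  t0 <- fit_latent_tree(z, rep(0L, 20), cbind(f = rep(0:1, 10)), tree_config())
  expect_length(extract_descriptions(t0), 0)
  expect_length(format_descriptions(extract_descriptions(t0)), 0)
})

test_that("trees are deterministic and serialize to JSON and DOT", {
  set.seed(35)
  z <- matrix(rnorm(300), 100, 3)
  y <- as.integer(z[, 1] > 0)
  f <- cbind(a = y, b = as.integer(z[, 2] > 0))
  t1 <- fit_latent_tree(z, y, f, tree_config(seed = 4))
  t2 <- fit_latent_tree(z, y, f, tree_config(seed = 4))
  expect_identical(tree_to_json(t1), tree_to_json(t2))
  js <- jsonlite::fromJSON(tree_to_json(t1))
  expect_identical(js$n, 100L)
  expect_match(tree_to_dot(t1), "digraph latent_tree")
})
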