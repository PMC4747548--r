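# Exhaustive midpoint-enumeration oracle for the best Gini split.
split_oracle <- function(values, labels, min_leaf = 1) {
  gini <- function(y) {
    p <- mean(y)
    2 * p * (1 - p)
  }
  v <- sort(unique(values))
  if (length(v) < 2 || length(unique(labels)) < 2) return(NULL)
  best <- NULL
  for (i in seq_len(length(v) - 1)) {
    thr <- (v[i] + v[i + 1]) / 2
    l <- labels[values <= thr]
    r <- labels[values > thr]
    if (length(l) < min_leaf || length(r) < min_leaf) next
    dec <- gini(labels) -
      (length(l) * gini(l) + length(r) * gini(r)) / length(labels)
    if (is.null(best) || dec > best$decrease)
      best <- list(threshold = thr, decrease = dec)
  }
  if (!is.null(best) && best$decrease <= 0) best <- NULL
  best
}

test_that("best_split enumerates midpoints and maximizes Gini decrease", {
  s <- best_split(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(s$threshold, 2.5)
  expect_equal(s$decrease, 0.5)
  expect_null(best_split(c(1, 2, 3), c(1, 1, 1)))      # pure labels
  expect_null(best_split(c(2, 2, 2, 2), c(0, 1, 0, 1))) # constant column
  # random datasets against the exhaustive oracle
  set.seed(6)
  for (rep in 1:50) {
    n <- sample(4:20, 1)
    v <- round(rnorm(n), 1)               # some ties among values
    y <- sample(0:1, n, replace = TRUE)
    mine <- best_split(v, y)
    oracle <- split_oracle(v, y)
    if (is.null(oracle)) {
      expect_null(mine)
    } else {
      expect_equal(mine$decrease, oracle$decrease, tolerance = 1e-9)
      # distinct thresholds are accepted only when their decreases tie to
      # floating-point precision (both implementations then maximize)
      if (!isTRUE(all.equal(mine$threshold, oracle$threshold))) {
        l <- y[v <= mine$threshold]
        r <- y[v > mine$threshold]
        gini <- function(z) 2 * mean(z) * (1 - mean(z))
        dec_mine <- gini(y) -
          (length(l) * gini(l) + length(r) * gini(r)) / length(y)
        expect_equal(dec_mine, oracle$decrease, tolerance = 1e-9)
      }
    }
  }
})

test_that("fit_tree handles separable, XOR and boundary cases", {
  # one perfectly separating feature -> depth-1 tree, training AUC 1
  x <- cbind(A = c(1, 2, 3, 10, 11, 12), B = rnorm(6))
  y <- c(0, 0, 0, 1, 1, 1)
  tr <- fit_tree(x, y, max_depth = 3, min_leaf = 1)
  expect_equal(tree_features(tr), "A")
  expect_equal(auc(predict(tr, x), y), 1)
  # XOR needs depth 2
  xx <- cbind(A = c(0, 0, 1, 1), B = c(0, 1, 0, 1))
  yy <- c(0, 1, 1, 0)
  tx <- fit_tree(xx, yy, max_depth = 2, min_leaf = 1)
  expect_equal(as.integer(predict(tx, xx) > 0.5), yy)
  # max_depth 0 -> single leaf scoring the smoothed prevalence
  t0 <- fit_tree(matrix(rnorm(66), 66, 1, dimnames = list(NULL, "A")),
                 rep(c(1, 0), c(33, 33)), max_depth = 0)
  expect_equal(t0$root$type, "leaf")
  expect_equal(predict(t0, matrix(0, 1, 1, dimnames = list(NULL, "A"))),
               (33 + 1) / (66 + 2))
  # single-class labels -> depth-0 tree, no error
  t1 <- fit_tree(matrix(rnorm(10), 10, 1, dimnames = list(NULL, "A")),
                 rep(1, 10))
  expect_equal(t1$root$type, "leaf")
  expect_gt(t1$root$score, 0.9)
  expect_error(fit_tree(matrix(0, 0, 1), integer(0)), "empty")
})

test_that("training-set consistency: leaves partition the sample", {
  set.seed(12)
  x <- matrix(rnorm(300), 60, 5, dimnames = list(NULL, paste0("F", 1:5)))
  y <- as.integer(x[, 1] + rnorm(60, 0, 0.6) > 0)
  tr <- fit_tree(x, y, max_depth = 4, min_leaf = 3)
  leaves <- kdsense:::tree_leaves(tr)
  expect_equal(sum(vapply(leaves, function(l) l$n_kd + l$n_fc, 0)), 60)
  expect_equal(sum(vapply(leaves, `[[`, 0, "n_kd")), sum(y))
  # every training point's leaf contains it: routing a training row gives
  # its leaf's smoothed score, checked by an independent routing oracle
  route_oracle <- function(node, xi) {
    while (node$type == "split")
      node <- if (xi[node$feature] <= node$threshold) node$left else
        node$right
    node$score
  }
  scores <- predict(tr, x)
  for (i in seq_len(60))
    expect_equal(scores[i], route_oracle(tr$root, x[i, ]))
})

test_that("unbounded depth with min_leaf 1 drives training error to zero", {
  set.seed(3)
  x <- matrix(round(rnorm(120), 2), 40, 3,
              dimnames = list(NULL, paste0("F", 1:3)))
  y <- sample(0:1, 40, replace = TRUE)
  # consistency: no duplicate rows with conflicting labels at this seed
  expect_equal(anyDuplicated(x), 0)
  tr <- fit_tree(x, y, max_depth = 100, min_leaf = 1)
  expect_equal(as.integer(predict(tr, x) > 0.5), y)
})

test_that("predict errors on a missing feature, naming it", {
  x <- cbind(A = c(1, 2, 3, 4), B = c(0, 0, 0, 1))
  tr <- fit_tree(x, c(0, 0, 1, 1), min_leaf = 1)
  expect_error(predict(tr, cbind(B = 1)), "A")
})

test_that("root split agrees with rpart on random small datasets", {
  skip_if_not_installed("rpart")
  set.seed(14)
  agree <- 0
  for (rep in 1:20) {
    n <- sample(10:20, 1)
    x <- matrix(rnorm(3 * n), n, 3, dimnames = list(NULL, c("a", "b", "c")))
    y <- as.integer(x[, sample(3, 1)] + rnorm(n, 0, 0.8) > 0)
    if (length(unique(y)) < 2) next
    mine <- fit_tree(x, y, max_depth = 1, min_leaf = 1)
    rp <- rpart::rpart(y ~ ., data = data.frame(x, y = y),
                       method = "class",
                       control = rpart::rpart.control(maxdepth = 1,
                                                      minsplit = 2,
                                                      minbucket = 1,
                                                      cp = 0, xval = 0))
    if (is.null(rp$splits) || mine$root$type == "leaf") next
    rp_feature <- rownames(rp$splits)[1]
    rp_threshold <- rp$splits[1, "index"]
    expect_equal(mine$root$feature, rp_feature)
    expect_equal(mine$root$threshold, unname(rp_threshold),
                 tolerance = 1e-8)
    agree <- agree + 1
  }
  expect_gte(agree, 15)  # most draws must actually exercise the check
})

test_that("tree JSON serialization carries the full structure", {
  x <- cbind(A = c(1, 2, 3, 10, 11, 12), B = c(5, 5, 5, 5, 5, 9))
  tr <- fit_tree(x, c(0, 0, 0, 1, 1, 1), min_leaf = 1)
  js <- jsonlite::fromJSON(tree_to_json(tr), simplifyVector = FALSE)
  expect_equal(js$root$feature, tr$root$feature)
  expect_equal(js$root$threshold, tr$root$threshold)
  expect_equal(js$n, 6)
})
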