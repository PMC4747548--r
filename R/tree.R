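#' Best binary split of one feature column by Gini impurity decrease
#'
#' Exhaustively evaluates thresholds at the midpoints between consecutive
#' distinct sorted values, with split rule `value <= threshold` going left,
#' and returns the split maximizing the decrease in Gini impurity
#' (parent impurity minus the size-weighted child impurities). Ties are
#' broken toward the lower threshold.
#'
#' @param values Numeric feature column.
#' @param labels Binary labels (0/1), same length.
#' @param min_leaf Minimum samples on each side of the split.
#' @return A list `(threshold, decrease)`, or `NULL` when no split has a
#'   positive decrease (pure node, constant column, or `min_leaf`
#'   infeasible).
#' @export
best_split <- function(values, labels, min_leaf = 1L) {
  n <- length(values)
  stopifnot(length(labels) == n)
  n1 <- sum(labels)
  if (n1 == 0L || n1 == n) return(NULL)          # pure node
  split_search(values, labels, n, n1, min_leaf, allow_zero = FALSE)
}

# Shared split scan. `allow_zero = TRUE` admits zero-decrease splits for
# impure nodes; used by fit_tree as an escape when an impure node has no
# positive-gain split (the classic greedy-Gini blindness on symmetric
# XOR-like arrangements), so that consistent data can always be driven to
# purity with unbounded depth.
split_search <- function(values, labels, n, n1, min_leaf, allow_zero) {
  o <- order(values)
  v <- values[o]
  y <- labels[o]
  cut <- which(diff(v) > 0)                      # split after position i
  cut <- cut[cut >= min_leaf & (n - cut) >= min_leaf]
  if (length(cut) == 0) return(NULL)
  c1 <- cumsum(y)
  nL <- cut
  nR <- n - cut
  p1L <- c1[cut] / nL
  p1R <- (n1 - c1[cut]) / nR
  p1 <- n1 / n
  g0 <- 2 * p1 * (1 - p1)
  decrease <- g0 - (nL * 2 * p1L * (1 - p1L) + nR * 2 * p1R * (1 - p1R)) / n
  best <- which.max(decrease)                    # first max = lowest threshold
  if (decrease[best] <= 0 && !allow_zero) return(NULL)
  list(threshold = (v[cut[best]] + v[cut[best] + 1]) / 2,
       decrease = max(0, decrease[best]))
}

#' Fit a CART-style classification tree with probabilistic leaf scores
#'
#' Greedy recursive binary partitioning on Gini impurity. At each node the
#' (feature, threshold) pair with maximal impurity decrease is chosen, with
#' deterministic tie-breaking (lower feature index, then lower threshold),
#' so fits are reproducible across platforms. Growth stops at `max_depth`,
#' when a child would fall below `min_leaf` samples, at purity, or when the
#' best decrease is below `min_impurity_decrease`. Leaves carry the class
#' counts and a Laplace-smoothed KD probability
#' `(n_kd + 1) / (n + 2)` used as the probabilistic score.
#'
#' @param x Numeric matrix, subjects x features, with column names.
#' @param y Binary labels (0/1 or `"KD"`/`"FC"`; KD = 1).
#' @param max_depth Maximum tree depth (0 = a single leaf).
#' @param min_leaf Minimum samples per leaf.
#' @param min_impurity_decrease Minimum Gini decrease to accept a split.
#' @return An object of class `csa_tree`.
#' @export
fit_tree <- function(x, y, max_depth = 3, min_leaf = 5,
                     min_impurity_decrease = 1e-7) {
  x <- as.matrix(x)
  if (nrow(x) == 0) stop("empty training matrix", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("F", seq_len(ncol(x)))
  y <- as_binary_labels(y)
  stopifnot(length(y) == nrow(x))
  grow <- function(idx, depth) {
    yi <- y[idx]
    n1 <- sum(yi)
    n <- length(idx)
    leaf <- list(type = "leaf", n_kd = n1, n_fc = n - n1,
                 score = (n1 + 1) / (n + 2))
    if (depth >= max_depth || n < 2 * min_leaf || n1 == 0L || n1 == n)
      return(leaf)
    scan <- function(allow_zero) {
      found <- NULL
      for (j in seq_len(ncol(x))) {
        s <- split_search(x[idx, j], yi, n, n1, min_leaf, allow_zero)
        if (is.null(s)) next
        if (is.null(found) || s$decrease > found$decrease) {
          found <- s
          found$feature_index <- j
        }
      }
      found
    }
    best <- scan(allow_zero = FALSE)
    if (is.null(best)) {
      # zero-gain escape: an impure node with no positive-gain split at
      # all (e.g. a symmetric XOR arrangement) may still be split at zero
      # decrease so that deeper splits can reach purity; a weak positive
      # split rejected by min_impurity_decrease stays a leaf
      best <- scan(allow_zero = TRUE)
      if (is.null(best)) return(leaf)
    } else if (best$decrease < min_impurity_decrease) {
      return(leaf)
    }
    go_left <- x[idx, best$feature_index] <= best$threshold
    list(type = "split",
         feature = colnames(x)[best$feature_index],
         feature_index = best$feature_index,
         threshold = best$threshold,
         decrease = best$decrease,
         n = n,
         left = grow(idx[go_left], depth + 1),
         right = grow(idx[!go_left], depth + 1))
  }
  structure(list(root = grow(seq_len(nrow(x)), 0),
                 features = colnames(x),
                 n = nrow(x), n_kd = sum(y),
                 params = list(max_depth = max_depth, min_leaf = min_leaf,
                               min_impurity_decrease = min_impurity_decrease)),
            class = "csa_tree")
}

# Route one sample (named numeric vector) to its leaf node.
route_to_leaf <- function(tree, xrow) {
  node <- tree$root
  while (node$type == "split") {
    val <- xrow[[node$feature]]
    if (is.null(val) || is.na(val))
      stop("missing feature required by the tree: ", node$feature,
           call. = FALSE)
    node <- if (val <= node$threshold) node$left else node$right
  }
  node
}

#' Predict probabilistic KD scores
#'
#' Routes each sample down the tree and returns the Laplace-smoothed KD
#' fraction of its leaf, a score in (0, 1); higher means more KD-like.
#'
#' @param object A `csa_tree`.
#' @param newdata Matrix or data frame containing every feature the tree
#'   references (by column name).
#' @param ... Unused.
#' @return Numeric vector of scores.
#' @export
predict.csa_tree <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  used <- tree_features(object)
  missing <- setdiff(used, colnames(newdata))
  if (length(missing) > 0)
    stop("missing feature required by the tree: ",
         paste(missing, collapse = ", "), call. = FALSE)
  vapply(seq_len(nrow(newdata)), function(i)
    route_to_leaf(object, as.list(newdata[i, , drop = TRUE]))$score, 0)
}

#' Features actually referenced by a fitted tree
#' @param tree A `csa_tree`.
#' @return Character vector of feature names (empty for a stump).
#' @export
tree_features <- function(tree) {
  walk <- function(node) {
    if (node$type == "leaf") return(character(0))
    c(node$feature, walk(node$left), walk(node$right))
  }
  unique(walk(tree$root))
}

# Leaves in left-to-right order (used for consistency checks).
tree_leaves <- function(tree) {
  walk <- function(node) {
    if (node$type == "leaf") return(list(node))
    c(walk(node$left), walk(node$right))
  }
  walk(tree$root)
}

#' @export
print.csa_tree <- function(x, digits = 4, ...) {
  cat(sprintf("CART decision tree: %d training subjects (%d KD, %d FC)\n",
              x$n, x$n_kd, x$n - x$n_kd))
  rec <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$type == "leaf") {
      cat(sprintf("%sleaf: score %.3f (KD %d, FC %d)\n", pad, node$score,
                  node$n_kd, node$n_fc))
    } else {
      cat(sprintf("%sif %s <= %s:\n", pad, node$feature,
                  format(node$threshold, digits = digits)))
      rec(node$left, indent + 1)
      cat(sprintf("%selse:\n", pad))
      rec(node$right, indent + 1)
    }
  }
  rec(x$root, 1)
  invisible(x)
}

#' Serialize a fitted tree to JSON
#'
#' Nested node structure with feature names, thresholds and leaf counts;
#' suitable for archiving a trained diagnostic model as a plain-text
#' artifact.
#'
#' @param tree A `csa_tree`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
tree_to_json <- function(tree, path = NULL) {
  obj <- list(root = tree$root, features = tree$features,
              n = tree$n, n_kd = tree$n_kd, params = tree$params)
  if (is.null(path))
    return(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE,
                                         digits = NA)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
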