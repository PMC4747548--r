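#' ROC area under the curve by the rank-pair (Mann-Whitney) formula
#'
#' `AUC = (#\{pos > neg\} + 0.5 * #\{ties\}) / (n_pos * n_neg)`, computed
#' via midranks; identical (to machine precision) to the trapezoidal area
#' under the tie-aware ROC sweep of [roc_curve()]. Higher scores are taken
#' as more KD-like.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (KD = 1 / positive).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as_binary_labels(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("AUC undefined: both classes must be present", call. = FALSE)
  r <- rank(scores)                       # midranks handle ties
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve by threshold sweep
#'
#' Sweeps the decision threshold over the distinct score values (predicting
#' KD when `score >= threshold`), producing the operating points from
#' (0, 0) to (1, 1). The `auc` field is the trapezoidal area, which equals
#' [auc()] exactly, including under ties.
#'
#' @inheritParams auc
#' @return An object of class `roc_curve` with `thresholds`, `tpr`, `fpr`
#'   and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as_binary_labels(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("ROC undefined: both classes must be present", call. = FALSE)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1L), 0) / n_pos
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0L), 0) / n_neg
  tpr <- c(0, tpr)
  fpr <- c(0, fpr)
  thresholds <- c(Inf, thr)
  area <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = thresholds, tpr = tpr, fpr = fpr, auc = area),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d operating points, AUC = %.4f\n",
              length(x$thresholds), x$auc))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, main = sprintf("ROC (AUC = %.3f)", x$auc),
                           ...) {
  graphics::plot(x$fpr, x$tpr, type = "s", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "1 - specificity (FPR)", ylab = "Sensitivity (TPR)",
                 main = main, ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

#' 2x2 contingency table at a decision threshold
#'
#' Predicts KD when `score >= threshold` (inclusive on the KD side) and
#' tabulates true/false positives/negatives with sensitivity and
#' specificity.
#'
#' @inheritParams auc
#' @param threshold Decision threshold.
#' @return An object of class `contingency`: `tp`, `fn`, `fp`, `tn`,
#'   `sensitivity`, `specificity` (fractions) and the `threshold`.
#' @export
contingency_at_threshold <- function(scores, labels, threshold) {
  labels <- as_binary_labels(labels)
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1L)
  fn <- sum(!pred & labels == 1L)
  fp <- sum(pred & labels == 0L)
  tn <- sum(!pred & labels == 0L)
  structure(list(tp = tp, fn = fn, fp = fp, tn = tn,
                 sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
                 threshold = threshold),
            class = "contingency")
}

#' @export
print.contingency <- function(x, ...) {
  cat(sprintf("Contingency table at threshold %.3f\n", x$threshold))
  cat(sprintf("           KD    FC\n"))
  cat(sprintf("  pred KD %4d  %4d\n", x$tp, x$fp))
  cat(sprintf("  pred FC %4d  %4d\n", x$fn, x$tn))
  cat(sprintf("  sensitivity %.1f%%, specificity %.1f%%\n",
              100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}

#' Choose a decision threshold
#'
#' `"fixed"` returns the given constant (default 0.5 on the probabilistic
#' score); `"youden"` maximizes Youden's J = sensitivity + specificity - 1
#' over the observed operating points (candidate thresholds are the
#' distinct scores), breaking ties toward the lower threshold.
#'
#' @inheritParams auc
#' @param rule `"fixed"` or `"youden"`.
#' @param fixed Threshold returned under the fixed rule.
#' @return A single threshold.
#' @export
choose_threshold <- function(scores, labels, rule = c("fixed", "youden"),
                             fixed = 0.5) {
  rule <- match.arg(rule)
  if (rule == "fixed") return(fixed)
  labels <- as_binary_labels(labels)
  if (!all(c(0L, 1L) %in% labels))
    stop("Youden threshold undefined: both classes must be present",
         call. = FALSE)
  cand <- sort(unique(scores))
  j <- vapply(cand, function(t) {
    ct <- contingency_at_threshold(scores, labels, t)
    ct$sensitivity + ct$specificity - 1
  }, 0)
  cand[which.max(j)]                      # first max = lowest threshold
}

# P(U <= u) under the exact tie-free permutation null. The number of rank
# arrangements with statistic u obeys the classical count recurrence
# C(n, m, u) = C(n-1, m, u-m) + C(n, m-1, u); equivalently, arrangements
# correspond to partitions of u into at most n parts each at most m. The
# DP below builds that table over m, vectorized over u.
u_exact_cdf <- function(u, n, m) {
  maxu <- n * m
  counts <- matrix(0, n + 1, maxu + 1)    # part bound m' = 0
  counts[, 1] <- 1
  for (mp in seq_len(m)) {
    new <- matrix(0, n + 1, maxu + 1)
    new[1, 1] <- 1
    for (k in seq_len(n)) {
      shifted <- c(rep(0, mp), new[k, seq_len(maxu + 1 - mp)])
      new[k + 1, ] <- shifted + counts[k + 1, ]
    }
    counts <- new
  }
  sum(counts[n + 1, seq_len(floor(u) + 1)]) / choose(n + m, n)
}

#' Mann-Whitney U test (two-sided)
#'
#' `U` counts pairs `(x_i, y_j)` with `x_i > y_j`, ties counted half. In
#' `"exact"` mode the permutation null is enumerated (tie-free data only;
#' intended for `min(n, m) <= 10`) and the two-sided p-value doubles the
#' smaller tail. In `"normal"` mode the tie-corrected normal approximation
#' with continuity correction is used. `"auto"` picks exact when the data
#' are tie-free and `min(n, m) <= 10`.
#'
#' @param x,y Numeric samples (non-empty).
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @return A list with `U`, `p.value` and the `mode` used.
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (length(x) == 0 || length(y) == 0)
    stop("both samples must be non-empty", call. = FALSE)
  n <- length(x)
  m <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2      # #{x > y} + 0.5 ties
  has_ties <- anyDuplicated(c(x, y)) > 0
  if (mode == "auto")
    mode <- if (!has_ties && min(n, m) <= 10) "exact" else "normal"
  if (mode == "exact") {
    if (has_ties)
      stop("exact mode requires tie-free data", call. = FALSE)
    lower <- u_exact_cdf(min(U, n * m - U), n, m)
    p <- min(1, 2 * lower)
  } else {
    mu <- n * m / 2
    Nt <- n + m
    tie_tab <- table(r)
    sigma2 <- n * m / 12 *
      ((Nt + 1) - sum(tie_tab^3 - tie_tab) / (Nt * (Nt - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(U - mu) - 0.5) / sqrt(sigma2)    # continuity correction
      z <- max(z, 0)
      p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
    }
  }
  list(U = U, p.value = p, mode = mode)
}

#' Per-feature Mann-Whitney discrimination screen
#'
#' Tests every compound-channel feature of a table for a KD-vs-FC location
#' difference (two-sided Mann-Whitney). Raw p-values are reported;
#' Benjamini-Hochberg q-values are added as a clearly-labelled extension of
#' the raw-p convention.
#'
#' @param table A `feature_table`.
#' @param mode Test mode passed to [mann_whitney_u()].
#' @return Data frame: feature, compound, channel, U, p, q (BH-adjusted).
#' @export
compound_tests <- function(table, mode = "auto") {
  stopifnot(inherits(table, "feature_table"))
  kd <- table$labels == 1L
  res <- lapply(seq_len(ncol(table$values)), function(k) {
    t <- mann_whitney_u(table$values[kd, k], table$values[!kd, k],
                        mode = mode)
    data.frame(feature = colnames(table$values)[k],
               U = t$U, p = t$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  parts <- strsplit(out$feature, "_(?=[RGB]$)", perl = TRUE)
  out$compound <- vapply(parts, `[[`, "", 1)
  out$channel <- vapply(parts, `[[`, "", 2)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out[, c("feature", "compound", "channel", "U", "p", "q")]
}
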