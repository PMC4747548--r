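#' Train the KD diagnostic model: GA panel selection plus final tree
#'
#' The headline fitting function. On a creatinine-normalized training
#' table it (1) runs the genetic-algorithm wrapper [evolve()] to select the
#' compound panel with maximal cross-validated decision-tree ROC AUC, and
#' (2) fits the final [fit_tree()] on the full training set restricted to
#' the selected panel. The decision threshold on the probabilistic score is
#' chosen on the training set by `threshold_rule` and carried unchanged to
#' any test cohort.
#'
#' @param table Creatinine-normalized training `feature_table`.
#' @param ga A [ga_config()].
#' @param tree Tree parameters for the final fit (defaults to the ones in
#'   `ga$tree`).
#' @param threshold_rule `"fixed"` (default, 0.5) or `"youden"` (chosen on
#'   training scores).
#' @param fixed_threshold Threshold used under the fixed rule.
#' @return An object of class `csa_model` with components `ga`
#'   (a `csa_ga`), `tree` (a `csa_tree`), `selected`, `threshold`,
#'   `train_auc` (resubstitution) and the training class counts.
#' @seealso [predict.csa_model()], [evaluate_model()], [run_pipeline()]
#' @export
csa_train <- function(table, ga = ga_config(), tree = ga$tree,
                      threshold_rule = c("fixed", "youden"),
                      fixed_threshold = 0.5) {
  stopifnot(inherits(table, "feature_table"))
  threshold_rule <- match.arg(threshold_rule)
  if (!isTRUE(table$normalized))
    warning("training on a non-normalized feature table")
  ga_result <- evolve(table, ga)
  cols <- mask_columns(table, ga_result$best_mask)
  x <- table$values[, cols, drop = FALSE]
  fit <- fit_tree(x, table$labels, max_depth = tree$max_depth,
                  min_leaf = tree$min_leaf,
                  min_impurity_decrease = tree$min_impurity_decrease)
  train_scores <- predict(fit, x)
  threshold <- choose_threshold(train_scores, table$labels,
                                rule = threshold_rule,
                                fixed = fixed_threshold)
  structure(list(ga = ga_result, tree = fit,
                 selected = ga_result$selected,
                 threshold = threshold, threshold_rule = threshold_rule,
                 train_auc = auc(train_scores, table$labels),
                 train_scores = stats::setNames(train_scores,
                                                table$subject_ids),
                 n_train = length(table$labels),
                 n_kd = sum(table$labels == 1L)),
            class = "csa_model")
}

#' @export
print.csa_model <- function(x, ...) {
  cat("KD colorimetric sensor-array diagnostic model\n")
  cat(sprintf("  panel: %d compounds (%s)\n", length(x$selected),
              paste(x$selected, collapse = ", ")))
  cat(sprintf("  GA mean CV AUC %.4f; training (resubstitution) AUC %.4f\n",
              x$ga$best_fitness, x$train_auc))
  cat(sprintf("  decision threshold %.3f (%s rule) on the probabilistic score\n",
              x$threshold, x$threshold_rule))
  invisible(x)
}

#' @export
summary.csa_model <- function(object, ...) {
  print(object)
  cat("\nFinal decision tree:\n")
  print(object$tree)
  invisible(object)
}

#' Score subjects with a trained diagnostic model
#'
#' @param object A `csa_model`.
#' @param newdata A `feature_table` (normalized the same way as training)
#'   or a feature matrix containing the model's features.
#' @param ... Unused.
#' @return Named numeric vector of probabilistic KD scores.
#' @export
predict.csa_model <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "feature_table")) newdata$values else
    as.matrix(newdata)
  s <- predict(object$tree, x)
  names(s) <- rownames(x)
  s
}

#' Evaluate a trained model on a labelled cohort
#'
#' Scores every subject exactly once, computes the ROC curve and AUC, and
#' the contingency table at the model's frozen decision threshold.
#'
#' @param model A `csa_model`.
#' @param table A labelled `feature_table`.
#' @return A list with `scores`, `roc` (a `roc_curve`), `auc`,
#'   `contingency` and `threshold`.
#' @export
evaluate_model <- function(model, table) {
  stopifnot(inherits(model, "csa_model"), inherits(table, "feature_table"))
  scores <- predict(model, table)
  roc <- roc_curve(scores, table$labels)
  list(scores = scores, roc = roc, auc = roc$auc,
       contingency = contingency_at_threshold(scores, table$labels,
                                              model$threshold),
       threshold = model$threshold)
}
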