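#' Genetic-algorithm configuration for compound-panel selection
#'
#' Hyperparameters of the wrapper GA that searches bit masks over the N
#' candidate compounds (a selected compound contributes all three of its
#' RGB channels). Defaults follow standard wrapper-GA practice: population
#' 50, 100 generations, tournament size 3, crossover probability 0.9 with
#' uniform per-bit mixing, per-bit mutation rate 1/N, one elite, 5-fold
#' stratified cross-validation for the fitness.
#'
#' @param population_size Chromosomes per generation (>= 2).
#' @param generations Number of generations (0 = evaluate the random
#'   initial population only).
#' @param tournament_size Tournament size for parent selection.
#' @param crossover_prob Probability a child is produced by uniform
#'   crossover rather than copied from one parent.
#' @param mutation_rate Per-bit flip probability; `NULL` means `1/N`.
#' @param elitism_count Number of best chromosomes copied unchanged.
#' @param cv_folds Stratified CV folds for the fitness.
#' @param subset_penalty Optional per-compound fitness penalty (lambda in
#'   `fitness - lambda * |mask|`); default 0 (off).
#' @param init_bit_prob Probability a bit is set at initialization; `NULL`
#'   means `11/N`, biasing the search toward small panels.
#' @param tree Tree parameters used inside the fitness (list with
#'   `max_depth`, `min_leaf`, `min_impurity_decrease`).
#' @param seed Integer seed; [evolve()] is a pure function of (table,
#'   config) including this seed.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(population_size = 50, generations = 100,
                      tournament_size = 3, crossover_prob = 0.9,
                      mutation_rate = NULL, elitism_count = 1,
                      cv_folds = 5, subset_penalty = 0,
                      init_bit_prob = NULL,
                      tree = list(max_depth = 3, min_leaf = 5,
                                  min_impurity_decrease = 1e-7),
                      seed = 1) {
  check_field(population_size >= 2, "population_size", "must be >= 2")
  check_field(generations >= 0, "generations", "must be >= 0")
  check_field(tournament_size >= 1, "tournament_size", "must be >= 1")
  check_field(crossover_prob >= 0 && crossover_prob <= 1, "crossover_prob",
              "must be in [0, 1]")
  check_field(is.null(mutation_rate) ||
              (mutation_rate >= 0 && mutation_rate <= 1), "mutation_rate",
              "must be in [0, 1]")
  check_field(elitism_count >= 0 && elitism_count < population_size,
              "elitism_count", "must be in [0, population_size)")
  check_field(cv_folds >= 2, "cv_folds", "must be >= 2")
  check_field(subset_penalty >= 0, "subset_penalty", "must be >= 0")
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 tournament_size = as.integer(tournament_size),
                 crossover_prob = crossover_prob,
                 mutation_rate = mutation_rate,
                 elitism_count = as.integer(elitism_count),
                 cv_folds = as.integer(cv_folds),
                 subset_penalty = subset_penalty,
                 init_bit_prob = init_bit_prob,
                 tree = tree, seed = as.integer(seed)),
            class = "ga_config")
}

# Seeded stratified k-fold assignment; returns an integer fold id per row.
stratified_folds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      if (length(idx) < k)
        stop("cannot stratify: class ", cls, " has fewer than ", k,
             " subjects", call. = FALSE)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

#' Cross-validated AUC fitness of a compound mask
#'
#' Restricts the feature table to the `3 * |mask|` channels of the selected
#' compounds, fits the decision tree on the training folds of a seeded
#' stratified k-fold partition, scores the held-out subjects, and returns
#' the unweighted mean held-out AUC over folds. Deterministic given
#' `(mask, table, cv_folds, seed)`. An empty mask has fitness 0 by
#' definition. If a partition leaves a fold with a single class, it is
#' re-drawn once before failing.
#'
#' @param mask Logical vector over compounds (or integer compound indices).
#' @param table A creatinine-normalized `feature_table`.
#' @param cv_folds Number of stratified folds.
#' @param seed Seed for the fold partition.
#' @param tree Tree parameter list (see [ga_config()]).
#' @param folds Optional precomputed fold assignment (overrides
#'   `cv_folds`/`seed`), used by [evolve()] so all masks share one
#'   partition.
#' @return Mean held-out AUC in `[0, 1]`.
#' @export
ga_fitness <- function(mask, table, cv_folds = 5, seed = 1,
                       tree = list(max_depth = 3, min_leaf = 5,
                                   min_impurity_decrease = 1e-7),
                       folds = NULL) {
  stopifnot(inherits(table, "feature_table"))
  if (is.logical(mask)) {
    if (!any(mask)) return(0)
  } else if (length(mask) == 0) return(0)
  cols <- mask_columns(table, mask)
  x <- table$values[, cols, drop = FALSE]
  y <- table$labels
  if (is.null(folds)) {
    folds <- stratified_folds(y, cv_folds, seed)
    for (attempt in 1:2) {
      ok <- all(vapply(seq_len(max(folds)), function(f)
        length(unique(y[folds == f])) == 2L, TRUE))
      if (ok) break
      if (attempt == 2)
        stop("fold with a single class after re-draw", call. = FALSE)
      folds <- stratified_folds(y, cv_folds, seed + 1L)
    }
  }
  aucs <- vapply(seq_len(max(folds)), function(f) {
    train <- folds != f
    fit <- fit_tree(x[train, , drop = FALSE], y[train],
                    max_depth = tree$max_depth, min_leaf = tree$min_leaf,
                    min_impurity_decrease = tree$min_impurity_decrease)
    auc(predict(fit, x[!train, , drop = FALSE]), y[!train])
  }, 0)
  mean(aucs)
}

#' Standard GA operators on compound bit masks
#'
#' `tournament_select` draws `k` population members at random and returns
#' the index of the fittest; `uniform_crossover` takes each bit from either
#' parent with probability `p`; `mutate_mask` flips each bit independently,
#' and if the result is all-zero sets one random bit (an empty panel is
#' never propagated). All three consume the current RNG stream.
#'
#' @param fitnesses Numeric fitness per population member.
#' @param k Tournament size.
#' @param a,b Parent masks (logical vectors).
#' @param p Per-bit probability of inheriting from parent `a`.
#' @param mask Logical mask.
#' @param rate Per-bit flip probability.
#' @return `tournament_select`: an index; the others: a logical mask.
#' @export
tournament_select <- function(fitnesses, k) {
  cand <- sample.int(length(fitnesses), k, replace = TRUE)
  cand[which.max(fitnesses[cand])]
}

#' @rdname tournament_select
#' @export
uniform_crossover <- function(a, b, p = 0.5) {
  from_a <- stats::runif(length(a)) < p
  ifelse(from_a, a, b)
}

#' @rdname tournament_select
#' @export
mutate_mask <- function(mask, rate) {
  flip <- stats::runif(length(mask)) < rate
  out <- xor(mask, flip)
  if (!any(out)) out[sample.int(length(out), 1)] <- TRUE
  out
}

# Chromosome comparison with deterministic tie-breaking: higher penalized
# score wins; at equal score fewer selected compounds wins; then the
# lexicographically lower mask.
mask_key <- function(mask) paste(as.integer(mask), collapse = "")
better_mask <- function(score_a, mask_a, score_b, mask_b) {
  if (score_a != score_b) return(score_a > score_b)
  na <- sum(mask_a); nb <- sum(mask_b)
  if (na != nb) return(na < nb)
  mask_key(mask_a) < mask_key(mask_b)
}

#' Evolve a compound panel by genetic-algorithm wrapper selection
#'
#' Searches bit masks over the candidate compounds for the subset whose
#' decision-tree classifier attains the maximum stratified cross-validated
#' ROC AUC. Initialization sets each bit with probability `11/N` (small
#' panels), then iterates tournament selection, uniform crossover, per-bit
#' mutation and elitism. One fold partition, seeded from the config, is
#' shared by all fitness evaluations so the fitness landscape is fixed
#' during the run; fitness values are cached per mask. Fully reproducible
#' from the config seed.
#'
#' @param table A creatinine-normalized `feature_table` with both classes.
#' @param config A [ga_config()].
#' @return An object of class `csa_ga`: `best_mask` (named logical),
#'   `selected` compound names, `best_fitness` (mean CV AUC of the best
#'   mask), `trajectory` (per-generation best/mean fitness), `evaluations`
#'   (tree-fitting fitness evaluations, cache misses only) and the config.
#' @export
evolve <- function(table, config = ga_config()) {
  stopifnot(inherits(table, "feature_table"), inherits(config, "ga_config"))
  if (!isTRUE(table$normalized))
    warning("feature table is not creatinine-normalized")
  if (length(unique(table$labels)) < 2L)
    stop("degenerate table: both classes must be present", call. = FALSE)
  if (length(table$subject_ids) == 0)
    stop("degenerate table: no subjects", call. = FALSE)
  N <- length(table$compounds)
  pop_size <- config$population_size
  rate <- if (is.null(config$mutation_rate)) 1 / N else config$mutation_rate
  p0 <- if (is.null(config$init_bit_prob)) min(1, 11 / N) else
    config$init_bit_prob
  folds <- stratified_folds(table$labels, config$cv_folds,
                            derive_seed(config$seed, "cv"))
  cache <- new.env(parent = emptyenv())
  evaluations <- 0L
  fitness_of <- function(mask) {
    key <- mask_key(mask)
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- ga_fitness(mask, table, tree = config$tree, folds = folds)
    evaluations <<- evaluations + 1L
    cache[[key]] <- val
    val
  }
  with_seed(config$seed, {
    pop <- lapply(seq_len(pop_size), function(i) {
      mask <- stats::runif(N) < p0
      if (!any(mask)) mask[sample.int(N, 1)] <- TRUE
      mask
    })
    fit <- vapply(pop, fitness_of, 0)
    score <- fit - config$subset_penalty * vapply(pop, sum, 0)
    best_i <- 1L
    for (i in seq_len(pop_size))
      if (better_mask(score[i], pop[[i]], score[best_i], pop[[best_i]]))
        best_i <- i
    best_mask <- pop[[best_i]]
    best_score <- score[best_i]
    traj_best <- max(score)
    traj_mean <- mean(fit)
    for (gen in seq_len(config$generations)) {
      ord <- order(score, -vapply(pop, sum, 0), decreasing = TRUE)
      elite <- pop[utils::head(ord, config$elitism_count)]
      children <- vector("list", pop_size - length(elite))
      for (i in seq_along(children)) {
        p1 <- pop[[tournament_select(score, config$tournament_size)]]
        child <- if (stats::runif(1) < config$crossover_prob) {
          p2 <- pop[[tournament_select(score, config$tournament_size)]]
          uniform_crossover(p1, p2, 0.5)
        } else p1
        children[[i]] <- mutate_mask(child, rate)
      }
      pop <- c(elite, children)
      fit <- vapply(pop, fitness_of, 0)
      score <- fit - config$subset_penalty * vapply(pop, sum, 0)
      for (i in seq_len(pop_size))
        if (better_mask(score[i], pop[[i]], best_score, best_mask)) {
          best_mask <- pop[[i]]
          best_score <- score[i]
        }
      traj_best <- c(traj_best, max(score))
      traj_mean <- c(traj_mean, mean(fit))
    }
    names(best_mask) <- table$compounds
    structure(list(
      best_mask = best_mask,
      selected = table$compounds[best_mask],
      best_fitness = fitness_of(unname(best_mask)),
      trajectory = data.frame(generation = seq_along(traj_best) - 1L,
                              best = traj_best, mean = traj_mean),
      evaluations = evaluations,
      config = config),
      class = "csa_ga")
  })
}

#' @export
print.csa_ga <- function(x, ...) {
  cat(sprintf("GA compound-panel selection: %d-compound panel, mean CV AUC %.4f\n",
              sum(x$best_mask), x$best_fitness))
  cat(sprintf("  selected: %s\n", paste(x$selected, collapse = ", ")))
  cat(sprintf("  %d generations, %d fitness evaluations\n",
              nrow(x$trajectory) - 1L, x$evaluations))
  invisible(x)
}

#' @export
plot.csa_ga <- function(x, main = "GA selection trajectory", ...) {
  graphics::plot(x$trajectory$generation, x$trajectory$best, type = "l",
                 ylim = range(x$trajectory[c("best", "mean")]),
                 xlab = "Generation", ylab = "Mean CV AUC fitness",
                 main = main, ...)
  graphics::lines(x$trajectory$generation, x$trajectory$mean, lty = 2,
                  col = "grey40")
  graphics::legend("bottomright", c("best", "population mean"),
                   lty = c(1, 2), col = c("black", "grey40"), bty = "n")
  invisible(x)
}

#' Serialize a GA result to JSON
#'
#' @param result A `csa_ga`.
#' @param path Optional file path.
#' @return `path` invisibly, or the JSON string.
#' @export
ga_to_json <- function(result, path = NULL) {
  obj <- list(selected = result$selected,
              best_fitness = result$best_fitness,
              trajectory = result$trajectory,
              evaluations = result$evaluations,
              config = unclass(result$config))
  if (is.null(path))
    return(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                                         dataframe = "columns")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
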