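#' Pipeline run configuration
#'
#' Bundles everything a full run needs: the synthetic cohort specification,
#' the frozen subject-level train/test split (explicit id lists, mirroring
#' fixed clinical cohorts rather than an internal random split), GA and
#' tree settings, the threshold rule and the global seed. All per-stage
#' seeds are derived from the global seed via [derive_seed()].
#'
#' @param cohort A [cohort_spec()].
#' @param train_ids,test_ids Subject id character vectors; must be
#'   disjoint.
#' @param ga A [ga_config()].
#' @param threshold_rule `"fixed"` or `"youden"`.
#' @param fixed_threshold Threshold under the fixed rule.
#' @param render_images If `TRUE`, plate scans are rendered to PNG and
#'   re-quantified through the imaging path; otherwise the tabular
#'   (pre-quantified) path is used.
#' @param expansion Difference-map gain for report figures.
#' @param seed Global integer seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(cohort, train_ids, test_ids, ga = NULL,
                       threshold_rule = "fixed", fixed_threshold = 0.5,
                       render_images = FALSE, expansion = 4, seed = 1) {
  stopifnot(inherits(cohort, "cohort_spec"))
  if (length(intersect(train_ids, test_ids)) > 0)
    stop("train and test ids overlap: ",
         paste(intersect(train_ids, test_ids), collapse = ", "),
         call. = FALSE)
  if (is.null(ga)) ga <- ga_config(seed = derive_seed(seed, "ga"))
  structure(list(cohort = cohort, train_ids = train_ids,
                 test_ids = test_ids, ga = ga,
                 threshold_rule = threshold_rule,
                 fixed_threshold = fixed_threshold,
                 render_images = isTRUE(render_images),
                 expansion = expansion, seed = as.integer(seed)),
            class = "run_config")
}

#' Packaged demonstration configuration
#'
#' A planted-signal experiment at desk scale: a 190-compound array with 10
#' informative compounds at standardized effect size 2.0, 40 + 40 training
#' and 20 + 20 testing subjects (simulated as one 60 + 60 cohort whose
#' split is frozen before any model sees the data).
#'
#' @param seed Global seed.
#' @param effect_size Planted standardized effect size (set 0 for a null
#'   run).
#' @return A `run_config`.
#' @export
demo_config <- function(seed = 1, effect_size = 2.0) {
  spec <- cohort_spec(n_kd = 60, n_fc = 60, n_compounds = 190,
                      n_informative = 10, effect_size = effect_size,
                      seed = derive_seed(seed, "cohort"))
  ids <- sprintf("S%03d", seq_len(120))       # first 60 KD, next 60 FC
  run_config(spec,
             train_ids = c(ids[1:40], ids[61:100]),
             test_ids = c(ids[41:60], ids[101:120]),
             ga = ga_config(seed = derive_seed(seed, "ga")),
             seed = seed)
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with fields matching [run_config()] (the `cohort`
#'   and `ga` blocks are passed to [cohort_spec()] and [ga_config()]).
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(cohort = do.call(cohort_spec, y$cohort),
             train_ids = unlist(y$train_ids),
             test_ids = unlist(y$test_ids),
             ga = if (is.null(y$ga)) NULL else do.call(ga_config, y$ga),
             threshold_rule = y$threshold_rule %||% "fixed",
             fixed_threshold = y$fixed_threshold %||% 0.5,
             render_images = isTRUE(y$render_images),
             expansion = y$expansion %||% 4,
             seed = y$seed %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full diagnostic pipeline
#'
#' Executes simulate, quantify, normalize, select, train, evaluate and
#' report in order, writing every stage's output as a plain file (CSV, PNG,
#' JSON) under `outdir`, plus a run manifest with the config hash and md5
#' checksums of every artifact. The train/test split is subject-level and
#' frozen before selection: the GA and the final tree see only training
#' subjects, and testing subjects are scored exactly once by the final
#' model.
#'
#' @param config A `run_config`.
#' @param outdir Output directory (created; existing artifacts are
#'   overwritten).
#' @param report Generate the markdown report and figures (default TRUE).
#' @return An object of class `csa_run` (invisibly): the model, evaluation
#'   results, paths and manifest.
#' @export
run_pipeline <- function(config, outdir, report = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(...) message(sprintf(...))

  # -- simulate ------------------------------------------------------------
  cohort <- simulate_cohort(config$cohort)
  write_cohort(cohort, file.path(outdir, "cohort"))
  log_stage("simulate: %d subjects, %d compounds, %d informative",
            length(cohort$subjects), length(cohort$compounds),
            length(cohort$informative))

  # -- quantify ------------------------------------------------------------
  if (config$render_images) {
    layout <- default_layout(length(cohort$compounds),
                             compounds = cohort$compounds)
    write_layout(layout, file.path(outdir, "layout.yaml"))
    img_dir <- file.path(outdir, "images")
    dir.create(img_dir, showWarnings = FALSE)
    vectors <- lapply(cohort$subjects, function(s) {
      img <- render_plate_image(s, layout,
                                seed = derive_seed(config$seed,
                                                   paste0("img_",
                                                          s$subject_id)))
      write_plate_image(img, file.path(img_dir,
                                       paste0(s$subject_id, ".png")))
      q <- quantify_plate(img, layout)
      compute_difference_vector(q$sample_rgb, q$blank_rgb,
                                subject_id = s$subject_id)
    })
    tab <- assemble_feature_table(
      vectors,
      labels = vapply(cohort$subjects, `[[`, "", "label"),
      creatinine = vapply(cohort$subjects, `[[`, 0, "creatinine"))
  } else {
    tab <- cohort_feature_table(cohort)
  }
  write_feature_table(tab, file.path(outdir, "features_raw.csv"))
  log_stage("quantify: %d x %d feature table (%s path)",
            nrow(tab$values), ncol(tab$values),
            if (config$render_images) "imaging" else "tabular")

  # -- normalize -----------------------------------------------------------
  tab <- normalize_by_creatinine(tab)
  write_feature_table(tab, file.path(outdir, "features_normalized.csv"))

  train_tab <- subset_subjects(tab, config$train_ids)
  test_tab <- subset_subjects(tab, config$test_ids)
  log_stage("split: %d training, %d testing subjects",
            length(config$train_ids), length(config$test_ids))

  # -- select + train (training subjects only) ----------------------------
  model <- csa_train(train_tab, ga = config$ga,
                     threshold_rule = config$threshold_rule,
                     fixed_threshold = config$fixed_threshold)
  ga_to_json(model$ga, file.path(outdir, "ga_result.json"))
  utils::write.csv(model$ga$trajectory,
                   file.path(outdir, "ga_trajectory.csv"),
                   row.names = FALSE)
  tree_to_json(model$tree, file.path(outdir, "tree.json"))
  writeLines(utils::capture.output(print(model$tree)),
             file.path(outdir, "tree.txt"))
  log_stage("select: %d-compound panel, CV AUC %.4f",
            length(model$selected), model$ga$best_fitness)

  # -- evaluate (test subjects scored exactly once) -----------------------
  train_eval <- evaluate_model(model, train_tab)
  test_eval <- evaluate_model(model, test_tab)
  write_roc_csv <- function(roc, path)
    utils::write.csv(data.frame(threshold = roc$thresholds, tpr = roc$tpr,
                                fpr = roc$fpr), path, row.names = FALSE)
  write_roc_csv(train_eval$roc, file.path(outdir, "roc_train.csv"))
  write_roc_csv(test_eval$roc, file.path(outdir, "roc_test.csv"))
  recovered <- intersect(model$selected,
                         cohort$compounds[cohort$informative])
  summary <- list(
    n_train = length(config$train_ids), n_test = length(config$test_ids),
    selected_panel = model$selected,
    panel_size = length(model$selected),
    threshold = model$threshold, threshold_rule = config$threshold_rule,
    cv_auc = model$ga$best_fitness,
    train_auc = train_eval$auc,
    train_sensitivity_pct = 100 * train_eval$contingency$sensitivity,
    train_specificity_pct = 100 * train_eval$contingency$specificity,
    test_auc = test_eval$auc,
    test_sensitivity_pct = 100 * test_eval$contingency$sensitivity,
    test_specificity_pct = 100 * test_eval$contingency$specificity,
    test_contingency = test_eval$contingency[c("tp", "fn", "fp", "tn")],
    planted_informative = cohort$compounds[cohort$informative],
    planted_recovered = recovered,
    n_planted_recovered = length(recovered),
    seed = config$seed)
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(
    data.frame(subject_id = names(test_eval$scores),
               score = unname(test_eval$scores),
               label = ifelse(test_tab$labels == 1, "KD", "FC")),
    file.path(outdir, "test_scores.csv"), row.names = FALSE)
  log_stage("evaluate: held-out AUC %.4f (sens %.0f%%, spec %.0f%%)",
            test_eval$auc, 100 * test_eval$contingency$sensitivity,
            100 * test_eval$contingency$specificity)

  # -- report --------------------------------------------------------------
  if (report) generate_report(outdir, model = model, table = tab,
                              config = config)

  # -- manifest ------------------------------------------------------------
  manifest <- build_manifest(config, outdir)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(structure(list(model = model, summary = summary,
                           train_eval = train_eval, test_eval = test_eval,
                           cohort = cohort, table = tab,
                           outdir = outdir, manifest = manifest),
                      class = "csa_run"))
}

#' @export
print.csa_run <- function(x, ...) {
  cat("Sensor-array pipeline run:", x$outdir, "\n")
  cat(sprintf("  panel %d compounds; train AUC %.3f; held-out AUC %.3f\n",
              x$summary$panel_size, x$summary$train_auc,
              x$summary$test_auc))
  cat(sprintf("  held-out sensitivity %.0f%%, specificity %.0f%% at threshold %.2f\n",
              x$summary$test_sensitivity_pct,
              x$summary$test_specificity_pct, x$summary$threshold))
  invisible(x)
}

# Manifest: config hash plus md5 checksums of every artifact file
# (the manifest itself excluded). Timestamps are recorded but play no part
# in the checksums, so identical runs yield identical `files` maps.
build_manifest <- function(config, outdir) {
  rel <- sort(list.files(outdir, recursive = TRUE))
  rel <- rel[basename(rel) != "manifest.json"]
  sums <- tools::md5sum(file.path(outdir, rel))
  names(sums) <- rel
  list(config_hash = json_hash(unclass_recursive(config)),
       seed = config$seed,
       files = as.list(sums),
       versions = list(kdsense = as.character(
                         utils::packageVersion("kdsense")),
                       r = R.version.string),
       timestamp = format(Sys.time(), tz = "UTC"))
}

unclass_recursive <- function(x) {
  if (is.list(x)) return(lapply(unclass(x), unclass_recursive))
  x
}

#' Generate the markdown run report
#'
#' Builds `report.md` plus PNG figures from a finished run directory: the
#' GA selection trajectory, training and testing ROC curves with the
#' contingency table, box-whisker panels of the creatinine-normalized
#' response for every selected compound, and class-averaged expanded RGB
#' difference maps. Content is deterministic given the artifacts (no
#' timestamps in the body).
#'
#' @param outdir Run directory containing the stage artifacts.
#' @param model,table,config Optional in-memory objects from
#'   [run_pipeline()]; reconstructed from the artifacts when omitted.
#' @return Path of `report.md`, invisibly.
#' @export
generate_report <- function(outdir, model = NULL, table = NULL,
                            config = NULL) {
  need <- c("summary.json", "ga_trajectory.csv", "roc_train.csv",
            "roc_test.csv", "features_normalized.csv")
  missing <- need[!file.exists(file.path(outdir, need))]
  if (length(missing) > 0)
    stop("missing artifacts: ", paste(missing, collapse = ", "),
         call. = FALSE)
  s <- jsonlite::read_json(file.path(outdir, "summary.json"),
                           simplifyVector = TRUE)
  if (is.null(table))
    table <- read_feature_table(file.path(outdir,
                                          "features_normalized.csv"))
  fig_dir <- file.path(outdir, "figures")
  dir.create(fig_dir, showWarnings = FALSE)
  traj <- utils::read.csv(file.path(outdir, "ga_trajectory.csv"))
  fig <- function(name, expr, width = 600, height = 450) {
    grDevices::png(file.path(fig_dir, name), width = width, height = height)
    on.exit(grDevices::dev.off())
    expr
  }
  fig("ga_trajectory.png", {
    graphics::plot(traj$generation, traj$best, type = "l",
                   xlab = "Generation", ylab = "Mean CV AUC fitness",
                   main = "GA selection trajectory",
                   ylim = range(traj[c("best", "mean")]))
    graphics::lines(traj$generation, traj$mean, lty = 2, col = "grey40")
  })
  roc_fig <- function(file, title) {
    r <- utils::read.csv(file.path(outdir, file))
    graphics::plot(r$fpr, r$tpr, type = "s", xlim = c(0, 1), ylim = c(0, 1),
                   xlab = "1 - specificity", ylab = "Sensitivity",
                   main = title)
    graphics::abline(0, 1, lty = 3, col = "grey50")
  }
  fig("roc.png", {
    graphics::par(mfrow = c(1, 2))
    roc_fig("roc_train.csv", sprintf("Training ROC (AUC %.3f)",
                                     s$train_auc))
    roc_fig("roc_test.csv", sprintf("Testing ROC (AUC %.3f)", s$test_auc))
  }, width = 900)
  panel <- unlist(s$selected_panel)
  if (length(panel) > 0) {
    fig("box_whisker.png", {
      nc <- min(4, length(panel))
      graphics::par(mfrow = c(ceiling(length(panel) / nc), nc),
                    mar = c(2.5, 4, 2, 0.5))
      kd <- table$labels == 1L
      for (cp in panel) {
        ch <- paste0(cp, "_R")
        v <- table$values[, ch]
        graphics::boxplot(list(FC = v[!kd], KD = v[kd]), main = cp,
                          col = c("seagreen3", "violetred"),
                          ylab = "normalized response")
      }
    }, width = 900, height = 250 * ceiling(length(panel) / 4))
  }
  # class-averaged expanded difference maps from the raw features
  raw_path <- file.path(outdir, "features_raw.csv")
  if (file.exists(raw_path)) {
    raw <- read_feature_table(raw_path)
    kd <- raw$labels == 1L
    to_mat <- function(v) matrix(v, ncol = 3, byrow = TRUE,
                                 dimnames = list(raw$compounds,
                                                 c("R", "G", "B")))
    for (cls in c("KD", "FC")) {
      rows <- if (cls == "KD") kd else !kd
      m <- render_difference_map(to_mat(colMeans(raw$values[rows, ,
                                                            drop = FALSE])),
                                 expansion = if (is.null(config)) 4 else
                                   config$expansion,
                                 tile_px = 10)
      png::writePNG(clip8(m) / 255,
                    file.path(fig_dir, paste0("diffmap_", cls, ".png")))
    }
  }
  lines <- c(
    "# Urinary colorimetric sensor-array diagnostic run",
    "",
    sprintf("Training subjects: %d; testing subjects: %d.", s$n_train,
            s$n_test),
    "",
    "## Compound panel (GA selection)",
    "",
    if (s$panel_size == 0)
      "No compounds were selected (empty panel)." else
      sprintf("Selected %d compounds: %s.", s$panel_size,
              paste(panel, collapse = ", ")),
    sprintf("Best mean cross-validated AUC during selection: %.4f.",
            s$cv_auc),
    "",
    "![GA trajectory](figures/ga_trajectory.png)",
    "",
    "## Classification performance",
    "",
    sprintf("Training (resubstitution) AUC: %.4f.", s$train_auc),
    sprintf(paste0("Held-out testing AUC: %.4f; sensitivity %.1f%%, ",
                   "specificity %.1f%% at threshold %.2f (%s rule)."),
            s$test_auc, s$test_sensitivity_pct, s$test_specificity_pct,
            s$threshold, s$threshold_rule),
    "",
    "Held-out contingency table (rows: predicted, columns: true):",
    "",
    "| | KD | FC |",
    "|---|---|---|",
    sprintf("| predicted KD | %d | %d |", s$test_contingency$tp,
            s$test_contingency$fp),
    sprintf("| predicted FC | %d | %d |", s$test_contingency$fn,
            s$test_contingency$tn),
    "",
    "![ROC](figures/roc.png)",
    "",
    "## Normalized responses of the selected panel",
    "",
    if (s$panel_size == 0)
      "No per-compound panels: the selected panel is empty." else
      "![Box-whisker panels](figures/box_whisker.png)",
    "",
    "## Expanded RGB difference maps (class averages)",
    "",
    "![KD](figures/diffmap_KD.png) ![FC](figures/diffmap_FC.png)",
    "")
  if (!is.null(s$planted_informative) &&
      length(unlist(s$planted_informative)) > 0)
    lines <- c(lines,
      "## Synthetic ground truth",
      "",
      sprintf("Planted informative compounds: %s.",
              paste(unlist(s$planted_informative), collapse = ", ")),
      sprintf("Recovered by the selected panel: %d of %d.",
              s$n_planted_recovered,
              length(unlist(s$planted_informative))),
      "")
  writeLines(lines, file.path(outdir, "report.md"))
  invisible(file.path(outdir, "report.md"))
}
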