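#' Specification of a synthetic urine sensor-array cohort
#'
#' Defines the statistical structure of a simulated two-class cohort
#' (Kawasaki disease vs. febrile control) read out on a colorimetric sensor
#' array. Each subject carries a per-compound matrix of pre-noise RGB
#' color-difference responses (sample minus saline blank, 8-bit intensity
#' units). A planted subset of `n_informative` compounds shifts its mean
#' response in the KD class by `effect_size * noise_sd` on one designated
#' channel, i.e. `effect_size` is a standardized (Cohen's d) shift. A
#' per-subject urine dilution factor, log-normal with median 1, multiplies
#' the analyte-driven responses and the urinary creatinine concentration
#' alike -- the mechanism that creatinine normalization is designed to
#' cancel.
#'
#' @param n_kd,n_fc Subjects per class.
#' @param n_compounds Number of candidate sensing compounds on the array.
#' @param n_informative Number of planted class-informative compounds.
#' @param effect_size Standardized mean shift (Cohen's d) per informative
#'   compound on the designated channel.
#' @param noise_sd Per-subject measurement noise s.d., 8-bit intensity units.
#' @param dilution_log_sd S.d. of the log of the dilution factor.
#' @param creatinine_baseline Pre-dilution urinary creatinine, mg/dL.
#' @param informative_channel Channel carrying the planted shift:
#'   `"R"`, `"G"` or `"B"`.
#' @param seed Integer RNG seed; identical seeds give bit-identical cohorts.
#' @return An object of class `cohort_spec`.
#' @seealso [simulate_cohort()]
#' @export
cohort_spec <- function(n_kd = 33, n_fc = 33, n_compounds = 190,
                        n_informative = 10, effect_size = 2,
                        noise_sd = 5, dilution_log_sd = 0.4,
                        creatinine_baseline = 100,
                        informative_channel = "R", seed = 1) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  check_field(num1(n_kd) && n_kd >= 1, "n_kd", "must be a count >= 1")
  check_field(num1(n_fc) && n_fc >= 1, "n_fc", "must be a count >= 1")
  check_field(num1(n_compounds) && n_compounds >= 1, "n_compounds",
              "must be a count >= 1")
  check_field(num1(n_informative) && n_informative >= 0, "n_informative",
              "must be a count >= 0")
  check_field(n_informative <= n_compounds, "n_informative",
              "must not exceed n_compounds")
  check_field(num1(effect_size) && effect_size >= 0, "effect_size",
              "must be >= 0")
  check_field(num1(noise_sd) && noise_sd >= 0, "noise_sd", "must be >= 0")
  check_field(num1(dilution_log_sd) && dilution_log_sd >= 0,
              "dilution_log_sd", "must be >= 0")
  check_field(num1(creatinine_baseline) && creatinine_baseline > 0,
              "creatinine_baseline", "must be > 0")
  check_field(is.character(informative_channel) &&
              all(informative_channel %in% c("R", "G", "B")),
              "informative_channel", "must be one or more of 'R','G','B'")
  check_field(num1(seed), "seed", "must be a single integer")
  structure(list(n_kd = as.integer(n_kd), n_fc = as.integer(n_fc),
                 n_compounds = as.integer(n_compounds),
                 n_informative = as.integer(n_informative),
                 effect_size = effect_size, noise_sd = noise_sd,
                 dilution_log_sd = dilution_log_sd,
                 creatinine_baseline = creatinine_baseline,
                 informative_channel = informative_channel,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort specification\n")
  cat(sprintf("  subjects: %d KD + %d FC\n", x$n_kd, x$n_fc))
  cat(sprintf("  compounds: %d (%d informative, d = %.2f on channel %s)\n",
              x$n_compounds, x$n_informative, x$effect_size,
              paste(x$informative_channel, collapse = "+")))
  cat(sprintf("  noise sd %.2f, dilution log-sd %.2f, creatinine %.0f mg/dL, seed %d\n",
              x$noise_sd, x$dilution_log_sd, x$creatinine_baseline, x$seed))
  invisible(x)
}

#' Simulate a synthetic KD/FC cohort
#'
#' Draws a cohort under a [cohort_spec()]. Every compound has a fixed
#' baseline color response common to both classes; informative compounds
#' additionally shift the KD mean by `effect_size * noise_sd` on the
#' designated channel. Each subject's pre-noise response matrix and
#' creatinine concentration are both multiplied by the same log-normal
#' dilution factor, so dividing responses by creatinine removes dilution
#' exactly by construction.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `csa_cohort`: a list with `subjects` (each a
#'   list with `subject_id`, `label`, `dilution`, `creatinine`,
#'   `true_response` as an `n_compounds` x 3 matrix), `compounds`,
#'   `informative` (ground-truth planted indices) and the `spec`.
#' @export
simulate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) spec <- do.call(cohort_spec, spec)
  with_seed(spec$seed, {
    n <- spec$n_kd + spec$n_fc
    N <- spec$n_compounds
    compounds <- sprintf("C%03d", seq_len(N))
    channels <- c("R", "G", "B")
    # compound-characteristic baseline response, shared by both classes
    mu <- matrix(stats::runif(3L * N, -20, 20), N, 3,
                 dimnames = list(compounds, channels))
    informative <- if (spec$n_informative > 0)
      sort(sample.int(N, spec$n_informative)) else integer(0)
    shift <- matrix(0, N, 3, dimnames = dimnames(mu))
    shift[informative, match(spec$informative_channel, channels)] <-
      spec$effect_size * spec$noise_sd
    labels <- c(rep("KD", spec$n_kd), rep("FC", spec$n_fc))
    subjects <- vector("list", n)
    for (i in seq_len(n)) {
      eps <- matrix(stats::rnorm(3L * N, 0, spec$noise_sd), N, 3,
                    dimnames = dimnames(mu))
      dilution <- exp(stats::rnorm(1L, 0, spec$dilution_log_sd))
      base <- mu + eps + if (labels[i] == "KD") shift else 0
      subjects[[i]] <- list(
        subject_id = sprintf("S%03d", i),
        label = labels[i],
        dilution = dilution,
        creatinine = spec$creatinine_baseline * dilution,
        true_response = base * dilution)
    }
    structure(list(subjects = subjects, compounds = compounds,
                   informative = informative, spec = spec),
              class = "csa_cohort")
  })
}

#' @export
print.csa_cohort <- function(x, ...) {
  labs <- vapply(x$subjects, `[[`, "", "label")
  cat(sprintf("Synthetic sensor-array cohort: %d subjects (%d KD, %d FC), %d compounds\n",
              length(labs), sum(labs == "KD"), sum(labs == "FC"),
              length(x$compounds)))
  cat(sprintf("  planted informative compounds: %s\n",
              if (length(x$informative) == 0) "none"
              else paste(x$compounds[x$informative], collapse = ", ")))
  invisible(x)
}

#' Cohort subject table
#'
#' @param x A `csa_cohort`.
#' @param ... Unused.
#' @return A data frame with one row per subject: id, label, creatinine,
#'   dilution.
#' @export
as.data.frame.csa_cohort <- function(x, ...) {
  data.frame(
    subject_id = vapply(x$subjects, `[[`, "", "subject_id"),
    label = vapply(x$subjects, `[[`, "", "label"),
    creatinine = vapply(x$subjects, `[[`, 0, "creatinine"),
    dilution = vapply(x$subjects, `[[`, 0, "dilution"),
    stringsAsFactors = FALSE)
}

#' Write a cohort to plain-text files
#'
#' Writes `cohort.csv` (one row per subject), per-subject response CSVs
#' (`responses/<id>.csv` with columns compound, dR, dG, dB), the spec as
#' YAML, and a small run-manifest JSON recording the seed and ground truth.
#'
#' @param cohort A `csa_cohort`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "csa_cohort"))
  dir.create(file.path(dir, "responses"), recursive = TRUE,
             showWarnings = FALSE)
  utils::write.csv(as.data.frame(cohort), file.path(dir, "cohort.csv"),
                   row.names = FALSE)
  for (s in cohort$subjects) {
    df <- data.frame(compound = cohort$compounds,
                     dR = s$true_response[, "R"],
                     dG = s$true_response[, "G"],
                     dB = s$true_response[, "B"])
    utils::write.csv(df, file.path(dir, "responses",
                                   paste0(s$subject_id, ".csv")),
                     row.names = FALSE)
  }
  yaml::write_yaml(unclass(cohort$spec), file.path(dir, "spec.yaml"))
  jsonlite::write_json(
    list(seed = cohort$spec$seed,
         informative_compounds = cohort$compounds[cohort$informative]),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `cohort.csv`, `responses/` and
#'   `spec.yaml`.
#' @return A `csa_cohort`.
#' @export
read_cohort <- function(dir) {
  tab <- utils::read.csv(file.path(dir, "cohort.csv"),
                         stringsAsFactors = FALSE)
  spec <- do.call(cohort_spec, yaml::read_yaml(file.path(dir, "spec.yaml")))
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  subjects <- lapply(seq_len(nrow(tab)), function(i) {
    df <- utils::read.csv(file.path(dir, "responses",
                                    paste0(tab$subject_id[i], ".csv")),
                          stringsAsFactors = FALSE)
    resp <- as.matrix(df[, c("dR", "dG", "dB")])
    dimnames(resp) <- list(df$compound, c("R", "G", "B"))
    list(subject_id = tab$subject_id[i], label = tab$label[i],
         dilution = tab$dilution[i], creatinine = tab$creatinine[i],
         true_response = resp)
  })
  compounds <- rownames(subjects[[1]]$true_response)
  structure(list(subjects = subjects, compounds = compounds,
                 informative = match(unlist(gt$informative_compounds),
                                     compounds),
                 spec = spec),
            class = "csa_cohort")
}
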