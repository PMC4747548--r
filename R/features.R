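#' Assemble the subjects x (3N) feature table
#'
#' Stacks per-subject color-difference vectors into a single feature matrix
#' with one column per compound-channel pair, named `<compound>_<channel>`
#' in compound-major order (C001_R, C001_G, C001_B, C002_R, ...). Compound
#' order must be identical across subjects; mismatches are an error, never
#' silently reordered.
#'
#' @param vectors List of `color_difference` objects, one per subject.
#' @param labels Class labels, `"KD"`/`"FC"` or 1/0 (KD = 1), one per
#'   subject.
#' @param creatinine Urinary creatinine (mg/dL), one per subject.
#' @return An object of class `feature_table`: list with `subject_ids`,
#'   `labels` (integer 0/1), `values` (subjects x 3N matrix), `creatinine`,
#'   `compounds`, `normalized` flag.
#' @export
assemble_feature_table <- function(vectors, labels, creatinine) {
  stopifnot(length(vectors) >= 1,
            all(vapply(vectors, inherits, TRUE, "color_difference")))
  n <- length(vectors)
  if (length(labels) != n || length(creatinine) != n)
    stop("one label and one creatinine value per subject required",
         call. = FALSE)
  ids <- vapply(vectors, `[[`, "", "subject_id")
  if (anyDuplicated(ids))
    stop("duplicate subject id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  compounds <- vectors[[1]]$compounds
  for (v in vectors)
    if (!identical(v$compounds, compounds))
      stop("alignment error: compound order of subject '", v$subject_id,
           "' differs from the first subject", call. = FALSE)
  N <- length(compounds)
  values <- matrix(NA_real_, n, 3L * N)
  for (i in seq_len(n))
    values[i, ] <- as.vector(t(vectors[[i]]$deltas))  # compound-major R,G,B
  colnames(values) <- paste0(rep(compounds, each = 3), "_",
                             rep(c("R", "G", "B"), N))
  rownames(values) <- ids
  structure(list(subject_ids = ids, labels = as_binary_labels(labels),
                 values = values, creatinine = as.numeric(creatinine),
                 compounds = compounds, normalized = FALSE),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("Feature table: %d subjects (%d KD, %d FC) x %d features (%d compounds)%s\n",
              length(x$subject_ids), sum(x$labels == 1), sum(x$labels == 0),
              ncol(x$values), length(x$compounds),
              if (x$normalized) ", creatinine-normalized" else ", raw"))
  invisible(x)
}

#' Creatinine normalization of sensor-array features
#'
#' Divides every feature of every subject (all three channels of every
#' compound) by that subject's urinary creatinine concentration, correcting
#' the multiplicative urine-dilution effect of differing hydration states.
#' Units change from intensity to intensity per (mg/dL). Guarded against
#' double application: normalizing an already-normalized table is an error,
#' never a silent second division.
#'
#' @param table A [assemble_feature_table()] result.
#' @return The table with `values` divided row-wise by creatinine and the
#'   `normalized` flag set.
#' @export
normalize_by_creatinine <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (isTRUE(table$normalized))
    stop("state error: feature table is already creatinine-normalized",
         call. = FALSE)
  bad <- !is.finite(table$creatinine) | table$creatinine <= 0
  if (any(bad))
    stop("creatinine must be > 0; offending subjects: ",
         paste(table$subject_ids[bad], collapse = ", "), call. = FALSE)
  table$values <- table$values / table$creatinine
  table$normalized <- TRUE
  table
}

#' Subset a feature table by subject id
#'
#' @param table A `feature_table`.
#' @param ids Subject ids to keep, in the given order.
#' @return A `feature_table` restricted to `ids`.
#' @export
subset_subjects <- function(table, ids) {
  stopifnot(inherits(table, "feature_table"))
  idx <- match(ids, table$subject_ids)
  if (anyNA(idx))
    stop("unknown subject ids: ", paste(ids[is.na(idx)], collapse = ", "),
         call. = FALSE)
  table$subject_ids <- table$subject_ids[idx]
  table$labels <- table$labels[idx]
  table$creatinine <- table$creatinine[idx]
  table$values <- table$values[idx, , drop = FALSE]
  table
}

# Column indices of the features belonging to a compound mask
# (logical length-N or integer compound indices).
mask_columns <- function(table, mask) {
  idx <- if (is.logical(mask)) which(mask) else as.integer(mask)
  as.vector(vapply(idx, function(j) (j - 1L) * 3L + 1:3, integer(3)))
}

#' Write / read a feature table as CSV plus a JSON schema sidecar
#'
#' The CSV has one row per subject (columns: subject_id, label, creatinine,
#' then the 3N features); the sidecar records compound order, channel
#' order and normalization state so a round trip is lossless.
#'
#' @param table A `feature_table`.
#' @param path CSV path; the sidecar is `<path>.schema.json`.
#' @return `path` (write) or a `feature_table` (read).
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- data.frame(subject_id = table$subject_ids,
                   label = ifelse(table$labels == 1, "KD", "FC"),
                   creatinine = table$creatinine,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(table$values, optional = TRUE))
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(compounds = table$compounds,
                            channels = c("R", "G", "B"),
                            normalized = table$normalized,
                            feature_names = colnames(table$values)),
                       paste0(path, ".schema.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  schema <- jsonlite::read_json(paste0(path, ".schema.json"),
                                simplifyVector = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  values <- as.matrix(df[, schema$feature_names, drop = FALSE])
  rownames(values) <- df$subject_id
  structure(list(subject_ids = df$subject_id,
                 labels = as_binary_labels(df$label),
                 values = values, creatinine = df$creatinine,
                 compounds = schema$compounds,
                 normalized = isTRUE(schema$normalized)),
            class = "feature_table")
}

#' Feature table from a synthetic cohort
#'
#' Convenience path from [simulate_cohort()] straight to a raw (still
#' unnormalized) feature table. Responses are quantized to the 8-bit scale
#' the imaging path would deliver: `round(clip(blank + delta)) - blank`
#' with a mid-gray 128 blank, so the tabular and imaging routes agree.
#'
#' @param cohort A `csa_cohort`.
#' @param quantize Apply 8-bit quantization (default TRUE).
#' @param blank_level Blank intensity used for quantization.
#' @return A raw `feature_table`.
#' @export
cohort_feature_table <- function(cohort, quantize = TRUE,
                                 blank_level = 128) {
  stopifnot(inherits(cohort, "csa_cohort"))
  vectors <- lapply(cohort$subjects, function(s) {
    d <- s$true_response
    if (quantize) d <- clip8(round(blank_level + d)) - blank_level
    compute_difference_vector(d, blank_rgb = c(0, 0, 0),
                              compounds = cohort$compounds,
                              subject_id = s$subject_id)
  })
  assemble_feature_table(
    vectors,
    labels = vapply(cohort$subjects, `[[`, "", "label"),
    creatinine = vapply(cohort$subjects, `[[`, 0, "creatinine"))
}
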