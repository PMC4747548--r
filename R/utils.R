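#' Derive a named sub-seed from a global seed
#'
#' Every stochastic stage of the pipeline draws its own seed from the global
#' run seed plus a stage label, so that stages are independently reproducible
#' and no two stages share an RNG stream. The result is always a non-negative
#' integer below 2^31.
#'
#' @param seed Integer global seed.
#' @param label Character stage label (e.g. `"cohort"`, `"ga"`).
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  codes <- utf8ToInt(label)
  h <- sum(codes * seq_along(codes)) %% 19993L
  as.integer((abs(as.integer(seed)) %% 100000L) * 19993L + h)
}

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Clip numeric data to the 8-bit intensity range (dims preserved).
clip8 <- function(x) {
  x[] <- pmin(255, pmax(0, x))
  x
}

# Validation helper: stop with a message naming the offending field.
check_field <- function(ok, field, what) {
  if (!isTRUE(ok)) stop(sprintf("invalid field '%s': %s", field, what),
                        call. = FALSE)
}

# Binary labels in canonical 0/1 integer form (KD = 1, FC = 0).
as_binary_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    bad <- setdiff(unique(labels), c("KD", "FC"))
    if (length(bad) > 0)
      stop("labels must be 'KD'/'FC' or 0/1; found: ",
           paste(bad, collapse = ", "), call. = FALSE)
    return(as.integer(labels == "KD"))
  }
  if (is.logical(labels)) return(as.integer(labels))
  if (!all(labels %in% c(0, 1)))
    stop("numeric labels must be 0 (FC) or 1 (KD)", call. = FALSE)
  as.integer(labels)
}

# md5 of an in-memory object via its serialized JSON (used for config hashes).
json_hash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(x, tf, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tf))
}
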