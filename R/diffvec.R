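#' Color-difference vector: sample minus blank, per compound and channel
#'
#' The core feature object: signed per-compound RGB deltas between the
#' sample-exposed spot colors and the saline-blank color, giving `3 * N`
#' scalar features per subject. No absolute value and no clipping is
#' applied; deltas are antisymmetric under swapping sample and blank.
#'
#' @param sample_rgb `N x 3` matrix of spot colors (rownames optional).
#' @param blank_rgb Either a length-3 vector (one plate blank) or an
#'   `N x 3` matrix of per-compound blanks.
#' @param compounds Compound names; defaults to `sample_rgb` rownames.
#' @param subject_id Subject identifier carried with the vector.
#' @return An object of class `color_difference` with fields `subject_id`,
#'   `compounds` and `deltas` (`N x 3`, columns R, G, B).
#' @export
compute_difference_vector <- function(sample_rgb, blank_rgb,
                                      compounds = rownames(sample_rgb),
                                      subject_id = "sample") {
  sample_rgb <- as.matrix(sample_rgb)
  if (ncol(sample_rgb) != 3)
    stop("shape error: sample_rgb must have 3 columns (R, G, B)",
         call. = FALSE)
  n <- nrow(sample_rgb)
  if (is.null(compounds)) compounds <- sprintf("C%03d", seq_len(n))
  if (length(compounds) != n)
    stop("shape error: ", length(compounds), " compound names for ", n,
         " rows", call. = FALSE)
  if (is.matrix(blank_rgb)) {
    if (!all(dim(blank_rgb) == c(n, 3)))
      stop("shape error: per-compound blank must be ", n, " x 3",
           call. = FALSE)
    deltas <- sample_rgb - blank_rgb
  } else {
    if (length(blank_rgb) != 3)
      stop("shape error: blank_rgb must be length 3 or an N x 3 matrix",
           call. = FALSE)
    deltas <- sweep(sample_rgb, 2, blank_rgb)
  }
  dimnames(deltas) <- list(compounds, c("R", "G", "B"))
  structure(list(subject_id = subject_id, compounds = compounds,
                 deltas = deltas),
            class = "color_difference")
}

#' @export
print.color_difference <- function(x, ...) {
  cat(sprintf("Color-difference vector '%s': %d compounds (3x%d features)\n",
              x$subject_id, length(x$compounds), length(x$compounds)))
  cat(sprintf("  delta range [%.1f, %.1f]\n", min(x$deltas), max(x$deltas)))
  invisible(x)
}

#' Render an expanded RGB difference map
#'
#' Visualizes a color-difference vector as a grid of colored tiles, one per
#' compound in compound order (row-major). Signed deltas are centered on
#' mid-gray so both directions of color change are visible:
#' `tile = clip(128 + expansion * delta, 0, 255)` per channel. Within the
#' non-clipped range the map at `expansion = 1` is invertible; see
#' [map_to_deltas()].
#'
#' @param x A `color_difference` (or bare `N x 3` delta matrix).
#' @param expansion Gain factor applied to deltas (> 0).
#' @param tile_px Tile side length in pixels.
#' @param ncol Tiles per row; default is the ceiling of the square root.
#' @return Integer RGB array with attributes `tile_px`, `expansion`,
#'   `grid` (tile rows/cols) and `compounds`.
#' @export
render_difference_map <- function(x, expansion = 4, tile_px = 8,
                                  ncol = NULL) {
  deltas <- if (inherits(x, "color_difference")) x$deltas else as.matrix(x)
  check_field(expansion > 0, "expansion", "must be > 0")
  n <- nrow(deltas)
  if (is.null(ncol)) ncol <- ceiling(sqrt(n))
  nrow_t <- ceiling(n / ncol)
  tiles <- clip8(round(128 + expansion * deltas))
  img <- array(0L, dim = c(nrow_t * tile_px, ncol * tile_px, 3))
  for (j in seq_len(n)) {
    tr <- (j - 1) %/% ncol
    tc <- (j - 1) %% ncol
    ys <- tr * tile_px + seq_len(tile_px)
    xs <- tc * tile_px + seq_len(tile_px)
    for (ch in 1:3) img[ys, xs, ch] <- tiles[j, ch]
  }
  structure(img, tile_px = tile_px, expansion = expansion,
            grid = c(rows = nrow_t, cols = ncol), n = n,
            compounds = rownames(deltas))
}

#' Invert a difference map back to deltas
#'
#' Reads the tile colors of a map produced by [render_difference_map()] and
#' reconstructs `delta = (tile - 128) / expansion`. Exact for integer
#' deltas at `expansion = 1` within the non-clipped range
#' `[-128, 127]`.
#'
#' @param map Array from [render_difference_map()].
#' @return `N x 3` delta matrix.
#' @export
map_to_deltas <- function(map) {
  tile_px <- attr(map, "tile_px")
  expansion <- attr(map, "expansion")
  grid <- attr(map, "grid")
  n <- attr(map, "n")
  stopifnot(!is.null(tile_px), !is.null(expansion), !is.null(n))
  deltas <- matrix(0, n, 3, dimnames = list(attr(map, "compounds"),
                                            c("R", "G", "B")))
  for (j in seq_len(n)) {
    tr <- (j - 1) %/% grid["cols"]
    tc <- (j - 1) %% grid["cols"]
    y <- tr * tile_px + 1
    x <- tc * tile_px + 1
    deltas[j, ] <- (map[y, x, ] - 128) / expansion
  }
  deltas
}

#' Write / read per-subject difference vectors as CSV
#'
#' Columns: compound, dR, dG, dB.
#'
#' @param x A `color_difference`.
#' @param path CSV path.
#' @param subject_id Subject id to attach on read.
#' @return `path` (write) or a `color_difference` (read).
#' @export
write_difference_csv <- function(x, path) {
  stopifnot(inherits(x, "color_difference"))
  utils::write.csv(data.frame(compound = x$compounds,
                              dR = x$deltas[, "R"],
                              dG = x$deltas[, "G"],
                              dB = x$deltas[, "B"]),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_difference_csv
#' @export
read_difference_csv <- function(path, subject_id = basename(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  deltas <- as.matrix(df[, c("dR", "dG", "dB")])
  dimnames(deltas) <- list(df$compound, c("R", "G", "B"))
  compute_difference_vector(sweep(deltas, 2, c(0, 0, 0)),
                            blank_rgb = c(0, 0, 0),
                            compounds = df$compound,
                            subject_id = sub("\\.csv$", "", subject_id))
}
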