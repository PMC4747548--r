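#' Sampling geometry of a plate scan
#'
#' Locates well centers on a scanned plate raster. Pixel coordinates are
#' 1-based with origin at the top-left; `x` runs along columns, `y` along
#' rows. The center of well (row, col) (0-based grid indices) is at
#' `(origin_x + col * pitch_px, origin_y + row * pitch_px)`.
#'
#' @param origin_x,origin_y Pixel coordinates of the center of well (0, 0).
#' @param pitch_px Center-to-center well spacing in pixels.
#' @param spot_radius_px Sampling radius in pixels.
#' @param rows,cols Well-grid dimensions.
#' @return An object of class `grid_geometry`.
#' @export
grid_geometry <- function(origin_x, origin_y, pitch_px, spot_radius_px,
                          rows, cols) {
  check_field(pitch_px > 0, "pitch_px", "must be > 0")
  check_field(spot_radius_px > 0, "spot_radius_px", "must be > 0")
  check_field(rows >= 1 && cols >= 1, "rows/cols", "must be >= 1")
  structure(list(origin_x = origin_x, origin_y = origin_y,
                 pitch_px = pitch_px, spot_radius_px = spot_radius_px,
                 rows = as.integer(rows), cols = as.integer(cols)),
            class = "grid_geometry")
}

well_center <- function(geometry, row, col) {
  c(x = geometry$origin_x + col * geometry$pitch_px,
    y = geometry$origin_y + row * geometry$pitch_px)
}

#' Render a subject's plate scan as an 8-bit RGB raster
#'
#' Paints each compound well as a disk of color
#' `blank_rgb + true_response[j, ]` and each blank well as `blank_rgb`, on a
#' uniform background, then adds optional per-pixel Gaussian noise and
#' rounds/clips to 8-bit integers. This is the fixture generator emulating a
#' flatbed scan of the sensor array; with `noise_sd = 0` the rendered plate
#' round-trips exactly through [quantify_plate()] (after integer clipping).
#'
#' @param subject A subject from [simulate_cohort()] (needs
#'   `true_response`), or an `n x 3` response matrix with compound rownames.
#' @param layout A [plate_layout()].
#' @param spot_radius_px,pitch_px,margin_px Disk radius, well pitch and
#'   outer margin in pixels; `pitch_px` must be at least `2 * spot_radius_px`.
#' @param background_rgb,blank_rgb Background and saline-blank colors,
#'   length-3 RGB in 0..255.
#' @param noise_sd Per-pixel Gaussian noise s.d. (intensity units).
#' @param seed Optional seed for the noise draw.
#' @return An integer array `height x width x 3` in 0..255, with the
#'   matching [grid_geometry()] attached as attribute `"geometry"`.
#' @export
render_plate_image <- function(subject, layout, spot_radius_px = 4,
                               pitch_px = 12, margin_px = pitch_px,
                               background_rgb = c(40, 40, 40),
                               blank_rgb = c(128, 128, 128),
                               noise_sd = 0, seed = NULL) {
  stopifnot(inherits(layout, "plate_layout"))
  resp <- if (is.list(subject) && !is.null(subject$true_response))
    subject$true_response else subject
  stopifnot(is.matrix(resp), ncol(resp) == 3)
  if (pitch_px < 2 * spot_radius_px)
    stop("geometry error: pitch_px < 2 * spot_radius_px (spots overlap)",
         call. = FALSE)
  width  <- 2L * margin_px + (layout$cols - 1L) * pitch_px + 1L
  height <- 2L * margin_px + (layout$rows - 1L) * pitch_px + 1L
  geometry <- grid_geometry(origin_x = margin_px + 1, origin_y = margin_px + 1,
                            pitch_px = pitch_px,
                            spot_radius_px = spot_radius_px,
                            rows = layout$rows, cols = layout$cols)
  img <- array(rep(background_rgb, each = height * width),
               dim = c(height, width, 3))
  paint <- function(row, col, color) {
    ctr <- well_center(geometry, row, col)
    xs <- seq(max(1, floor(ctr["x"] - spot_radius_px)),
              min(width, ceiling(ctr["x"] + spot_radius_px)))
    ys <- seq(max(1, floor(ctr["y"] - spot_radius_px)),
              min(height, ceiling(ctr["y"] + spot_radius_px)))
    d2 <- outer((ys - ctr["y"])^2, (xs - ctr["x"])^2, `+`)
    inside <- d2 <= spot_radius_px^2
    for (ch in 1:3) {
      plane <- img[ys, xs, ch]
      plane[inside] <- color[ch]
      img[ys, xs, ch] <<- plane
    }
  }
  cw <- layout$compound_wells
  lookup <- match(cw$compound, rownames(resp))
  if (anyNA(lookup))
    stop("layout compounds missing from response matrix: ",
         paste(cw$compound[is.na(lookup)], collapse = ", "), call. = FALSE)
  for (i in seq_len(nrow(cw)))
    paint(cw$row[i], cw$col[i], blank_rgb + resp[lookup[i], ])
  bw <- layout$blank_wells
  for (i in seq_len(nrow(bw)))
    paint(bw$row[i], bw$col[i], blank_rgb)
  if (noise_sd > 0) {
    noise <- if (is.null(seed))
      stats::rnorm(length(img), 0, noise_sd)
    else with_seed(seed, stats::rnorm(length(img), 0, noise_sd))
    img <- img + noise
  }
  img <- array(as.integer(round(clip8(img))), dim = dim(img))
  attr(img, "geometry") <- geometry
  img
}

#' Extract the RGB readout of one well
#'
#' Returns the channel-wise median over all pixels whose center lies within
#' `spot_radius_px` of the well center. The median makes the readout robust
#' to dust and specular artifacts covering less than half the spot.
#'
#' @param image 8-bit RGB array (`height x width x 3`).
#' @param geometry A [grid_geometry()].
#' @param row,col 0-based well indices.
#' @return Numeric length-3 vector `(R, G, B)`.
#' @export
extract_spot_rgb <- function(image, geometry, row, col) {
  stopifnot(inherits(geometry, "grid_geometry"),
            length(dim(image)) == 3, dim(image)[3] == 3)
  if (row < 0 || row >= geometry$rows || col < 0 || col >= geometry$cols)
    stop(sprintf("geometry error: well (%d, %d) outside %dx%d grid",
                 row, col, geometry$rows, geometry$cols), call. = FALSE)
  ctr <- well_center(geometry, row, col)
  r <- geometry$spot_radius_px
  h <- dim(image)[1]; w <- dim(image)[2]
  if (ctr["x"] - r < 1 || ctr["x"] + r > w ||
      ctr["y"] - r < 1 || ctr["y"] + r > h)
    stop("geometry error: sampling disk exceeds raster bounds", call. = FALSE)
  xs <- seq(floor(ctr["x"] - r), ceiling(ctr["x"] + r))
  ys <- seq(floor(ctr["y"] - r), ceiling(ctr["y"] + r))
  d2 <- outer((ys - ctr["y"])^2, (xs - ctr["x"])^2, `+`)
  inside <- d2 <= r^2
  vapply(1:3, function(ch) stats::median(image[ys, xs, ch][inside]), 0)
}

#' Quantify a full plate scan
#'
#' Extracts every compound well and every blank well of `layout` from
#' `image`. The plate blank is the channel-wise median across blank wells
#' of their per-well medians (one saline blank per plate by default; pass
#' the returned matrices to [compute_difference_vector()]).
#'
#' @param image 8-bit RGB array.
#' @param geometry A [grid_geometry()]; defaults to the one attached to a
#'   raster produced by [render_plate_image()].
#' @param layout A [plate_layout()].
#' @return A list with `sample_rgb` (`n_compounds x 3`, rownames =
#'   compounds) and `blank_rgb` (length-3 median blank color).
#' @export
quantify_plate <- function(image, layout, geometry = attr(image, "geometry")) {
  stopifnot(inherits(layout, "plate_layout"))
  if (is.null(geometry))
    stop("no grid_geometry supplied and none attached to the image",
         call. = FALSE)
  cw <- layout$compound_wells
  sample_rgb <- t(vapply(seq_len(nrow(cw)), function(i)
    extract_spot_rgb(image, geometry, cw$row[i], cw$col[i]), numeric(3)))
  dimnames(sample_rgb) <- list(cw$compound, c("R", "G", "B"))
  bw <- layout$blank_wells
  blanks <- t(vapply(seq_len(nrow(bw)), function(i)
    extract_spot_rgb(image, geometry, bw$row[i], bw$col[i]), numeric(3)))
  blank_rgb <- apply(blanks, 2, stats::median)
  names(blank_rgb) <- c("R", "G", "B")
  list(sample_rgb = sample_rgb, blank_rgb = blank_rgb)
}

#' Read / write an 8-bit RGB plate image (PNG or TIFF)
#'
#' @param path File path; format chosen by extension (`.png`, `.tif`,
#'   `.tiff`).
#' @param image Integer RGB array in 0..255.
#' @return `read_plate_image`: an integer `height x width x 3` array in
#'   0..255. `write_plate_image`: `path`, invisibly.
#' @export
read_plate_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext, call. = FALSE))
  if (length(dim(raw)) == 2) raw <- array(rep(raw, 3), c(dim(raw), 3))
  if (dim(raw)[3] > 3) raw <- raw[, , 1:3]
  array(as.integer(round(raw * 255)), dim = dim(raw))
}

#' @rdname read_plate_image
#' @export
write_plate_image <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  norm <- clip8(image) / 255
  switch(ext,
    png = png::writePNG(norm, path),
    tif = ,
    tiff = tiff::writeTIFF(norm, path, bits.per.sample = 8L),
    stop("unsupported image format: ", ext, call. = FALSE))
  invisible(path)
}
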