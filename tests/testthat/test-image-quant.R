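make_flat_image <- function(h, w, rgb) {
  array(rep(rgb, each = h * w), dim = c(h, w, 3))
}

test_that("extract_spot_rgb returns the channel medians of the disk", {
  geo <- grid_geometry(origin_x = 10, origin_y = 10, pitch_px = 12,
                       spot_radius_px = 4, rows = 2, cols = 2)
  img <- make_flat_image(40, 40, c(10, 200, 30))
  expect_equal(extract_spot_rgb(img, geo, 0, 0), c(10, 200, 30))

  # corrupting under half the pixels must not move the median
  img2 <- img
  ctr <- c(10, 10)
  xs <- (ctr[1] - 4):(ctr[1] + 4)
  ys <- (ctr[2] - 4):(ctr[2] + 4)
  d2 <- outer((ys - ctr[2])^2, (xs - ctr[1])^2, `+`)
  inside <- which(d2 <= 16, arr.ind = TRUE)
  n_in <- nrow(inside)
  set.seed(9)
  corrupt <- inside[sample(n_in, floor((n_in - 1) / 2)), , drop = FALSE]
  for (k in seq_len(nrow(corrupt)))
    img2[ys[corrupt[k, 1]], xs[corrupt[k, 2]], ] <- c(255, 255, 255)
  expect_equal(extract_spot_rgb(img2, geo, 0, 0), c(10, 200, 30))
  # direct per-channel median oracle over the disk
  for (ch in 1:3) {
    disk <- img2[ys, xs, ch][d2 <= 16]
    expect_equal(extract_spot_rgb(img2, geo, 0, 0)[ch], median(disk))
  }
})

test_that("wells outside the grid or raster raise geometry errors", {
  geo <- grid_geometry(10, 10, 12, 4, rows = 16, cols = 24)
  img <- make_flat_image(40, 40, c(0, 0, 0))
  expect_error(extract_spot_rgb(img, geo, 16, 0), "geometry")
  expect_error(extract_spot_rgb(img, geo, -1, 0), "geometry")
  expect_error(extract_spot_rgb(img, geo, 3, 3), "bounds")
  expect_error(grid_geometry(10, 10, 0, 4, 2, 2), "pitch_px")
})

test_that("difference vectors are signed element-wise subtraction", {
  d <- compute_difference_vector(matrix(c(120, 90, 100), 1), c(100, 100, 100))
  expect_equal(unname(d$deltas[1, ]), c(20, -10, 0))
  s <- matrix(c(5, 5, 5), 1)
  expect_equal(unname(compute_difference_vector(s, c(5, 5, 5))$deltas[1, ]),
               c(0, 0, 0))
  # random pairs against the brute-force subtraction oracle, and
  # antisymmetry under swapping sample and blank
  set.seed(4)
  for (rep in 1:20) {
    n <- sample(2:30, 1)
    sm <- matrix(runif(3 * n, 0, 255), n)
    bl <- runif(3, 0, 255)
    dv <- compute_difference_vector(sm, bl)$deltas
    oracle <- sm - matrix(bl, n, 3, byrow = TRUE)
    expect_equal(unname(dv), unname(oracle))
    swapped <- compute_difference_vector(
      matrix(bl, n, 3, byrow = TRUE), sm)$deltas
    expect_equal(unname(swapped), -unname(dv))
  }
  expect_error(compute_difference_vector(matrix(1, 2, 3), c(1, 2)),
               "shape")
  expect_error(compute_difference_vector(matrix(1, 2, 3), matrix(1, 3, 3)),
               "shape")
})

test_that("difference maps center on mid-gray, scale, clip and invert", {
  d0 <- cd_from_deltas(matrix(c(0, 0, 0), 1))
  m0 <- render_difference_map(d0, expansion = 7, tile_px = 4)
  expect_true(all(m0 == 128))
  d1 <- cd_from_deltas(matrix(c(20, -10, 0), 1))
  m1 <- render_difference_map(d1, expansion = 4, tile_px = 2)
  expect_equal(as.vector(m1[1, 1, ]), c(208, 88, 128))
  d2 <- cd_from_deltas(matrix(c(100, 0, 0), 1))
  m2 <- render_difference_map(d2, expansion = 4)
  expect_equal(m2[1, 1, 1], 255)
  # injective (exactly invertible) at expansion 1 in the non-clipped range
  set.seed(8)
  deltas <- matrix(sample(-128:127, 60, replace = TRUE), 20, 3)
  map <- render_difference_map(cd_from_deltas(deltas), expansion = 1)
  expect_equal(unname(map_to_deltas(map)), deltas)
})

test_that("noise-free rendered plates round-trip exactly", {
  co <- tiny_cohort(n_kd = 2, n_fc = 2, n_compounds = 12, seed = 21)
  layout <- default_layout(12, rows = 4, cols = 4,
                           compounds = co$compounds)
  blank <- c(128, 128, 128)
  for (s in co$subjects[1:2]) {
    img <- render_plate_image(s, layout, blank_rgb = blank, noise_sd = 0)
    q <- quantify_plate(img, layout)
    dv <- compute_difference_vector(q$sample_rgb, q$blank_rgb)
    truth <- kdsense:::clip8(round(sweep(s$true_response, 2, -blank))) -
      matrix(blank, 12, 3, byrow = TRUE)
    expect_equal(unname(dv$deltas), unname(truth))
  }
})

test_that("rendering respects spot geometry and noise behaves as drawn", {
  co <- tiny_cohort(n_kd = 1, n_fc = 1, n_compounds = 6, seed = 2)
  layout <- default_layout(6, rows = 3, cols = 3, compounds = co$compounds)
  expect_error(render_plate_image(co$subjects[[1]], layout,
                                  spot_radius_px = 8, pitch_px = 12),
               "geometry")
  # constructed response renders blank + delta exactly
  resp <- matrix(0, 6, 3, dimnames = list(co$compounds, c("R", "G", "B")))
  resp[1, ] <- c(20, -10, 0)
  img <- render_plate_image(resp, layout, blank_rgb = c(100, 100, 100),
                            noise_sd = 0)
  geo <- attr(img, "geometry")
  expect_equal(extract_spot_rgb(img, geo, 0, 0), c(120, 90, 100))
  expect_equal(extract_spot_rgb(img, geo, 0, 1), c(100, 100, 100))
  # with noise, the per-spot median stays within 1 intensity unit of truth
  co2 <- tiny_cohort(n_kd = 1, n_fc = 1, n_compounds = 6, seed = 3,
                     noise_sd = 0)
  s <- co2$subjects[[1]]
  img2 <- render_plate_image(s, layout, noise_sd = 2, seed = 77,
                             spot_radius_px = 6, pitch_px = 16)
  q <- quantify_plate(img2, layout)
  truth <- kdsense:::clip8(round(128 + s$true_response))
  expect_true(max(abs(q$sample_rgb - truth)) <= 1)
})

test_that("plate images round-trip through PNG and TIFF files", {
  co <- tiny_cohort(n_kd = 1, n_fc = 1, n_compounds = 6, seed = 13)
  layout <- default_layout(6, rows = 2, cols = 4, compounds = co$compounds)
  img <- render_plate_image(co$subjects[[1]], layout, noise_sd = 0)
  for (ext in c("png", "tiff")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_plate_image(img, path)
    back <- read_plate_image(path)
    expect_equal(as.vector(back), as.vector(img))
  }
})
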