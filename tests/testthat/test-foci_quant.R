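# Puncta detection, per-nucleus means and the normalised nuclear readouts.

# bright plateau on a uniform field; sigma = 0 keeps component areas exact
plateau_image <- function(areas, nr = 64, nc = 64, bg = 50, fg = 300,
                          origin = cbind(c(10, 40), c(10, 40))) {
  img <- matrix(bg, nr, nc)
  for (i in seq_along(areas)) {
    side <- ceiling(sqrt(areas[i]))
    rows <- origin[i, 1] + seq_len(side) - 1
    cols <- origin[i, 2] + seq_len(side) - 1
    cells <- cbind(rep(rows, side), rep(cols, each = side))
    img[cells[seq_len(areas[i]), , drop = FALSE]] <- fg
  }
  img
}

test_that("detect_puncta filters by exact area and border contact", {
  # two plateaus, 250 px and 150 px: only the large one survives
  img <- plateau_image(c(250, 150))
  got <- detect_puncta(img, sigma = 0, min_area = 200, window = 41)
  expect_equal(nrow(got), 1L)
  expect_equal(got$area_px, 250L)
  expect_equal(got$mean_intensity, 300)

  # boundary exactness at min_area - 1 / min_area / min_area + 1
  for (a in c(199L, 200L, 201L)) {
    img_a <- plateau_image(a, origin = cbind(20, 20))
    got_a <- detect_puncta(img_a, sigma = 0, min_area = 200, window = 41)
    # the oracle: exhaustive 8-connected component enumeration
    olab <- oracle_label(img_a > 50, 8)
    osize <- if (max(olab) > 0) tabulate(olab) else integer()
    expect_equal(nrow(got_a), sum(osize >= 200))
    if (a >= 200L) expect_equal(got_a$area_px, a)
  }

  # a qualifying blob touching the border is removed
  img_b <- plateau_image(250, origin = cbind(1, 20))
  expect_equal(nrow(detect_puncta(img_b, sigma = 0, min_area = 200,
                                  window = 41)), 0L)

  # blank image: empty table
  expect_equal(nrow(detect_puncta(matrix(0, 64, 64), sigma = 0,
                                  min_area = 200, window = 41)), 0L)

  expect_error(detect_puncta(matrix(1, 10, 10), window = 21), "larger")
})

test_that("detect_puncta is translation-equivariant away from borders", {
  img <- plateau_image(225, origin = cbind(15, 15))
  base <- detect_puncta(img, sigma = 1, min_area = 100, window = 41)
  shifted <- plateau_image(225, origin = cbind(15 + 7, 15 + 11))
  moved <- detect_puncta(shifted, sigma = 1, min_area = 100, window = 41)
  expect_equal(nrow(base), 1L)
  expect_equal(moved$area_px, base$area_px)
  expect_equal(moved$centroid_y - base$centroid_y, 7)
  expect_equal(moved$centroid_x - base$centroid_x, 11)
})

test_that("synthetic nuclear scenes are resolved into the >= 200 px puncta", {
  for (seed in 1:3) {
    sc_big <- make_nuclear_scene(scene_params(
      punctum_area_px = 250, seed = seed,
      psf_sigma_px = 0, noise_poisson_gain = 0, noise_gaussian_sd = 0))
    got <- detect_puncta(average_projection(sc_big$channel, 3, 4))
    expect_equal(nrow(got), nrow(sc_big$truth$puncta))

    sc_small <- make_nuclear_scene(scene_params(
      punctum_area_px = 150, seed = seed,
      psf_sigma_px = 0, noise_poisson_gain = 0, noise_gaussian_sd = 0))
    got_small <- detect_puncta(average_projection(sc_small$channel, 3, 4))
    expect_equal(nrow(got_small), 0L)
  }
})

test_that("nucleus_means equals brute-force masked averaging", {
  img <- matrix(0, 10, 10)
  lab <- matrix(0L, 10, 10)
  img[2:4, 2:4] <- 42; lab[2:4, 2:4] <- 1L
  got <- nucleus_means(img, lab)
  expect_equal(got$mean_intensity, 42)

  img[6:8, 6:8] <- 20; lab[6:8, 6:8] <- 2L
  img[2:4, 2:4] <- 10
  got2 <- nucleus_means(img, lab)
  expect_equal(got2$mean_intensity, c(10, 20))
  expect_equal(got2$nucleus_id, c(1L, 2L))

  set.seed(41)
  r <- matrix(runif(100), 10)
  got3 <- nucleus_means(r, lab)
  for (i in seq_len(nrow(got3))) {
    id <- got3$nucleus_id[i]
    acc <- 0; cnt <- 0
    for (y in 1:10) for (x in 1:10)
      if (lab[y, x] == id) { acc <- acc + r[y, x]; cnt <- cnt + 1 }
    expect_equal(got3$mean_intensity[i], acc / cnt)
  }
  expect_warning(empty <- nucleus_means(r, matrix(0L, 10, 10)), "no nucleus")
  expect_equal(nrow(empty), 0L)
  expect_error(nucleus_means(r, matrix(0L, 5, 5)), "dimensions")
})

test_that("normalised_region_level reproduces its closed form and invariances", {
  e <- matrix(c(rep(50, 8), rep(10, 8)), 4)
  k <- matrix(c(rep(80, 8), rep(10, 8)), 4)
  lv <- normalised_region_level(e, k, expr_bg = 10, ctrl_bg = 10)
  expect_equal(lv, (50 - 10) / (80 - 10), tolerance = 1e-12)

  # identical images normalise to 1
  expect_equal(normalised_region_level(k, k, 10, 10), 1, tolerance = 1e-12)

  # gain invariance
  expect_equal(normalised_region_level(3 * e, 3 * k, 30, 30), lv,
               tolerance = 1e-12)

  # degenerate control: inside mean equals outside mean
  m <- matrix(rep(c(TRUE, FALSE), each = 8), 4)
  expect_error(normalised_region_level(e, matrix(10, 4, 4), 10, 10,
                                       expr_mask = m, ctrl_mask = m),
               "undefined")
  # empty foreground names the offending image
  dim_img <- matrix(5, 4, 4)
  expect_error(normalised_region_level(dim_img, k, 10, 10), "expressing")
})

test_that("nc_ratio reproduces its closed form and rejects degenerate masks", {
  e <- matrix(c(rep(60, 8), rep(30, 8)), 4)
  k <- matrix(c(rep(90, 8), rep(30, 8)), 4)
  m <- matrix(rep(c(TRUE, FALSE), each = 8), 4)
  expect_equal(nc_ratio(e, k, m, m), (60 / 30) / (90 / 30), tolerance = 1e-12)
  expect_equal(nc_ratio(e, e, m, m), 1, tolerance = 1e-12)
  expect_error(nc_ratio(e, k, matrix(TRUE, 4, 4), m), "whole")
  expect_error(nc_ratio(e, k, matrix(FALSE, 4, 4), m), "empty")
  # adding the same structure to both regions leaves the ratio at 1
  expect_equal(nc_ratio(e + 5, e + 5, m, m), 1, tolerance = 1e-12)
})
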