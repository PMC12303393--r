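# Generator contracts: determinism, ground-truth self-consistency,
# parameter recovery in the noise-free limit.

fast_params <- function(...) {
  scene_params(size = 96, n_cells = 4, psf_sigma_px = 0,
               noise_poisson_gain = 0, noise_gaussian_sd = 0, ...)
}

test_that("identical seeds reproduce scenes bit for bit", {
  a <- make_epithelium_scene(scene_params(size = 96, n_cells = 4, seed = 9,
                                          vesicle_density = 2))
  b <- make_epithelium_scene(scene_params(size = 96, n_cells = 4, seed = 9,
                                          vesicle_density = 2))
  expect_identical(a$query$voxels, b$query$voxels)
  expect_identical(a$partner$voxels, b$partner$voxels)
  expect_identical(a$truth$vesicles, b$truth$vesicles)

  n1 <- make_nuclear_scene(scene_params(seed = 4))
  n2 <- make_nuclear_scene(scene_params(seed = 4))
  expect_identical(n1$channel$voxels, n2$channel$voxels)
  expect_identical(n1$labels, n2$labels)

  d1 <- make_de_pair(500, 0.2, 0.2, 0.5, seed = 11)
  d2 <- make_de_pair(500, 0.2, 0.2, 0.5, seed = 11)
  expect_identical(d1$a, d2$a)
  expect_identical(d1$b, d2$b)

  # the generators leave the caller's RNG stream untouched
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(make_de_pair(100, 0.1, 0.1, 0.5, seed = 2))
  expect_identical(runif(1), before)
})

test_that("generators never emit NaN or negative intensities", {
  sc <- make_epithelium_scene(scene_params(size = 96, n_cells = 4, seed = 2))
  expect_false(anyNA(sc$query$voxels))
  expect_true(all(sc$query$voxels >= 0))
  ns <- make_nuclear_scene(scene_params(seed = 2))
  expect_false(anyNA(ns$channel$voxels))
  expect_true(all(ns$channel$voxels >= 0))
})

test_that("epithelium ground truth is self-consistent with the noise-free scene", {
  sc <- make_epithelium_scene(fast_params(membrane_halfwidth_px = 3,
                                          vesicle_density = 0))
  # the skeleton separates exactly the labelled cells
  cells <- label_cells(sc$truth$skeleton, min_cell_area_px = 1,
                       exclude_border_cells = FALSE)
  expect_equal(max(cells), max(sc$truth$cell_labels))
  # noise-free compartment means match the painted design intensities
  proj <- average_projection(sc$query)
  part <- build_partition(cells, 3)
  keep <- !vapply(part$cells, `[[`, logical(1), "flagged")
  tab <- measure_partition(proj, part)
  ok <- tab$cells[!tab$cells$flagged, ]
  w <- mean(wingquant:::z_envelope(n_slices(sc$query)))
  expect_equal(ok$membrane_mean / w,
               rep(sc$truth$membrane_intensity, nrow(ok)), tolerance = 1e-9)
  expect_equal(ok$cytoplasm_mean / w,
               rep(sc$truth$cytoplasm_intensity, nrow(ok)), tolerance = 1e-9)
})

test_that("coloc_rho forces the realised colocalised fraction at its ends", {
  sc1 <- make_epithelium_scene(fast_params(vesicle_density = 3, coloc_rho = 1,
                                           seed = 3))
  expect_equal(sc1$truth$realised_coloc_frac, 1)
  sc0 <- make_epithelium_scene(fast_params(vesicle_density = 3, coloc_rho = 0,
                                           seed = 3))
  expect_equal(sc0$truth$realised_coloc_frac, 0)
})

test_that("noise-free disc ratio recovery is exact in the band regime", {
  for (ratio in c(0.2, 1)) {
    sc <- make_epithelium_scene(scene_params(
      size = 128, n_cells = 9, psf_sigma_px = 0,
      noise_poisson_gain = 0, noise_gaussian_sd = 0,
      membrane_halfwidth_px = 3, vesicle_density = 0,
      cytoplasm_intensity = 200 * ratio, seed = 8))
    tab <- measure_partition(
      average_projection(sc$query),
      build_partition(label_cells(sc$truth$skeleton), 3))
    expect_equal(tab$disc$cyto_to_border_ratio, ratio, tolerance = 1e-12)
  }
})

test_that("nuclear ground truth matches direct measurement of the clean scene", {
  sc <- make_nuclear_scene(scene_params(
    puncta_per_nucleus = 0, psf_sigma_px = 0,
    noise_poisson_gain = 0, noise_gaussian_sd = 0))
  proj <- average_projection(sc$channel, 3, 4)
  w <- mean(wingquant:::z_envelope(n_slices(sc$channel))[3:6])
  got <- nucleus_means(proj, sc$labels)
  expect_equal(got$mean_intensity / w, sc$truth$nuclei$true_mean,
               tolerance = 1e-9)
  # puncta carry their exact designed pixel area
  sc2 <- make_nuclear_scene(scene_params(
    punctum_area_px = 250, psf_sigma_px = 0,
    noise_poisson_gain = 0, noise_gaussian_sd = 0))
  expect_true(all(sc2$truth$puncta$area_px == 250L))
  # expressing / control design values follow expr_factor exactly
  tr <- sc$truth
  expect_equal((tr$expr_nucleus_value - tr$background) /
                 (tr$ctrl_nucleus_value - tr$background), tr$expr_factor)
})

test_that("nuclear generation errors on infeasible geometry", {
  expect_error(make_nuclear_scene(scene_params(size = 64,
                                               nucleus_radius_px = 40)),
               "too large|placement")
  expect_error(make_nuclear_scene(scene_params(nucleus_intensity = 5,
                                               nucleus_background = 40)),
               "exceed")
})

test_that("make_de_pair designs the promised overlap structure", {
  # shared_frac 1, noise-free: full overlap, full agreement, r^2 = 1
  dp1 <- make_de_pair(1000, 0.1, 0.2, 1, noise_sd = 0, seed = 5)
  cc1 <- concordance(dp1$a, dp1$b)
  expect_equal(cc1$n_overlap, min(cc1$n_a, cc1$n_b))
  expect_equal(cc1$consistent_frac, 1)
  expect_equal(cc1$r_squared, 1)

  # shared_frac 0, noise-free: designed overlap zero
  dp0 <- make_de_pair(1000, 0.1, 0.2, 0, noise_sd = 0, seed = 5)
  cc0 <- concordance(dp0$a, dp0$b)
  expect_equal(cc0$n_overlap, 0L)
  expect_equal(dp0$truth$design_n_overlap, 0L)

  # designed calls are exactly the sub-alpha, supra-cutoff genes
  called <- call_degs(dp1$a)
  expect_equal(sum(called$call != "ns"), dp1$truth$design_n_a)

  expect_error(make_de_pair(100, 0.9, 0.9, 0, seed = 1), "exceed")
  expect_error(make_de_pair(100, 1.2, 0.1, 0.5), "fractions")
})

test_that("random-overlap of unshared designs stays near the hypergeometric null", {
  # shared_frac 0 puts the two DE sets in disjoint blocks by construction;
  # a randomised-universe draw of equal sizes has mean n_a * n_b / N
  dp <- make_de_pair(4000, 0.1, 0.15, 0, noise_sd = 0, seed = 13)
  cc <- concordance(dp$a, dp$b)
  expect_equal(cc$n_overlap, 0L)
  # randomising one table's gene labels reproduces the null overlap level
  set.seed(13)
  ov <- replicate(40, {
    b2 <- dp$b
    b2$gene_id <- sample(b2$gene_id)
    concordance(dp$a, b2)$n_overlap
  })
  N <- 4000; na <- cc$n_a; nb <- cc$n_b
  mu <- na * nb / N
  sdv <- sqrt(na * nb / N * (1 - na / N) * ((N - nb) / (N - 1)))
  expect_lt(abs(mean(ov) - mu), 3 * sdv / sqrt(40))
})
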