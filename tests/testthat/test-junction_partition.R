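# Cell labelling, membrane/cytoplasm partitioning and intensity measurement.

test_that("label_components matches flood fill and EBImage at both connectivities", {
  set.seed(21)
  for (i in 1:10) {
    m <- matrix(runif(30 * 30) < 0.35, 30)
    l4 <- label_components(m, 4)
    l8 <- label_components(m, 8)
    o4 <- oracle_label(m, 4)
    o8 <- oracle_label(m, 8)
    # same partition (label values may differ in order)
    expect_equal(max(l4), max(o4))
    expect_equal(max(l8), max(o8))
    expect_true(all(tapply(o4[m], l4[m], function(v) length(unique(v))) == 1))
    expect_true(all(tapply(o8[m], l8[m], function(v) length(unique(v))) == 1))
    # EBImage::bwlabel is an independent 4-connected implementation
    expect_equal(max(l4), max(EBImage::bwlabel(matrix(as.numeric(m), 30))))
  }
})

test_that("label_cells separates cells, filters area and border contact", {
  sk <- plus_skeleton(9)
  expect_equal(max(label_cells(sk, min_cell_area_px = 1,
                               exclude_border_cells = FALSE)), 4L)
  # all cells touch the border of a 9x9 field
  expect_warning(out <- label_cells(sk, min_cell_area_px = 1,
                                    exclude_border_cells = TRUE),
                 "no cell")
  expect_equal(max(out), 0L)
  # all-false skeleton: one cell covering the image
  blank <- matrix(FALSE, 8, 8)
  expect_equal(max(label_cells(blank, min_cell_area_px = 1,
                               exclude_border_cells = FALSE)), 1L)
  # all-true skeleton warns, not errors
  expect_warning(label_cells(matrix(TRUE, 5, 5)), "no cells")
  # area filter
  sk2 <- matrix(FALSE, 12, 12); sk2[, 4] <- TRUE
  lab <- label_cells(sk2, min_cell_area_px = 40, exclude_border_cells = FALSE)
  expect_equal(max(lab), 1L)  # the 3-column region (36 px) is dropped
})

test_that("build_partition reproduces the worked small-cell geometries", {
  # 5x5 cell, radius 1: cytoplasm collapses to the single centre pixel
  cells <- matrix(0L, 7, 7); cells[2:6, 2:6] <- 1L
  part <- build_partition(cells, radius = 1)
  cc <- part$cells[[1]]
  expect_false(cc$flagged)
  expect_equal(length(cc$cytoplasm_idx), 1L)
  expect_equal(arrayInd(cc$cytoplasm_idx, c(7, 7)), cbind(4L, 4L))

  # 3x3 cell, radius 1: cytoplasm empty, cell flagged
  cells3 <- matrix(0L, 5, 5); cells3[2:4, 2:4] <- 1L
  part3 <- build_partition(cells3, radius = 1)
  expect_true(part3$cells[[1]]$flagged)
  expect_warning(tab <- measure_partition(matrix(1, 5, 5), part3),
                 "no unflagged")
  expect_true(is.na(tab$cells$cytoplasm_mean[1]))
})

test_that("partition masks equal exhaustive city-block computation", {
  set.seed(22)
  for (case in 1:25) {
    nr <- sample(12:32, 1); nc <- sample(12:32, 1)
    sk <- matrix(runif(nr * nc) < 0.25, nr, nc)
    cells <- label_cells(sk, min_cell_area_px = 4,
                         exclude_border_cells = FALSE)
    if (max(cells) == 0L) next
    radius <- sample(1:3, 1)
    part <- build_partition(cells, radius)
    for (cc in part$cells) {
      region <- cells == cc$cell_id
      perim <- oracle_perimeter(region)
      mem <- oracle_dilate_cityblock(perim, radius)
      expect_identical(sort(cc$membrane_idx), which(mem))
      expect_identical(sort(cc$cytoplasm_idx), which(region & !mem))
      # invariants: disjoint compartments covering the region
      expect_length(intersect(cc$membrane_idx, cc$cytoplasm_idx), 0L)
      expect_true(all(cc$cytoplasm_idx %in% cc$region_idx))
      expect_true(all(which(perim) %in% cc$membrane_idx))
      expect_setequal(
        cc$region_idx,
        c(intersect(cc$membrane_idx, cc$region_idx), cc$cytoplasm_idx))
    }
  }
})

test_that("dilate_cityblock equals the exhaustive distance check", {
  set.seed(23)
  for (case in 1:10) {
    m <- matrix(runif(20 * 20) < 0.08, 20)
    r <- sample(1:4, 1)
    expect_identical(dilate_cityblock(m, r), oracle_dilate_cityblock(m, r))
  }
})

test_that("measure_partition computes compartment statistics and disc summaries", {
  # constant membrane 100 / cytoplasm 10 scene
  sk <- plus_skeleton(17)
  cells <- label_cells(sk, min_cell_area_px = 1, exclude_border_cells = FALSE)
  part <- build_partition(cells, radius = 1)
  img <- matrix(10, 17, 17)
  for (cc in part$cells) img[cc$membrane_idx] <- 100
  tab <- measure_partition(img, part)
  expect_true(all(tab$cells$membrane_mean == 100))
  expect_true(all(tab$cells$cytoplasm_mean == 10))
  expect_equal(tab$disc$cyto_to_border_ratio, 0.1)

  # conservation on integer images: totals add to the union-mask sum
  set.seed(24)
  ri <- matrix(sample(0:4095, 17 * 17, replace = TRUE), 17)
  tab2 <- measure_partition(ri, part)
  for (k in seq_along(part$cells)) {
    cc <- part$cells[[k]]
    union_idx <- union(cc$membrane_idx, cc$cytoplasm_idx)
    expect_identical(tab2$cells$membrane_total[k] + tab2$cells$cytoplasm_total[k],
                     sum(ri[union_idx]))
  }
  expect_error(measure_partition(matrix(1, 4, 4), part), "partition expects")
})

test_that("raising the radius never raises cytoplasm means on membrane-bright scenes", {
  sc <- make_epithelium_scene(scene_params(
    size = 96, n_cells = 4, membrane_halfwidth_px = 2, vesicle_density = 0,
    psf_sigma_px = 1, noise_poisson_gain = 0, noise_gaussian_sd = 0))
  proj <- average_projection(sc$query)
  cells <- label_cells(sc$truth$skeleton, exclude_border_cells = FALSE)
  prev <- Inf
  for (r in 1:4) {
    tab <- measure_partition(proj, build_partition(cells, r))
    cur <- mean(tab$cells$cytoplasm_mean, na.rm = TRUE)
    expect_lte(cur, prev + 1e-9)
    prev <- cur
  }
})

test_that("intensity tables serialise with provenance and a summary row", {
  sk <- plus_skeleton(11)
  cells <- label_cells(sk, min_cell_area_px = 1, exclude_border_cells = FALSE)
  tab <- measure_partition(matrix(5, 11, 11), build_partition(cells, 1))
  f <- tempfile(fileext = ".csv")
  write_intensity_table(tab, f, quant_params())
  lines <- readLines(f)
  expect_true(startsWith(lines[1], "# wingquant"))
  df <- read.csv(f, comment.char = "#")
  expect_equal(sum(df$row_type == "cell"), 4L)
  expect_equal(sum(df$row_type == "disc_summary"), 1L)
})
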