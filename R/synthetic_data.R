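# Seeded generators of synthetic epithelium and nuclear scenes, and of
# paired differential-expression tables, each returning the complete ground
# truth so every quantification stage has a parameter-recovery test.

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Parameters of the synthetic scenes
#'
#' One record holding every knob of the image generators. Defaults
#' describe a 256 x 256 px field at 0.06 um/px holding 9 cells (apical
#' domains of roughly 5 um, several PSF widths across), a bright 1 px
#' junctional skeleton (membrane 200, cytoplasm 40, i.e. a
#' cytoplasm:border ratio of 0.2), sparse intracellular vesicles, nuclei
#' of radius 40 px (about 5 um across) on a dim background, single
#' 250 px puncta, a 1 px
#' Gaussian PSF and mixed Poisson-Gaussian noise. Axial structure is a
#' multiplicative intensity envelope peaking at the middle slice, the
#' plane where the junctional signal is in focus.
#'
#' @param size square field side in pixels.
#' @param pixel_size_um,z_step_um calibration.
#' @param n_slices slices per stack.
#' @param n_cells lattice seed count.
#' @param membrane_intensity,cytoplasm_intensity painted intensities; their
#'   ratio is the scene's true cytoplasm:border ratio.
#' @param membrane_halfwidth_px half-width of the painted junctional
#'   band: 0 paints the 1 px junction line itself (the thin-junction
#'   regime of real membrane stainings); a positive value paints the
#'   union of every cell's perimeter dilated by that city-block radius,
#'   which coincides exactly with the measured membrane compartment when
#'   it equals the measurement dilation radius.
#' @param vesicle_density expected vesicles per cell (Poisson).
#' @param vesicle_radius_px,vesicle_intensity vesicle geometry and added
#'   intensity.
#' @param coloc_rho probability that a query vesicle has a partner vesicle
#'   at the same site (in `[0, 1]`).
#' @param nucleus_radius_px,nucleus_intensity,nucleus_background nuclear
#'   disk radius, total intensity and non-nuclear background.
#' @param expr_factor expressing-region factor scaling the above-background
#'   nuclear signal (control = 1).
#' @param puncta_per_nucleus,punctum_area_px,punctum_intensity intranuclear
#'   puncta: count per nucleus, exact pixel area, added intensity.
#' @param blobs list of `list(area_px =, intensity =)` apoptotic blobs.
#' @param psf_sigma_px isotropic Gaussian PSF sigma (0 = none).
#' @param noise_poisson_gain photons per intensity unit (0 disables shot
#'   noise).
#' @param noise_gaussian_sd read-noise standard deviation (0 disables).
#' @param seed integer fixing all randomness of a scene.
#' @return A list of class `wq_scene_params`.
#' @export
scene_params <- function(size = 256L, pixel_size_um = 0.06, z_step_um = 0.38,
                         n_slices = 8L, n_cells = 9L,
                         membrane_intensity = 200, cytoplasm_intensity = 40,
                         membrane_halfwidth_px = 0L,
                         vesicle_density = 2, vesicle_radius_px = 2L,
                         vesicle_intensity = 150, coloc_rho = 0,
                         nucleus_radius_px = 40L, nucleus_intensity = 80,
                         nucleus_background = 40, expr_factor = 0.5,
                         puncta_per_nucleus = 1L, punctum_area_px = 250L,
                         punctum_intensity = 150,
                         blobs = list(),
                         psf_sigma_px = 1, noise_poisson_gain = 1,
                         noise_gaussian_sd = 2, seed = 1L) {
  p <- as.list(environment())
  if (coloc_rho < 0 || coloc_rho > 1) stopf("'coloc_rho' must lie in [0, 1]")
  if (expr_factor < 0) stopf("'expr_factor' must be >= 0")
  for (nm in c("membrane_intensity", "cytoplasm_intensity", "vesicle_intensity",
               "nucleus_intensity", "nucleus_background", "punctum_intensity",
               "vesicle_density", "psf_sigma_px", "noise_poisson_gain",
               "noise_gaussian_sd"))
    if (p[[nm]] < 0) stopf("'%s' must be >= 0", nm)
  for (nm in c("size", "n_slices", "n_cells", "membrane_halfwidth_px",
               "vesicle_radius_px", "nucleus_radius_px", "punctum_area_px"))
    p[[nm]] <- as.integer(p[[nm]])
  if (p$membrane_halfwidth_px < 0L)
    stopf("'membrane_halfwidth_px' must be >= 0")
  if (p$size < 16L) stopf("'size' must be >= 16 px")
  class(p) <- "wq_scene_params"
  p
}

# Euclidean-disk pixel offsets of radius r (including the centre).
disk_offsets <- function(r) {
  d <- expand.grid(dy = -r:r, dx = -r:r)
  d[d$dx^2 + d$dy^2 <= r^2, ]
}

paint_disk <- function(img, x, y, r, value, additive = TRUE) {
  off <- disk_offsets(r)
  yy <- y + off$dy; xx <- x + off$dx
  ok <- yy >= 1 & yy <= nrow(img) & xx >= 1 & xx <= ncol(img)
  idx <- cbind(yy[ok], xx[ok])
  if (additive) img[idx] <- img[idx] + value else img[idx] <- value
  img
}

# Compact blob of exactly `area` pixels around (x, y): the `area` nearest
# pixels by squared Euclidean distance, ties broken in raster order.
blob_pixels <- function(x, y, area, nr, nc) {
  r <- ceiling(sqrt(area / pi)) + 2L
  g <- expand.grid(yy = (y - r):(y + r), xx = (x - r):(x + r))
  g <- g[g$yy >= 1 & g$yy <= nr & g$xx >= 1 & g$xx <= nc, ]
  d2 <- (g$yy - y)^2 + (g$xx - x)^2
  ord <- order(d2, g$xx, g$yy)
  if (nrow(g) < area) stopf("blob of %d px does not fit inside the image", area)
  g[ord[seq_len(area)], ]
}

apply_psf_noise <- function(stack_arr, p) {
  nz <- dim(stack_arr)[3]
  for (k in seq_len(nz)) {
    s <- stack_arr[, , k]
    if (p$psf_sigma_px > 0) s <- EBImage::gblur(s, sigma = p$psf_sigma_px)
    if (p$noise_poisson_gain > 0)
      s <- rpois(length(s), pmax(s, 0) * p$noise_poisson_gain) /
        p$noise_poisson_gain
    if (p$noise_gaussian_sd > 0)
      s <- s + rnorm(length(s), 0, p$noise_gaussian_sd)
    stack_arr[, , k] <- pmax(matrix(s, nrow(stack_arr)), 0)
  }
  stack_arr
}

# Multiplicative axial envelope, peak 1 at the middle slice.
z_envelope <- function(nz) {
  zc <- (nz + 1) / 2
  exp(-0.5 * ((seq_len(nz) - zc) / (nz / 4))^2)
}

build_stack <- function(base2d, p, name) {
  w <- z_envelope(p$n_slices)
  arr <- array(0, c(dim(base2d), p$n_slices))
  for (k in seq_len(p$n_slices)) arr[, , k] <- base2d * w[k]
  clean <- arr
  if (p$psf_sigma_px > 0)
    for (k in seq_len(p$n_slices))
      clean[, , k] <- EBImage::gblur(clean[, , k], sigma = p$psf_sigma_px)
  noisy <- apply_psf_noise(arr, p)
  list(stack = image_stack(noisy, p$pixel_size_um, p$z_step_um, name),
       clean = clean)
}

#' Generate a synthetic epithelium scene with ground truth
#'
#' A relaxed-Voronoi lattice of `n_cells` defines the cells; their shared
#' boundaries are drawn as a 1 px junction skeleton, a city-block band
#' around it is painted at `membrane_intensity` and cell interiors at
#' `cytoplasm_intensity`, in both channels. Vesicles are placed uniformly
#' in the cytoplasm of the query channel; each receives a partner-channel
#' vesicle at the same site with probability `coloc_rho`, otherwise the
#' partner vesicle lands at an independent site in the same cell. Slices
#' share the lateral structure under a multiplicative axial envelope
#' peaking at the middle slice; the PSF blur and Poisson-Gaussian noise
#' are then applied. The same seed always reproduces the scene exactly.
#'
#' @param params a [scene_params()].
#' @return A list of class `wq_scene`: `query` and `partner`
#'   [image_stack()]s and `truth` (skeleton, cell label map, painted
#'   membrane zone, design intensities and true cytoplasm:border ratio,
#'   vesicle table with realised colocalised fraction, noise-free
#'   post-PSF stacks, seed).
#' @export
make_epithelium_scene <- function(params = scene_params()) {
  stopifnot(inherits(params, "wq_scene_params"))
  p <- params
  with_seed(p$seed, {
    n <- p$size
    geom <- voronoi_lattice(n, p$n_cells)
    skeleton <- geom$skeleton
    cells_gt <- geom$labels
    cells_gt[skeleton] <- 0L

    if (p$membrane_halfwidth_px == 0L) {
      # thin-junction regime: the bright signal is the 1 px skeleton
      mem_zone <- skeleton
    } else {
      # band regime: the union of every cell's dilated perimeter -- the
      # same geometry the measurement stage uses -- so the noise-free
      # compartment means equal the painted intensities exactly
      part_gt <- build_partition(cells_gt, p$membrane_halfwidth_px)
      mem_zone <- matrix(FALSE, n, n)
      for (cc in part_gt$cells) mem_zone[cc$membrane_idx] <- TRUE
    }
    base <- matrix(p$cytoplasm_intensity, n, n)
    base[mem_zone] <- p$membrane_intensity

    qves <- matrix(0, n, n); pves <- matrix(0, n, n)
    ves_rows <- list()
    if (p$vesicle_density > 0) {
      cyto_ok <- !mem_zone & cells_gt > 0L
      zone_all <- which(cyto_ok)
      for (id in seq_len(max(cells_gt))) {
        zone <- which(cyto_ok & cells_gt == id)
        if (!length(zone)) next
        nv <- rpois(1L, p$vesicle_density)
        if (nv == 0L) next
        for (v in seq_len(nv)) {
          site <- zone[sample.int(length(zone), 1L)]
          yx <- arrayInd(site, c(n, n))
          qves <- paint_disk(qves, yx[2], yx[1], p$vesicle_radius_px,
                             p$vesicle_intensity)
          colocalised <- runif(1L) < p$coloc_rho
          if (colocalised) {
            pves <- paint_disk(pves, yx[2], yx[1], p$vesicle_radius_px,
                               p$vesicle_intensity)
          } else {
            # independent placement anywhere in the cytoplasm, so that at
            # coloc_rho = 0 the two channels' vesicle fields are a true
            # independence null
            px_site <- zone_all[sample.int(length(zone_all), 1L)]
            pyx <- arrayInd(px_site, c(n, n))
            pves <- paint_disk(pves, pyx[2], pyx[1], p$vesicle_radius_px,
                               p$vesicle_intensity)
          }
          ves_rows[[length(ves_rows) + 1L]] <- data.frame(
            cell_id = id, x = yx[2], y = yx[1], colocalised = colocalised)
        }
      }
    }
    vesicles <- if (length(ves_rows)) do.call(rbind, ves_rows)
    else data.frame(cell_id = integer(), x = integer(), y = integer(),
                    colocalised = logical())
    realised_coloc_frac <- if (nrow(vesicles)) mean(vesicles$colocalised)
    else NA_real_

    qb <- build_stack(base + qves, p, "query")
    pb <- build_stack(base + pves, p, "partner")

    structure(list(
      query = qb$stack, partner = pb$stack,
      truth = list(
        skeleton = skeleton, cell_labels = cells_gt, membrane_zone = mem_zone,
        membrane_intensity = p$membrane_intensity,
        cytoplasm_intensity = p$cytoplasm_intensity,
        true_ratio = p$cytoplasm_intensity / p$membrane_intensity,
        vesicles = vesicles, realised_coloc_frac = realised_coloc_frac,
        clean_query = qb$clean, clean_partner = pb$clean,
        seed = p$seed, params = p)), class = "wq_scene")
  })
}

# Jittered-grid seeds relaxed by two Lloyd iterations; returns the
# nearest-seed label map and the 1 px inter-cell skeleton.
voronoi_lattice <- function(n, n_cells) {
  g <- ceiling(sqrt(n_cells))
  spacing <- n / g
  centres <- expand.grid(gy = seq_len(g), gx = seq_len(g))
  centres <- centres[seq_len(n_cells), ]
  cx <- (centres$gx - 0.5) * spacing + runif(n_cells, -0.3, 0.3) * spacing
  cy <- (centres$gy - 0.5) * spacing + runif(n_cells, -0.3, 0.3) * spacing
  cx <- pmin(pmax(cx, 1), n); cy <- pmin(pmax(cy, 1), n)
  px <- rep(seq_len(n), each = n)   # column (x) of each pixel, column-major
  py <- rep(seq_len(n), times = n)  # row (y)
  assign_nearest <- function() {
    d2 <- outer(px, cx, function(a, b) (a - b)^2) +
      outer(py, cy, function(a, b) (a - b)^2)
    max.col(-d2, ties.method = "first")
  }
  for (it in 1:2) {
    a <- assign_nearest()
    for (id in seq_len(n_cells)) {
      sel <- a == id
      if (any(sel)) { cx[id] <- mean(px[sel]); cy[id] <- mean(py[sel]) }
    }
  }
  labels <- matrix(assign_nearest(), n, n)
  up <- rbind(labels[1, ], labels[-n, ])
  left <- cbind(labels[, 1], labels[, -n])
  skeleton <- (labels != up) | (labels != left)
  list(labels = labels, skeleton = skeleton)
}

#' Generate a synthetic nuclear scene with ground truth
#'
#' A field split into a transgene-expressing left half and a control right
#' half. Nuclei are disks on a jittered grid; control nuclei carry
#' `nucleus_intensity` and expressing nuclei carry
#' `background + expr_factor * (nucleus_intensity - background)`, so the
#' expressing:control ratio of background-subtracted nuclear signal is
#' exactly `expr_factor`. Each nucleus receives `puncta_per_nucleus`
#' compact puncta of exactly `punctum_area_px` pixels with
#' `punctum_intensity` added on top of the nuclear level. The stack is
#' built, blurred and degraded as in [make_epithelium_scene()].
#'
#' @param params a [scene_params()].
#' @return A list of class `wq_nuclear_scene`: `channel`
#'   ([image_stack()]), `labels` (nucleus label map), and `truth`
#'   (per-nucleus table, puncta table, region design values, noise-free
#'   stack, seed).
#' @export
make_nuclear_scene <- function(params = scene_params()) {
  stopifnot(inherits(params, "wq_scene_params"))
  p <- params
  if (p$nucleus_intensity <= p$nucleus_background)
    stopf("nucleus_intensity must exceed nucleus_background")
  with_seed(p$seed, {
    n <- p$size
    r <- p$nucleus_radius_px
    margin <- r + 3L
    spacing <- 3L * r
    if (margin + r > n - margin)
      stopf("nucleus radius %d px too large for a %d px field", r, n)
    xs <- seq(margin + r, n - margin, by = spacing)
    ys <- seq(margin + r, n - margin, by = spacing)
    grid <- expand.grid(x = xs, y = ys)
    # keep nuclei clear of the expressing/control boundary at n/2
    half <- n / 2
    grid <- grid[abs(grid$x - half) > r + 1, ]
    if (!nrow(grid)) stopf("no nucleus placement fits the field")
    grid$x <- grid$x + sample(-1:1, nrow(grid), replace = TRUE)
    grid$y <- grid$y + sample(-1:1, nrow(grid), replace = TRUE)
    grid$region <- ifelse(grid$x <= half, "expressing", "control")

    expr_value <- p$nucleus_background +
      p$expr_factor * (p$nucleus_intensity - p$nucleus_background)
    base <- matrix(p$nucleus_background, n, n)
    labels <- matrix(0L, n, n)
    nuclei <- grid
    nuclei$nucleus_id <- seq_len(nrow(grid))
    nuclei$true_mean <- ifelse(nuclei$region == "expressing",
                               expr_value, p$nucleus_intensity)
    for (i in seq_len(nrow(nuclei))) {
      val <- nuclei$true_mean[i]
      base <- paint_disk(base, nuclei$x[i], nuclei$y[i], r, val,
                         additive = FALSE)
      off <- disk_offsets(r)
      idx <- cbind(nuclei$y[i] + off$dy, nuclei$x[i] + off$dx)
      labels[idx] <- nuclei$nucleus_id[i]
    }

    punc_rows <- list()
    if (p$puncta_per_nucleus > 0 && p$punctum_area_px > 0) {
      for (i in seq_len(nrow(nuclei))) {
        for (j in seq_len(p$puncta_per_nucleus)) {
          jit <- max(1L, r %/% 3L)
          cxp <- nuclei$x[i] + sample(-jit:jit, 1L)
          cyp <- nuclei$y[i] + sample(-jit:jit, 1L)
          bp <- blob_pixels(cxp, cyp, p$punctum_area_px, n, n)
          idx <- cbind(bp$yy, bp$xx)
          base[idx] <- base[idx] + p$punctum_intensity
          punc_rows[[length(punc_rows) + 1L]] <- data.frame(
            nucleus_id = nuclei$nucleus_id[i], area_px = nrow(bp),
            centroid_x = mean(bp$xx), centroid_y = mean(bp$yy))
        }
      }
    }
    puncta <- if (length(punc_rows)) do.call(rbind, punc_rows)
    else data.frame(nucleus_id = integer(), area_px = integer(),
                    centroid_x = numeric(), centroid_y = numeric())

    sb <- build_stack(base, p, "nuclear")
    structure(list(
      channel = sb$stack, labels = labels,
      truth = list(
        nuclei = nuclei, puncta = puncta,
        expr_factor = p$expr_factor,
        expr_nucleus_value = expr_value,
        ctrl_nucleus_value = p$nucleus_intensity,
        background = p$nucleus_background,
        expressing_cols = seq_len(floor(half)),
        clean = sb$clean, seed = p$seed, params = p)),
      class = "wq_nuclear_scene")
  })
}

#' Generate a pair of DE tables with a controlled shared effect
#'
#' A fixture generator (not a simulation of count-based DE inference):
#' a designed fraction of differentially expressed genes carries the same
#' signed latent log2-fold-change effect in both tables, the remaining DE
#' genes carry independent effects in disjoint gene sets, and all other
#' genes have a null effect. Observed `log2fc` is effect plus Gaussian
#' noise; adjusted p-values are assigned deterministically from effect
#' rank so that exactly the designed genes fall below `alpha`.
#'
#' @param n_genes universe size.
#' @param frac_de_a,frac_de_b fractions of genes designed DE in each
#'   table.
#' @param shared_frac fraction of the smaller DE set sharing its effect
#'   with the other table (in `[0, 1]`).
#' @param lfc_scale effect magnitude scale; designed effects span
#'   `0.75..1.5` times this value.
#' @param noise_sd per-table Gaussian noise on the observed fold change.
#' @param seed integer seed.
#' @param alpha FDR threshold the designed calls are built around.
#' @return A list of class `wq_de_pair`: tables `a` and `b` (`gene_id`,
#'   `log2fc`, `padj`) and `truth` (designed set sizes, designed overlap
#'   and consistency, expected sign-agreement probability under the noise
#'   model, shared ids, seed).
#' @export
make_de_pair <- function(n_genes = 12956L, frac_de_a = 0.145,
                         frac_de_b = 0.318, shared_frac = 0.47,
                         lfc_scale = 2, noise_sd = 0.25, seed = 1L,
                         alpha = 0.05) {
  n_genes <- as.integer(n_genes)
  if (any(c(frac_de_a, frac_de_b, shared_frac) < 0) ||
      any(c(frac_de_a, frac_de_b, shared_frac) > 1))
    stopf("fractions must lie in [0, 1]")
  n_a <- round(frac_de_a * n_genes)
  n_b <- round(frac_de_b * n_genes)
  n_shared <- round(shared_frac * min(n_a, n_b))
  if (n_a + n_b - n_shared > n_genes)
    stopf("designed DE sets (%d + %d - %d shared) exceed the universe of %d",
          n_a, n_b, n_shared, n_genes)
  with_seed(seed, {
    ids <- sprintf("g%06d", seq_len(n_genes))
    shared_idx <- seq_len(n_shared)
    own_a_idx <- seq_len(n_a - n_shared) + n_shared
    own_b_idx <- seq_len(n_b - n_shared) + n_a

    magnitude <- function(m) lfc_scale * runif(m, 0.75, 1.5)
    signs <- function(m) sample(c(-1, 1), m, replace = TRUE)

    eff_a <- numeric(n_genes); eff_b <- numeric(n_genes)
    sh_eff <- signs(n_shared) * magnitude(n_shared)
    eff_a[shared_idx] <- sh_eff
    eff_b[shared_idx] <- sh_eff
    eff_a[own_a_idx] <- signs(length(own_a_idx)) * magnitude(length(own_a_idx))
    eff_b[own_b_idx] <- signs(length(own_b_idx)) * magnitude(length(own_b_idx))

    make_table <- function(eff, de_idx) {
      lfc <- eff + if (noise_sd > 0) rnorm(n_genes, 0, noise_sd) else 0
      padj <- numeric(n_genes)
      de <- seq_len(n_genes) %in% de_idx
      # deterministic from effect rank: stronger designed effects get
      # smaller adjusted p-values; non-DE genes sit strictly above alpha
      r_de <- rank(-abs(eff[de]), ties.method = "first")
      padj[de] <- alpha * r_de / (sum(de) + 1)
      r_ns <- rank(-abs(lfc[!de]), ties.method = "first")
      padj[!de] <- alpha + (1 - alpha) * r_ns / (sum(!de) + 1)
      data.frame(gene_id = ids, log2fc = lfc, padj = padj)
    }
    a <- make_table(eff_a, c(shared_idx, own_a_idx))
    b <- make_table(eff_b, c(shared_idx, own_b_idx))

    expected_consistent_prob <- if (n_shared == 0L) NA_real_
    else if (noise_sd == 0) 1
    else {
      pk <- stats::pnorm(abs(sh_eff) / noise_sd)
      mean(pk^2 + (1 - pk)^2)
    }
    structure(list(
      a = a, b = b,
      truth = list(
        n_genes = n_genes, design_n_a = n_a, design_n_b = n_b,
        design_n_overlap = n_shared,
        design_consistent_frac = if (n_shared > 0L) 1 else NA_real_,
        expected_consistent_prob = expected_consistent_prob,
        shared_ids = ids[shared_idx], alpha = alpha,
        noise_sd = noise_sd, seed = seed)), class = "wq_de_pair")
  })
}
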