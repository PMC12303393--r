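# Calibrated image containers and the shared low-level primitives:
# projections, 3x3 smoothing, isodata (intermeans) thresholding,
# fold-over-background masks and ROI means.

#' Calibrated z-stack of a single fluorescence channel
#'
#' The raw microscopy unit of the pipeline: a 3-D grid of non-negative
#' intensities together with its lateral pixel size and axial step.
#' Slices are stored as `voxels[, , k]` with `k = 1` the first section.
#'
#' @param voxels numeric array `(y, x, z)` of non-negative intensities,
#'   or a matrix (interpreted as a single slice).
#' @param pixel_size_um lateral pixel size in micrometres (x = y).
#' @param z_step_um distance between consecutive slices in micrometres.
#' @param channel_name free-text channel label.
#' @return An object of class `wq_stack`.
#' @examples
#' s <- image_stack(array(1, c(4, 4, 2)), pixel_size_um = 0.1, z_step_um = 0.38)
#' n_slices(s)
#' @export
image_stack <- function(voxels, pixel_size_um, z_step_um = pixel_size_um,
                        channel_name = "") {
  if (is.matrix(voxels)) voxels <- array(voxels, c(dim(voxels), 1L))
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stopf("'voxels' must be a (y, x, z) array or a matrix")
  d <- dim(voxels)
  if (d[1] < 2L || d[2] < 2L)
    stopf("each slice must be at least 2x2 px, got %dx%d", d[1], d[2])
  if (d[3] < 1L) stopf("stack must contain at least one slice")
  if (anyNA(voxels) || any(voxels < 0))
    stopf("intensities must be non-negative and finite")
  check_scalar_pos(pixel_size_um, "pixel_size_um")
  check_scalar_pos(z_step_um, "z_step_um")
  structure(
    list(voxels = voxels, pixel_size_um = pixel_size_um,
         z_step_um = z_step_um, channel_name = as.character(channel_name)),
    class = "wq_stack")
}

#' @export
print.wq_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<wq_stack> %s: %d x %d px, %d slices, %.3g um/px, dz %.3g um\n",
              if (nzchar(x$channel_name)) x$channel_name else "(unnamed)",
              d[2], d[1], d[3], x$pixel_size_um, x$z_step_um))
  invisible(x)
}

#' @rdname image_stack
#' @param x a `wq_stack`.
#' @export
n_slices <- function(x) dim(x$voxels)[3]

#' 2-D projection of a stack
#'
#' Carries the projected pixels, the projection method, the slice interval
#' used, and the lateral calibration inherited from the source stack.
#'
#' @param pixels numeric matrix of projected intensities.
#' @param method `"average"` or `"max"`.
#' @param z_range integer vector `c(first, last)` (1-based, inclusive).
#' @param pixel_size_um lateral calibration in micrometres.
#' @param channel_name free-text channel label.
#' @return An object of class `wq_projection`.
#' @export
projection <- function(pixels, method = c("average", "max"),
                       z_range = c(1L, 1L), pixel_size_um = 1,
                       channel_name = "") {
  method <- match.arg(method)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stopf("'pixels' must be a numeric matrix")
  check_scalar_pos(pixel_size_um, "pixel_size_um")
  structure(
    list(pixels = pixels, method = method,
         z_range = as.integer(z_range), pixel_size_um = pixel_size_um,
         channel_name = as.character(channel_name)),
    class = "wq_projection")
}

#' @export
print.wq_projection <- function(x, ...) {
  cat(sprintf("<wq_projection> %s: %d x %d px (%s of z %d..%d), %.3g um/px\n",
              if (nzchar(x$channel_name)) x$channel_name else "(unnamed)",
              ncol(x$pixels), nrow(x$pixels), x$method,
              x$z_range[1], x$z_range[2], x$pixel_size_um))
  invisible(x)
}

# Accept a projection or a bare matrix wherever only pixels matter.
as_pixels <- function(x) {
  if (inherits(x, "wq_projection")) return(x$pixels)
  if (is.matrix(x) && is.numeric(x)) return(x)
  stopf("expected a wq_projection or a numeric matrix")
}

#' Project a z-stack over a window of consecutive slices
#'
#' `average_projection()` reproduces the per-pixel arithmetic-mean projection
#' used throughout the pipeline (e.g. the mean of 4 consecutive sections
#' around the nuclear centres); `max_projection()` is retained for ROI
#' tracing support.
#'
#' @param stack a [image_stack()].
#' @param z_start first slice of the window (1-based).
#' @param n_slices_used number of consecutive slices; defaults to all
#'   remaining slices.
#' @return A [projection()] with calibration copied from the stack.
#' @examples
#' s <- image_stack(array(rep(1:4, each = 4), c(2, 2, 4)), 0.1)
#' average_projection(s)$pixels  # all pixels 2.5
#' @export
average_projection <- function(stack, z_start = 1L,
                               n_slices_used = n_slices(stack) - z_start + 1L) {
  project_window(stack, z_start, n_slices_used, "average")
}

#' @rdname average_projection
#' @export
max_projection <- function(stack, z_start = 1L,
                           n_slices_used = n_slices(stack) - z_start + 1L) {
  project_window(stack, z_start, n_slices_used, "max")
}

project_window <- function(stack, z_start, n, method) {
  stopifnot(inherits(stack, "wq_stack"))
  nz <- n_slices(stack)
  z_start <- as.integer(z_start); n <- as.integer(n)
  if (n < 1L || z_start < 1L || z_start + n - 1L > nz)
    stopf("slice window [%d, %d] outside stack with %d slices",
          z_start, z_start + n - 1L, nz)
  sub <- stack$voxels[, , z_start:(z_start + n - 1L), drop = FALSE]
  px <- if (method == "average") {
    rowMeans(sub, dims = 2L)
  } else {
    apply(sub, c(1L, 2L), max)
  }
  projection(px, method, c(z_start, z_start + n - 1L),
             stack$pixel_size_um, stack$channel_name)
}

# Summed-area table with a zero guard row/column, so window sums over
# arbitrary clipped rectangles are O(1).
sat <- function(x) {
  y <- apply(x, 2L, cumsum)
  if (!is.matrix(y)) y <- matrix(y, nrow = nrow(x))
  y <- t(apply(y, 1L, cumsum))
  rbind(0, cbind(0, y))
}

# In-bounds box sum and pixel count over a (2r+1)x(2r+1) window clipped to
# the image; the basis of both smooth_3x3 and the local-mean threshold.
box_stats <- function(x, r) {
  nr <- nrow(x); nc <- ncol(x)
  s <- sat(x)
  i0 <- pmax(seq_len(nr) - r, 1L); i1 <- pmin(seq_len(nr) + r, nr)
  j0 <- pmax(seq_len(nc) - r, 1L); j1 <- pmin(seq_len(nc) + r, nc)
  sums <- s[i1 + 1L, j1 + 1L, drop = FALSE] - s[i0, j1 + 1L, drop = FALSE] -
    s[i1 + 1L, j0, drop = FALSE] + s[i0, j0, drop = FALSE]
  counts <- outer(i1 - i0 + 1L, j1 - j0 + 1L)
  list(sum = sums, count = counts)
}

#' Smooth an image with a 3x3 mean filter
#'
#' Replaces every pixel with the arithmetic mean of its 3x3 neighbourhood,
#' the standard pre-blur applied before background thresholding. At edges
#' and corners the mean is taken over the in-bounds neighbours only, so no
#' padding value is invented.
#'
#' @param image a [projection()] or numeric matrix, at least 2x2 px.
#' @return Same type as the input, smoothed.
#' @export
smooth_3x3 <- function(image) {
  px <- as_pixels(image)
  if (nrow(px) < 2L || ncol(px) < 2L) stopf("image must be at least 2x2 px")
  b <- box_stats(px, 1L)
  out <- b$sum / b$count
  if (inherits(image, "wq_projection")) {
    image$pixels <- out
    image
  } else out
}

#' Iterative intermeans (isodata) threshold
#'
#' The automatic global threshold used to binarise channels before
#' colocalisation analysis (ImageJ's "Default" method). The histogram is
#' built on 256 equal bins spanning the image range; starting from the
#' global mean, the threshold is iterated as the midpoint of the means of
#' the two classes it induces until successive values differ by less than
#' half a bin width. Ties at a bin boundary fall to the lower class.
#'
#' @param image a [projection()] or numeric matrix with at least two
#'   distinct values.
#' @return The converged threshold, on the intensity scale of the image.
#' @examples
#' isodata_threshold(matrix(c(10, 10, 200, 200), 2))  # 105
#' @export
isodata_threshold <- function(image) {
  px <- as_pixels(image)
  lo <- min(px); hi <- max(px)
  if (!(hi > lo))
    stopf("isodata threshold undefined for a constant image (all pixels %g)", lo)
  nb <- 256L
  width <- (hi - lo) / nb
  bin <- pmin(floor((px - lo) / width) + 1L, nb)  # ties to the lower bin edge
  counts <- tabulate(bin, nbins = nb)
  centres <- lo + (seq_len(nb) - 0.5) * width
  t_cur <- sum(counts * centres) / sum(counts)   # global mean start
  for (iter in seq_len(1000L)) {
    below <- centres <= t_cur
    n_lo <- sum(counts[below]); n_hi <- sum(counts[!below])
    if (n_lo == 0L) { t_cur <- centres[1L]; next }
    if (n_hi == 0L) { t_cur <- centres[nb]; break }
    mu_lo <- sum(counts[below] * centres[below]) / n_lo
    mu_hi <- sum(counts[!below] * centres[!below]) / n_hi
    t_new <- (mu_lo + mu_hi) / 2
    if (abs(t_new - t_cur) < width / 2) return(t_new)
    t_cur <- t_new
  }
  t_cur
}

#' Binary mask of pixels above a multiple of the background
#'
#' The 2x-background rule used for cleaved-caspase particles and the
#' nuclear-level foreground: a pixel is foreground when its intensity
#' strictly exceeds `fold * background`. A pixel exactly at the cutoff is
#' excluded.
#'
#' @param image a [projection()] or numeric matrix.
#' @param background mean background intensity (> 0), typically measured in
#'   a caller-chosen region free of signal.
#' @param fold multiplier applied to the background (default 2).
#' @return A logical matrix of the same dimensions.
#' @export
fold_background_mask <- function(image, background, fold = 2) {
  check_scalar_pos(background, "background")
  check_scalar_pos(fold, "fold")
  as_pixels(image) > fold * background
}

#' Rectangular and polygonal regions of interest
#'
#' Coordinates are 1-based pixel positions: pixel `(x, y)` is column `x`,
#' row `y`. A rectangle of width `w` and height `h` anchored at `(x, y)`
#' covers columns `x .. x+w-1` and rows `y .. y+h-1`. For polygons a pixel
#' belongs to the ROI when its centre lies inside the closed polygon.
#'
#' @param x,y anchor column and row (rectangle) in pixels.
#' @param width,height rectangle extent in pixels.
#' @param xs,ys polygon vertex coordinates (pixel units, closed implicitly).
#' @param label free-text ROI label.
#' @return An object of class `wq_roi`.
#' @export
roi_rect <- function(x, y, width, height, label = "") {
  if (width < 1 || height < 1) stopf("ROI must cover at least 1 px")
  structure(list(type = "rect", x = x, y = y, width = width, height = height,
                 label = label), class = "wq_roi")
}

#' @rdname roi_rect
#' @export
roi_polygon <- function(xs, ys, label = "") {
  if (length(xs) != length(ys) || length(xs) < 3L)
    stopf("polygon needs >= 3 vertices with matching x and y")
  structure(list(type = "polygon", xs = as.numeric(xs), ys = as.numeric(ys),
                 label = label), class = "wq_roi")
}

#' @export
print.wq_roi <- function(x, ...) {
  if (x$type == "rect")
    cat(sprintf("<wq_roi> rect %gx%g at (%g, %g) '%s'\n",
                x$width, x$height, x$x, x$y, x$label))
  else
    cat(sprintf("<wq_roi> polygon with %d vertices '%s'\n",
                length(x$xs), x$label))
  invisible(x)
}

# Logical membership mask of an ROI on an nr x nc image. Errors when the
# ROI extends outside the image or selects no pixel.
roi_mask <- function(roi, nr, nc) {
  stopifnot(inherits(roi, "wq_roi"))
  m <- matrix(FALSE, nr, nc)
  if (roi$type == "rect") {
    x0 <- roi$x; y0 <- roi$y
    x1 <- x0 + roi$width - 1; y1 <- y0 + roi$height - 1
    if (x0 < 1 || y0 < 1 || x1 > nc || y1 > nr)
      stopf("ROI [%g..%g] x [%g..%g] outside %d x %d image", x0, x1, y0, y1, nc, nr)
    m[y0:y1, x0:x1] <- TRUE
  } else {
    if (min(roi$xs) < 0.5 || max(roi$xs) > nc + 0.5 ||
        min(roi$ys) < 0.5 || max(roi$ys) > nr + 0.5)
      stopf("polygon ROI outside %d x %d image", nc, nr)
    cx <- rep(seq_len(nc), each = nr)
    cy <- rep(seq_len(nr), times = nc)
    inside <- pracma::inpolygon(cx, cy, roi$xs, roi$ys, boundary = TRUE)
    m[cbind(cy[inside], cx[inside])] <- TRUE
  }
  if (!any(m)) stopf("ROI selects no pixel")
  m
}

#' Mean intensity inside a region of interest
#'
#' Arithmetic mean of the pixels whose centres fall inside the ROI; the
#' measurement behind reporter-level readouts such as a 50x50 px square
#' positioned over an expressing or control region.
#'
#' @param image a [projection()] or numeric matrix.
#' @param roi a [roi_rect()] or [roi_polygon()].
#' @return Mean intensity (scalar).
#' @export
roi_mean <- function(image, roi) {
  px <- as_pixels(image)
  mean(px[roi_mask(roi, nrow(px), ncol(px))])
}

#' Numeric settings of the quantification procedures
#'
#' One container for every tunable constant of the pipeline, with defaults
#' matching the published procedure: 3x3 mean pre-smoothing, boundary
#' dilation radius 3 px, Gaussian sigma 2 px and 200 px minimum area for
#' nuclear puncta, 4 um^2 minimum particle size and 2x background threshold
#' for apoptosis scoring, FDR 0.05 and |log2 fold change| > 1 for DE calls,
#' and 50 px ROI squares for reporter levels.
#'
#' @param dilation_radius_px city-block radius of the boundary dilation.
#' @param gaussian_sigma_px sigma of the Gaussian pre-blur for puncta.
#' @param min_punctum_area_px minimum punctum area, in pixels.
#' @param min_particle_area_um2 minimum apoptotic-particle area, in um^2.
#' @param background_fold background multiplier of the foreground cutoff.
#' @param de_alpha FDR threshold for differential-expression calls.
#' @param de_lfc_cutoff absolute log2-fold-change cutoff for DE calls.
#' @param roi_side_px side of the square reporter ROI, in pixels.
#' @return A list of class `wq_params`.
#' @export
quant_params <- function(dilation_radius_px = 3L, gaussian_sigma_px = 2,
                         min_punctum_area_px = 200L,
                         min_particle_area_um2 = 4, background_fold = 2,
                         de_alpha = 0.05, de_lfc_cutoff = 1,
                         roi_side_px = 50L) {
  p <- list(dilation_radius_px = as.integer(dilation_radius_px),
            gaussian_sigma_px = gaussian_sigma_px,
            min_punctum_area_px = as.integer(min_punctum_area_px),
            min_particle_area_um2 = min_particle_area_um2,
            background_fold = background_fold,
            de_alpha = de_alpha, de_lfc_cutoff = de_lfc_cutoff,
            roi_side_px = as.integer(roi_side_px))
  for (nm in names(p)) check_scalar_pos(p[[nm]], nm)
  if (de_alpha >= 1) stopf("'de_alpha' must lie in (0, 1)")
  class(p) <- "wq_params"
  p
}
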