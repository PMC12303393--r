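# Nuclear-compartment quantification: adaptive-threshold puncta detection,
# per-nucleus means over external label maps, background-subtracted
# control-normalised region levels, and nuclear/cytoplasm ratios.

#' Detect bright nuclear puncta by adaptive local thresholding
#'
#' The image is smoothed with a Gaussian kernel, binarised against a
#' local-mean threshold, and 8-connected components are filtered by a
#' minimum area and a border rule. A pixel is foreground when its smoothed
#' value exceeds `(2 - sensitivity)` times the local mean over a square
#' window: at the default sensitivity 0.5 the cutoff sits at 1.5x the
#' local mean, which for an isolated bright punctum on a darker nucleus
#' lands near the half-maximum of the blurred edge, so detected areas
#' track the true punctum footprint. Components smaller than `min_area`
#' or touching any image border are removed. Areas are reported in pixels
#' exactly as filtered (no micrometre conversion), so the default 200 px
#' floor is calibration-dependent.
#'
#' @param image a [projection()] or numeric matrix.
#' @param sigma Gaussian pre-blur sigma in pixels (default 2; 0 disables
#'   the blur).
#' @param min_area minimum punctum area in pixels (default 200).
#' @param window odd side of the local-mean window; default an odd number
#'   near one-eighth of the smaller image dimension.
#' @param sensitivity local-threshold sensitivity in (0, 1]; larger values
#'   lower the cutoff and detect more.
#' @return Data frame with one row per punctum: `id`, `area_px`,
#'   `mean_intensity` (measured on the unsmoothed image), `centroid_x`,
#'   `centroid_y`.
#' @export
detect_puncta <- function(image, sigma = 2, min_area = 200L, window = NULL,
                          sensitivity = 0.5) {
  px <- as_pixels(image)
  nr <- nrow(px); nc <- ncol(px)
  if (is.null(window)) {
    window <- floor(min(nr, nc) / 8)
    window <- max(3L, window + (window %% 2L == 0L))
  }
  window <- as.integer(window)
  if (window %% 2L == 0L) stopf("'window' must be odd")
  if (window > min(nr, nc))
    stopf("local window (%d px) larger than the image (%d x %d)", window, nc, nr)
  if (sensitivity <= 0 || sensitivity > 1)
    stopf("'sensitivity' must lie in (0, 1]")
  sm <- if (sigma > 0) EBImage::gblur(px, sigma = sigma) else px
  b <- box_stats(sm, (window - 1L) %/% 2L)
  fg <- sm > (2 - sensitivity) * (b$sum / b$count)
  lab <- label_components(fg, connectivity = 8L)
  empty <- data.frame(id = integer(), area_px = integer(),
                      mean_intensity = numeric(),
                      centroid_x = numeric(), centroid_y = numeric())
  n <- max(lab)
  if (n == 0L) return(empty)
  areas <- tabulate(lab, nbins = n)
  border_ids <- setdiff(unique(c(lab[1L, ], lab[nr, ], lab[, 1L], lab[, nc])), 0L)
  keep <- which(areas >= min_area & !(seq_len(n) %in% border_ids))
  if (!length(keep)) return(empty)
  rows <- lapply(seq_along(keep), function(i) {
    idx <- which(lab == keep[i], arr.ind = TRUE)
    data.frame(id = i, area_px = nrow(idx),
               mean_intensity = mean(px[idx]),
               centroid_x = mean(idx[, 2L]), centroid_y = mean(idx[, 1L]))
  })
  do.call(rbind, rows)
}

#' Per-nucleus mean intensities over a label map
#'
#' One mean per distinct nonzero label, in increasing label order, as used
#' for nucleus-by-nucleus protein levels over an externally produced
#' segmentation.
#'
#' @param image a [projection()] or numeric matrix.
#' @param labels integer label map of the same dimensions (0 = background).
#' @return Data frame with `nucleus_id`, `area_px`, `mean_intensity`.
#'   Warns and returns zero rows for an empty label map.
#' @export
nucleus_means <- function(image, labels) {
  px <- as_pixels(image)
  stopifnot(is.matrix(labels))
  if (!identical(dim(px), dim(labels)))
    stopf("image and label map differ in dimensions")
  nz <- labels > 0L
  if (!any(nz)) {
    warnf("label map contains no nucleus")
    return(data.frame(nucleus_id = integer(), area_px = integer(),
                      mean_intensity = numeric()))
  }
  ids <- sort(unique(labels[nz]))
  means <- vapply(ids, function(id) mean(px[labels == id]), numeric(1))
  areas <- vapply(ids, function(id) sum(labels == id), integer(1))
  data.frame(nucleus_id = as.integer(ids), area_px = areas,
             mean_intensity = means)
}

region_in_out <- function(px, mask, what) {
  if (!any(mask)) stopf("empty foreground in the %s image", what)
  if (all(mask)) stopf("foreground covers the whole %s image", what)
  c(inside = mean(px[mask]), outside = mean(px[!mask]))
}

#' Background-subtracted, control-normalised region level
#'
#' The average-nuclear-level readout: in each (pre-smoothed) image the
#' foreground is the set of pixels above `fold` times that image's
#' measured background; the level is
#' `(expr_in - expr_out) / (ctrl_in - ctrl_out)`, where `in`/`out` are
#' mean intensities inside and outside the foreground. The subtraction of
#' the outside mean is the background correction; division by the control
#' (non-expressing) region normalises out staining strength. A shared
#' mask (e.g. one defined on the control region's signal) may be supplied
#' to override the per-image thresholds.
#'
#' @param expr_img,ctrl_img [projection()]s or matrices of the
#'   transgene-expressing and control regions (smooth upstream with
#'   [smooth_3x3()] to mirror the standard procedure).
#' @param expr_bg,ctrl_bg measured background means (> 0); ignored for an
#'   image whose mask is supplied directly.
#' @param fold background multiplier of the foreground cutoff (default 2).
#' @param expr_mask,ctrl_mask optional logical foreground masks.
#' @return The normalised level (dimensionless scalar).
#' @examples
#' e <- matrix(c(50, 50, 10, 10), 2); c0 <- matrix(c(80, 80, 10, 10), 2)
#' normalised_region_level(e, c0, expr_bg = 10, ctrl_bg = 10)  # 40/70
#' @export
normalised_region_level <- function(expr_img, ctrl_img, expr_bg, ctrl_bg,
                                    fold = 2, expr_mask = NULL,
                                    ctrl_mask = NULL) {
  pe <- as_pixels(expr_img); pc <- as_pixels(ctrl_img)
  if (is.null(expr_mask)) expr_mask <- fold_background_mask(pe, expr_bg, fold)
  if (is.null(ctrl_mask)) ctrl_mask <- fold_background_mask(pc, ctrl_bg, fold)
  e <- region_in_out(pe, expr_mask, "expressing")
  k <- region_in_out(pc, ctrl_mask, "control")
  denom <- k[["inside"]] - k[["outside"]]
  if (denom <= 0)
    stopf("control inside-outside difference is %.4g: normalisation undefined", denom)
  (e[["inside"]] - e[["outside"]]) / denom
}

#' Control-normalised nuclear/cytoplasm intensity ratio
#'
#' For each region the ratio of mean intensity inside the foreground mask
#' to the mean outside it is formed; the result is the expressing-region
#' ratio divided by the control-region ratio.
#'
#' @param expr_img,ctrl_img [projection()]s or matrices.
#' @param expr_mask,ctrl_mask logical foreground (nuclear) masks, neither
#'   empty nor covering the whole image.
#' @return The normalised ratio (dimensionless scalar).
#' @examples
#' e <- matrix(c(60, 60, 30, 30), 2); c0 <- matrix(c(90, 90, 30, 30), 2)
#' m <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2)
#' nc_ratio(e, c0, m, m)  # (60/30)/(90/30) = 2/3
#' @export
nc_ratio <- function(expr_img, ctrl_img, expr_mask, ctrl_mask) {
  e <- region_in_out(as_pixels(expr_img), expr_mask, "expressing")
  k <- region_in_out(as_pixels(ctrl_img), ctrl_mask, "control")
  (e[["inside"]] / e[["outside"]]) / (k[["inside"]] / k[["outside"]])
}
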