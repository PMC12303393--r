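# Apoptosis scoring from cleaved-caspase (Dcp-1) staining: 3x3 smoothing,
# 2x-background thresholding, particle analysis with a physical area floor,
# reported as the percent of the ROI covered by qualifying particles.

#' Apoptotic area fraction of a region of interest
#'
#' The cleaved-Dcp-1 procedure: the projection is smoothed with the 3x3
#' mean filter, thresholded at `background_fold` times the measured
#' background (strictly above), and 8-connected particles are counted
#' within the ROI. Particles are clipped to the ROI before the size test,
#' so a particle straddling the ROI edge counts only its inside pixels;
#' particles whose clipped area is at least `min_particle_area_um2`
#' (default 4 um^2, converted through the pixel size) qualify. The result
#' is the percentage of ROI pixels covered by qualifying particles.
#'
#' @param image a [projection()] (calibrated) or numeric matrix with
#'   `pixel_size_um` supplied.
#' @param roi a [roi_rect()] or [roi_polygon()] tracing the scored region
#'   (e.g. the wing pouch).
#' @param background mean background intensity measured outside apoptotic
#'   cells, on the raw (unsmoothed) projection.
#' @param params a [quant_params()]; `background_fold` and
#'   `min_particle_area_um2` are used.
#' @param pixel_size_um lateral calibration, required when `image` is a
#'   bare matrix.
#' @return A list of class `wq_apoptosis`: `roi_area_px`, `roi_area_um2`,
#'   `particle_count`, `particle_area_um2`, `area_fraction_pct`.
#' @export
dcp1_area_fraction <- function(image, roi, background,
                               params = quant_params(),
                               pixel_size_um = NULL) {
  if (inherits(image, "wq_projection") && is.null(pixel_size_um))
    pixel_size_um <- image$pixel_size_um
  if (is.null(pixel_size_um))
    stopf("pixel_size_um is required (missing calibration)")
  check_scalar_pos(pixel_size_um, "pixel_size_um")
  px <- as_pixels(image)
  sm <- smooth_3x3(px)
  mask <- fold_background_mask(sm, background, params$background_fold)
  inroi <- roi_mask(roi, nrow(px), ncol(px))
  clipped <- mask & inroi
  lab <- label_components(clipped, connectivity = 8L)
  n <- max(lab)
  qual_px <- 0L; qual_n <- 0L
  if (n > 0L) {
    areas <- tabulate(lab, nbins = n)
    qual <- areas * pixel_size_um^2 >= params$min_particle_area_um2
    qual_px <- sum(areas[qual])
    qual_n <- sum(qual)
  }
  structure(list(
    roi_area_px = sum(inroi),
    roi_area_um2 = sum(inroi) * pixel_size_um^2,
    particle_count = qual_n,
    particle_area_um2 = qual_px * pixel_size_um^2,
    area_fraction_pct = 100 * qual_px / sum(inroi)), class = "wq_apoptosis")
}

#' @export
print.wq_apoptosis <- function(x, ...) {
  cat(sprintf("<wq_apoptosis> %d particles, %.4g um^2, %.3f%% of %.4g um^2 ROI\n",
              x$particle_count, x$particle_area_um2, x$area_fraction_pct,
              x$roi_area_um2))
  invisible(x)
}
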