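# File interfaces: grayscale TIFF stacks and projections, binary masks
# (TIFF/PNG), 16-bit label maps, ROI sidecars, and DE result tables.

#' Read a grayscale TIFF z-stack
#'
#' Single- and multi-page grayscale TIFF, 8/16-bit integer (read in native
#' intensity units) or 32-bit float. Multi-sample (RGB) pages are rejected.
#'
#' @param path TIFF file.
#' @param pixel_size_um,z_step_um calibration, supplied by the caller
#'   (TIFF resolution tags are not trusted for confocal data).
#' @param channel_name channel label; defaults to the file name.
#' @return A [image_stack()].
#' @export
read_stack <- function(path, pixel_size_um, z_step_um = pixel_size_um,
                       channel_name = basename(path)) {
  info <- tiff::readTIFF(path, payload = FALSE)
  # integer TIFFs are read in native units; 32-bit (float-scaled) TIFFs
  # come back on the [0, 1] storage scale of write_image_tiff()
  as_is <- info$bits.per.sample[1] <= 16
  pages <- tiff::readTIFF(path, all = TRUE, as.is = as_is)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) {
      if (dim(p)[3] != 1L) stopf("'%s' is not single-channel grayscale", path)
      p <- p[, , 1L]
    }
    p
  })
  d <- dim(pages[[1L]])
  if (!all(vapply(pages, function(p) identical(dim(p), d), logical(1))))
    stopf("pages of '%s' differ in size", path)
  vox <- array(unlist(pages, use.names = FALSE), c(d, length(pages)))
  image_stack(vox, pixel_size_um, z_step_um, channel_name)
}

#' Write and read floating-point images as TIFF
#'
#' Intensities are stored scaled into `[0, 1]` by `max_value` (32-bit
#' storage), so arbitrary non-negative dynamic ranges survive the trip;
#' `read_image_tiff()` applies the inverse scale.
#'
#' @param image a [projection()], [image_stack()] or numeric matrix/array.
#' @param path destination/source file.
#' @param max_value full-scale intensity; default the image maximum (or 1
#'   for an all-zero image).
#' @return `write_image_tiff()` returns `max_value` invisibly;
#'   `read_image_tiff()` a numeric matrix or `(y, x, z)` array.
#' @export
write_image_tiff <- function(image, path, max_value = NULL) {
  x <- if (inherits(image, "wq_stack")) image$voxels else as_pixels_or_array(image)
  if (is.null(max_value)) max_value <- max(x, 1e-12)
  if (length(dim(x)) == 3L) {
    pages <- lapply(seq_len(dim(x)[3]), function(k) x[, , k] / max_value)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  } else {
    tiff::writeTIFF(x / max_value, path, bits.per.sample = 32L)
  }
  invisible(max_value)
}

as_pixels_or_array <- function(x) {
  if (inherits(x, "wq_projection")) return(x$pixels)
  if (is.array(x) || is.matrix(x)) return(x)
  stopf("unsupported image type")
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path, max_value = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 1L) return(pages[[1L]] * max_value)
  array(unlist(pages, use.names = FALSE),
        c(dim(pages[[1L]]), length(pages))) * max_value
}

#' Read and write binary masks (junction skeletons, thresholds)
#'
#' Masks are any TIFF or PNG in which nonzero means foreground; they are
#' written as 8-bit images with foreground 255.
#'
#' @param path TIFF or PNG file (by extension).
#' @param mask logical matrix.
#' @return `read_mask()` returns a logical matrix.
#' @export
read_mask <- function(path) {
  img <- read_raster(path)
  img > 0
}

#' @rdname read_mask
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.logical(mask), is.matrix(mask))
  x <- matrix(as.numeric(mask), nrow(mask))
  if (grepl("\\.png$", path, ignore.case = TRUE)) png::writePNG(x, path)
  else tiff::writeTIFF(x, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read and write 16-bit label maps (nucleus or cell segmentations)
#'
#' Label maps are integer images with 0 = background and positive ids for
#' objects, as produced by external segmentation tools.
#'
#' @param path TIFF or PNG file.
#' @param labels integer matrix with values in `0 .. 65535`.
#' @return `read_label_map()` returns an integer matrix.
#' @export
read_label_map <- function(path) {
  img <- read_raster(path, as_is = TRUE)
  storage.mode(img) <- "integer"
  img
}

#' @rdname read_label_map
#' @export
write_label_map <- function(labels, path) {
  stopifnot(is.matrix(labels), min(labels) >= 0, max(labels) <= 65535)
  x <- labels / 65535
  if (grepl("\\.png$", path, ignore.case = TRUE)) png::writePNG(x, path)
  else tiff::writeTIFF(x, path, bits.per.sample = 16L)
  invisible(path)
}

read_raster <- function(path, as_is = FALSE) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    if (as_is) img <- round(img * 65535)
    img
  } else {
    img <- tiff::readTIFF(path, as.is = as_is)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    img
  }
}

#' Read ROIs from a plain-text sidecar
#'
#' CSV with columns `label`, `type`, and coordinates: rectangles use one
#' row with `x`, `y`, `width`, `height`; polygons use one row per vertex
#' with `x`, `y` (rows grouped by label, in vertex order).
#'
#' @param path CSV file.
#' @return A named list of [roi_rect()]/[roi_polygon()] objects.
#' @export
read_rois <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "type", "x", "y")
  if (!all(need %in% names(df)))
    stopf("ROI file '%s' must have columns %s", path, paste(need, collapse = ", "))
  out <- list()
  for (lb in unique(df$label)) {
    rows <- df[df$label == lb, , drop = FALSE]
    ty <- rows$type[1L]
    out[[as.character(lb)]] <- if (ty == "rect") {
      roi_rect(rows$x[1L], rows$y[1L], rows$width[1L], rows$height[1L], label = lb)
    } else if (ty == "polygon") {
      roi_polygon(rows$x, rows$y, label = lb)
    } else stopf("unknown ROI type '%s' for label '%s'", ty, lb)
  }
  out
}

#' @rdname read_rois
#' @param rois named list of ROI objects.
#' @export
write_rois <- function(rois, path) {
  rows <- lapply(rois, function(r) {
    if (r$type == "rect")
      data.frame(label = r$label, type = "rect", x = r$x, y = r$y,
                 width = r$width, height = r$height)
    else
      data.frame(label = r$label, type = "polygon", x = r$xs, y = r$ys,
                 width = NA, height = NA)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a differential-expression result table
#'
#' CSV or TSV (by extension or sniffed separator) with required columns
#' `gene_id`, `log2fc` and `padj`; extra columns are ignored. Missing
#' adjusted p-values are kept as `NA` (they yield non-significant calls,
#' never silent row drops).
#'
#' @param path CSV/TSV file.
#' @return A `data.frame` with columns `gene_id`, `log2fc`, `padj`.
#' @export
read_de_table <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("gene_id", "log2fc", "padj")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("DE table '%s' lacks column(s): %s", path, paste(miss, collapse = ", "))
  out <- df[, need]
  out$gene_id <- as.character(out$gene_id)
  out$log2fc <- as.numeric(out$log2fc)
  out$padj <- as.numeric(out$padj)
  out
}

#' Read a gene set from newline-delimited text
#'
#' @param path text file, one identifier per line; blank lines and lines
#'   starting with `#` are skipped.
#' @return Character vector of unique identifiers.
#' @export
read_gene_set <- function(path) {
  x <- trimws(readLines(path))
  unique(x[nzchar(x) & !startsWith(x, "#")])
}
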