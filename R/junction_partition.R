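# Per-cell membrane/cytoplasm partitioning from a junction-skeleton mask:
# 4-connected cell labelling, city-block dilation of each cell's perimeter
# into a membrane compartment, and intensity measurement in both.

#' Label connected components of a binary mask
#'
#' Thin wrapper around the package's two-pass union-find labeller. Cells
#' are labelled with 4-connectivity (so a 1-px 8-connected skeleton fully
#' separates neighbours); bright blobs (puncta, particles) with
#' 8-connectivity.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return Integer matrix; 0 = background, components numbered from 1 in
#'   raster order of first encounter.
#' @export
label_components <- function(mask, connectivity = 4L) {
  stopifnot(is.matrix(mask))
  if (!is.logical(mask)) {
    if (!all(mask %in% c(0, 1))) stopf("mask must be binary")
    mask <- mask > 0
  }
  .cc_label(mask, as.integer(connectivity))
}

#' Dilate a binary mask by a city-block (L1) ball
#'
#' The "diamond" morphological dilation used both to grow cell perimeters
#' into membrane compartments and to widen the junction skeleton into the
#' excluded border zone of cytoplasm-only colocalisation. A radius-`r`
#' city-block ball covers all pixels at Manhattan distance `<= r`.
#'
#' @param mask logical matrix.
#' @param radius city-block radius in pixels (>= 1).
#' @return Logical matrix of the same dimensions.
#' @export
dilate_cityblock <- function(mask, radius = 3L) {
  stopifnot(is.matrix(mask), is.logical(mask))
  radius <- as.integer(radius)
  if (radius < 1L) stopf("'radius' must be >= 1")
  if (!any(mask)) return(mask)
  brush <- EBImage::makeBrush(2L * radius + 1L, shape = "diamond")
  EBImage::dilate(matrix(as.numeric(mask), nrow(mask)), brush) > 0
}

#' Identify cells as connected regions between junctions
#'
#' Every 4-connected region of non-skeleton pixels becomes a candidate
#' cell; regions below `min_cell_area_px` (segmentation specks) are
#' dropped, and regions touching the image border are dropped by default
#' because cropped fields make them partial cells.
#'
#' @param skeleton logical matrix, `TRUE` on the 1-px junction network.
#' @param min_cell_area_px minimum region area kept, in pixels.
#' @param exclude_border_cells drop regions touching the image border.
#' @return Integer label map (0 = skeleton/dropped, cells numbered 1..n).
#'   Warns and returns an all-zero map when no cell survives.
#' @examples
#' sk <- matrix(FALSE, 9, 9); sk[5, ] <- TRUE; sk[, 5] <- TRUE
#' max(label_cells(sk, min_cell_area_px = 1, exclude_border_cells = FALSE))
#' @export
label_cells <- function(skeleton, min_cell_area_px = 20L,
                        exclude_border_cells = TRUE) {
  stopifnot(is.matrix(skeleton))
  if (!is.logical(skeleton)) skeleton <- skeleton > 0
  lab <- label_components(!skeleton, connectivity = 4L)
  n <- max(lab)
  if (n == 0L) {
    warnf("skeleton covers the whole image: no cells found")
    return(lab)
  }
  keep <- tabulate(lab, nbins = n) >= min_cell_area_px
  if (exclude_border_cells) {
    border_ids <- unique(c(lab[1L, ], lab[nrow(lab), ], lab[, 1L], lab[, ncol(lab)]))
    keep[setdiff(border_ids, 0L)] <- FALSE
  }
  if (!any(keep)) {
    warnf("no cell passes the area/border filters")
    return(matrix(0L, nrow(lab), ncol(lab)))
  }
  remap <- integer(n)
  remap[keep] <- seq_len(sum(keep))
  out <- matrix(0L, nrow(lab), ncol(lab))
  nz <- lab > 0L
  out[nz] <- remap[lab[nz]]
  out
}

# Perimeter pixels of a region: region pixels with a 4-neighbour outside
# the region, or lying on the image border.
region_perimeter <- function(region) {
  nr <- nrow(region); nc <- ncol(region)
  inner <- matrix(FALSE, nr, nc)
  if (nr > 2L && nc > 2L) {
    core <- region[2:(nr - 1), 2:(nc - 1)] &
      region[1:(nr - 2), 2:(nc - 1)] & region[3:nr, 2:(nc - 1)] &
      region[2:(nr - 1), 1:(nc - 2)] & region[2:(nr - 1), 3:nc]
    inner[2:(nr - 1), 2:(nc - 1)] <- core
  }
  region & !inner
}

#' Partition labelled cells into membrane and cytoplasm compartments
#'
#' For each cell the perimeter of its region is dilated by a city-block
#' ball of the given radius; the dilated band is the cell's membrane
#' compartment (it may extend onto the skeleton and into neighbouring
#' cells, so membrane masks of adjacent cells can overlap), and the
#' region minus the band is its cytoplasm. Cells whose cytoplasm is
#' consumed entirely by the dilation are flagged and their cytoplasm
#' statistics reported as undefined.
#'
#' @param cells integer label map from [label_cells()].
#' @param radius city-block dilation radius in pixels (default 3).
#' @return A `wq_partition`: per cell the pixel indices of region,
#'   membrane and cytoplasm masks, plus the radius used.
#' @export
build_partition <- function(cells, radius = 3L) {
  stopifnot(is.matrix(cells))
  radius <- as.integer(radius)
  if (radius < 1L) stopf("'radius' must be >= 1")
  n <- max(cells)
  d <- dim(cells)
  per_cell <- vector("list", n)
  for (id in seq_len(n)) {
    region <- cells == id
    perim <- region_perimeter(region)
    membrane <- dilate_cityblock(perim, radius)
    cytoplasm <- region & !membrane
    per_cell[[id]] <- list(
      cell_id = id,
      region_idx = which(region),
      membrane_idx = which(membrane),
      cytoplasm_idx = which(cytoplasm),
      flagged = !any(cytoplasm))
  }
  structure(list(cells = per_cell, dim = d, radius = radius),
            class = "wq_partition")
}

#' @export
print.wq_partition <- function(x, ...) {
  nf <- sum(vapply(x$cells, `[[`, logical(1), "flagged"))
  cat(sprintf("<wq_partition> %d cells (%d flagged), radius %d, %d x %d px\n",
              length(x$cells), nf, x$radius, x$dim[2], x$dim[1]))
  invisible(x)
}

#' Measure channel intensities per membrane/cytoplasm compartment
#'
#' Per-cell mean and total (sum of pixel intensities) for the membrane and
#' cytoplasm masks, and disc-level summaries computed as unweighted means
#' over non-flagged cells, so each cell contributes equally regardless of
#' its size. The headline readout is `cyto_to_border_ratio`, the ratio of
#' the disc-level cytoplasm and membrane means.
#'
#' @param channel a [projection()] or numeric matrix matching the
#'   partition's dimensions.
#' @param partition a [build_partition()] result.
#' @return A `wq_intensity_table`: `$cells` data frame (one row per cell)
#'   and `$disc` data frame with `disc_border_mean`, `disc_cyto_mean` and
#'   `cyto_to_border_ratio`.
#' @export
measure_partition <- function(channel, partition) {
  stopifnot(inherits(partition, "wq_partition"))
  px <- as_pixels(channel)
  if (!identical(dim(px), partition$dim))
    stopf("channel is %d x %d but partition expects %d x %d",
          nrow(px), ncol(px), partition$dim[1], partition$dim[2])
  if (!length(partition$cells)) {
    warnf("no unflagged cell to summarise")
    return(structure(list(
      cells = data.frame(cell_id = integer(), membrane_px = integer(),
                         membrane_mean = numeric(), membrane_total = numeric(),
                         cytoplasm_px = integer(), cytoplasm_mean = numeric(),
                         cytoplasm_total = numeric(), flagged = logical()),
      disc = data.frame(n_cells = 0L, disc_border_mean = NA_real_,
                        disc_cyto_mean = NA_real_,
                        cyto_to_border_ratio = NA_real_)),
      class = "wq_intensity_table"))
  }
  rows <- lapply(partition$cells, function(cc) {
    mem <- px[cc$membrane_idx]
    cyt <- px[cc$cytoplasm_idx]
    data.frame(
      cell_id = cc$cell_id,
      membrane_px = length(mem),
      membrane_mean = mean(mem),
      membrane_total = sum(mem),
      cytoplasm_px = length(cyt),
      cytoplasm_mean = if (cc$flagged) NA_real_ else mean(cyt),
      cytoplasm_total = if (cc$flagged) NA_real_ else sum(cyt),
      flagged = cc$flagged)
  })
  cells <- do.call(rbind, rows)
  ok <- cells[!cells$flagged, , drop = FALSE]
  if (nrow(ok) == 0L) {
    warnf("no unflagged cell to summarise")
    disc <- data.frame(n_cells = 0L, disc_border_mean = NA_real_,
                       disc_cyto_mean = NA_real_, cyto_to_border_ratio = NA_real_)
  } else {
    disc <- data.frame(
      n_cells = nrow(ok),
      disc_border_mean = mean(ok$membrane_mean),
      disc_cyto_mean = mean(ok$cytoplasm_mean),
      cyto_to_border_ratio = mean(ok$cytoplasm_mean) / mean(ok$membrane_mean))
  }
  structure(list(cells = cells, disc = disc), class = "wq_intensity_table")
}

#' @export
print.wq_intensity_table <- function(x, ...) {
  cat(sprintf("<wq_intensity_table> %d cells; border mean %.4g, cyto mean %.4g, ratio %.4g\n",
              nrow(x$cells), x$disc$disc_border_mean, x$disc$disc_cyto_mean,
              x$disc$cyto_to_border_ratio))
  invisible(x)
}

#' Write an intensity table as CSV (cells plus a disc-summary row)
#'
#' @param x a `wq_intensity_table`.
#' @param path output CSV.
#' @param params optional parameter list recorded in `#` header lines.
#' @export
write_intensity_table <- function(x, path, params = NULL) {
  stopifnot(inherits(x, "wq_intensity_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(params), con)
  cells <- x$cells
  cells$row_type <- "cell"
  summ <- data.frame(cell_id = NA, membrane_px = NA,
                     membrane_mean = x$disc$disc_border_mean, membrane_total = NA,
                     cytoplasm_px = NA, cytoplasm_mean = x$disc$disc_cyto_mean,
                     cytoplasm_total = NA, flagged = NA, row_type = "disc_summary")
  write.csv(rbind(cells, summ), con, row.names = FALSE)
  invisible(path)
}

provenance_header <- function(params = NULL) {
  # no timestamp: outputs must be byte-identical across reruns
  h <- sprintf("# wingquant %s", as.character(packageVersion("wingquant")))
  if (!is.null(params)) {
    kv <- vapply(names(params), function(k) {
      sprintf("%s=%s", k, paste(format(params[[k]]), collapse = ";"))
    }, character(1))
    h <- c(h, paste0("# params: ", paste(kv, collapse = " ")))
  }
  h
}
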