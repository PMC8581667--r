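# Single-cell detection on the nuclear channel and per-cell marker
# quantification over detected footprints.

#' Detect cell nuclei by thresholding and watershed splitting
#'
#' Thresholds the nuclear (hematoxylin) channel inside the ROI (Otsu on the
#' ROI-restricted histogram unless a threshold is given), splits touching
#' nuclei by a distance-transform watershed, and keeps connected components
#' with area within `[min_area_px, max_area_px]`. Deterministic.
#'
#' @param hematoxylin A `gray_image` of the nuclear channel.
#' @param roi A `binary_mask` restricting the detection, same grid.
#' @param min_area_px,max_area_px Area gate for retained nuclei.
#' @param threshold Optional fixed nuclear threshold; default Otsu.
#' @param watershed_tolerance Minimum object-height difference for the
#'   watershed split (in distance-map units).
#' @return Data frame with `cell_id`, centroid `x`, `y` (pixels) and
#'   `area_px`, carrying the labeled footprint matrix as attribute
#'   `labels` and the threshold used as attribute `threshold`.
#' @export
detect_cells <- function(hematoxylin, roi, min_area_px = 5L,
                         max_area_px = 200L, threshold = NULL,
                         watershed_tolerance = 0.5) {
  stopifnot(inherits(hematoxylin, "gray_image"), inherits(roi, "binary_mask"),
            identical(dim(hematoxylin$pixels), dim(roi$pixels)))
  if (!any(roi$pixels))
    stop("empty ROI: no cells detectable", call. = FALSE)
  px <- hematoxylin$pixels
  if (is.null(threshold)) {
    h <- intensity_histogram(px[roi$pixels])
    threshold <- if (sum(h > 0) < 2L) Inf else otsu_from_histogram(h)
  }
  mask <- roi$pixels & (px > threshold)
  empty <- data.frame(cell_id = integer(0), x = numeric(0), y = numeric(0),
                      area_px = integer(0))
  if (!any(mask)) {
    attr(empty, "labels") <- matrix(0L, nrow(px), ncol(px))
    attr(empty, "threshold") <- as.numeric(threshold)
    attr(empty, "pixel_size_um") <- hematoxylin$pixel_size_um
    return(empty)
  }
  dm <- EBImage::distmap(mask * 1)
  lab <- EBImage::watershed(dm, tolerance = watershed_tolerance, ext = 1L)
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(px), ncol(px))
  n <- max(lab)
  areas <- tabulate(lab, nbins = n)
  keep <- which(areas >= min_area_px & areas <= max_area_px)
  if (!length(keep)) {
    attr(empty, "labels") <- matrix(0L, nrow(px), ncol(px))
    attr(empty, "threshold") <- as.numeric(threshold)
    attr(empty, "pixel_size_um") <- hematoxylin$pixel_size_um
    return(empty)
  }
  remap <- integer(n)
  remap[keep] <- seq_along(keep)
  idx <- which(lab > 0L)
  lab[idx] <- remap[lab[idx]]
  idx <- which(lab > 0L)
  l <- lab[idx]
  rows <- ((idx - 1L) %% nrow(px)) + 1L
  cols <- ((idx - 1L) %/% nrow(px)) + 1L
  area <- tabulate(l, nbins = length(keep))
  cx <- rowsum(as.numeric(cols), l)[, 1L] / area
  cy <- rowsum(as.numeric(rows), l)[, 1L] / area
  out <- data.frame(cell_id = seq_along(keep), x = cx, y = cy,
                    area_px = area)
  attr(out, "labels") <- lab
  attr(out, "threshold") <- as.numeric(threshold)
  attr(out, "pixel_size_um") <- hematoxylin$pixel_size_um
  out
}

#' Quantify mean marker intensities over detected cell footprints
#'
#' For every detected cell and every channel of the stack, computes the
#' mean intensity over the cell's pixel footprint (the labeled matrix
#' produced by [detect_cells()]).
#'
#' @param cells Output of [detect_cells()] (must carry the `labels`
#'   attribute).
#' @param stack A `marker_stack` on the same grid.
#' @param panel Markers to quantify; defaults to every channel. A marker
#'   absent from the stack is a panel mismatch and raises an error.
#' @return A `cell_table` data frame: the cell records plus one mean
#'   intensity column per marker.
#' @export
quantify_markers <- function(cells, stack, panel = names(stack$channels)) {
  stopifnot(is.data.frame(cells), inherits(stack, "marker_stack"))
  lab <- attr(cells, "labels")
  if (is.null(lab)) stop("cells must carry the 'labels' footprint attribute")
  missing <- setdiff(panel, names(stack$channels))
  if (length(missing))
    stop("panel mismatch: markers missing from stack: ",
         paste(missing, collapse = ", "), call. = FALSE)
  out <- as.data.frame(cells)
  n <- nrow(out)
  idx <- which(lab > 0L)
  l <- lab[idx]
  for (mk in panel) {
    if (n == 0L) { out[[mk]] <- numeric(0); next }
    sums <- rowsum(as.numeric(stack$channels[[mk]][idx]), l)
    means <- rep(NA_real_, n)
    means[as.integer(rownames(sums))] <- sums[, 1L] / out$area_px
    out[[mk]] <- means
  }
  attr(out, "pixel_size_um") <- stack$pixel_size_um
  attr(out, "marker_panel") <- panel
  class(out) <- c("cell_table", "data.frame")
  out
}
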