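#' @importFrom stats rnorm rpois rexp rlnorm rbinom runif median quantile
#'   pchisq setNames complete.cases uniroot cor
#' @importFrom utils write.csv read.csv head
"_PACKAGE"

# Intensity convention throughout: 8-bit grayscale in [0, 255], signal-high
# (post-inversion space for chromogenic stains). Matrices are indexed
# [row = y, col = x], origin at the top-left pixel (1-based in R).

#' Grayscale image with physical pixel size
#'
#' A minimal container for a single-marker image: a numeric matrix of
#' intensities in \[0, 255\] plus the physical pixel edge length in
#' micrometres, which anchors all area and density computations.
#'
#' @param pixels Numeric matrix of intensities in \[0, 255\]; rows are y,
#'   columns are x.
#' @param pixel_size_um Positive scalar, micrometres per pixel edge.
#' @return An object of class `gray_image`.
#' @export
gray_image <- function(pixels, pixel_size_um) {
  pixels <- as.matrix(pixels)
  stopifnot(is.numeric(pixels), all(is.finite(pixels)),
            length(pixel_size_um) == 1L, pixel_size_um > 0)
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("gray_image intensities must lie in [0, 255]")
  structure(list(pixels = pixels, pixel_size_um = as.numeric(pixel_size_um)),
            class = "gray_image")
}

#' Binary mask on a pixel grid
#'
#' @param pixels Logical matrix (TRUE = inside the region).
#' @param pixel_size_um Positive scalar, micrometres per pixel edge.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(pixels, pixel_size_um) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "logical"
  stopifnot(!anyNA(pixels), length(pixel_size_um) == 1L, pixel_size_um > 0)
  structure(list(pixels = pixels, pixel_size_um = as.numeric(pixel_size_um)),
            class = "binary_mask")
}

#' Area of a binary mask in square millimetres
#'
#' `area_mm2 = (number of TRUE pixels) * (pixel_size_um / 1000)^2`.
#'
#' @param mask A `binary_mask`.
#' @return Scalar area in mm^2.
#' @export
mask_area_mm2 <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$pixels) * (mask$pixel_size_um / 1000)^2
}

#' Named stack of coregistered marker images
#'
#' All channels share one pixel grid and one physical pixel size; channel
#' names are the marker names of the panel (e.g. "CD3", "hematoxylin").
#'
#' @param channels Named list of numeric matrices, identical dimensions.
#' @param pixel_size_um Positive scalar, micrometres per pixel edge.
#' @return An object of class `marker_stack`.
#' @export
marker_stack <- function(channels, pixel_size_um) {
  stopifnot(is.list(channels), length(channels) >= 1L,
            !is.null(names(channels)), !anyDuplicated(names(channels)))
  dims <- lapply(channels, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1L]])))
    stop("all channels must share one pixel grid")
  structure(list(channels = channels,
                 pixel_size_um = as.numeric(pixel_size_um)),
            class = "marker_stack")
}

#' @export
print.marker_stack <- function(x, ...) {
  d <- dim(x$channels[[1L]])
  cat(sprintf("marker_stack: %d channels, %d x %d px @ %.3g um/px\n",
              length(x$channels), d[1L], d[2L], x$pixel_size_um))
  cat(" markers:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' Invert a chromogenic (signal-dark) image to signal-high convention
#'
#' Chromogenic IHC renders stain as dark pixels; downstream thresholding
#' assumes signal-high intensities, so images are inverted pixelwise:
#' `out = 255 - in`. The operation is an involution.
#'
#' @param image A `gray_image`.
#' @return The inverted `gray_image`.
#' @export
invert_chromogenic <- function(image) {
  stopifnot(inherits(image, "gray_image"))
  gray_image(255 - image$pixels, image$pixel_size_um)
}

#' Result of nest/stroma tissue segmentation
#'
#' Bundles the four region masks and the thresholds that produced them, and
#' enforces the partition invariants: nest and stroma tile the ROI exactly
#' and are disjoint; ROI and blank tile the frame.
#'
#' @param roi,nest,stroma,blank `binary_mask` objects on one grid.
#' @param nest_threshold Intensity threshold used for the nest mask.
#' @param tissue_threshold Intensity threshold used for the tissue/blank
#'   split (NA when the ROI was supplied externally).
#' @return An object of class `segmentation_result`.
#' @export
segmentation_result <- function(roi, nest, stroma, blank,
                                nest_threshold = NA_real_,
                                tissue_threshold = NA_real_) {
  for (m in list(roi, nest, stroma, blank)) stopifnot(inherits(m, "binary_mask"))
  stopifnot(identical(dim(roi$pixels), dim(nest$pixels)),
            identical(dim(roi$pixels), dim(stroma$pixels)),
            identical(dim(roi$pixels), dim(blank$pixels)))
  if (!identical(nest$pixels | stroma$pixels, roi$pixels))
    stop("invariant violated: nest | stroma must equal roi exactly")
  if (any(nest$pixels & stroma$pixels))
    stop("invariant violated: nest and stroma must be disjoint")
  if (any(roi$pixels & blank$pixels))
    stop("invariant violated: roi and blank must be disjoint")
  if (!all(roi$pixels | blank$pixels))
    stop("invariant violated: roi | blank must cover the frame")
  structure(list(roi = roi, nest = nest, stroma = stroma, blank = blank,
                 nest_threshold = nest_threshold,
                 tissue_threshold = tissue_threshold),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf(
    "segmentation_result: roi %.3f mm2 = nest %.3f + stroma %.3f; nest threshold %s\n",
    mask_area_mm2(x$roi), mask_area_mm2(x$nest), mask_area_mm2(x$stroma),
    format(x$nest_threshold)))
  invisible(x)
}

# 256-bin histogram of integer-rounded intensities (bins 0..255)
intensity_histogram <- function(values) {
  v <- pmin(pmax(round(values), 0), 255)
  tabulate(v + 1L, nbins = 256L)
}
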