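# Image-cleaning by mathematical morphology (EBImage backend).

#' Morphology parameters for mask cleaning
#'
#' Disk structuring elements are used throughout. A radius of zero disables
#' the corresponding operation; `max_hole_area_px = Inf` fills every
#' enclosed hole and `min_object_area_px = 0` keeps every component.
#'
#' @param opening_radius_px,closing_radius_px Non-negative integer disk radii.
#' @param max_hole_area_px Fill enclosed background holes with area at most
#'   this many pixels (default `Inf`: unconditional).
#' @param min_object_area_px Remove connected foreground components smaller
#'   than this many pixels.
#' @return An object of class `morph_params`.
#' @export
morph_params <- function(opening_radius_px = 3L, closing_radius_px = 5L,
                         max_hole_area_px = Inf, min_object_area_px = 500L) {
  stopifnot(opening_radius_px >= 0, closing_radius_px >= 0,
            max_hole_area_px >= 0, min_object_area_px >= 0)
  structure(list(opening_radius_px = as.integer(opening_radius_px),
                 closing_radius_px = as.integer(closing_radius_px),
                 max_hole_area_px = max_hole_area_px,
                 min_object_area_px = as.integer(min_object_area_px)),
            class = "morph_params")
}

disc_kernel <- function(radius_px) {
  EBImage::makeBrush(2L * radius_px + 1L, shape = "disc")
}

# Fill background holes (components of the complement not touching the
# frame border) whose area does not exceed max_area_px.
fill_holes <- function(m, max_area_px) {
  if (max_area_px <= 0) return(m)
  lab <- EBImage::bwlabel(!m)
  n <- max(lab)
  if (n == 0L) return(m)
  border_labs <- unique(c(lab[1L, ], lab[nrow(lab), ], lab[, 1L], lab[, ncol(lab)]))
  areas <- tabulate(lab, nbins = n)
  fill <- setdiff(which(areas <= max_area_px), border_labs)
  if (length(fill)) m[lab %in% fill] <- TRUE
  m
}

# Drop connected components with area < min_area_px.
remove_small_objects <- function(m, min_area_px) {
  if (min_area_px <= 0) return(m)
  lab <- EBImage::bwlabel(m)
  n <- max(lab)
  if (n == 0L) return(m)
  areas <- tabulate(lab, nbins = n)
  drop <- which(areas < min_area_px)
  if (length(drop)) m[lab %in% drop] <- FALSE
  m
}

#' Clean a binary mask by morphological operations
#'
#' Applies, in this fixed order: morphological closing (disk of
#' `closing_radius_px`), hole filling (enclosed background components of
#' area at most `max_hole_area_px`), morphological opening (disk of
#' `opening_radius_px`), and removal of connected components smaller than
#' `min_object_area_px`. Closing and hole filling can only add pixels and
#' opening can only remove them; both monotonicity properties are asserted
#' on every call. With all parameters zero the mask is returned unchanged.
#'
#' @param mask A `binary_mask`.
#' @param params A `morph_params` object.
#' @return The cleaned `binary_mask`.
#' @export
clean_mask <- function(mask, params = morph_params()) {
  stopifnot(inherits(mask, "binary_mask"), inherits(params, "morph_params"))
  m <- mask$pixels
  if (params$closing_radius_px > 0) {
    closed <- EBImage::closing(m * 1, disc_kernel(params$closing_radius_px)) > 0.5
    if (any(m & !closed)) stop("internal error: closing removed pixels")
    m <- closed
  }
  filled <- fill_holes(m, params$max_hole_area_px)
  if (any(m & !filled)) stop("internal error: hole filling removed pixels")
  m <- filled
  if (params$opening_radius_px > 0) {
    opened <- EBImage::opening(m * 1, disc_kernel(params$opening_radius_px)) > 0.5
    if (any(opened & !m)) stop("internal error: opening added pixels")
    m <- opened
  }
  m <- remove_small_objects(m, params$min_object_area_px)
  binary_mask(m, mask$pixel_size_um)
}
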