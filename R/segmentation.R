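# Nest/stroma tissue segmentation: tumor-marker thresholding inside the ROI
# (Huang fuzzy method) plus mask cleaning, and stroma by exact subtraction.

#' Segment tumor cell nests inside a region of interest
#'
#' Builds the intensity histogram of the tumor-marker channel restricted to
#' ROI pixels only, selects the Huang fuzzy threshold on that histogram,
#' takes ROI pixels with intensity strictly above the threshold as the raw
#' nest mask, and applies [clean_mask()]. The result is always a subset of
#' the ROI.
#'
#' If the ROI-restricted histogram is degenerate (a single populated bin,
#' e.g. a uniformly zero tumor channel), no threshold exists and an empty
#' nest mask is returned with a warning and attribute `degenerate = TRUE`.
#' Likewise, when the background/foreground class means at the selected
#' threshold differ by no more than `min_contrast` gray levels, the
#' histogram carries no nest-level structure (automatic thresholding on a
#' unimodal noise histogram would otherwise binarize the noise itself) and
#' the nest mask is empty, so that stroma = ROI.
#'
#' @param tumor_marker A `gray_image` of the neoplastic-cell marker
#'   (signal-high convention).
#' @param roi A `binary_mask` of analyzable tissue, same grid.
#' @param params A `morph_params` for the cleaning step.
#' @param min_contrast Minimum separation of class means (gray levels)
#'   for a threshold to count as real nest signal; default 25,
#'   comparable to the channel noise floor.
#' @return A `binary_mask` of nest pixels with attribute `threshold`.
#' @export
segment_nests <- function(tumor_marker, roi, params = morph_params(),
                          min_contrast = 25) {
  stopifnot(inherits(tumor_marker, "gray_image"), inherits(roi, "binary_mask"),
            identical(dim(tumor_marker$pixels), dim(roi$pixels)))
  if (!any(roi$pixels))
    stop("empty ROI: nothing to segment", call. = FALSE)
  h <- intensity_histogram(tumor_marker$pixels[roi$pixels])
  if (sum(h > 0) < 2L) {
    warning("degenerate ROI histogram: no nest threshold exists, returning empty nest mask")
    out <- binary_mask(matrix(FALSE, nrow(roi$pixels), ncol(roi$pixels)),
                       roi$pixel_size_um)
    attr(out, "threshold") <- NA_real_
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  t <- huang_threshold(h)
  g <- 0:255
  m_b <- sum(g[g <= t] * h[g <= t]) / sum(h[g <= t])
  m_f <- sum(g[g > t] * h[g > t]) / sum(h[g > t])
  if (!is.finite(m_f) || (m_f - m_b) <= min_contrast) {
    out <- binary_mask(matrix(FALSE, nrow(roi$pixels), ncol(roi$pixels)),
                       roi$pixel_size_um)
    attr(out, "threshold") <- as.numeric(t)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  raw <- binary_mask(roi$pixels & (tumor_marker$pixels > t), roi$pixel_size_um)
  cleaned <- clean_mask(raw, params)
  out <- binary_mask(cleaned$pixels & roi$pixels, roi$pixel_size_um)
  attr(out, "threshold") <- as.numeric(t)
  attr(out, "degenerate") <- FALSE
  out
}

#' Derive intratumoral stroma by subtracting nests from the ROI
#'
#' Exact set difference: `stroma = roi & !nest`. The nest mask must be a
#' subset of the ROI.
#'
#' @param roi,nest `binary_mask` objects on one grid.
#' @return The stroma `binary_mask`.
#' @export
derive_stroma <- function(roi, nest) {
  stopifnot(inherits(roi, "binary_mask"), inherits(nest, "binary_mask"),
            identical(dim(roi$pixels), dim(nest$pixels)))
  if (any(nest$pixels & !roi$pixels))
    stop("inconsistent inputs: nest mask is not a subset of the ROI", call. = FALSE)
  binary_mask(roi$pixels & !nest$pixels, roi$pixel_size_um)
}

#' Full slide segmentation into nest, stroma and blank regions
#'
#' Convenience wrapper running the whole tissue-segmentation chain on a
#' marker stack: (1) tissue/blank classification of the structural channel
#' (hematoxylin by default) with [compute_tissue_mask()] followed by
#' cleaning; (2) nest extraction from the tumor-marker channel inside the
#' tissue ROI with [segment_nests()]; (3) stroma by subtraction.
#'
#' @param stack A `marker_stack` containing the named tumor and structural
#'   channels.
#' @param tumor_channel,tissue_channel Channel names (defaults `"tumor"`,
#'   `"hematoxylin"`).
#' @param tissue_method Threshold method for the tissue/blank split.
#' @param tissue_smooth_sigma_px Gaussian pre-smoothing for the tissue
#'   split (default 4 px), suppressing nucleus-scale texture; see
#'   [compute_tissue_mask()].
#' @param tissue_params,nest_params `morph_params` for the two cleaning
#'   passes; the tissue pass defaults to unconditional hole filling so
#'   interior blank speckles do not survive into the ROI.
#' @return A `segmentation_result`.
#' @export
segment_slide <- function(stack,
                          tumor_channel = "tumor",
                          tissue_channel = "hematoxylin",
                          tissue_method = "otsu",
                          tissue_smooth_sigma_px = 4,
                          tissue_params = morph_params(),
                          nest_params = morph_params()) {
  stopifnot(inherits(stack, "marker_stack"))
  for (ch in c(tumor_channel, tissue_channel))
    if (!ch %in% names(stack$channels))
      stop(sprintf("channel '%s' missing from stack", ch), call. = FALSE)
  px_um <- stack$pixel_size_um
  tissue_img <- gray_image(stack$channels[[tissue_channel]], px_um)
  tissue_raw <- compute_tissue_mask(tissue_img, method = tissue_method,
                                    smooth_sigma_px = tissue_smooth_sigma_px)
  roi <- clean_mask(tissue_raw, tissue_params)
  nest <- segment_nests(gray_image(stack$channels[[tumor_channel]], px_um),
                        roi, nest_params)
  stroma <- derive_stroma(roi, nest)
  blank <- binary_mask(!roi$pixels, px_um)
  segmentation_result(roi = roi, nest = nest, stroma = stroma, blank = blank,
                      nest_threshold = attr(nest, "threshold"),
                      tissue_threshold = attr(tissue_raw, "threshold"))
}

#' Axis-aligned ROI box
#'
#' @param x,y 1-based pixel coordinates of the top-left corner.
#' @param width_px,height_px Box extents in pixels.
#' @param pixel_size_um Micrometres per pixel.
#' @return An object of class `roi_box` with an `area_mm2` field.
#' @export
roi_box <- function(x, y, width_px, height_px, pixel_size_um) {
  structure(list(x = as.integer(x), y = as.integer(y),
                 width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 area_mm2 = width_px * height_px * (pixel_size_um / 1000)^2),
            class = "roi_box")
}

# Integral-image box sums: S[i, j] = sum of m[1:i, 1:j], zero-padded.
integral_image <- function(m) {
  s <- apply(m, 2L, cumsum)
  s <- t(apply(s, 1L, cumsum))
  rbind(0, cbind(0, s))
}

box_sum <- function(S, y, x, h, w) {
  S[y + h, x + w] - S[y, x + w] - S[y + h, x] + S[y, x]
}

#' Select high-CD3-density regions of interest
#'
#' Greedily places up to `k` non-overlapping square windows (side
#' `window_mm`, default 2.5 mm, i.e. about 6.25 mm^2 each) maximizing the
#' integrated CD3 signal within tissue. Candidate positions lie on a
#' regular grid of stride `stride_mm`; ties are broken by top-left scan
#' order (row by row, left to right), making the selection deterministic.
#' Windows larger than the image are shrunk to fit, and windows containing
#' no tissue are never selected, so fewer than `k` boxes may be returned
#' when the analyzable area is small.
#'
#' @param cd3 A `gray_image` of the CD3 channel.
#' @param tissue A `binary_mask` of analyzable tissue, same grid.
#' @param k Maximum number of boxes (default 3).
#' @param window_mm Window side length in mm (default 2.5).
#' @param stride_mm Candidate grid stride in mm (default 0.25).
#' @return List of `roi_box` objects, in decreasing order of CD3 signal.
#' @export
select_rois <- function(cd3, tissue, k = 3L, window_mm = 2.5, stride_mm = 0.25) {
  stopifnot(inherits(cd3, "gray_image"), inherits(tissue, "binary_mask"),
            identical(dim(cd3$pixels), dim(tissue$pixels)), k >= 1)
  if (!any(tissue$pixels))
    stop("empty tissue mask: nothing analyzable", call. = FALSE)
  px_um <- cd3$pixel_size_um
  nr <- nrow(cd3$pixels); nc <- ncol(cd3$pixels)
  win <- max(1L, round(window_mm * 1000 / px_um))
  win_h <- min(win, nr); win_w <- min(win, nc)
  stride <- max(1L, round(stride_mm * 1000 / px_um))
  S_sig <- integral_image(cd3$pixels * tissue$pixels)
  S_tis <- integral_image(tissue$pixels * 1)
  ys <- unique(c(seq(1L, nr - win_h + 1L, by = stride), nr - win_h + 1L))
  xs <- unique(c(seq(1L, nc - win_w + 1L, by = stride), nc - win_w + 1L))
  cand <- expand.grid(x = xs, y = ys)[, c("y", "x")]  # row-major scan order
  score <- mapply(function(y, x) box_sum(S_sig, y, x, win_h, win_w),
                  cand$y, cand$x)
  has_tissue <- mapply(function(y, x) box_sum(S_tis, y, x, win_h, win_w) > 0,
                       cand$y, cand$x)
  alive <- has_tissue
  boxes <- list()
  while (length(boxes) < k && any(alive)) {
    idx <- which(alive)
    best <- idx[which.max(score[idx])]
    by <- cand$y[best]; bx <- cand$x[best]
    boxes[[length(boxes) + 1L]] <- roi_box(bx, by, win_w, win_h, px_um)
    overlap <- cand$y < by + win_h & cand$y + win_h > by &
      cand$x < bx + win_w & cand$x + win_w > bx
    alive <- alive & !overlap
  }
  boxes
}

#' Crop an image or mask to an ROI box
#'
#' @param x A `gray_image` or `binary_mask`.
#' @param box A `roi_box`.
#' @return The cropped object of the same class.
#' @export
crop_to_box <- function(x, box) {
  stopifnot(inherits(box, "roi_box"))
  rows <- box$y:(box$y + box$height_px - 1L)
  cols <- box$x:(box$x + box$width_px - 1L)
  if (inherits(x, "gray_image"))
    gray_image(x$pixels[rows, cols, drop = FALSE], x$pixel_size_um)
  else if (inherits(x, "binary_mask"))
    binary_mask(x$pixels[rows, cols, drop = FALSE], x$pixel_size_um)
  else stop("crop_to_box expects a gray_image or binary_mask")
}
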