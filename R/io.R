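# Plain-format IO: grayscale TIFF/PNG images, 8-bit 0/255 mask PNGs,
# multi-page TIFF stacks, CSV tables, YAML specs, JSON reports.

#' Read a grayscale image (TIFF or PNG)
#'
#' Multi-sample images are collapsed to grayscale by channel averaging;
#' intensities are rescaled from \[0, 1\] to \[0, 255\].
#'
#' @param path File path (`.tif`, `.tiff` or `.png`).
#' @param pixel_size_um Physical pixel size to attach.
#' @return A `gray_image`.
#' @export
read_gray_image <- function(path, pixel_size_um) {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
              tif = , tiff = tiff::readTIFF(path),
              png = png::readPNG(path),
              stop("unsupported image format: ", ext))
  if (length(dim(a)) == 3L) a <- apply(a, c(1L, 2L), mean)
  gray_image(a * 255, pixel_size_um)
}

#' Write a grayscale image as PNG
#'
#' @param image A `gray_image`.
#' @param path Output path.
#' @export
write_gray_png <- function(image, path) {
  stopifnot(inherits(image, "gray_image"))
  png::writePNG(image$pixels / 255, path)
  invisible(path)
}

#' Write a binary mask as an 8-bit 0/255 PNG
#'
#' @param mask A `binary_mask`.
#' @param path Output path.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  png::writePNG(mask$pixels * 1, path)
  invisible(path)
}

#' Read a 0/255 PNG back into a binary mask
#'
#' @param path PNG path.
#' @param pixel_size_um Physical pixel size to attach.
#' @return A `binary_mask`.
#' @export
read_mask_png <- function(path, pixel_size_um) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1L]
  binary_mask(a > 0.5, pixel_size_um)
}

#' Write a marker stack as a multi-page grayscale TIFF
#'
#' One page per marker. Channel names and the physical pixel size are
#' stored in a JSON sidecar (`<path>.json`) so the stack round-trips.
#'
#' @param stack A `marker_stack`.
#' @param path Output `.tif` path.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "marker_stack"))
  pages <- lapply(stack$channels, function(ch) ch / 255)
  tiff::writeTIFF(unname(pages), path)
  jsonlite::write_json(list(markers = names(stack$channels),
                            pixel_size_um = stack$pixel_size_um),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF written by [write_stack_tiff()]
#'
#' @param path TIFF path.
#' @param pixel_size_um Physical pixel size; defaults to the sidecar value.
#' @return A `marker_stack`; channel names come from the JSON sidecar when
#'   present, else `channel1..N`.
#' @export
read_stack_tiff <- function(path, pixel_size_um = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  channels <- lapply(pages, function(p) {
    a <- p
    if (length(dim(a)) == 3L) a <- apply(a, c(1L, 2L), mean)
    as.matrix(a) * 255
  })
  nms <- paste0("channel", seq_along(pages))
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (length(meta$markers) == length(pages)) nms <- meta$markers
    if (is.null(pixel_size_um)) pixel_size_um <- meta$pixel_size_um
  }
  if (is.null(pixel_size_um))
    stop("pixel_size_um is required when no sidecar metadata exists")
  names(channels) <- nms
  marker_stack(channels, pixel_size_um)
}

#' Write a cell table as CSV
#'
#' One row per cell; hidden truth columns (leading dot) are kept so
#' synthetic tables round-trip.
#'
#' @param table A `cell_table` (or plain data frame).
#' @param path Output CSV path.
#' @export
write_cell_csv <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Read a cell table from CSV
#'
#' Accepts externally extracted tables in the same dialect; an optional
#' column-name mapping adapts foreign exports (e.g. CellProfiler column
#' names) to the package's schema.
#'
#' @param path CSV path.
#' @param pixel_size_um Physical pixel size to attach.
#' @param column_map Optional named character vector `c(ours = theirs)`
#'   renaming foreign columns.
#' @return A `cell_table`.
#' @export
read_cell_csv <- function(path, pixel_size_um, column_map = NULL) {
  tab <- read.csv(path, check.names = FALSE)
  if (!is.null(column_map))
    for (ours in names(column_map)) {
      theirs <- column_map[[ours]]
      if (!theirs %in% names(tab))
        stop("mapped column absent from CSV: ", theirs)
      names(tab)[names(tab) == theirs] <- ours
    }
  attr(tab, "pixel_size_um") <- pixel_size_um
  class(tab) <- c("cell_table", "data.frame")
  tab
}

#' Serialize an object (spec, config, manifest) to YAML
#'
#' @param x A list-like object.
#' @param path Output YAML path.
#' @export
write_spec_yaml <- function(x, path) {
  yaml::write_yaml(unclass(x), path)
  invisible(path)
}

#' Write results as JSON (bare numbers, unboxed)
#'
#' @param x A list of results.
#' @param path Output JSON path.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Export a KM curve as CSV (time, survival, at-risk)
#'
#' @param curve A `km_curve`.
#' @param path Output CSV path.
#' @export
write_km_csv <- function(curve, path) {
  stopifnot(inherits(curve, "km_curve"))
  write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
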