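# Synthetic slide generator: marker image stacks with known nest/stroma
# ground truth and known per-cell lineages, so segmentation, cytometry and
# gating are testable without slide data.

#' Default marker panel
#'
#' The discovery panel carries the full lineage-defining marker set plus
#' the tumor marker and hematoxylin; the validation panel is the reduced
#' 7-channel CD4-based panel.
#'
#' @param variant `"discovery"` or `"validation"`.
#' @return Character vector of marker names.
#' @export
default_marker_panel <- function(variant = c("discovery", "validation")) {
  variant <- match.arg(variant)
  if (variant == "discovery")
    c("CD45", "CD3", "CD4", "CD8", "Foxp3", "Tbet", "GATA3", "CD20", "CD56",
      "CD66b", "Tryptase", "CD68", "CSF1R", "CD163", "PD1", "tumor",
      "hematoxylin")
  else
    c("CD3", "CD4", "CD8", "Foxp3", "PD1", "tumor", "hematoxylin")
}

# positive markers per simulated lineage (besides hematoxylin, which every
# nucleated cell carries)
sim_lineage_markers <- list(
  tumor        = c("tumor"),
  cd8_t        = c("CD45", "CD3", "CD8"),
  cd8_t_pd1    = c("CD45", "CD3", "CD8", "PD1"),
  treg         = c("CD45", "CD3", "CD4", "Foxp3"),
  treg_pd1     = c("CD45", "CD3", "CD4", "Foxp3", "PD1"),
  helper_t     = c("CD45", "CD3", "CD4"),
  helper_t_pd1 = c("CD45", "CD3", "CD4", "PD1"),
  th1          = c("CD45", "CD3", "CD4", "Tbet"),
  th2          = c("CD45", "CD3", "CD4", "GATA3"),
  b_cell       = c("CD45", "CD20"),
  nk           = c("CD45", "CD56"),
  granulocyte  = c("CD45", "CD66b"),
  mast         = c("CD45", "Tryptase"),
  tam_cd163pos = c("CD45", "CD68", "CSF1R", "CD163"),
  tam_cd163neg = c("CD45", "CD68", "CSF1R")
)

#' Default per-lineage marker intensity profiles
#'
#' Each profile gives the mean 8-bit intensity per panel marker (200 for
#' lineage-defining positive markers, 230 for the tumor marker on tumor
#' cells, 220 for hematoxylin on every cell, 0 otherwise) and one
#' coefficient of variation shared by all markers of the lineage. PD-1
#' expression is modeled through dedicated PD-1+ lineage variants
#' (`helper_t_pd1`, `treg_pd1`, `cd8_t_pd1`).
#'
#' @param variant Marker panel variant.
#' @param cv Coefficient of variation of per-cell intensities (default 0.1).
#' @param positive_mean Mean intensity of positive markers (default 200).
#' @return Named list of profiles, each `list(means = <named numeric>, cv)`.
#' @export
default_lineage_profiles <- function(variant = c("discovery", "validation"),
                                     cv = 0.1, positive_mean = 200) {
  variant <- match.arg(variant)
  panel <- default_marker_panel(variant)
  lapply(sim_lineage_markers, function(pos) {
    means <- setNames(rep(0, length(panel)), panel)
    pos <- intersect(pos, panel)
    means[pos] <- positive_mean
    if ("tumor" %in% pos) means["tumor"] <- 230
    means["hematoxylin"] <- 220
    list(means = means, cv = cv)
  })
}

#' Default per-lineage, per-compartment cell densities (cells/mm^2)
#'
#' Chosen once for testability at moderate crowding: helper T, B cells and
#' granulocytes denser in stroma, TAM (especially CD163-) denser in nests,
#' TH1/TH2 ratio high in nests and low in stroma, tumor cells confined to
#' nests.
#'
#' @return `list(nest = <named numeric>, stroma = <named numeric>)`.
#' @export
default_densities_per_mm2 <- function() {
  list(
    nest = c(tumor = 130, th1 = 36, th2 = 9, helper_t = 18,
             helper_t_pd1 = 21, treg = 12, treg_pd1 = 7, cd8_t = 27,
             cd8_t_pd1 = 9, b_cell = 5, nk = 2, granulocyte = 7,
             mast = 2, tam_cd163pos = 18, tam_cd163neg = 23),
    stroma = c(tumor = 0, th1 = 18, th2 = 27, helper_t = 39,
               helper_t_pd1 = 27, treg = 15, treg_pd1 = 11, cd8_t = 36,
               cd8_t_pd1 = 11, b_cell = 27, nk = 5, granulocyte = 27,
               mast = 7, tam_cd163pos = 21, tam_cd163neg = 13)
  )
}

# gate-level truth for a simulated lineage: PD-1 variants collapse to their
# parent gate; tumor cells gate as "other" (CD45-)
gate_label_for <- function(sim_lineage) {
  lab <- sub("_pd1$", "", sim_lineage)
  ifelse(lab == "tumor", "other", lab)
}

#' Specification of a synthetic slide
#'
#' Defines the geometry (image size, physical pixel size, blank margin,
#' number and radius range of tumor cell nests), the marker panel with
#' per-lineage intensity profiles, per-compartment cell densities, channel
#' noise and the seed. The defaults emulate a 2.8 x 2.8 mm intratumoral
#' field at 4 um/px with five nests of 150-400 um radius.
#'
#' @param width_px,height_px Image size in pixels.
#' @param pixel_size_um Micrometres per pixel edge.
#' @param n_nests Number of disjoint disk-shaped tumor nests.
#' @param nest_radius_um_range `c(min, max)` nest radii in micrometres.
#' @param blank_margin_px Tissue-free border width in pixels.
#' @param marker_panel Ordered character vector of marker names (unique).
#' @param lineage_profiles Named list of per-lineage intensity profiles,
#'   see [default_lineage_profiles()].
#' @param densities_per_mm2 `list(nest=, stroma=)` of named densities,
#'   see [default_densities_per_mm2()].
#' @param background_noise_sd Gaussian channel noise SD (default 15).
#' @param nucleus_radius_px,marker_radius_px Rendered disk radii for the
#'   nuclear channel and the lineage markers.
#' @param struct_intensity Structural channel levels:
#'   `tumor_nest`/`tumor_stroma` background of the tumor channel and
#'   `tissue` background of the hematoxylin channel.
#' @param seed Integer RNG seed; identical spec + seed reproduces output
#'   bit for bit.
#' @return An object of class `image_sim_spec`.
#' @export
image_sim_spec <- function(width_px = 700L, height_px = 700L,
                           pixel_size_um = 4,
                           n_nests = 5L,
                           nest_radius_um_range = c(150, 400),
                           blank_margin_px = 30L,
                           marker_panel = default_marker_panel("discovery"),
                           lineage_profiles = default_lineage_profiles("discovery"),
                           densities_per_mm2 = default_densities_per_mm2(),
                           background_noise_sd = 15,
                           nucleus_radius_px = 2L,
                           marker_radius_px = 3L,
                           struct_intensity = c(tumor_nest = 200,
                                                tumor_stroma = 20,
                                                tissue = 60),
                           seed = 1L) {
  stopifnot(width_px >= 1, height_px >= 1, pixel_size_um > 0, n_nests >= 0,
            length(nest_radius_um_range) == 2L,
            all(nest_radius_um_range > 0),
            nest_radius_um_range[1] <= nest_radius_um_range[2],
            blank_margin_px >= 0, background_noise_sd >= 0,
            !anyDuplicated(marker_panel))
  for (comp in names(densities_per_mm2)) {
    d <- densities_per_mm2[[comp]]
    stopifnot(all(d >= 0))
    missing_prof <- setdiff(names(d)[d > 0], names(lineage_profiles))
    if (length(missing_prof))
      stop("lineages without a profile: ", paste(missing_prof, collapse = ", "))
  }
  for (lp in lineage_profiles)
    stopifnot(all(names(lp$means) %in% marker_panel), lp$cv >= 0,
              all(lp$means >= 0), all(lp$means <= 255))
  r_max_px <- nest_radius_um_range[2] / pixel_size_um
  if (n_nests > 0 &&
      (2 * r_max_px + 2 * blank_margin_px >= min(width_px, height_px)))
    stop(errorCondition("nest radii do not fit inside the image",
                        class = c("nestseg_infeasible_geometry", "error",
                                  "condition")))
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 pixel_size_um = pixel_size_um, n_nests = as.integer(n_nests),
                 nest_radius_um_range = nest_radius_um_range,
                 blank_margin_px = as.integer(blank_margin_px),
                 marker_panel = marker_panel,
                 lineage_profiles = lineage_profiles,
                 densities_per_mm2 = densities_per_mm2,
                 background_noise_sd = background_noise_sd,
                 nucleus_radius_px = as.integer(nucleus_radius_px),
                 marker_radius_px = as.integer(marker_radius_px),
                 struct_intensity = struct_intensity,
                 seed = as.integer(seed)),
            class = "image_sim_spec")
}

# disk pixel offsets (dy, dx) for a given radius
disk_offsets <- function(radius_px) {
  r <- radius_px
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g[g$dy^2 + g$dx^2 <= r^2, , drop = FALSE]
}

# Place disjoint nest disks and build the compartment masks.
# RNG: draws radii (n), then centers (2 per attempt).
sim_geometry <- function(spec) {
  nr <- spec$height_px; nc <- spec$width_px
  m <- spec$blank_margin_px
  roi <- matrix(FALSE, nr, nc)
  roi[(m + 1L):(nr - m), (m + 1L):(nc - m)] <- TRUE
  nest <- matrix(FALSE, nr, nc)
  centers <- matrix(numeric(0), 0L, 2L)
  radii <- numeric(0)
  if (spec$n_nests > 0) {
    r_px <- runif(spec$n_nests, spec$nest_radius_um_range[1],
                  spec$nest_radius_um_range[2]) / spec$pixel_size_um
    for (i in seq_len(spec$n_nests)) {
      r <- r_px[i]
      placed <- FALSE
      for (attempt in seq_len(1000L)) {
        cy <- runif(1, m + r + 1, nr - m - r)
        cx <- runif(1, m + r + 1, nc - m - r)
        if (nrow(centers) == 0L ||
            all(sqrt((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2) >
                r + radii)) {
          centers <- rbind(centers, c(cy, cx))
          radii <- c(radii, r)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop(errorCondition(
          "could not place disjoint nests in 1000 attempts: infeasible geometry",
          class = c("nestseg_infeasible_geometry", "error", "condition")))
      rows <- max(1L, floor(cy - r)):min(nr, ceiling(cy + r))
      cols <- max(1L, floor(cx - r)):min(nc, ceiling(cx + r))
      d2 <- outer((rows - cy)^2, (cols - cx)^2, `+`)
      nest[rows, cols] <- nest[rows, cols] | (d2 <= r^2)
    }
  }
  nest <- nest & roi
  list(roi = roi, nest = nest, stroma = roi & !nest)
}

# Draw Poisson cell counts per (compartment, lineage) and uniform positions
# within the compartment. RNG: per compartment (nest, stroma) in order, per
# lineage in densities order: one rpois then one sample().
sim_cells <- function(spec, geom) {
  px_mm2 <- (spec$pixel_size_um / 1000)^2
  nr <- spec$height_px
  out <- list()
  for (comp in c("nest", "stroma")) {
    mask <- geom[[comp]]
    area <- sum(mask) * px_mm2
    dens <- spec$densities_per_mm2[[comp]]
    avail <- which(mask)
    for (lin in names(dens)) {
      if (dens[[lin]] <= 0 || area <= 0) next
      n <- rpois(1L, dens[[lin]] * area)
      if (n == 0L) next
      idx <- sample(avail, n, replace = TRUE)
      out[[length(out) + 1L]] <- data.frame(
        x = ((idx - 1L) %/% nr) + 1L,
        y = ((idx - 1L) %% nr) + 1L,
        sim_lineage = lin, compartment = comp,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(x = integer(0), y = integer(0),
                      sim_lineage = character(0), compartment = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# Per-cell, per-marker intensities from the lineage profiles, clipped to
# [0, 255]. RNG: one rnorm block per lineage (cells x markers), lineages in
# profile order.
sim_intensities <- function(spec, cells) {
  panel <- spec$marker_panel
  vals <- matrix(0, nrow(cells), length(panel), dimnames = list(NULL, panel))
  for (lin in names(spec$lineage_profiles)) {
    rows <- which(cells$sim_lineage == lin)
    if (!length(rows)) next
    prof <- spec$lineage_profiles[[lin]]
    for (mk in panel) {
      mu <- if (mk %in% names(prof$means)) prof$means[[mk]] else 0
      if (mu <= 0) next
      vals[rows, mk] <- pmin(pmax(rnorm(length(rows), mu, prof$cv * mu), 0), 255)
    }
  }
  vals
}

#' Generate a synthetic marker image stack with ground truth
#'
#' Builds a slide-like image: a rectangular tissue sheet inside a blank
#' margin, disjoint disk-shaped tumor nests, structural background signal
#' (tumor marker high in nests and low in stroma; hematoxylin over all
#' tissue and near zero in the margin), Poisson-placed cells per lineage
#' and compartment rendered as disks of their profile intensities, and
#' Gaussian channel noise clipped to \[0, 255\]. Identical spec and seed
#' reproduce the output bit for bit.
#'
#' @param spec An `image_sim_spec`.
#' @return `list(stack = <marker_stack>, truth = <list>)` where `truth`
#'   has `roi_mask` and `nest_mask` (`binary_mask`) and `cells`, a data
#'   frame with per-cell `x`, `y`, `sim_lineage`, gate-level `lineage`,
#'   `pd1` and `compartment`.
#' @export
generate_image_stack <- function(spec) {
  stopifnot(inherits(spec, "image_sim_spec"))
  set.seed(spec$seed)
  geom <- sim_geometry(spec)
  cells <- sim_cells(spec, geom)
  vals <- sim_intensities(spec, cells)
  nr <- spec$height_px; nc <- spec$width_px
  channels <- lapply(setNames(spec$marker_panel, spec$marker_panel),
                     function(mk) matrix(0, nr, nc))
  si <- spec$struct_intensity
  if ("tumor" %in% spec$marker_panel) {
    channels$tumor[geom$stroma] <- si[["tumor_stroma"]]
    channels$tumor[geom$nest] <- si[["tumor_nest"]]
  }
  if ("hematoxylin" %in% spec$marker_panel)
    channels$hematoxylin[geom$roi] <- si[["tissue"]]
  if (nrow(cells)) {
    off_m <- disk_offsets(spec$marker_radius_px)
    off_n <- disk_offsets(spec$nucleus_radius_px)
    for (mk in spec$marker_panel) {
      v <- vals[, mk]
      sel <- which(v > 0)
      if (!length(sel)) next
      off <- if (mk == "hematoxylin") off_n else off_m
      k <- nrow(off)
      py <- rep(cells$y[sel], each = k) + off$dy
      px <- rep(cells$x[sel], each = k) + off$dx
      pv <- rep(v[sel], each = k)
      ok <- py >= 1L & py <= nr & px >= 1L & px <= nc
      py <- py[ok]; px <- px[ok]; pv <- pv[ok]
      ord <- order(pv)  # ascending: later (larger) writes win on overlap
      ind <- (px[ord] - 1L) * nr + py[ord]
      pv <- pv[ord]
      ch <- channels[[mk]]
      ch[ind] <- pmax(ch[ind], pv)
      channels[[mk]] <- ch
    }
  }
  if (spec$background_noise_sd > 0)
    for (mk in spec$marker_panel)
      channels[[mk]] <- channels[[mk]] +
        matrix(rnorm(nr * nc, 0, spec$background_noise_sd), nr, nc)
  channels <- lapply(channels, function(ch) pmin(pmax(ch, 0), 255))
  truth_cells <- cells
  truth_cells$lineage <- gate_label_for(cells$sim_lineage)
  truth_cells$pd1 <- grepl("_pd1$", cells$sim_lineage)
  list(stack = marker_stack(channels, spec$pixel_size_um),
       truth = list(
         roi_mask = binary_mask(geom$roi, spec$pixel_size_um),
         nest_mask = binary_mask(geom$nest, spec$pixel_size_um),
         cells = truth_cells))
}

#' Generate a synthetic single-cell table without rendering images
#'
#' Image-free fast path for gating tests: the same geometry and cell
#' placement as [generate_image_stack()], but per-cell marker intensities
#' are drawn directly from the lineage profiles instead of being rendered
#' and re-measured. True labels are retained in hidden columns
#' (`.true_sim_lineage`, `.true_lineage`, `.true_pd1`,
#' `.true_compartment`).
#'
#' @param spec An `image_sim_spec`.
#' @return A `cell_table` data frame (one row per cell: `cell_id`, `x`,
#'   `y`, `area_px`, one column per panel marker, hidden truth columns)
#'   with attributes `pixel_size_um` and `marker_panel`.
#' @export
generate_cell_table <- function(spec) {
  stopifnot(inherits(spec, "image_sim_spec"))
  set.seed(spec$seed)
  geom <- sim_geometry(spec)
  cells <- sim_cells(spec, geom)
  vals <- sim_intensities(spec, cells)
  n <- nrow(cells)
  tab <- data.frame(cell_id = seq_len(n),
                    x = if (n) cells$x else integer(0),
                    y = if (n) cells$y else integer(0),
                    area_px = rep(nrow(disk_offsets(spec$marker_radius_px)), n))
  for (mk in spec$marker_panel) tab[[mk]] <- vals[, mk]
  tab$.true_sim_lineage <- if (n) cells$sim_lineage else character(0)
  tab$.true_lineage <- gate_label_for(tab$.true_sim_lineage)
  tab$.true_pd1 <- grepl("_pd1$", tab$.true_sim_lineage)
  tab$.true_compartment <- if (n) cells$compartment else character(0)
  attr(tab, "pixel_size_um") <- spec$pixel_size_um
  attr(tab, "marker_panel") <- spec$marker_panel
  class(tab) <- c("cell_table", "data.frame")
  tab
}

#' Convert a signal-high stack to chromogenic-style (signal-dark) images
#'
#' Emits the pre-inversion representation of every channel (`255 - x`),
#' for exercising the [invert_chromogenic()] path.
#'
#' @param stack A `marker_stack`.
#' @return The inverted `marker_stack`.
#' @export
as_chromogenic <- function(stack) {
  stopifnot(inherits(stack, "marker_stack"))
  marker_stack(lapply(stack$channels, function(ch) 255 - ch),
               stack$pixel_size_um)
}
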