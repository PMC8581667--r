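# Region-stratified metrics: region assignment, densities, composition
# percentages, TH1/TH2 ratios, polarization classes, region validation.

#' Assign each cell to nest, stroma or outside
#'
#' A cell belongs to the region containing its rounded centroid pixel:
#' `"nest"` if inside the nest mask, `"stroma"` if inside the stroma mask,
#' `"outside"` otherwise. Boundary cells are therefore deterministic.
#'
#' @param table A `cell_table` with `x`, `y` centroids on the
#'   segmentation's pixel grid.
#' @param seg A `segmentation_result`.
#' @return The table with a `region` column appended.
#' @export
assign_region <- function(table, seg) {
  stopifnot(is.data.frame(table), inherits(seg, "segmentation_result"))
  nr <- nrow(seg$roi$pixels); nc <- ncol(seg$roi$pixels)
  py <- pmin(pmax(round(table$y), 1L), nr)
  px <- pmin(pmax(round(table$x), 1L), nc)
  ind <- (px - 1L) * nr + py
  region <- rep("outside", nrow(table))
  region[seg$nest$pixels[ind]] <- "nest"
  region[seg$stroma$pixels[ind]] <- "stroma"
  out <- table
  out$region <- region
  out
}

#' Region-stratified counts, densities and composition
#'
#' For each region (nest, stroma) and lineage: cell count, region area in
#' mm^2, density in cells/mm^2, and the lineage's percentage of CD45+
#' cells in the region. PD-1+ subset densities are reported for helper T
#' (helper_t + th1 + th2), TREG and CD8 T cells. A zero-area region yields
#' counts with `NA` densities.
#'
#' @param table A gated `cell_table` with `lineage`, `pd1` and `region`
#'   columns (see [classify_cells()], [assign_region()]).
#' @param seg The `segmentation_result` providing region areas.
#' @return An object of class `region_stats`: list with `by_lineage` and
#'   `pd1` data frames and named `areas_mm2`.
#' @export
compute_region_stats <- function(table, seg) {
  stopifnot(all(c("lineage", "region") %in% names(table)),
            inherits(seg, "segmentation_result"))
  areas <- c(nest = mask_area_mm2(seg$nest), stroma = mask_area_mm2(seg$stroma))
  lineages <- sort(unique(c(table$lineage, "other")))
  cd45_pos <- if ("CD45" %in% names(table)) table$CD45 >= 127
              else table$lineage != "other"
  by_lineage <- do.call(rbind, lapply(c("nest", "stroma"), function(rg) {
    in_rg <- table$region == rg
    n_cd45 <- sum(cd45_pos & in_rg)
    counts <- vapply(lineages, function(l) sum(in_rg & table$lineage == l),
                     numeric(1))
    cd45_counts <- vapply(lineages, function(l)
      sum(in_rg & cd45_pos & table$lineage == l), numeric(1))
    data.frame(region = rg, lineage = lineages, count = counts,
               area_mm2 = areas[[rg]],
               density = if (areas[[rg]] > 0) counts / areas[[rg]] else NA_real_,
               pct_of_cd45 = if (n_cd45 > 0) 100 * cd45_counts / n_cd45
                             else NA_real_,
               row.names = NULL)
  }))
  pd1_subsets <- list(helper_t = helper_lineages, treg = "treg",
                      cd8_t = "cd8_t")
  pd1 <- do.call(rbind, lapply(c("nest", "stroma"), function(rg) {
    in_rg <- table$region == rg
    counts <- vapply(pd1_subsets, function(lins)
      sum(in_rg & table$lineage %in% lins & table$pd1 %in% TRUE), numeric(1))
    data.frame(region = rg, subset = names(pd1_subsets), count = counts,
               density = if (areas[[rg]] > 0) counts / areas[[rg]]
                         else NA_real_,
               row.names = NULL)
  }))
  structure(list(by_lineage = by_lineage, pd1 = pd1, areas_mm2 = areas),
            class = "region_stats")
}

#' @export
print.region_stats <- function(x, ...) {
  cat(sprintf("region_stats: nest %.3f mm2, stroma %.3f mm2\n",
              x$areas_mm2[["nest"]], x$areas_mm2[["stroma"]]))
  print(x$by_lineage)
  invisible(x)
}

# density of a lineage set in one region
region_density <- function(stats, region, lineages) {
  df <- stats$by_lineage
  sel <- df$region == region & df$lineage %in% lineages
  area <- stats$areas_mm2[[region]]
  if (area <= 0) return(NA_real_)
  sum(df$count[sel]) / area
}

#' TH1/TH2 ratio in one region
#'
#' Ratio of TH1 to TH2 cell counts. A specimen with no TH2 cells in the
#' region cannot contribute a ratio and is flagged excluded.
#'
#' @param stats A `region_stats`.
#' @param region `"nest"` or `"stroma"`.
#' @return `list(ratio = <real or NA>, excluded = <logical>)`.
#' @export
th1_th2_ratio <- function(stats, region = c("nest", "stroma")) {
  region <- match.arg(region)
  df <- stats$by_lineage
  th1 <- sum(df$count[df$region == region & df$lineage == "th1"])
  th2 <- sum(df$count[df$region == region & df$lineage == "th2"])
  if (th2 == 0) list(ratio = NA_real_, excluded = TRUE)
  else list(ratio = th1 / th2, excluded = FALSE)
}

#' Polarization class of a nest/stroma density pair
#'
#' Based on the ratio r = nest density / stroma density: nest-polarized
#' when r > 2.0, stroma-polarized when r < 0.5, balanced in between
#' (boundaries 0.5 and 2.0 inclusive to balanced). A zero stroma density
#' with positive nest density is nest-polarized by convention; both zero
#' is undefined.
#'
#' @param density_nest,density_stroma Non-negative densities (cells/mm^2).
#' @return One of `"nest_polarized"`, `"stroma_polarized"`, `"balanced"`,
#'   `"undefined"`.
#' @export
polarization_class <- function(density_nest, density_stroma) {
  stopifnot(density_nest >= 0, density_stroma >= 0)
  if (density_stroma == 0) {
    if (density_nest == 0) return("undefined")
    return("nest_polarized")
  }
  r <- density_nest / density_stroma
  if (r > 2.0) "nest_polarized"
  else if (r < 0.5) "stroma_polarized"
  else "balanced"
}

#' Validate tissue segmentation by cell-class composition per region
#'
#' Splits the cells of each region into three mutually exclusive classes -
#' CD45+, CD45- tumor-marker-, and tumor-marker+ (CD45 taking precedence) -
#' and reports their percentages, which sum to 100 per non-empty region.
#' A correctly segmented slide shows the tumor-marker+ fraction
#' concentrated in nests.
#'
#' @param table A `cell_table` with `CD45` and tumor-marker columns and a
#'   `region` column.
#' @param tumor_marker Name of the tumor-marker column (default
#'   `"tumor"`).
#' @param thresholds Positivity thresholds for the two markers.
#' @return Data frame (region, pct_cd45, pct_double_negative, pct_tumor);
#'   `NA` percentages for an empty region.
#' @export
region_validation <- function(table, tumor_marker = "tumor",
                              thresholds = c(CD45 = 127, tumor = 127)) {
  stopifnot(all(c("CD45", tumor_marker, "region") %in% names(table)))
  cd45 <- table$CD45 >= thresholds[["CD45"]]
  tum <- !cd45 & table[[tumor_marker]] >= thresholds[["tumor"]]
  dneg <- !cd45 & !tum
  do.call(rbind, lapply(c("nest", "stroma"), function(rg) {
    in_rg <- table$region == rg
    n <- sum(in_rg)
    if (n == 0)
      return(data.frame(region = rg, pct_cd45 = NA_real_,
                        pct_double_negative = NA_real_, pct_tumor = NA_real_))
    data.frame(region = rg,
               pct_cd45 = 100 * sum(cd45 & in_rg) / n,
               pct_double_negative = 100 * sum(dneg & in_rg) / n,
               pct_tumor = 100 * sum(tum & in_rg) / n)
  }))
}
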