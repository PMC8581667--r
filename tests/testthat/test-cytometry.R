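# Cell detection, marker quantification, gating, region assignment and
# region-stratified metrics.

make_seg <- function(nr = 10, nc = 10, roi_cols = 1:8, nest_cols = 1:4,
                     px_um = 1000) {
  roi <- matrix(FALSE, nr, nc); roi[, roi_cols] <- TRUE
  nest <- matrix(FALSE, nr, nc); nest[, nest_cols] <- TRUE
  nest <- nest & roi
  segmentation_result(binary_mask(roi, px_um), binary_mask(nest, px_um),
                      binary_mask(roi & !nest, px_um),
                      binary_mask(!roi, px_um))
}

test_that("well-separated nuclei are each detected once with accurate centroids", {
  nr <- 200; nc <- 200
  hema <- matrix(60, nr, nc)
  centers <- expand.grid(y = seq(15, 185, by = 17), x = seq(15, 185, by = 17))
  centers <- centers[1:50, ]
  for (i in seq_len(50)) {
    yy <- centers$y[i]; xx <- centers$x[i]
    for (dy in -2:2) for (dx in -2:2)
      if (dy^2 + dx^2 <= 4) hema[yy + dy, xx + dx] <- 220
  }
  img <- gray_image(hema, 4)
  roi <- binary_mask(matrix(TRUE, nr, nc), 4)
  cells <- detect_cells(img, roi)
  expect_equal(nrow(cells), 50L)
  d <- sapply(seq_len(50), function(i)
    min(sqrt((cells$x - centers$x[i])^2 + (cells$y - centers$y[i])^2)))
  expect_true(all(d <= 2))
})

test_that("blank image yields zero detections; empty ROI errors", {
  img <- gray_image(matrix(0, 50, 50), 4)
  roi <- binary_mask(matrix(TRUE, 50, 50), 4)
  expect_equal(nrow(detect_cells(img, roi)), 0L)
  expect_error(detect_cells(img, binary_mask(matrix(FALSE, 50, 50), 4)),
               "empty ROI")
})

test_that("two overlapping disks with distinct cores are split into two cells", {
  hema <- matrix(0, 40, 40)
  for (ct in list(c(20, 17), c(20, 23)))
    for (dy in -3:3) for (dx in -3:3)
      if (dy^2 + dx^2 <= 9) hema[ct[1] + dy, ct[2] + dx] <- 220
  img <- gray_image(hema, 4)
  roi <- binary_mask(matrix(TRUE, 40, 40), 4)
  cells <- detect_cells(img, roi, threshold = 100)
  expect_equal(nrow(cells), 2L)
})

test_that("marker quantification averages over the exact footprint", {
  lab <- matrix(0L, 6, 6)
  lab[2:3, 2:3] <- 1L
  cells <- data.frame(cell_id = 1L, x = 2.5, y = 2.5, area_px = 4L)
  attr(cells, "labels") <- lab
  uniform <- marker_stack(list(CD3 = matrix(77, 6, 6)), 4)
  expect_equal(quantify_markers(cells, uniform)$CD3, 77)
  half <- matrix(0, 6, 6); half[, 3:6] <- 200
  expect_equal(quantify_markers(cells, marker_stack(list(CD3 = half), 4))$CD3,
               100)
  expect_error(quantify_markers(cells, uniform, panel = c("CD3", "CD8")),
               "panel mismatch")
})

test_that("rendered profile means are recovered through the image path", {
  spec <- tiny_image_spec(seed = 21, lineage_profiles =
                            default_lineage_profiles("discovery", cv = 0))
  sim <- generate_image_stack(spec)
  seg <- segment_slide(sim$stack)
  cells <- detect_cells(gray_image(sim$stack$channels$hematoxylin, 4), seg$roi)
  tab <- quantify_markers(cells, sim$stack)
  # match detections to ground-truth cells by nearest neighbor
  truth <- sim$truth$cells
  nn <- vapply(seq_len(nrow(tab)), function(i) {
    which.min((truth$x - tab$x[i])^2 + (truth$y - tab$y[i])^2)
  }, integer(1))
  close <- sqrt((truth$x[nn] - tab$x)^2 + (truth$y[nn] - tab$y)^2) <= 1
  helper <- close & truth$sim_lineage[nn] == "helper_t"
  expect_gt(sum(helper), 20)
  # mean CD3 of matched helper T cells is near the profile mean of 200
  # (rendering, footprint trimming and channel noise perturb it slightly)
  expect_lt(abs(mean(tab$CD3[helper]) - 200), 10)
})

test_that("gating follows the lineage hierarchy", {
  panel <- default_marker_panel("discovery")
  mk <- function(...) {
    v <- setNames(rep(0, length(panel)), panel)
    v[c(...)] <- 200
    as.data.frame(as.list(v))
  }
  tab <- rbind(
    mk("CD45", "CD3", "CD8"),                    # CD8 T
    mk("CD45", "CD3", "Foxp3"),                  # TREG
    mk("CD45", "CD3", "Tbet"),                   # TH1
    mk("CD45", "CD3", "GATA3"),                  # TH2
    mk("CD45", "CD3"),                           # helper, no subtype
    mk("CD45", "CD20"),                          # B
    mk("CD45", "CD56"),                          # NK
    mk("CD45", "CD66b"),                         # granulocyte
    mk("CD45", "Tryptase"),                      # mast
    mk("CD45", "CD68", "CSF1R", "CD163"),        # TAM CD163+
    mk("CD45", "CD68", "CSF1R"),                 # TAM CD163-
    mk("CD45", "CD3", "CD8", "Foxp3"),           # CD8 wins over TREG
    mk("tumor"),                                 # tumor cell -> other
    mk())                                        # all below threshold
  out <- classify_cells(tab, gating_config("discovery"))
  expect_equal(out$lineage,
               c("cd8_t", "treg", "th1", "th2", "helper_t", "b_cell", "nk",
                 "granulocyte", "mast", "tam_cd163pos", "tam_cd163neg",
                 "cd8_t", "other", "other"))
  expect_false(any(out$pd1))
  withpd1 <- mk("CD45", "CD3", "PD1")
  expect_true(classify_cells(withpd1, gating_config("discovery"))$pd1)
})

test_that("validation-panel gating uses the CD4-based definitions", {
  panel <- default_marker_panel("validation")
  mk <- function(...) {
    v <- setNames(rep(0, length(panel)), panel)
    v[c(...)] <- 200
    as.data.frame(as.list(v))
  }
  tab <- rbind(mk("CD3", "CD4"), mk("CD3", "CD4", "Foxp3"),
               mk("CD3", "CD8"), mk("CD3"))
  out <- classify_cells(tab, gating_config("validation"))
  expect_equal(out$lineage, c("helper_t", "treg", "cd8_t", "other"))
})

test_that("noise-free gating recovers every hidden truth label", {
  tab <- generate_cell_table(flat_table_spec(seed = 22, cv = 0))
  out <- classify_cells(tab, gating_config("discovery"))
  expect_true(all(out$lineage == tab$.true_lineage))
  expect_true(all(out$pd1 == tab$.true_pd1))
})

test_that("gating agreement stays high at CV 0.15", {
  tab <- generate_cell_table(flat_table_spec(seed = 23, cv = 0.15))
  out <- classify_cells(tab, gating_config("discovery"))
  expect_gte(mean(out$lineage == tab$.true_lineage), 0.95)
})

test_that("region assignment uses rounded centroid containment", {
  seg <- make_seg()
  tab <- data.frame(cell_id = 1:3, x = c(2, 6, 9.4), y = c(2, 2, 2))
  out <- assign_region(tab, seg)
  expect_equal(out$region, c("nest", "stroma", "outside"))
})

test_that("densities and CD45 composition follow their definitions", {
  seg <- make_seg(nest_cols = 1:2, roi_cols = 1:6, px_um = 1000)
  # nest area = 20 px x 1 mm2 ... use 10x10 grid: nest = 2 cols x 10 = 20 mm2
  # scale to the documented example: 100 cells in 2.0 mm2 -> 50 cells/mm2
  seg2 <- make_seg(nr = 1, nc = 10, roi_cols = 1:6, nest_cols = 1:2,
                   px_um = 1000)
  expect_equal(mask_area_mm2(seg2$nest), 2)
  tab <- data.frame(cell_id = 1:100, x = rep(c(1, 2), 50), y = 1,
                    lineage = "helper_t", pd1 = FALSE)
  tab <- assign_region(tab, seg2)
  st <- compute_region_stats(tab, seg2)
  expect_equal(st$by_lineage$density[st$by_lineage$region == "nest" &
                                       st$by_lineage$lineage == "helper_t"],
               50.0)
  # empty region: zero densities
  expect_equal(sum(st$by_lineage$count[st$by_lineage$region == "stroma"]), 0)
  expect_true(all(st$by_lineage$density[st$by_lineage$region == "stroma"] == 0))
  # counts per region partition the cells
  expect_equal(sum(st$by_lineage$count), nrow(tab))
})

test_that("TH1/TH2 ratio computes and flags the zero-TH2 exclusion", {
  seg <- make_seg(nr = 1, nc = 10, roi_cols = 1:6, nest_cols = 1:2,
                  px_um = 1000)
  tab <- data.frame(cell_id = 1:40,
                    x = c(rep(1, 30), rep(2, 10)), y = 1,
                    lineage = c(rep("th1", 30), rep("th2", 10)),
                    pd1 = FALSE)
  tab <- assign_region(tab, seg)
  st <- compute_region_stats(tab, seg)
  r <- th1_th2_ratio(st, "nest")
  expect_equal(r$ratio, 3.0)
  expect_false(r$excluded)
  tab2 <- tab[tab$lineage == "th1", ]
  st2 <- compute_region_stats(tab2, seg)
  r2 <- th1_th2_ratio(st2, "nest")
  expect_true(r2$excluded)
  tab3 <- tab; tab3$lineage <- rev(tab3$lineage)
  st3 <- compute_region_stats(assign_region(tab3[1:10, ], seg), seg)
  expect_equal(th1_th2_ratio(st3, "nest")$ratio, 0.0)
})

test_that("polarization classes follow the printed thresholds", {
  expect_equal(polarization_class(3, 1), "nest_polarized")
  expect_equal(polarization_class(1, 1), "balanced")
  expect_equal(polarization_class(0.4, 1), "stroma_polarized")
  expect_equal(polarization_class(2, 1), "balanced")    # r = 2.0 inclusive
  expect_equal(polarization_class(0.5, 1), "balanced")  # r = 0.5 inclusive
  expect_equal(polarization_class(5, 0), "nest_polarized")
  expect_equal(polarization_class(0, 0), "undefined")
})

test_that("region validation percentages partition each region", {
  seg <- make_seg(nr = 1, nc = 10, roi_cols = 1:6, nest_cols = 1:2,
                  px_um = 1000)
  tab <- data.frame(cell_id = 1:6, x = c(1, 1, 2, 4, 5, 6), y = 1,
                    CD45 = c(0, 0, 0, 200, 0, 200),
                    tumor = c(200, 200, 200, 0, 0, 200))
  tab <- assign_region(tab, seg)
  rv <- region_validation(tab)
  nest <- rv[rv$region == "nest", ]
  expect_equal(c(nest$pct_cd45, nest$pct_double_negative, nest$pct_tumor),
               c(0, 0, 100))
  expect_equal(rowSums(rv[, -1]), c(100, 100), ignore_attr = TRUE)
  # CD45 takes precedence over the tumor marker
  stroma <- rv[rv$region == "stroma", ]
  expect_equal(stroma$pct_cd45, 200 / 3, tolerance = 1e-10)
})

test_that("segmented regions agree with ground-truth compartments for nearly all cells", {
  spec <- tiny_image_spec(seed = 24)
  sim <- generate_image_stack(spec)
  seg <- segment_slide(sim$stack)
  truth <- sim$truth$cells
  out <- assign_region(truth, seg)
  expect_gte(mean(out$region == truth$compartment), 0.98)
})

test_that("tumor-marker-positive cells concentrate in nests on synthetic slides", {
  spec <- tiny_image_spec(seed = 25)
  sim <- generate_image_stack(spec)
  seg <- segment_slide(sim$stack)
  cells <- detect_cells(gray_image(sim$stack$channels$hematoxylin, 4), seg$roi)
  tab <- assign_region(quantify_markers(cells, sim$stack), seg)
  rv <- region_validation(tab)
  expect_gt(rv$pct_tumor[rv$region == "nest"],
            rv$pct_tumor[rv$region == "stroma"])
})
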