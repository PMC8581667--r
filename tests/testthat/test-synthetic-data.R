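# Synthetic slide and cohort generators: ground-truth consistency,
# reproducibility, Poisson placement, profile statistics.

test_that("no-nest spec yields an empty nest mask and stroma-only cells", {
  spec <- tiny_image_spec(seed = 1, n_nests = 0L)
  sim <- generate_image_stack(spec)
  expect_equal(sum(sim$truth$nest_mask$pixels), 0)
  expect_true(all(sim$truth$cells$compartment == "stroma"))
})

test_that("zero densities yield structural signal plus noise only", {
  spec <- tiny_image_spec(seed = 2,
                          densities_per_mm2 = list(nest = c(tumor = 0),
                                                   stroma = c(tumor = 0)))
  sim <- generate_image_stack(spec)
  expect_equal(nrow(sim$truth$cells), 0L)
  # CD3 channel has no structural signal: noise only
  expect_lt(mean(sim$stack$channels$CD3), 4 * spec$background_noise_sd)
  # tumor channel keeps its structural contrast
  nest <- sim$truth$nest_mask$pixels
  stroma <- sim$truth$roi_mask$pixels & !nest
  expect_gt(mean(sim$stack$channels$tumor[nest]),
            mean(sim$stack$channels$tumor[stroma]) + 100)
})

test_that("structural channels follow the slide geometry", {
  spec <- tiny_image_spec(seed = 3)
  sim <- generate_image_stack(spec)
  roi <- sim$truth$roi_mask$pixels
  hema <- sim$stack$channels$hematoxylin
  expect_gt(mean(hema[roi]), 50)
  expect_lt(mean(hema[!roi]), 20)      # blank margin near zero
  # every cell lies inside the ROI, and compartments match the masks
  cells <- sim$truth$cells
  ind <- cbind(cells$y, cells$x)
  expect_true(all(roi[ind]))
  in_nest <- sim$truth$nest_mask$pixels[ind]
  expect_true(all(in_nest == (cells$compartment == "nest")))
})

test_that("identical spec and seed reproduce output bit for bit", {
  spec <- tiny_image_spec(seed = 7)
  a <- generate_image_stack(spec)
  b <- generate_image_stack(spec)
  expect_identical(a$stack$channels, b$stack$channels)
  expect_identical(a$truth$cells, b$truth$cells)
  ta <- generate_cell_table(spec)
  tb <- generate_cell_table(spec)
  expect_identical(ta, tb)
  cs <- cohort_sim_spec(seed = 7)
  expect_identical(generate_cohort(cs), generate_cohort(cs))
  # a different seed changes the draw
  spec2 <- tiny_image_spec(seed = 8)
  expect_false(identical(generate_image_stack(spec2)$stack$channels,
                         a$stack$channels))
})

test_that("cell counts are Poisson with mean density x area", {
  # fixed stroma geometry (no nests): area is deterministic, so the count
  # over seeds is Poisson(density x area)
  dens <- 100
  spec0 <- image_sim_spec(width_px = 250L, height_px = 250L,
                          pixel_size_um = 8, n_nests = 0L,
                          blank_margin_px = 0L,
                          densities_per_mm2 = list(
                            nest = c(helper_t = 0),
                            stroma = c(helper_t = dens)),
                          background_noise_sd = 0, seed = 1L)
  area <- (250 * 8 / 1000)^2  # 4 mm2
  lambda <- dens * area
  counts <- vapply(1:100, function(s) {
    spec <- spec0; spec$seed <- s
    nrow(generate_cell_table(spec))
  }, numeric(1))
  expect_lt(abs(mean(counts) - lambda), 4 * sqrt(lambda / 100) + 1)
  expect_lt(abs(var(counts) / lambda - 1), 0.5)  # Poisson: var == mean
})

test_that("zero-CV profiles reproduce their means exactly; empty densities give headers", {
  spec <- flat_table_spec(seed = 4, cv = 0)
  tab <- generate_cell_table(spec)
  helper <- tab[tab$.true_sim_lineage == "helper_t", ]
  expect_true(all(helper$CD3 == 200))
  expect_true(all(helper$CD45 == 200))
  expect_true(all(helper$CD8 == 0))
  th1 <- tab[tab$.true_sim_lineage == "th1", ]
  expect_true(all(th1$Tbet == 200))
  empty <- flat_table_spec(seed = 4)
  empty$densities_per_mm2 <- list(nest = c(tumor = 0), stroma = c(tumor = 0))
  et <- generate_cell_table(empty)
  expect_equal(nrow(et), 0L)
  expect_true(all(c("cell_id", "x", "y", "area_px",
                    default_marker_panel("discovery")) %in% names(et)))
})

test_that("sample mean intensity approaches the profile mean (CV 0.1)", {
  spec <- flat_table_spec(seed = 5, cv = 0.1,
                          densities = list(nest = c(tumor = 0),
                                           stroma = c(helper_t = 500)))
  tab <- generate_cell_table(spec)
  expect_gt(nrow(tab), 800)
  expect_lt(abs(mean(tab$CD3) - 200) / 200, 0.01)
})

test_that("infeasible nest geometry is rejected", {
  expect_error(
    image_sim_spec(width_px = 120L, height_px = 120L, pixel_size_um = 4,
                   n_nests = 1L, nest_radius_um_range = c(300, 400),
                   blank_margin_px = 10L),
    class = "nestseg_infeasible_geometry")
  # feasible radii but too many disjoint disks to place
  spec <- image_sim_spec(width_px = 220L, height_px = 220L, pixel_size_um = 4,
                         n_nests = 20L, nest_radius_um_range = c(150, 160),
                         blank_margin_px = 5L, seed = 1L)
  expect_error(generate_image_stack(spec),
               class = "nestseg_infeasible_geometry")
})

test_that("chromogenic emission inverts the stack", {
  spec <- tiny_image_spec(seed = 9)
  sim <- generate_image_stack(spec)
  dark <- as_chromogenic(sim$stack)
  back <- invert_chromogenic(gray_image(dark$channels$tumor, 4))
  expect_equal(back$pixels, sim$stack$channels$tumor)
})

test_that("cohort generator honors its survival contract", {
  spec <- cohort_sim_spec(n_patients = 400, censor_rate = 0, seed = 11)
  coh <- generate_cohort(spec)
  expect_true(all(coh$time_months > 0))
  expect_true(all(coh$event))           # censor_rate 0: all events
  expect_equal(coh$group_high,
               coh$pd1_helper_nest >= mean(coh$pd1_helper_nest))
  spec2 <- cohort_sim_spec(n_patients = 2000, censor_rate = 0.5, seed = 12)
  coh2 <- generate_cohort(spec2)
  cr <- 1 - mean(coh2$event)
  expect_gt(cr, 0.35)
  expect_lt(cr, 0.65)
})

test_that("high-group hazard shift shortens observed survival", {
  spec <- cohort_sim_spec(n_patients = 3000, log_hazard_beta = log(3),
                          censor_rate = 0, seed = 13)
  coh <- generate_cohort(spec)
  ratio <- mean(coh$time_months[!coh$group_high]) /
    mean(coh$time_months[coh$group_high])
  expect_gt(ratio, 2.5)
  expect_lt(ratio, 3.6)
})
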