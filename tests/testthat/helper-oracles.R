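# Independent oracles and small fixtures shared across tests.

jaccard <- function(a, b) sum(a & b) / sum(a | b)

# Brute-force Huang-Wang fuzziness minimizer: for every candidate t the
# class means and the fuzziness are evaluated by direct summation, with no
# cumulative-moment shortcuts. Returns the smallest minimizing t.
huang_bruteforce <- function(h) {
  g_all <- 0:255
  pop <- g_all[h > 0]
  g_min <- min(pop); g_max <- max(pop)
  C <- g_max - g_min
  best_t <- NA_integer_
  best_E <- Inf
  for (t in g_min:(g_max - 1L)) {
    lo <- pop[pop <= t]; hi <- pop[pop > t]
    m_b <- sum(lo * h[lo + 1L]) / sum(h[lo + 1L])
    m_f <- sum(hi * h[hi + 1L]) / sum(h[hi + 1L])
    m <- ifelse(pop <= t, m_b, m_f)
    mu <- 1 / (1 + abs(pop - m) / C)
    s <- ifelse(mu > 0 & mu < 1,
                -mu * log(mu) - (1 - mu) * log(1 - mu), 0)
    E <- sum(h[pop + 1L] * s)
    if (E < best_E - 1e-12) { best_E <- E; best_t <- t }
  }
  best_t
}

# histogram of a synthetic two-Gaussian intensity sample
bimodal_histogram <- function(n1, mu1, sd1, n2, mu2, sd2, seed = 1L) {
  set.seed(seed)
  v <- c(rnorm(n1, mu1, sd1), rnorm(n2, mu2, sd2))
  tabulate(pmin(pmax(round(v), 0), 255) + 1L, nbins = 256L)
}

# small slide spec for fast image tests (1.2 x 1.2 mm at 4 um/px)
tiny_image_spec <- function(seed = 1L, n_nests = 2L,
                            nest_radius_um_range = c(100, 200), ...) {
  image_sim_spec(width_px = 300L, height_px = 300L, pixel_size_um = 4,
                 n_nests = n_nests,
                 nest_radius_um_range = nest_radius_um_range,
                 blank_margin_px = 16L, seed = seed, ...)
}

# cell-table spec without geometry randomness (no nests)
flat_table_spec <- function(seed = 1L, cv = 0.1, densities = NULL) {
  profiles <- default_lineage_profiles("discovery", cv = cv)
  if (is.null(densities))
    densities <- list(nest = c(tumor = 0),
                      stroma = default_densities_per_mm2()$stroma)
  image_sim_spec(width_px = 400L, height_px = 400L, pixel_size_um = 4,
                 n_nests = 0L, blank_margin_px = 10L,
                 lineage_profiles = profiles,
                 densities_per_mm2 = densities, seed = seed)
}

# exponential-survival sample without censoring
exp_cohort <- function(n, rate, seed = 1L) {
  set.seed(seed)
  data.frame(time_months = rexp(n, rate), event = rep(TRUE, n))
}
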