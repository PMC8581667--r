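# Automatic threshold selection on 256-bin histograms (bins 0..255).
# Candidate thresholds t split intensities into background (g <= t) and
# foreground (g > t); candidates range over [g_min, g_max - 1] so that both
# classes are non-empty. Ties are broken toward the smallest t.

check_histogram <- function(h) {
  stopifnot(is.numeric(h), length(h) == 256L, all(h >= 0), all(is.finite(h)))
  pop <- which(h > 0) - 1L
  if (length(pop) < 2L)
    stop("histogram has fewer than two populated bins: no threshold exists",
         call. = FALSE)
  pop
}

# counts as doubles so cumulative moments cannot overflow integer range
as_double_hist <- function(h) as.numeric(h)

# Shannon entropy of a fuzzy membership value; S(0) = S(1) = 0
shannon_fuzzy <- function(mu) {
  s <- numeric(length(mu))
  ok <- mu > 0 & mu < 1
  m <- mu[ok]
  s[ok] <- -m * log(m) - (1 - m) * log(1 - m)
  s
}

#' Huang fuzzy minimum-fuzziness threshold
#'
#' Selects the intensity threshold minimizing the Huang--Wang measure of
#' fuzziness. For a candidate threshold t, each gray level g is assigned a
#' membership \eqn{\mu_t(g) = 1 / (1 + |g - m(g,t)| / C)} to the class
#' (background mean for \eqn{g \le t}, foreground mean for \eqn{g > t})
#' containing it, where C is the dynamic range \eqn{g_{max} - g_{min}}.
#' The fuzziness is the histogram-weighted Shannon entropy of the
#' memberships, \eqn{E(t) = \sum_g h(g) S(\mu_t(g))}, and the returned
#' threshold minimizes E with ties broken toward the smallest t.
#'
#' Background/foreground means are evaluated from cumulative histogram
#' moments so each candidate costs O(populated bins).
#'
#' @param histogram Numeric vector of 256 bin counts (gray levels 0..255),
#'   at least two populated bins.
#' @return Integer threshold t in `[g_min, g_max - 1]`; pixels with
#'   intensity `> t` are foreground. The attribute `"fuzziness"` carries
#'   E(t) at the optimum.
#' @references Huang, L.-K. and Wang, M.-J. J. (1995) Image thresholding by
#'   minimizing the measures of fuzziness. Pattern Recognition 28(1), 41-51.
#' @export
huang_threshold <- function(histogram) {
  pop <- check_histogram(histogram)
  histogram <- as_double_hist(histogram)
  g_min <- pop[1L]
  g_max <- pop[length(pop)]
  C <- g_max - g_min
  g <- 0:255
  cum_n <- cumsum(histogram)
  cum_s <- cumsum(g * histogram)
  n_tot <- cum_n[256L]
  s_tot <- cum_s[256L]
  cand <- g_min:(g_max - 1L)
  E <- vapply(cand, function(t) {
    n_b <- cum_n[t + 1L]
    m_b <- cum_s[t + 1L] / n_b
    m_f <- (s_tot - cum_s[t + 1L]) / (n_tot - n_b)
    m_g <- ifelse(pop <= t, m_b, m_f)
    mu <- 1 / (1 + abs(pop - m_g) / C)
    sum(histogram[pop + 1L] * shannon_fuzzy(mu))
  }, numeric(1L))
  i <- which.min(E)
  structure(cand[i], fuzziness = E[i])
}

#' Kapur maximum-entropy threshold
#'
#' Maximizes the sum of the Shannon entropies of the background and
#' foreground gray-level distributions, the classic "maximum entropy"
#' automatic threshold.
#'
#' @inheritParams huang_threshold
#' @return Integer threshold; pixels `> t` are foreground.
#' @export
kapur_threshold <- function(histogram) {
  pop <- check_histogram(histogram)
  histogram <- as_double_hist(histogram)
  g_min <- pop[1L]
  g_max <- pop[length(pop)]
  p <- histogram / sum(histogram)
  cum_p <- cumsum(p)
  plogp <- ifelse(p > 0, p * log(p), 0)
  cum_plogp <- cumsum(plogp)
  tot_plogp <- cum_plogp[256L]
  cand <- g_min:(g_max - 1L)
  H <- vapply(cand, function(t) {
    P_b <- cum_p[t + 1L]
    P_f <- 1 - P_b
    H_b <- log(P_b) - cum_plogp[t + 1L] / P_b
    H_f <- log(P_f) - (tot_plogp - cum_plogp[t + 1L]) / P_f
    H_b + H_f
  }, numeric(1L))
  cand[which.max(H)]
}

#' Triangle threshold
#'
#' Geometric method for unimodal histograms: a line is drawn from the
#' histogram peak to the far end of its longer tail, and the threshold is
#' the bin maximizing the perpendicular distance between the histogram and
#' that line.
#'
#' @inheritParams huang_threshold
#' @return Integer threshold; pixels `> t` are foreground.
#' @export
triangle_threshold <- function(histogram) {
  pop <- check_histogram(histogram)
  histogram <- as_double_hist(histogram)
  g_min <- pop[1L]
  g_max <- pop[length(pop)]
  peak <- which.max(histogram) - 1L
  h_peak <- max(histogram)
  # walk down the longer tail
  end <- if ((peak - g_min) >= (g_max - peak)) g_min else g_max
  if (end == peak) return(peak)
  gs <- if (end > peak) (peak:(end - 1L)) else ((end + 1L):peak)
  # distance from (g, h(g)) to the line through (peak, h_peak) and (end, 0)
  dx <- end - peak
  dy <- 0 - h_peak
  d <- abs(dy * (gs - peak) - dx * (histogram[gs + 1L] - h_peak)) /
    sqrt(dx^2 + dy^2)
  gs[which.max(d)]
}

#' Otsu threshold from a histogram
#'
#' Maximizes the between-class variance; the workhorse for bimodal
#' histograms (tissue/blank splits, nuclear-channel thresholding).
#'
#' @inheritParams huang_threshold
#' @return Integer threshold; pixels `> t` are foreground.
#' @export
otsu_from_histogram <- function(histogram) {
  pop <- check_histogram(histogram)
  histogram <- as_double_hist(histogram)
  g_min <- pop[1L]
  g_max <- pop[length(pop)]
  g <- 0:255
  cum_n <- cumsum(histogram)
  cum_s <- cumsum(g * histogram)
  n_tot <- cum_n[256L]
  s_tot <- cum_s[256L]
  cand <- g_min:(g_max - 1L)
  bcv <- vapply(cand, function(t) {
    n_b <- cum_n[t + 1L]
    n_f <- n_tot - n_b
    m_b <- cum_s[t + 1L] / n_b
    m_f <- (s_tot - cum_s[t + 1L]) / n_f
    n_b * n_f * (m_b - m_f)^2
  }, numeric(1L))
  cand[which.max(bcv)]
}

#' Classify tissue versus blank regions of a slide image
#'
#' Thresholds a structural channel (hematoxylin by default upstream) into
#' tissue (foreground, signal-high) versus blank background. The threshold
#' method is pluggable: `"max_entropy"` (Kapur, default), a `"fixed"`
#' value, the `"triangle"` method, or `"otsu"`. Entropy-based thresholds
#' are unreliable when one class is a narrow near-delta mode (blank glass
#' after inversion); Otsu with pre-smoothing is the robust choice there
#' and is what [segment_slide()] uses.
#'
#' A constant image admits no threshold; in that degenerate case an
#' all-TRUE mask is returned with attribute `degenerate = TRUE` and a
#' warning.
#'
#' `smooth_sigma_px > 0` applies a Gaussian low-pass filter before
#' histogramming and thresholding. On nuclear-counterstain channels this
#' suppresses the bright nucleus-scale texture that would otherwise form a
#' third histogram mode and mislead entropy-based thresholding, leaving
#' the clean tissue-versus-blank bimodality. The default (0) preserves
#' exact pixel-level method semantics.
#'
#' @param image A `gray_image`.
#' @param method One of `"max_entropy"`, `"fixed"`, `"triangle"`.
#' @param fixed_value Threshold used when `method = "fixed"` (default 127).
#' @param smooth_sigma_px Gaussian pre-smoothing sigma in pixels (0 = off).
#' @return A `binary_mask` of tissue pixels (intensity strictly above the
#'   threshold) with attributes `threshold` and `degenerate`.
#' @export
compute_tissue_mask <- function(image,
                                method = c("max_entropy", "fixed", "triangle",
                                           "otsu"),
                                fixed_value = 127, smooth_sigma_px = 0) {
  stopifnot(inherits(image, "gray_image"), length(image$pixels) > 0,
            smooth_sigma_px >= 0)
  method <- match.arg(method)
  px <- image$pixels
  if (smooth_sigma_px > 0)
    px <- pmin(pmax(as.matrix(EBImage::gblur(px, sigma = smooth_sigma_px)),
                    0), 255)
  h <- intensity_histogram(px)
  if (sum(h > 0) < 2L) {
    warning("constant image: threshold undefined, returning all-true mask")
    out <- binary_mask(matrix(TRUE, nrow(px), ncol(px)), image$pixel_size_um)
    attr(out, "threshold") <- NA_real_
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  t <- switch(method,
              max_entropy = kapur_threshold(h),
              triangle = triangle_threshold(h),
              otsu = otsu_from_histogram(h),
              fixed = fixed_value)
  out <- binary_mask(px > t, image$pixel_size_um)
  attr(out, "threshold") <- as.numeric(t)
  attr(out, "degenerate") <- FALSE
  out
}
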