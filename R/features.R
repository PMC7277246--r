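#' Configuration for the scalar feature battery
#'
#' @param glcm_levels Grey levels for co-occurrence quantization.
#' @param glcm_offset Pixel offset `(dy, dx)` of the co-occurring neighbour.
#' @param entropy_bins Histogram bins for channel entropies (over `[0, 1]`).
#' @param canny_low,canny_high Hysteresis thresholds on the max-normalized
#'   gradient magnitude (`0 < low < high < 1`).
#' @param canny_sigma Gaussian smoothing sd (pixels) before edge detection.
#' @param jpeg_quality JPEG quality (0-100) used for the compressibility
#'   feature.
#' @param clutter_scales Gaussian-pyramid levels pooled by the clutter
#'   features.
#' @param colour_bin_width CIELAB bin width (units) for the colour count.
#' @return A `feature_config` list.
#' @export
feature_config <- function(glcm_levels = 8L, glcm_offset = c(0L, 1L),
                           entropy_bins = 256L, canny_low = 0.11,
                           canny_high = 0.27, canny_sigma = 1,
                           jpeg_quality = 75, clutter_scales = 3L,
                           colour_bin_width = 10) {
  stopifnot(canny_low > 0, canny_low < canny_high, canny_high < 1,
            glcm_levels >= 2, entropy_bins >= 2, clutter_scales >= 1)
  structure(
    list(glcm_levels = as.integer(glcm_levels),
         glcm_offset = as.integer(glcm_offset),
         entropy_bins = as.integer(entropy_bins),
         canny_low = canny_low, canny_high = canny_high,
         canny_sigma = canny_sigma, jpeg_quality = jpeg_quality,
         clutter_scales = as.integer(clutter_scales),
         colour_bin_width = colour_bin_width),
    class = "feature_config"
  )
}

#' Grey-level co-occurrence features
#'
#' Quantizes luminance to `glcm_levels` equal-width bins, accumulates the
#' symmetric, normalized co-occurrence matrix at the configured offset, and
#' returns its contrast, correlation, energy and homogeneity. A constant
#' image has undefined correlation (zero marginal variance); it is returned
#' as 0 with a warning and a `correlation_defined = FALSE` flag.
#'
#' @param image Height x width x 3 array in `[0, 1]`.
#' @param cfg A [feature_config()].
#' @return Named list: `glcm_contrast`, `glcm_correlation`, `glcm_energy`,
#'   `glcm_homogeneity`, `correlation_defined`.
#' @export
glcm_features <- function(image, cfg = feature_config()) {
  g <- luminance(image)
  L <- cfg$glcm_levels
  q <- pmin(floor(g * L) + 1L, L)
  dy <- cfg$glcm_offset[1]; dx <- cfg$glcm_offset[2]
  h <- nrow(q); w <- ncol(q)
  rows <- seq_len(h - abs(dy)); cols <- seq_len(w - abs(dx))
  i <- q[rows, cols, drop = FALSE]
  j <- q[rows + abs(dy), cols + abs(dx), drop = FALSE]
  counts <- matrix(tabulate((as.vector(i) - 1L) * L + as.vector(j), nbins = L * L),
                   L, L, byrow = TRUE)
  p <- counts + t(counts)
  p <- p / sum(p)
  idx <- seq_len(L)
  ii <- matrix(idx, L, L); jj <- t(ii)
  contrast <- sum(p * (ii - jj)^2)
  energy <- sum(p^2)
  homogeneity <- sum(p / (1 + abs(ii - jj)))
  mu_i <- sum(ii * p); mu_j <- sum(jj * p)
  var_i <- sum((ii - mu_i)^2 * p); var_j <- sum((jj - mu_j)^2 * p)
  if (var_i <= 0 || var_j <= 0) {
    warning("GLCM correlation undefined for (near-)constant image; returning 0")
    correlation <- 0
    defined <- FALSE
  } else {
    correlation <- sum((ii - mu_i) * (jj - mu_j) * p) / sqrt(var_i * var_j)
    defined <- TRUE
  }
  list(glcm_contrast = contrast, glcm_correlation = correlation,
       glcm_energy = energy, glcm_homogeneity = homogeneity,
       correlation_defined = defined)
}

#' Colour features
#'
#' Computed in CIELAB (sRGB, D65): colourfulness is
#' `sqrt(sd_a^2 + sd_b^2) + 0.3 * sqrt(mean_a^2 + mean_b^2)`; colour count
#' is the number of occupied CIELAB cubes of side `colour_bin_width` holding
#' at least 0.01% of the pixels; colour harmony scores the chroma-weighted
#' agreement of the hue distribution with the best rotated arc template
#' (a stand-in for proprietary harmony software — values are comparable
#' within this package only).
#'
#' @inheritParams glcm_features
#' @return Named list: `colourfulness`, `colour_count`, `colour_harmony`.
#' @export
colour_features <- function(image, cfg = feature_config()) {
  lab <- lab_channels(image)
  a <- as.vector(lab$a); b <- as.vector(lab$b); L <- as.vector(lab$L)
  n <- length(a)
  colourfulness <- sqrt(stats::var(a) * (n - 1) / n + stats::var(b) * (n - 1) / n)
  colourfulness <- colourfulness + 0.3 * sqrt(mean(a)^2 + mean(b)^2)
  if (!is.finite(colourfulness)) colourfulness <- 0

  bw <- cfg$colour_bin_width
  key <- paste(floor(L / bw), floor(a / bw), floor(b / bw))
  tab <- table(key)
  colour_count <- sum(tab >= max(1, 1e-4 * n))

  chroma <- sqrt(a^2 + b^2)
  if (sum(chroma) < 1e-8) {
    harmony <- 0
  } else {
    hue <- atan2(b, a)  # radians in (-pi, pi]
    harmony <- harmony_template_score(hue, chroma)
  }
  list(colourfulness = colourfulness, colour_count = colour_count,
       colour_harmony = harmony)
}

# chroma-weighted fraction of hues inside the best rotated arc template;
# templates are classical single/double-arc hue layouts
harmony_template_score <- function(hue, weight) {
  deg <- (hue * 180 / pi) %% 360
  templates <- list(
    i = c(18), I = c(18, 18), V = c(93.6), X = c(93.6, 93.6), T = c(180)
  )
  offsets <- list(i = 0, I = 180, V = 0, X = 180, T = 0)
  best <- 0
  wsum <- sum(weight)
  for (nm in names(templates)) {
    widths <- templates[[nm]]
    for (rot in seq(0, 355, by = 5)) {
      centres <- (rot + cumsum(c(0, offsets[[nm]])))[seq_along(widths)] %% 360
      inside <- rep(FALSE, length(deg))
      for (k in seq_along(widths)) {
        d <- abs(((deg - centres[k] + 180) %% 360) - 180)
        inside <- inside | (d <= widths[k] / 2)
      }
      best <- max(best, sum(weight[inside]) / wsum)
    }
  }
  best
}

shannon_entropy <- function(x, bins = 256L, lo = 0, hi = 1) {
  x <- pmin(pmax(x, lo), hi)
  idx <- pmin(floor((x - lo) / (hi - lo) * bins) + 1L, bins)
  p <- tabulate(idx, nbins = bins)
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Channel entropies, variances, mean luminance and size
#'
#' Shannon entropies (base 2, 256-bin histograms over `[0, 1]`) of the R, G,
#' B, hue, saturation and value channels plus the whole-image (luminance)
#' entropy; variances of the flattened RGB matrix and of each channel; mean
#' luminance; and the pixel count.
#'
#' @inheritParams glcm_features
#' @return Named list of 13 scalars.
#' @export
entropy_variance_features <- function(image, cfg = feature_config()) {
  bins <- cfg$entropy_bins
  r <- image[, , 1]; g <- image[, , 2]; b <- image[, , 3]
  hsv <- grDevices::rgb2hsv(rbind(as.vector(r), as.vector(g), as.vector(b)),
                            maxColorValue = 1)
  lum <- luminance(image)
  list(
    entropy_R = shannon_entropy(r, bins), entropy_G = shannon_entropy(g, bins),
    entropy_B = shannon_entropy(b, bins),
    entropy_H = shannon_entropy(hsv[1, ], bins),
    entropy_S = shannon_entropy(hsv[2, ], bins),
    entropy_V = shannon_entropy(hsv[3, ], bins),
    entropy_whole = shannon_entropy(lum, bins),
    variance_all = stats::var(as.vector(image)),
    variance_R = stats::var(as.vector(r)),
    variance_G = stats::var(as.vector(g)),
    variance_B = stats::var(as.vector(b)),
    mean_luminance = mean(lum),
    pixel_count = nrow(lum) * ncol(lum)
  )
}

#' Feature-congestion clutter features
#'
#' Follows the feature-congestion idea of pooling local feature variability
#' over a small Gaussian pyramid: colour clutter is the mean (over pixels
#' and scales) volume `sqrt(det)` of the local 2x2 covariance of the CIELAB
#' a, b planes; contrast clutter is the local standard deviation of a
#' band-pass (difference-of-Gaussians) luminance map, summarized by its mean
#' and variance over pixels and scales; sub-band entropy is the mean Shannon
#' entropy of the orientation sub-band coefficients of a 3-level Haar
#' wavelet decomposition of luminance.
#'
#' @inheritParams glcm_features
#' @return Named list: `colour_clutter`, `contrast_clutter_mean`,
#'   `contrast_clutter_var`, `subband_entropy`.
#' @export
clutter_features <- function(image, cfg = feature_config()) {
  lab <- lab_channels(image)
  n_scales <- cfg$clutter_scales
  min_dim <- min(dim(lab$L))
  max_scales <- max(1L, floor(log2(min_dim / 8)) + 1L)
  if (n_scales > max_scales) {
    warning("image too small for ", n_scales, " clutter scales; using ",
            max_scales)
    n_scales <- max_scales
  }

  a <- lab$a; b <- lab$b; L <- lab$L
  colour_vals <- numeric(0)
  contrast_vals <- numeric(0)
  for (s in seq_len(n_scales)) {
    # local covariance of (a, b) under a Gaussian window
    k <- gauss_kernel(2)
    ma <- sep_filter(a, k); mb <- sep_filter(b, k)
    caa <- pmax(sep_filter(a * a, k) - ma^2, 0)
    cbb <- pmax(sep_filter(b * b, k) - mb^2, 0)
    cab <- sep_filter(a * b, k) - ma * mb
    det2 <- pmax(caa * cbb - cab^2, 0)
    colour_vals <- c(colour_vals, sqrt(sqrt(det2)))  # ~ geometric-mean sd

    bp <- gauss_blur(L, 1) - gauss_blur(L, 3)
    mbp <- sep_filter(bp, k)
    vbp <- pmax(sep_filter(bp * bp, k) - mbp^2, 0)
    contrast_vals <- c(contrast_vals, sqrt(vbp))

    if (s < n_scales) {
      a <- pyr_down(a); b <- pyr_down(b); L <- pyr_down(L)
    }
  }

  list(
    colour_clutter = mean(colour_vals),
    contrast_clutter_mean = mean(contrast_vals),
    contrast_clutter_var = stats::var(contrast_vals) *
      (length(contrast_vals) - 1) / length(contrast_vals),
    subband_entropy = haar_subband_entropy(luminance(image))
  )
}

# mean entropy of the 9 orientation sub-bands of a 3-level Haar decomposition
haar_subband_entropy <- function(m, levels = 3L, bins = 256L) {
  ent <- numeric(0)
  ll <- m
  for (lev in seq_len(levels)) {
    h <- nrow(ll) %/% 2L * 2L
    w <- ncol(ll) %/% 2L * 2L
    if (h < 2 || w < 2) break
    x <- ll[seq_len(h), seq_len(w), drop = FALSE]
    od <- seq(1, h, by = 2); ev <- od + 1
    lo_r <- (x[od, , drop = FALSE] + x[ev, , drop = FALSE]) / sqrt(2)
    hi_r <- (x[od, , drop = FALSE] - x[ev, , drop = FALSE]) / sqrt(2)
    odc <- seq(1, w, by = 2); evc <- odc + 1
    LL <- (lo_r[, odc, drop = FALSE] + lo_r[, evc, drop = FALSE]) / sqrt(2)
    LH <- (lo_r[, odc, drop = FALSE] - lo_r[, evc, drop = FALSE]) / sqrt(2)
    HL <- (hi_r[, odc, drop = FALSE] + hi_r[, evc, drop = FALSE]) / sqrt(2)
    HH <- (hi_r[, odc, drop = FALSE] - hi_r[, evc, drop = FALSE]) / sqrt(2)
    for (band in list(LH, HL, HH)) {
      rng <- range(band)
      if (diff(rng) < 1e-12) ent <- c(ent, 0)
      else ent <- c(ent, shannon_entropy(band, bins, rng[1], rng[2]))
    }
    ll <- LL
  }
  if (length(ent) == 0) 0 else mean(ent)
}

#' Structural features: edge density, JPEG ratio, frequency factor
#'
#' Edge density is the fraction of pixels marked by a Canny detector
#' (Gaussian smoothing `canny_sigma`, non-maximum suppression, hysteresis at
#' `canny_low`/`canny_high` on the max-normalized gradient magnitude; the
#' normalizer is floored at 0.25 so near-flat images do not have their
#' noise amplified into edges). The
#' JPEG compression ratio divides the uncompressed size (3 bytes/pixel) by
#' the JPEG byte size at `jpeg_quality`. The frequency factor is the radial
#' spatial frequency below which 99% of the FFT power (DC included) lies,
#' divided by the Nyquist frequency (0.5 cycles/pixel along the shorter
#' axis); broadband images can only reach 99% beyond the Nyquist circle, so
#' the value is capped at 1.
#'
#' @inheritParams glcm_features
#' @return Named list: `edge_density`, `jpeg_ratio`, `frequency_factor`.
#' @export
structure_features <- function(image, cfg = feature_config()) {
  g <- luminance(image)
  edges <- canny_edges(g, cfg$canny_low, cfg$canny_high, cfg$canny_sigma)
  raw_bytes <- 3 * nrow(g) * ncol(g)
  jpg <- jpeg::writeJPEG(image, raw(), quality = cfg$jpeg_quality / 100)
  list(
    edge_density = mean(edges),
    jpeg_ratio = raw_bytes / length(jpg),
    frequency_factor = frequency_factor(g)
  )
}

canny_edges <- function(g, low = 0.11, high = 0.27, sigma = 1) {
  gs <- gauss_blur(g, sigma)
  gx <- (shift_mat(gs, 0L, 1L) - shift_mat(gs, 0L, -1L)) / 2
  gy <- (shift_mat(gs, 1L, 0L) - shift_mat(gs, -1L, 0L)) / 2
  mag <- sqrt(gx^2 + gy^2)
  if (max(mag) < 1e-12) return(matrix(FALSE, nrow(g), ncol(g)))
  # normalize by the maximum magnitude (so thresholds are relative, as in
  # classical implementations) but floor the normalizer: a near-flat image
  # must not have its sensor-level noise amplified into "edges"
  mag <- mag / max(max(mag), 0.25)
  ang <- atan2(gy, gx)
  sector <- floor(((ang + pi) / pi * 4 + 0.5)) %% 4  # 0:E-W,1:NE-SW,2:N-S,3:NW-SE
  n1 <- mag; n2 <- mag
  for (s in 0:3) {
    d <- switch(as.character(s),
      "0" = c(0L, 1L), "1" = c(1L, 1L), "2" = c(1L, 0L), "3" = c(1L, -1L))
    sel <- sector == s
    n1[sel] <- shift_mat(mag, d[1], d[2])[sel]
    n2[sel] <- shift_mat(mag, -d[1], -d[2])[sel]
  }
  keep <- mag >= n1 & mag >= n2
  strong <- keep & mag >= high
  weak <- keep & mag >= low
  if (!any(strong)) return(matrix(FALSE, nrow(g), ncol(g)))
  lab <- EBImage::bwlabel(weak)
  good <- unique(lab[strong])
  weak & (lab %in% good[good > 0])
}

frequency_factor <- function(g) {
  p <- Mod(stats::fft(g))^2
  total <- sum(p)
  if (total < 1e-20) return(0)
  h <- nrow(g); w <- ncol(g)
  fy <- (seq_len(h) - 1) / h; fy <- ifelse(fy > 0.5, fy - 1, fy)
  fx <- (seq_len(w) - 1) / w; fx <- ifelse(fx > 0.5, fx - 1, fx)
  r <- sqrt(outer(fy^2, fx^2, "+"))
  ord <- order(r)
  cum <- cumsum(p[ord])
  r99 <- r[ord][which(cum >= 0.99 * total)[1]]
  min(r99 / 0.5, 1)
}
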