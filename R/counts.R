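#' Keypoint and region counts
#'
#' Mid-level and proto-object counts with a pluggable backend. The
#' `"reference"` backend is self-contained: a difference-of-Gaussians (DoG)
#' scale-space extremum counter stands in for SIFT keypoint counts, a
#' determinant-of-Hessian blob counter for SURF counts, a stable-threshold
#' connected-region counter for MSER counts, and mean-shift mode seeking on
#' a downscaled CIELAB raster for the mean-shift region count. The
#' `"external"` backend instead looks the four counts up in a table (e.g.
#' produced by dedicated detector software) by `image_id`.
#'
#' @param image Height x width x 3 array in `[0, 1]`.
#' @param backend `"reference"` or `"external"`.
#' @param cfg A [feature_config()] (reserved for future thresholds).
#' @param external_counts Data frame with columns `image_id`, `sift_count`,
#'   `surf_count`, `mser_count`, `meanshift_region_count` (external backend).
#' @param image_id Id used for the external lookup.
#' @return Named list: `sift_count`, `surf_count`, `mser_count`,
#'   `meanshift_region_count` (non-negative integers).
#' @export
count_features <- function(image, backend = c("reference", "external"),
                           cfg = feature_config(), external_counts = NULL,
                           image_id = NULL) {
  if (length(backend) == 1 && !backend %in% c("reference", "external")) {
    stop("unknown count backend: ", backend, call. = FALSE)
  }
  backend <- match.arg(backend)
  if (backend == "external") {
    if (is.null(external_counts) || is.null(image_id)) {
      stop("external backend requires external_counts and image_id", call. = FALSE)
    }
    row <- external_counts[external_counts$image_id == image_id, , drop = FALSE]
    if (nrow(row) == 0) {
      stop("no external counts for image id: ", image_id, call. = FALSE)
    }
    return(list(
      sift_count = as.integer(row$sift_count[1]),
      surf_count = as.integer(row$surf_count[1]),
      mser_count = as.integer(row$mser_count[1]),
      meanshift_region_count = as.integer(row$meanshift_region_count[1])
    ))
  }
  g <- luminance(image)
  list(
    sift_count = dog_keypoint_count(g),
    surf_count = hessian_blob_count(g),
    mser_count = stable_region_count(g),
    meanshift_region_count = meanshift_region_count(image)
  )
}

# count 3x3x3 scale-space extrema of a difference-of-Gaussians stack
dog_keypoint_count <- function(g, n_scales = 6L, sigma0 = 1.6,
                               contrast_thresh = 0.015) {
  sigmas <- sigma0 * 2^((seq_len(n_scales) - 1) / 3)
  blurred <- lapply(sigmas, function(s) gauss_blur(g, s))
  dogs <- lapply(seq_len(n_scales - 1), function(k) blurred[[k + 1]] - blurred[[k]])
  shifts <- expand.grid(dy = -1:1, dx = -1:1)
  count <- 0L
  for (k in 2:(length(dogs) - 1)) {
    d <- dogs[[k]]
    others_max <- matrix(-Inf, nrow(d), ncol(d))
    others_min <- matrix(Inf, nrow(d), ncol(d))
    for (lev in (k - 1):(k + 1)) {
      dd <- dogs[[lev]]
      for (r in seq_len(nrow(shifts))) {
        if (lev == k && shifts$dy[r] == 0 && shifts$dx[r] == 0) next
        sh <- shift_mat(dd, shifts$dy[r], shifts$dx[r])
        others_max <- pmax(others_max, sh)
        others_min <- pmin(others_min, sh)
      }
    }
    extremum <- (d > others_max | d < others_min) & abs(d) > contrast_thresh
    # exclude the replicate-padded border
    extremum[c(1, nrow(d)), ] <- FALSE
    extremum[, c(1, ncol(d))] <- FALSE
    count <- count + sum(extremum)
  }
  as.integer(count)
}

# count local maxima of the determinant of the Hessian across a few scales
hessian_blob_count <- function(g, sigmas = c(2, 4, 6), thresh = 2e-4) {
  count <- 0L
  for (s in sigmas) {
    b <- gauss_blur(g, s)
    dxx <- shift_mat(b, 0L, 1L) - 2 * b + shift_mat(b, 0L, -1L)
    dyy <- shift_mat(b, 1L, 0L) - 2 * b + shift_mat(b, -1L, 0L)
    dxy <- (shift_mat(b, 1L, 1L) - shift_mat(b, 1L, -1L) -
              shift_mat(b, -1L, 1L) + shift_mat(b, -1L, -1L)) / 4
    # scale-normalized response
    det_h <- (dxx * dyy - (0.9 * dxy)^2) * s^4
    local_max <- det_h
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      local_max <- pmax(local_max, shift_mat(det_h, dy, dx))
    }
    hit <- det_h >= local_max & det_h > thresh
    hit[c(1, nrow(g)), ] <- FALSE
    hit[, c(1, ncol(g))] <- FALSE
    count <- count + sum(hit)
  }
  as.integer(count)
}

# count connected regions that stay stable (area change < 50%) across
# consecutive luminance thresholds, on both polarities; overlapping stable
# regions across adjacent levels are counted once
stable_region_count <- function(g, levels = seq(0.1, 0.9, by = 0.1),
                                min_area = 16L, max_rel_change = 0.5) {
  total <- 0L
  counted <- list()
  for (polarity in c("dark", "bright")) {
    masks <- lapply(levels, function(t) {
      if (polarity == "dark") g <= t else g >= t
    })
    labs <- lapply(masks, function(m) EBImage::bwlabel(m * 1))
    prev_stable <- list()
    for (k in 2:(length(levels) - 1)) {
      lab_k <- labs[[k]]
      if (max(lab_k) == 0) { prev_stable <- list(); next }
      areas_k <- tabulate(lab_k[lab_k > 0])
      cur_stable <- list()
      for (comp in which(areas_k >= min_area)) {
        pix <- which(lab_k == comp)
        # containing component at the next (more permissive) level
        big_lab <- labs[[k + 1]][pix[1]]
        area_big <- if (big_lab > 0) sum(labs[[k + 1]] == big_lab) else Inf
        # largest contained component at the previous level
        inner <- labs[[k - 1]][pix]
        inner <- inner[inner > 0]
        area_small <- if (length(inner) > 0) max(tabulate(inner)) else 0
        if (is.finite(area_big) &&
            (area_big - area_small) / areas_k[comp] < max_rel_change) {
          # dedupe against stable regions one level down
          same <- function(ps) {
            length(intersect(pix, ps)) / max(length(pix), length(ps)) > 0.5
          }
          dup <- any(vapply(prev_stable, same, logical(1))) ||
            any(vapply(counted, same, logical(1)))
          if (!dup) {
            total <- total + 1L
            counted[[length(counted) + 1]] <- pix
          }
          cur_stable[[length(cur_stable) + 1]] <- pix
        }
      }
      prev_stable <- cur_stable
    }
  }
  total
}

# mean-shift mode count on a downscaled joint (space, CIELAB) raster
meanshift_region_count <- function(image, max_dim = 24L, hs = 7, hr = 12,
                                   max_iter = 20L) {
  small <- downscale_rgb(image, max_dim)
  lab <- lab_channels(small)
  h <- nrow(lab$L); w <- ncol(lab$L)
  feats <- cbind(
    as.vector(row(lab$L)) / hs, as.vector(col(lab$L)) / hs,
    as.vector(lab$L) / hr, as.vector(lab$a) / hr, as.vector(lab$b) / hr
  )
  x <- feats
  f2 <- rowSums(feats^2)
  for (it in seq_len(max_iter)) {
    d2 <- outer(rowSums(x^2), f2, "+") - 2 * x %*% t(feats)
    win <- d2 <= 1
    new_x <- (win %*% feats) / rowSums(win)
    if (max(abs(new_x - x)) < 1e-4) { x <- new_x; break }
    x <- new_x
  }
  # merge converged modes within half a bandwidth
  d <- stats::dist(x)
  cl <- stats::cutree(stats::hclust(d, method = "single"), h = 0.5)
  length(unique(cl))
}
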