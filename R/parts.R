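#' Decompose an image into overlapping discs
#'
#' Disc centers form a square grid from `radius` to `dim - radius` along
#' each axis at stride `round(1.2 * radius)` (so neighbouring discs
#' overlap); grid positions are generated 1-based and reported 0-based. An
#' axis shorter than `2 * radius` collapses to a single centered row/column
#' of discs. Each disc raster is a `(2r+1) x (2r+1)` square crop with
#' pixels outside the disc (or outside the image) set to mid-gray 0.5, so
#' feature extraction on discs is well-defined.
#'
#' A typical 375 x 500 frame at the default radius yields a 5 x 7 grid of
#' 35 discs.
#'
#' @param image Height x width x 3 array in `[0, 1]`.
#' @param radius Disc radius in pixels.
#' @param image_id Id recorded in the manifest.
#' @return List with `manifest` (tibble `disc_id`, `image_id`,
#'   `center_row`, `center_col`, `radius`; centers 0-based) and `discs`
#'   (list of disc rasters, same order).
#' @export
decompose_discs <- function(image, radius = 50L, image_id = "image") {
  h <- dim(image)[1]; w <- dim(image)[2]
  stride <- round(1.2 * radius)
  axis_centers <- function(d) {
    if (d - radius < radius) return(max(round(d / 2) - 1L, 0L))
    seq(radius, d - radius, by = stride) - 1L
  }
  rows <- axis_centers(h)
  cols <- axis_centers(w)
  grid <- expand.grid(center_row = rows, center_col = cols)
  n <- nrow(grid)
  discs <- vector("list", n)
  for (k in seq_len(n)) {
    discs[[k]] <- extract_disc(image, grid$center_row[k], grid$center_col[k],
                               radius)
  }
  manifest <- tibble::tibble(
    disc_id = sprintf("%s_disc_%03d", image_id, seq_len(n)),
    image_id = image_id,
    center_row = grid$center_row, center_col = grid$center_col,
    radius = as.integer(radius)
  )
  list(manifest = manifest, discs = discs)
}

extract_disc <- function(image, center_row0, center_col0, radius) {
  h <- dim(image)[1]; w <- dim(image)[2]
  side <- 2L * radius + 1L
  out <- array(0.5, dim = c(side, side, 3))
  rr <- (center_row0 - radius):(center_row0 + radius) + 1L  # 1-based source rows
  cc <- (center_col0 - radius):(center_col0 + radius) + 1L
  valid_r <- rr >= 1 & rr <= h
  valid_c <- cc >= 1 & cc <= w
  out[valid_r, valid_c, ] <- image[rr[valid_r], cc[valid_c], , drop = FALSE]
  dy <- matrix(rep(-radius:radius, times = side), side, side)
  dx <- matrix(rep(-radius:radius, each = side), side, side)
  outside <- dy^2 + dx^2 > radius^2
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[outside] <- 0.5
    out[, , ch] <- plane
  }
  out
}

#' Rate discs from 2AFC disc comparisons
#'
#' Thin delegation to [rate_comparisons()]: disc comparisons are scored
#' exactly like whole-image comparisons.
#'
#' @inheritParams rate_comparisons
#' @return A `rating_table` over disc ids.
#' @export
rate_discs <- function(records, cfg = rating_config(), items = NULL) {
  rate_comparisons(records, cfg, items)
}

#' Dense complexity map from disc ratings
#'
#' Interpolates the disc rating means, which live on the regular grid of
#' disc centers, to a full-resolution per-pixel surface. With at least 4
#' centers per axis the interpolation is bicubic (Catmull-Rom, which passes
#' through the node values); with fewer it falls back to bilinear with a
#' warning. Pixels beyond the outermost centers take the boundary value
#' (clamped extension).
#'
#' @param ratings A `rating_table` over disc ids (or tibble `item_id`,
#'   `mu`).
#' @param manifest Disc manifest from [decompose_discs()] (one image).
#' @param size Output `c(height, width)` in pixels.
#' @return A `height x width` numeric matrix; at each disc center the map
#'   equals that disc's rating mean.
#' @export
complexity_map <- function(ratings, manifest, size) {
  mu <- stats::setNames(ratings$mu, ratings$item_id)
  if (!all(manifest$disc_id %in% names(mu))) {
    stop("rating missing for disc(s): ",
         paste(utils::head(setdiff(manifest$disc_id, names(mu)), 5),
               collapse = ", "), call. = FALSE)
  }
  rows <- sort(unique(manifest$center_row))
  cols <- sort(unique(manifest$center_col))
  grid <- matrix(NA_real_, length(rows), length(cols))
  for (k in seq_len(nrow(manifest))) {
    grid[match(manifest$center_row[k], rows),
         match(manifest$center_col[k], cols)] <- mu[[manifest$disc_id[k]]]
  }
  if (anyNA(grid)) stop("manifest does not form a complete center grid", call. = FALSE)
  h <- size[1]; w <- size[2]
  gy <- grid_coord(seq_len(h) - 1L, rows)
  gx <- grid_coord(seq_len(w) - 1L, cols)
  if (length(rows) >= 4 && length(cols) >= 4) {
    tmp <- t(apply(grid, 1, cubic_interp_1d, g = gx))     # rows x w
    out <- apply(tmp, 2, cubic_interp_1d, g = gy)          # h x w
  } else {
    warning("fewer than 4 centers per axis; bilinear fallback")
    tmp <- t(apply(grid, 1, linear_interp_1d, g = gx))
    out <- apply(tmp, 2, linear_interp_1d, g = gy)
  }
  matrix(out, h, w)
}

# fractional grid coordinate of pixel positions relative to node positions,
# clamped at the ends (boundary extension)
grid_coord <- function(px, nodes) {
  if (length(nodes) == 1) return(rep(1, length(px)))
  i <- findInterval(px, nodes, rightmost.closed = FALSE)
  i <- pmin(pmax(i, 1L), length(nodes) - 1L)
  frac <- (px - nodes[i]) / (nodes[i + 1] - nodes[i])
  pmin(pmax(i + frac, 1), length(nodes))
}

# Catmull-Rom cubic interpolation of values v at fractional coords g
# (1-based); end segments use clamped (replicated) nodes
cubic_interp_1d <- function(v, g) {
  n <- length(v)
  i <- pmin(pmax(floor(g), 1L), n - 1L)
  t <- g - i
  idx <- function(k) pmin(pmax(i + k, 1L), n)
  p0 <- v[idx(-1L)]; p1 <- v[idx(0L)]; p2 <- v[idx(1L)]; p3 <- v[idx(2L)]
  0.5 * ((2 * p1) + (-p0 + p2) * t + (2 * p0 - 5 * p1 + 4 * p2 - p3) * t^2 +
           (-p0 + 3 * p1 - 3 * p2 + p3) * t^3)
}

linear_interp_1d <- function(v, g) {
  n <- length(v)
  if (n == 1) return(rep(v, length(g)))
  i <- pmin(pmax(floor(g), 1L), n - 1L)
  t <- g - i
  v[i] * (1 - t) + v[i + 1L] * t
}

#' Part-whole predictors from disc ratings
#'
#' Aggregates member-disc rating means per image into the two part-based
#' predictors of whole-image complexity: the mean disc rating and the
#' summed disc rating. Summed ratings confound disc count (hence image
#' size); `sum_comparable` is `TRUE` only when every image has the same
#' number of discs, mirroring the practice of restricting sums to
#' same-size images.
#'
#' @param ratings A `rating_table` over disc ids.
#' @param manifest Disc manifest (may span many images).
#' @return Tibble `image_id`, `n_discs`, `mean_rating`, `sum_rating`, with
#'   attribute `sum_comparable`.
#' @export
part_whole_predictors <- function(ratings, manifest) {
  mu <- stats::setNames(ratings$mu, ratings$item_id)
  missing_discs <- setdiff(manifest$disc_id, names(mu))
  if (length(missing_discs) > 0) {
    stop("rating missing for disc(s): ",
         paste(utils::head(missing_discs, 5), collapse = ", "), call. = FALSE)
  }
  df <- dplyr::summarise(
    dplyr::group_by(
      dplyr::mutate(manifest, mu = unname(mu[disc_id])), image_id),
    n_discs = dplyr::n(),
    mean_rating = mean(mu),
    sum_rating = sum(mu),
    .groups = "drop"
  )
  attr(df, "sum_comparable") <- length(unique(df$n_discs)) == 1
  if (!attr(df, "sum_comparable")) {
    warning("images have unequal disc counts; summed ratings are not ",
            "comparable across images")
  }
  df
}

#' Image-grouped train/validation split of discs
#'
#' Holds out a fraction of the source images (not of the discs): the
#' validation set contains all and only the discs of the held-out images,
#' so no image contributes discs to both sides.
#'
#' @param manifest Disc manifest with `disc_id` and `image_id`.
#' @param holdout_fraction Fraction of images held out (default 0.1).
#' @param seed Integer seed.
#' @return List with `train` and `validation` manifests and
#'   `holdout_images`.
#' @export
grouped_split <- function(manifest, holdout_fraction = 0.1, seed = 1L) {
  images <- unique(manifest$image_id)
  if (length(images) < 2) stop("grouped split requires >= 2 images", call. = FALSE)
  n_hold <- max(1L, round(holdout_fraction * length(images)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  hold <- sample(images, n_hold)
  list(
    train = manifest[!manifest$image_id %in% hold, , drop = FALSE],
    validation = manifest[manifest$image_id %in% hold, , drop = FALSE],
    holdout_images = hold
  )
}
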