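#' Sample a latent complexity world
#'
#' Draws true (latent) complexity scores for a set of items from a normal
#' distribution. The defaults mirror the empirical distribution of scores
#' observed for large natural-scene rating studies: mean 25.0, standard
#' deviation 5.5.
#'
#' @param n_items Number of items (> 0).
#' @param mean,sd Latent score distribution parameters (`sd > 0`).
#' @param seed Integer seed.
#' @return A `latent_world` list with `scores` (named numeric vector),
#'   `score_mean`, `score_sd`.
#' @export
sample_latent <- function(n_items, mean = 25, sd = 5.5, seed = 1L) {
  if (!is.numeric(n_items) || n_items <= 0) {
    stop("n_items must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(sd) || sd <= 0) stop("sd must be > 0", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n_items <- as.integer(n_items)
  scores <- stats::rnorm(n_items, mean, sd)
  names(scores) <- item_label(seq_len(n_items), n_items)
  structure(
    list(scores = scores, score_mean = mean, score_sd = sd),
    class = "latent_world"
  )
}

#' Observer model for simulated 2AFC choices
#'
#' A Thurstonian observer: each item evokes an internal value equal to its
#' latent score plus independent Gaussian noise of sd `noise_sd`, and the
#' item with the larger internal value is chosen, so
#' `P(choose A) = Phi((s_A - s_B) / (sqrt(2) * noise_sd))`. With probability
#' `lapse_rate` the observer instead answers uniformly at random.
#'
#' The default `noise_sd = 2` (score units, against a latent spread of 5.5)
#' produces imperfect but well-above-chance consistency, comparable to
#' human 2AFC complexity judgements; `lapse_rate` defaults to 0.
#'
#' @param noise_sd Perceptual noise sd in score units (>= 0).
#' @param lapse_rate Probability of a uniformly random choice, in `[0, 1]`.
#' @return An `observer_model` list.
#' @export
observer_model <- function(noise_sd = 2, lapse_rate = 0) {
  stopifnot(noise_sd >= 0, lapse_rate >= 0, lapse_rate <= 1)
  structure(list(noise_sd = noise_sd, lapse_rate = lapse_rate),
            class = "observer_model")
}

#' Simulate one 2AFC choice
#'
#' @param score_a,score_b Latent scores of the two presented items.
#' @param obs An [observer_model()].
#' @return `"a"` or `"b"`.
#' @export
simulate_choice <- function(score_a, score_b, obs = observer_model()) {
  n <- max(length(score_a), length(score_b))
  lapse <- stats::runif(n) < obs$lapse_rate
  if (obs$noise_sd == 0) {
    pick_a <- ifelse(score_a == score_b, stats::runif(n) < 0.5, score_a > score_b)
  } else {
    p_a <- stats::pnorm((score_a - score_b) / (sqrt(2) * obs$noise_sd))
    pick_a <- stats::runif(n) < p_a
  }
  pick_a[lapse] <- (stats::runif(sum(lapse)) < 0.5)
  ifelse(pick_a, "a", "b")
}

#' Fill a comparison design with simulated choices
#'
#' @param world A [sample_latent()] world containing every design item.
#' @param design A comparison tibble from [generate_design()].
#' @param obs An [observer_model()] (applied to all observers alike).
#' @param seed Integer seed.
#' @return The design tibble with `chosen` filled in.
#' @export
simulate_comparisons <- function(world, design, obs = observer_model(), seed = 1L) {
  missing_items <- setdiff(unique(c(design$item_a, design$item_b)),
                           names(world$scores))
  if (length(missing_items) > 0) {
    stop("design item(s) absent from world: ",
         paste(utils::head(missing_items, 10), collapse = ", "), call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  side <- simulate_choice(unname(world$scores[design$item_a]),
                          unname(world$scores[design$item_b]), obs)
  design$chosen <- ifelse(side == "a", design$item_a, design$item_b)
  design
}

# the 20 VOC object classes, used as the synthetic tag vocabulary
voc_classes <- c(
  "person", "bird", "cat", "cow", "dog", "horse", "sheep",
  "aeroplane", "bicycle", "boat", "bus", "car", "motorbike", "train",
  "bottle", "chair", "diningtable", "pottedplant", "sofa", "tvmonitor"
)

#' Specify a procedural synthetic image
#'
#' @param width,height Raster size in pixels (>= 8).
#' @param n_shapes Number of random shapes to draw (>= 0).
#' @param palette_size Number of distinct colours available (>= 1).
#' @param texture_noise_sd Background texture noise sd in `[0, 1]`.
#' @param seed Integer seed.
#' @return A `synthetic_image_spec` list.
#' @export
synthetic_image_spec <- function(width = 128, height = 128, n_shapes = 5,
                                 palette_size = 8, texture_noise_sd = 0.05,
                                 seed = 1L) {
  stopifnot(width >= 8, height >= 8, n_shapes >= 0, palette_size >= 1,
            texture_noise_sd >= 0, texture_noise_sd <= 1)
  structure(
    list(width = as.integer(width), height = as.integer(height),
         n_shapes = as.integer(n_shapes), palette_size = as.integer(palette_size),
         texture_noise_sd = texture_noise_sd, seed = as.integer(seed)),
    class = "synthetic_image_spec"
  )
}

#' Generate a procedural tagged image
#'
#' Draws `n_shapes` random filled ellipses and polygons, coloured from a
#' random palette of `palette_size` colours, over a textured mid-gray
#' background (Gaussian noise of sd `texture_noise_sd`, clipped to `[0, 1]`).
#' Each shape gets a bounding-box tag with a class label drawn from the
#' 20-name VOC vocabulary. Complexity drivers (shape count, palette size,
#' texture level) are thus known exactly, which is what makes the image end
#' of the pipeline testable without real photographs.
#'
#' @param spec A [synthetic_image_spec()].
#' @return A list with `image` (height x width x 3 array in `[0, 1]`) and
#'   `tags` (tibble `image_id`, `class_name`, `xmin`, `ymin`, `xmax`,
#'   `ymax`; 0-based, half-open pixel coordinates, x = column, y = row).
#' @export
generate_image <- function(spec) {
  stopifnot(inherits(spec, "synthetic_image_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  h <- spec$height
  w <- spec$width

  img <- array(0.5, dim = c(h, w, 3))
  if (spec$texture_noise_sd > 0) {
    noise <- matrix(stats::rnorm(h * w, 0, spec$texture_noise_sd), h, w)
    for (ch in 1:3) img[, , ch] <- img[, , ch] + noise
  }

  # random palette; always includes chromatic colours unless palette greys
  palette <- matrix(stats::runif(spec$palette_size * 3), ncol = 3)

  tags <- vector("list", spec$n_shapes)
  xs <- matrix(rep(seq_len(w), each = h), h, w)    # column index
  ys <- matrix(rep(seq_len(h), times = w), h, w)   # row index
  for (s in seq_len(spec$n_shapes)) {
    col <- palette[sample.int(spec$palette_size, 1), ]
    cx <- stats::runif(1, 0.1 * w, 0.9 * w)
    cy <- stats::runif(1, 0.1 * h, 0.9 * h)
    rx <- stats::runif(1, 0.04, 0.2) * w
    ry <- stats::runif(1, 0.04, 0.2) * h
    kind <- sample(c("ellipse", "rect", "triangle"), 1)
    mask <- switch(kind,
      ellipse = ((xs - cx) / rx)^2 + ((ys - cy) / ry)^2 <= 1,
      rect = abs(xs - cx) <= rx & abs(ys - cy) <= ry,
      triangle = {
        # upright triangle inscribed in the ellipse box
        inside <- abs(xs - cx) <= rx * (1 - (cy - ys) / (2 * ry)) &
          ys >= cy - ry & ys <= cy + ry
        inside & abs(xs - cx) <= rx
      }
    )
    mask <- mask & xs >= 1 & xs <= w & ys >= 1 & ys <= h
    if (!any(mask)) {
      # degenerate off-raster shape: tag a single clamped pixel
      px <- min(max(round(cx), 1), w)
      py <- min(max(round(cy), 1), h)
      mask[py, px] <- TRUE
    }
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[mask] <- col[ch]
      img[, , ch] <- plane
    }
    cols_hit <- range(xs[mask])
    rows_hit <- range(ys[mask])
    tags[[s]] <- tibble::tibble(
      class_name = sample(voc_classes, 1),
      xmin = cols_hit[1] - 1L, ymin = rows_hit[1] - 1L,
      xmax = cols_hit[2], ymax = rows_hit[2]
    )
  }
  img <- pmin(pmax(img, 0), 1)
  tags <- if (spec$n_shapes > 0) dplyr::bind_rows(tags) else
    tibble::tibble(class_name = character(0), xmin = integer(0),
                   ymin = integer(0), xmax = integer(0), ymax = integer(0))
  list(image = img, tags = tags)
}

#' Generate a directory of synthetic tagged images
#'
#' Convenience wrapper writing PNG images plus a JSON tag file, e.g. to feed
#' [extract_features()] and the object-tag predictors.
#'
#' @param n_images Number of images.
#' @param dir Output directory (created if needed).
#' @param width,height Raster size.
#' @param n_shapes_range Inclusive range the per-image shape count is drawn
#'   from uniformly.
#' @param palette_range Inclusive range for per-image palette size.
#' @param texture_range Range for per-image texture noise sd.
#' @param seed Integer seed.
#' @return Tibble with `image_id`, `path`, `n_shapes`, `palette_size`,
#'   `texture_noise_sd`; tags are written to `file.path(dir, "tags.json")`.
#' @export
generate_image_set <- function(n_images, dir, width = 96, height = 96,
                               n_shapes_range = c(0, 20),
                               palette_range = c(2, 12),
                               texture_range = c(0.01, 0.15), seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n_shapes <- sample(n_shapes_range[1]:n_shapes_range[2], n_images, replace = TRUE)
  palette <- sample(palette_range[1]:palette_range[2], n_images, replace = TRUE)
  texture <- stats::runif(n_images, texture_range[1], texture_range[2])
  seeds <- sample.int(.Machine$integer.max, n_images)
  ids <- sprintf("img_%04d", seq_len(n_images))
  paths <- file.path(dir, paste0(ids, ".png"))
  all_tags <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    gen <- generate_image(synthetic_image_spec(
      width = width, height = height, n_shapes = n_shapes[i],
      palette_size = palette[i], texture_noise_sd = texture[i],
      seed = seeds[i]
    ))
    write_image(gen$image, paths[i])
    if (nrow(gen$tags) > 0) {
      all_tags[[i]] <- dplyr::mutate(gen$tags, image_id = ids[i],
                                     .before = 1)
    }
  }
  tags <- dplyr::bind_rows(all_tags)
  jsonlite::write_json(tags, file.path(dir, "tags.json"), dataframe = "rows")
  tibble::tibble(image_id = ids, path = paths, n_shapes = n_shapes,
                 palette_size = palette, texture_noise_sd = texture)
}
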