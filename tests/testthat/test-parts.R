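test_that("a 375x500 frame decomposes into the expected 5x7 disc grid", {
  img <- array(0.5, dim = c(375, 500, 3))
  dd <- decompose_discs(img, radius = 50, image_id = "frame")
  expect_equal(nrow(dd$manifest), 35)
  expect_equal(length(unique(dd$manifest$center_row)), 5)
  expect_equal(length(unique(dd$manifest$center_col)), 7)
  expect_true(nrow(dd$manifest) >= 30 && nrow(dd$manifest) <= 50)
  # stride < diameter: neighbouring discs overlap
  expect_lt(diff(sort(unique(dd$manifest$center_row)))[1], 100)
})

test_that("an image no larger than one disc yields a single centered disc", {
  img <- array(0.2, dim = c(100, 100, 3))
  dd <- decompose_discs(img, radius = 50)
  expect_equal(nrow(dd$manifest), 1)
  expect_equal(dd$manifest$center_row, 49)
  expect_equal(dd$manifest$center_col, 49)
})

test_that("disc rasters are square crops masked to mid-gray outside", {
  img <- array(1, dim = c(375, 500, 3))
  dd <- decompose_discs(img, radius = 50)
  # a fully interior disc: every in-circle pixel kept, the rest mid-gray
  k <- which(dd$manifest$center_row >= 50 & dd$manifest$center_row <= 324 &
               dd$manifest$center_col >= 50 & dd$manifest$center_col <= 449)[1]
  disc <- dd$discs[[k]]
  expect_equal(dim(disc), c(101, 101, 3))
  expect_equal(disc[51, 51, 1], 1)      # center belongs to the disc
  expect_equal(disc[1, 1, 1], 0.5)      # corner is outside the radius
  dy <- matrix(rep(-50:50, times = 101), 101, 101)
  dx <- matrix(rep(-50:50, each = 101), 101, 101)
  outside <- dy^2 + dx^2 > 50^2
  expect_true(all(disc[, , 1][outside] == 0.5))
  expect_true(all(disc[, , 1][!outside] == 1))
  # a border disc keeps its off-image part mid-gray
  border <- dd$discs[[1]]
  expect_true(all(border[1, , 1] == 0.5))
})

test_that("typical photo frames break into 30 to 50 discs", {
  for (short_side in seq(350, 500, by = 25)) {
    img <- array(0.5, dim = c(short_side, 500, 3))
    n <- nrow(decompose_discs(img, radius = 50)$manifest)
    expect_true(n >= 30 && n <= 50)
  }
})

test_that("disc rating recovers synthetic disc complexities", {
  img <- array(0.5, dim = c(375, 500, 3))
  manifest <- decompose_discs(img, radius = 50, image_id = "im1")$manifest
  world <- sample_latent(nrow(manifest), seed = 5)
  names(world$scores) <- manifest$disc_id
  design <- generate_design(design_spec(nrow(manifest), 25 * nrow(manifest) / 2,
                                        5, seed = 6))
  relabel <- stats::setNames(manifest$disc_id,
                             complexr:::item_label(seq_len(nrow(manifest)),
                                                   nrow(manifest)))
  design$item_a <- unname(relabel[design$item_a])
  design$item_b <- unname(relabel[design$item_b])
  judged <- simulate_comparisons(world, design, observer_model(2, 0), seed = 7)
  tab <- rate_discs(judged)
  rho <- cor(unname(world$scores[tab$item_id]), tab$mu, method = "spearman")
  expect_gte(rho, 0.9)
  # empty comparisons keep priors
  empty <- judged[0, ]
  t0 <- rate_discs(empty, items = manifest$disc_id)
  expect_equal(unique(t0$mu), 25)
})

test_that("complexity maps interpolate through the disc ratings", {
  img <- array(0.5, dim = c(375, 500, 3))
  manifest <- decompose_discs(img, radius = 50, image_id = "im1")$manifest

  # constant ratings give a constant, zero-gradient map
  flat <- rating_table(manifest$disc_id, 12.5)
  map <- complexity_map(flat, manifest, c(375, 500))
  expect_equal(dim(map), c(375, 500))
  expect_equal(max(abs(map - 12.5)), 0, tolerance = 1e-9)

  # the map passes through every node value
  set.seed(3)
  vals <- rating_table(manifest$disc_id, rnorm(nrow(manifest), 25, 5))
  map2 <- complexity_map(vals, manifest, c(375, 500))
  at_centers <- map2[cbind(manifest$center_row + 1, manifest$center_col + 1)]
  expect_equal(at_centers, vals$mu[match(manifest$disc_id, vals$item_id)],
               tolerance = 1e-9)
  expect_true(all(is.finite(map2)))

  # a left-to-right ramp of ratings yields a column-monotone map
  ramp_mu <- 10 + manifest$center_col / 50
  ramp <- rating_table(manifest$disc_id, ramp_mu)
  map3 <- complexity_map(ramp, manifest, c(375, 500))
  expect_true(all(apply(map3, 1, function(row) all(diff(row) >= -1e-9))))

  # fewer than 4 centers per axis: bilinear fallback with warning
  small <- decompose_discs(array(0.5, dim = c(150, 150, 3)), 50, "sm")$manifest
  flat_small <- rating_table(small$disc_id, 5)
  expect_warning(m <- complexity_map(flat_small, small, c(150, 150)),
                 "bilinear")
  expect_equal(max(abs(m - 5)), 0, tolerance = 1e-9)

  # missing disc rating errors
  expect_error(complexity_map(rating_table("wrong_id", 1), small, c(150, 150)),
               "missing")
})

test_that("part-whole aggregation follows the mean/sum definitions", {
  manifest <- tibble::tibble(
    disc_id = c("d1", "d2", "d3", "e1"),
    image_id = c("A", "A", "A", "B"),
    center_row = 0, center_col = 0, radius = 50L
  )
  ratings <- rating_table(c("d1", "d2", "d3", "e1"), c(10, 20, 30, 40))
  expect_warning(pw <- part_whole_predictors(ratings, manifest), "unequal")
  expect_equal(pw$mean_rating[pw$image_id == "A"], 20)
  expect_equal(pw$sum_rating[pw$image_id == "A"], 60)
  # single-disc image: mean equals sum equals the disc rating
  expect_equal(pw$mean_rating[pw$image_id == "B"], 40)
  expect_equal(pw$sum_rating[pw$image_id == "B"], 40)
  expect_false(attr(pw, "sum_comparable"))

  # duplicating every disc leaves the mean unchanged and doubles the sum
  m2 <- dplyr::bind_rows(manifest, dplyr::mutate(manifest,
                                                 disc_id = paste0(disc_id, "_b")))
  r2 <- rating_table(m2$disc_id, rep(c(10, 20, 30, 40), 2))
  expect_warning(pw2 <- part_whole_predictors(r2, m2), "unequal")
  expect_equal(pw2$mean_rating, pw$mean_rating)
  expect_equal(pw2$sum_rating, 2 * pw$sum_rating)

  expect_error(part_whole_predictors(rating_table("d1", 1), manifest),
               "missing")
})

test_that("mean disc ratings predict a part-driven whole-image score", {
  set.seed(13)
  n_img <- 24; discs_per <- 12
  manifest <- tibble::tibble(
    disc_id = sprintf("d%03d", seq_len(n_img * discs_per)),
    image_id = rep(sprintf("im%02d", seq_len(n_img)), each = discs_per),
    center_row = 0, center_col = 0, radius = 50L
  )
  # discs of one image share an image-level complexity component, plus a
  # local deviation; the whole-image latent is the mean of its parts
  base <- sample_latent(n_img, seed = 14)
  world <- sample_latent(nrow(manifest), seed = 14)
  world$scores <- rep(unname(base$scores), each = discs_per) +
    rnorm(nrow(manifest), 0, 2.75)
  names(world$scores) <- manifest$disc_id
  design <- generate_design(design_spec(nrow(manifest),
                                        25 * nrow(manifest) / 2, 5, seed = 15))
  relabel <- stats::setNames(manifest$disc_id,
                             complexr:::item_label(seq_len(nrow(manifest)),
                                                   nrow(manifest)))
  design$item_a <- unname(relabel[design$item_a])
  design$item_b <- unname(relabel[design$item_b])
  judged <- simulate_comparisons(world, design, observer_model(2, 0), seed = 16)
  pw <- part_whole_predictors(rate_discs(judged), manifest)
  latent_mean <- tapply(world$scores, manifest$image_id, mean)
  whole <- latent_mean + rnorm(n_img, 0, 0.5 * 5.5)
  r <- cor(pw$mean_rating, whole[pw$image_id])
  expect_gte(r, 0.7)
})

test_that("grouped splits hold out whole images", {
  manifest <- tibble::tibble(
    disc_id = sprintf("d%04d", 1:1000),
    image_id = rep(sprintf("im%03d", 1:100), each = 10)
  )
  sp <- grouped_split(manifest, 0.1, seed = 2)
  expect_equal(length(sp$holdout_images), 10)
  expect_equal(length(intersect(sp$train$image_id, sp$validation$image_id)), 0)
  expect_setequal(unique(sp$validation$image_id), sp$holdout_images)
  expect_equal(nrow(sp$train) + nrow(sp$validation), 1000)
  expect_identical(grouped_split(manifest, 0.1, seed = 2)$holdout_images,
                   sp$holdout_images)

  ten <- manifest[manifest$image_id %in% sprintf("im%03d", 1:10), ]
  expect_equal(length(grouped_split(ten, 0.1, seed = 3)$holdout_images), 1)
  expect_error(grouped_split(manifest[manifest$image_id == "im001", ]),
               ">= 2 images")
})
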