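test_that("a constant image zeroes every variability feature", {
  img <- constant_image(0.4)
  expect_warning(g <- glcm_features(img), "correlation")
  expect_equal(g$glcm_contrast, 0)
  expect_equal(g$glcm_energy, 1)
  expect_equal(g$glcm_homogeneity, 1)
  expect_equal(g$glcm_correlation, 0)
  expect_false(g$correlation_defined)

  cf <- colour_features(img)
  expect_equal(cf$colourfulness, 0, tolerance = 1e-6)
  expect_equal(cf$colour_count, 1)

  ev <- entropy_variance_features(img)
  for (nm in grep("entropy", names(ev), value = TRUE)) {
    expect_equal(ev[[nm]], 0)
  }
  for (nm in grep("variance", names(ev), value = TRUE)) {
    expect_equal(ev[[nm]], 0)
  }
  expect_equal(ev$pixel_count, 32 * 32)

  cl <- clutter_features(img)
  expect_equal(cl$colour_clutter, 0, tolerance = 1e-6)
  expect_equal(cl$contrast_clutter_mean, 0, tolerance = 1e-8)
  expect_equal(cl$contrast_clutter_var, 0, tolerance = 1e-8)
  expect_equal(cl$subband_entropy, 0)

  st <- structure_features(img)
  expect_equal(st$edge_density, 0)
  expect_equal(st$frequency_factor, 0)
  expect_gt(st$jpeg_ratio, 1)

  ct <- count_features(img)
  expect_equal(ct$sift_count, 0)
  expect_equal(ct$surf_count, 0)
  expect_equal(ct$meanshift_region_count, 1)
  expect_lte(ct$mser_count, 1)
})

test_that("checkerboard co-occurrence matches the hand-built matrix", {
  # 2-level quantization of a 1-px checkerboard: only (0,1) and (1,0)
  # co-occurrences, equiprobable
  img <- checkerboard_image()
  g <- glcm_features(img, feature_config(glcm_levels = 2))
  expect_equal(g$glcm_contrast, 1)
  expect_equal(g$glcm_energy, 0.5)
  expect_equal(g$glcm_homogeneity, 0.5)
  expect_equal(g$glcm_correlation, -1)
  expect_lte(g$glcm_energy, 1)
})

test_that("entropy and mean luminance follow the histogram definition", {
  # two equiprobable gray levels: exactly 1 bit everywhere
  img <- checkerboard_image(lo = 0.25, hi = 0.75)
  ev <- entropy_variance_features(img)
  expect_equal(ev$entropy_whole, 1)
  expect_equal(ev$entropy_R, 1)
  expect_equal(ev$mean_luminance, 0.5)
})

test_that("colour features follow their CIELAB definitions", {
  # uniform single-hue image: sd terms vanish, colourfulness = 0.3*|mean ab|
  img <- array(0, dim = c(16, 16, 3))
  img[, , 1] <- 0.8; img[, , 2] <- 0.2; img[, , 3] <- 0.2
  lab <- grDevices::convertColor(matrix(c(0.8, 0.2, 0.2), 1), "sRGB", "Lab",
                                 from.ref.white = "D65", to.ref.white = "D65")
  cf <- colour_features(img)
  expect_equal(cf$colourfulness, 0.3 * sqrt(lab[2]^2 + lab[3]^2),
               tolerance = 1e-6)
  expect_equal(cf$colour_count, 1)

  # two well-separated saturated colours occupy two bins
  img2 <- img
  img2[, 9:16, 1] <- 0.1; img2[, 9:16, 2] <- 0.1; img2[, 9:16, 3] <- 0.9
  expect_equal(colour_features(img2)$colour_count, 2)

  # grayscale image: zero chroma everywhere
  gray <- array(rep(matrix(seq(0, 1, length.out = 16), 16, 16), 3),
                dim = c(16, 16, 3))
  expect_equal(colour_features(gray)$colourfulness, 0, tolerance = 1e-6)
  expect_warning(cl <- clutter_features(gray), "clutter scales")
  expect_equal(cl$colour_clutter, 0, tolerance = 1e-6)
})

test_that("structural features order images by compressibility and bandwidth", {
  const <- constant_image(0.5, 64, 64)
  set.seed(2)
  noise <- array(runif(64 * 64 * 3), dim = c(64, 64, 3))
  expect_gt(structure_features(const)$jpeg_ratio,
            structure_features(noise)$jpeg_ratio)
  # white noise is broadband: frequency factor saturates
  for (s in 1:10) {
    set.seed(s)
    ff <- complexr:::frequency_factor(matrix(runif(64 * 64), 64, 64))
    expect_gte(ff, 0.9)
  }
})

test_that("feature extraction is deterministic and container-invariant", {
  gen <- generate_image(synthetic_image_spec(48, 48, n_shapes = 5, seed = 4))
  f1 <- image_features(gen$image)
  f2 <- image_features(gen$image)
  expect_identical(f1, f2)

  # identical pixels through PNG and TIFF containers give identical features
  dir <- withr::local_tempdir()
  png_path <- file.path(dir, "img.png")
  tif_path <- file.path(dir, "img.tif")
  write_image(gen$image, png_path)
  quantized <- png::readPNG(png_path)
  tiff::writeTIFF(quantized, tif_path, bits.per.sample = 8)
  tif_pixels <- tiff::readTIFF(tif_path)
  expect_identical(image_features(quantized), image_features(tif_pixels))
})

test_that("synthetic complexity drivers move their features upward", {
  seeds <- 1:10
  mean_ed <- sapply(c(0, 10, 40), function(ns) {
    mean(sapply(seeds, function(s) {
      gen <- generate_image(synthetic_image_spec(64, 64, n_shapes = ns,
                                                 palette_size = 8,
                                                 texture_noise_sd = 0.02,
                                                 seed = s))
      structure_features(gen$image)$edge_density
    }))
  })
  expect_true(all(diff(mean_ed) > 0))

  mean_cc <- sapply(c(2, 16), function(p) {
    mean(sapply(seeds, function(s) {
      gen <- generate_image(synthetic_image_spec(64, 64, n_shapes = 12,
                                                 palette_size = p,
                                                 texture_noise_sd = 0.02,
                                                 seed = s))
      colour_features(gen$image)$colour_count
    }))
  })
  expect_gt(mean_cc[2], mean_cc[1])

  counts <- sapply(c(1, 10), function(ns) {
    colMeans(t(sapply(seeds, function(s) {
      gen <- generate_image(synthetic_image_spec(64, 64, n_shapes = ns,
                                                 palette_size = 8,
                                                 texture_noise_sd = 0.02,
                                                 seed = s))
      ct <- count_features(gen$image)
      c(ct$mser_count, ct$meanshift_region_count)
    })))
  })
  expect_gt(counts[1, 2], counts[1, 1])  # stable regions grow with shapes
  expect_gt(counts[2, 2], counts[2, 1])  # mean-shift regions too

  mean_se <- sapply(c(0.03, 0.06), function(tx) {
    mean(sapply(seeds, function(s) {
      gen <- generate_image(synthetic_image_spec(64, 64, n_shapes = 5,
                                                 palette_size = 8,
                                                 texture_noise_sd = tx,
                                                 seed = s))
      clutter_features(gen$image)$subband_entropy
    }))
  })
  expect_gt(mean_se[2], mean_se[1])  # doubling texture noise adds entropy
})

test_that("directory extraction merges external columns strictly", {
  dir <- withr::local_tempdir()
  info <- generate_image_set(3, dir, width = 32, height = 32, seed = 6)
  feats <- extract_features(dir)
  expect_equal(nrow(feats), 3)
  numeric_cols <- vapply(feats, is.numeric, logical(1))
  expect_true(all(vapply(feats[numeric_cols], function(c) all(is.finite(c)),
                         logical(1))))

  ext <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(image_id = info$image_id[1:2],
                                  object_count = c(4, 7)), ext)
  merged <- extract_features(dir, external_csv = ext)
  expect_true("object_count" %in% names(merged))
  # image without an external row gets an explicit NA, not a zero
  expect_true(is.na(merged$object_count[merged$image_id == info$image_id[3]]))

  dup <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(image_id = rep(info$image_id[1], 2),
                                  object_count = c(1, 2)), dup)
  expect_error(extract_features(dir, external_csv = dup), "duplicate")
})

test_that("count backends validate their configuration", {
  img <- constant_image()
  expect_error(count_features(img, backend = "magic"), "backend")
  ext <- tibble::tibble(image_id = "a", sift_count = 1, surf_count = 2,
                        mser_count = 3, meanshift_region_count = 4)
  out <- count_features(img, backend = "external", external_counts = ext,
                        image_id = "a")
  expect_equal(out$surf_count, 2L)
  expect_error(count_features(img, backend = "external",
                              external_counts = ext, image_id = "zzz"),
               "zzz")
})
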