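# shared fixture builders, all generated in code

constant_image <- function(value = 0.4, h = 32, w = 32) {
  array(value, dim = c(h, w, 3))
}

# 1-px checkerboard of two gray values
checkerboard_image <- function(h = 16, w = 16, lo = 0, hi = 1) {
  m <- (outer(seq_len(h), seq_len(w), "+") %% 2) * (hi - lo) + lo
  array(rep(m, 3), dim = c(h, w, 3))
}

# rate a simulated world end to end, returning pieces for inspection
simulate_and_rate <- function(n_items, n_comparisons, noise_sd = 2,
                              lapse_rate = 0, seed = 1,
                              cfg = rating_config(shuffle_seed = seed)) {
  world <- sample_latent(n_items, seed = seed)
  design <- generate_design(design_spec(n_items, n_comparisons, 5,
                                        seed = seed + 1000))
  judged <- simulate_comparisons(world, design,
                                 observer_model(noise_sd, lapse_rate),
                                 seed = seed + 2000)
  table <- rate_comparisons(judged, cfg)
  list(world = world, judged = judged, table = table)
}

# random tag tables with known central/background structure
random_tags <- function(n_images, seed = 1, max_tags = 5,
                        classes = c("cat", "dog", "car", "chair", "bird")) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n_images)) {
    k <- sample.int(max_tags, 1)
    sz <- sample(5:60, k, replace = TRUE)
    x0 <- sample(0:40, k, replace = TRUE)
    y0 <- sample(0:40, k, replace = TRUE)
    rows[[i]] <- tibble::tibble(
      image_id = sprintf("im%03d", i),
      class_name = sample(classes, k, replace = TRUE),
      xmin = x0, ymin = y0, xmax = x0 + sz, ymax = y0 + sz
    )
  }
  dplyr::bind_rows(rows)
}
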