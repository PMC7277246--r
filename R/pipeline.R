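#' Configure an end-to-end synthetic replication run
#'
#' Bundles the sizes, noise levels and stage configurations of a full
#' synthetic run: latent scores -> balanced design -> simulated 2AFC
#' choices -> rating -> feature extraction and model fit -> disc
#' decomposition, disc rating, complexity map and part-whole predictors.
#'
#' @param n_items,n_comparisons,n_observers Whole-image rating scale.
#' @param score_mean,score_sd Latent score distribution.
#' @param noise_sd,lapse_rate Observer model.
#' @param n_images Procedural images for the feature stage.
#' @param image_size `c(height, width)` of the procedural images.
#' @param n_part_images Images for the disc stage.
#' @param part_image_size `c(height, width)` for the disc stage (the
#'   default 375 x 500 yields 35 discs per image).
#' @param disc_radius Disc radius in pixels.
#' @param comparisons_per_disc Simulated comparisons per disc.
#' @param rating A [rating_config()].
#' @param features A [feature_config()].
#' @param model A [model_config()].
#' @param seed Master seed; every stage seed is derived from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_items = 200L, n_comparisons = 4000L,
                            n_observers = 10L, score_mean = 25,
                            score_sd = 5.5, noise_sd = 2, lapse_rate = 0,
                            n_images = 24L, image_size = c(96L, 96L),
                            n_part_images = 10L,
                            part_image_size = c(375L, 500L),
                            disc_radius = 50L, comparisons_per_disc = 25L,
                            rating = rating_config(),
                            features = feature_config(),
                            model = model_config("ridge", "kfold10"),
                            seed = 1L) {
  structure(
    list(n_items = as.integer(n_items),
         n_comparisons = as.integer(n_comparisons),
         n_observers = as.integer(n_observers),
         score_mean = score_mean, score_sd = score_sd,
         noise_sd = noise_sd, lapse_rate = lapse_rate,
         n_images = as.integer(n_images), image_size = as.integer(image_size),
         n_part_images = as.integer(n_part_images),
         part_image_size = as.integer(part_image_size),
         disc_radius = as.integer(disc_radius),
         comparisons_per_disc = as.integer(comparisons_per_disc),
         rating = rating, features = features, model = model,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

derive_seed <- function(seed, k) (seed * 48271 + k * 1299721) %% 2147483647

#' Run the full synthetic replication
#'
#' Executes every stage on synthetic data with known ground truth and
#' returns (optionally writes) a JSON-serializable report of summary
#' statistics: design balance, rating distribution and convergence,
#' consistency, latent-score recovery, feature-model validation
#' correlations, and disc-level part-whole statistics. The report carries
#' the hash of the exact configuration that produced it; re-running with
#' the same config reproduces the report.
#'
#' @param config A [pipeline_config()].
#' @param out_json Optional path to write the report to.
#' @param work_dir Directory for intermediate images (a temporary
#'   directory by default).
#' @return The report, invisibly a named list.
#' @export
run_synthetic_replication <- function(config = pipeline_config(),
                                      out_json = NULL,
                                      work_dir = tempfile("complexr_")) {
  stopifnot(inherits(config, "pipeline_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  report <- list(config_hash = rlang::hash(config),
                 config = config[setdiff(names(config),
                                         c("rating", "features", "model"))])

  # --- stage 1: design -------------------------------------------------
  design <- stage("design", {
    generate_design(design_spec(config$n_items, config$n_comparisons,
                                config$n_observers,
                                seed = derive_seed(config$seed, 1)))
  })
  participation <- table(c(design$item_a, design$item_b))
  report$design <- list(
    n_items = config$n_items, n_comparisons = config$n_comparisons,
    mean_participation = mean(participation),
    participation_spread = max(participation) - min(participation)
  )

  # --- stage 2: simulate + rate ---------------------------------------
  world <- stage("simulate", {
    sample_latent(config$n_items, config$score_mean, config$score_sd,
                  seed = derive_seed(config$seed, 2))
  })
  judged <- stage("simulate", {
    simulate_comparisons(world, design,
                         observer_model(config$noise_sd, config$lapse_rate),
                         seed = derive_seed(config$seed, 3))
  })
  ratings <- stage("rate", rate_comparisons(judged, config$rating))
  rec <- correlation_metrics(unname(world$scores[ratings$item_id]), ratings$mu)
  report$ratings <- list(
    mean_mu = mean(ratings$mu), sd_mu = stats::sd(ratings$mu),
    consistency = consistency_score(judged, ratings),
    recovery_pearson_r = rec$pearson_r,
    recovery_spearman_rho = rec$spearman_rho,
    epoch_trace = attr(ratings, "epoch_trace")
  )

  # --- stage 3: features + fit ----------------------------------------
  img_dir <- file.path(work_dir, "images")
  imgset <- stage("features", {
    generate_image_set(config$n_images, img_dir,
                       width = config$image_size[2],
                       height = config$image_size[1],
                       seed = derive_seed(config$seed, 4))
  })
  feats <- stage("features", extract_features(img_dir, config$features))
  # image-level complexity target driven by the known generators
  set.seed(derive_seed(config$seed, 5))
  target <- config$score_mean +
    config$score_sd * scale(imgset$n_shapes + 0.5 * imgset$palette_size +
                              10 * imgset$texture_noise_sd)[, 1] +
    stats::rnorm(config$n_images, 0, 1)
  img_ratings <- tibble::tibble(image_id = imgset$image_id, rating = target)
  fit <- stage("fit", fit_feature_models(feats, img_ratings, config$model))
  report$features <- list(
    n_images = config$n_images,
    model_kind = config$model$model_kind, cv_scheme = config$model$cv_scheme,
    pearson_r = fit$pearson_r, spearman_rho = fit$spearman_rho,
    edge_density_vs_shapes = stats::cor(
      feats$edge_density[match(imgset$image_id, feats$image_id)],
      imgset$n_shapes, method = "spearman")
  )

  # --- stage 4: discs, map, part-whole --------------------------------
  parts <- stage("discs", {
    run_parts_stage(config)
  })
  report$parts <- parts

  if (!is.null(out_json)) {
    dir.create(dirname(out_json), showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, out_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(report)
}

# disc-level synthetic study: known disc latents per image, whole-image
# latent = mean of part latents + noise, simulated disc comparisons
run_parts_stage <- function(config) {
  h <- config$part_image_size[1]; w <- config$part_image_size[2]
  template <- decompose_discs(array(0.5, dim = c(h, w, 3)),
                              radius = config$disc_radius, image_id = "tmpl")
  n_discs_per_image <- nrow(template$manifest)
  manifests <- lapply(seq_len(config$n_part_images), function(i) {
    m <- template$manifest
    m$image_id <- sprintf("pimg_%03d", i)
    m$disc_id <- sprintf("%s_disc_%03d", m$image_id, seq_len(nrow(m)))
    m
  })
  manifest <- dplyr::bind_rows(manifests)

  # discs of one image share an image-level complexity component plus a
  # local deviation (half the image-level spread)
  base <- sample_latent(config$n_part_images, config$score_mean,
                        config$score_sd, seed = derive_seed(config$seed, 6))
  set.seed(derive_seed(config$seed, 11))
  disc_world <- structure(
    list(scores = stats::setNames(
      rep(unname(base$scores), each = n_discs_per_image) +
        stats::rnorm(nrow(manifest), 0, config$score_sd / 2),
      manifest$disc_id),
      score_mean = config$score_mean, score_sd = config$score_sd),
    class = "latent_world")
  n_cmp <- config$comparisons_per_disc * nrow(manifest) / 2
  design <- generate_design(design_spec(nrow(manifest), n_cmp,
                                        config$n_observers,
                                        seed = derive_seed(config$seed, 7)))
  relabel <- stats::setNames(manifest$disc_id,
                             item_label(seq_len(nrow(manifest)), nrow(manifest)))
  design$item_a <- unname(relabel[design$item_a])
  design$item_b <- unname(relabel[design$item_b])
  judged <- simulate_comparisons(disc_world, design,
                                 observer_model(config$noise_sd,
                                                config$lapse_rate),
                                 seed = derive_seed(config$seed, 8))
  disc_ratings <- rate_discs(judged, config$rating)
  rec <- correlation_metrics(unname(disc_world$scores[disc_ratings$item_id]),
                             disc_ratings$mu)

  pw <- part_whole_predictors(disc_ratings, manifest)
  set.seed(derive_seed(config$seed, 9))
  latent_means <- vapply(split(manifest$disc_id, manifest$image_id),
                         function(ids) mean(disc_world$scores[ids]), numeric(1))
  whole <- latent_means + stats::rnorm(length(latent_means),
                                       0, 0.5 * config$score_sd)
  ord <- match(pw$image_id, names(whole))
  pw_r <- correlation_metrics(pw$mean_rating, whole[ord])
  sum_r <- correlation_metrics(pw$sum_rating, whole[ord])

  m1 <- manifests[[1]]
  cmap <- complexity_map(disc_ratings, m1, c(h, w))
  centers_ok <- max(abs(cmap[cbind(m1$center_row + 1, m1$center_col + 1)] -
                          disc_ratings$mu[match(m1$disc_id,
                                                disc_ratings$item_id)]))

  split_res <- grouped_split(manifest, 0.1, seed = derive_seed(config$seed, 10))

  list(
    n_part_images = config$n_part_images,
    n_discs_per_image = n_discs_per_image,
    n_discs = nrow(manifest),
    disc_recovery_spearman = rec$spearman_rho,
    part_whole_mean_r = pw_r$pearson_r,
    part_whole_sum_r = sum_r$pearson_r,
    map_center_max_abs_err = centers_ok,
    grouped_split_leak = length(intersect(split_res$train$image_id,
                                          split_res$validation$image_id))
  )
}
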