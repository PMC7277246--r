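#' Pearson and Spearman correlation between predictions and ratings
#'
#' @param x,y Equal-length finite numeric vectors (length >= 3).
#' @return List with `pearson_r` and `spearman_rho`.
#' @export
correlation_metrics <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("correlation requires equal-length vectors of length >= 3", call. = FALSE)
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("correlation inputs must be finite", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero-variance input", call. = FALSE)
  }
  list(pearson_r = stats::cor(x, y),
       spearman_rho = stats::cor(x, y, method = "spearman"))
}

#' Configure a feature-based complexity predictor
#'
#' @param model_kind One of `"linear"`, `"lasso"`, `"ridge"`, `"svr"`,
#'   `"mlp"`.
#' @param cv_scheme `"kfold10"`, `"loo"`, or `"grouped"` (10 folds over
#'   groups, e.g. source images of discs; requires `groups` in
#'   [fit_feature_models()]).
#' @param alpha_grid Regularization strengths searched for lasso/ridge: 10
#'   log-spaced values spanning 1e-15 to 20.
#' @param svr_cost,svr_epsilon RBF support-vector regression parameters.
#' @param mlp_layers Hidden/output unit counts of the neural network.
#' @param seed Seed for fold assignment and model initialization.
#' @return A `model_config` list.
#' @export
model_config <- function(model_kind = c("linear", "lasso", "ridge", "svr", "mlp"),
                         cv_scheme = c("kfold10", "loo", "grouped"),
                         alpha_grid = 10^seq(-15, log10(20), length.out = 10),
                         svr_cost = 1, svr_epsilon = 0.1,
                         mlp_layers = c(128, 64, 32, 1), seed = 1L) {
  structure(
    list(model_kind = match.arg(model_kind), cv_scheme = match.arg(cv_scheme),
         alpha_grid = alpha_grid, svr_cost = svr_cost,
         svr_epsilon = svr_epsilon, mlp_layers = mlp_layers,
         seed = as.integer(seed)),
    class = "model_config"
  )
}

make_folds <- function(n, scheme, groups = NULL, k = 10L) {
  if (scheme == "loo") return(seq_len(n))
  if (scheme == "grouped") {
    if (is.null(groups)) stop("grouped CV requires a groups vector", call. = FALSE)
    ug <- unique(groups)
    if (length(ug) < 2) stop("grouped CV requires >= 2 groups", call. = FALSE)
    kk <- min(k, length(ug))
    gfold <- stats::setNames(sample(rep_len(seq_len(kk), length(ug))), ug)
    return(unname(gfold[as.character(groups)]))
  }
  if (n < k) stop("fewer observations (", n, ") than folds (", k, ")", call. = FALSE)
  sample(rep_len(seq_len(k), n))
}

standardize_fit <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  list(mean = mu, sd = sd)
}

standardize_apply <- function(X, st) {
  sweep(sweep(X, 2, st$mean, "-"), 2, st$sd, "/")
}

# pick the regularization strength by inner 5-fold CV on the training fold
select_alpha <- function(X, y, alpha_grid, ridge) {
  n <- nrow(X)
  k <- min(5L, n)
  fold <- sample(rep_len(seq_len(k), n))
  mse <- matrix(NA_real_, k, length(alpha_grid))
  for (f in seq_len(k)) {
    tr <- fold != f
    if (sum(tr) < 2 || stats::sd(y[tr]) == 0) next
    fit <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr],
                          alpha = if (ridge) 0 else 1,
                          lambda = sort(alpha_grid, decreasing = TRUE),
                          standardize = FALSE)
    pred <- stats::predict(fit, X[!tr, , drop = FALSE], s = alpha_grid, exact = FALSE)
    mse[f, ] <- colMeans((pred - y[!tr])^2)
  }
  alpha_grid[which.min(colMeans(mse, na.rm = TRUE))]
}

train_predict <- function(kind, cfg, X_tr, y_tr, X_va) {
  switch(kind,
    linear = {
      fit <- stats::lm.fit(cbind(1, X_tr), y_tr)
      coefs <- fit$coefficients
      coefs[is.na(coefs)] <- 0
      list(pred = as.vector(cbind(1, X_va) %*% coefs), coef = coefs)
    },
    lasso = ,
    ridge = {
      if (stats::sd(y_tr) == 0) {
        # degenerate target: the undefined-correlation error surfaces later
        return(list(pred = rep(y_tr[1], nrow(X_va)), coef = NULL))
      }
      alpha <- select_alpha(X_tr, y_tr, cfg$alpha_grid, ridge = kind == "ridge")
      fit <- glmnet::glmnet(X_tr, y_tr, alpha = if (kind == "ridge") 0 else 1,
                            lambda = sort(unique(c(cfg$alpha_grid, alpha)),
                                          decreasing = TRUE),
                            standardize = FALSE)
      list(pred = as.vector(stats::predict(fit, X_va, s = alpha)),
           coef = as.vector(stats::coef(fit, s = alpha)), alpha = alpha)
    },
    svr = {
      fit <- e1071::svm(X_tr, y_tr, type = "eps-regression", kernel = "radial",
                        cost = cfg$svr_cost, epsilon = cfg$svr_epsilon,
                        scale = FALSE)
      list(pred = as.vector(stats::predict(fit, X_va)), coef = NULL)
    },
    mlp = {
      fit <- mlp_fit(X_tr, y_tr, layers = cfg$mlp_layers, seed = cfg$seed)
      list(pred = mlp_predict(fit, X_va), coef = NULL)
    },
    stop("unknown model kind: ", kind, call. = FALSE)
  )
}

#' Fit and cross-validate a feature-based complexity predictor
#'
#' Aligns a feature table with ratings by id, then runs the configured
#' model under the configured cross-validation scheme. Features are
#' standardized to zero mean and unit variance using training-fold
#' statistics only; ratings are never rescaled. Lasso/ridge regularization
#' strength is chosen on each training fold by inner 5-fold CV over the
#' configured grid. The reported correlations are computed on the pooled
#' out-of-fold predictions.
#'
#' @param features Tibble with an `image_id` column plus numeric feature
#'   columns (non-numeric and all-`NA` columns are dropped).
#' @param ratings A `rating_table` (`item_id`, `mu`) or a tibble with
#'   `image_id` and `rating` columns.
#' @param cfg A [model_config()].
#' @param groups Optional grouping vector (same order as `features`) for
#'   `cv_scheme = "grouped"`.
#' @return A `complexity_fit` with pooled out-of-fold `predictions`,
#'   `pearson_r`, `spearman_rho`, mean `coefficients` (where defined), and
#'   the per-fold standardization parameters.
#' @export
fit_feature_models <- function(features, ratings, cfg = model_config(),
                               groups = NULL) {
  y_tab <- normalize_ratings(ratings)
  df <- dplyr::inner_join(features, y_tab, by = "image_id")
  if (nrow(df) < nrow(features)) {
    warning(nrow(features) - nrow(df), " feature row(s) had no rating and were dropped")
  }
  if (!is.null(groups)) {
    stopifnot(length(groups) == nrow(features))
    groups <- groups[match(df$image_id, features$image_id)]
  }
  num_cols <- names(df)[vapply(df, is.numeric, logical(1))]
  num_cols <- setdiff(num_cols, c("rating", "trial_index"))
  X_all <- as.matrix(df[num_cols])
  keep <- colSums(is.na(X_all)) == 0 & apply(X_all, 2, function(c) all(is.finite(c)))
  X_all <- X_all[, keep, drop = FALSE]
  y <- df$rating
  n <- nrow(X_all)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)
  fold <- make_folds(n, cfg$cv_scheme, groups)
  pred <- rep(NA_real_, n)
  coefs <- list()
  st_last <- NULL
  for (f in sort(unique(fold))) {
    va <- fold == f
    st <- standardize_fit(X_all[!va, , drop = FALSE])
    X_tr <- standardize_apply(X_all[!va, , drop = FALSE], st)
    X_va <- standardize_apply(X_all[va, , drop = FALSE], st)
    out <- train_predict(cfg$model_kind, cfg, X_tr, y[!va], X_va)
    pred[va] <- out$pred
    if (!is.null(out$coef)) coefs[[length(coefs) + 1]] <- out$coef
    st_last <- st
  }
  metrics <- correlation_metrics(pred, y)
  structure(
    list(
      predictions = tibble::tibble(image_id = df$image_id, fold = fold,
                                   observed = y, predicted = pred),
      pearson_r = metrics$pearson_r,
      spearman_rho = metrics$spearman_rho,
      coefficients = if (length(coefs) > 0) Reduce("+", coefs) / length(coefs) else NULL,
      standardization = st_last,
      model_kind = cfg$model_kind,
      cv_scheme = cfg$cv_scheme
    ),
    class = "complexity_fit"
  )
}

normalize_ratings <- function(ratings) {
  if (all(c("item_id", "mu") %in% names(ratings))) {
    tibble::tibble(image_id = ratings$item_id, rating = ratings$mu)
  } else if (all(c("image_id", "rating") %in% names(ratings))) {
    tibble::tibble(image_id = ratings$image_id, rating = ratings$rating)
  } else {
    stop("ratings must have columns item_id/mu or image_id/rating", call. = FALSE)
  }
}

#' @export
print.complexity_fit <- function(x, ...) {
  cat("<complexity_fit>", x$model_kind, "under", x$cv_scheme, "\n")
  cat(sprintf("  n = %d, Pearson r = %.3f, Spearman rho = %.3f\n",
              nrow(x$predictions), x$pearson_r, x$spearman_rho))
  invisible(x)
}

#' Linear regression on raw pixel vectors
#'
#' Baseline pixel-level predictor: every image is resized to a common small
#' raster (default 64 x 64), flattened to an RGB vector, and regressed on
#' the ratings under 10-fold cross-validation. Because the pixel dimension
#' far exceeds the sample size, the least-squares fit is ridge-stabilized
#' (glmnet, inner alpha selection on the configured grid).
#'
#' @param image_dir Directory of PNG/JPEG images.
#' @param ratings As in [fit_feature_models()].
#' @param cfg A [model_config()] (the `model_kind` is ignored; ridge is
#'   used).
#' @param raster Target `c(height, width)` before flattening.
#' @return A `complexity_fit`.
#' @export
pixel_regression <- function(image_dir, ratings, cfg = model_config("ridge"),
                             raster = c(64, 64)) {
  files <- list.files(image_dir, pattern = "\\.(png|jpg|jpeg)$",
                      ignore.case = TRUE, full.names = TRUE)
  if (length(files) == 0) stop("no images found in ", image_dir, call. = FALSE)
  ids <- tools::file_path_sans_ext(basename(files))
  vecs <- lapply(files, function(f) {
    img <- read_image(f)
    as.vector(resize_rgb(img, raster[1], raster[2]))
  })
  X <- do.call(rbind, vecs)
  feats <- tibble::as_tibble(as.data.frame(X))
  names(feats) <- paste0("px_", seq_len(ncol(X)))
  feats$image_id <- ids
  cfg$model_kind <- "ridge"
  cfg$cv_scheme <- "kfold10"
  fit_feature_models(feats, ratings, cfg)
}

resize_rgb <- function(image, h, w) {
  out <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) {
    out[, , ch] <- EBImage::resize(image[, , ch], w = h, h = w)
  }
  out
}

#' Fixed-length descriptor vectors by keypoint resampling
#'
#' Controls for keypoint count by sampling exactly `n_sample` keypoints
#' from each image with replacement and concatenating their descriptors,
#' giving every image a vector of length `n_sample * d` (64,000 for d = 128
#' descriptors, 32,000 for d = 64).
#'
#' @param descriptors Named list; each element a `keypoints x d` matrix
#'   (>= 1 row, common `d`).
#' @param n_sample Keypoints sampled per image (with replacement).
#' @param seed Integer seed.
#' @return Matrix `n_images x (n_sample * d)` with the list names as row
#'   names.
#' @export
descriptor_vectors <- function(descriptors, n_sample = 500L, seed = 1L) {
  if (length(descriptors) == 0) stop("no descriptor sets given", call. = FALSE)
  d <- unique(vapply(descriptors, ncol, integer(1)))
  if (length(d) != 1) stop("descriptor dimensions differ across images", call. = FALSE)
  zero <- names(descriptors)[vapply(descriptors, nrow, integer(1)) == 0]
  if (length(zero) > 0) {
    stop("image(s) with zero keypoints: ", paste(zero, collapse = ", "),
         call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  out <- t(vapply(descriptors, function(m) {
    idx <- sample.int(nrow(m), n_sample, replace = TRUE)
    as.vector(t(m[idx, , drop = FALSE]))
  }, numeric(n_sample * d)))
  rownames(out) <- names(descriptors)
  out
}
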