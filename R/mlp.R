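# Minimal feed-forward ReLU network trained with Adam, used as the "mlp"
# model kind. Hidden layers ReLU, linear output; mean-squared-error loss;
# early stopping on an inner 10% split.

mlp_fit <- function(X, y, layers = c(128, 64, 32, 1), epochs = 200L,
                    lr = 1e-3, batch = 32L, patience = 20L, seed = 1L,
                    val_fraction = 0.1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n <- nrow(X); p <- ncol(X)
  sizes <- c(p, layers)
  n_layer <- length(sizes) - 1L
  W <- vector("list", n_layer); b <- vector("list", n_layer)
  for (l in seq_len(n_layer)) {
    # He initialization for ReLU stacks
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1], 0,
                                  sqrt(2 / sizes[l])), sizes[l], sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(x) x * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; step <- 0

  n_val <- max(1L, round(val_fraction * n))
  val_idx <- sample.int(n, n_val)
  tr_idx <- setdiff(seq_len(n), val_idx)
  if (length(tr_idx) == 0) { tr_idx <- seq_len(n); val_idx <- seq_len(n) }
  best_val <- Inf; best <- list(W = W, b = b); since_best <- 0L

  forward <- function(W, b, X) {
    acts <- list(X)
    for (l in seq_len(n_layer)) {
      z <- sweep(acts[[l]] %*% W[[l]], 2, b[[l]], "+")
      acts[[l + 1]] <- if (l < n_layer) pmax(z, 0) else z
    }
    acts
  }

  for (epoch in seq_len(epochs)) {
    ord <- sample(tr_idx)
    for (start in seq(1, length(ord), by = batch)) {
      idx <- ord[start:min(start + batch - 1, length(ord))]
      acts <- forward(W, b, X[idx, , drop = FALSE])
      pred <- acts[[n_layer + 1]][, 1]
      delta <- matrix(2 * (pred - y[idx]) / length(idx), ncol = 1)
      for (l in n_layer:1) {
        gW <- t(acts[[l]]) %*% delta
        gb <- colSums(delta)
        if (l > 1) {
          delta <- (delta %*% t(W[[l]])) * (acts[[l]] > 0)
        }
        step <- step + 1
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        corr1 <- 1 - beta1^step; corr2 <- 1 - beta2^step
        W[[l]] <- W[[l]] - lr * (mW[[l]] / corr1) / (sqrt(vW[[l]] / corr2) + eps)
        b[[l]] <- b[[l]] - lr * (mb[[l]] / corr1) / (sqrt(vb[[l]] / corr2) + eps)
      }
    }
    val_pred <- forward(W, b, X[val_idx, , drop = FALSE])[[n_layer + 1]][, 1]
    val_mse <- mean((val_pred - y[val_idx])^2)
    if (val_mse < best_val - 1e-10) {
      best_val <- val_mse; best <- list(W = W, b = b); since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= patience) break
    }
  }
  structure(list(W = best$W, b = best$b, n_layer = n_layer), class = "complexr_mlp")
}

mlp_predict <- function(model, X) {
  a <- X
  for (l in seq_len(model$n_layer)) {
    z <- sweep(a %*% model$W[[l]], 2, model$b[[l]], "+")
    a <- if (l < model$n_layer) pmax(z, 0) else z
  }
  a[, 1]
}
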