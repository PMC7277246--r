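#' Configure the Bayesian pairwise rating engine
#'
#' Each item carries a Gaussian belief over its latent complexity with mean
#' `mu` (the reported complexity score) and standard deviation `sigma` (the
#' engine's confidence). Every 2AFC trial is treated as a two-player game
#' whose winner is the chosen item; beliefs are updated after each game with
#' the classical truncated-Gaussian skill update.
#'
#' Defaults follow the standard parameterization of skill-rating systems:
#' prior `mu0 = 25`, `sigma0 = 25/3`, performance noise `beta = sigma0/2`,
#' dynamics noise `tau = sigma0/100`, and no draws (the forced-choice task
#' always yields a winner).
#'
#' @param mu0 Prior mean.
#' @param sigma0 Prior standard deviation (> 0).
#' @param beta Performance noise standard deviation (> 0).
#' @param tau Dynamics standard deviation added (in variance) before every
#'   update (>= 0).
#' @param epochs_max Maximum number of full passes over the comparison list.
#' @param epsilon_converge Stop when the mean absolute per-item change of
#'   `mu` over an epoch falls below this (> 0).
#' @param shuffle_seed Seed for the per-epoch shuffling of trial order.
#' @return A `rating_config` list.
#' @export
rating_config <- function(mu0 = 25, sigma0 = 25 / 3, beta = sigma0 / 2,
                          tau = sigma0 / 100, epochs_max = 10L,
                          epsilon_converge = 0.01, shuffle_seed = 1L) {
  stopifnot(sigma0 > 0, beta > 0, tau >= 0, epochs_max >= 1,
            epsilon_converge > 0)
  structure(
    list(mu0 = mu0, sigma0 = sigma0, beta = beta, tau = tau,
         epochs_max = as.integer(epochs_max),
         epsilon_converge = epsilon_converge,
         shuffle_seed = as.integer(shuffle_seed)),
    class = "rating_config"
  )
}

#' Truncated-Gaussian correction moments
#'
#' The win/loss update multiplies a Gaussian belief by the probability that
#' the winner's performance exceeded the loser's. The resulting posterior
#' mean and variance corrections are governed by the additive and
#' multiplicative moments of a Gaussian truncated at zero:
#' `v(t) = phi(t) / Phi(t)` and `w(t) = v(t) * (v(t) + t)`, where `t` is the
#' standardized performance margin. Both are evaluated in log space so they
#' remain accurate for margins as extreme as `t = -30`.
#'
#' @param t Standardized margin (finite numeric vector).
#' @return A list with components `v` (> 0) and `w` (in (0, 1]).
#' @examples
#' gaussian_moments(0)  # v = sqrt(2/pi), w = 2/pi
#' @export
gaussian_moments <- function(t) {
  stopifnot(all(is.finite(t)))
  v <- exp(stats::dnorm(t, log = TRUE) - stats::pnorm(t, log.p = TRUE))
  w <- v * (v + t)
  # guard against rounding at the extremes; w -> 1 as t -> -Inf, -> 0 as t -> Inf
  w <- pmin(pmax(w, 0), 1)
  list(v = v, w = w)
}

#' One win/loss belief update
#'
#' Applies the two-player skill update to the winner's and loser's Gaussian
#' beliefs. With `c^2 = 2 beta^2 + sigma_w^2 + sigma_l^2` and standardized
#' margin `t = (mu_w - mu_l) / c`:
#' \deqn{\mu_w \leftarrow \mu_w + (\sigma_w^2/c)\,v(t), \quad
#'       \mu_l \leftarrow \mu_l - (\sigma_l^2/c)\,v(t)}
#' and each variance is multiplied by `1 - (sigma^2/c^2) w(t)`. The dynamics
#' variance `tau^2` is added to both beliefs before the update. The winner's
#' mean strictly increases, the loser's strictly decreases, and (at
#' `tau = 0`) neither standard deviation grows.
#'
#' @param winner,loser Numeric vectors `c(mu, sigma)` or lists with `mu` and
#'   `sigma` elements.
#' @param cfg A [rating_config()].
#' @return A list with updated `winner` and `loser` beliefs (each a list
#'   with `mu` and `sigma`).
#' @export
update_pair <- function(winner, loser, cfg = rating_config()) {
  wb <- as_belief(winner)
  lb <- as_belief(loser)
  if (!all(is.finite(c(wb$mu, wb$sigma, lb$mu, lb$sigma)))) {
    stop("non-finite belief passed to update_pair", call. = FALSE)
  }
  s2w <- wb$sigma^2 + cfg$tau^2
  s2l <- lb$sigma^2 + cfg$tau^2
  c2 <- 2 * cfg$beta^2 + s2w + s2l
  cc <- sqrt(c2)
  t <- (wb$mu - lb$mu) / cc
  m <- gaussian_moments(t)
  list(
    winner = list(mu = wb$mu + s2w / cc * m$v,
                  sigma = sqrt(s2w * (1 - s2w / c2 * m$w))),
    loser = list(mu = lb$mu - s2l / cc * m$v,
                 sigma = sqrt(s2l * (1 - s2l / c2 * m$w)))
  )
}

as_belief <- function(x) {
  if (is.list(x)) list(mu = x$mu, sigma = x$sigma)
  else list(mu = x[[1]], sigma = x[[2]])
}

#' Rate items from 2AFC comparisons
#'
#' Converts a table of judged comparisons into per-item complexity scores by
#' sequential win/loss updates ([update_pair()]). The comparison list is
#' replayed for several epochs, shuffled anew each epoch, until the mean
#' absolute change in `mu` per item falls below `epsilon_converge` or
#' `epochs_max` is reached. Items named in `items` but never compared keep
#' the prior belief.
#'
#' @param records Comparison tibble with `item_a`, `item_b`, `chosen`
#'   columns; every `chosen` must be set.
#' @param cfg A [rating_config()].
#' @param items Optional character vector of item ids to include even if
#'   they appear in no comparison.
#' @return A `rating_table`: a tibble with columns `item_id`, `mu`, `sigma`,
#'   carrying the per-epoch mean absolute `mu` change as attribute
#'   `epoch_trace`.
#' @examples
#' recs <- tibble::tibble(
#'   observer_id = "o1",
#'   item_a = c("A", "B", "A"), item_b = c("B", "C", "C"),
#'   chosen = c("A", "B", "A")
#' )
#' rate_comparisons(recs)
#' @export
rate_comparisons <- function(records, cfg = rating_config(), items = NULL) {
  if (nrow(records) > 0) {
    if (any(is.na(records$chosen) | records$chosen == "")) {
      stop("rate_comparisons requires every chosen field to be set", call. = FALSE)
    }
    validate_comparisons(records)
  }
  ids <- sort(unique(c(records$item_a, records$item_b, items)))
  n <- length(ids)
  mu <- rep(cfg$mu0, n)
  sigma2 <- rep(cfg$sigma0^2, n)
  names_idx <- stats::setNames(seq_len(n), ids)
  trace <- numeric(0)

  if (nrow(records) > 0) {
    win <- unname(names_idx[ifelse(records$chosen == records$item_a,
                                   records$item_a, records$item_b)])
    los <- unname(names_idx[ifelse(records$chosen == records$item_a,
                                   records$item_b, records$item_a)])
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(cfg$shuffle_seed)
    beta2 <- cfg$beta^2
    tau2 <- cfg$tau^2
    for (epoch in seq_len(cfg$epochs_max)) {
      mu_prev <- mu
      ord <- sample.int(length(win))
      for (k in ord) {
        i <- win[k]; j <- los[k]
        s2i <- sigma2[i] + tau2
        s2j <- sigma2[j] + tau2
        c2 <- 2 * beta2 + s2i + s2j
        cc <- sqrt(c2)
        t <- (mu[i] - mu[j]) / cc
        v <- exp(stats::dnorm(t, log = TRUE) - stats::pnorm(t, log.p = TRUE))
        w <- min(max(v * (v + t), 0), 1)
        mu[i] <- mu[i] + s2i / cc * v
        mu[j] <- mu[j] - s2j / cc * v
        sigma2[i] <- s2i * (1 - s2i / c2 * w)
        sigma2[j] <- s2j * (1 - s2j / c2 * w)
      }
      trace <- c(trace, mean(abs(mu - mu_prev)))
      if (trace[epoch] < cfg$epsilon_converge) break
    }
  }

  out <- tibble::tibble(item_id = ids, mu = mu, sigma = sqrt(sigma2))
  attr(out, "epoch_trace") <- trace
  class(out) <- c("rating_table", class(out))
  out
}

#' Assemble a rating table by hand
#'
#' @param item_id Character vector of item ids.
#' @param mu,sigma Numeric vectors (recycled) of belief means and sds.
#' @return A `rating_table` tibble.
#' @export
rating_table <- function(item_id, mu, sigma = 25 / 3) {
  out <- tibble::tibble(item_id = as.character(item_id),
                        mu = as.numeric(mu),
                        sigma = rep_len(as.numeric(sigma), length(item_id)))
  class(out) <- c("rating_table", class(out))
  out
}

#' Consistency between judgements and final ratings
#'
#' Fraction of comparisons whose chosen item ended with the strictly higher
#' rating mean; pairs with exactly equal means contribute 0.5 (an unbiased
#' convention under exchangeability). Values near 1 indicate internally
#' consistent judgements; a fair-coin observer converges to 0.5.
#'
#' @param records Judged comparison tibble.
#' @param table A `rating_table` covering every item in `records`.
#' @return A fraction in `[0, 1]`.
#' @export
consistency_score <- function(records, table) {
  if (nrow(records) == 0) return(NaN)
  mu <- stats::setNames(table$mu, table$item_id)
  missing_items <- setdiff(unique(c(records$item_a, records$item_b)), names(mu))
  if (length(missing_items) > 0) {
    stop("item(s) missing from rating table: ",
         paste(utils::head(missing_items, 10), collapse = ", "), call. = FALSE)
  }
  other <- ifelse(records$chosen == records$item_a, records$item_b, records$item_a)
  mu_chosen <- unname(mu[records$chosen])
  mu_other <- unname(mu[other])
  mean((mu_chosen > mu_other) + 0.5 * (mu_chosen == mu_other))
}
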