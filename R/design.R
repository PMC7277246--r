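#' Specify a balanced 2AFC comparison design
#'
#' A design spec describes how many items are to be compared, how many
#' two-alternative forced-choice (2AFC) trials to schedule, and how many
#' observers the trials are spread over. Designs are balanced: every item
#' takes part in close to `2 * n_comparisons / n_items` trials and every
#' observer judges close to `n_comparisons / n_observers` trials.
#'
#' @param n_items Number of items (>= 2).
#' @param n_comparisons Number of 2AFC trials to schedule (>= 1).
#' @param n_observers Number of observers the trials are split across (>= 1).
#' @param seed Integer seed making the design reproducible.
#' @return A `design_spec` list.
#' @export
design_spec <- function(n_items, n_comparisons, n_observers = 1L, seed = 1L) {
  if (!is.numeric(n_items) || n_items < 2) {
    stop("invalid design: n_items must be >= 2", call. = FALSE)
  }
  if (!is.numeric(n_comparisons) || n_comparisons < 1) {
    stop("invalid design: n_comparisons must be >= 1", call. = FALSE)
  }
  if (!is.numeric(n_observers) || n_observers < 1) {
    stop("invalid design: n_observers must be >= 1", call. = FALSE)
  }
  structure(
    list(
      n_items = as.integer(n_items),
      n_comparisons = as.integer(n_comparisons),
      n_observers = as.integer(n_observers),
      seed = as.integer(seed)
    ),
    class = "design_spec"
  )
}

#' Generate a balanced comparison design
#'
#' Schedules `n_comparisons` unordered item pairs such that item
#' participation counts are approximately equal (max - min <= 2) and
#' per-observer trial counts differ by at most 1. Pairs are scheduled by a
#' randomized round-robin tournament (circle method): one cycle visits
#' every unordered pair exactly once, organized into rounds that are
#' near-perfect matchings (every item appears once per round, except a
#' rotating bye when `n_items` is odd). Item labels and round order are
#' shuffled per cycle, so consecutive designs differ while balance is
#' guaranteed by construction, and a pair can only repeat after the whole
#' pair pool has been exhausted.
#'
#' @param spec A [design_spec()].
#' @return A tibble of comparison records with columns `observer_id`,
#'   `item_a`, `item_b`, `chosen` (`NA`, to be filled by an observer or
#'   simulator) and `trial_index`. Item ids are `"item_0001"`-style strings;
#'   presentation order within a pair (a vs b) is randomized and carries no
#'   meaning.
#' @seealso [simulate_comparisons()] to fill in choices,
#'   [rate_comparisons()] to score them.
#' @examples
#' d <- generate_design(design_spec(4, 6, n_observers = 2, seed = 1))
#' table(c(d$item_a, d$item_b))  # participation 3 each
#' @export
generate_design <- function(spec) {
  stopifnot(inherits(spec, "design_spec"))
  n <- spec$n_items
  m <- spec$n_comparisons

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  ia <- integer(m)
  ib <- integer(m)
  filled <- 0L
  while (filled < m) {
    cyc <- round_robin_cycle(n)
    take <- min(length(cyc$a), m - filled)
    idx <- filled + seq_len(take)
    ia[idx] <- cyc$a[seq_len(take)]
    ib[idx] <- cyc$b[seq_len(take)]
    filled <- filled + take
  }

  # randomize presentation order within pairs
  flip <- sample(c(TRUE, FALSE), m, replace = TRUE)
  a_final <- ifelse(flip, ib, ia)
  b_final <- ifelse(flip, ia, ib)

  # balanced random observer assignment
  obs <- sample(rep_len(seq_len(spec$n_observers), m))

  tibble::tibble(
    observer_id = sprintf("obs_%03d", obs),
    item_a = item_label(a_final, n),
    item_b = item_label(b_final, n),
    chosen = NA_character_,
    trial_index = seq_len(m) - 1L
  )
}

# One full round-robin cycle over n items with random labels and round
# order: every unordered pair exactly once, rounds are matchings (odd n
# gets a rotating bye via a dummy slot)
round_robin_cycle <- function(n) {
  n_slots <- if (n %% 2L == 1L) n + 1L else n
  labels <- c(sample.int(n), if (n_slots > n) 0L)  # 0 = bye slot
  n_rounds <- n_slots - 1L
  half <- n_slots %/% 2L
  rounds <- vector("list", n_rounds)
  rot <- seq_len(n_slots - 1L)  # circle positions, slot n_slots is fixed
  for (r in seq_len(n_rounds)) {
    order_now <- c(rot, n_slots)
    a_pos <- order_now[seq_len(half)]
    b_pos <- order_now[n_slots + 1L - seq_len(half)]
    a <- labels[a_pos]; b <- labels[b_pos]
    keep <- a != 0L & b != 0L
    rounds[[r]] <- cbind(a[keep], b[keep])
    rot <- c(rot[length(rot)], rot[-length(rot)])  # rotate
  }
  rounds <- rounds[sample.int(n_rounds)]
  # shuffle pairs within each round too
  rounds <- lapply(rounds, function(p) p[sample.int(nrow(p)), , drop = FALSE])
  all <- do.call(rbind, rounds)
  list(a = all[, 1], b = all[, 2])
}

item_label <- function(i, n) {
  width <- max(4L, nchar(as.character(n)))
  sprintf(paste0("item_%0", width, "d"), i)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Read and write comparison tables
#'
#' Comparison tables are UTF-8 CSV files with the mandatory header
#' `observer_id,item_a,item_b,chosen` (plus an optional `trial_index`
#' column). `read_comparisons()` validates each row: `item_a != item_b` and
#' `chosen` must be one of the pair (or empty for an unjudged trial);
#' offending rows are reported with their row numbers.
#'
#' @param path File path.
#' @return `read_comparisons()`: a tibble of comparison records.
#' @export
read_comparisons <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  required <- c("observer_id", "item_a", "item_b", "chosen")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("comparison CSV missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if ("trial_index" %in% names(df)) {
    df$trial_index <- as.integer(df$trial_index)
  } else {
    df$trial_index <- seq_len(nrow(df)) - 1L
  }
  df <- df[c(required, "trial_index")]
  validate_comparisons(df)
  tibble::as_tibble(df)
}

validate_comparisons <- function(df) {
  bad_self <- which(df$item_a == df$item_b)
  chosen_set <- !is.na(df$chosen) & df$chosen != ""
  bad_choice <- which(chosen_set & df$chosen != df$item_a & df$chosen != df$item_b)
  msgs <- character(0)
  if (length(bad_self) > 0) {
    msgs <- c(msgs, paste0("item_a equals item_b in row(s): ",
                           paste(utils::head(bad_self, 10), collapse = ", ")))
  }
  if (length(bad_choice) > 0) {
    msgs <- c(msgs, paste0("chosen is not one of {item_a, item_b} in row(s): ",
                           paste(utils::head(bad_choice, 10), collapse = ", ")))
  }
  if (length(msgs) > 0) {
    stop("invalid comparison record(s):\n  ", paste(msgs, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(df)
}

#' @rdname read_comparisons
#' @param records A tibble of comparison records.
#' @export
write_comparisons <- function(records, path) {
  validate_comparisons(records)
  readr::write_csv(records, path, progress = FALSE)
  invisible(path)
}

#' Read and write rating tables
#'
#' Ratings CSVs hold one row per item: `item_id,mu,sigma`.
#'
#' @param path File path.
#' @return `read_ratings()`: tibble with columns `item_id`, `mu`, `sigma`.
#' @export
read_ratings <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    item_id = readr::col_character(),
    mu = readr::col_double(),
    sigma = readr::col_double()
  ), progress = FALSE)
}

#' @rdname read_ratings
#' @param ratings A rating tibble (`item_id`, `mu`, `sigma`), e.g. from
#'   [rating_table()].
#' @export
write_ratings <- function(ratings, path) {
  readr::write_csv(ratings[c("item_id", "mu", "sigma")], path, progress = FALSE)
  invisible(path)
}
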