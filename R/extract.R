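#' Extract the full feature battery for a directory of images
#'
#' Computes every scalar feature in the battery for each PNG/JPEG image in
#' `image_dir` and, optionally, merges externally supplied feature columns
#' (e.g. detector-based object counts, deep salience statistics, or search
#' reaction times, which require trained models or human data and are not
#' computed here). External values missing for an image are explicit `NA`s,
#' never silent zeros.
#'
#' @param image_dir Directory containing `.png`/`.jpg`/`.jpeg` files; the
#'   image id is the file name without extension.
#' @param cfg A [feature_config()].
#' @param backend Count backend passed to [count_features()].
#' @param external_csv Optional path to a CSV with an `image_id` column and
#'   arbitrary extra feature columns (must not duplicate ids).
#' @return A tibble with one row per readable image: `image_id` plus one
#'   column per feature.
#' @export
extract_features <- function(image_dir, cfg = feature_config(),
                             backend = "reference", external_csv = NULL) {
  files <- list.files(image_dir, pattern = "\\.(png|jpg|jpeg)$",
                      ignore.case = TRUE, full.names = TRUE)
  if (length(files) == 0) stop("no images found in ", image_dir, call. = FALSE)

  external <- NULL
  if (!is.null(external_csv)) {
    external <- readr::read_csv(external_csv, show_col_types = FALSE,
                                progress = FALSE)
    if (!"image_id" %in% names(external)) {
      stop("external CSV must have an image_id column", call. = FALSE)
    }
    dup <- external$image_id[duplicated(external$image_id)]
    if (length(dup) > 0) {
      stop("duplicate image id(s) in external CSV: ",
           paste(unique(dup), collapse = ", "), call. = FALSE)
    }
  }

  rows <- list()
  for (f in files) {
    id <- tools::file_path_sans_ext(basename(f))
    img <- tryCatch(read_image(f), error = function(e) NULL)
    if (is.null(img)) {
      message("skipping unreadable image: ", f)
      next
    }
    rows[[id]] <- c(list(image_id = id), image_features(img, cfg, backend))
  }
  out <- dplyr::bind_rows(rows)
  if (!is.null(external)) {
    out <- dplyr::left_join(out, external, by = "image_id")
  }
  out
}

#' Compute all scalar features for one in-memory image
#'
#' @param image Height x width x 3 array in `[0, 1]`.
#' @inheritParams extract_features
#' @return Named list of scalar features (the battery minus external
#'   columns).
#' @export
image_features <- function(image, cfg = feature_config(), backend = "reference") {
  glcm <- suppressWarnings(glcm_features(image, cfg))
  glcm$correlation_defined <- NULL
  c(
    glcm,
    colour_features(image, cfg),
    entropy_variance_features(image, cfg),
    suppressWarnings(clutter_features(image, cfg)),
    structure_features(image, cfg),
    count_features(image, backend, cfg)
  )
}
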