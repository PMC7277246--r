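#' Read bounding-box object tags
#'
#' Accepts VOC-style XML annotation files (one per image, `<object>` nodes
#' with `<name>` and `<bndbox>`) or a JSON array of records
#' `{image_id, class_name (or class), bbox:[xmin,ymin,xmax,ymax]}`.
#' Coordinates are normalized to 0-based, half-open pixels.
#'
#' @param paths Character vector of XML file paths (image id = file name
#'   sans extension) or a single JSON file path.
#' @return Tag tibble: `image_id`, `class_name`, `xmin`, `ymin`, `xmax`,
#'   `ymax`.
#' @export
read_tags <- function(paths) {
  if (length(paths) == 1 && grepl("\\.json$", paths, ignore.case = TRUE)) {
    return(read_tags_json(paths))
  }
  dplyr::bind_rows(lapply(paths, read_voc_xml))
}

read_voc_xml <- function(path) {
  doc <- xml2::read_xml(path)
  fname <- xml2::xml_text(xml2::xml_find_first(doc, "./filename"))
  id <- if (!is.na(fname) && nzchar(fname)) {
    tools::file_path_sans_ext(fname)
  } else {
    tools::file_path_sans_ext(basename(path))
  }
  objs <- xml2::xml_find_all(doc, ".//object")
  if (length(objs) == 0) {
    return(tibble::tibble(image_id = character(0), class_name = character(0),
                          xmin = numeric(0), ymin = numeric(0),
                          xmax = numeric(0), ymax = numeric(0)))
  }
  num <- function(node, tag) as.numeric(xml2::xml_text(
    xml2::xml_find_first(node, paste0(".//", tag))))
  out <- tibble::tibble(
    image_id = id,
    class_name = xml2::xml_text(xml2::xml_find_all(objs, "./name")),
    # VOC boxes are 1-based inclusive; convert to 0-based half-open
    xmin = vapply(objs, num, numeric(1), "xmin") - 1,
    ymin = vapply(objs, num, numeric(1), "ymin") - 1,
    xmax = vapply(objs, num, numeric(1), "xmax"),
    ymax = vapply(objs, num, numeric(1), "ymax")
  )
  validate_tags(out)
}

read_tags_json <- function(path) {
  recs <- jsonlite::fromJSON(path)
  if (length(recs) == 0 || (is.data.frame(recs) && nrow(recs) == 0)) {
    return(tibble::tibble(image_id = character(0), class_name = character(0),
                          xmin = numeric(0), ymin = numeric(0),
                          xmax = numeric(0), ymax = numeric(0)))
  }
  if (!is.data.frame(recs)) recs <- dplyr::bind_rows(recs)
  if ("class" %in% names(recs) && !"class_name" %in% names(recs)) {
    recs$class_name <- recs$class
  }
  if ("bbox" %in% names(recs)) {
    bb <- do.call(rbind, recs$bbox)
    recs$xmin <- bb[, 1]; recs$ymin <- bb[, 2]
    recs$xmax <- bb[, 3]; recs$ymax <- bb[, 4]
  }
  validate_tags(tibble::as_tibble(
    recs[c("image_id", "class_name", "xmin", "ymin", "xmax", "ymax")]))
}

validate_tags <- function(tags) {
  bad <- which(tags$xmax <= tags$xmin | tags$ymax <= tags$ymin)
  if (length(bad) > 0) {
    stop("degenerate bounding box in tag row(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  tags
}

bbox_area <- function(tags) (tags$xmax - tags$xmin) * (tags$ymax - tags$ymin)

#' Central object of one image
#'
#' The tag with the largest bounding-box area; ties are broken by first
#' occurrence in file order. All other tags are "background objects".
#'
#' @param tags Tag tibble rows of a single image (>= 1 row).
#' @return The winning tag row (one-row tibble).
#' @export
central_object <- function(tags) {
  if (nrow(tags) == 0) stop("central_object requires at least one tag", call. = FALSE)
  tags[which.max(bbox_area(tags)), , drop = FALSE]
}

#' Per-class complexity table
#'
#' For every object class, the mean rating of the images containing it
#' (i) anywhere, (ii) as the central (largest-box) object, and (iii) only
#' in the background (present but not central). The central and background
#' image sets partition the anywhere set, so the anywhere mean is exactly
#' their image-count-weighted mean. Empty cells are `NaN` with a count of
#' 0.
#'
#' @param tags Tag tibble (many images).
#' @param ratings A `rating_table` (`item_id`, `mu`) covering every tagged
#'   image.
#' @return Tibble: `class_name`, `n_anywhere`, `mean_anywhere`,
#'   `n_central`, `mean_central`, `n_background`, `mean_background`, plus
#'   attribute `global_mean` (mean rating over all tagged images).
#' @export
class_complexity_table <- function(tags, ratings) {
  mu <- stats::setNames(ratings$mu, ratings$item_id)
  missing_items <- setdiff(unique(tags$image_id), names(mu))
  if (length(missing_items) > 0) {
    stop("rating missing for tagged image(s): ",
         paste(utils::head(missing_items, 10), collapse = ", "), call. = FALSE)
  }
  central <- dplyr::bind_rows(lapply(split(tags, tags$image_id), central_object))
  central_key <- paste(central$image_id, central$class_name)

  # image-level class presence (one row per image x class)
  pres <- dplyr::distinct(tags, image_id, class_name)
  pres$rating <- unname(mu[pres$image_id])
  pres$central <- paste(pres$image_id, pres$class_name) %in% central_key

  tab <- dplyr::summarise(
    dplyr::group_by(pres, class_name),
    n_anywhere = dplyr::n(),
    mean_anywhere = mean(rating),
    n_central = sum(central),
    mean_central = ifelse(sum(central) > 0, mean(rating[central]), NaN),
    n_background = sum(!central),
    mean_background = ifelse(sum(!central) > 0, mean(rating[!central]), NaN),
    .groups = "drop"
  )
  attr(tab, "global_mean") <- mean(unname(mu[unique(tags$image_id)]))
  tab
}

#' Predict image complexity from object tags
#'
#' Tag-only predictors built from a per-class complexity table:
#' \describe{
#'   \item{biggest}{the anywhere-mean of the image's central-object class}
#'   \item{all_sum / all_mean}{sum / mean of the anywhere-means of every
#'     class present in the image}
#'   \item{background_sum / background_mean}{sum / mean of the
#'     background-means of every class present in the image's background}
#'   \item{tag_count}{the number of tagged objects}
#' }
#' Classes absent from the table (or with an empty required cell) fall
#' back to the table's global mean rating, keeping predictions total.
#'
#' @param tags Tag tibble of the images to predict.
#' @param table Output of [class_complexity_table()].
#' @param method One of the methods above.
#' @param use_central_means If `TRUE`, `all_sum`/`all_mean` use the
#'   central-object means instead of the anywhere-means.
#' @return Tibble `image_id`, `prediction`.
#' @export
predict_from_tags <- function(tags, table,
                              method = c("biggest", "all_sum", "all_mean",
                                         "background_sum", "background_mean",
                                         "tag_count"),
                              use_central_means = FALSE) {
  if (length(method) == 1 && !method %in% c("biggest", "all_sum", "all_mean",
                                            "background_sum", "background_mean",
                                            "tag_count")) {
    stop("unknown prediction method: ", method, call. = FALSE)
  }
  method <- match.arg(method)
  global_mean <- attr(table, "global_mean")
  if (is.null(global_mean)) global_mean <- mean(table$mean_anywhere, na.rm = TRUE)
  anywhere <- stats::setNames(table$mean_anywhere, table$class_name)
  central_m <- stats::setNames(table$mean_central, table$class_name)
  backgr <- stats::setNames(table$mean_background, table$class_name)
  lookup <- function(map, cls) {
    v <- unname(map[cls])
    v[is.na(v)] <- global_mean
    v
  }
  all_map <- if (use_central_means) central_m else anywhere

  per_image <- split(tags, tags$image_id)
  preds <- vapply(per_image, function(tg) {
    switch(method,
      biggest = lookup(anywhere, central_object(tg)$class_name),
      all_sum = sum(lookup(all_map, unique(tg$class_name))),
      all_mean = mean(lookup(all_map, unique(tg$class_name))),
      background_sum = ,
      background_mean = {
        bg_rows <- tg[-which.max(bbox_area(tg)), , drop = FALSE]
        bg <- unique(bg_rows$class_name)
        if (length(bg) == 0) {
          global_mean
        } else if (method == "background_sum") {
          sum(lookup(backgr, bg))
        } else {
          mean(lookup(backgr, bg))
        }
      },
      tag_count = nrow(tg)
    )
  }, numeric(1))
  tibble::tibble(image_id = names(per_image), prediction = unname(preds))
}

#' Presence and count vectors over a class vocabulary
#'
#' @param tags Tag tibble.
#' @param vocabulary Class vocabulary (default the 20 VOC names).
#' @param allow_unknown Map classes outside the vocabulary to an `OTHER`
#'   bucket instead of erroring.
#' @param image_ids Optional full id set; ids without tags get zero
#'   vectors.
#' @return List with `presence` and `count` integer matrices
#'   (`images x vocabulary`), rownames = image ids.
#' @export
vectorize_tags <- function(tags, vocabulary = voc_classes,
                           allow_unknown = FALSE, image_ids = NULL) {
  unknown <- setdiff(unique(tags$class_name), vocabulary)
  if (length(unknown) > 0) {
    if (!allow_unknown) {
      stop("class(es) outside vocabulary: ", paste(unknown, collapse = ", "),
           "; use allow_unknown = TRUE to bucket them", call. = FALSE)
    }
    vocabulary <- c(vocabulary, "OTHER")
    tags$class_name[tags$class_name %in% unknown] <- "OTHER"
  }
  ids <- sort(unique(c(tags$image_id, image_ids)))
  count <- matrix(0L, length(ids), length(vocabulary),
                  dimnames = list(ids, vocabulary))
  tb <- table(tags$image_id, tags$class_name)
  count[rownames(tb), colnames(tb)] <- as.integer(tb)
  list(presence = (count > 0) * 1L, count = count)
}
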