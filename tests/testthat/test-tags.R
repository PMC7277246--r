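toy_tags <- function() {
  # A: cat is the (only, hence central) object; B: cat in the background
  # behind a bigger dog; C: dog central
  tibble::tibble(
    image_id = c("A", "B", "B", "C"),
    class_name = c("cat", "dog", "cat", "dog"),
    xmin = c(0, 0, 2, 0), ymin = c(0, 0, 2, 0),
    xmax = c(30, 40, 10, 25), ymax = c(30, 40, 10, 25)
  )
}

toy_ratings <- function() rating_table(c("A", "B", "C"), c(10, 30, 20))

test_that("the central object is the largest box, ties to file order", {
  tags <- toy_tags()
  expect_equal(central_object(tags[1, ])$class_name, "cat")
  expect_equal(central_object(tags[tags$image_id == "B", ])$class_name, "dog")
  tied <- tibble::tibble(image_id = "x", class_name = c("cat", "dog"),
                         xmin = 0, ymin = 0, xmax = 10, ymax = 10)
  expect_equal(central_object(tied)$class_name, "cat")
  expect_error(central_object(tied[0, ]), "at least one")
})

test_that("class complexity cells match hand arithmetic and pool exactly", {
  tab <- class_complexity_table(toy_tags(), toy_ratings())
  cat_row <- tab[tab$class_name == "cat", ]
  expect_equal(cat_row$mean_central, 10)      # A only
  expect_equal(cat_row$mean_background, 30)   # B only
  expect_equal(cat_row$mean_anywhere, 20)     # pooled
  dog_row <- tab[tab$class_name == "dog", ]
  expect_equal(dog_row$mean_central, 25)      # B and C
  expect_equal(dog_row$n_background, 0)
  expect_true(is.nan(dog_row$mean_background))

  expect_error(class_complexity_table(toy_tags(), rating_table("A", 10)),
               "missing")

  # pooling identity on random tag sets: anywhere-mean is exactly the
  # image-weighted mean of the central and background cells
  for (s in 1:10) {
    tags <- random_tags(30, seed = s)
    ratings <- rating_table(unique(tags$image_id),
                            rnorm(length(unique(tags$image_id)), 25, 5.5))
    tab <- class_complexity_table(tags, ratings)
    pooled <- with(tab, ifelse(n_central > 0, n_central * mean_central, 0) +
                     ifelse(n_background > 0, n_background * mean_background, 0))
    expect_equal(tab$mean_anywhere, pooled / tab$n_anywhere, tolerance = 1e-12)
  }
})

test_that("tag-based predictions follow their definitions", {
  tab <- class_complexity_table(toy_tags(), toy_ratings())
  both <- tibble::tibble(image_id = "new", class_name = c("cat", "dog"),
                         xmin = c(0, 0), ymin = c(0, 0),
                         xmax = c(20, 10), ymax = c(20, 10))
  # cat anywhere 20, dog anywhere 25
  expect_equal(predict_from_tags(both, tab, "all_sum")$prediction, 45)
  expect_equal(predict_from_tags(both, tab, "all_mean")$prediction, 22.5)
  expect_equal(predict_from_tags(both, tab, "biggest")$prediction, 20)
  expect_equal(predict_from_tags(both, tab, "tag_count")$prediction, 2)
  # background of "new" is the dog; dog has no background cell ->
  # global mean fallback keeps the prediction defined
  expect_equal(predict_from_tags(both, tab, "background_mean")$prediction,
               attr(tab, "global_mean"))
  # single-class image under all_mean: that class's anywhere-mean
  single <- both[1, ]
  expect_equal(predict_from_tags(single, tab, "all_mean")$prediction, 20)
  # unseen class falls back to the global mean
  alien <- single; alien$class_name <- "zebra"
  expect_equal(predict_from_tags(alien, tab, "all_mean")$prediction,
               attr(tab, "global_mean"))
  expect_error(predict_from_tags(both, tab, "nope"), "method")
})

test_that("presence/count vectors follow the vocabulary contract", {
  tags <- tibble::tibble(image_id = c("x", "x", "x"),
                         class_name = c("cat", "cat", "dog"),
                         xmin = 0, ymin = 0, xmax = 5, ymax = 5)
  v <- vectorize_tags(tags)
  expect_equal(unname(v$count["x", "cat"]), 2L)
  expect_equal(unname(v$count["x", "dog"]), 1L)
  expect_equal(sum(v$presence["x", ]), 2L)
  expect_true(all(v$count >= v$presence))
  # untagged image gets explicit zero vectors
  v2 <- vectorize_tags(tags, image_ids = c("x", "y"))
  expect_equal(sum(v2$count["y", ]), 0L)
  # unknown classes error unless bucketed
  bad <- tags; bad$class_name[1] <- "unicorn"
  expect_error(vectorize_tags(bad), "vocabulary")
  v3 <- vectorize_tags(bad, allow_unknown = TRUE)
  expect_equal(unname(v3$count["x", "OTHER"]), 1L)
})

test_that("VOC XML and JSON tag files parse to identical records", {
  dir <- withr::local_tempdir()
  xml <- file.path(dir, "img_001.xml")
  writeLines(c(
    "<annotation><filename>img_001.png</filename>",
    "<object><name>cat</name><bndbox>",
    "<xmin>11</xmin><ymin>21</ymin><xmax>40</xmax><ymax>60</ymax>",
    "</bndbox></object>",
    "<object><name>dog</name><bndbox>",
    "<xmin>1</xmin><ymin>1</ymin><xmax>90</xmax><ymax>80</ymax>",
    "</bndbox></object>",
    "</annotation>"), xml)
  from_xml <- read_tags(xml)
  expect_equal(nrow(from_xml), 2)
  expect_equal(from_xml$xmin, c(10, 0))  # 1-based inclusive -> 0-based
  expect_equal(from_xml$xmax, c(40, 90))

  json <- file.path(dir, "tags.json")
  jsonlite::write_json(
    list(list(image_id = "img_001", class = "cat", bbox = c(10, 20, 40, 60)),
         list(image_id = "img_001", class = "dog", bbox = c(0, 0, 90, 80))),
    json, auto_unbox = TRUE)
  from_json <- read_tags(json)
  expect_equal(from_json$class_name, from_xml$class_name)
  expect_equal(from_json$xmin, from_xml$xmin)
  expect_equal(from_json$ymax, from_xml$ymax)

  # degenerate boxes are rejected
  bad <- file.path(dir, "bad.json")
  jsonlite::write_json(
    list(list(image_id = "z", class = "cat", bbox = c(10, 10, 10, 20))),
    bad, auto_unbox = TRUE)
  expect_error(read_tags(bad), "degenerate")
})

test_that("background presence tracks busier images on average", {
  # synthetic worlds where complexity grows with object count: a class
  # seen in the background shares its image with a bigger object, so
  # background cells should average at least as high as central cells
  diffs <- numeric(10)
  for (s in 1:10) {
    tags <- random_tags(60, seed = 100 + s)
    n_tags <- table(tags$image_id)
    ratings <- rating_table(names(n_tags), 10 + 3 * as.vector(n_tags) +
                              rnorm(length(n_tags), 0, 1))
    tab <- class_complexity_table(tags, ratings)
    ok <- tab$n_central > 0 & tab$n_background > 0
    diffs[s] <- mean(tab$mean_background[ok] - tab$mean_central[ok])
  }
  expect_gt(mean(diffs), 0)
})

test_that("count vectors out-predict presence vectors when counts drive load", {
  r_count <- numeric(10); r_pres <- numeric(10)
  for (s in 1:10) {
    tags <- random_tags(120, seed = 200 + s, max_tags = 8)
    n_tags <- table(tags$image_id)
    ids <- names(n_tags)
    rating <- 10 + 3 * as.vector(n_tags) + rnorm(length(ids), 0, 2)
    v <- vectorize_tags(tags, vocabulary = unique(tags$class_name))
    fit_one <- function(M) {
      feats <- tibble::as_tibble(as.data.frame(M))
      names(feats) <- paste0("c_", seq_len(ncol(M)))
      feats$image_id <- rownames(M)
      fit_feature_models(feats,
                         tibble::tibble(image_id = ids, rating = rating),
                         model_config("svr", "kfold10", seed = s))$pearson_r
    }
    r_count[s] <- fit_one(v$count)
    r_pres[s] <- fit_one(v$presence)
  }
  expect_gt(mean(r_count), mean(r_pres))
})
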