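#' Read an image as a height x width x 3 array in [0, 1]
#'
#' PNG, JPEG and BMP-free formats are handled through the png and jpeg
#' codecs; grayscale and alpha-carrying rasters are expanded/flattened to
#' plain RGB.
#'
#' @param path File path (.png, .jpg, .jpeg).
#' @return Numeric array `c(height, width, 3)` in `[0, 1]`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    stop("unsupported image format: ", ext, call. = FALSE)
  )
  as_rgb_array(raw)
}

as_rgb_array <- function(raw) {
  if (length(dim(raw)) == 2) {
    raw <- array(rep(raw, 3), dim = c(dim(raw), 3))
  } else if (dim(raw)[3] == 2) {
    raw <- array(rep(raw[, , 1], 3), dim = c(dim(raw)[1:2], 3))
  } else if (dim(raw)[3] == 4) {
    raw <- raw[, , 1:3]
  }
  raw
}

#' @rdname read_image
#' @param image Height x width x 3 array in `[0, 1]`.
#' @export
write_image <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

# luminance as the classical Rec. 601 weighting
luminance <- function(image) {
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

# sRGB (D65) -> CIELAB; returns list of h x w matrices L, a, b
lab_channels <- function(image) {
  d <- dim(image)
  px <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
              as.vector(image[, , 3]))
  lab <- grDevices::convertColor(px, from = "sRGB", to = "Lab",
                                 from.ref.white = "D65", to.ref.white = "D65")
  list(L = matrix(lab[, 1], d[1], d[2]),
       a = matrix(lab[, 2], d[1], d[2]),
       b = matrix(lab[, 3], d[1], d[2]))
}

# shift a matrix by (dy, dx) with replicate (clamped) boundary
shift_mat <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  m[pmin(pmax(seq_len(h) + dy, 1L), h), pmin(pmax(seq_len(w) + dx, 1L), w)]
}

gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k / sum(k)
}

# separable filtering with replicate boundary
sep_filter <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k)) out <- out + k[i] * shift_mat(m, 0L, i - r - 1L)
  m2 <- out
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k)) out <- out + k[i] * shift_mat(m2, i - r - 1L, 0L)
  out
}

gauss_blur <- function(m, sigma) sep_filter(m, gauss_kernel(sigma))

# 2x decimation after blurring (Gaussian pyramid step)
pyr_down <- function(m, sigma = 1) {
  b <- gauss_blur(m, sigma)
  b[seq(1, nrow(m), by = 2), seq(1, ncol(m), by = 2), drop = FALSE]
}

# downscale an RGB array so its longer side is <= max_dim (box averaging)
downscale_rgb <- function(image, max_dim = 32L) {
  h <- dim(image)[1]; w <- dim(image)[2]
  f <- ceiling(max(h, w) / max_dim)
  if (f <= 1L) return(image)
  hh <- floor(h / f); ww <- floor(w / f)
  out <- array(0, dim = c(hh, ww, 3))
  for (ch in 1:3) {
    m <- image[seq_len(hh * f), seq_len(ww * f), ch]
    dim(m) <- c(f, hh, f, ww)
    out[, , ch] <- apply(m, c(2, 4), mean)
  }
  out
}
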