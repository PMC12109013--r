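# Shared helpers: image containers, colour conversions, seeded evaluation.
#
# Images are plain numeric arrays, H x W x 3, with 8-bit intensities stored
# as doubles in [0, 255].  Network activations use the [-1, 1] scale; the
# converters below are the only place that mapping lives.

assert_rgb_image <- function(img, arg = "image") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L ||
      !is.numeric(img)) {
    abort(sprintf("`%s` must be a numeric H x W x 3 array", arg),
          class = "ki67gan_format_error")
  }
  invisible(img)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Relative luminance of an RGB image
#'
#' Rec. 709 luminance on the [0, 1] scale, used by the quality filter and the
#' HE nuclear-fraction index proxy.
#'
#' @param img numeric H x W x 3 array with intensities in [0, 255].
#' @return numeric H x W matrix in [0, 1].
#' @keywords internal
luminance <- function(img) {
  (0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]) / 255
}

# hue (degrees), saturation, value for a matrix of RGB rows in [0, 255]
rgb_to_hsv_rows <- function(m) {
  hsv <- grDevices::rgb2hsv(t(m), maxColorValue = 255)
  tibble::tibble(h = hsv[1, ] * 360, s = hsv[2, ], v = hsv[3, ])
}

# CIE Lab rows from RGB rows in [0, 255]; perceptual space for clustering
rgb_to_lab_rows <- function(m) {
  grDevices::convertColor(m / 255, from = "sRGB", to = "Lab")
}

#' Evaluate code under a fixed RNG seed without disturbing the session RNG
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# stack a list of H x W x 3 images into an H x W x 3 x N tensor in [-1, 1]
images_to_tensor <- function(images) {
  if (is.array(images) && length(dim(images)) == 4L) return(images / 127.5 - 1)
  stopifnot(length(images) >= 1L)
  d <- dim(images[[1]])
  x <- array(0, c(d[1], d[2], d[3], length(images)))
  for (i in seq_along(images)) x[, , , i] <- images[[i]]
  x / 127.5 - 1
}

# map a raw synthesis-network output tensor back to 8-bit image arrays
tensor_to_images <- function(x) {
  n <- dim(x)[4]
  px <- clamp((x + 1) * 127.5, 0, 255)
  lapply(seq_len(n), function(i) px[, , , i, drop = TRUE])
}

#' Read and write 8-bit PNG images
#'
#' Thin wrappers around \pkg{png} keeping the package's [0, 255] convention.
#'
#' @param path file path.
#' @param img numeric H x W x 3 array in [0, 255].
#' @return `read_image()` returns an H x W x 3 array in [0, 255].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("image file does not exist: %s", path),
          class = "ki67gan_io_error")
  }
  x <- png::readPNG(path)
  if (length(dim(x)) == 2L) x <- array(rep(x, 3L), c(dim(x), 3L))
  if (dim(x)[3] == 4L) x <- x[, , 1:3, drop = FALSE]
  round(x * 255)
}

#' @rdname read_image
#' @export
write_image <- function(img, path) {
  assert_rgb_image(img)
  png::writePNG(clamp(img, 0, 255) / 255, target = path)
  invisible(path)
}
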