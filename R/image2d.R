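#' Single-channel 2D image
#'
#' An `image2d` is a numeric matrix of intensities in `[0, 1]`, indexed as
#' `pixels[y + 1, x + 1]` under the package-wide 0-based `(x, y)` convention
#' (`x` = column, `y` = row). Grids smaller than 8 pixels per side are
#' rejected: the registration network downsamples repeatedly and cannot
#' operate on smaller inputs.
#'
#' @param pixels numeric matrix of intensities in `[0, 1]`.
#' @param clip if `TRUE`, clamp values into `[0, 1]` instead of erroring.
#' @return an `image2d` object (a classed matrix).
#' @examples
#' img <- image2d(matrix(runif(64), 8, 8))
#' dim(img)
#' @export
image2d <- function(pixels, clip = FALSE) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stopf("image2d requires a numeric matrix")
  }
  if (nrow(pixels) < 8 || ncol(pixels) < 8) {
    stopf("image2d requires at least 8x8 pixels, got %dx%d",
          nrow(pixels), ncol(pixels))
  }
  if (any(!is.finite(pixels))) stopf("image2d intensities must be finite")
  if (clip) {
    pixels <- clamp(pixels, 0, 1)
  } else if (any(pixels < 0) || any(pixels > 1)) {
    stopf("image2d intensities must lie in [0, 1]")
  }
  structure(unclass(pixels), class = c("image2d", "matrix"))
}

#' @export
print.image2d <- function(x, ...) {
  cat(sprintf("<image2d %dx%d, range [%.3f, %.3f]>\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

is_image2d <- function(x) inherits(x, "image2d")

as_matrix <- function(x) {
  m <- unclass(x)
  attr(m, "class") <- NULL
  m
}
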