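#' Dense 2D displacement field
#'
#' A displacement field stores per-pixel offsets `(dx, dy)` in pixels, in the
#' 0-based `(x, y)` convention (`x` = column index, `y` = row index). The
#' associated transformation grid is `phi(x, y) = (x + dx(x, y), y + dy(x, y))`
#' and is always derived, never stored.
#'
#' @param dx,dy numeric matrices of equal shape holding the x- and y-offsets.
#' @return a `displacement_field` object.
#' @examples
#' f <- displacement_field(matrix(1, 8, 8), matrix(0, 8, 8))
#' f
#' @export
displacement_field <- function(dx, dy) {
  if (!is.matrix(dx) || !is.matrix(dy)) stopf("dx and dy must be matrices")
  if (!all(dim(dx) == dim(dy))) {
    stopf("dx and dy must have identical shapes (%dx%d vs %dx%d)",
          nrow(dx), ncol(dx), nrow(dy), ncol(dy))
  }
  if (any(!is.finite(dx)) || any(!is.finite(dy))) {
    stopf("displacement offsets must be finite")
  }
  structure(list(dx = unname(dx), dy = unname(dy)),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  mag <- sqrt(x$dx^2 + x$dy^2)
  cat(sprintf("<displacement_field %dx%d, mean |u| = %.3f px, max |u| = %.3f px>\n",
              nrow(x$dx), ncol(x$dx), mean(mag), max(mag)))
  invisible(x)
}

#' @export
dim.displacement_field <- function(x) dim(x$dx)

is_field <- function(x) inherits(x, "displacement_field")

field_h <- function(f) nrow(f$dx)
field_w <- function(f) ncol(f$dx)

#' Affine map of the plane
#'
#' Represents `phi(p) = linear %*% p + offset` acting on 0-based pixel
#' coordinates `p = (x, y)`.
#'
#' @param linear 2x2 numeric matrix.
#' @param offset numeric 2-vector `(tx, ty)`, in pixels.
#' @return an `affine_map` object.
#' @examples
#' a <- affine_map(diag(2), c(3, -2))
#' affine_det(a)
#' @export
affine_map <- function(linear = diag(2), offset = c(0, 0)) {
  linear <- matrix(as.numeric(linear), 2, 2)
  offset <- as.numeric(offset)
  if (length(offset) != 2) stopf("offset must have length 2")
  if (any(!is.finite(linear)) || any(!is.finite(offset))) {
    stopf("affine parameters must be finite")
  }
  structure(list(linear = linear, offset = offset), class = "affine_map")
}

#' @export
print.affine_map <- function(x, ...) {
  cat(sprintf("<affine_map det=%.4f offset=(%.2f, %.2f)>\n",
              affine_det(x), x$offset[1], x$offset[2]))
  invisible(x)
}

#' Determinant of the linear part of an affine map
#'
#' The map is orientation-preserving iff the determinant is positive.
#'
#' @param a an [affine_map()].
#' @return a scalar determinant.
#' @export
affine_det <- function(a) {
  a$linear[1, 1] * a$linear[2, 2] - a$linear[1, 2] * a$linear[2, 1]
}

# Composition (a then applied to the output of b): phi_a(phi_b(p)).
affine_compose <- function(a, b) {
  affine_map(a$linear %*% b$linear,
             as.numeric(a$linear %*% b$offset) + a$offset)
}

affine_invert <- function(a) {
  li <- solve(a$linear)
  affine_map(li, as.numeric(-li %*% a$offset))
}

#' Identity displacement field
#'
#' The zero element of the field algebra: warping any image by it returns the
#' image unchanged.
#'
#' @param h,w grid height and width in pixels (both at least 8).
#' @return a `displacement_field` with all offsets zero.
#' @export
identity_field <- function(h, w) {
  if (h < 8 || w < 8) stopf("fields require at least 8x8 pixels, got %dx%d", h, w)
  displacement_field(matrix(0, h, w), matrix(0, h, w))
}

#' Dense displacement field of an affine map
#'
#' Evaluates `phi(p) = linear %*% p + offset` at every pixel centre and
#' returns the displacement `phi - id`.
#'
#' @param a an [affine_map()].
#' @param h,w grid dimensions in pixels.
#' @return a `displacement_field`.
#' @export
from_affine <- function(a, h, w) {
  if (h < 8 || w < 8) stopf("fields require at least 8x8 pixels, got %dx%d", h, w)
  g <- coord_grids(h, w)
  A <- a$linear
  dx <- (A[1, 1] - 1) * g$X + A[1, 2] * g$Y + a$offset[1]
  dy <- A[2, 1] * g$X + (A[2, 2] - 1) * g$Y + a$offset[2]
  displacement_field(dx, dy)
}

#' Warp an image through a displacement field
#'
#' The registered image is `out(p) = img(phi(p))` with bilinear interpolation;
#' samples falling outside the image use the constant background 0 and the
#' output is clipped to `[0, 1]`.
#'
#' @param img an [image2d()].
#' @param field a [displacement_field()] of the same shape.
#' @return an [image2d()].
#' @export
warp_image <- function(img, field) {
  h <- nrow(img); w <- ncol(img)
  check_same_shape(h, w, field_h(field), field_w(field), "image and field")
  g <- coord_grids(h, w)
  v <- bilinear_sample_zero(as_matrix(img), g$X + field$dx, g$Y + field$dy)
  image2d(matrix(clamp(v, 0, 1), h, w))
}

#' Warp a label image through a displacement field
#'
#' Nearest-neighbour sampling so that labels are never blended; out-of-bounds
#' samples become the background label 0.
#'
#' @param seg integer matrix of non-negative labels.
#' @param field a [displacement_field()] of the same shape.
#' @return an integer label matrix.
#' @export
warp_labels <- function(seg, field) {
  if (!is.matrix(seg)) stopf("seg must be a matrix of labels")
  if (any(seg < 0) || any(seg != round(seg))) {
    stopf("labels must be non-negative integers")
  }
  h <- nrow(seg); w <- ncol(seg)
  check_same_shape(h, w, field_h(field), field_w(field), "labels and field")
  g <- coord_grids(h, w)
  v <- nearest_sample(seg, g$X + field$dx, g$Y + field$dy, background = 0)
  matrix(as.integer(v), h, w)
}

#' Compose two displacement fields
#'
#' Returns the field `c` with `phi_c(p) = phi_first(phi_second(p))` at every
#' pixel `p`. Evaluating `phi_first` at non-integer locations bilinearly
#' interpolates its displacement components (not absolute coordinates) and
#' extends displacements beyond the border by edge replication.
#'
#' @param first,second [displacement_field()]s of identical shape.
#' @return a `displacement_field`.
#' @export
compose_fields <- function(first, second) {
  h <- field_h(first); w <- field_w(first)
  check_same_shape(h, w, field_h(second), field_w(second), "fields")
  g <- coord_grids(h, w)
  xs <- g$X + second$dx
  ys <- g$Y + second$dy
  ufx <- bilinear_sample_replicate(first$dx, xs, ys)
  ufy <- bilinear_sample_replicate(first$dy, xs, ys)
  displacement_field(matrix(ufx, h, w) + second$dx,
                     matrix(ufy, h, w) + second$dy)
}

#' Sample a displacement field at arbitrary locations
#'
#' Bilinearly interpolates the displacement components at 0-based, possibly
#' non-integer `(x, y)` locations, with edge replication outside the grid.
#'
#' @param field a [displacement_field()].
#' @param x,y numeric vectors of coordinates.
#' @return a list with numeric vectors `dx` and `dy`.
#' @export
sample_field <- function(field, x, y) {
  list(dx = bilinear_sample_replicate(field$dx, x, y),
       dy = bilinear_sample_replicate(field$dy, x, y))
}

#' Jacobian determinant grid of a displacement field
#'
#' Estimates the determinant of the 2x2 Jacobian of `phi = id + u` at each
#' pixel using central finite differences in the interior and one-sided
#' differences on the border rows/columns. The stencil is exact for affine
#' fields, borders included.
#'
#' @param field a [displacement_field()].
#' @return an HxW numeric matrix of determinants.
#' @export
jacobian_determinant <- function(field) {
  h <- field_h(field); w <- field_w(field)
  g <- coord_grids(h, w)
  px <- g$X + field$dx
  py <- g$Y + field$dy
  # derivative along x (columns) and y (rows), central inside, one-sided at edges
  ddx <- function(m) {
    out <- matrix(0, h, w)
    if (w >= 3) out[, 2:(w - 1)] <- (m[, 3:w] - m[, 1:(w - 2)]) / 2
    out[, 1] <- m[, 2] - m[, 1]
    out[, w] <- m[, w] - m[, w - 1]
    out
  }
  ddy <- function(m) {
    out <- matrix(0, h, w)
    if (h >= 3) out[2:(h - 1), ] <- (m[3:h, ] - m[1:(h - 2), ]) / 2
    out[1, ] <- m[2, ] - m[1, ]
    out[h, ] <- m[h, ] - m[h - 1, ]
    out
  }
  ddx(px) * ddy(py) - ddy(px) * ddx(py)
}

#' Fraction of folded ("corrupted") pixels
#'
#' A pixel is corrupted when the Jacobian determinant of `phi` is
#' non-positive, indicating local folding or collapse of the transformation.
#'
#' @param field a [displacement_field()].
#' @return a fraction in `[0, 1]`.
#' @export
corrupted_fraction <- function(field) {
  mean(jacobian_determinant(field) <= 0)
}

#' Mean displacement magnitude of a set of fields
#'
#' Pools every pixel of every field and averages the Euclidean norm of the
#' displacement vectors. Used as the normalizing constant `T` of the endpoint
#' error (computed from training data).
#'
#' @param fields a list of [displacement_field()]s (a single field is accepted).
#' @return mean displacement magnitude in pixels.
#' @export
mean_displacement_norm <- function(fields) {
  if (is_field(fields)) fields <- list(fields)
  if (length(fields) == 0) stopf("mean_displacement_norm requires at least one field")
  tot <- 0; n <- 0
  for (f in fields) {
    tot <- tot + sum(sqrt(f$dx^2 + f$dy^2))
    n <- n + length(f$dx)
  }
  tot / n
}
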