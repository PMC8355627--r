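#' Paired landmark set
#'
#' Stores `N` corresponding landmark coordinates in reference and moving
#' space, 0-based `(x, y)`. At least 3 points are needed to build a dense
#' field, and reference points must be pairwise distinct (the radial basis
#' system is singular otherwise).
#'
#' @param ref_points,mov_points numeric Nx2 matrices of `(x, y)` coordinates.
#' @return a `keypoint_set` object.
#' @export
keypoint_set <- function(ref_points, mov_points) {
  ref_points <- as_xy_matrix(ref_points, "ref_points")
  mov_points <- as_xy_matrix(mov_points, "mov_points")
  if (nrow(ref_points) != nrow(mov_points)) {
    stopf("ref_points and mov_points must have equal point counts")
  }
  structure(list(ref_points = ref_points, mov_points = mov_points),
            class = "keypoint_set")
}

as_xy_matrix <- function(p, what) {
  p <- as.matrix(p)
  if (length(p) == 0) p <- matrix(numeric(0), 0, 2)
  if (ncol(p) != 2) stopf("%s must be an Nx2 matrix", what)
  if (any(!is.finite(p))) stopf("%s must be finite", what)
  unname(p)
}

#' @export
print.keypoint_set <- function(x, ...) {
  cat(sprintf("<keypoint_set with %d landmark pairs>\n", nrow(x$ref_points)))
  invisible(x)
}

#' @export
length.keypoint_set <- function(x) nrow(x$ref_points)

rbf_kernel_fun <- function(kernel, scale = 1) {
  switch(kernel,
    "thin-plate" = function(r) {
      k <- r^2 * log(r)
      k[r == 0] <- 0
      k
    },
    "multiquadric" = function(r) sqrt(r^2 + scale^2),
    stopf("unknown RBF kernel '%s' (use 'thin-plate' or 'multiquadric')", kernel)
  )
}

#' Dense displacement field interpolating landmark pairs
#'
#' Solves a radial-basis-function interpolation problem (thin-plate spline by
#' default, multiquadric optionally), with an affine polynomial term, for each
#' displacement component `mov - ref`, and evaluates the resulting smooth
#' transformation at every pixel. The field interpolates exactly:
#' `phi(ref_i) = mov_i` at every landmark.
#'
#' @param kps a [keypoint_set()] with at least 3 pairwise-distinct reference points.
#' @param h,w output grid dimensions in pixels.
#' @param kernel `"thin-plate"` (default) or `"multiquadric"`.
#' @return a [displacement_field()].
#' @export
from_keypoints <- function(kps, h, w, kernel = c("thin-plate", "multiquadric")) {
  kernel <- match.arg(kernel)
  n <- nrow(kps$ref_points)
  if (n < 3) stopf("at least 3 landmark pairs are required, got %d", n)
  P <- kps$ref_points
  D2 <- as.matrix(stats::dist(P))
  if (any(D2[upper.tri(D2)] < 1e-9)) {
    stopf("coincident reference points make the RBF system singular")
  }
  scale <- mean(apply(D2 + diag(Inf, n), 1, min))  # mean nearest-neighbour gap
  kf <- rbf_kernel_fun(kernel, scale)
  K <- kf(D2)
  Pol <- cbind(1, P)
  A <- rbind(cbind(K, Pol), cbind(t(Pol), matrix(0, 3, 3)))
  disp <- kps$mov_points - kps$ref_points
  rhs <- rbind(disp, matrix(0, 3, 2))
  coef <- tryCatch(solve(A, rhs), error = function(e) {
    stopf("RBF system is singular: %s", conditionMessage(e))
  })
  g <- coord_grids(h, w)
  q <- cbind(as.vector(g$X), as.vector(g$Y))
  # kernel matrix grid-points x landmarks, built without forming a cross dist object
  G <- kf(sqrt(outer(q[, 1], P[, 1], "-")^2 + outer(q[, 2], P[, 2], "-")^2))
  vals <- G %*% coef[1:n, , drop = FALSE] +
    cbind(1, q) %*% coef[(n + 1):(n + 3), , drop = FALSE]
  displacement_field(matrix(vals[, 1], h, w), matrix(vals[, 2], h, w))
}
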