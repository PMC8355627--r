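#' Image error between two same-modality images
#'
#' Mean squared pixel difference between the ground-truth registered image
#' and the predicted one. The mean (rather than the plain squared L2 norm)
#' makes the term resolution-independent and commensurate with the other
#' loss terms, which is required for an unweighted sum to be meaningful.
#'
#' @param i_true,i_pred [image2d()]s of identical shape.
#' @return a non-negative scalar.
#' @export
image_error <- function(i_true, i_pred) {
  check_same_shape(nrow(i_true), ncol(i_true), nrow(i_pred), ncol(i_pred),
                   "images")
  mean((unclass(i_true) - unclass(i_pred))^2)
}

#' Normalized squared average endpoint error
#'
#' The optical-flow endpoint error in its squared, normalized form: the
#' per-pixel Euclidean distances between true and predicted displacement
#' vectors are averaged over the grid, divided by the normalizer `t` (the
#' training-set mean displacement magnitude), and the result is squared.
#' A constant displacement error of magnitude `d` therefore yields exactly
#' `(d / t)^2`.
#'
#' @param u_true,u_pred [displacement_field()]s of identical shape.
#' @param t positive normalizer in pixels.
#' @return a non-negative scalar.
#' @export
endpoint_error <- function(u_true, u_pred, t) {
  if (t <= 0) stopf("the normalizer t must be positive")
  check_same_shape(field_h(u_true), field_w(u_true),
                   field_h(u_pred), field_w(u_pred), "fields")
  s <- sum(sqrt((u_true$dx - u_pred$dx)^2 + (u_true$dy - u_pred$dy)^2))
  (s / (length(u_true$dx) * t))^2
}

#' Perceptual similarity loss on displacement-field components
#'
#' Treats the x and y components of each field as images: each component is
#' rescaled by the backbone's `input_scale`, clamped, replicated to the
#' backbone's input channels and passed through the feature extractor.
#' Per-layer features are channel-unit-normalized; squared differences are
#' weighted by the layer weights and averaged spatially, then summed over
#' layers. The returned value is the sum of the dx-pair and dy-pair
#' distances. The distance is symmetric in its two field arguments and zero
#' iff the fields are equal.
#'
#' @param u_true,u_pred [displacement_field()]s of identical shape (at least
#'   32x32 pixels).
#' @param backbone a [perceptual_backbone()].
#' @return a non-negative scalar.
#' @export
perceptual_field_loss <- function(u_true, u_pred, backbone) {
  h <- field_h(u_true); w <- field_w(u_true)
  check_same_shape(h, w, field_h(u_pred), field_w(u_pred), "fields")
  check_backbone_size(h, w)
  d <- 0
  for (comp in c("dx", "dy")) {
    f1 <- backbone_fwd(backbone, u_true[[comp]])
    f2 <- backbone_fwd(backbone, u_pred[[comp]])
    d <- d + backbone_distance(backbone, f1, f2)
  }
  d
}

new_loss_report <- function(image_error, endpoint_error, perceptual,
                            endpoint_error_inverse, perceptual_inverse, t) {
  structure(list(
    image_error = image_error,
    endpoint_error = endpoint_error,
    perceptual = perceptual,
    endpoint_error_inverse = endpoint_error_inverse,
    perceptual_inverse = perceptual_inverse,
    total = image_error + endpoint_error + endpoint_error_inverse +
      perceptual + perceptual_inverse,
    T = t), class = "loss_report")
}

#' @export
print.loss_report <- function(x, ...) {
  cat(sprintf(paste0("<loss_report total=%.4f | IE=%.4f EPE=%.4f+%.4f ",
                     "LPIPS=%.4f+%.4f, T=%.1f px>\n"),
              x$total, x$image_error, x$endpoint_error,
              x$endpoint_error_inverse, x$perceptual, x$perceptual_inverse,
              x$T))
  invisible(x)
}

#' Full supervised registration loss
#'
#' Computes the three-term training loss on a sample: the image error between
#' the ground-truth registered image and the predicted one, plus the
#' normalized squared endpoint error and the perceptual field loss — each of
#' the latter two in both directions (forward prediction against the ground
#' truth `u`, and the swapped-pair prediction against `u^{-1}`, computed
#' numerically by scattered data interpolation). The total is the unweighted
#' sum of all five components.
#'
#' @param sample a `registration_sample` with a folding-free truth.
#' @param u_pred predicted forward field (moving-to-reference registration).
#' @param u_pred_inverse predicted reverse field.
#' @param backbone a [perceptual_backbone()].
#' @param t positive normalizer in pixels.
#' @param truth_inverse optional precomputed `invert_field(sample$truth)`;
#'   pass it when evaluating many predictions on one sample to avoid
#'   recomputing the numerical inverse.
#' @return a `loss_report`.
#' @export
total_loss <- function(sample, u_pred, u_pred_inverse, backbone, t,
                       truth_inverse = NULL) {
  if (is.null(truth_inverse)) truth_inverse <- invert_field(sample$truth)
  i_reg <- warp_image(sample$moving, sample$truth)
  i_reg_hat <- warp_image(sample$moving, u_pred)
  new_loss_report(
    image_error = image_error(i_reg, i_reg_hat),
    endpoint_error = endpoint_error(sample$truth, u_pred, t),
    perceptual = perceptual_field_loss(sample$truth, u_pred, backbone),
    endpoint_error_inverse = endpoint_error(truth_inverse, u_pred_inverse, t),
    perceptual_inverse = perceptual_field_loss(truth_inverse, u_pred_inverse,
                                               backbone),
    t = t)
}
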