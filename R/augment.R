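#' Augmentation configuration
#'
#' Parameters for the two augmentation families: photometric (blur,
#' brightness, gamma, additive noise — geometry untouched) and geometric
#' (a smooth elastic warp `psi` interpolated from perturbed edge control
#' points, with the ground truth updated so training labels stay consistent).
#'
#' @param n_control_points number of edge control points for the elastic warp.
#' @param max_control_displacement maximum per-coordinate control-point
#'   perturbation in pixels; `NULL` defaults to 8% of the smaller image side
#'   at use time. Must not exceed 15% of the smaller side (folded warps are
#'   rejected and resampled, and beyond that bound rejection dominates).
#' @param blur_sigma_range range of the Gaussian blur sigma in pixels.
#' @param brightness_delta_range range of the additive brightness shift.
#' @param gamma_range range of the gamma-correction exponent.
#' @param noise_sigma standard deviation of additive Gaussian noise.
#' @param seed integer seed.
#' @return an `augment_config` object.
#' @export
augment_config <- function(n_control_points = 8L,
                           max_control_displacement = NULL,
                           blur_sigma_range = c(0.5, 1.5),
                           brightness_delta_range = c(-0.15, 0.15),
                           gamma_range = c(0.7, 1.4),
                           noise_sigma = 0.02,
                           seed = 1L) {
  structure(list(n_control_points = as.integer(n_control_points),
                 max_control_displacement = max_control_displacement,
                 blur_sigma_range = blur_sigma_range,
                 brightness_delta_range = brightness_delta_range,
                 gamma_range = gamma_range,
                 noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "augment_config")
}

#' Photometric augmentation of an image
#'
#' Applies, each with independent probability 1/2: Gaussian blur, an additive
#' brightness shift, gamma correction, and additive Gaussian noise. The
#' output is clipped to `[0, 1]`. Spatial content is never moved, so the
#' ground-truth deformation of a sample is unchanged by this augmentation.
#'
#' @param img an [image2d()].
#' @param cfg an [augment_config()].
#' @return an [image2d()].
#' @export
intensity_augment <- function(img, cfg) {
  m <- as_matrix(img)
  with_seed(cfg$seed, {
    if (runif(1) < 0.5) {
      sigma <- runif(1, cfg$blur_sigma_range[1], cfg$blur_sigma_range[2])
      m <- gaussian_blur(m, sigma)
    }
    if (runif(1) < 0.5) {
      m <- m + runif(1, cfg$brightness_delta_range[1], cfg$brightness_delta_range[2])
    }
    if (runif(1) < 0.5) {
      gam <- runif(1, cfg$gamma_range[1], cfg$gamma_range[2])
      m <- clamp(m, 0, 1)^gam
    }
    if (runif(1) < 0.5 && cfg$noise_sigma > 0) {
      m <- m + matrix(rnorm(length(m), 0, cfg$noise_sigma), nrow(m), ncol(m))
    }
  })
  image2d(clamp(m, 0, 1))
}

#' Geometric (elastic) augmentation of a registration sample
#'
#' Samples control points on the section boundary of the moving image,
#' perturbs them by up to `max_control_displacement` pixels, interpolates the
#' perturbations into a smooth warp `psi` with radial basis functions, and
#' returns the sample with `moving' = moving o psi` and
#' `truth' = psi^{-1} o truth` (composition evaluated as
#' `phi_first(phi_second(p))`). This choice makes the warp-consistency
#' identity hold: warping the augmented moving image by the augmented truth
#' reproduces the original registered image. Folded warps (or augmented
#' truths) are rejected and resampled a bounded number of times.
#'
#' @param sample a `registration_sample`.
#' @param cfg an [augment_config()].
#' @return a `registration_sample`.
#' @export
geometric_augment <- function(sample, cfg) {
  h <- nrow(sample$moving); w <- ncol(sample$moving)
  mcd <- cfg$max_control_displacement
  if (is.null(mcd)) mcd <- 0.08 * min(h, w)
  if (mcd > 0.15 * min(h, w)) {
    stopf("max_control_displacement %.1f exceeds 15%% of the smaller side (%d)",
          mcd, min(h, w))
  }
  if (mcd == 0) return(sample)
  with_seed(cfg$seed, {
    for (attempt in 1:10) {
      kps <- extract_edge_control_points(sample$moving, cfg$n_control_points,
                                         seed = floor(runif(1, 0, 2^30)))
      if (length(kps) < 3) {
        stopf("not enough edge control points for geometric augmentation")
      }
      kps$mov_points <- kps$ref_points +
        matrix(runif(2 * length(kps), -mcd, mcd), ncol = 2)
      psi <- from_keypoints(kps, h, w)
      if (corrupted_fraction(psi) > 0) next
      truth2 <- compose_fields(invert_field(psi), sample$truth)
      if (corrupted_fraction(truth2) > 0) next
      moving2 <- warp_image(sample$moving, psi)
      return(new_registration_sample(sample$reference, moving2, truth2,
                                     sample$meta))
    }
    stopf("geometric augmentation failed to produce a folding-free warp")
  })
}
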