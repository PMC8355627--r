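#' Perceptual feature backbone for field similarity
#'
#' The perceptual loss treats the x and y components of a displacement field
#' as images, passes them through a convolutional feature extractor, and
#' compares channel-unit-normalized activations layer by layer. Two backbone
#' flavours exist:
#'
#' * `"fixed-seed-random-conv"` (default): a small convolutional stack whose
#'   weights are drawn once from `seed` and then frozen. Random convolutional
#'   features are known to yield usable perceptual distances, and this
#'   backbone is fully reproducible offline.
#' * `"pretrained-vgg-lin"`: the classical VGG-based configuration. It
#'   requires externally supplied weights (a directory of NPY files named
#'   `convN_W.npy` / `convN_b.npy` matching the same stack layout); without
#'   them construction fails with an informative error.
#'
#' @param name backbone flavour.
#' @param layer_weights non-negative per-layer weights; at least one must be
#'   positive.
#' @param input_scale divisor mapping pixel displacements into the network's
#'   input range before clamping to `[-3, 3]`; typically the dataset's mean
#'   displacement `T`.
#' @param channels convolution widths of the random backbone.
#' @param norm_eps floor inside the channel-normalization square root. It
#'   damps the normalized features where activation norms are tiny (flat
#'   field regions), so the distance between two nearly identical smooth
#'   fields vanishes instead of being dominated by amplified
#'   micro-differences.
#' @param seed seed for the frozen random weights.
#' @param weights_dir directory of NPY weights for `"pretrained-vgg-lin"`.
#' @return a `perceptual_backbone` object.
#' @export
perceptual_backbone <- function(name = c("fixed-seed-random-conv",
                                         "pretrained-vgg-lin"),
                                layer_weights = NULL,
                                input_scale = 20,
                                channels = c(8, 16, 16),
                                norm_eps = 0.1,
                                seed = 7L,
                                weights_dir = NULL) {
  name <- match.arg(name)
  n_layers <- length(channels)
  if (is.null(layer_weights)) layer_weights <- rep(1, n_layers)
  if (length(layer_weights) != n_layers || any(layer_weights < 0) ||
      !any(layer_weights > 0)) {
    stopf("layer_weights must be %d non-negative values with at least one positive",
          n_layers)
  }
  convs <- vector("list", n_layers)
  if (name == "fixed-seed-random-conv") {
    with_seed(seed, {
      cin <- 3L
      for (i in seq_len(n_layers)) {
        cv <- new_conv(cin, channels[i], stride = 1L)
        # zero-mean filters: random band-pass/edge detectors that respond to
        # local structure rather than local intensity level, mimicking the
        # texture sensitivity of trained perceptual features
        Wk <- cv$W
        dim(Wk) <- c(9L, cin, channels[i])
        Wk <- sweep(Wk, c(2, 3), colMeans(Wk))
        dim(Wk) <- c(9L * cin, channels[i])
        cv$W <- Wk
        convs[[i]] <- cv
        cin <- channels[i]
      }
    })
  } else {
    if (is.null(weights_dir) || !dir.exists(weights_dir)) {
      stopf(paste("the pretrained-vgg-lin backbone needs a weights_dir of NPY",
                  "files (convN_W.npy / convN_b.npy); none was supplied.",
                  "Use the fixed-seed-random-conv backbone for a",
                  "download-free setup."))
    }
    cin <- 3L
    for (i in seq_len(n_layers)) {
      W <- read_npy(file.path(weights_dir, sprintf("conv%d_W.npy", i)))
      b <- read_npy(file.path(weights_dir, sprintf("conv%d_b.npy", i)))
      convs[[i]] <- list(type = "conv", W = matrix(W, 9 * cin, channels[i]),
                         b = as.numeric(b), cin = cin, cout = channels[i],
                         stride = 1L)
      cin <- channels[i]
    }
  }
  structure(list(name = name, convs = convs, layer_weights = layer_weights,
                 input_scale = input_scale, norm_eps = norm_eps,
                 seed = as.integer(seed)),
            class = "perceptual_backbone")
}

#' @export
print.perceptual_backbone <- function(x, ...) {
  cat(sprintf("<perceptual_backbone %s, %d layers, input_scale %.1f>\n",
              x$name, length(x$convs), x$input_scale))
  invisible(x)
}

# Forward pass of one scaled component image; returns the channel-normalized
# features of every tap layer plus the caches needed for the backward pass.
backbone_fwd <- function(backbone, comp) {
  h <- nrow(comp); w <- ncol(comp)
  z <- clamp(comp / backbone$input_scale, -3, 3)
  mask <- abs(comp / backbone$input_scale) < 3
  x <- array(rep(z, 3), c(h, w, 3))
  feats <- list(); caches <- list()
  for (i in seq_along(backbone$convs)) {
    cv <- conv_fwd(backbone$convs[[i]], x)
    rl <- relu_fwd(cv$out)
    dd <- dim(rl$out)
    eps <- if (is.null(backbone$norm_eps)) 0.1 else backbone$norm_eps
    nrmc <- matrix(sqrt(rowSums(matrix(rl$out^2, dd[1] * dd[2], dd[3])) + eps^2),
                   dd[1], dd[2])
    nf <- rl$out / as.vector(nrmc)
    feats[[i]] <- nf
    caches[[i]] <- list(conv = cv$cache, relu = rl$cache, act = rl$out,
                        nrm = nrmc, nf = nf)
    if (i < length(backbone$convs)) {
      pl <- avgpool2_fwd(rl$out)
      caches[[i]]$pool <- pl$cache
      x <- pl$out
    }
  }
  list(feats = feats, caches = caches, mask = mask)
}

# Gradient of the LPIPS-style distance with respect to the *second* input
# component, given both forward passes.
backbone_bwd <- function(backbone, fwd1, fwd2) {
  n_layers <- length(backbone$convs)
  dx_carry <- NULL
  for (i in n_layers:1) {
    c2 <- fwd2$caches[[i]]
    hw <- prod(dim(c2$nf)[1:2])
    # distance term at this layer: w_i * mean_xy sum_c (n1 - n2)^2
    dnf <- -2 * backbone$layer_weights[i] *
      (fwd1$caches[[i]]$nf - c2$nf) / hw
    # back through channel unit-normalization: (I - n n^T) / |f|
    dd <- dim(c2$nf)
    dot <- rowSums(matrix(dnf * c2$nf, dd[1] * dd[2], dd[3]))
    dact_norm <- (dnf - c2$nf * dot) / as.vector(c2$nrm)
    dact <- dact_norm
    if (!is.null(dx_carry)) dact <- dact + dx_carry
    drelu <- relu_bwd(c2$relu, dact)
    dx <- conv_bwd(backbone$convs[[i]], c2$conv, drelu)$dx
    if (i > 1) {
      dx_carry <- avgpool2_bwd(fwd2$caches[[i - 1]]$pool, dx)
    } else {
      dx_carry <- dx
    }
  }
  dz <- dx_carry[, , 1] + dx_carry[, , 2] + dx_carry[, , 3]
  dz * fwd2$mask / backbone$input_scale
}

# Distance between two already-computed feature stacks.
backbone_distance <- function(backbone, fwd1, fwd2) {
  d <- 0
  for (i in seq_along(backbone$convs)) {
    df <- fwd1$feats[[i]] - fwd2$feats[[i]]
    hw <- prod(dim(df)[1:2])
    d <- d + backbone$layer_weights[i] * sum(df^2) / hw
  }
  d
}

check_backbone_size <- function(h, w) {
  if (h < 32 || w < 32) {
    stopf("perceptual loss requires fields of at least 32x32 pixels, got %dx%d",
          h, w)
  }
}
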