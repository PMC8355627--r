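#' Registration network configuration
#'
#' Architecture hyperparameters of the two-stage registration network: a
#' global module regressing six affine parameters from the stacked image
#' pair (spatial-transformer style: stride-2 convolutions, then dense
#' layers), and a local module predicting a dense elastic displacement from
#' the reference stacked with the globally aligned moving image (an
#' encoder-decoder with skip connections). Input sizes need not be divisible
#' by `2^depth`: the encoder halves with ceiling division and the decoder
#' crops after upsampling.
#'
#' @param input_shape integer `(H, W)`, both at least `2^depth` and >= 8.
#' @param global_conv_channels stride-2 convolution widths of the global
#'   module.
#' @param global_dense_units dense-layer widths of the global module (the
#'   final 6-parameter layer is implicit).
#' @param local_encoder_channels encoder widths (one per downsampling level).
#' @param local_decoder_channels decoder widths (`depth + 1` entries).
#' @param depth number of downsampling levels of the local module.
#' @param displacement_cap bound on each local displacement component in
#'   pixels (the flow output is `cap * tanh(z)`); default `0.35 * min(H, W)`.
#' @param offset_gain scale from the two raw translation outputs to pixels.
#' @param seed parameter-initialization seed.
#' @return a `model_config` object.
#' @export
model_config <- function(input_shape,
                         global_conv_channels = c(16, 32, 64, 128),
                         global_dense_units = c(128, 64),
                         local_encoder_channels = c(16, 32, 32, 32),
                         local_decoder_channels = c(32, 32, 32, 16, 16),
                         depth = length(local_encoder_channels),
                         displacement_cap = NULL,
                         offset_gain = 20,
                         seed = 1L) {
  input_shape <- as.integer(input_shape)
  if (length(input_shape) != 2 || any(input_shape < 8)) {
    stopf("input_shape must be (H, W) with both at least 8")
  }
  if (length(local_encoder_channels) != depth) {
    stopf("local_encoder_channels must have one entry per depth level (%d)", depth)
  }
  if (length(local_decoder_channels) != depth + 1) {
    stopf("local_decoder_channels must have depth + 1 = %d entries", depth + 1)
  }
  if (any(input_shape < 2^depth)) {
    stopf("input_shape %dx%d is too small for depth %d",
          input_shape[1], input_shape[2], depth)
  }
  if (is.null(displacement_cap)) displacement_cap <- 0.35 * min(input_shape)
  if (displacement_cap <= 0) stopf("displacement_cap must be positive")
  structure(list(input_shape = input_shape,
                 global_conv_channels = global_conv_channels,
                 global_dense_units = global_dense_units,
                 local_encoder_channels = local_encoder_channels,
                 local_decoder_channels = local_decoder_channels,
                 depth = as.integer(depth),
                 displacement_cap = displacement_cap,
                 offset_gain = offset_gain,
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Build the two-stage registration network
#'
#' Instantiates all trainable layers from a [model_config()], with
#' He-initialized weights drawn from the config seed. Use [init_identity()]
#' to make the untrained network predict the exact identity transformation.
#'
#' @param cfg a [model_config()].
#' @return a `registration_model`.
#' @export
build_model <- function(cfg) {
  h <- cfg$input_shape[1]; w <- cfg$input_shape[2]
  layers <- list()
  with_seed(cfg$seed, {
    cin <- 2L; hh <- h; ww <- w
    for (i in seq_along(cfg$global_conv_channels)) {
      layers[[paste0("gconv", i)]] <- new_conv(cin, cfg$global_conv_channels[i],
                                               stride = 2L)
      cin <- cfg$global_conv_channels[i]
      hh <- (hh - 1L) %/% 2L + 1L
      ww <- (ww - 1L) %/% 2L + 1L
    }
    flat <- hh * ww * cin
    nin <- flat
    for (j in seq_along(cfg$global_dense_units)) {
      layers[[paste0("gdense", j)]] <- new_dense(nin, cfg$global_dense_units[j])
      nin <- cfg$global_dense_units[j]
    }
    layers[["gfinal"]] <- new_dense(nin, 6L)

    d <- cfg$depth
    cin <- 2L
    skip_ch <- integer(d + 1)  # channels of x0, e1, ..., eD
    skip_ch[1] <- 2L
    for (i in seq_len(d)) {
      layers[[paste0("enc", i)]] <- new_conv(cin, cfg$local_encoder_channels[i],
                                             stride = 2L)
      cin <- cfg$local_encoder_channels[i]
      skip_ch[i + 1] <- cin
    }
    dch <- cfg$local_encoder_channels[d]
    for (i in seq_len(d)) {
      layers[[paste0("dec", i)]] <- new_conv(dch, cfg$local_decoder_channels[i],
                                             stride = 1L)
      dch <- cfg$local_decoder_channels[i] + skip_ch[d - i + 1]
    }
    layers[[paste0("dec", d + 1)]] <- new_conv(dch, cfg$local_decoder_channels[d + 1],
                                               stride = 1L)
    layers[["flow"]] <- new_conv(cfg$local_decoder_channels[d + 1], 2L,
                                 stride = 1L)
  })
  structure(list(cfg = cfg, layers = layers), class = "registration_model")
}

#' @export
print.registration_model <- function(x, ...) {
  cat(sprintf("<registration_model %dx%d, depth %d, %d parameters>\n",
              x$cfg$input_shape[1], x$cfg$input_shape[2], x$cfg$depth,
              count_parameters(x)))
  invisible(x)
}

#' Number of trainable parameters
#'
#' @param model a `registration_model`.
#' @return an integer count; a pure function of the configuration.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$layers, function(l) length(l$W) + length(l$b), numeric(1)))
}

#' Identity initialization
#'
#' Zeroes the final affine regression layer and the flow convolution so the
#' untrained network predicts exactly the identity transformation (standard
#' practice for registration networks: training starts from "do nothing").
#'
#' @param model a `registration_model`.
#' @return the modified model.
#' @export
init_identity <- function(model) {
  model$layers$gfinal$W[] <- 0
  model$layers$gfinal$b[] <- 0
  model$layers$flow$W[] <- 0
  model$layers$flow$b[] <- 0
  model
}

# Full forward pass. With train = TRUE every intermediate needed by
# model_backward() is kept.
forward_pass <- function(model, ref, mov, train = FALSE) {
  cfg <- model$cfg
  h <- cfg$input_shape[1]; w <- cfg$input_shape[2]
  check_same_shape(nrow(ref), ncol(ref), h, w, "reference image and model input")
  check_same_shape(nrow(mov), ncol(mov), h, w, "moving image and model input")
  ref <- as_matrix(ref); mov <- as_matrix(mov)
  L <- model$layers
  fw <- list(gconv = list(), enc = list(), dec = list())

  # ---- global module ----
  x <- array(c(ref, mov), c(h, w, 2))
  for (i in seq_along(cfg$global_conv_channels)) {
    cv <- conv_fwd(L[[paste0("gconv", i)]], x)
    rl <- lrelu_fwd(cv$out)
    if (train) fw$gconv[[i]] <- list(conv = cv$cache, relu = rl$cache)
    x <- rl$out
  }
  flat_dim <- dim(x)
  v <- as.vector(x)
  fw$gdense <- list()
  for (j in seq_along(cfg$global_dense_units)) {
    dn <- dense_fwd(L[[paste0("gdense", j)]], v)
    rl <- lrelu_fwd(dn$out)
    if (train) fw$gdense[[j]] <- list(dense = dn$cache, relu = rl$cache)
    v <- rl$out
  }
  fin <- dense_fwd(L$gfinal, v)
  p <- fin$out
  if (train) fw$gfinal_cache <- fin$cache
  A <- matrix(c(1 + p[1], p[2], p[3], 1 + p[4]), 2, 2)
  off <- c(p[5], p[6]) * cfg$offset_gain

  g <- coord_grids(h, w)
  ugx <- (A[1, 1] - 1) * g$X + A[1, 2] * g$Y + off[1]
  ugy <- A[2, 1] * g$X + (A[2, 2] - 1) * g$Y + off[2]

  # globally aligned moving image feeds the local module
  wf <- warp_fwd(mov, ugx, ugy)
  mov_al <- wf$out

  # ---- local module (encoder-decoder with skips) ----
  x0 <- array(c(ref, mov_al), c(h, w, 2))
  skips <- list(x0)
  x <- x0
  for (i in seq_len(cfg$depth)) {
    cv <- conv_fwd(L[[paste0("enc", i)]], x)
    rl <- lrelu_fwd(cv$out)
    if (train) fw$enc[[i]] <- list(conv = cv$cache, relu = rl$cache)
    x <- rl$out
    skips[[i + 1]] <- x
  }
  for (i in seq_len(cfg$depth)) {
    cv <- conv_fwd(L[[paste0("dec", i)]], x)
    rl <- lrelu_fwd(cv$out)
    skip <- skips[[cfg$depth - i + 1]]
    up <- up2_fwd(rl$out, dim(skip)[1], dim(skip)[2])
    if (train) {
      fw$dec[[i]] <- list(conv = cv$cache, relu = rl$cache, up = up$cache,
                          nch = dim(rl$out)[3], skip_ch = dim(skip)[3])
    }
    x <- array(c(up$out, skip), c(dim(skip)[1], dim(skip)[2],
                                  dim(rl$out)[3] + dim(skip)[3]))
  }
  cv <- conv_fwd(L[[paste0("dec", cfg$depth + 1)]], x)
  rl <- lrelu_fwd(cv$out)
  if (train) fw$dec[[cfg$depth + 1]] <- list(conv = cv$cache, relu = rl$cache)
  fl <- conv_fwd(L$flow, rl$out)
  th <- tanh(fl$out)
  ul_dx <- cfg$displacement_cap * th[, , 1]
  ul_dy <- cfg$displacement_cap * th[, , 2]

  # ---- composition: phi_hat = phi_global o phi_local ----
  sx <- g$X + ul_dx; sy <- g$Y + ul_dy
  csx <- grid_sample_fwd(ugx, sx, sy)
  csy <- grid_sample_fwd(ugy, sx, sy)
  cdx <- matrix(csx$out, h, w) + ul_dx
  cdy <- matrix(csy$out, h, w) + ul_dy

  wr <- warp_fwd(mov, cdx, cdy)

  out <- list(p = p, A = A, off = off, ugx = ugx, ugy = ugy,
              ul_dx = ul_dx, ul_dy = ul_dy, cdx = cdx, cdy = cdy,
              registered = wr$out, mov_al = mov_al)
  if (train) {
    out$fw <- fw
    out$flow_cache <- fl$cache
    out$th <- th
    out$csx <- csx; out$csy <- csy
    out$wf_cache <- wf$cache
    out$wr_cache <- wr$cache
    out$flat_dim <- flat_dim
    out$grids <- g
  }
  out
}

zero_grads <- function(model) {
  lapply(model$layers, function(l) list(W = l$W * 0, b = l$b * 0))
}

add_grads <- function(a, b) {
  for (nm in names(b)) {
    a[[nm]]$W <- a[[nm]]$W + b[[nm]]$W
    a[[nm]]$b <- a[[nm]]$b + b[[nm]]$b
  }
  a
}

scale_grads <- function(a, s) {
  lapply(a, function(g) list(W = g$W * s, b = g$b * s))
}

# Backward pass through the whole network. d_cdx / d_cdy are gradients of the
# loss with respect to the combined displacement components; d_reg (optional)
# with respect to the registered image.
model_backward <- function(model, pass, d_cdx, d_cdy, d_reg = NULL) {
  cfg <- model$cfg
  h <- cfg$input_shape[1]; w <- cfg$input_shape[2]
  L <- model$layers
  fw <- pass$fw
  grads <- zero_grads(model)

  if (!is.null(d_reg)) {
    wb <- warp_bwd(pass$wr_cache, d_reg)
    d_cdx <- d_cdx + wb$ddx
    d_cdy <- d_cdy + wb$ddy
  }

  # composition backward
  gxx <- matrix(pass$csx$gx, h, w); gxy <- matrix(pass$csx$gy, h, w)
  gyx <- matrix(pass$csy$gx, h, w); gyy <- matrix(pass$csy$gy, h, w)
  d_ul_dx <- d_cdx * (gxx + 1) + d_cdy * gyx
  d_ul_dy <- d_cdx * gxy + d_cdy * (gyy + 1)
  d_ugx <- grid_sample_bwd_grid(pass$csx$cache, as.vector(d_cdx))
  d_ugy <- grid_sample_bwd_grid(pass$csy$cache, as.vector(d_cdy))

  # local flow backward (tanh * cap)
  dth1 <- d_ul_dx * cfg$displacement_cap
  dth2 <- d_ul_dy * cfg$displacement_cap
  dz <- array(0, dim(pass$th))
  dz[, , 1] <- dth1 * (1 - pass$th[, , 1]^2)
  dz[, , 2] <- dth2 * (1 - pass$th[, , 2]^2)

  bl <- conv_bwd(L$flow, pass$flow_cache, dz)
  grads$flow <- list(W = bl$dW, b = bl$db)
  dx <- bl$dx

  dd <- fw$dec[[cfg$depth + 1]]
  dx <- lrelu_bwd(dd$relu, dx)
  bl <- conv_bwd(L[[paste0("dec", cfg$depth + 1)]], dd$conv, dx)
  grads[[paste0("dec", cfg$depth + 1)]] <- list(W = bl$dW, b = bl$db)
  dx <- bl$dx

  d_skips <- vector("list", cfg$depth + 1)  # gradients flowing into skips
  for (i in cfg$depth:1) {
    dd <- fw$dec[[i]]
    nch <- dd$nch
    d_up <- dx[, , seq_len(nch), drop = FALSE]
    d_skips[[cfg$depth - i + 1]] <- dx[, , nch + seq_len(dd$skip_ch), drop = FALSE]
    dx <- up2_bwd(dd$up, d_up)
    dx <- lrelu_bwd(dd$relu, dx)
    bl <- conv_bwd(L[[paste0("dec", i)]], dd$conv, dx)
    grads[[paste0("dec", i)]] <- list(W = bl$dW, b = bl$db)
    dx <- bl$dx
  }

  # encoder backward, merging decoder skip gradients (e_i is skips[[i + 1]])
  for (i in cfg$depth:1) {
    if (i + 1 <= length(d_skips) && !is.null(d_skips[[i + 1]])) {
      dx <- dx + d_skips[[i + 1]]
    }
    dx <- lrelu_bwd(fw$enc[[i]]$relu, dx)
    bl <- conv_bwd(L[[paste0("enc", i)]], fw$enc[[i]]$conv, dx)
    grads[[paste0("enc", i)]] <- list(W = bl$dW, b = bl$db)
    dx <- bl$dx
  }
  d_x0 <- dx
  if (!is.null(d_skips[[1]])) d_x0 <- d_x0 + d_skips[[1]]
  d_mov_al <- d_x0[, , 2]

  # globally-aligned warp backward adds to the global field gradient
  wb <- warp_bwd(pass$wf_cache, d_mov_al)
  d_ugx <- d_ugx + wb$ddx
  d_ugy <- d_ugy + wb$ddy

  # affine parameter gradients from the dense global-field gradient
  g <- pass$grids
  dp <- c(sum(d_ugx * g$X), sum(d_ugy * g$X),
          sum(d_ugx * g$Y), sum(d_ugy * g$Y),
          sum(d_ugx) * cfg$offset_gain, sum(d_ugy) * cfg$offset_gain)

  bl <- dense_bwd(L$gfinal, fw$gfinal_cache, dp)
  grads$gfinal <- list(W = bl$dW, b = bl$db)
  dv <- bl$dx
  for (j in rev(seq_along(cfg$global_dense_units))) {
    dv <- lrelu_bwd(fw$gdense[[j]]$relu, dv)
    bl <- dense_bwd(L[[paste0("gdense", j)]], fw$gdense[[j]]$dense, dv)
    grads[[paste0("gdense", j)]] <- list(W = bl$dW, b = bl$db)
    dv <- bl$dx
  }
  dx <- array(dv, pass$flat_dim)
  for (i in rev(seq_along(cfg$global_conv_channels))) {
    dx <- lrelu_bwd(fw$gconv[[i]]$relu, dx)
    bl <- conv_bwd(L[[paste0("gconv", i)]], fw$gconv[[i]]$conv, dx)
    grads[[paste0("gconv", i)]] <- list(W = bl$dW, b = bl$db)
    dx <- bl$dx
  }
  grads
}

#' Register a moving image to a reference
#'
#' Runs the network forward and returns the predicted affine map, the global
#' and local displacement fields, their composition, and the registered
#' moving image. Deterministic: two calls on the same inputs are
#' bit-identical.
#'
#' @param model a `registration_model`.
#' @param reference,moving [image2d()]s matching the configured input shape.
#' @return a `registration_output` with elements `affine`, `global_field`,
#'   `local_field`, `combined_field`, `registered`.
#' @export
forward <- function(model, reference, moving) {
  pass <- forward_pass(model, reference, moving, train = FALSE)
  h <- model$cfg$input_shape[1]; w <- model$cfg$input_shape[2]
  structure(list(
    affine = affine_map(pass$A, pass$off),
    global_field = displacement_field(pass$ugx, pass$ugy),
    local_field = displacement_field(pass$ul_dx, pass$ul_dy),
    combined_field = displacement_field(pass$cdx, pass$cdy),
    registered = image2d(clamp(pass$registered, 0, 1))
  ), class = "registration_output")
}

#' @export
print.registration_output <- function(x, ...) {
  cat(sprintf("<registration_output: affine det %.3f, max |u_local| %.2f px, corrupted %.2f%%>\n",
              affine_det(x$affine),
              max(abs(x$local_field$dx), abs(x$local_field$dy)),
              100 * corrupted_fraction(x$combined_field)))
  invisible(x)
}

#' Bidirectional registration
#'
#' Applies the network to the pair and to the swapped pair. The second
#' output's combined field registers the reference to the moving image and
#' serves as the predicted inverse transformation in the bidirectional loss.
#'
#' @inheritParams forward
#' @return a list with elements `forward` and `backward`, both
#'   `registration_output`s.
#' @export
forward_bidirectional <- function(model, reference, moving) {
  list(forward = forward(model, reference, moving),
       backward = forward(model, moving, reference))
}
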