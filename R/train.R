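#' Training configuration
#'
#' Optimization hyperparameters for supervised training: RMSProp with
#' learning rate 1e-3, forgetting factor 0.9 and batch size 4 by default.
#' The endpoint-error normalizer `t_normalizer` defaults to the mean
#' displacement magnitude of the training ground truths.
#'
#' @param steps number of minibatch steps.
#' @param learning_rate RMSProp learning rate (> 0).
#' @param forgetting_factor RMSProp forgetting factor in (0, 1).
#' @param batch_size minibatch size (>= 1).
#' @param t_normalizer endpoint-error normalizer in pixels; `NULL` computes
#'   it from the training ground truths.
#' @param augment an [augment_config()] enabling on-the-fly augmentation
#'   (photometric always a candidate, elastic with probability 1/2), or
#'   `NULL` for none.
#' @param loss_weights named weights for `image_error`, `endpoint_error` and
#'   `perceptual`; a zero weight removes the term (used for loss ablations).
#' @param freeze_local if `TRUE` the local module's parameters are not
#'   updated (affine-only training).
#' @param backbone a [perceptual_backbone()], or `NULL` to build the default
#'   fixed-seed backbone with `input_scale = t_normalizer`.
#' @param seed integer seed controlling batch order and augmentation.
#' @return a `train_config` object.
#' @export
train_config <- function(steps = 100L,
                         learning_rate = 1e-3,
                         forgetting_factor = 0.9,
                         batch_size = 4L,
                         t_normalizer = NULL,
                         augment = NULL,
                         loss_weights = c(image_error = 1, endpoint_error = 1,
                                          perceptual = 1),
                         freeze_local = FALSE,
                         backbone = NULL,
                         seed = 1L) {
  if (learning_rate <= 0) stopf("learning_rate must be positive")
  if (forgetting_factor <= 0 || forgetting_factor >= 1) {
    stopf("forgetting_factor must lie strictly between 0 and 1")
  }
  if (batch_size < 1) stopf("batch_size must be at least 1")
  lw <- c(image_error = 1, endpoint_error = 1, perceptual = 1)
  lw[names(loss_weights)] <- loss_weights
  structure(list(steps = as.integer(steps), learning_rate = learning_rate,
                 forgetting_factor = forgetting_factor,
                 batch_size = as.integer(batch_size),
                 t_normalizer = t_normalizer, augment = augment,
                 loss_weights = lw, freeze_local = isTRUE(freeze_local),
                 backbone = backbone, seed = as.integer(seed)),
            class = "train_config")
}

# Per-sample fixed quantities reused across steps.
prepare_sample <- function(sample, backbone, use_perceptual) {
  u_inv <- invert_field(sample$truth)
  prep <- list(sample = sample,
               i_reg = as_matrix(warp_image(sample$moving, sample$truth)),
               u_inv = u_inv)
  if (use_perceptual) {
    prep$bb_truth <- list(dx = backbone_fwd(backbone, sample$truth$dx),
                          dy = backbone_fwd(backbone, sample$truth$dy))
    prep$bb_inv <- list(dx = backbone_fwd(backbone, u_inv$dx),
                        dy = backbone_fwd(backbone, u_inv$dy))
  }
  prep
}

# Loss components and combined-field/registered-image gradients for one
# direction of one sample.
direction_loss <- function(pass, u_true, bb_true, backbone, t, lw,
                           i_reg = NULL) {
  h <- nrow(pass$cdx); w <- ncol(pass$cdx)
  n <- h * w
  out <- list(image_error = 0, endpoint_error = 0, perceptual = 0,
              d_cdx = matrix(0, h, w), d_cdy = matrix(0, h, w), d_reg = NULL)

  ddx <- pass$cdx - u_true$dx
  ddy <- pass$cdy - u_true$dy
  nrm <- sqrt(ddx^2 + ddy^2)
  s <- sum(nrm)
  out$endpoint_error <- (s / (n * t))^2
  if (lw[["endpoint_error"]] > 0) {
    coef <- lw[["endpoint_error"]] * 2 * s / (n * t)^2
    inv_nrm <- 1 / pmax(nrm, 1e-12)
    out$d_cdx <- out$d_cdx + coef * ddx * inv_nrm
    out$d_cdy <- out$d_cdy + coef * ddy * inv_nrm
  }

  if (!is.null(i_reg)) {
    diff <- i_reg - pass$registered
    out$image_error <- mean(diff^2)
    if (lw[["image_error"]] > 0) {
      out$d_reg <- lw[["image_error"]] * (-2 / n) * diff
    }
  }

  if (lw[["perceptual"]] > 0) {
    fpx <- backbone_fwd(backbone, pass$cdx)
    fpy <- backbone_fwd(backbone, pass$cdy)
    out$perceptual <- backbone_distance(backbone, bb_true$dx, fpx) +
      backbone_distance(backbone, bb_true$dy, fpy)
    out$d_cdx <- out$d_cdx +
      lw[["perceptual"]] * backbone_bwd(backbone, bb_true$dx, fpx)
    out$d_cdy <- out$d_cdy +
      lw[["perceptual"]] * backbone_bwd(backbone, bb_true$dy, fpy)
  }
  out
}

#' Train a registration network
#'
#' Minibatch RMSProp on the bidirectional three-term loss. Each step samples
#' a batch, optionally augments each sample on the fly (photometric always a
#' candidate, elastic with probability 1/2), runs the network on the pair and
#' the swapped pair, and backpropagates the image error, the normalized
#' squared endpoint errors (forward and inverse) and the perceptual field
#' losses (forward and inverse).
#'
#' @param model a `registration_model` built for the samples' shape.
#' @param train_samples non-empty list of `registration_sample`s.
#' @param cfg a [train_config()].
#' @return a list with elements `model` (trained network) and `history`
#'   (tibble of per-step loss components, with attribute `t_normalizer`).
#' @export
train <- function(model, train_samples, cfg) {
  if (length(train_samples) == 0) stopf("training requires at least one sample")
  empty_history <- tibble::tibble(step = integer(), image_error = numeric(),
                                  endpoint_error = numeric(),
                                  perceptual = numeric(),
                                  endpoint_error_inverse = numeric(),
                                  perceptual_inverse = numeric(),
                                  total = numeric())
  t_norm <- cfg$t_normalizer
  if (is.null(t_norm)) {
    t_norm <- mean_displacement_norm(lapply(train_samples, `[[`, "truth"))
    if (t_norm <= 0) t_norm <- 1
  }
  if (cfg$steps == 0) {
    attr(empty_history, "t_normalizer") <- t_norm
    return(list(model = model, history = empty_history))
  }
  lw <- cfg$loss_weights
  use_perc <- lw[["perceptual"]] > 0
  backbone <- cfg$backbone
  if (is.null(backbone) && use_perc) {
    backbone <- perceptual_backbone(input_scale = t_norm)
  }
  preps <- lapply(train_samples, prepare_sample, backbone = backbone,
                  use_perceptual = use_perc)
  n <- length(train_samples)
  ms <- lapply(model$layers, function(l) list(W = l$W * 0, b = l$b * 0))
  frozen <- if (cfg$freeze_local) {
    grep("^(enc|dec|flow)", names(model$layers), value = TRUE)
  } else character(0)
  hist_rows <- vector("list", cfg$steps)

  with_seed(cfg$seed, {
    for (step in seq_len(cfg$steps)) {
      idx <- sample.int(n, cfg$batch_size, replace = cfg$batch_size > n)
      grads <- zero_grads(model)
      comp <- c(image_error = 0, endpoint_error = 0, perceptual = 0,
                endpoint_error_inverse = 0, perceptual_inverse = 0)
      for (k in idx) {
        prep <- preps[[k]]
        if (!is.null(cfg$augment)) {
          smp <- prep$sample
          acfg <- cfg$augment
          acfg$seed <- derive_seed(cfg$seed, step * 1000 + k, salt = 3L)
          if (runif(1) < 0.5) smp <- geometric_augment(smp, acfg)
          smp$moving <- intensity_augment(smp$moving, acfg)
          prep <- prepare_sample(smp, backbone, use_perc)
        }
        smp <- prep$sample
        p1 <- forward_pass(model, smp$reference, smp$moving, train = TRUE)
        p2 <- forward_pass(model, smp$moving, smp$reference, train = TRUE)
        l1 <- direction_loss(p1, smp$truth, prep$bb_truth, backbone, t_norm,
                             lw, i_reg = prep$i_reg)
        l2 <- direction_loss(p2, prep$u_inv, prep$bb_inv, backbone, t_norm, lw)
        grads <- add_grads(grads, model_backward(model, p1, l1$d_cdx, l1$d_cdy,
                                                 l1$d_reg))
        grads <- add_grads(grads, model_backward(model, p2, l2$d_cdx, l2$d_cdy))
        comp <- comp + c(l1$image_error, l1$endpoint_error, l1$perceptual,
                         l2$endpoint_error, l2$perceptual)
      }
      grads <- scale_grads(grads, 1 / cfg$batch_size)
      for (nm in names(model$layers)) {
        if (nm %in% frozen) next
        gW <- grads[[nm]]$W; gb <- grads[[nm]]$b
        ms[[nm]]$W <- cfg$forgetting_factor * ms[[nm]]$W +
          (1 - cfg$forgetting_factor) * gW^2
        ms[[nm]]$b <- cfg$forgetting_factor * ms[[nm]]$b +
          (1 - cfg$forgetting_factor) * gb^2
        model$layers[[nm]]$W <- model$layers[[nm]]$W -
          cfg$learning_rate * gW / (sqrt(ms[[nm]]$W) + 1e-8)
        model$layers[[nm]]$b <- model$layers[[nm]]$b -
          cfg$learning_rate * gb / (sqrt(ms[[nm]]$b) + 1e-8)
      }
      comp <- comp / cfg$batch_size
      hist_rows[[step]] <- tibble::tibble(
        step = step, image_error = comp[[1]], endpoint_error = comp[[2]],
        perceptual = comp[[3]], endpoint_error_inverse = comp[[4]],
        perceptual_inverse = comp[[5]], total = sum(comp))
    }
  })
  history <- do.call(rbind, hist_rows)
  attr(history, "t_normalizer") <- t_norm
  list(model = model, history = history)
}
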