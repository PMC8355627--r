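tiny_cfg <- function(h = 32L, w = 32L, seed = 5) {
  model_config(c(h, w), global_conv_channels = c(6, 8),
               global_dense_units = c(16),
               local_encoder_channels = c(6, 8),
               local_decoder_channels = c(8, 8, 6), depth = 2, seed = seed)
}

test_that("configuration invariants are enforced", {
  expect_error(model_config(c(4, 64)), "at least 8")
  expect_error(model_config(c(64, 64), local_encoder_channels = c(8, 8),
                            local_decoder_channels = c(8, 8), depth = 2),
               "depth \\+ 1")
  expect_error(model_config(c(8, 8), depth = 4,
                            local_encoder_channels = c(8, 8, 8, 8),
                            local_decoder_channels = c(8, 8, 8, 8, 8)),
               "too small")
  expect_error(model_config(c(64, 64), displacement_cap = 0,
                            local_encoder_channels = c(8, 8),
                            local_decoder_channels = c(8, 8, 8), depth = 2),
               "positive")
})

test_that("identity initialization predicts the exact identity transformation", {
  m <- init_identity(build_model(tiny_cfg()))
  ref <- rand_image(32, 32, seed = 1)
  mov <- rand_image(32, 32, seed = 2)
  out <- forward(m, ref, mov)
  expect_equal(out$affine$linear, diag(2))
  expect_equal(out$affine$offset, c(0, 0))
  expect_equal(max_abs_field_diff(out$local_field, identity_field(32, 32)), 0)
  expect_equal(max_abs_field_diff(out$combined_field, identity_field(32, 32)), 0)
  expect_equal(max(abs(out$registered - mov)), 0)
  expect_equal(corrupted_fraction(out$combined_field), 0)
})

test_that("forward outputs satisfy the composition and boundedness invariants", {
  m <- build_model(tiny_cfg(seed = 11))  # random weights, non-trivial output
  ref <- rand_image(32, 32, seed = 3)
  mov <- rand_image(32, 32, seed = 4)
  out <- forward(m, ref, mov)

  cap <- m$cfg$displacement_cap
  expect_lte(max(abs(out$local_field$dx)), cap)
  expect_lte(max(abs(out$local_field$dy)), cap)

  cc <- compose_fields(out$global_field, out$local_field)
  expect_equal(max_abs_field_diff(cc, out$combined_field), 0)

  expect_equal(max(abs(warp_image(mov, out$combined_field) - out$registered)), 0)

  out2 <- forward(m, ref, mov)
  expect_identical(out$combined_field$dx, out2$combined_field$dx)

  expect_error(forward(m, rand_image(16, 16, seed = 1), mov), "mismatch")
})

test_that("the model accepts shapes that are not divisible by 2^depth", {
  cfg <- model_config(c(36L, 52L), global_conv_channels = c(6, 8),
                      global_dense_units = c(16),
                      local_encoder_channels = c(6, 8),
                      local_decoder_channels = c(8, 8, 6), depth = 2, seed = 2)
  m <- init_identity(build_model(cfg))
  out <- forward(m, rand_image(36, 52, seed = 5), rand_image(36, 52, seed = 6))
  expect_equal(dim(out$combined_field), c(36L, 52L))
})

test_that("parameter count is a pure function of the configuration", {
  c1 <- count_parameters(build_model(tiny_cfg(seed = 1)))
  c2 <- count_parameters(build_model(tiny_cfg(seed = 99)))
  expect_identical(c1, c2)
  bigger <- tiny_cfg()
  bigger$global_dense_units <- c(32)
  expect_gt(count_parameters(build_model(bigger)), c1)
})

test_that("bidirectional forward swaps the roles of the images", {
  m <- init_identity(build_model(tiny_cfg()))
  ref <- rand_image(32, 32, seed = 7)
  mov <- rand_image(32, 32, seed = 8)
  both <- forward_bidirectional(m, ref, mov)
  expect_equal(max_abs_field_diff(both$forward$combined_field,
                                  identity_field(32, 32)), 0)
  expect_equal(max_abs_field_diff(both$backward$combined_field,
                                  identity_field(32, 32)), 0)

  mr <- build_model(tiny_cfg(seed = 13))
  sym <- forward_bidirectional(mr, ref, ref)
  expect_identical(sym$forward$combined_field$dx,
                   sym$backward$combined_field$dx)
})

test_that("analytic gradients of the full loss match finite differences", {
  set.seed(99)
  smp <- generate_section_pair(section_spec("SST", 250, seed = 12,
                                            shape = c(32L, 32L)))
  model <- build_model(tiny_cfg(seed = 5))
  model$layers$gfinal$W <- model$layers$gfinal$W * 0.01
  model$layers$flow$W <- model$layers$flow$W * 0.05
  # keep pre-activations off the (measure-positive) zero-background kink
  set.seed(7)
  for (nm in names(model$layers)) {
    model$layers[[nm]]$b <- rnorm(length(model$layers[[nm]]$b), 0, 0.05)
  }
  t_norm <- max(mean_displacement_norm(list(smp$truth)), 1)
  bb <- perceptual_backbone(input_scale = t_norm, seed = 11)
  # image error + endpoint errors only: the perceptual term's zero-mean
  # filters leave many ReLU pre-activations at the kink, where single finite
  # differences are meaningless (the backbone gradient has its own check)
  lw <- c(image_error = 1, endpoint_error = 1, perceptual = 0)
  prep <- sectionalign:::prepare_sample(smp, bb, TRUE)
  lag <- function(model, want = TRUE) {
    p1 <- sectionalign:::forward_pass(model, smp$reference, smp$moving, train = want)
    p2 <- sectionalign:::forward_pass(model, smp$moving, smp$reference, train = want)
    l1 <- sectionalign:::direction_loss(p1, smp$truth, prep$bb_truth, bb,
                                        t_norm, lw, i_reg = prep$i_reg)
    l2 <- sectionalign:::direction_loss(p2, prep$u_inv, prep$bb_inv, bb,
                                        t_norm, lw)
    tot <- l1$image_error + l1$endpoint_error + l1$perceptual +
      l2$endpoint_error + l2$perceptual
    if (!want) return(list(total = tot))
    list(total = tot, grads = sectionalign:::add_grads(
      sectionalign:::model_backward(model, p1, l1$d_cdx, l1$d_cdy, l1$d_reg),
      sectionalign:::model_backward(model, p2, l2$d_cdx, l2$d_cdy)))
  }
  base <- lag(model)
  expect_true(is.finite(base$total) && base$total > 0)
  eps <- 1e-5
  set.seed(3)
  checks <- list(c("gconv1", "W"), c("gconv1", "b"), c("gdense1", "W"),
                 c("gfinal", "b"), c("enc1", "W"), c("enc2", "b"),
                 c("dec1", "W"), c("dec3", "b"), c("flow", "W"), c("flow", "b"))
  rels <- c()
  for (tg in checks) {
    layer <- tg[1]; field <- tg[2]
    idx <- sample(length(model$layers[[layer]][[field]]), 1)
    m2 <- model
    m2$layers[[layer]][[field]][idx] <- m2$layers[[layer]][[field]][idx] + eps
    up <- lag(m2, FALSE)$total
    m2$layers[[layer]][[field]][idx] <- m2$layers[[layer]][[field]][idx] - 2 * eps
    dn <- lag(m2, FALSE)$total
    fd <- (up - dn) / (2 * eps)
    an <- base$grads[[layer]][[field]][idx]
    if (abs(fd) > 1e-6) {
      rels <- c(rels, abs(fd - an) / max(abs(fd), abs(an)))
    }
  }
  # the loss is only piecewise smooth (bilinear sampling, |.|), so single
  # finite differences may straddle a kink; demand agreement in the bulk and
  # boundedness everywhere
  expect_gte(mean(rels < 5e-3), 0.8)
  expect_lt(max(rels), 0.05)
})

test_that("the perceptual backbone gradient matches finite differences", {
  set.seed(21)
  bb <- perceptual_backbone(input_scale = 5, seed = 11)
  # shift ReLU pre-activations off their kink so finite differences are
  # informative; the gradient code is agnostic to the bias values
  for (i in seq_along(bb$convs)) {
    bb$convs[[i]]$b <- rnorm(length(bb$convs[[i]]$b), 0.05, 0.05)
  }
  u <- rand_rbf_field(32, 32, n = 6, amp = 3, seed = 31)
  v <- rand_rbf_field(32, 32, n = 6, amp = 3, seed = 32)
  f1 <- sectionalign:::backbone_fwd(bb, u$dx)
  f2 <- sectionalign:::backbone_fwd(bb, v$dx)
  an <- sectionalign:::backbone_bwd(bb, f1, f2)
  lossf <- function(m) {
    g2 <- sectionalign:::backbone_fwd(bb, m)
    sectionalign:::backbone_distance(bb, f1, g2)
  }
  eps <- 1e-5
  rels <- c()
  for (idx in sample(length(v$dx), 10)) {
    m <- v$dx
    m[idx] <- m[idx] + eps
    up <- lossf(m)
    m[idx] <- m[idx] - 2 * eps
    dn <- lossf(m)
    fd <- (up - dn) / (2 * eps)
    if (abs(fd) > 1e-8) rels <- c(rels, abs(fd - an[idx]) / max(abs(fd), abs(an[idx])))
  }
  expect_gte(mean(rels < 5e-3), 0.8)
  expect_lt(max(rels), 0.05)
})
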