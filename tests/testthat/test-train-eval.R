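# Lightweight stand-in samples for split logic (splits only read metadata).
fake_sample <- function(gene, section, seed = 1) {
  sectionalign:::new_registration_sample(
    image2d(matrix(0.5, 8, 8)), image2d(matrix(0.5, 8, 8)),
    identity_field(8, 8),
    section_spec(gene, section, seed, c(8L, 8L)))
}

fake_dataset <- function(genes = GENE_PANEL, per_cell = 4) {
  ds <- list()
  k <- 0
  for (g in genes) for (sec in c(50, 250, 450)) for (i in seq_len(per_cell)) {
    k <- k + 1
    ds[[k]] <- fake_sample(g, sec + i, seed = k)
  }
  ds
}

test_that("stratified split balances every gene-by-tercile stratum", {
  ds <- fake_dataset()  # 7 genes x 3 terciles x 4 samples = 84
  sp <- stratified_split(ds, test_fraction = 0.25, seed = 3)
  expect_length(sp$test, 21)
  expect_length(sp$train, 63)
  meta <- dataset_meta(sp$test)
  tercile <- cut(meta$section_index, c(0, 176, 352, 528), labels = FALSE)
  counts <- table(meta$gene_id, tercile)
  expect_true(all(counts == 1))  # 25% of 4, exactly, in every stratum

  sp2 <- stratified_split(ds, test_fraction = 0.25, seed = 3)
  expect_identical(dataset_meta(sp2$test), meta)

  two <- list(fake_sample("CCK", 10), fake_sample("CCK", 20))
  half <- stratified_split(two, 0.5, seed = 1)
  expect_length(half$test, 1)
  expect_length(half$train, 1)

  lone <- list(fake_sample("CCK", 10))
  expect_warning(sp3 <- stratified_split(lone, 0.5, seed = 1), "train")
  expect_length(sp3$train, 1)
  expect_length(sp3$test, 0)

  expect_error(stratified_split(ds, 0), "strictly between")
})

test_that("gene holdout is exhaustive and disjoint", {
  ds <- fake_dataset(per_cell = 2)
  sp <- gene_holdout_split(ds, "PVALB")
  expect_equal(sort(unique(dataset_meta(sp$test)$gene_id)), "PVALB")
  expect_length(sp$test, 6)
  expect_equal(length(sp$train) + length(sp$test), length(ds))
  expect_equal(length(unique(dataset_meta(sp$train)$gene_id)), 6)

  expect_error(gene_holdout_split(ds, "GAPDH"), "not present")
  solo <- list(fake_sample("CCK", 10), fake_sample("CCK", 20))
  expect_error(gene_holdout_split(solo, "CCK"), "empty train")
})

simple_tree <- function() {
  data.frame(id = c(1L, 2L, 3L, 4L, 5L, 6L, 7L),
             parent = c(NA, 1L, 1L, 2L, 2L, 3L, 3L),
             level = c(0L, 1L, 1L, 2L, 2L, 2L, 2L))
}

test_that("hierarchical Dice matches the brute-force weighted oracle", {
  tree <- simple_tree()
  set.seed(31)
  a <- matrix(sample(c(0L, 4L, 5L, 6L, 7L), 64, replace = TRUE), 8, 8)
  b <- matrix(sample(c(0L, 4L, 5L, 6L, 7L), 64, replace = TRUE), 8, 8)

  expect_equal(hierarchical_dice(a, a, tree, 0), 100)
  expect_equal(hierarchical_dice(a, a, tree, 1), 100)
  expect_equal(hierarchical_dice(a, a, tree, 2), 100)

  for (lv in 0:2) {
    ca <- collapse_labels(a, tree, lv)
    cb <- collapse_labels(b, tree, lv)
    expect_equal(hierarchical_dice(a, b, tree, lv), brute_weighted_dice(ca, cb),
                 tolerance = 1e-9)
  }
  expect_error(hierarchical_dice(a, b, tree, 5), "exceeds")
})

test_that("level-0 collapse yields exactly background and foreground", {
  tree <- simple_tree()
  lab <- matrix(c(0L, 4L, 5L, 6L, 7L, 0L, 4L, 7L), 4, 2)
  c0 <- collapse_labels(lab, tree, 0)
  expect_equal(sort(unique(as.vector(c0))), c(0L, 1L))

  # disjoint equal-area foregrounds on a large background, level 0:
  # foreground Dice 0, background Dice computed by hand
  a <- matrix(0L, 8, 8); a[1:2, 1:2] <- 4L
  b <- matrix(0L, 8, 8); b[7:8, 7:8] <- 4L
  got <- hierarchical_dice(a, b, tree, 0)
  bg_dice <- 2 * 56 / (60 + 60)  # 56 shared background pixels of 60 each
  expect_equal(got, 100 * (60 * bg_dice + 4 * 0) / 64, tolerance = 1e-9)
})

test_that("synthetic hierarchies are well-formed and nested", {
  smp <- generate_section_pair(section_spec("CALB2", 260, seed = 17,
                                            shape = c(48L, 64L)))
  hier <- generate_hierarchy(smp)
  expect_s3_class(hier, "seg_hierarchy")
  expect_gte(hier$max_level, 4)
  c0 <- collapse_labels(hier$labels, hier$tree, 0)
  expect_equal(sort(unique(as.vector(c0))), c(0L, 1L))
  # deeper collapses refine coarser ones: level-1 classes nest inside level-0
  c1 <- collapse_labels(hier$labels, hier$tree, 1)
  expect_true(all(c1[c0 == 0] == 0))
  expect_true(all(c1[c0 == 1] != 0))
})

test_that("evaluation of the exact truth is near-perfect, identity is exact", {
  ident <- generate_section_pair(section_spec("CCK", 264, seed = 23,
                                              shape = c(48L, 64L)),
                                 elastic_amplitude = 0, affine = FALSE)
  cfg <- model_config(c(48L, 64L), global_conv_channels = c(6, 8),
                      global_dense_units = c(16),
                      local_encoder_channels = c(6, 8),
                      local_decoder_channels = c(8, 8, 6), depth = 2, seed = 2)
  m <- init_identity(build_model(cfg))
  rep <- evaluate(m, list(ident), levels = c(0, 2, 4))
  expect_equal(rep$dice_by_level$mean, rep(100, 3))
  expect_equal(unname(rep$corrupted_pct["mean"]), 0)

  # pretending the prediction equals a deformed truth: only SDI residual left
  smp <- generate_section_pair(section_spec("CCK", 264, seed = 29,
                                            shape = c(48L, 64L)))
  rep2 <- evaluate(m, list(smp), levels = c(0, 2),
                   predictions = list(smp$truth))
  d0 <- rep2$per_sample$dice_0
  expect_gte(d0, 99)

  # report means are the arithmetic means of the per-sample table
  rep3 <- evaluate(m, list(ident, smp), levels = c(0, 2),
                   predictions = list(ident$truth, smp$truth))
  expect_equal(rep3$dice_by_level$mean[1], mean(rep3$per_sample$dice_0))
  expect_equal(unname(rep3$corrupted_pct["mean"]),
               mean(rep3$per_sample$corrupted_pct))
})

test_that("training bookkeeping: zero steps, t normalizer, frozen local branch", {
  samples <- lapply(1:2, function(i) {
    generate_section_pair(section_spec("NPY", 150 + i, seed = 60 + i,
                                       shape = c(32L, 32L)))
  })
  cfg <- model_config(c(32L, 32L), global_conv_channels = c(6, 8),
                      global_dense_units = c(16),
                      local_encoder_channels = c(6, 8),
                      local_decoder_channels = c(8, 8, 6), depth = 2, seed = 4)
  m <- init_identity(build_model(cfg))

  fit0 <- train(m, samples, train_config(steps = 0))
  expect_identical(fit0$model$layers, m$layers)
  expect_equal(nrow(fit0$history), 0)
  expect_equal(attr(fit0$history, "t_normalizer"),
               mean_displacement_norm(lapply(samples, `[[`, "truth")))

  expect_error(train(m, list(), train_config(steps = 1)), "at least one")
  expect_error(train_config(learning_rate = 0), "positive")
  expect_error(train_config(forgetting_factor = 1), "strictly")

  fit <- train(m, samples, train_config(steps = 6, seed = 2,
                                        freeze_local = TRUE))
  expect_equal(nrow(fit$history), 6)
  expect_true(all(is.finite(fit$history$total)))
  expect_identical(fit$model$layers$flow, m$layers$flow)
  expect_identical(fit$model$layers$enc1, m$layers$enc1)
  expect_false(identical(fit$model$layers$gfinal, m$layers$gfinal))
})

test_that("a short training run reduces the loss and supports augmentation", {
  samples <- lapply(1:3, function(i) {
    generate_section_pair(section_spec("SST", 100 + 40 * i, seed = 70 + i,
                                       shape = c(32L, 48L)))
  })
  cfg <- model_config(c(32L, 48L), global_conv_channels = c(6, 8),
                      global_dense_units = c(16),
                      local_encoder_channels = c(6, 8),
                      local_decoder_channels = c(8, 8, 6), depth = 2, seed = 4)
  m <- init_identity(build_model(cfg))
  fit <- train(m, samples, train_config(steps = 40, seed = 5))
  h <- fit$history
  expect_lt(mean(tail(h$total, 5)), mean(head(h$total, 5)))

  # augmented path runs and stays finite
  fit2 <- train(m, samples,
                train_config(steps = 3, seed = 6,
                             augment = augment_config(noise_sigma = 0.01)))
  expect_true(all(is.finite(fit2$history$total)))

  # ablated loss: the perceptual columns are zero, others positive
  fit3 <- train(m, samples,
                train_config(steps = 3, seed = 7,
                             loss_weights = c(perceptual = 0)))
  expect_true(all(fit3$history$perceptual == 0))
  expect_true(all(fit3$history$endpoint_error > 0))
})
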