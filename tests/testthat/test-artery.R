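test_that("combined loss vanishes exactly on perfect predictions", {
  g <- random_blob_mask(12, 12, 2, seed = 2)
  expect_lt(combined_loss(g * 1, g), 1e-5)
  # loss is nonnegative and positive for an imperfect prediction
  expect_gt(combined_loss(pmin(pmax(g * 1 - 0.3, 0), 1), g), 0)
})

test_that("an all-background prediction saturates the region terms", {
  g <- matrix(FALSE, 8, 8); g[3:5, 3:5] <- TRUE
  # weights isolate each term
  lj <- combined_loss(matrix(0, 8, 8), g, weights = c(1, 0, 0))
  lt <- combined_loss(matrix(0, 8, 8), g, weights = c(0, 1, 0))
  expect_equal(lj, 1, tolerance = 1e-5)
  expect_equal(lt, 1, tolerance = 1e-5)
})

test_that("the Tversky term reproduces hand counts at alpha 0.3", {
  # two pixels: one TP (p=1,g=1), one FP (p=1,g=0) -> TI = 1/(1+0.3)
  p <- matrix(c(1, 1), 1, 2)
  g <- matrix(c(TRUE, FALSE), 1, 2)
  lt <- combined_loss(p, g, weights = c(0, 1, 0), tversky_alpha = 0.3,
                      tversky_beta = 0.7)
  expect_equal(lt, 1 - 1 / 1.3, tolerance = 1e-5)
})

test_that("Tversky reduces to Dice and Jaccard at the classic settings", {
  set.seed(4)
  p <- matrix(runif(64), 8, 8)
  g <- random_blob_mask(8, 8, 2, seed = 6)
  spg <- sum(p * g); sp <- sum(p); sg <- sum(g)
  dice <- 1 - 2 * spg / (sp + sg)
  jacc <- 1 - spg / (sp + sg - spg)
  half <- combined_loss(p, g, weights = c(0, 1, 0), tversky_alpha = 0.5,
                        tversky_beta = 0.5)
  # TI(0.5, 0.5) = spg / (spg + 0.5 fp + 0.5 fn) = dice index
  expect_equal(half, dice, tolerance = 1e-5)
  one <- combined_loss(p, g, weights = c(0, 1, 0), tversky_alpha = 1,
                       tversky_beta = 1)
  expect_equal(one, jacc, tolerance = 1e-5)
})

test_that("combined loss is permutation invariant over pixels", {
  set.seed(9)
  p <- matrix(runif(36), 6, 6)
  g <- random_blob_mask(6, 6, 1, seed = 1)
  perm <- sample(36)
  expect_equal(combined_loss(p, g),
               combined_loss(matrix(p[perm], 6, 6),
                             matrix(g[perm], 6, 6)),
               tolerance = 1e-12)
})

test_that("loss gradient matches finite differences", {
  set.seed(2)
  z <- array(rnorm(5 * 4), dim = c(5, 4, 1))
  g <- array(random_blob_mask(5, 4, 1, 3) * 1, dim = c(5, 4, 1))
  r <- plaqueseg:::.combined_loss_grad(z, g)
  ng <- z * 0
  for (i in seq_along(z)) {
    zp <- z; zp[i] <- zp[i] + 1e-6
    zm <- z; zm[i] <- zm[i] - 1e-6
    ng[i] <- (plaqueseg:::.combined_loss_grad(zp, g)$value -
              plaqueseg:::.combined_loss_grad(zm, g)$value) / 2e-6
  }
  expect_lt(max(abs(ng - r$dx)), 1e-6)
})

test_that("the cyclic schedule is triangular, periodic and bounded", {
  cfg <- cyclic_lr_config(step_size = 50)
  expect_equal(cyclic_lr_value(0, cfg), 1e-4)
  expect_equal(cyclic_lr_value(50, cfg), 1e-1)
  expect_equal(cyclic_lr_value(100, cfg), 1e-4)
  steps <- 0:400
  vals <- cyclic_lr_value(steps, cfg)
  expect_true(all(vals >= 1e-4 & vals <= 1e-1))
  expect_equal(vals, cyclic_lr_value(steps + 100, cfg))
  # midpoint of the rise
  expect_equal(cyclic_lr_value(25, cfg), 1e-4 + (1e-1 - 1e-4) / 2)
})

test_that("training reduces the loss and respects the patience rule", {
  m <- fixture_dataset()
  cfg <- seg_model_config(architecture = "unet", base_channels = 4,
                          input_size = c(24, 32), learning_rate = 5e-3,
                          epochs = 3, batch_size = 4,
                          early_stop_patience = 10, seed = 2)
  fit <- train_segmenter(m, cfg)
  expect_s3_class(fit, "artery_model")
  expect_lt(fit$history$train_loss[nrow(fit$history)],
            fit$history$train_loss[1])
  # halted no later than best epoch + patience
  best_epoch <- which.max(fit$history$val_miou)
  expect_lte(nrow(fit$history), best_epoch + cfg$early_stop_patience)
  expect_error(train_segmenter(m[m$split != "val", ], cfg), "val split")
})

test_that("training is deterministic for a fixed seed without augmentation", {
  m <- fixture_dataset()
  cfg <- seg_model_config(architecture = "unet", base_channels = 4,
                          input_size = c(24, 32), learning_rate = 5e-3,
                          epochs = 1, batch_size = 4, seed = 31)
  f1 <- train_segmenter(m, cfg)
  f2 <- train_segmenter(m, cfg)
  expect_identical(f1$history$train_loss, f2$history$train_loss)
  expect_identical(f1$params, f2$params)
})

test_that("snapshot count equals epochs divided by cycle length", {
  m <- fixture_dataset()
  n_train <- sum(m$split == "train")
  bpe <- ceiling(n_train / 4)
  cfg <- seg_model_config(architecture = "unet", base_channels = 4,
                          input_size = c(24, 32), epochs = 4,
                          batch_size = 4, seed = 2)
  lrc <- cyclic_lr_config(base_lr = 1e-3, max_lr = 2e-2, step_size = bpe)
  ens <- train_snapshot_ensemble(m, cfg, lrc)
  expect_length(ens$snapshots, 2L)
  expect_length(ens$val_scores, 2L)
  # snapshots are captured where the schedule returns to its minimum
  expect_equal(cyclic_lr_value(2 * bpe, lrc), lrc$base_lr)
  # epochs not divisible by the cycle length is refused with a suggestion
  cfg_bad <- cfg; cfg_bad$epochs <- 5L
  expect_error(train_snapshot_ensemble(m, cfg_bad, lrc), "multiple")
})

test_that("prediction returns full-resolution logit maps", {
  m <- fixture_dataset()
  cfg <- seg_model_config(architecture = "unet", base_channels = 4,
                          input_size = c(24, 32), learning_rate = 5e-3,
                          epochs = 1, batch_size = 4, seed = 2)
  fit <- train_segmenter(m, cfg)
  g <- fixture_slide(0.3, 7, c(96L, 128L))
  pm <- predict_prob_map(fit, g$slide)
  expect_s3_class(pm, "prob_map")
  expect_equal(pm$activation_state, "logit")
  expect_equal(dim(pm$values), c(96L, 128L))
  # a zero-weight network emits logit 0 -> probability 0.5 everywhere
  zero <- fit
  zero$params <- lapply(fit$params, function(v) v * 0)
  pz <- predict_prob_map(zero, g$slide)
  expect_true(all(abs(pz$values) < 1e-12))
  # source exactly at input size skips interpolation: logits equal the
  # direct forward pass
  small <- generate_slide(synth_params(image_size = c(24, 32),
                                       target_plaque_fraction = 0,
                                       seed = 2))$slide
  pm2 <- predict_prob_map(fit, small)
  direct <- plaqueseg:::nn_forward_value(fit$net, fit$params,
                                         small$pixels / 255)[, , 1]
  expect_equal(pm2$values, direct, tolerance = 1e-12)
})
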