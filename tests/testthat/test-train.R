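test_that("stratified split respects per-class floor rounding", {
  co <- tiny_cohort(n_per_class = 5, shape = c(6, 6, 6))
  sp <- split_cohort(co, 0.8, seed = 1)
  expect_length(sp$train, 8)
  expect_length(sp$validation, 2)
  lab_tr <- vapply(sp$train, function(s) s$label, integer(1))
  lab_va <- vapply(sp$validation, function(s) s$label, integer(1))
  expect_equal(sum(lab_tr == 1), 4)
  expect_equal(sum(lab_va == 1), 1)

  # identical seed, identical index sets; different seed differs
  sp2 <- split_cohort(co, 0.8, seed = 1)
  expect_identical(attr(sp, "train_idx"), attr(sp2, "train_idx"))
  sp3 <- split_cohort(co, 0.8, seed = 2)
  expect_false(identical(attr(sp, "train_idx"), attr(sp3, "train_idx")))
})

test_that("the clinical cohort sizes follow per-class floor arithmetic", {
  # 351 AD + 415 NC at 80/20: train 280 + 332 = 612, validation 154
  labels <- c(rep(1L, 351), rep(0L, 415))
  fake <- lapply(seq_along(labels), function(i)
    sample_record(array(0, c(1, 1, 1)), numeric(0), labels[i],
                  paste0("s", i)))
  sp <- split_cohort(fake, 0.8, seed = 0)
  expect_length(sp$train, 612)
  expect_length(sp$validation, 154)
  lab_tr <- vapply(sp$train, function(s) s$label, integer(1))
  expect_equal(sum(lab_tr == 1), 280)
  expect_equal(sum(lab_tr == 0), 332)
})

test_that("oversampling weights are inverse class frequencies", {
  expect_equal(oversample_weights(c(0, 1, 0, 1)), rep(1, 4))
  w <- oversample_weights(c(rep(1, 351), rep(0, 415)))
  expect_equal(w[1] / w[400], 415 / 351)
  expect_equal(mean(w), 1)
  expect_error(oversample_weights(rep(1, 5)), "both classes")

  # weighted draws from a 1:3 cohort balance the classes in expectation
  set.seed(60)
  labels <- c(rep(1, 25), rep(0, 75))
  w <- oversample_weights(labels)
  draws <- sample(labels, 1e5, replace = TRUE, prob = w / sum(w))
  se <- sqrt(0.25 / 1e5)
  expect_lt(abs(mean(draws) - 0.5), 3 * se)
})

test_that("learning rate warms up, plateaus, and decays by steps of five", {
  ctrl <- recnn_control()
  spe <- 20L
  expect_equal(learning_rate(0, spe, ctrl), 0)
  # linear ramp across the first two epochs
  ramp <- vapply(0:(2 * spe), learning_rate, 0, steps_per_epoch = spe,
                 control = ctrl)
  expect_true(all(diff(ramp) >= 0))
  expect_equal(ramp[2 * spe + 1], 5e-4)
  expect_equal(learning_rate(spe, spe, ctrl), 5e-4 / 2)
  # plateau anywhere in epochs 2..39
  for (ep in c(2, 17, 39))
    expect_equal(learning_rate(ep * spe + 3, spe, ctrl), 5e-4)
  # shrink by 5 at epoch 40 and 25 at epoch 80
  expect_equal(learning_rate(50 * spe, spe, ctrl), 1e-4)
  expect_equal(learning_rate(90 * spe, spe, ctrl), 2e-5)
})

test_that("a short fit runs end to end with finite, decreasing loss", {
  co <- tiny_cohort(n_per_class = 10, shape = c(8, 10, 8), seed = 1)
  arch <- recnn_arch(input_shape = c(8, 10, 8), channels = c(2, 2, 4, 4, 4))
  fit <- recnn(co, latent_dim = 4, alpha = 1, arch = arch,
               control = recnn_control(epochs = 3, batch_size = 8),
               seed = 0)
  expect_s3_class(fit, "recnn")
  expect_equal(nrow(fit$history), 3)
  expect_true(all(is.finite(fit$history$total)))
  expect_true(all(c("ce", "kl", "val_auc", "val_kl", "lr") %in%
                    names(fit$history)))
  expect_s3_class(fit$validation, "eval_report")
  # prediction machinery round-trips
  p <- predict(fit, co[1:3], type = "prob")
  expect_equal(dim(p), c(3, 2))
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-12)
  cls <- predict(fit, co[1:3], type = "class")
  expect_true(all(cls %in% c(0L, 1L)))
  lat <- predict(fit, co[1:3], type = "latent")
  expect_equal(dim(lat$mu), c(3, 4))
})

test_that("fits are bit-reproducible for identical seed and config", {
  co <- tiny_cohort(n_per_class = 6, shape = c(8, 10, 8), seed = 2)
  arch <- recnn_arch(input_shape = c(8, 10, 8), channels = c(2, 2, 2, 2, 2))
  ctrl <- recnn_control(epochs = 2, batch_size = 8)
  f1 <- recnn(co, latent_dim = 3, alpha = 0.5, arch = arch, control = ctrl,
              seed = 3)
  f2 <- recnn(co, latent_dim = 3, alpha = 0.5, arch = arch, control = ctrl,
              seed = 3)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
  # a different seed changes the trajectory
  f3 <- recnn(co, latent_dim = 3, alpha = 0.5, arch = arch, control = ctrl,
              seed = 4)
  expect_false(identical(f1$history$total, f3$history$total))
})

test_that("alpha = 0 removes the KL term from the objective", {
  co <- tiny_cohort(n_per_class = 6, shape = c(8, 10, 8), seed = 3)
  arch <- recnn_arch(input_shape = c(8, 10, 8), channels = c(2, 2, 2, 2, 2))
  fit <- recnn(co, latent_dim = 3, alpha = 0, arch = arch,
               control = recnn_control(epochs = 2, batch_size = 8), seed = 0)
  expect_equal(fit$history$total, fit$history$ce)
})

test_that("latent_dim = 0 degenerates to the metrics-only MLP", {
  co <- tiny_cohort(n_per_class = 10, shape = c(6, 6, 6), seed = 4)
  fit <- recnn(co, latent_dim = 0, alpha = 0,
               control = recnn_control(epochs = 5, batch_size = 10), seed = 0)
  expect_null(fit$arch)
  expect_true(is.na(fit$val_kl))
  p <- predict(fit, co[1:2], type = "score")
  expect_length(p, 2)
  expect_error(predict(fit, co[1:2], type = "latent"), "latent")
})

test_that("cross-validation summarizes per-seed reports order-independently", {
  co <- tiny_cohort(n_per_class = 8, shape = c(6, 6, 6), seed = 5)
  ctrl <- recnn_control(epochs = 3, batch_size = 8)
  cv1 <- cross_validate(co, seeds = c(0, 1), latent_dim = 0, alpha = 0,
                        control = ctrl)
  expect_equal(nrow(cv1$reports), 2)
  cv2 <- cross_validate(co, seeds = c(1, 0), latent_dim = 0, alpha = 0,
                        control = ctrl)
  expect_equal(cv1$summary$mean, cv2$summary$mean, tolerance = 1e-12)
  expect_equal(cv1$summary$sd, cv2$summary$sd, tolerance = 1e-12)
  # single seed: SD reported as zero
  cv3 <- cross_validate(co, seeds = 7, latent_dim = 0, alpha = 0,
                        control = ctrl)
  expect_equal(cv3$summary$sd, rep(0, 4))
})
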