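# Augmentation, metrics, optimizer behaviour, schedules, model selection.

test_that("reverse augmentation doubles, negates and inverts codes", {
  data <- fixture_samples(5L)
  aug <- reverse_augment(data)
  expect_length(aug, 10L)
  y <- vapply(aug, `[[`, numeric(1), "ddg")
  expect_equal(y[1:5] + y[6:10], rep(0, 5))
  expect_equal(mean(y), 0)
  for (k in 1:5) {
    expect_equal(format_mutation(aug[[5 + k]]$mutations[[1]]),
                 format_mutation(invert_mutation(data[[k]]$mutations[[1]])))
    expect_identical(aug[[5 + k]]$wt$aa, data[[k]]$mut$aa)
  }
})

test_that("metrics match closed forms on hand-built vectors", {
  m <- compute_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(m$rp, 1)
  expect_equal(m$rmse, 0)
  expect_equal(m$mae, 0)

  m2 <- compute_metrics(c(1, 2, 3), c(2, 4, 6))
  expect_equal(m2$rp, 1)
  expect_equal(m2$rmse, sqrt(14 / 3), tolerance = 1e-9)
  expect_equal(m2$mae, 2)

  m3 <- compute_metrics(-c(1, 2, 4), c(1, 2, 4))
  expect_equal(m3$rp, -1)

  expect_error(compute_metrics(1, 1), "fewer than 2")
  expect_error(compute_metrics(c(1, 2), c(1, 2, 3)), "length")
})

test_that("metrics agree with independent formulas on random vectors", {
  set.seed(14)
  for (r in 1:100) {
    p <- rnorm(20); y <- rnorm(20)
    m <- compute_metrics(p, y)
    rp_ref <- sum((p - mean(p)) * (y - mean(y))) /
      sqrt(sum((p - mean(p))^2) * sum((y - mean(y))^2))
    expect_equal(m$rp, rp_ref, tolerance = 1e-10)
    expect_equal(m$rmse, sqrt(sum((p - y)^2) / 20), tolerance = 1e-10)
    expect_equal(m$mae, sum(abs(p - y)) / 20, tolerance = 1e-10)
    expect_gte(m$rmse, m$mae)
  }
})

test_that("optimization ratio matches enumeration including degenerate case", {
  expect_equal(optimization_ratio(c(-1, -1, 1), c(-2, 0.5, 3)), 0.5)
  expect_equal(optimization_ratio(c(-1, -2), c(-1, -3)), 1.0)
  und <- optimization_ratio(c(1, 2, 3), c(-1, -2, -3))
  expect_true(is.na(und))
  expect_true(attr(und, "undefined"))

  set.seed(15)
  for (r in 1:50) {
    p <- rnorm(30); y <- rnorm(30)
    ref <- sum(p < 0 & y < 0) / sum(p < 0)
    expect_equal(as.numeric(optimization_ratio(p, y)), ref)
  }
})

test_that("training is deterministic and reduces the loss", {
  data <- fixture_samples(12L)
  cfg <- test_config()
  f1 <- ddg_fit(data, cfg, epochs = 40L, lr = 1e-3, seed = 5L)
  f2 <- ddg_fit(data, cfg, epochs = 40L, lr = 1e-3, seed = 5L)
  expect_equal(f1$history$loss, f2$history$loss, tolerance = 1e-10)
  expect_lt(f1$history$loss[40], f1$history$loss[1])
  expect_equal(nrow(f1$history), 40L)
})

test_that("minibatch training runs and matches the dataset size contract", {
  data <- fixture_samples(12L)
  cfg <- test_config()
  f <- ddg_fit(data, cfg, epochs = 5L, lr = 1e-3, batch_size = 8L, seed = 2L)
  expect_equal(nrow(f$history), 5L)
  expect_true(all(is.finite(f$history$loss)))
})

test_that("the learning rate halves after a forced plateau checkpoint", {
  data <- fixture_samples(4L)
  cfg <- test_config()
  # lr so small the loss cannot improve measurably -> plateau at epoch 100
  f <- ddg_fit(data, cfg, epochs = 101L, lr = 1e-15, seed = 3L,
               check_every = 100L, patience = 10L)
  expect_equal(f$history$lr[100], 1e-15)
  expect_equal(f$history$lr[101], 5e-16)
})

test_that("dropout training stays finite and differs from the clean path", {
  data <- fixture_samples(6L)
  cfg <- test_config(dropout = 0.3)
  f <- ddg_fit(data, cfg, epochs = 10L, lr = 1e-3, seed = 7L)
  expect_true(all(is.finite(f$history$loss)))
  cfg0 <- test_config()
  f0 <- ddg_fit(data, cfg0, epochs = 10L, lr = 1e-3, seed = 7L)
  expect_false(isTRUE(all.equal(f$history$loss, f0$history$loss)))
})

test_that("grid search returns the argmin of its validation log", {
  data <- fixture_samples(10L)
  train <- data[1:8]; val <- data[9:10]
  cfg <- test_config()
  gs <- grid_search(train, val, cfg,
                    grid = list(dropout = 0, batch_size = 8L,
                                learning_rate = c(1e-3, 1e-5)),
                    epochs = 10L, seed = 1L)
  expect_equal(nrow(gs$log), 2L)
  expect_equal(gs$best$val_loss, min(gs$log$val_loss))

  single <- grid_search(train, val, cfg,
                        grid = list(dropout = 0.3, batch_size = 4L,
                                    learning_rate = 1e-4),
                        epochs = 5L, seed = 1L)
  expect_equal(single$best$dropout, 0.3)
  expect_equal(single$best$batch_size, 4L)
  expect_equal(single$best$learning_rate, 1e-4)
  expect_error(grid_search(train, list(), cfg), "validation")
})

test_that("retraining honours the selected epoch budget with fresh weights", {
  data <- fixture_samples(10L)
  cfg <- test_config()
  f1 <- ddg_fit(data[1:8], cfg, epochs = 15L, lr = 1e-3, seed = 9L)
  f2 <- retrain_full(data[1:8], data[9:10], epochs = 12L, config = cfg,
                     lr = 1e-3, seed = 9L)
  expect_equal(nrow(f2$history), 12L)
  expect_false(isTRUE(all.equal(coef(f1)$Wi1, coef(f2)$Wi1)))
  f3 <- retrain_full(data[1:8], data[9:10], epochs = 12L, config = cfg,
                     lr = 1e-3, seed = 9L)
  expect_equal(f2$history$loss, f3$history$loss, tolerance = 1e-10)
})

test_that("model object methods expose fit, residuals and predictions", {
  data <- fixture_samples(8L)
  cfg <- test_config()
  fit <- ddg_fit(data[1:6], cfg, epochs = 25L, lr = 1e-3, seed = 11L)
  expect_s3_class(fit, "ddg_model")
  expect_output(print(fit), "blocks")
  expect_output(print(summary(fit)), "Rp")
  expect_length(residuals(fit), 6L)
  expect_equal(residuals(fit), fit$labels - fit$fitted)
  expect_named(coef(fit)["Wddg"], "Wddg")

  preds <- predict(fit, data[7:8])
  expect_length(preds, 2L)
  expect_true(all(is.finite(preds)))
  pc <- predict(fit, data[7], type = "contributions")
  expect_equal(sum(pc[[1]]$contributions), pc[[1]]$total, tolerance = 1e-6)
})

test_that("weights round-trip through the text checkpoint format", {
  cfg <- test_config()
  params <- init_params(cfg, 17L)
  tf <- tempfile(fileext = ".json")
  save_weights(params, cfg, tf)
  back <- load_weights(tf)
  expect_equal(back$config$d_model, cfg$d_model)
  for (nm in names(params)) expect_equal(back$params[[nm]], params[[nm]])

  s <- fixture_samples(1L)[[1]]
  expect_equal(predict_ddg(s, back$params, back$config),
               predict_ddg(s, params, cfg), tolerance = 1e-12)
  unlink(tf)
})
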