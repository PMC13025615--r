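test_that("feature dimensions follow the variant contracts", {
  fx <- test_scan_null()
  n <- ncol(fx$dataset$genotypes)
  xr <- build_features(fx$scan, fx$dataset, "xr", "ls")
  expect_equal(ncol(xr$features), 2 * n)
  raw <- build_features(fx$scan, fx$dataset, "raw", "ls")
  expect_equal(ncol(raw$features), 4 * n)
  af <- build_features(fx$scan, fx$dataset, "af", "qls")
  expect_equal(ncol(af$features), 3)
  # XR rows are (X, R) in pedigree order
  expect_equal(xr$features[1, 1:n], as.numeric(fx$dataset$genotypes[1, ]),
               ignore_attr = TRUE)
  expect_equal(xr$features[1, (n + 1):(2 * n)],
               attr(fx$scan, "residuals")[1, ], ignore_attr = TRUE)
  expect_equal(af$features[, 1], fx$scan$xtr[af$rows])
})

test_that("ensemble target is the signed max statistic", {
  expect_equal(ensemble_target(2, -1), 2)
  expect_equal(ensemble_target(-3, 1), -3)
  expect_equal(ensemble_target(1.5, 1.5), 1.5)
  fx <- test_scan_null()
  z <- ensemble_target(fx$scan$z_ls, fx$scan$z_qls)
  expect_true(all(z^2 >= fx$scan$s_ls - 1e-12, na.rm = TRUE))
  expect_true(all(z^2 >= fx$scan$s_qls - 1e-12, na.rm = TRUE))
  expect_equal(z^2, pmax(fx$scan$s_ls, fx$scan$s_qls), tolerance = 1e-12)
})

test_that("variance-preserving loss follows its definition", {
  expect_equal(vp_loss(1:5, 1:5), 0)
  p <- c(1, 2, 4); t <- c(1, 3, 3)
  expect_equal(vp_loss(p, t, lambda_var = 0), mean((p - t)^2))
  # constant prediction: loss = MSE + lambda * sd(target)^2
  t2 <- c(0, 1, 2, 5)
  expect_equal(vp_loss(rep(2, 4), t2, lambda_var = 1.5),
               mean((2 - t2)^2) + 1.5 * sd(t2)^2)
  expect_error(vp_loss(1, 1), "length")
})

test_that("train/test splits are disjoint, exhaustive and seeded", {
  s <- split_dataset(5000, seed = 3)
  expect_length(s$train, 4000)
  expect_length(s$test, 1000)
  expect_length(intersect(s$train, s$test), 0)
  expect_setequal(c(s$train, s$test), 1:5000)
  expect_identical(split_dataset(5000, seed = 3), s)
  expect_false(identical(split_dataset(5000, seed = 4)$train, s$train))
})

test_that("architecture resolution matches the variant definitions", {
  base <- emulator_config()
  expect_equal(resolve_architecture("xr", base)$hidden, c(64, 64, 32, 16))
  raw <- resolve_architecture("raw", base)
  expect_equal(raw$hidden, c(64, 128, 64, 32, 16))
  expect_equal(raw$dropout[2], 0.4)
  expect_equal(resolve_architecture("af", base)$hidden, 8)
})

test_that("training is deterministic given a seed and prediction is pure", {
  fx <- test_scan_null()
  fb <- build_features(fx$scan, fx$dataset, "af", "ls")
  cfg <- emulator_config(epochs = 20)
  m1 <- train_emulator(fb$features, fb$target, "af", cfg, seed = 5)
  m2 <- train_emulator(fb$features, fb$target, "af", cfg, seed = 5)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$nets, m2$nets)
  m3 <- train_emulator(fb$features, fb$target, "af", cfg, seed = 6)
  expect_false(identical(m1$history, m3$history))
  p1 <- predict(m1, fb$features)
  p2 <- predict(m1, fb$features)
  expect_identical(p1, p2)
  expect_true(all(p1$p_pred > 0 & p1$p_pred <= 1))
  expect_equal(p1$s_pred, p1$z_pred^2)
})

test_that("an untrained (zero-epoch) model has no predictive value", {
  fx <- test_scan_null()
  fb <- build_features(fx$scan, fx$dataset, "xr", "ls")
  m0 <- train_emulator(fb$features, fb$target, "xr",
                       emulator_config(epochs = 0), seed = 1)
  p <- predict(m0, fb$features)
  expect_lt(abs(cor(p$z_pred, fb$target)), 0.4)
  expect_lt(accuracy_metrics(p$z_pred, fb$target)$r_squared, 0.2)
})

test_that("a short AF training already tracks the statistic", {
  fx <- test_scan_null()
  es <- emulate_split(fx$scan, fx$dataset, "af", "ls",
                      config = emulator_config(epochs = 60),
                      split_seed = 2, seed = 2)
  expect_gt(cor(es$pred$z_pred, es$pred$z_true), 0.9)
})

test_that("feature-dimension mismatch is a schema error", {
  fx <- test_scan_null()
  fb <- build_features(fx$scan, fx$dataset, "af", "ls")
  m <- train_emulator(fb$features, fb$target, "af",
                      emulator_config(epochs = 2), seed = 1)
  expect_error(predict(m, fb$features[, 1:2]), "dimension")
})

test_that("emulator persistence restores bit-identical predictions", {
  fx <- test_scan_null()
  fb <- build_features(fx$scan, fx$dataset, "af", "ls")
  m <- train_emulator(fb$features, fb$target, "af",
                      emulator_config(epochs = 10), seed = 8)
  path <- withr::local_tempfile(fileext = ".json")
  write_emulator(m, path)
  m2 <- read_emulator(path)
  expect_identical(predict(m, fb$features), predict(m2, fb$features))
})

test_that("bagged training averages seeded networks", {
  fx <- test_scan_null()
  fb <- build_features(fx$scan, fx$dataset, "af", "ls")
  cfg <- emulator_config(epochs = 10)
  mb <- train_emulator(fb$features, fb$target, "af", cfg, seed = 5, bag = 2)
  ma <- train_emulator(fb$features, fb$target, "af", cfg, seed = 5)
  m_next <- train_emulator(fb$features, fb$target, "af", cfg, seed = 6)
  # compare the uncalibrated network outputs: the bagged forward pass is the
  # mean of the two seeded networks' forward passes
  mb$calibration <- ma$calibration <- m_next$calibration <- c(0, 1)
  pb <- predict(mb, fb$features)$z_pred
  expect_equal(pb, (predict(ma, fb$features)$z_pred +
                    predict(m_next, fb$features)$z_pred) / 2,
               tolerance = 1e-12)
})

test_that("tidiers expose the training history and model summary", {
  fx <- test_scan_null()
  fb <- build_features(fx$scan, fx$dataset, "af", "ls")
  m <- train_emulator(fb$features, fb$target, "af",
                      emulator_config(epochs = 5), seed = 1)
  td <- tidy(m)
  expect_equal(nrow(td), 5)
  expect_true(all(is.finite(td$loss)))
  gl <- glance(m)
  expect_equal(gl$variant, "af")
  expect_equal(gl$feature_dim, 3)
})
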