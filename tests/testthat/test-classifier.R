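# Model construction, prediction vectors, ensembles, and training behaviour.

test_that("the linear baseline has exactly 6*3*500*5 + 5 parameters", {
  m <- build_model("linear", seed = 1)
  expect_equal(sum(vapply(m$params, length, 0L)), 6L * 3L * 500L * 5L + 5L)
})

test_that("the residual model's first convolution spans 6x3 channels with width 7", {
  m <- build_model("resnet18", width = 8, seed = 2)
  expect_equal(dim(m$params$conv1.W), c(8L, 18L * 7L))
})

test_that("every model kind emits a normalized five-component y vector", {
  x <- preprocess_voltset(reversible_set())
  for (kind in c("resnet18", "linear", "mlp", "mlp_attention", "mlp_shared")) {
    m <- build_model(kind, width = 8, seed = 3)
    pr <- predict_ensemble(m, x)
    expect_named(pr$y, mechanism_levels())
    expect_true(all(pr$y >= 0))
    expect_equal(sum(pr$y), 1, tolerance = 1e-6)
  }
  # all-zero tensor is still a valid input with a normalized output
  z <- array(0, dim = c(6, 3, 500))
  class(z) <- "cv_tensor"
  pr0 <- predict_ensemble(build_model("resnet18", width = 8, seed = 4), z)
  expect_equal(sum(pr0$y), 1, tolerance = 1e-6)
})

test_that("ensemble averaging equals the manual mean of member outputs", {
  x <- preprocess_voltset(reversible_set())
  xm <- tensor_flat(x)
  models <- lapply(5:7, function(s) build_model("resnet18", width = 8, seed = s))
  pr <- predict_ensemble(models, x)
  manual <- Reduce(`+`, lapply(models, function(m)
    as.numeric(cvmech:::nn_predict_tensor_cpp(m$params, m$kind, m$width, xm)))) / 3
  expect_lt(max(abs(pr$y - manual)), 1e-12)

  # eight copies of one model give that model's output exactly
  one <- models[[1]]
  pr8 <- predict_ensemble(rep(list(one), 8), x)
  pr1 <- predict_ensemble(one, x)
  expect_lt(max(abs(pr8$y - pr1$y)), 1e-12)
})

test_that("an untrained model scores at five-class chance on a balanced pool", {
  pool <- tiny_pool()
  m <- build_model("resnet18", width = 8, seed = 11)    # 0 training epochs
  ev <- evaluate_ensemble(m, pool, sigma = 0.3, seed = 12)
  n <- length(pool$label)
  # binomial band around 0.2 (3 sigma)
  expect_lt(abs(ev$accuracy - 0.2), 0.2 + 3 * sqrt(0.2 * 0.8 / n))
})

test_that("a small pool is memorized to high training accuracy", {
  pool <- tiny_pool()                        # 40 systems
  m <- build_model("resnet18", width = 8, seed = 21)
  cfg <- train_config(epochs = 80, width = 8, train_noise_sigma = 0,
                      batch_size = 20)
  m <- train_classifier(m, pool, cfg = cfg, seed = 22)
  expect_gte(tail(m$history$acc, 1), 0.99)
})

test_that("training is reproducible bit-for-bit under one seed", {
  pool <- tiny_pool()
  cfg <- train_config(epochs = 2, width = 8, batch_size = 20)
  m1 <- train_classifier(build_model("resnet18", width = 8, seed = 31),
                         pool, cfg = cfg, seed = 33)
  m2 <- train_classifier(build_model("resnet18", width = 8, seed = 31),
                         pool, cfg = cfg, seed = 33)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
})

test_that("training reduces the loss and the history is recorded", {
  pool <- tiny_pool()
  m <- build_model("resnet18", width = 8, seed = 41)
  m <- train_classifier(m, pool, cfg = train_config(epochs = 6, width = 8),
                        seed = 42)
  expect_length(m$history$loss, 6L)
  expect_lt(tail(m$history$loss, 1), m$history$loss[1])
})

test_that("ensemble spread is a finite per-mechanism statistic", {
  pool <- tiny_pool()
  models <- lapply(1:3, function(s) build_model("resnet18", width = 8, seed = s))
  sp <- ensemble_spread(models, pool, idx = 1:10)
  expect_equal(dim(sp), c(10L, 5L))
  expect_true(all(is.finite(sp)))
  expect_true(all(sp >= 0))
  expect_identical(colnames(sp), mechanism_levels())
})

test_that("argmax ties break toward the canonical mechanism order", {
  y <- c(0.3, 0.3, 0.2, 0.1, 0.1)
  pr <- cvmech:::.new_prediction(y)
  expect_equal(pr$mechanism, "E")
})
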