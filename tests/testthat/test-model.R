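test_that("compiled forward pass matches the loop-based reference network", {
  for (seed in c(7L, 19L)) {
    toy <- ref_toy_model(nf = 4L, width = 20L, seed = seed)
    rf <- ref_forward(toy$model$params, toy$x)
    expect_equal(predict(toy$model, toy$x, type = "logit"), rf$logit,
                 tolerance = 1e-10)
    sal <- encore:::model_saliency(toy$model, toy$x)
    # layer-1 activations: direct 2D cross-correlation oracle (Eq.-style)
    for (k in 1:4)
      expect_equal(matrix(sal$activations[[1]][, k], nrow = 5, byrow = TRUE),
                   rf$A1[[k]], tolerance = 1e-10)
    expect_equal(sal$activations[[7]], rf$acts[[6]], tolerance = 1e-10)
  }
})

test_that("an all-zero model outputs probability exactly 0.5", {
  m <- build_model(model_config(n_filters = 4L, width = 16L))
  m$params <- lapply(m$params, function(w) w * 0)
  x <- matrix(runif(5 * 16), 5, 16)
  expect_identical(predict(m, x), 0.5)
})

test_that("predictions are probabilities, deterministic, and shape-checked", {
  toy <- ref_toy_model(seed = 3L)
  withr::with_seed(1, {
    X <- array(abs(rnorm(5 * 20 * 10)), c(5, 20, 10))
  })
  p <- predict(toy$model, X)
  expect_length(p, 10L)
  expect_true(all(p > 0 & p < 1))
  expect_identical(p, predict(toy$model, X))
  expect_error(predict(toy$model, matrix(0, 5, 32)), "width")
})

test_that("pooling and collapse geometry follow the architecture contract", {
  toy <- ref_toy_model(nf = 4L, width = 40L, seed = 2L)
  sal <- encore:::model_saliency(toy$model, toy$x)
  # conv1 keeps all 5 assay rows at full width
  expect_equal(nrow(sal$activations[[1]]), 5L * 40L)
  # after the 1x4 max-pool the 1D stage runs at width/4 positions
  expect_equal(nrow(sal$activations[[2]]), 10L)
  expect_equal(nrow(sal$activations[[7]]), 10L)
  expect_equal(sal$pooled_width, 10L)
})

test_that("balanced class weights equalise the two classes' total weight", {
  y <- rep(c(1L, 0L), c(10L, 100L))
  w <- encore:::class_weight_vector(y, "balanced")
  expect_equal(sum(w[y == 1L]), sum(w[y == 0L]))
  expect_equal(w[y == 1L][1], 110 / (2 * 10))
  expect_equal(w[y == 0L][1], 110 / (2 * 100))
})

test_that("training learns a separable toy problem and is seed-deterministic", {
  sim <- fx_sim_small()
  cfg <- train_config(learning_rate = 5e-4, epochs = 4L, patience = 10L,
                      seed = 9L)
  m <- build_model(model_config(n_filters = 8L), sim$dataset$panel, seed = 9L)
  fit1 <- train_model(m, sim$dataset, cfg)
  expect_lt(tail(fit1$history$val_loss, 1), fit1$history$val_loss[1])
  expect_true(all(is.finite(fit1$history$train_loss)))

  fit2 <- train_model(m, sim$dataset, cfg)
  expect_identical(fit1$history, fit2$history)
  expect_identical(predict(fit1, sim$dataset), predict(fit2, sim$dataset))

  # the 80-20 split is stratified by label
  val <- fit1$fit$val_idx
  expect_equal(mean(sim$dataset$label[val]),
               mean(sim$dataset$label), tolerance = 0.02)
  expect_equal(length(val), round(0.2 * length(sim$dataset$label)))
})

test_that("zero-epoch training returns the initial model with empty history", {
  sim <- fx_sim_small()
  m <- build_model(model_config(n_filters = 8L), sim$dataset$panel, seed = 1L)
  fit <- train_model(m, sim$dataset, train_config(epochs = 0L))
  expect_equal(nrow(fit$history), 0L)
  expect_identical(fit$params, m$params)
})

test_that("training refuses single-class data", {
  sim <- fx_sim_small()
  onlypos <- subset_dataset(sim$dataset, sim$dataset$label == 1L)
  m <- build_model(model_config(n_filters = 8L), sim$dataset$panel)
  expect_error(train_model(m, onlypos), "both positive and negative")
})

test_that("save/load round-trips the model bitwise", {
  fitted <- fx_model_small()
  p <- withr::local_tempfile(fileext = ".rds")
  save_model(fitted, p)
  re <- load_model(p)
  withr::with_seed(2, {
    X <- array(abs(rnorm(5 * 400 * 10)), c(5, 400, 10))
  })
  expect_identical(predict(re, X), predict(fitted, X))
  expect_identical(unclass(re$panel), unclass(fitted$panel))
  expect_identical(re$seed, fitted$seed)
  expect_identical(re$history, fitted$history)

  # truncated archives are rejected
  raw <- readBin(p, "raw", n = 100L)
  p2 <- withr::local_tempfile(fileext = ".rds")
  writeBin(raw, p2)
  expect_error(load_model(p2), "corrupt|format")
  p3 <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(a = 1), p3)
  expect_error(load_model(p3), "format")
})
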