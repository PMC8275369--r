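test_that("channel weights match a central finite-difference oracle", {
  toy <- ref_toy_model(nf = 4L, width = 20L, seed = 7L)
  for (layer in c(1L, 4L, 7L)) {
    fd <- ref_fd_actgrad(toy$model$params, toy$x, layer, eps = 1e-4)
    a_fd <- if (layer == 1L) vapply(fd, mean, 0) else colMeans(fd)
    a <- channel_importance(toy$model, toy$x, layer)
    expect_equal(a, a_fd, tolerance = 1e-3)
  }
})

test_that("gradcam_map equals the rectified weighted activation sum", {
  toy <- ref_toy_model(nf = 2L, width = 20L, seed = 11L)
  sal <- encore:::model_saliency(toy$model, toy$x)
  # hand arithmetic on the two filters of the first conv layer
  a <- c(mean(sal$gradients[[1]][, 1]), mean(sal$gradients[[1]][, 2]))
  hand <- pmax(a[1] * sal$activations[[1]][, 1] +
                 a[2] * sal$activations[[1]][, 2], 0)
  gm <- gradcam_map(toy$model, toy$x, 1L)
  expect_equal(gm$kind, "feature-wise")
  expect_equal(as.numeric(t(gm$values)), as.numeric(hand))

  # last 1D layer: weighted sum, ReLU, then linear interpolation to bins
  a7 <- colMeans(sal$gradients[[7]])
  pre <- pmax(as.numeric(sal$activations[[7]] %*% a7), 0)
  centers <- 4 * (seq_along(pre) - 1) + 1.5
  hand7 <- approx(centers, pre, xout = 0:19, rule = 2)$y
  gm7 <- gradcam_map(toy$model, toy$x, 7L)
  expect_equal(gm7$kind, "position-wise")
  expect_equal(gm7$values, hand7)
})

test_that("maps are non-negative with exact shapes on every input", {
  toy <- ref_toy_model(nf = 4L, width = 32L, seed = 23L)
  withr::with_seed(5, {
    for (rep in 1:5) {
      x <- matrix(abs(rnorm(5 * 32)), 5, 32)
      pw <- gradcam_map(toy$model, x, 7L)$values
      fw <- gradcam_map(toy$model, x, 1L)$values
      expect_length(pw, 32L)
      expect_equal(dim(fw), c(5L, 32L))
      expect_true(all(pw >= 0) && all(fw >= 0))
    }
  })
})

test_that("position-wise scores are length 400 deterministic bin scores", {
  fitted <- fx_model_small()
  sim <- fx_sim_small()
  m <- sim$dataset$x[, , 1]
  s1 <- positionwise_scores(fitted, m)
  expect_length(s1, 400L)
  expect_true(all(s1 >= 0))
  expect_identical(s1, positionwise_scores(fitted, m))
})

test_that("the map rescales linearly with a consistent activation rescaling", {
  # scaling the weighted activation sum scales the pre-interpolation map:
  # interpolation is linear, so the exported map scales identically
  toy <- ref_toy_model(nf = 4L, width = 20L, seed = 13L)
  sal <- encore:::model_saliency(toy$model, toy$x)
  a <- colMeans(sal$gradients[[7]])
  pre <- pmax(as.numeric(sal$activations[[7]] %*% a), 0)
  centers <- 4 * (seq_along(pre) - 1) + 1.5
  m1 <- approx(centers, pre, xout = 0:19, rule = 2)$y
  m3 <- approx(centers, 3 * pre, xout = 0:19, rule = 2)$y
  expect_equal(m3, 3 * m1)
})

test_that("position-wise importance localises a centered planted enhancer", {
  sim <- fx_sim_centered()
  fitted <- fx_model_centered()
  ds <- sim$dataset
  pos_idx <- which(ds$label == 1L)[1:5]
  hits <- 0L
  for (i in pos_idx) {
    w <- ds$windows[i, ]
    core <- sim$truth[sim$truth$chrom == w$chrom &
                        sim$truth$start >= w$start &
                        sim$truth$end <= w$end, ][1, ]
    s <- positionwise_scores(fitted, ds$x[, , i])
    peak_pos <- w$start + (which.max(s) - 1) * 10 + 5
    if (peak_pos >= core$start && peak_pos < core$end) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("feature-wise scores localise the informative signal", {
  # only accessibility carries signal: histone amplitude is negligible.
  # Note the 5 x 10 kernels span all assay rows, so every conv1 output row
  # sees the accessibility track and per-row attribution is smeared by
  # design; the testable properties are (i) importance concentrates at the
  # signal position (the window centre) and (ii) the dominant row lies
  # within one kernel step of the accessibility row.
  sim <- fx("sim_acconly", function() {
    simulate_dataset(sim_config(n_positive = 20L, noise_scale = 0.2,
                                histone_amplitude = 0.01, trough_depth = 0,
                                offset_range = 0L, seed = 303L))
  })
  fitted <- fx("model_acconly", function() {
    m <- build_model(model_config(n_filters = 8L), sim$dataset$panel, seed = 8L)
    train_model(m, sim$dataset,
                train_config(learning_rate = 5e-4, epochs = 12L,
                             patience = 6L, seed = 8L))
  })
  prof <- mean_featurewise_profile(
    fitted, sim$dataset$x[, , which(sim$dataset$label == 1L)[1:10]])
  expect_equal(dim(prof), c(5L, 400L))
  curve <- colMeans(prof)
  central <- mean(curve[151:250])
  outer <- mean(curve[c(1:50, 351:400)])
  expect_gt(central, outer)
  expect_true(which.max(rowMeans(prof)) %in% 2:4)
})

test_that("a zero model on zero input yields an all-zero feature map", {
  m <- build_model(model_config(n_filters = 4L, width = 16L))
  m$params <- lapply(m$params, function(w) w * 0)
  fw <- featurewise_scores(m, matrix(0, 5, 16))
  expect_true(all(fw == 0))
})
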