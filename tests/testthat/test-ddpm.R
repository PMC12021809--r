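# Small schedules and grids keep the diffusion tests CPU-friendly; the
# algebra under test is scale-free.

test_that("noise schedule invariants hold for the default and custom schedules", {
  sch <- noise_schedule()
  expect_identical(sch$T, 1000L)
  expect_true(all(sch$beta > 0))
  expect_true(all(diff(sch$beta) >= 0))
  expect_true(all(diff(sch$alpha_bar) < 0))
  expect_lt(sch$alpha_bar[sch$T], 1e-3)
  set.seed(4)
  for (i in 1:5) {
    b <- sort(runif(20, 1e-4, 0.3))
    s <- noise_schedule(beta = b)
    expect_true(all(diff(s$alpha_bar) < 0))
    expect_equal(s$alpha_bar, cumprod(1 - b))
  }
  expect_error(noise_schedule(beta = c(0.1, 0.05)), "non-decreasing")
  expect_error(noise_schedule(beta = c(0, 0.1)), "in \\(0, 1\\)")
})

test_that("forward noising reduces to the identity for a vanishing schedule", {
  sch <- noise_schedule(beta = rep(1e-12, 10))
  x0 <- matrix(runif(16, -1, 1), 4, 4)
  for (t in c(1, 5, 10)) {
    expect_equal(forward_noising(x0, t, sch, seed = 1)$x_t, x0,
      tolerance = 1e-5
    )
  }
  expect_error(forward_noising(x0, 11, sch), "out of range")
  expect_error(forward_noising(x0, 0, sch), "out of range")
})

test_that("closed-form forward marginal matches stepwise iteration of the kernel", {
  sch <- noise_schedule(n_steps = 50, beta_start = 1e-3, beta_end = 0.08)
  x0 <- matrix(c(0.8, -0.5, 0.2, -0.9), 2, 2)
  t_probe <- 25L
  n_draws <- 4000L
  set.seed(77)
  # oracle: iterate x_s = sqrt(1-beta_s) x_{s-1} + sqrt(beta_s) eps_s
  step_draws <- vapply(seq_len(n_draws), function(i) {
    x <- x0
    for (s in seq_len(t_probe)) {
      x <- sqrt(1 - sch$beta[s]) * x + sqrt(sch$beta[s]) *
        matrix(rnorm(4), 2, 2)
    }
    as.vector(x)
  }, numeric(4))
  ab <- sch$alpha_bar[t_probe]
  mu_th <- sqrt(ab) * as.vector(x0)
  var_th <- 1 - ab
  se_mu <- sqrt(var_th / n_draws)
  se_var <- var_th * sqrt(2 / (n_draws - 1))
  for (k in 1:4) {
    expect_lt(abs(mean(step_draws[k, ]) - mu_th[k]), 3 * se_mu)
    expect_lt(abs(var(step_draws[k, ]) - var_th), 3 * se_var)
  }
  # and the closed form itself produces the same moments
  closed <- vapply(seq_len(n_draws), function(i) {
    as.vector(forward_noising(x0, t_probe, sch)$x_t)
  }, numeric(4))
  for (k in 1:4) {
    expect_lt(abs(mean(closed[k, ]) - mu_th[k]), 3 * se_mu)
    expect_lt(abs(var(closed[k, ]) - var_th), 3 * se_var)
  }
})

test_that("terminal-time marginal of the default schedule is standard normal", {
  sch <- noise_schedule()
  x0 <- matrix(0.9, 3, 3)
  set.seed(5)
  draws <- replicate(3000, forward_noising(x0, sch$T, sch)$x_t[1, 1])
  expect_lt(abs(mean(draws)), 3 / sqrt(3000))
  expect_lt(abs(var(draws) - 1), 3 * sqrt(2 / 2999))
})

test_that("reverse step is the identity in the zero-noise, zero-prediction limit", {
  sch <- noise_schedule(beta = rep(1e-12, 5))
  null_model <- list(predict = function(x, t) 0 * x)
  x <- matrix(rnorm(16), 4, 4)
  expect_equal(reverse_step(x, 3, null_model, sch, noise = 0), x,
    tolerance = 1e-9
  )
  expect_error(reverse_step(x, 6, null_model, sch), "out of range")
})

test_that("noise-free reverse chain with the exact-noise oracle recovers x0", {
  sch <- noise_schedule(n_steps = 50, beta_start = 1e-3, beta_end = 0.08)
  set.seed(8)
  x0 <- matrix(runif(64, -0.9, 0.9), 8, 8)
  # oracle predicts the noise consistent with the closed-form marginal at t
  oracle <- list(predict = function(x, t) {
    (x - sqrt(sch$alpha_bar[t]) * x0) / sqrt(1 - sch$alpha_bar[t])
  })
  x <- forward_noising(x0, sch$T, sch, seed = 2)$x_t
  for (t in rev(seq_len(sch$T))) {
    x <- reverse_step(x, t, oracle, sch, noise = 0 * x)
  }
  expect_lt(max(abs(x - x0)), 1e-3)
})

test_that("denoiser training reduces the loss and is seed-reproducible", {
  sch <- noise_schedule(n_steps = 40, beta_start = 1e-3, beta_end = 0.09)
  fx <- lapply(1:12, function(i) {
    generate_lge_like_fixture(
      fixture_params(shape = c(16, 16), correlation_length = 3),
      seed = mix_seed(5, "fx", i)
    )
  })
  cfg <- ddpm_train_config(epochs = 8, seed = 4, batch_size = 6)
  m <- train_ddpm(fx, cfg, sch,
    model = ddpm_unet(channels = c(4, 6, 8), seed = 11)
  )
  expect_length(m$loss_trace, 8)
  expect_lt(m$loss_trace[8], m$loss_trace[1])
  m2 <- train_ddpm(fx, cfg, sch,
    model = ddpm_unet(channels = c(4, 6, 8), seed = 11)
  )
  expect_identical(m$loss_trace, m2$loss_trace)
  expect_error(train_ddpm(list(), cfg, sch), "at least 2")
})

test_that("a denoiser trained on constant maps collapses its samples", {
  sch <- noise_schedule(n_steps = 40, beta_start = 1e-3, beta_end = 0.09)
  const_maps <- lapply(1:8, function(i) matrix(1, 16, 16)) # 1 IIR = 0 in model range
  m <- train_ddpm(
    const_maps,
    ddpm_train_config(epochs = 250, seed = 9, batch_size = 2, lr = 3e-3), sch,
    model = ddpm_unet(channels = c(6, 10, 14), seed = 2)
  )
  s <- sample_maps(m, sch, 4, seed = 3, shape = c(16, 16))
  sds <- vapply(s, sd, numeric(1))
  expect_true(all(sds < 0.1))
  # and the collapse point is the training constant (1 IIR)
  expect_true(all(abs(vapply(s, mean, numeric(1)) - 1) < 0.1))
})

test_that("sampling is seed-reproducible and produces 96x96 maps by default", {
  sch <- noise_schedule(n_steps = 6, beta_start = 0.05, beta_end = 0.3)
  m <- ddpm_unet(channels = c(2, 3, 4), seed = 5)
  s1 <- sample_maps(m, sch, 1, seed = 10)
  expect_identical(dim(s1[[1]]), c(96L, 96L))
  expect_identical(attr(s1[[1]], "source"), "synthetic")
  expect_true(all(s1[[1]] >= 0 & s1[[1]] <= 2))
  s2 <- sample_maps(m, sch, 1, seed = 10)
  expect_identical(unclass(s1[[1]]), unclass(s2[[1]]))
})

test_that("a fixture-trained denoiser emits maps that mostly pass the entropy filter", {
  # quarter-scale study conditions: 24 px maps with the correlation length
  # and filter smoothing scaled by the same factor as the grid
  px <- 24
  sch <- noise_schedule(n_steps = 50, beta_start = 1e-3, beta_end = 0.09)
  fx <- lapply(1:24, function(i) {
    generate_lge_like_fixture(
      fixture_params(shape = c(px, px), correlation_length = 8 * px / 96),
      seed = mix_seed(5, "fx", i)
    )
  })
  cfg <- spatial_stats_config(filter_sigma = 3 * px / 96)
  expect_gte(length(filter_by_entropy(fx, cfg)) / length(fx), 0.8)
  m <- train_ddpm(fx, ddpm_train_config(epochs = 60, seed = 4), sch)
  s <- sample_maps(m, sch, 50, seed = 6, shape = c(px, px))
  kept <- filter_by_entropy(s, cfg)
  expect_gte(length(kept), 40)
})
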