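test_that("dominant frequency finds spectral peaks and honours the 20 Hz cap", {
  t_s <- seq(0, 1.999, by = 0.001)
  n_nodes <- 4
  v <- matrix(-80, n_nodes, length(t_s))
  v[1, ] <- -20 + 45 * sin(2 * pi * 7 * t_s) # crosses -40: active
  v[2, ] <- -20 + 10 * sin(2 * pi * 6 * t_s) + 45 * sin(2 * pi * 25 * t_s)
  # node 3: action-potential-like train at 250 ms cycle length
  v[3, ] <- -80 + 100 * (t_s %% 0.25 < 0.08)
  # node 4 stays quiescent at rest
  res <- fake_result(v, dims = c(2, 2))
  df <- dominant_frequency_map(res, out_dim = 2)$la
  expect_equal(df[1, 1], 7, tolerance = 0.51)
  expect_equal(df[2, 1], 6, tolerance = 0.51) # 25 Hz peak excluded
  expect_equal(df[1, 2], 4, tolerance = 0.51) # 1 / 0.25 s
  expect_equal(df[2, 2], 0) # quiescent
  expect_true(all(df <= 20))
  short <- fake_result(v[, 1:500, drop = FALSE], dims = c(2, 2))
  expect_error(dominant_frequency_map(short), "shorter than 2 periods")
})

test_that("winding-number detector matches analytic vortices and brute force", {
  n <- 31
  xx <- col(matrix(0, n, n)); yy <- row(matrix(0, n, n))
  vortex <- atan2(yy - 16, xx - 16)
  s <- detect_phase_singularities(vortex)
  expect_identical(nrow(s), 1L)
  expect_equal(s$charge, 1)
  expect_lt(abs(s$x - 16) + abs(s$y - 16), 2)
  # uniform phase: nothing
  expect_identical(nrow(detect_phase_singularities(matrix(1.2, n, n))), 0L)
  # figure-of-eight: mirrored vortices of opposite charge, zero total
  fig8 <- atan2(yy - 16, xx - 8) - atan2(yy - 16, xx - 24)
  s8 <- detect_phase_singularities(fig8)
  expect_identical(nrow(s8), 2L)
  expect_identical(sum(s8$charge), 0L)
  # agreement with the explicit loop-integral oracle on random smooth fields
  set.seed(3)
  for (i in 1:3) {
    f <- fibrotwin:::smooth_matrix(matrix(rnorm(31 * 31), 31, 31), 2) * 40
    ours <- detect_phase_singularities(atan2(sin(f), cos(f)))
    oracle <- ps_bruteforce(atan2(sin(f), cos(f)))
    n_oracle <- if (is.null(oracle)) 0L else nrow(oracle)
    expect_identical(nrow(ours), n_oracle)
    if (n_oracle > 0) {
      expect_equal(sort(ours$charge), sort(oracle[, 3]))
    }
  }
})

test_that("phase extraction flags rotating activity and validates the frame index", {
  # voltage whose analytic phase is a rotating vortex
  n <- 21; n_t <- 200
  xx <- col(matrix(0, n, n)); yy <- row(matrix(0, n, n))
  # core at a plaquette center so the stationary rotor pins to one pixel
  theta <- atan2(yy - 11.5, xx - 11.5)
  v <- matrix(0, n * n, n_t)
  for (fr in seq_len(n_t)) {
    v[, fr] <- -40 + 30 * cos(as.vector(theta) - 2 * pi * 8 * fr / 1000)
  }
  res <- fake_result(v, dims = c(n, n))
  ps <- phase_and_singularities(res, 100)
  expect_identical(nrow(ps$singularities), 1L)
  expect_lt(abs(ps$singularities$x - 11.5) + abs(ps$singularities$y - 11.5), 3)
  expect_true(all(ps$phase$la > -pi & ps$phase$la <= pi + 1e-12))
  expect_error(phase_and_singularities(res, 0), "out of range")
  expect_error(phase_and_singularities(res, n_t + 1), "out of range")

  # stationary rotor: raw PSD counts concentrate at the core and their
  # total equals the number of detections (conservation, no smoothing)
  psd <- psd_map(res, smoothing_sigma = 0, out_dim = n)
  expect_identical(sum(unlist(lapply(psd$raw, sum))), as.numeric(psd$n_detections))
  core <- which(psd$raw$la == max(psd$raw$la), arr.ind = TRUE)[1, ]
  expect_lt(abs(core[1] - 12) + abs(core[2] - 12), 3)
  expect_gte(max(psd$raw$la), 0.9 * n_t)

  # no activity: all-zero map
  quiet <- fake_result(matrix(-80, 16, 100), dims = c(4, 4))
  psd0 <- psd_map(quiet, out_dim = 4)
  expect_identical(psd0$n_detections, 0L)
  expect_true(all(psd0$psd$la == 0))
})

test_that("termination labels implement the closed 0-60 percent last-peak rule", {
  mk <- function(last_peak_frac, n = 16, n_t = 1000) {
    v <- matrix(-80, n, n_t)
    pk <- max(2, round(last_peak_frac * n_t) - 1)
    for (t in seq(100, pk, by = 150)) v[, t] <- 10 # peaks above -40
    v[, pk] <- 10
    fake_result(v, dims = c(4, 4))
  }
  all_res <- list(
    "PVI" = mk(0.5), "PVI+LA" = mk(0.98),
    "PVI+RA" = mk(0.6), "PVI+LA+RA" = mk(0.2)
  )
  gt <- ground_truth_label(all_res)
  expect_identical(gt$strategy, ablation_strategies())
  expect_true(gt$terminated[1]) # quiet after 50%
  expect_false(gt$terminated[2]) # active through the end
  expect_true(gt$terminated[3]) # boundary 0.6 inclusive
  expect_true(gt$terminated[4])
  expect_true(all(gt$mean_last_peak_fraction >= 0 &
    gt$mean_last_peak_fraction <= 1))
  expect_equal(gt$mean_last_peak_fraction[4], 0.2, tolerance = 0.01)
  expect_error(ground_truth_label(all_res[1:3]), "missing strategy")
})

test_that("feature stacks carry five aligned, normalized channels per atrium", {
  la <- generate_lge_like_fixture(fixture_params(shape = c(24, 24)), seed = 21)
  ra <- generate_lge_like_fixture(fixture_params(shape = c(24, 24)), seed = 22)
  sh <- tissue_sheet(la, ra, solver_dim = 24, spacing = 4, chi = 2.3)
  init <- initiate_spirals(sh, 4, seed = 2)
  res <- run_monodomain(sh, duration = 0.5, dt = 0.05, n_sub = 2, init = init$state)
  fs <- feature_stack(res, la, ra, out_dim = 24)
  expect_s3_class(fs, "feature_stack")
  expect_identical(dim(fs$la), c(24L, 24L, 5L))
  expect_identical(dim(fs$ra), c(24L, 24L, 5L))
  expect_length(fs$channels, 5)
  # masks binary; RA PVI channel all zeros; everything normalized
  expect_true(all(fs$la[, , 1] %in% c(0, 1)))
  expect_true(all(fs$ra[, , 1] == 0))
  expect_true(all(fs$la[, , 2] %in% c(0, 1)))
  expect_true(all(fs$la >= 0 & fs$la <= 1.01))
  expect_true(all(fs$ra >= 0 & fs$ra <= 1.01))
  expect_true(all(fs$la[, , 4] <= 1)) # DF / f_max
})
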