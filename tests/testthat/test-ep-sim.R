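# The strand and single-cell runs take a couple of seconds each; the chi
# calibration is cached per session by default_chi().

test_that("single-cell action potential matches an independent adaptive-ODE integration", {
  skip_if_not_installed("deSolve")
  cell <- fibrotwin:::strand_sheet(1, af_remodeling = FALSE)
  res <- run_monodomain(cell,
    duration = 0.6, dt = 0.02, n_sub = 1, record_dt = 1,
    stim = list(nodes = 1, start = 10, dur = 2, amp = 40)
  )
  v_cpp <- res$voltage[1, ]
  expect_gt(v_cpp[5], -85)
  expect_lt(v_cpp[5], -75)
  expect_gt(max(v_cpp), 0)
  sc <- as.list(ionic_scaling_for(0, af_remodeling_on = FALSE)[1, ])
  out <- deSolve::lsoda(
    courtemanche_rest(), seq(0, 600, by = 1), courtemanche_derivs,
    parms = list(
      scaling = sc,
      stim = function(t) if (t >= 10 && t < 12) 40 else 0
    ),
    rtol = 1e-6, atol = 1e-8
  )
  v_r <- out[, "V"]
  # same upstroke timing and morphology: compare away from the stiff
  # upstroke sample where 1 ms sampling aliases the comparison
  idx <- 30:600
  expect_lt(sqrt(mean((v_cpp[idx] - v_r[idx])^2)), 1)
  expect_lt(abs(max(v_cpp) - max(v_r)), 5)
})

test_that("resting tissue without stimulus stays quiescent for a second", {
  m <- fibrosis_map(matrix(0.5, 12, 12), map_id = "quiet")
  sh <- tissue_sheet(m, solver_dim = 12, spacing = 1, chi = 2.3)
  res <- run_monodomain(sh, duration = 1, dt = 0.05, n_sub = 2)
  drift <- apply(res$voltage, 1, function(v) max(abs(v - v[1])))
  expect_lt(max(drift), 1)
  expect_true(all(res$upstrokes == 0))
})

test_that("the diffusion operator conserves the spatial mean (no-flux)", {
  m <- fibrosis_map(matrix(runif(64, 0, 2), 8, 8), map_id = "d")
  sh <- tissue_sheet(m, solver_dim = 8, spacing = 1, chi = 2.3)
  set.seed(2)
  v <- rnorm(sh$n_nodes)
  dt <- 0.1
  m0 <- mean(v)
  for (i in 1:1000) { # 100 ms of pure diffusion
    dv <- numeric(sh$n_nodes)
    f <- sh$edge_w * (v[sh$edges[, 2]] - v[sh$edges[, 1]])
    for (e in seq_along(f)) {
      dv[sh$edges[e, 1]] <- dv[sh$edges[e, 1]] + f[e]
      dv[sh$edges[e, 2]] <- dv[sh$edges[e, 2]] - f[e]
    }
    v <- v + dt * dv
  }
  expect_lt(abs(mean(v) - m0), 1e-6)
  expect_lt(sd(v), 1) # and it actually diffused
})

test_that("fully ablated tissue can never be activated", {
  m <- fibrosis_map(matrix(0.5, 10, 10), map_id = "abl")
  sh <- tissue_sheet(m,
    solver_dim = 10, spacing = 1, chi = 2.3,
    masks = list(la = matrix(TRUE, 10, 10))
  )
  res <- run_monodomain(sh,
    duration = 0.2, dt = 0.05, n_sub = 1,
    stim = list(nodes = 1:10, start = 5, dur = 2, amp = 80)
  )
  expect_true(all(res$voltage < -40))
  expect_true(all(res$last_activation < 0))
  expect_false(is_sustained(res))
})

test_that("calibrated conduction velocities reproduce the published bin values", {
  chi <- default_chi()
  expect_equal(measure_cv(0.40, chi = chi), 0.81, tolerance = 0.02)
  expect_equal(measure_cv(0.31, chi = chi), 0.74, tolerance = 0.10)
  expect_equal(measure_cv(0.28, chi = chi), 0.71, tolerance = 0.10)
  expect_equal(measure_cv(0.19, chi = chi), 0.58, tolerance = 0.10)
})

test_that("CV is monotone in conductivity and follows square-root scaling", {
  chi <- default_chi()
  cvs <- vapply(c(0.19, 0.28, 0.31, 0.40), measure_cv, numeric(1), chi = chi)
  expect_true(all(diff(cvs) > 0))
  # sqrt(D) scaling is a continuum property: check on a fine strand
  chif <- calibrate_chi(n_nodes = 250, spacing = 0.1, dt = 0.01)
  r <- measure_cv(0.4, chi = chif, n_nodes = 250, spacing = 0.1, dt = 0.01) /
    measure_cv(0.1, chi = chif, n_nodes = 250, spacing = 0.1, dt = 0.01)
  expect_equal(r, 2, tolerance = 0.05)
})

test_that("halving the time step changes measured CV by well under two percent", {
  chi <- default_chi()
  cv1 <- measure_cv(0.31, chi = chi, dt = 0.02)
  cv2 <- measure_cv(0.31, chi = chi, dt = 0.01)
  expect_lt(abs(cv1 - cv2) / cv1, 0.02)
})

test_that("conduction block raises an error rather than returning a velocity", {
  expect_error(measure_cv(0.004, chi = default_chi()), "block")
})

test_that("a too-coarse diffusion step is rejected with a stability error", {
  sh <- fibrotwin:::strand_sheet(10, spacing = 0.01, sigma = 0.4, chi = 2.3)
  expect_error(run_monodomain(sh, duration = 0.01, dt = 0.02), "stability")
})

test_that("spiral initial conditions carry the requested number of phase singularities", {
  m1 <- generate_lge_like_fixture(fixture_params(shape = c(48, 48)), seed = 3)
  sh <- tissue_sheet(m1, solver_dim = 48, spacing = 1, chi = 2.3)
  one <- initiate_spirals(sh, n_spirals = 1, seed = 5)
  ps <- ps_bruteforce(one$phase$la)
  expect_identical(nrow(ps), 1L)
  expect_equal(ps[1, 3], 1)
  # core location within a pixel of the detected singularity
  expect_lt(abs(ps[1, 1] - one$cores[[1]]$xy[2]), 1.5)
  expect_lt(abs(ps[1, 2] - one$cores[[1]]$xy[1]), 1.5)
  m2 <- generate_lge_like_fixture(fixture_params(shape = c(48, 48)), seed = 4)
  sh2 <- tissue_sheet(m1, m2, solver_dim = 48, spacing = 1, chi = 2.3)
  four <- initiate_spirals(sh2, n_spirals = 4, seed = 6)
  expect_identical(nrow(ps_bruteforce(four$phase$la)), 2L)
  expect_identical(nrow(ps_bruteforce(four$phase$ra)), 2L)
  # reproducible placement and state
  four2 <- initiate_spirals(sh2, n_spirals = 4, seed = 6)
  expect_identical(four$state, four2$state)
  expect_identical(four$cores, four2$cores)
  expect_error(
    initiate_spirals(sh, cores = list(list(sheet = "la", xy = c(500, 5)))),
    "outside"
  )
})

test_that("the sustainability rule keys on the latest upstroke time", {
  fake <- function(last, dur = 1) {
    structure(list(duration = dur, last_activation = last),
      class = "simulation_result"
    )
  }
  expect_true(is_sustained(fake(800))) # 80% of duration
  expect_false(is_sustained(fake(500))) # 50%
  expect_true(is_sustained(fake(600))) # boundary: >= 60%
  expect_false(is_sustained(fake(-1))) # never activated
  expect_error(is_sustained(fake(10, dur = 0)), "zero-duration")
})

test_that("identical configuration and seed give bit-identical traces", {
  m <- generate_lge_like_fixture(fixture_params(shape = c(24, 24)), seed = 9)
  sh <- tissue_sheet(m, solver_dim = 24, spacing = 2, chi = 2.3)
  init <- initiate_spirals(sh, 2, seed = 11)
  r1 <- run_monodomain(sh, duration = 0.2, dt = 0.05, n_sub = 2, init = init$state)
  r2 <- run_monodomain(sh, duration = 0.2, dt = 0.05, n_sub = 2, init = init$state)
  expect_identical(r1$voltage, r2$voltage)
  expect_identical(r1$final_state, r2$final_state)
})
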