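test_that("noise maps span exactly [0.25, 1.75] IIR and are seed-reproducible", {
  m <- generate_noise_map(seed = 11)
  expect_s3_class(m, "fibrosis_map")
  expect_identical(dim(m), c(96L, 96L))
  expect_equal(min(m), 0.25)
  expect_equal(max(m), 1.75)
  expect_identical(attr(m, "source"), "noise")
  expect_equal(
    unclass(generate_noise_map(seed = 11)),
    unclass(m)
  )
  expect_false(isTRUE(all.equal(
    unclass(generate_noise_map(seed = 12)), unclass(m)
  )))
  # a single-pixel draw has zero dynamic range: rescaling is undefined
  expect_error(generate_noise_map(shape = c(1, 1), seed = 1), "dynamic range")
  expect_error(generate_noise_map(shape = c(0, 4), seed = 1), "positive")
})

test_that("a 100-map noise ensemble has grand mean intensity near 1.0 IIR", {
  maps <- generate_map_ensemble(100, seed = 101, kind = "noise")
  grand <- mean(vapply(maps, mean, numeric(1)))
  expect_gt(grand, 0.98)
  expect_lt(grand, 1.02)
})

test_that("LGE-like fixtures reproduce the clinical summary statistics", {
  fx <- generate_map_ensemble(100, seed = 202, kind = "fixture")
  means <- vapply(fx, mean, numeric(1))
  expect_lt(abs(mean(means) - 1.1), 0.2)
  expect_gt(mean(abs(means - 1.1) < 0.2), 0.95)
  # patchy suprathreshold clusters on (nearly) every map
  frac <- vapply(fx, function(m) mean(m > 1.22), numeric(1))
  expect_gt(mean(frac >= 0.05 & frac <= 0.40), 0.9)
  expect_true(all(vapply(fx, min, numeric(1)) >= 0))
  expect_true(all(vapply(fx, max, numeric(1)) <= 2))
  expect_equal(
    unclass(generate_lge_like_fixture(seed = 5)),
    unclass(generate_lge_like_fixture(seed = 5))
  )
  expect_error(generate_lge_like_fixture(fixture_params(correlation_length = 0),
    seed = 1
  ), "correlation_length")
})

test_that("fixture maps degrade to near-constant as correlation length grows past the grid", {
  wide <- generate_lge_like_fixture(
    fixture_params(correlation_length = 192),
    seed = 3
  )
  expect_lt(sd(wide), 0.05)
})

test_that("gaussian smoothing preserves constants, shape and the noise-variance law", {
  const <- matrix(1.3, 20, 20)
  expect_equal(gaussian_smooth(const, 3), const)
  set.seed(42)
  ratios <- replicate(8, {
    w <- matrix(rnorm(96 * 96), 96, 96)
    s <- gaussian_smooth(w, 3)
    var(as.vector(s[20:77, 20:77])) / var(as.vector(w))
  })
  # white noise smoothed with sigma = 3: variance shrinks by ~ 1/(4*pi*9)
  expect_lt(abs(mean(ratios) - 1 / (4 * pi * 9)) / (1 / (4 * pi * 9)), 0.25)
  set.seed(1)
  x <- matrix(runif(64), 8, 8)
  expect_lt(max(abs(gaussian_smooth(x, 0.05) - x)), 1e-6)
  expect_identical(dim(gaussian_smooth(x, 2)), dim(x))
  expect_error(gaussian_smooth(x, 0), "sigma")
})

test_that("pixel-mass entropy matches hand values and the brute-force oracle", {
  raw <- spatial_stats_config(filter_sigma = NULL, se_mode = "weighted_eq34")
  expect_equal(shannon_entropy(matrix(0.7, 12, 12), raw), 1)
  one <- matrix(0, 6, 6); one[3, 4] <- 2
  expect_equal(shannon_entropy(one, raw), 0)
  two <- matrix(0, 4, 4); two[1, 1] <- 0.5; two[3, 2] <- 0.5
  expect_equal(shannon_entropy(two, raw), 0.25)
  set.seed(7)
  for (i in 1:5) {
    m <- matrix(runif(64), 8, 8)
    expect_equal(shannon_entropy(m, raw), entropy_bruteforce(m),
      tolerance = 1e-12
    )
  }
  expect_error(shannon_entropy(matrix(0, 4, 4), raw), "all-zero")
  for (mode in c("histogram", "binary_fraction")) {
    cfg <- spatial_stats_config(filter_sigma = NULL, se_mode = mode)
    se <- shannon_entropy(matrix(runif(256, 0, 2), 16, 16), cfg)
    expect_gte(se, 0); expect_lte(se, 1)
  }
})

test_that("Moran's I matches hand values, the O(n^2) oracle and ape", {
  raw <- spatial_stats_config(filter_sigma = NULL)
  cb <- matrix(c(1, -1), 4, 4); cb[, c(2, 4)] <- -cb[, c(2, 4)]
  expect_equal(morans_i(cb, raw), -1)
  set.seed(9)
  for (i in 1:5) {
    m <- matrix(rnorm(64), 8, 8)
    expect_equal(morans_i(m, raw), moran_bruteforce(m), tolerance = 1e-12)
  }
  # independent library cross-check (ape uses the same statistic)
  skip_if_not_installed("ape")
  m <- matrix(rnorm(64), 8, 8)
  W <- matrix(0, 64, 64)
  for (i in 1:8) for (j in 1:8) {
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      p <- c(i, j) + d
      if (all(p >= 1 & p <= 8)) W[(j - 1) * 8 + i, (p[2] - 1) * 8 + p[1]] <- 1
    }
  }
  W <- W / rowSums(W)
  expect_equal(morans_i(m, raw),
    unname(ape::Moran.I(as.vector(m), W)$observed),
    tolerance = 1e-10
  )
  expect_error(morans_i(matrix(2, 5, 5), raw), "zero variance")
  expect_lt(abs(morans_i(generate_noise_map(seed = 3), raw)), 0.05)
})

test_that("Moran's I of smoothed noise increases with smoothing scale", {
  m <- generate_noise_map(seed = 21)
  vals <- vapply(
    c(0.5, 1, 2, 3),
    function(s) morans_i(m, spatial_stats_config(filter_sigma = s)),
    numeric(1)
  )
  expect_true(all(diff(vals) > 0))
})

test_that("entropy ordering separates noise from structured fixtures", {
  noise <- generate_map_ensemble(25, seed = 31, kind = "noise")
  fix <- generate_map_ensemble(25, seed = 32, kind = "fixture")
  for (mode in c("histogram", "binary_fraction")) {
    cfg <- spatial_stats_config(se_mode = mode)
    expect_lt(
      mean(vapply(noise, shannon_entropy, numeric(1), config = cfg)),
      mean(vapply(fix, shannon_entropy, numeric(1), config = cfg))
    )
  }
  # the literal pixel-mass statistic inverts the ordering: smoothed noise is
  # nearly uniform, and uniform maps maximize pixel-mass entropy
  cfgw <- spatial_stats_config(se_mode = "weighted_eq34")
  expect_gt(
    mean(vapply(noise, shannon_entropy, numeric(1), config = cfgw)),
    mean(vapply(fix, shannon_entropy, numeric(1), config = cfgw))
  )
})

test_that("the entropy filter rejects maps at or below the threshold", {
  fix <- generate_map_ensemble(12, seed = 44, kind = "fixture")
  cfg <- spatial_stats_config()
  se <- vapply(fix, shannon_entropy, numeric(1), config = cfg)
  kept <- filter_by_entropy(fix, cfg)
  expect_identical(
    vapply(kept, function(m) attr(m, "map_id"), character(1)),
    vapply(fix[se > 0.66], function(m) attr(m, "map_id"), character(1))
  )
  # boundary: a map whose entropy equals the threshold exactly is excluded
  cfg_at <- spatial_stats_config(se_reject_threshold = se[1])
  expect_false(attr(fix[[1]], "map_id") %in%
    vapply(
      filter_by_entropy(fix, cfg_at),
      function(m) attr(m, "map_id"), character(1)
    ))
  expect_identical(filter_by_entropy(list(), cfg), list())
})

test_that("map text serialization round-trips values and metadata", {
  dir <- withr::local_tempdir()
  m <- generate_lge_like_fixture(seed = 77)
  write_fibrosis_map(m, file.path(dir, "m1.tsv"))
  back <- read_fibrosis_map(file.path(dir, "m1.tsv"))
  expect_equal(unclass(back), unclass(m), tolerance = 1e-9)
  expect_identical(attr(back, "map_id"), attr(m, "map_id"))
  expect_identical(attr(back, "source"), "fixture")
  write_fibrosis_map(generate_noise_map(seed = 8), file.path(dir, "m2.tsv"))
  maps <- ingest_map_dir(dir)
  expect_length(maps, 2)
  stats <- map_stats(maps)
  expect_s3_class(stats, "tbl_df")
  expect_identical(nrow(stats), 2L)
  expect_true(all(c("mean_iir", "shannon_entropy", "morans_i") %in%
    names(stats)))
})
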