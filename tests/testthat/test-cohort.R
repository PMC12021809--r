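test_that("cohort assembly is leakage-safe, sourced correctly and reproducible", {
  cfg <- experiment_config("smoke",
    seed = 42, n_train_real = 6, n_train_comparison = 4,
    n_validation = 3, n_test = 3,
    pool_sizes = c(train = 8L, validation = 3L, test = 3L)
  )
  co <- build_cohort(cfg)
  expect_identical(nrow(co$cases), 16L)
  expect_identical(sum(co$cases$split == "train_real"), 6L)
  expect_identical(sum(co$cases$split == "train_comparison"), 4L)
  expect_identical(sum(co$cases$split == "validation"), 3L)
  expect_identical(sum(co$cases$split == "test"), 3L)
  # map pools of different splits never share a map id
  used <- split(
    c(co$cases$la_map_id, co$cases$ra_map_id),
    rep(co$cases$split, 2)
  )
  splits <- names(used)
  for (i in seq_along(splits)) {
    for (j in seq_len(i - 1)) {
      if (co$pool_of_split[[splits[i]]] != co$pool_of_split[[splits[j]]]) {
        expect_length(intersect(used[[i]], used[[j]]), 0)
      }
    }
  }
  # every case references exactly two maps from its own split's pool
  for (r in seq_len(nrow(co$cases))) {
    pool <- co$pools[[co$pool_of_split[[co$cases$split[r]]]]]
    expect_true(co$cases$la_map_id[r] %in% names(pool))
    expect_true(co$cases$ra_map_id[r] %in% names(pool))
  }
  # comparison pool carries the configured source
  expect_true(all(vapply(
    co$pools$comparison,
    function(m) attr(m, "source"), character(1)
  ) == "noise"))
  # identical global seed, identical manifest
  co2 <- build_cohort(cfg)
  expect_identical(co$cases, co2$cases)
  d <- withr::local_tempdir()
  write_cohort_manifest(co, file.path(d, "m1.json"))
  write_cohort_manifest(co2, file.path(d, "m2.json"))
  expect_identical(
    readLines(file.path(d, "m1.json")),
    readLines(file.path(d, "m2.json"))
  )
})

test_that("fixture-sourced comparison pools are supported and validated", {
  cfg <- experiment_config("smoke",
    seed = 2, comparison_source = "fixture",
    n_train_real = 1, n_train_comparison = 2, n_validation = 1, n_test = 1,
    pool_sizes = c(train = 3L, validation = 2L, test = 2L)
  )
  co <- build_cohort(cfg)
  expect_true(all(vapply(
    co$pools$comparison,
    function(m) attr(m, "source"), character(1)
  ) == "fixture"))
  expect_error(
    experiment_config("smoke", comparison_source = "synthetic"),
    "ddpm_model"
  )
  expect_error(experiment_config("smoke", n_test = 0), ">= 1")
})

test_that("a virtual patient runs end to end with reproducible labels", {
  cfg <- experiment_config("smoke",
    seed = 5, n_train_real = 1, n_train_comparison = 1,
    n_validation = 1, n_test = 1,
    pool_sizes = c(train = 2L, validation = 2L, test = 2L),
    duration = 0.4, solver_dim = 24L, spacing = 2, chi = 2.2814,
    feature_dim = 24L
  )
  co <- build_cohort(cfg)
  rec <- run_case(co, "case-001")
  expect_false(rec$failed)
  expect_length(rec$labels, 4)
  expect_s3_class(rec$gt, "tbl_df")
  expect_identical(rec$gt$strategy, ablation_strategies())
  expect_s3_class(rec$features, "feature_stack")
  expect_identical(dim(rec$features$la), c(24L, 24L, 5L))
  expect_true(all(rec$gt$mean_last_peak_fraction >= 0 &
    rec$gt$mean_last_peak_fraction <= 1))
  rec2 <- run_case(co, "case-001")
  expect_identical(rec$labels, rec2$labels)
  expect_identical(rec$features$la, rec2$features$la)
  expect_error(run_case(co, "case-999"), "unknown case")
})

test_that("solver failures are captured per case, not propagated", {
  cfg <- experiment_config("smoke",
    seed = 5, n_train_real = 1, n_train_comparison = 1,
    n_validation = 1, n_test = 1,
    pool_sizes = c(train = 2L, validation = 2L, test = 2L),
    duration = 0.05, solver_dim = 12L, spacing = 2,
    chi = 1e-6 # absurd coupling: guaranteed stability failure
  )
  co <- build_cohort(cfg)
  rec <- run_case(co, "case-001")
  expect_true(rec$failed)
  expect_match(rec$error, "stability|unstable")
  recs <- run_cohort(co)
  expect_length(recs, 4)
  expect_true(all(vapply(recs, function(r) r$failed, logical(1))))
})

test_that("YAML round-trip reproduces an experiment configuration", {
  d <- withr::local_tempdir()
  writeLines(c(
    "profile: smoke", "seed: 11", "duration: 0.5",
    "comparison_source: fixture", "n_test: 2"
  ), file.path(d, "cfg.yaml"))
  cfg <- read_experiment_config(file.path(d, "cfg.yaml"))
  expect_identical(cfg$profile, "smoke")
  expect_identical(cfg$seed, 11L)
  expect_equal(cfg$duration, 0.5)
  expect_identical(cfg$comparison_source, "fixture")
  expect_identical(cfg$n_test, 2L)
  expect_identical(cfg$solver_dim, 48L) # profile default retained
})
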