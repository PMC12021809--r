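# Synthetic feature stacks (32x32, from helper-fakes.R) keep these tests
# CPU-friendly; the network is resolution-agnostic (global average pooling).

test_that("exported fusion blocks match their definitions on toy latents", {
  mo <- moab_fuse(c(1, 2), c(3, 4))
  expect_equal(mo$channels[, , 1], matrix(c(4, 5, 5, 6), 2, 2)) # outer sum
  expect_equal(mo$channels[, , 2], matrix(c(3, 6, 4, 8), 2, 2)) # outer product
  expect_equal(mo$channels[, , 3], matrix(c(-2, -1, -3, -2), 2, 2))
  expect_equal(mo$channels[, , 4], matrix(c(1 / 3, 2 / 3, 1 / 4, 1 / 2), 2, 2),
    tolerance = 1e-5
  )
  z <- moab_fuse(rep(0, 4), rep(0, 4))
  expect_true(all(z$channels == 0))
  expect_error(moab_fuse(1:3, 1:4), "length mismatch")
  set.seed(2)
  u <- rnorm(32); v <- rnorm(32)
  f <- foaa_fuse(u, v)
  expect_length(f, 30) # post-FC width
  # cross-attention is direction-sensitive
  expect_false(isTRUE(all.equal(f, foaa_fuse(v, u))))
  # zeroed second modality: output is a deterministic function of u alone
  expect_identical(foaa_fuse(u, rep(0, 32)), foaa_fuse(u, rep(0, 32)))
  expect_false(isTRUE(all.equal(
    foaa_fuse(u, rep(0, 32)),
    foaa_fuse(rnorm(32), rep(0, 32))
  )))
  expect_error(foaa_fuse(1:3, 1:4), "length mismatch")
})

test_that("all four outputs are probabilities for arbitrary inputs", {
  set.seed(7)
  cases <- lapply(1:5, synth_case)
  for (fm in c("concat", "moab", "foaa")) {
    m <- siamese_classifier(fusion = fusion_config(fm), seed = 3)
    p <- predict(m, cases)
    expect_identical(dim(p), c(5L, 4L))
    expect_true(all(p >= 0 & p <= 1))
    expect_identical(colnames(p), ablation_strategies())
  }
})

test_that("rank AUC matches the degenerate and Monte Carlo references", {
  labs <- c(1, 1, 0, 0, 1)
  expect_equal(auc_rank(labs, labs), 1) # perfect scores
  expect_equal(auc_rank(1 - labs, labs), 0) # inverted scores
  expect_true(is.na(auc_rank(runif(5), rep(1, 5))))
  set.seed(11)
  labels <- rep(c(0, 1), 500)
  expect_equal(auc_rank(runif(1000), labels), 0.5, tolerance = 0.05)
  skip_if_not_installed("pROC")
  sc <- runif(200); lb <- rbinom(200, 1, 0.4)
  expect_equal(
    auc_rank(sc, lb),
    as.numeric(suppressMessages(pROC::auc(lb, sc, direction = "<"))),
    tolerance = 1e-10
  )
})

test_that("a separable synthetic cohort is learned to high validation AUC", {
  set.seed(1)
  cases <- lapply(1:48, synth_case)
  val <- lapply(101:130, synth_case)
  m <- train_classifier(cases, fusion_config("concat"),
    classifier_train_config(epochs = 40, seed = 3),
    val_cases = val
  )
  expect_gte(max(m$val_auc_trace), 0.95)
})

test_that("label-shuffled training collapses validation AUC to chance", {
  set.seed(2)
  cases <- lapply(1:40, synth_case)
  val <- lapply(201:230, synth_case)
  shuffle <- function(cs, perm) {
    lapply(seq_along(cs), function(i) {
      cs[[i]]$labels <- cs[[perm[i]]]$labels
      cs[[i]]
    })
  }
  cases <- shuffle(cases, sample(length(cases)))
  val <- shuffle(val, sample(length(val)))
  m <- train_classifier(cases, fusion_config("concat"),
    classifier_train_config(epochs = 12, seed = 5),
    val_cases = val
  )
  ev <- suppressWarnings(evaluate_roc_auc(m, val))
  expect_gt(ev$mean_auc, 0.3)
  expect_lt(ev$mean_auc, 0.7)
})

test_that("training is reproducible and rejects degenerate label sets", {
  set.seed(3)
  cases <- lapply(1:8, synth_case, d = 16)
  cfg <- classifier_train_config(epochs = 2, seed = 9)
  m1 <- train_classifier(cases, fusion_config("concat"), cfg)
  m2 <- train_classifier(cases, fusion_config("concat"), cfg)
  expect_identical(m1$loss_trace, m2$loss_trace)
  expect_identical(m1$params, m2$params)
  const_cases <- lapply(cases, function(cs) {
    cs$labels <- c(1, 1, 1, 1)
    cs
  })
  expect_error(train_classifier(const_cases, fusion_config("concat"), cfg),
    "single-class"
  )
})

test_that("one-class outputs are excluded from the mean AUC with a warning", {
  set.seed(4)
  cases <- lapply(1:10, synth_case, d = 16)
  for (i in seq_along(cases)) cases[[i]]$labels[3] <- 1 # PVI+RA one-class
  m <- siamese_classifier(fusion = fusion_config("concat"), seed = 1)
  expect_warning(ev <- evaluate_roc_auc(m, cases), "PVI\\+RA")
  expect_true(is.na(ev$per_strategy["PVI+RA"]))
  expect_false(is.na(ev$mean_auc))
})

test_that("grouped k-fold keeps map pools disjoint and is deterministic", {
  set.seed(5)
  cases <- lapply(1:20, synth_case, d = 16)
  groups <- rep(1:10, each = 2) # two cases share each map pool
  cv <- kfold_crossvalidate(cases,
    k = 5,
    config = classifier_train_config(epochs = 2, seed = 1),
    groups = groups, seed = 7
  )
  expect_s3_class(tidy(cv), "tbl_df")
  expect_identical(nrow(cv$folds), 5L)
  expect_true(all(cv$folds$mean_auc >= 0 & cv$folds$mean_auc <= 1))
  # partition: each case in exactly one fold; groups never split
  expect_length(cv$fold_assignment, 20)
  expect_true(all(table(cv$fold_assignment) > 0))
  for (g in unique(groups)) {
    expect_length(unique(cv$fold_assignment[groups == g]), 1)
  }
  cv2 <- kfold_crossvalidate(cases,
    k = 5,
    config = classifier_train_config(epochs = 2, seed = 1),
    groups = groups, seed = 7
  )
  expect_identical(cv$folds$mean_auc, cv2$folds$mean_auc)
  expect_error(kfold_crossvalidate(cases, k = 21), "exceeds")
  expect_error(kfold_crossvalidate(cases, k = 1), ">= 2")
  g <- glance(cv)
  expect_identical(nrow(g), 1L)
})
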