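#' Experiment configuration
#'
#' Bundles every knob of the in-silico study: cohort sizes per split, the
#' fibrosis source of the comparison training split, the map pools (with
#' the 80/10/10 leakage-safe partition of the "real-like" pool), episode
#' and solver settings, feature and classifier settings, and one global
#' seed from which every stage derives its own stream.
#'
#' Profiles: `smoke` (10/10/5/5 cases, 2 s episodes, 48 px sheets at 2 mm)
#' runs end-to-end on one CPU within the hour; `desk` (40/40/10/10, 64 px
#' at 1.5 mm) is the package default study; `full` (400/400/100/100, 15 s
#' episodes, 192 px at 0.5 mm) retains the full-scale protocol for cluster
#' use.
#'
#' @param profile `"smoke"`, `"desk"` or `"full"`.
#' @param seed global seed.
#' @param comparison_source `"noise"`, `"fixture"` or `"synthetic"`
#'   (synthetic requires `ddpm_model` + `ddpm_schedule`).
#' @param train_source which training split feeds the classifier:
#'   `"real"` (the fixture pool standing in for real maps) or
#'   `"comparison"`.
#' @param ... overrides of any profile field (see the returned list).
#' @param ddpm_model,ddpm_schedule trained denoiser for
#'   `comparison_source = "synthetic"`.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(profile = c("desk", "smoke", "full"),
                              seed = 1, comparison_source = "noise",
                              train_source = "real",
                              ddpm_model = NULL, ddpm_schedule = NULL, ...) {
  profile <- match.arg(profile)
  base <- switch(profile,
    smoke = list(
      n_train_real = 10L, n_train_comparison = 10L, n_validation = 5L,
      n_test = 5L, pool_sizes = c(train = 16L, validation = 6L, test = 6L),
      duration = 2, solver_dim = 48L, spacing = 2, dt = 0.05, n_sub = 2L,
      feature_dim = 48L, clf_epochs = 20L
    ),
    desk = list(
      n_train_real = 40L, n_train_comparison = 40L, n_validation = 10L,
      n_test = 10L, pool_sizes = c(train = 80L, validation = 10L, test = 10L),
      duration = 2, solver_dim = 64L, spacing = 1.5, dt = 0.05, n_sub = 2L,
      feature_dim = 96L, clf_epochs = 40L
    ),
    full = list(
      n_train_real = 400L, n_train_comparison = 400L, n_validation = 100L,
      n_test = 100L, pool_sizes = c(train = 80L, validation = 10L, test = 10L),
      duration = 15, solver_dim = 192L, spacing = 0.5, dt = 0.02, n_sub = 5L,
      feature_dim = 96L, clf_epochs = 100L
    )
  )
  cfg <- utils::modifyList(c(base, list(
    profile = profile, seed = as.integer(seed),
    comparison_source = comparison_source, train_source = train_source,
    map_shape = c(96L, 96L), n_spirals = 4L, chi = NULL,
    exclude_non_sustained = FALSE, quiet_exit_ms = 200,
    fusion = "concat", backbone = "densenet_like",
    clf_lr = 1e-3, clf_batch = 16L, clf_patience = 20L,
    fibrotic_threshold = 1.22, ablation_threshold = 1.22
  )), list(...))
  if (any(unlist(cfg[c(
    "n_train_real", "n_train_comparison", "n_validation", "n_test"
  )]) < 1)) {
    abort("cohort sizes must be >= 1")
  }
  cfg$ddpm_model <- ddpm_model
  cfg$ddpm_schedule <- ddpm_schedule
  if (comparison_source == "synthetic" &&
    (is.null(ddpm_model) || is.null(ddpm_schedule))) {
    abort("comparison_source = 'synthetic' needs `ddpm_model` and `ddpm_schedule`")
  }
  structure(cfg, class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' @param path YAML file with a `profile` field and any overrides.
#' @return an [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  profile <- y$profile %||% "desk"
  y$profile <- NULL
  do.call(experiment_config, c(list(profile = profile), y))
}

#' Assemble a leakage-safe virtual cohort
#'
#' Generates disjoint fibrosis-map pools per split - LGE-like fixtures for
#' the train/validation/test pools (the stand-ins for real maps, split
#' 80/10/10 by default) and the configured source for the comparison
#' training pool - then assigns each virtual patient two seeded draws from
#' its own split's pool only (LA and RA). Map reuse is allowed within a
#' split, never across splits.
#'
#' @param config an [experiment_config()].
#' @return list of class `cohort`: `cases` tibble (case_id, split,
#'   la_map_id, ra_map_id, per-case seeds), `pools` (named list of maps by
#'   id), `pool_of_split`, and the config.
#' @export
build_cohort <- function(config) {
  seed <- config$seed
  mk_fixture_pool <- function(n, tag) {
    maps <- lapply(seq_len(n), function(i) {
      generate_lge_like_fixture(
        fixture_params(shape = config$map_shape),
        seed = mix_seed(seed, "pool", tag, i)
      )
    })
    names(maps) <- sprintf("%s-%03d", tag, seq_len(n))
    maps
  }
  pools <- list(
    train = mk_fixture_pool(config$pool_sizes[["train"]], "train"),
    validation = mk_fixture_pool(config$pool_sizes[["validation"]], "val"),
    test = mk_fixture_pool(config$pool_sizes[["test"]], "test")
  )
  n_cmp <- config$pool_sizes[["train"]]
  pools$comparison <- switch(config$comparison_source,
    noise = {
      maps <- lapply(seq_len(n_cmp), function(i) {
        generate_noise_map(config$map_shape,
          seed = mix_seed(seed, "pool", "noise", i)
        )
      })
      names(maps) <- sprintf("noise-%03d", seq_len(n_cmp))
      maps
    },
    fixture = mk_fixture_pool(n_cmp, "cmp"),
    synthetic = {
      maps <- sample_maps(config$ddpm_model, config$ddpm_schedule,
        n = n_cmp, seed = mix_seed(seed, "pool", "synth"),
        shape = config$map_shape
      )
      maps <- filter_by_entropy(maps, spatial_stats_config())
      if (length(maps) < 2) abort("too few synthetic maps pass the entropy filter")
      names(maps) <- vapply(maps, function(m) attr(m, "map_id"), character(1))
      maps
    }
  )
  splits <- c(
    rep("train_real", config$n_train_real),
    rep("train_comparison", config$n_train_comparison),
    rep("validation", config$n_validation),
    rep("test", config$n_test)
  )
  pool_of_split <- c(
    train_real = "train", train_comparison = "comparison",
    validation = "validation", test = "test"
  )
  cases <- with_seed(mix_seed(seed, "assign"), {
    bind_rows(lapply(seq_along(splits), function(i) {
      pool <- pools[[pool_of_split[[splits[i]]]]]
      ids <- names(pool)
      tibble(
        case_id = sprintf("case-%03d", i),
        split = splits[i],
        la_map_id = sample(ids, 1),
        ra_map_id = sample(ids, 1),
        seed_spirals = mix_seed(seed, "spirals", i),
        seed_solver = mix_seed(seed, "solver", i)
      )
    }))
  })
  structure(list(
    cases = cases, pools = pools, pool_of_split = pool_of_split,
    config = config
  ), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "<cohort> %d cases (%s), pools: %s\n",
    nrow(x$cases),
    paste(sprintf("%s=%d", names(table(x$cases$split)), table(x$cases$split)),
      collapse = ", "
    ),
    paste(sprintf("%s=%d", names(x$pools), lengths(x$pools)), collapse = ", ")
  ))
  invisible(x)
}

#' Write the cohort manifest
#'
#' JSON manifest tracing every case to its maps and seeds; identical
#' global seeds reproduce identical manifests.
#'
#' @param cohort a [build_cohort()] result.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_cohort_manifest <- function(cohort, path) {
  jsonlite::write_json(list(
    seed = cohort$config$seed, profile = cohort$config$profile,
    comparison_source = cohort$config$comparison_source,
    pools = lapply(cohort$pools, names),
    cases = cohort$cases
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

case_maps <- function(cohort, case) {
  pool <- cohort$pools[[cohort$pool_of_split[[case$split]]]]
  list(la = pool[[case$la_map_id]], ra = pool[[case$ra_map_id]])
}

#' Simulate one virtual patient
#'
#' Runs the pre-ablation AF episode from four spiral waves, extracts the
#' feature stack, then one post-ablation episode per strategy restarting
#' from the pre-ablation final state with the strategy's lesions applied
#' as non-conducting tissue, and labels each strategy by the last-peak
#' rule. Solver failures are caught and recorded, not propagated.
#'
#' @param cohort a [build_cohort()] result.
#' @param case_id one of `cohort$cases$case_id`.
#' @return a case record: `case_id`, `split`, `sustained`, `features`
#'   ([feature_stack()]), `labels` (4 x 0/1 terminated), `gt` tibble,
#'   `failed`/`error`.
#' @export
run_case <- function(cohort, case_id) {
  config <- cohort$config
  case <- cohort$cases[cohort$cases$case_id == case_id, ]
  if (nrow(case) != 1) abort(sprintf("unknown case '%s'", case_id))
  maps <- case_maps(cohort, case)
  rec <- list(
    case_id = case_id, split = case$split, failed = FALSE, error = NULL,
    la_map_id = case$la_map_id, ra_map_id = case$ra_map_id
  )
  tryCatch({
    chi <- config$chi %||% default_chi()
    pre_sheet <- tissue_sheet(maps$la, maps$ra,
      solver_dim = config$solver_dim, spacing = config$spacing, chi = chi,
      fibrotic_threshold = config$fibrotic_threshold
    )
    init <- initiate_spirals(pre_sheet, config$n_spirals,
      seed = case$seed_spirals
    )
    pre <- run_monodomain(pre_sheet,
      duration = config$duration,
      dt = config$dt, n_sub = config$n_sub, init = init$state,
      quiet_exit_ms = config$quiet_exit_ms
    )
    rec$sustained <- is_sustained(pre)
    rec$features <- feature_stack(pre, maps$la, maps$ra,
      threshold = config$ablation_threshold, out_dim = config$feature_dim
    )
    post <- list()
    for (st in ablation_strategies()) {
      masks <- build_ablation_masks(maps$la, maps$ra, st,
        threshold = config$ablation_threshold
      )
      post_sheet <- tissue_sheet(maps$la, maps$ra,
        solver_dim = config$solver_dim, spacing = config$spacing, chi = chi,
        masks = masks, fibrotic_threshold = config$fibrotic_threshold
      )
      post[[st]] <- run_monodomain(post_sheet,
        duration = config$duration,
        dt = config$dt, n_sub = config$n_sub, init = pre$final_state,
        quiet_exit_ms = config$quiet_exit_ms
      )
    }
    rec$gt <- ground_truth_label(post)
    rec$labels <- as.numeric(rec$gt$terminated)
    rec
  }, error = function(e) {
    rec$failed <- TRUE
    rec$error <- conditionMessage(e)
    rec
  })
}

#' Run every case of a cohort
#'
#' @param cohort a [build_cohort()] result.
#' @param progress print one line per completed case.
#' @return list of case records (see [run_case()]).
#' @export
run_cohort <- function(cohort, progress = FALSE) {
  lapply(cohort$cases$case_id, function(id) {
    t0 <- Sys.time()
    rec <- run_case(cohort, id)
    if (progress) {
      message(sprintf(
        "%s [%s] %s in %.1f s", id, rec$split,
        if (rec$failed) "FAILED" else paste0(
          "labels ", paste(rec$labels, collapse = "")
        ),
        as.numeric(difftime(Sys.time(), t0, units = "secs"))
      ))
    }
    rec
  })
}

#' Run the full in-silico experiment
#'
#' Cohort assembly, simulation campaign, classifier training on the chosen
#' training split (early stopping on validation mean ROC-AUC) and final
#' evaluation on the held-out test split.
#'
#' @param config an [experiment_config()].
#' @param progress forwarded to [run_cohort()].
#' @return list of class `experiment_result`: `metrics` tibble (one row
#'   per strategy plus the mean), `model`, `records`, `cohort`, `config`.
#' @export
run_experiment <- function(config, progress = FALSE) {
  cohort <- build_cohort(config)
  records <- run_cohort(cohort, progress = progress)
  ok <- !vapply(records, function(r) r$failed, logical(1))
  if (config$exclude_non_sustained) {
    ok <- ok & vapply(records, function(r) isTRUE(r$sustained), logical(1))
  }
  split_of <- vapply(records, function(r) r$split, character(1))
  train_split <- if (config$train_source == "real") {
    "train_real"
  } else {
    "train_comparison"
  }
  train <- records[ok & split_of == train_split]
  val <- records[ok & split_of == "validation"]
  test <- records[ok & split_of == "test"]
  if (length(train) == 0 || length(val) == 0 || length(test) == 0) {
    abort("empty split after filtering failed cases")
  }
  model <- train_classifier(train,
    fusion = fusion_config(config$fusion),
    config = classifier_train_config(
      epochs = config$clf_epochs, lr = config$clf_lr,
      batch_size = config$clf_batch, patience = config$clf_patience,
      seed = mix_seed(config$seed, "clf")
    ),
    val_cases = val, backbone = config$backbone
  )
  ev <- suppressWarnings(evaluate_roc_auc(model, test))
  metrics <- bind_rows(
    tibble(
      strategy = ablation_strategies(),
      test_auc = unname(ev$per_strategy),
      n_test = length(test)
    ),
    tibble(
      strategy = "mean", test_auc = ev$mean_auc,
      n_test = length(test)
    )
  )
  structure(list(
    metrics = metrics, model = model, records = records, cohort = cohort,
    config = config,
    n_sustained = sum(vapply(
      records,
      function(r) isTRUE(r$sustained), logical(1)
    )),
    n_failed = sum(!ok)
  ), class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf(
    "<experiment_result> %s profile, %d cases (%d sustained pre-ablation)\n",
    x$config$profile, length(x$records), x$n_sustained
  ))
  print(x$metrics)
  invisible(x)
}

#' @export
tidy.experiment_result <- function(x, ...) x$metrics

#' @export
glance.experiment_result <- function(x, ...) {
  tibble(
    profile = x$config$profile, seed = x$config$seed,
    n_cases = length(x$records), n_failed = x$n_failed,
    n_sustained = x$n_sustained,
    mean_test_auc = x$metrics$test_auc[x$metrics$strategy == "mean"]
  )
}

#' Write experiment reports (CSV metrics + JSON summary)
#'
#' @param result an `experiment_result`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_experiment_report <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(result$metrics, file.path(dir, "metrics.csv"),
    row.names = FALSE
  )
  labels <- lapply(result$records, function(r) {
    list(
      case_id = r$case_id, split = r$split, failed = r$failed,
      sustained = r$sustained %||% NA,
      labels = r$labels %||% NULL
    )
  })
  jsonlite::write_json(list(
    seed = result$config$seed, profile = result$config$profile,
    metrics = result$metrics, cases = labels
  ), file.path(dir, "experiment.json"), auto_unbox = TRUE, digits = NA)
  write_cohort_manifest(result$cohort, file.path(dir, "cohort.json"))
  invisible(dir)
}

#' Plot a voltage snapshot of a simulation
#'
#' @param object a `simulation_result`.
#' @param frame frame index (default: last).
#' @param ... unused.
#' @return a ggplot of the membrane-potential field(s).
#' @export
autoplot.simulation_result <- function(object, frame = ncol(object$voltage),
                                       ...) {
  sheets <- split_by_sheet(object, object$voltage[, frame])
  df <- bind_rows(lapply(names(sheets), function(nm) {
    m <- sheets[[nm]]
    d <- expand.grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
    d$v <- as.vector(m)
    d$sheet <- nm
    d
  }))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$v)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~sheet) +
    ggplot2::scale_fill_viridis_c(name = "V (mV)", option = "inferno") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = sprintf("t = %.0f ms", frame * object$record_dt)
    )
}
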