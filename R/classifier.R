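#' Fusion configuration for the Siamese classifier
#'
#' The two 32-long head latents can be fused by plain concatenation, by a
#' multi-modal outer arithmetic block (MOAB: outer sum, product, difference
#' and stabilized division stacked as four 32x32 channels and reduced by a
#' convolution), or by flattened outer arithmetic attention (FOAA: the four
#' outer operations replace the scaled dot product in a bidirectional
#' cross-attention between learned query/key/value projections, with a
#' skip connection to the single-modality features).
#'
#' @param mode `"concat"`, `"moab"` or `"foaa"`.
#' @param fc1,fc2 widths of the two fully connected layers (48 and 30).
#' @param dropout dropout rate in \[0, 1).
#' @param eps stabilizer added to the divisor of the outer division.
#' @return list of class `fusion_config`.
#' @export
fusion_config <- function(mode = c("concat", "moab", "foaa"),
                          fc1 = 48, fc2 = 30, dropout = 0.1, eps = 1e-6) {
  mode <- match.arg(mode)
  if (dropout < 0 || dropout >= 1) abort("`dropout` must be in [0, 1)")
  structure(list(
    mode = mode, fc1 = as.integer(fc1), fc2 = as.integer(fc2),
    dropout = dropout, eps = eps
  ), class = "fusion_config")
}

# ---- head backbones --------------------------------------------------------

head_params <- function(kind, in_ch = 5, latent = 32) {
  if (kind == "densenet_like") {
    list(
      stem = init_conv(3, 3, in_ch, 8), stem_b = numeric(8),
      db1 = init_conv(3, 3, 8, 8), db1_b = numeric(8),
      db2 = init_conv(3, 3, 16, 8), db2_b = numeric(8),
      db3 = init_conv(3, 3, 24, 8), db3_b = numeric(8),
      fc = init_dense(32, latent), fc_b = numeric(latent)
    )
  } else {
    list(
      s1 = init_conv(3, 3, in_ch, 12), s1_b = numeric(12),
      s2 = init_conv(3, 3, 12, 24), s2_b = numeric(24),
      s3 = init_conv(3, 3, 24, 32), s3_b = numeric(32),
      s4 = init_conv(3, 3, 32, 32), s4_b = numeric(32),
      fc = init_dense(32, latent), fc_b = numeric(latent)
    )
  }
}

# shared-weight (Siamese) head: 5-channel stack -> latent vector
head_forward <- function(tape, pn, kind, x) {
  p <- function(nm) pn[[paste0("head_", nm)]]
  if (kind == "densenet_like") {
    h <- nd_silu(tape, nd_conv2d(tape, x, p("stem"), p("stem_b")))
    h <- nd_avgpool2(tape, nd_avgpool2(tape, h))
    b <- nd_silu(tape, nd_conv2d(tape, h, p("db1"), p("db1_b")))
    h <- nd_avgpool2(tape, nd_concat_last(tape, h, b))
    b <- nd_silu(tape, nd_conv2d(tape, h, p("db2"), p("db2_b")))
    h <- nd_avgpool2(tape, nd_concat_last(tape, h, b))
    b <- nd_silu(tape, nd_conv2d(tape, h, p("db3"), p("db3_b")))
    h <- nd_concat_last(tape, h, b)
  } else {
    h <- x
    for (nm in c("s1", "s2", "s3", "s4")) {
      h <- nd_silu(tape, nd_conv2d(tape, h, p(nm), p(paste0(nm, "_b")),
        stride = 2L, pad = 1L
      ))
    }
  }
  nd_dense(tape, nd_global_mean_hw(tape, h), p("fc"), p("fc_b"))
}

# ---- fusion blocks ---------------------------------------------------------

fusion_params <- function(cfg, latent = 32) {
  out <- list()
  if (cfg$mode == "concat") {
    out$fc1 <- init_dense(2 * latent, cfg$fc1)
  } else if (cfg$mode == "moab") {
    out$conv <- init_conv(3, 3, 4, 4)
    out$conv_b <- numeric(4)
    out$fc1 <- init_dense(4 * (latent / 2)^2, cfg$fc1)
  } else {
    out$wq <- init_dense(latent, latent)
    out$wk <- init_dense(latent, latent)
    out$wv <- init_dense(latent, latent)
    out$conv1 <- init_conv(1, 3, 1, 4)
    out$conv1_b <- numeric(4)
    out$fc1 <- init_dense(2 * latent * 4, cfg$fc1)
  }
  out$fc1_b <- numeric(cfg$fc1)
  out$fc2 <- init_dense(cfg$fc1, cfg$fc2)
  out$fc2_b <- numeric(cfg$fc2)
  out$ln_g <- rep(1, cfg$fc2)
  out$ln_b <- numeric(cfg$fc2)
  out
}

outer_ops <- function(tape, u, v, eps) {
  list(
    nd_outer_pair(tape, u, v, "sum"),
    nd_outer_pair(tape, u, v, "prod"),
    nd_outer_pair(tape, u, v, "diff"),
    nd_outer_pair(tape, u, v, "div", eps = eps)
  )
}

# FOAA cross-attention in one direction: queries from `a`, keys/values
# from `b`; the four outer-arithmetic score maps replace the dot product
foaa_attend <- function(tape, pn, a, b, eps) {
  q <- nd_matmul(tape, a, pn$fus_wq)
  k <- nd_matmul(tape, b, pn$fus_wk)
  v <- nd_matmul(tape, b, pn$fus_wv)
  d <- ncol(q$val)
  att <- NULL
  for (sc in outer_ops(tape, q, k, eps)) {
    p <- nd_softmax_last(tape, nd_scale(tape, sc, 1 / sqrt(d)))
    vv <- nd_reshape(tape, v, c(dim(v$val)[1], d, 1))
    o <- nd_reshape(tape, nd_bmm3(tape, p, vv), dim(q$val))
    att <- if (is.null(att)) o else nd_add(tape, att, o)
  }
  att
}

fusion_forward <- function(tape, pn, cfg, zla, zra, training = FALSE) {
  latent <- ncol(zla$val)
  n <- nrow(zla$val)
  if (cfg$mode == "concat") {
    f <- nd_concat_last(tape, zla, zra)
  } else if (cfg$mode == "moab") {
    ops <- outer_ops(tape, zla, zra, cfg$eps)
    ch <- NULL
    for (o in ops) {
      o4 <- nd_reshape(tape, o, c(n, latent, latent, 1))
      ch <- if (is.null(ch)) o4 else nd_concat_last(tape, ch, o4)
    }
    red <- nd_silu(tape, nd_conv2d(tape, ch, pn$fus_conv, pn$fus_conv_b,
      stride = 2L, pad = 1L
    ))
    f <- nd_reshape(tape, red, c(n, 4 * (latent / 2)^2))
  } else {
    att_la <- foaa_attend(tape, pn, zla, zra, cfg$eps)
    att_ra <- foaa_attend(tape, pn, zra, zla, cfg$eps)
    o_la <- nd_add(tape, zla, att_la) # skip connections
    o_ra <- nd_add(tape, zra, att_ra)
    f <- nd_concat_last(tape, o_la, o_ra) # [N, 64]
    f3 <- nd_reshape(tape, f, c(n, 1, 2 * latent, 1))
    c1 <- nd_silu(tape, nd_conv2d(tape, f3, pn$fus_conv1, pn$fus_conv1_b,
      stride = 1L, pad = NULL
    ))
    f <- nd_reshape(tape, c1, c(n, 2 * latent * 4))
  }
  h <- nd_silu(tape, nd_dense(tape, f, pn$fus_fc1, pn$fus_fc1_b))
  h <- nd_dense(tape, h, pn$fus_fc2, pn$fus_fc2_b)
  h <- nd_layernorm(tape, h, pn$fus_ln_g, pn$fus_ln_b)
  h <- nd_dropout(tape, h, cfg$dropout, training = training)
  nd_silu(tape, h)
}

#' Build a Siamese ablation-outcome classifier
#'
#' One shared-weight convolutional head maps each atrium's five-channel
#' 96x96 feature stack to a 32-long latent; the two latents are fused
#' (concat, MOAB or FOAA), passed through fully connected layers of width
#' 48 and 30 with layer normalization and dropout, and projected to four
#' logits - one termination probability per ablation strategy, in
#' [ablation_strategies()] order.
#'
#' @param backbone `"densenet_like"` (3 dense blocks) or `"convnext_like"`
#'   (4 downsampling stages); compact CPU-scale variants.
#' @param fusion a [fusion_config()].
#' @param latent head output width (32).
#' @param in_ch input channels per atrium (5).
#' @param seed weight-initialization seed.
#' @return list of class `siamese_classifier`.
#' @export
siamese_classifier <- function(backbone = c("densenet_like", "convnext_like"),
                               fusion = fusion_config(), latent = 32,
                               in_ch = 5, seed = 1) {
  backbone <- match.arg(backbone)
  params <- with_seed(seed, {
    hp <- head_params(backbone, in_ch, latent)
    names(hp) <- paste0("head_", names(hp))
    fp <- fusion_params(fusion, latent)
    names(fp) <- paste0("fus_", names(fp))
    op <- list(out = init_dense(fusion$fc2, 4), out_b = numeric(4))
    c(hp, fp, op)
  })
  structure(list(
    params = params,
    desc = list(
      backbone = backbone, fusion = fusion, latent = latent,
      in_ch = in_ch, seed = seed
    )
  ), class = "siamese_classifier")
}

classifier_logits <- function(tape, params, desc, xla, xra, training = FALSE) {
  pn <- nn_params_nodes(tape, params)
  zla <- head_forward(tape, pn, desc$backbone, nd_const(tape, xla))
  zra <- head_forward(tape, pn, desc$backbone, nd_const(tape, xra))
  f <- fusion_forward(tape, pn, desc$fusion, zla, zra, training)
  list(logits = nd_dense(tape, f, pn$out, pn$out_b), pn = pn)
}

stacks_to_batch <- function(cases, idx) {
  d <- dim(cases[[idx[1]]]$features$la)
  xla <- array(0, c(length(idx), d[1], d[2], d[3]))
  xra <- xla
  for (i in seq_along(idx)) {
    xla[i, , , ] <- cases[[idx[i]]]$features$la
    xra[i, , , ] <- cases[[idx[i]]]$features$ra
  }
  list(xla = xla, xra = xra)
}

#' Predict termination probabilities
#'
#' @param object a trained `siamese_classifier`.
#' @param cases list of case records (each with `$features`, a
#'   [feature_stack()]).
#' @param ... unused.
#' @return matrix `n_cases x 4` of probabilities in \[0, 1\], columns in
#'   [ablation_strategies()] order.
#' @export
predict.siamese_classifier <- function(object, cases, ...) {
  out <- matrix(NA_real_, length(cases), 4,
    dimnames = list(NULL, ablation_strategies())
  )
  for (start in seq(1, length(cases), by = 16)) {
    idx <- start:min(length(cases), start + 15)
    b <- stacks_to_batch(cases, idx)
    tape <- nn_tape()
    lg <- classifier_logits(tape, object$params, object$desc, b$xla, b$xra)
    out[idx, ] <- 1 / (1 + exp(-lg$logits$val))
  }
  out
}

#' Rank-based ROC-AUC per strategy
#'
#' Standard Mann-Whitney AUC for each of the four outputs; an output whose
#' labels are single-class in `cases` is reported as `NA` with a warning
#' and excluded from the mean.
#'
#' @param model a trained `siamese_classifier`.
#' @param cases list of labelled case records (`$features`, `$labels`).
#' @return list with `per_strategy` (named numeric, possibly `NA`) and
#'   `mean_auc`.
#' @export
evaluate_roc_auc <- function(model, cases) {
  probs <- predict(model, cases)
  labels <- do.call(rbind, lapply(cases, function(cs) cs$labels))
  per <- vapply(1:4, function(k) auc_rank(probs[, k], labels[, k]), numeric(1))
  names(per) <- ablation_strategies()
  if (any(is.na(per))) {
    warn(paste(
      "single-class labels for:",
      paste(names(per)[is.na(per)], collapse = ", "),
      "- excluded from the mean AUC"
    ))
  }
  list(per_strategy = per, mean_auc = mean(per, na.rm = TRUE))
}

#' Mann-Whitney (rank) ROC-AUC
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels.
#' @return AUC in \[0, 1\], or `NA` when only one class is present.
#' @export
auc_rank <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Training configuration for the classifier
#'
#' The `full` profile uses the full-scale Adam rate of 4e-7; the default
#' `desk` profile uses 1e-3, which the small cohorts trained here need to
#' converge within tens of epochs.
#'
#' @param profile `"desk"` or `"full"`.
#' @param epochs,lr,batch_size,patience overrides.
#' @param seed integer seed.
#' @return list of class `classifier_train_config`.
#' @export
classifier_train_config <- function(profile = c("desk", "full"),
                                    epochs = NULL, lr = NULL,
                                    batch_size = NULL, patience = 20,
                                    seed = 1) {
  profile <- match.arg(profile)
  base <- if (profile == "full") {
    list(epochs = 200L, lr = 4e-7, batch_size = 16L)
  } else {
    list(epochs = 50L, lr = 1e-3, batch_size = 16L)
  }
  structure(list(
    profile = profile, epochs = as.integer(epochs %||% base$epochs),
    lr = lr %||% base$lr, batch_size = as.integer(batch_size %||% base$batch_size),
    patience = as.integer(patience), seed = as.integer(seed)
  ), class = "classifier_train_config")
}

#' Train the Siamese classifier
#'
#' Minimizes summed binary cross-entropy over the four outputs with Adam;
#' when validation cases are supplied, keeps the weights of the epoch with
#' the best validation mean ROC-AUC and stops early after `patience`
#' epochs without improvement. Fully seeded.
#'
#' @param cases training case records (`$features`, `$labels`).
#' @param fusion a [fusion_config()].
#' @param config a [classifier_train_config()].
#' @param val_cases optional validation records for early stopping.
#' @param backbone backbone kind.
#' @param model optional pre-built [siamese_classifier()].
#' @return trained `siamese_classifier` with `loss_trace` and, when
#'   validated, `val_auc_trace`.
#' @export
train_classifier <- function(cases, fusion = fusion_config(),
                             config = classifier_train_config(),
                             val_cases = NULL,
                             backbone = "densenet_like", model = NULL) {
  if (length(cases) < 2) abort("need at least 2 training cases")
  labels <- do.call(rbind, lapply(cases, function(cs) cs$labels))
  if (all(vapply(
    1:4, function(k) length(unique(labels[, k])) < 2,
    logical(1)
  ))) {
    abort("labels are single-class for all four outputs; AUC is undefined")
  }
  if (is.null(model)) {
    model <- siamese_classifier(backbone,
      fusion = fusion,
      seed = mix_seed(config$seed, "init")
    )
  }
  params <- model$params
  desc <- model$desc
  opt <- adam_init(params)
  n <- length(cases)
  trace <- numeric(0)
  val_trace <- numeric(0)
  best <- list(auc = -Inf, params = params, epoch = 0L)
  with_seed(mix_seed(config$seed, "clf-train"), {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(n, start + config$batch_size - 1)]
        b <- stacks_to_batch(cases, idx)
        yb <- labels[idx, , drop = FALSE]
        tape <- nn_tape()
        lg <- classifier_logits(tape, params, desc, b$xla, b$xra,
          training = TRUE
        )
        loss <- nd_bce_logits(tape, lg$logits, yb)
        nn_backward(tape, loss)
        grads <- nn_collect_grads(lg$pn, params)
        st <- adam_step(opt, params, grads, config$lr)
        opt <- st$state; params <- st$params
        losses <- c(losses, loss$val)
      }
      trace <- c(trace, mean(losses))
      if (!is.null(val_cases)) {
        model$params <- params
        ev <- suppressWarnings(evaluate_roc_auc(model, val_cases))
        val_trace <- c(val_trace, ev$mean_auc)
        # mean AUC can be NaN when every output is single-class in the
        # validation set; treat that as no improvement
        if (is.finite(ev$mean_auc) && ev$mean_auc > best$auc) {
          best <- list(auc = ev$mean_auc, params = params, epoch = ep)
        } else if (ep - best$epoch >= config$patience) {
          break
        }
      }
    }
  })
  model$params <- if (!is.null(val_cases) && best$epoch > 0) {
    best$params
  } else {
    params
  }
  model$loss_trace <- trace
  model$val_auc_trace <- val_trace
  model$train_config <- config
  model
}

#' Grouped k-fold cross-validation
#'
#' Folds partition the cases and are disjoint over the source
#' fibrosis-map pools (`groups`), so no map contributes to both a training
#' and an evaluation fold (the leakage rule). Each fold's model is also
#' evaluated on a fixed hold-out test set when one is given.
#'
#' @param cases labelled case records.
#' @param k number of folds (>= 2, <= number of cases).
#' @param fusion,config,backbone as in [train_classifier()].
#' @param groups grouping vector (one per case, e.g. map-pool id); `NULL`
#'   treats every case as its own group.
#' @param test_cases optional fixed hold-out set.
#' @param seed fold-assignment seed.
#' @return list of class `cv_result`: `folds` tibble (per-fold validation
#'   and test mean AUC), `mean_auc`, `sd_auc`.
#' @export
kfold_crossvalidate <- function(cases, k = 5, fusion = fusion_config(),
                                config = classifier_train_config(),
                                backbone = "densenet_like", groups = NULL,
                                test_cases = NULL, seed = 1) {
  n <- length(cases)
  if (k < 2) abort("`k` must be >= 2")
  if (k > n) abort("`k` exceeds the number of cases")
  groups <- groups %||% seq_len(n)
  ug <- unique(groups)
  fold_of_group <- with_seed(
    mix_seed(seed, "folds"),
    setNames(sample(rep(seq_len(k), length.out = length(ug))), ug)
  )
  fold <- unname(fold_of_group[as.character(groups)])
  rows <- lapply(seq_len(k), function(f) {
    tr <- cases[fold != f]
    ho <- cases[fold == f]
    m <- train_classifier(tr,
      fusion = fusion,
      config = classifier_train_config(
        profile = config$profile, epochs = config$epochs, lr = config$lr,
        batch_size = config$batch_size, patience = config$patience,
        seed = mix_seed(config$seed, "fold", f)
      ),
      backbone = backbone
    )
    ev <- suppressWarnings(evaluate_roc_auc(m, ho))
    te <- if (!is.null(test_cases)) {
      suppressWarnings(evaluate_roc_auc(m, test_cases))$mean_auc
    } else {
      NA_real_
    }
    tibble(fold = f, n_train = length(tr), n_eval = length(ho),
      mean_auc = ev$mean_auc, test_mean_auc = te)
  })
  folds <- bind_rows(rows)
  structure(list(
    folds = folds, fold_assignment = fold,
    mean_auc = mean(folds$mean_auc), sd_auc = sd(folds$mean_auc)
  ), class = "cv_result")
}

#' Standalone MOAB fusion of two latent vectors
#'
#' Stacks the four outer arithmetic operations of `u` and `v` as channels
#' and reduces them with a (deterministically initialized) convolution and
#' flatten. Exposed mainly for inspection and testing; training uses the
#' same code path inside the classifier graph.
#'
#' @param u,v numeric latent vectors of equal length.
#' @param eps divisor stabilizer.
#' @param seed seed for the reduction weights.
#' @return list with `channels` (4 stacked outer matrices) and `fused`
#'   (the flattened reduced vector).
#' @export
moab_fuse <- function(u, v, eps = 1e-6, seed = 1) {
  if (length(u) != length(v)) abort("latent length mismatch")
  d <- length(u)
  tape <- nn_tape()
  un <- nd_const(tape, matrix(u, 1)); vn <- nd_const(tape, matrix(v, 1))
  ops <- outer_ops(tape, un, vn, eps)
  ch <- array(0, c(d, d, 4))
  for (i in 1:4) ch[, , i] <- ops[[i]]$val[1, , ]
  w <- with_seed(seed, list(k = init_conv(3, 3, 4, 4), b = numeric(4)))
  x4 <- nd_const(tape, array(ch, c(1, d, d, 4)))
  red <- nd_silu(tape, nd_conv2d(tape, x4, nd_const(tape, w$k),
    nd_const(tape, w$b),
    stride = 2L, pad = 1L
  ))
  list(
    channels = ch,
    fused = as.vector(red$val),
    op_names = c("sum", "prod", "diff", "div")
  )
}

#' Standalone FOAA fusion of two latent vectors
#'
#' Full flattened outer arithmetic attention with deterministically
#' initialized projections: bidirectional cross-attention whose scores are
#' the four outer operations, skip connections, 1D convolution and the
#' 48/30 fully connected stack with layer normalization.
#'
#' @inheritParams moab_fuse
#' @param config a [fusion_config()] with `mode = "foaa"`.
#' @return the fused representation (length `config$fc2`, default 30).
#' @export
foaa_fuse <- function(u, v, eps = 1e-6, seed = 1,
                      config = fusion_config("foaa", eps = eps)) {
  if (length(u) != length(v)) abort("latent length mismatch")
  d <- length(u)
  params <- with_seed(seed, {
    fp <- fusion_params(config, latent = d)
    names(fp) <- paste0("fus_", names(fp))
    fp
  })
  tape <- nn_tape()
  pn <- nn_params_nodes(tape, params)
  un <- nd_const(tape, matrix(u, 1)); vn <- nd_const(tape, matrix(v, 1))
  f <- fusion_forward(tape, pn, config, un, vn, training = FALSE)
  as.vector(f$val)
}

#' @export
print.siamese_classifier <- function(x, ...) {
  cat(sprintf(
    "<siamese_classifier> %s head, %s fusion, latent %d\n",
    x$desc$backbone, x$desc$fusion$mode, x$desc$latent
  ))
  invisible(x)
}

#' @export
tidy.cv_result <- function(x, ...) x$folds

#' @export
glance.cv_result <- function(x, ...) {
  tibble(
    k = nrow(x$folds), mean_auc = x$mean_auc, sd_auc = x$sd_auc,
    mean_test_auc = mean(x$folds$test_mean_auc)
  )
}

#' @export
tidy.siamese_classifier <- function(x, ...) {
  tibble(
    epoch = seq_along(x$loss_trace), loss = x$loss_trace,
    val_mean_auc = if (length(x$val_auc_trace) > 0) {
      c(x$val_auc_trace, rep(NA, length(x$loss_trace) - length(x$val_auc_trace)))
    } else {
      NA_real_
    }
  )
}

#' @export
glance.siamese_classifier <- function(x, ...) {
  tibble(
    backbone = x$desc$backbone, fusion = x$desc$fusion$mode,
    epochs_run = length(x$loss_trace),
    final_loss = x$loss_trace[length(x$loss_trace)],
    best_val_auc = if (length(x$val_auc_trace) > 0) {
      max(x$val_auc_trace)
    } else {
      NA_real_
    }
  )
}
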