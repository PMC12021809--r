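#' Variance schedule for the diffusion process
#'
#' The forward (noising) process corrupts a map over `T` steps,
#' \deqn{q(x_t | x_{t-1}) = N(x_t; \sqrt{1-\beta_t}\, x_{t-1}, \beta_t I),}
#' with \eqn{\beta_t} controlling how much Gaussian noise each step adds.
#' The schedule also carries \eqn{\alpha_t = 1-\beta_t} and
#' \eqn{\bar\alpha_t = \prod_{s \le t} \alpha_s}, which give the closed-form
#' marginal used for training. The default is the original linear schedule:
#' 1000 steps from 1e-4 to 0.02, for which \eqn{\bar\alpha_T < 10^{-3}} so
#' the terminal marginal is indistinguishable from a standard normal.
#'
#' @param n_steps number of timesteps `T`.
#' @param beta_start,beta_end linear schedule endpoints.
#' @param beta optional explicit beta sequence (overrides the endpoints).
#' @return list of class `noise_schedule` with `T`, `beta`, `alpha`,
#'   `alpha_bar`.
#' @export
noise_schedule <- function(n_steps = 1000L, beta_start = 1e-4,
                           beta_end = 0.02, beta = NULL) {
  if (is.null(beta)) {
    beta <- seq(beta_start, beta_end, length.out = n_steps)
  }
  n_steps <- length(beta)
  if (any(beta <= 0) || any(beta >= 1)) abort("beta values must lie in (0, 1)")
  if (any(diff(beta) < -1e-12)) abort("beta schedule must be non-decreasing")
  alpha <- 1 - beta
  structure(list(
    T = as.integer(n_steps), beta = beta, alpha = alpha,
    alpha_bar = cumprod(alpha)
  ), class = "noise_schedule")
}

check_t <- function(t, schedule) {
  if (any(t < 1) || any(t > schedule$T)) {
    abort(sprintf("timestep out of range [1, %d]", schedule$T))
  }
  as.integer(t)
}

#' Forward noising (closed-form marginal)
#'
#' Returns \eqn{x_t = \sqrt{\bar\alpha_t}\, x_0 + \sqrt{1-\bar\alpha_t}\,
#' \epsilon}, \eqn{\epsilon \sim N(0, I)}: the marginal obtained by
#' iterating the one-step forward kernel `t` times.
#'
#' @param x0 matrix in model range (\[-1, 1\]).
#' @param t timestep in `1..T`.
#' @param schedule a [noise_schedule()].
#' @param seed integer seed for the noise draw, or `NULL` to use the
#'   current RNG stream.
#' @param eps optional explicit noise matrix (overrides the draw).
#' @return list with `x_t` and the noise `eps` used.
#' @export
forward_noising <- function(x0, t, schedule, seed = NULL, eps = NULL) {
  t <- check_t(t, schedule)
  if (is.null(eps)) {
    eps <- if (is.null(seed)) {
      matrix(rnorm(length(x0)), nrow(x0), ncol(x0))
    } else {
      with_seed(seed, matrix(rnorm(length(x0)), nrow(x0), ncol(x0)))
    }
  }
  ab <- schedule$alpha_bar[t]
  list(x_t = sqrt(ab) * x0 + sqrt(1 - ab) * eps, eps = eps)
}

## ---- U-Net denoiser -------------------------------------------------------

sinusoidal_embedding <- function(t, dim) {
  half <- dim %/% 2
  freq <- exp(-log(10000) * (seq_len(half) - 1) / max(1, half - 1))
  ang <- outer(t / 1000, freq * 1000)
  cbind(sin(ang), cos(ang))
}

#' Build a U-Net noise predictor
#'
#' Three resolution levels with 3x3 convolutions and SiLU activations,
#' single-head self-attention at the second and third levels, sinusoidal
#' timestep embeddings injected as per-level channel scale-and-shift (FiLM)
#' conditioning, and skip connections from encoder to decoder. The network maps a noisy map
#' `x_t` (any H, W divisible by 4) and its timestep to a predicted noise
#' field of the same shape. Default widths (8, 16, 32) are sized for
#' CPU-scale training; wider configurations are constructible through
#' `channels`.
#'
#' @param channels per-level channel widths (length 3).
#' @param attention_levels levels (2 and/or 3) that get self-attention.
#' @param time_dim sinusoidal embedding width.
#' @param seed integer seed for weight initialization.
#' @return list of class `ddpm_model` with `params` and `desc`.
#' @export
ddpm_unet <- function(channels = c(8, 16, 32), attention_levels = c(2, 3),
                      time_dim = 32, seed = 1) {
  c1 <- channels[1]; c2 <- channels[2]; c3 <- channels[3]
  params <- with_seed(seed, {
    p <- list(
      temb_w1 = init_dense(time_dim, time_dim), temb_b1 = numeric(time_dim),
      temb1 = init_dense(time_dim, c1), temb1b = numeric(c1),
      temb2 = init_dense(time_dim, c2), temb2b = numeric(c2),
      temb3 = init_dense(time_dim, c3), temb3b = numeric(c3),
      temb2d = init_dense(time_dim, c2), temb2db = numeric(c2),
      temb1d = init_dense(time_dim, c1), temb1db = numeric(c1),
      # zero-initialized FiLM scale projections (identity at start)
      temb1s = matrix(0, time_dim, c1), temb2s = matrix(0, time_dim, c2),
      temb3s = matrix(0, time_dim, c3), temb2ds = matrix(0, time_dim, c2),
      temb1ds = matrix(0, time_dim, c1),
      e1a = init_conv(3, 3, 1, c1), e1ab = numeric(c1),
      e1b = init_conv(3, 3, c1, c1), e1bb = numeric(c1),
      e2a = init_conv(3, 3, c1, c2), e2ab = numeric(c2),
      e2b = init_conv(3, 3, c2, c2), e2bb = numeric(c2),
      m1 = init_conv(3, 3, c2, c3), m1b = numeric(c3),
      m2 = init_conv(3, 3, c3, c3), m2b = numeric(c3),
      d2a = init_conv(3, 3, c3 + c2, c2), d2ab = numeric(c2),
      d2b = init_conv(3, 3, c2, c2), d2bb = numeric(c2),
      d1a = init_conv(3, 3, c2 + c1, c1), d1ab = numeric(c1),
      d1b = init_conv(3, 3, c1, c1), d1bb = numeric(c1),
      out = init_conv(1, 1, c1, 1, scale = 0.1), outb = numeric(1)
    )
    if (2 %in% attention_levels) {
      p$att2_q <- init_dense(c2, c2); p$att2_k <- init_dense(c2, c2)
      p$att2_v <- init_dense(c2, c2)
      p$att2_o <- init_dense(c2, c2, scale = 0.1)
    }
    if (3 %in% attention_levels) {
      p$att3_q <- init_dense(c3, c3); p$att3_k <- init_dense(c3, c3)
      p$att3_v <- init_dense(c3, c3)
      p$att3_o <- init_dense(c3, c3, scale = 0.1)
    }
    p
  })
  structure(list(
    params = params,
    desc = list(
      channels = channels, attention_levels = attention_levels,
      time_dim = time_dim, seed = seed, kind = "unet3"
    )
  ), class = "ddpm_model")
}

# single-head self-attention over spatial positions, residual form
attn_block <- function(tape, h, pn, prefix) {
  d <- dim(h$val)
  n <- d[1]; l <- d[2] * d[3]; cc <- d[4]
  hm <- nd_reshape(tape, h, c(n * l, cc))
  q <- nd_reshape(tape, nd_matmul(tape, hm, pn[[paste0(prefix, "_q")]]), c(n, l, cc))
  k <- nd_reshape(tape, nd_matmul(tape, hm, pn[[paste0(prefix, "_k")]]), c(n, l, cc))
  v <- nd_reshape(tape, nd_matmul(tape, hm, pn[[paste0(prefix, "_v")]]), c(n, l, cc))
  sc <- nd_scale(tape, nd_bmm3(tape, q, k, tb = TRUE), 1 / sqrt(cc))
  p <- nd_softmax_last(tape, sc)
  o <- nd_bmm3(tape, p, v)
  o <- nd_reshape(tape, o, c(n * l, cc))
  o <- nd_matmul(tape, o, pn[[paste0(prefix, "_o")]])
  nd_add(tape, h, nd_reshape(tape, o, d))
}

# note: h and w of the input must be divisible by 4 (two poolings)
unet_forward <- function(tape, pn, desc, x, tvec) {
  att <- desc$attention_levels
  temb <- sinusoidal_embedding(tvec, desc$time_dim)
  te <- nd_silu(tape, nd_dense(
    tape, nd_const(tape, temb),
    pn$temb_w1, pn$temb_b1
  ))
  # timestep conditioning: per-channel scale and shift (FiLM), which gives
  # the noise predictor the strongly t-dependent gain it needs
  add_temb <- function(h, wnm, bnm) {
    bias <- nd_dense(tape, te, pn[[wnm]], pn[[bnm]]) # [N, C]
    scale <- nd_matmul(tape, te, pn[[paste0(wnm, "s")]])
    nd_scale_shift_chan(tape, h, scale, bias)
  }
  h1 <- nd_silu(tape, nd_conv2d(tape, x, pn$e1a, pn$e1ab))
  h1 <- add_temb(h1, "temb1", "temb1b")
  h1 <- nd_silu(tape, nd_conv2d(tape, h1, pn$e1b, pn$e1bb))
  h2 <- nd_avgpool2(tape, h1)
  h2 <- nd_silu(tape, nd_conv2d(tape, h2, pn$e2a, pn$e2ab))
  h2 <- add_temb(h2, "temb2", "temb2b")
  h2 <- nd_silu(tape, nd_conv2d(tape, h2, pn$e2b, pn$e2bb))
  if (2 %in% att) h2 <- attn_block(tape, h2, pn, "att2")
  h3 <- nd_avgpool2(tape, h2)
  h3 <- nd_silu(tape, nd_conv2d(tape, h3, pn$m1, pn$m1b))
  h3 <- add_temb(h3, "temb3", "temb3b")
  h3 <- nd_silu(tape, nd_conv2d(tape, h3, pn$m2, pn$m2b))
  if (3 %in% att) h3 <- attn_block(tape, h3, pn, "att3")
  u2 <- nd_concat_last(tape, nd_upsample2(tape, h3), h2)
  u2 <- nd_silu(tape, nd_conv2d(tape, u2, pn$d2a, pn$d2ab))
  u2 <- add_temb(u2, "temb2d", "temb2db")
  u2 <- nd_silu(tape, nd_conv2d(tape, u2, pn$d2b, pn$d2bb))
  if (2 %in% att) u2 <- attn_block(tape, u2, pn, "att2")
  u1 <- nd_concat_last(tape, nd_upsample2(tape, u2), h1)
  u1 <- nd_silu(tape, nd_conv2d(tape, u1, pn$d1a, pn$d1ab))
  u1 <- add_temb(u1, "temb1d", "temb1db")
  u1 <- nd_silu(tape, nd_conv2d(tape, u1, pn$d1b, pn$d1bb))
  nd_conv2d(tape, u1, pn$out, pn$outb)
}

#' Predict the noise component of a noisy map
#'
#' Deterministic given weights and inputs. `model` may be a trained
#' `ddpm_model` or any list with a `predict(x, t)` function (used for
#' analytic reference models in tests).
#'
#' @param model a `ddpm_model`.
#' @param x matrix (model range) or array `[N, H, W, 1]`.
#' @param t timestep (scalar, or length-N for a batch).
#' @return predicted noise with the shape of `x`.
#' @export
denoiser_predict <- function(model, x, t) {
  if (!is.null(model$predict)) return(model$predict(x, t))
  was_mat <- is.matrix(x)
  xa <- if (was_mat) array(x, c(1, nrow(x), ncol(x), 1)) else x
  tape <- nn_tape()
  pn <- nn_params_nodes(tape, model$params)
  out <- unet_forward(
    tape, pn, model$desc, nd_const(tape, xa),
    rep(t, length.out = dim(xa)[1])
  )
  if (was_mat) matrix(out$val, nrow(x), ncol(x)) else out$val
}

#' One reverse (denoising) step
#'
#' Samples \eqn{x_{t-1} \sim N(\mu_\theta(x_t, t), \sigma_t^2 I)} with the
#' fixed-variance parameterization \eqn{\sigma_t^2 = \beta_t} and
#' \deqn{\mu_\theta = \frac{1}{\sqrt{\alpha_t}}\left(x_t -
#'  \frac{\beta_t}{\sqrt{1-\bar\alpha_t}}\hat\epsilon_\theta(x_t,t)\right).}
#' No noise is added at `t = 1` (the terminal step).
#'
#' @param x_t current noisy map (matrix).
#' @param t timestep in `1..T`.
#' @param model denoiser (see [denoiser_predict()]).
#' @param schedule a [noise_schedule()].
#' @param noise optional explicit noise matrix; pass `0` for the
#'   deterministic (noise-free) variant.
#' @return the map at `t - 1`.
#' @export
reverse_step <- function(x_t, t, model, schedule, noise = NULL) {
  t <- check_t(t, schedule)
  eps_hat <- denoiser_predict(model, x_t, t)
  beta <- schedule$beta[t]
  mu <- (x_t - beta / sqrt(1 - schedule$alpha_bar[t]) * eps_hat) /
    sqrt(schedule$alpha[t])
  if (t == 1L) return(mu)
  if (is.null(noise)) {
    noise <- matrix(rnorm(length(x_t)), nrow(x_t), ncol(x_t))
  }
  mu + sqrt(beta) * noise
}

#' Training configuration for the denoiser
#'
#' The `full` profile is the full-scale configuration (500 epochs, Adam at
#' 2.5e-5); the default `desk` profile trains the compact U-Net on small
#' ensembles in minutes on one CPU.
#'
#' @param profile `"desk"` or `"full"`.
#' @param epochs,lr,batch_size overrides of the profile values.
#' @param seed integer seed (weights, batching and noise draws).
#' @return list of class `ddpm_train_config`.
#' @export
ddpm_train_config <- function(profile = c("desk", "full"), epochs = NULL,
                              lr = NULL, batch_size = NULL, seed = 1) {
  profile <- match.arg(profile)
  base <- if (profile == "full") {
    list(epochs = 500L, lr = 2.5e-5, batch_size = 16L)
  } else {
    list(epochs = 60L, lr = 2e-3, batch_size = 8L)
  }
  out <- list(
    profile = profile,
    epochs = as.integer(epochs %||% base$epochs),
    lr = lr %||% base$lr,
    batch_size = as.integer(batch_size %||% base$batch_size),
    seed = as.integer(seed)
  )
  if (out$epochs < 1) abort("`epochs` must be >= 1")
  if (out$lr <= 0) abort("`lr` must be > 0")
  structure(out, class = "ddpm_train_config")
}

iir_to_model <- function(m) m - 1
model_to_iir <- function(m) pmax(pmin(m + 1, 2), 0)

#' Train the diffusion denoiser
#'
#' Standard DDPM objective: draw a timestep uniformly per sample, noise the
#' map with the closed-form forward marginal, and regress the injected
#' noise with mean squared error (Adam). Maps are mapped linearly from
#' \[0, 2\] IIR to the model range \[-1, 1\]. Fully seeded: identical
#' config and seed give identical loss traces and weights.
#'
#' @param maps list of `fibrosis_map` objects or matrices (>= 2).
#' @param config a [ddpm_train_config()].
#' @param schedule a [noise_schedule()].
#' @param model optional pre-built [ddpm_unet()] (otherwise one is created
#'   with the config seed).
#' @return a `ddpm_model` with a `loss_trace` (per-epoch mean loss).
#' @export
train_ddpm <- function(maps, config = ddpm_train_config(),
                       schedule = noise_schedule(), model = NULL) {
  if (length(maps) < 2) abort("need at least 2 training maps")
  xs <- lapply(maps, function(m) {
    iir_to_model(if (inherits(m, "fibrosis_map")) map_values(m) else m)
  })
  hw <- dim(xs[[1]])
  if (any(hw %% 4 != 0)) abort("map dimensions must be divisible by 4")
  if (is.null(model)) model <- ddpm_unet(seed = mix_seed(config$seed, "init"))
  params <- model$params
  opt <- adam_init(params)
  n <- length(xs)
  trace <- numeric(config$epochs)
  with_seed(mix_seed(config$seed, "train"), {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_losses <- c()
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(n, start + config$batch_size - 1)]
        nb <- length(idx)
        tvec <- sample.int(schedule$T, nb, replace = TRUE)
        xb <- array(0, c(nb, hw[1], hw[2], 1))
        eb <- array(rnorm(nb * prod(hw)), c(nb, hw[1], hw[2], 1))
        for (i in seq_len(nb)) {
          ab <- schedule$alpha_bar[tvec[i]]
          xb[i, , , 1] <- sqrt(ab) * xs[[idx[i]]] +
            sqrt(1 - ab) * eb[i, , , 1]
        }
        tape <- nn_tape()
        pn <- nn_params_nodes(tape, params)
        eps_hat <- unet_forward(tape, pn, model$desc, nd_const(tape, xb), tvec)
        loss <- nd_mse(tape, eps_hat, eb)
        nn_backward(tape, loss)
        grads <- nn_collect_grads(pn, params)
        st <- adam_step(opt, params, grads, config$lr)
        opt <- st$state; params <- st$params
        ep_losses <- c(ep_losses, loss$val)
      }
      trace[ep] <- mean(ep_losses)
    }
  })
  model$params <- params
  model$loss_trace <- trace
  model$train_config <- config
  model
}

#' Sample fibrosis maps from a trained denoiser
#'
#' Runs the full `T`-step reverse chain from standard-normal noise,
#' rescales to IIR and clips to \[0, 2\]. Bit-reproducible for a fixed
#' seed, weights and schedule.
#'
#' @param model a trained `ddpm_model`.
#' @param schedule a [noise_schedule()].
#' @param n number of maps.
#' @param seed integer seed.
#' @param shape grid dimensions (divisible by 4).
#' @return list of `fibrosis_map` objects with `source = "synthetic"`.
#' @export
sample_maps <- function(model, schedule, n, seed, shape = c(96, 96)) {
  if (n < 1) abort("`n` must be >= 1")
  lapply(seq_len(n), function(i) {
    s <- mix_seed(seed, "sample", i)
    x <- with_seed(s, {
      x <- matrix(rnorm(prod(shape)), shape[1], shape[2])
      for (t in rev(seq_len(schedule$T))) {
        x <- reverse_step(x, t, model, schedule)
      }
      x
    })
    fibrosis_map(model_to_iir(x),
      source = "synthetic",
      map_id = sprintf("synthetic-%d-%d", as.integer(seed), i), seed = s
    )
  })
}

#' Save / load a denoiser checkpoint
#'
#' Single-file checkpoint carrying weights, architecture descriptor,
#' training config and loss trace.
#'
#' @param model a `ddpm_model`.
#' @param path file path.
#' @return `read_ddpm()` returns the model.
#' @export
write_ddpm <- function(model, path) {
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname write_ddpm
#' @export
read_ddpm <- function(path) {
  structure(readRDS(path), class = "ddpm_model")
}

#' @export
print.ddpm_model <- function(x, ...) {
  cat(sprintf(
    "<ddpm_model> U-Net channels (%s), attention at levels %s\n",
    paste(x$desc$channels, collapse = ", "),
    paste(x$desc$attention_levels, collapse = ", ")
  ))
  if (!is.null(x$loss_trace)) {
    cat(sprintf(
      "  trained %d epochs, final loss %.4f\n",
      length(x$loss_trace), x$loss_trace[length(x$loss_trace)]
    ))
  }
  invisible(x)
}
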