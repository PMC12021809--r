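# Reverse-mode automatic differentiation on dense arrays.
#
# Both neural components of the pipeline (the DDPM denoiser and the Siamese
# outcome classifier) are trained through this small define-by-run engine:
# each forward pass records nodes on a tape; backward() walks the tape in
# reverse, accumulating gradients. Image activations are [N, H, W, C]
# arrays (batch, rows, cols, channels); dense activations are [N, D].

nn_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$k <- 0L
  t
}

nd_node <- function(tape, val, parents = list(), backward = NULL) {
  n <- new.env(parent = emptyenv())
  n$val <- val
  n$grad <- NULL
  n$parents <- parents
  n$backward <- backward
  tape$k <- tape$k + 1L
  if (tape$k > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  n$id <- tape$k
  tape$nodes[[tape$k]] <- n
  n
}

nd_const <- function(tape, val) nd_node(tape, val)

nd_acc <- function(p, g) {
  p$grad <- if (is.null(p$grad)) g else p$grad + g
  invisible(NULL)
}

# Backpropagate from a scalar loss node through the tape.
nn_backward <- function(tape, loss) {
  loss$grad <- array(1, dim = dim1(loss$val))
  for (i in rev(seq_len(loss$id))) {
    n <- tape$nodes[[i]]
    if (!is.null(n) && !is.null(n$grad) && !is.null(n$backward)) {
      n$backward(n$grad)
    }
  }
  invisible(NULL)
}

dim1 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

as_arr <- function(x, d) array(x, dim = d)

## ---- elementwise ----------------------------------------------------------

nd_add <- function(tape, a, b) {
  nd_node(tape, a$val + b$val, list(a, b), function(g) {
    nd_acc(a, g); nd_acc(b, g)
  })
}

nd_sub <- function(tape, a, b) {
  nd_node(tape, a$val - b$val, list(a, b), function(g) {
    nd_acc(a, g); nd_acc(b, -g)
  })
}

nd_mul <- function(tape, a, b) {
  nd_node(tape, a$val * b$val, list(a, b), function(g) {
    nd_acc(a, g * b$val); nd_acc(b, g * a$val)
  })
}

nd_scale <- function(tape, a, s) {
  nd_node(tape, a$val * s, list(a), function(g) nd_acc(a, g * s))
}

# multiply by a fixed array (dropout masks, normalization constants)
nd_mul_const <- function(tape, a, m) {
  nd_node(tape, a$val * m, list(a), function(g) nd_acc(a, g * m))
}

nd_relu <- function(tape, a) {
  mask <- a$val > 0
  nd_node(tape, a$val * mask, list(a), function(g) nd_acc(a, g * mask))
}

nd_silu <- function(tape, a) {
  s <- 1 / (1 + exp(-a$val))
  nd_node(tape, a$val * s, list(a), function(g) {
    nd_acc(a, g * (s * (1 + a$val * (1 - s))))
  })
}

nd_sigmoid <- function(tape, a) {
  s <- 1 / (1 + exp(-a$val))
  nd_node(tape, s, list(a), function(g) nd_acc(a, g * s * (1 - s)))
}

nd_tanh <- function(tape, a) {
  t_ <- tanh(a$val)
  nd_node(tape, t_, list(a), function(g) nd_acc(a, g * (1 - t_^2)))
}

## ---- shape ----------------------------------------------------------------

nd_reshape <- function(tape, a, d) {
  d0 <- dim1(a$val)
  nd_node(tape, array(a$val, dim = d), list(a), function(g) {
    nd_acc(a, array(g, dim = d0))
  })
}

# channel concat along the last dimension
nd_concat_last <- function(tape, a, b) {
  da <- dim1(a$val); db <- dim1(b$val)
  k <- length(da)
  val <- array(c(a$val, b$val), dim = c(da[-k], da[k] + db[k]))
  nd_node(tape, val, list(a, b), function(g) {
    na <- prod(da)
    nd_acc(a, array(g[seq_len(na)], dim = da))
    nd_acc(b, array(g[-seq_len(na)], dim = db))
  })
}

## ---- dense / matmul -------------------------------------------------------

nd_matmul <- function(tape, a, b) {
  nd_node(tape, a$val %*% b$val, list(a, b), function(g) {
    nd_acc(a, g %*% t(b$val))
    nd_acc(b, t(a$val) %*% g)
  })
}

# add a length-C bias along the trailing dimension of an [ ..., C ] array
nd_add_bias <- function(tape, a, b) {
  d <- dim1(a$val)
  cdim <- d[length(d)]
  lead <- prod(d) / cdim
  val <- a$val + as_arr(rep(b$val, each = lead), d)
  nd_node(tape, val, list(a, b), function(g) {
    nd_acc(a, g)
    nd_acc(b, colSums(matrix(g, nrow = lead, ncol = cdim)))
  })
}

nd_dense <- function(tape, x, w, b = NULL) {
  out <- nd_matmul(tape, x, w)
  if (!is.null(b)) out <- nd_add_bias(tape, out, b)
  out
}

# add a per-(sample, channel) bias [N, C] to an [N, H, W, C] activation
nd_add_sample_chan_bias <- function(tape, h, bias) {
  d <- dim1(h$val)
  n <- d[1]; cc <- d[4]
  bfull <- aperm(array(bias$val, c(n, cc, d[2], d[3])), c(1, 3, 4, 2))
  nd_node(tape, h$val + bfull, list(h, bias), function(g) {
    nd_acc(h, g)
    gb <- rowSums(matrix(aperm(g, c(1, 4, 2, 3)), nrow = n * cc))
    nd_acc(bias, matrix(gb, n, cc))
  })
}

# FiLM-style conditioning: h * (1 + scale) + bias with per-(sample, channel)
# scale and bias [N, C] broadcast over the spatial dimensions
nd_scale_shift_chan <- function(tape, h, scale, bias) {
  d <- dim1(h$val)
  n <- d[1]; cc <- d[4]
  expand <- function(m) aperm(array(m, c(n, cc, d[2], d[3])), c(1, 3, 4, 2))
  sfull <- expand(1 + scale$val)
  bfull <- expand(bias$val)
  nd_node(tape, h$val * sfull + bfull, list(h, scale, bias), function(g) {
    nd_acc(h, g * sfull)
    reduce <- function(x) {
      matrix(rowSums(matrix(aperm(x, c(1, 4, 2, 3)), nrow = n * cc)), n, cc)
    }
    nd_acc(scale, reduce(g * h$val))
    nd_acc(bias, reduce(g))
  })
}

## ---- reductions and losses ------------------------------------------------

nd_mean <- function(tape, a) {
  n <- length(a$val)
  d <- dim1(a$val)
  nd_node(tape, sum(a$val) / n, list(a), function(g) {
    nd_acc(a, as_arr(rep(as.numeric(g) / n, n), d))
  })
}

nd_mse <- function(tape, pred, target) {
  diff <- pred$val - target
  n <- length(diff)
  nd_node(tape, sum(diff^2) / n, list(pred), function(g) {
    nd_acc(pred, as.numeric(g) * 2 * diff / n)
  })
}

# mean binary cross-entropy on logits (numerically stable softplus form)
nd_bce_logits <- function(tape, logits, labels) {
  z <- logits$val
  n <- length(z)
  sp <- ifelse(z > 0, z + log1p(exp(-z)), log1p(exp(z)))
  val <- sum(sp - labels * z) / n
  nd_node(tape, val, list(logits), function(g) {
    nd_acc(logits, as.numeric(g) * (1 / (1 + exp(-z)) - labels) / n)
  })
}

## ---- normalization --------------------------------------------------------

# layer normalization over the feature dimension of an [N, D] matrix
nd_layernorm <- function(tape, x, gamma, beta, eps = 1e-5) {
  xv <- x$val
  mu <- rowMeans(xv)
  xc <- xv - mu
  v <- rowMeans(xc^2)
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * istd
  gv <- gamma$val
  val <- sweep(xhat, 2, gv, "*")
  val <- sweep(val, 2, beta$val, "+")
  nd_node(tape, val, list(x, gamma, beta), function(g) {
    nd_acc(gamma, colSums(g * xhat))
    nd_acc(beta, colSums(g))
    gy <- sweep(g, 2, gv, "*")
    d <- ncol(xv)
    gx <- istd * (gy - rowMeans(gy) - xhat * rowMeans(gy * xhat))
    nd_acc(x, gx)
  })
}

## ---- conv / pool / resize -------------------------------------------------

pad_nhwc <- function(x, p) {
  if (p == 0) return(x)
  d <- dim(x)
  out <- array(0, c(d[1], d[2] + 2 * p, d[3] + 2 * p, d[4]))
  out[, p + seq_len(d[2]), p + seq_len(d[3]), ] <- x
  out
}

#' @noRd
# 2D convolution on [N,H,W,C] with weights [kh,kw,Cin,Cout]; implemented as
# kh*kw shifted-slice matmuls, which keeps everything in BLAS.
nd_conv2d <- function(tape, x, w, b = NULL, stride = 1L, pad = NULL) {
  dw <- dim(w$val)
  kh <- dw[1]; kw <- dw[2]; cin <- dw[3]; cout <- dw[4]
  if (is.null(pad)) pad <- (kh - 1L) %/% 2L
  xv <- pad_nhwc(x$val, pad)
  d <- dim(xv)
  n <- d[1]; hp <- d[2]; wp <- d[3]
  ho <- (hp - kh) %/% stride + 1L
  wo <- (wp - kw) %/% stride + 1L
  m <- n * ho * wo
  wmat <- matrix(w$val, nrow = kh * kw * cin, ncol = cout)
  slices <- vector("list", kh * kw)
  out <- matrix(0, m, cout)
  idx <- 0L
  for (dj in seq_len(kw)) {
    for (di in seq_len(kh)) {
      idx <- idx + 1L
      rows <- di + (seq_len(ho) - 1L) * stride
      cols <- dj + (seq_len(wo) - 1L) * stride
      sl <- matrix(xv[, rows, cols, , drop = FALSE], nrow = m, ncol = cin)
      slices[[idx]] <- sl
      wrow <- ((idx - 1L) * cin) + seq_len(cin)
      out <- out + sl %*% wmat[wrow, , drop = FALSE]
    }
  }
  val <- array(out, c(n, ho, wo, cout))
  node <- nd_node(tape, val, list(x, w), function(g) {
    gmat <- matrix(g, nrow = m, ncol = cout)
    gw <- matrix(0, kh * kw * cin, cout)
    gx <- array(0, d)
    idx <- 0L
    for (dj in seq_len(kw)) {
      for (di in seq_len(kh)) {
        idx <- idx + 1L
        wrow <- ((idx - 1L) * cin) + seq_len(cin)
        gw[wrow, ] <- crossprod(slices[[idx]], gmat)
        gsl <- array(
          gmat %*% t(wmat[wrow, , drop = FALSE]),
          c(n, ho, wo, cin)
        )
        rows <- di + (seq_len(ho) - 1L) * stride
        cols <- dj + (seq_len(wo) - 1L) * stride
        gx[, rows, cols, ] <- gx[, rows, cols, , drop = FALSE] + gsl
      }
    }
    nd_acc(w, array(gw, dw))
    if (pad > 0) {
      gx <- gx[, pad + seq_len(d[2] - 2 * pad), pad + seq_len(d[3] - 2 * pad),
        ,
        drop = FALSE
      ]
    }
    nd_acc(x, gx)
  })
  if (!is.null(b)) node <- nd_add_bias(tape, node, b)
  node
}

nd_avgpool2 <- function(tape, x) {
  d <- dim(x$val)
  stopifnot(d[2] %% 2 == 0, d[3] %% 2 == 0)
  h2 <- d[2] %/% 2L; w2 <- d[3] %/% 2L
  oi <- seq(1L, d[2], 2L); oj <- seq(1L, d[3], 2L)
  val <- (x$val[, oi, oj, , drop = FALSE] + x$val[, oi + 1L, oj, , drop = FALSE] +
    x$val[, oi, oj + 1L, , drop = FALSE] +
    x$val[, oi + 1L, oj + 1L, , drop = FALSE]) / 4
  dim(val) <- c(d[1], h2, w2, d[4])
  nd_node(tape, val, list(x), function(g) {
    gx <- array(0, d)
    for (a in 0:1) for (b in 0:1) {
      gx[, oi + a, oj + b, ] <- array(g / 4, c(d[1], h2, w2, d[4]))
    }
    nd_acc(x, gx)
  })
}

nd_upsample2 <- function(tape, x) {
  d <- dim(x$val)
  ih <- rep(seq_len(d[2]), each = 2)
  iw <- rep(seq_len(d[3]), each = 2)
  val <- x$val[, ih, iw, , drop = FALSE]
  nd_node(tape, val, list(x), function(g) {
    oi <- seq(1L, 2L * d[2], 2L); oj <- seq(1L, 2L * d[3], 2L)
    gs <- g[, oi, oj, , drop = FALSE] + g[, oi + 1L, oj, , drop = FALSE] +
      g[, oi, oj + 1L, , drop = FALSE] + g[, oi + 1L, oj + 1L, , drop = FALSE]
    nd_acc(x, array(gs, d))
  })
}

nd_global_mean_hw <- function(tape, x) {
  d <- dim(x$val)
  m <- d[2] * d[3]
  val <- apply(x$val, c(1, 4), mean)
  dim(val) <- c(d[1], d[4])
  nd_node(tape, val, list(x), function(g) {
    gx <- array(0, d)
    for (c_ in seq_len(d[4])) {
      gx[, , , c_] <- array(rep(g[, c_] / m, m), c(d[1], d[2], d[3]))
    }
    nd_acc(x, gx)
  })
}

## ---- softmax / batched matmul / outer ops ---------------------------------

# softmax along the trailing dimension of any array
nd_softmax_last <- function(tape, x) {
  d <- dim1(x$val)
  k <- d[length(d)]
  m <- matrix(x$val, ncol = k)
  m <- exp(m - apply(m, 1, max))
  p <- m / rowSums(m)
  val <- as_arr(p, d)
  nd_node(tape, val, list(x), function(g) {
    gm <- matrix(g, ncol = k)
    gx <- p * (gm - rowSums(gm * p))
    nd_acc(x, as_arr(gx, d))
  })
}

# batched matrix product over the leading (batch) dimension
nd_bmm3 <- function(tape, a, b, ta = FALSE, tb = FALSE) {
  da <- dim1(a$val); db <- dim1(b$val)
  n <- da[1]
  av <- a$val; bv <- b$val
  one <- function(m, i, d3) matrix(m[i, , ], d3[2], d3[3])
  outl <- lapply(seq_len(n), function(i) {
    A <- one(av, i, da); B <- one(bv, i, db)
    if (ta) A <- t(A)
    if (tb) B <- t(B)
    A %*% B
  })
  do <- c(n, dim(outl[[1]]))
  val <- array(0, do)
  for (i in seq_len(n)) val[i, , ] <- outl[[i]]
  nd_node(tape, val, list(a, b), function(g) {
    ga <- array(0, da); gb <- array(0, db)
    for (i in seq_len(n)) {
      G <- matrix(g[i, , ], do[2], do[3])
      A <- one(av, i, da); B <- one(bv, i, db)
      if (ta) A <- t(A)
      if (tb) B <- t(B)
      gA <- G %*% t(B); gB <- t(A) %*% G
      if (ta) gA <- t(gA)
      if (tb) gB <- t(gB)
      ga[i, , ] <- gA; gb[i, , ] <- gB
    }
    nd_acc(a, ga); nd_acc(b, gb)
  })
}

# outer arithmetic between two [N, D] latents -> [N, D, D]:
# out[n, i, j] = u[n, i] (op) v[n, j], op in sum/prod/diff/div
nd_outer_pair <- function(tape, u, v, op = c("sum", "prod", "diff", "div"),
                          eps = 1e-6) {
  op <- match.arg(op)
  du <- dim1(u$val)
  n <- du[1]; dd <- du[2]
  au <- array(rep(u$val, times = dd), c(n, dd, dd)) # depends on (n, i)
  av <- aperm(array(rep(v$val, times = dd), c(n, dd, dd)), c(1, 3, 2)) # (n, j)
  val <- switch(op,
    sum = au + av,
    prod = au * av,
    diff = au - av,
    div = au / (av + eps)
  )
  nd_node(tape, val, list(u, v), function(g) {
    gu_full <- switch(op,
      sum = g, prod = g * av, diff = g, div = g / (av + eps)
    )
    gv_full <- switch(op,
      sum = g, prod = g * au, diff = -g,
      div = -g * au / (av + eps)^2
    )
    nd_acc(u, apply(gu_full, c(1, 2), sum))
    nd_acc(v, apply(gv_full, c(1, 3), sum))
  })
}

## ---- dropout --------------------------------------------------------------

nd_dropout <- function(tape, x, rate, training = TRUE) {
  if (!training || rate <= 0) return(x)
  mask <- array(
    (runif(length(x$val)) >= rate) / (1 - rate),
    dim1(x$val)
  )
  nd_mul_const(tape, x, mask)
}

## ---- parameter handling / Adam --------------------------------------------

# wrap a flat named list of arrays as tape nodes
nn_params_nodes <- function(tape, params) {
  lapply(params, function(p) nd_node(tape, p))
}

nn_collect_grads <- function(pnodes, params) {
  lapply(setNames(names(params), names(params)), function(nm) {
    g <- pnodes[[nm]]$grad
    if (is.null(g)) array(0, dim1(params[[nm]])) else g
  })
}

adam_init <- function(params) {
  list(
    m = lapply(params, function(p) array(0, dim1(p))),
    v = lapply(params, function(p) array(0, dim1(p))),
    t = 0
  )
}

adam_step <- function(state, params, grads, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(state = state, params = params)
}

# He-style initializers (seeded by the caller's RNG state)
init_conv <- function(kh, kw, cin, cout, scale = 1) {
  array(rnorm(kh * kw * cin * cout, 0, scale * sqrt(2 / (kh * kw * cin))),
    dim = c(kh, kw, cin, cout)
  )
}

init_dense <- function(din, dout, scale = 1) {
  matrix(rnorm(din * dout, 0, scale * sqrt(2 / din)), din, dout)
}
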