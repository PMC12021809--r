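#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' previous RNG state, so library functions never disturb a caller's stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a reproducible sub-seed from a parent seed
#'
#' Deterministic integer mixing so that each pipeline stage (map draws,
#' spiral cores, solver noise, weight init) gets its own stream from one
#' global seed. Result is always in \[1, 2^31 - 2\].
#'
#' @param seed parent integer seed.
#' @param ... further integers or strings identifying the stage.
#' @return a positive integer below 2^31.
#' @export
mix_seed <- function(seed, ...) {
  parts <- list(...)
  h <- as.double(seed) %% 2147483647
  for (p in parts) {
    if (is.character(p)) {
      p <- sum(utf8ToInt(p) * seq_along(utf8ToInt(p)))
    }
    h <- (h * 48271 + as.double(p) * 16807 + 12345) %% 2147483647
  }
  as.integer(h %% 2147483645 + 1)
}

#' Nearest-neighbour resampling of a 2D grid
#'
#' Maps a matrix to a new resolution by nearest-neighbour index lookup;
#' used to move fields between the 96x96 map grid and the solver lattice.
#'
#' @param mat numeric matrix.
#' @param out_dim integer length-2 target dimensions (rows, cols).
#' @return matrix of dimension `out_dim`.
#' @export
resample_grid <- function(mat, out_dim) {
  out_dim <- rep(as.integer(out_dim), length.out = 2)
  ri <- pmin(nrow(mat), pmax(1L, as.integer(ceiling(seq_len(out_dim[1]) *
    nrow(mat) / out_dim[1] - 0.5 + 1e-9))))
  ci <- pmin(ncol(mat), pmax(1L, as.integer(ceiling(seq_len(out_dim[2]) *
    ncol(mat) / out_dim[2] - 0.5 + 1e-9))))
  mat[ri, ci, drop = FALSE]
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be > 0", name))
  }
  invisible(x)
}
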