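#' Fibrosis maps in image-intensity-ratio units
#'
#' A `fibrosis_map` is a 2D grid (default 96 x 96, the unfolded
#' universal-atrial-coordinate view of one atrium) of image intensity ratio
#' (IIR) values: LGE-MRI voxel intensity divided by blood-pool intensity.
#' IIR is dimensionless; healthy myocardium sits near 1 and fibrotic tissue
#' above it. Maps are the common currency of the whole pipeline: the
#' diffusion model generates them, the spatial statistics filter them, the
#' remodeling rules consume them, and the classifier sees them as a channel.
#'
#' @param values numeric matrix of non-negative, finite IIR values.
#' @param source provenance tag, one of `"real"`, `"synthetic"`, `"noise"`,
#'   `"fixture"`.
#' @param map_id unique identifier string.
#' @param seed integer seed used to draw the map, or `NULL`.
#' @return a `fibrosis_map` object (a matrix with metadata attributes).
#' @export
fibrosis_map <- function(values, source = "fixture",
                         map_id = "map", seed = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix")
  }
  if (any(!is.finite(values))) abort("fibrosis map values must be finite")
  if (any(values < 0)) abort("fibrosis map values must be >= 0")
  source <- match.arg(source, c("real", "synthetic", "noise", "fixture"))
  if (source == "noise") {
    if (abs(min(values) - 0.25) > 1e-9 || abs(max(values) - 1.75) > 1e-9) {
      abort("noise-source maps must span exactly [0.25, 1.75] IIR")
    }
  }
  structure(values,
    source = source, map_id = as.character(map_id),
    seed = if (is.null(seed)) NULL else as.integer(seed),
    class = c("fibrosis_map", "matrix", "array")
  )
}

#' @export
print.fibrosis_map <- function(x, ...) {
  cat(sprintf(
    "<fibrosis_map %s> %dx%d, source=%s, IIR in [%.3f, %.3f], mean %.3f\n",
    attr(x, "map_id"), nrow(x), ncol(x), attr(x, "source"),
    min(x), max(x), mean(x)
  ))
  invisible(x)
}

map_values <- function(map) {
  v <- unclass(map)
  attributes(v) <- list(dim = dim(map))
  v
}

#' Generate a Gaussian-noise baseline map
#'
#' Draws independent standard-normal values per pixel and min-max rescales
#' the map so its minimum is exactly 0.25 IIR and its maximum exactly
#' 1.75 IIR, the intensity range of the synthetic fibrosis distributions it
#' serves as a spatially unstructured baseline for.
#'
#' @param shape integer length-2 grid dimensions (default `c(96, 96)`).
#' @param seed integer seed (required; maps are reproducible by seed).
#' @param range length-2 IIR range after normalization.
#' @return a `fibrosis_map` with `source = "noise"`.
#' @export
generate_noise_map <- function(shape = c(96, 96), seed, range = c(0.25, 1.75)) {
  if (missing(seed)) abort("`seed` is required for noise maps")
  shape <- rep(as.integer(shape), length.out = 2)
  if (any(shape < 1)) abort("`shape` must be positive in both dimensions")
  vals <- with_seed(seed, matrix(rnorm(prod(shape)), shape[1], shape[2]))
  lo <- min(vals); hi <- max(vals)
  if (hi - lo < .Machine$double.eps) {
    abort("degenerate draw: zero dynamic range, min-max rescaling undefined")
  }
  vals <- range[1] + (vals - lo) / (hi - lo) * (range[2] - range[1])
  fibrosis_map(vals,
    source = "noise",
    map_id = sprintf("noise-%d", as.integer(seed)), seed = seed
  )
}

#' Parameters for the LGE-like fixture generator
#'
#' The fixture generator is a stand-in for real LGE-MRI fibrosis maps: a
#' smooth Gaussian random field warped through a Gaussian copula onto a
#' right-skewed intensity distribution, calibrated to the summary statistics
#' reported for clinical atrial LGE-MRI (per-map mean about 1.1 IIR, pixel
#' spread about 0.25, patchy suprathreshold clusters).
#'
#' @param correlation_length spatial correlation length in pixels (> 0).
#' @param target_mean target per-map mean intensity (IIR).
#' @param target_sd target within-map pixel spread (IIR).
#' @param clip length-2 IIR clipping range.
#' @param gamma_shape shape of the right-skewed marginal (gamma family).
#' @param mean_jitter_sd between-map SD of the mean shift (emulates
#'   patient-to-patient fibrosis burden variation).
#' @param sd_jitter_log between-map log-SD of the spread factor.
#' @param shape grid dimensions.
#' @return a list of class `fixture_params`.
#' @export
fixture_params <- function(correlation_length = 8, target_mean = 1.1,
                           target_sd = 0.25, clip = c(0, 2),
                           gamma_shape = 4, mean_jitter_sd = 0.04,
                           sd_jitter_log = 0.06, shape = c(96, 96)) {
  if (correlation_length <= 0) abort("`correlation_length` must be > 0")
  stopifnot_scalar_number(target_mean, "target_mean", positive = TRUE)
  stopifnot_scalar_number(target_sd, "target_sd", positive = TRUE)
  structure(list(
    correlation_length = correlation_length, target_mean = target_mean,
    target_sd = target_sd, clip = clip, gamma_shape = gamma_shape,
    mean_jitter_sd = mean_jitter_sd, sd_jitter_log = sd_jitter_log,
    shape = rep(as.integer(shape), length.out = 2)
  ), class = "fixture_params")
}

#' Generate an LGE-like fixture map
#'
#' Smooths white noise with a Gaussian kernel of sigma =
#' `correlation_length / 2`, standardizes by the theoretical marginal SD of
#' the smoothed field, and maps through a Gaussian copula onto a shifted
#' gamma marginal with the target mean and spread, then clips. A per-map
#' mean/spread jitter emulates inter-patient variation.
#'
#' @param params a [fixture_params()] list.
#' @param seed integer seed.
#' @return a `fibrosis_map` with `source = "fixture"`.
#' @export
generate_lge_like_fixture <- function(params = fixture_params(), seed) {
  if (missing(seed)) abort("`seed` is required for fixture maps")
  p <- params
  sig <- p$correlation_length / 2
  with_seed(seed, {
    field <- matrix(rnorm(prod(p$shape)), p$shape[1], p$shape[2])
    field <- smooth_matrix(field, sig)
    # theoretical marginal SD of 2D Gaussian-smoothed unit white noise;
    # deliberately not the empirical spatial SD so that correlation lengths
    # comparable to the grid degrade gracefully to near-constant maps
    sd_th <- sqrt(1 / (4 * pi * sig^2))
    z <- field / sd_th
    k <- p$gamma_shape
    y <- p$target_mean +
      p$target_sd * (stats::qgamma(stats::pnorm(z), shape = k) - k) / sqrt(k)
    y <- y + rnorm(1, 0, p$mean_jitter_sd)
    y <- mean(y) + (y - mean(y)) * exp(rnorm(1, 0, p$sd_jitter_log))
    y <- pmax(pmin(y, p$clip[2]), p$clip[1])
    fibrosis_map(y,
      source = "fixture",
      map_id = sprintf("fixture-%d", as.integer(seed)), seed = seed
    )
  })
}

#' Generate an ensemble of maps
#'
#' @param n number of maps.
#' @param seed global seed; map `i` uses a sub-seed derived from it.
#' @param kind `"noise"` or `"fixture"`.
#' @param ... passed to the underlying generator.
#' @return list of `fibrosis_map` objects.
#' @export
generate_map_ensemble <- function(n, seed, kind = c("noise", "fixture"), ...) {
  kind <- match.arg(kind)
  lapply(seq_len(n), function(i) {
    s <- mix_seed(seed, kind, i)
    if (kind == "noise") generate_noise_map(seed = s, ...)
    else generate_lge_like_fixture(seed = s, ...)
  })
}

# separable Gaussian smoothing with symmetric (reflective) boundaries,
# implemented as row/column smoothing matrices so rows always sum to one
smoother_matrix <- function(n, sigma) {
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  off <- (-r):r
  k <- exp(-off^2 / (2 * sigma^2))
  k <- k / sum(k)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i + off
    # half-sample symmetric reflection ( ... 2 1 | 1 2 .. n-1 n | n n-1 ... ),
    # exact for arbitrarily wide kernels via the period-2n folding
    j0 <- ((j - 1L) %% (2L * n) + 2L * n) %% (2L * n)
    j <- ifelse(j0 < n, j0 + 1L, 2L * n - j0)
    for (m in seq_along(off)) W[i, j[m]] <- W[i, j[m]] + k[m]
  }
  W
}

smooth_matrix <- function(mat, sigma) {
  Wr <- smoother_matrix(nrow(mat), sigma)
  Wc <- if (ncol(mat) == nrow(mat)) Wr else smoother_matrix(ncol(mat), sigma)
  Wr %*% mat %*% t(Wc)
}

#' Gaussian smoothing of a fibrosis map
#'
#' 2D Gaussian convolution (separable) with reflective boundary handling,
#' used before the spatial statistics so that the entropy and
#' autocorrelation of a map are judged on its cluster structure rather than
#' on pixel-level noise.
#'
#' @param map a `fibrosis_map` or numeric matrix.
#' @param sigma kernel standard deviation in pixels (> 0).
#' @return smoothed object of the same class and shape.
#' @export
gaussian_smooth <- function(map, sigma) {
  stopifnot_scalar_number(sigma, "sigma", positive = TRUE)
  sm <- smooth_matrix(
    if (inherits(map, "fibrosis_map")) map_values(map) else map, sigma
  )
  if (inherits(map, "fibrosis_map")) {
    fibrosis_map(pmax(sm, 0),
      source = attr(map, "source"),
      map_id = attr(map, "map_id"), seed = attr(map, "seed")
    )
  } else {
    sm
  }
}

#' Write / read fibrosis maps as plain text
#'
#' One tab-separated values file per map plus a JSON sidecar carrying the
#' metadata (`map_id`, `source`, `seed`). `read_fibrosis_map()` inverts it;
#' `ingest_map_dir()` loads every `*.tsv` in a directory, which is also the
#' entry point for externally deposited IIR maps exported to text.
#'
#' @param map a `fibrosis_map`.
#' @param path file path for the TSV (sidecar gets `.json` appended).
#' @return `write_fibrosis_map()` returns `path` invisibly;
#'   `read_fibrosis_map()` a `fibrosis_map`; `ingest_map_dir()` a list.
#' @export
write_fibrosis_map <- function(map, path) {
  utils::write.table(map_values(map), path,
    sep = "\t",
    row.names = FALSE, col.names = FALSE
  )
  meta <- list(
    map_id = attr(map, "map_id"), source = attr(map, "source"),
    seed = attr(map, "seed")
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_fibrosis_map
#' @export
read_fibrosis_map <- function(path) {
  vals <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(vals) <- NULL
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) {
    jsonlite::read_json(side, simplifyVector = TRUE)
  } else {
    list(map_id = basename(path), source = "real", seed = NULL)
  }
  fibrosis_map(vals,
    source = meta$source %||% "real",
    map_id = meta$map_id %||% basename(path), seed = meta$seed
  )
}

#' @rdname write_fibrosis_map
#' @param dir directory containing `*.tsv` maps.
#' @export
ingest_map_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  lapply(files, read_fibrosis_map)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ensemble summary statistics for a set of maps
#'
#' @param maps list of `fibrosis_map` objects.
#' @param config a [spatial_stats_config()].
#' @return a tibble with one row per map: id, source, mean/sd IIR, Shannon
#'   entropy (configured mode) and Moran's I.
#' @export
map_stats <- function(maps, config = spatial_stats_config()) {
  tibble(
    map_id = vapply(maps, function(m) attr(m, "map_id"), character(1)),
    source = vapply(maps, function(m) attr(m, "source"), character(1)),
    mean_iir = vapply(maps, mean, numeric(1)),
    sd_iir = vapply(maps, sd, numeric(1)),
    shannon_entropy = vapply(maps, shannon_entropy, numeric(1),
      config = config
    ),
    morans_i = vapply(maps, morans_i, numeric(1), config = config)
  )
}

#' Plot a fibrosis map
#'
#' @param object a `fibrosis_map`.
#' @param ... ignored.
#' @return a ggplot raster of the IIR field.
#' @export
autoplot.fibrosis_map <- function(object, ...) {
  df <- expand.grid(row = seq_len(nrow(object)), col = seq_len(ncol(object)))
  df$iir <- as.vector(map_values(object))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$iir)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "IIR", limits = c(0, 2)) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = attr(object, "map_id"),
      subtitle = paste("source:", attr(object, "source")),
      x = NULL, y = NULL
    )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
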