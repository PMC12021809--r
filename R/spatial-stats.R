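#' Configuration for the map spatial statistics
#'
#' Controls the pre-smoothing and the Shannon-entropy estimator used by the
#' quality filter. Three entropy modes are provided because normalized
#' pixel-mass entropy (`weighted`), gray-level histogram entropy
#' (`histogram`) and the binary entropy of the suprathreshold pixel fraction
#' (`binary_fraction`) measure different things on near-uniform images; the
#' quality filter defaults to `binary_fraction`, which separates structured
#' fibrosis patterns from smoothed noise by their fibrotic-cluster burden.
#'
#' @param filter_sigma Gaussian pre-smoothing SD in pixels (> 0), or `NULL`
#'   to compute the statistic on the raw map.
#' @param se_mode entropy estimator: `"weighted_eq34"`, `"histogram"` or
#'   `"binary_fraction"`.
#' @param histogram_bins number of gray-level bins for `"histogram"`.
#' @param binary_threshold IIR threshold defining fibrotic pixels (default
#'   1.22, the ablation-mask threshold).
#' @param se_reject_threshold maps with entropy at or below this value are
#'   rejected by [filter_by_entropy()] (default 0.66).
#' @return list of class `spatial_stats_config`.
#' @export
spatial_stats_config <- function(filter_sigma = 3,
                                 se_mode = c(
                                   "binary_fraction", "weighted_eq34",
                                   "histogram"
                                 ),
                                 histogram_bins = 64,
                                 binary_threshold = 1.22,
                                 se_reject_threshold = 0.66) {
  if (!is.null(filter_sigma)) {
    stopifnot_scalar_number(filter_sigma, "filter_sigma", positive = TRUE)
  }
  if (se_reject_threshold < 0 || se_reject_threshold > 1) {
    abort("`se_reject_threshold` must be in [0, 1]")
  }
  structure(list(
    filter_sigma = filter_sigma, se_mode = match.arg(se_mode),
    histogram_bins = as.integer(histogram_bins),
    binary_threshold = binary_threshold,
    se_reject_threshold = se_reject_threshold
  ), class = "spatial_stats_config")
}

maybe_smooth <- function(map, config) {
  m <- if (inherits(map, "fibrosis_map")) map_values(map) else map
  if (!is.null(config$filter_sigma)) m <- smooth_matrix(m, config$filter_sigma)
  m
}

#' Normalized Shannon entropy of a fibrosis map
#'
#' All modes return a value in \[0, 1\]. In `weighted_eq34` mode each pixel's
#' share of the total intensity mass is treated as a probability,
#' \deqn{SE = -\frac{1}{\log_2(N_x N_y)} \sum_{ij} P_{ij} \log_2 P_{ij},
#'       \qquad P_{ij} = S_{ij} / \sum_{ij} S_{ij},}
#' so a uniform map scores 1 and a single-pixel map scores 0. `histogram`
#' mode bins pixel intensities over \[0, 2\] IIR and normalizes the bin-count
#' entropy by the same \eqn{\log_2(N_x N_y)} factor. `binary_fraction` mode
#' reports the binary entropy of the fraction of pixels above
#' `binary_threshold`; it is the default for the quality filter because it
#' tracks the presence of fibrotic clusters rather than overall smoothness.
#'
#' @param map a `fibrosis_map` or numeric matrix (non-negative).
#' @param config a [spatial_stats_config()]; smoothing is applied first.
#' @return entropy in \[0, 1\].
#' @export
shannon_entropy <- function(map, config = spatial_stats_config()) {
  m <- maybe_smooth(map, config)
  if (any(m < -1e-9)) abort("entropy requires a non-negative map")
  m <- pmax(m, 0)
  n_pix <- length(m)
  switch(config$se_mode,
    weighted_eq34 = {
      tot <- sum(m)
      if (tot <= 0) abort("all-zero map: pixel-mass distribution undefined")
      p <- m / tot
      p <- p[p > 0]
      -sum(p * log2(p)) / log2(n_pix)
    },
    histogram = {
      b <- config$histogram_bins
      idx <- pmin(b, pmax(1L, as.integer(floor(m / 2 * b)) + 1L))
      cnt <- tabulate(idx, nbins = b)
      p <- cnt[cnt > 0] / n_pix
      -sum(p * log2(p)) / log2(n_pix)
    },
    binary_fraction = {
      f <- mean(m > config$binary_threshold)
      if (f <= 0 || f >= 1) 0 else -f * log2(f) - (1 - f) * log2(1 - f)
    }
  )
}

#' Moran's I spatial autocorrelation of a map
#'
#' Standard Moran statistic with row-normalized rook (4-neighbour)
#' adjacency on the pixel lattice:
#' \deqn{I = \frac{n}{\sum_{ij} w_{ij}}
#'       \frac{\sum_{ij} w_{ij} z_i z_j}{\sum_i z_i^2},}
#' with \eqn{z} the mean-centred pixel values. Smooth clustered fields score
#' near +1, checkerboard alternation -1, spatial white noise near 0
#' (expectation \eqn{-1/(n-1)}). Computed via neighbour sums, so it scales
#' to 96 x 96 grids without forming the weight matrix.
#'
#' @inheritParams shannon_entropy
#' @return Moran's I (dimensionless).
#' @export
morans_i <- function(map, config = spatial_stats_config()) {
  m <- maybe_smooth(map, config)
  z <- m - mean(m)
  ss <- sum(z^2)
  if (ss < .Machine$double.eps * length(z)) {
    abort("constant map: Moran's I undefined (zero variance)")
  }
  nr <- nrow(z); nc <- ncol(z)
  nb_sum <- matrix(0, nr, nc)
  deg <- matrix(0, nr, nc)
  nb_sum[-1, ] <- nb_sum[-1, ] + z[-nr, ]; deg[-1, ] <- deg[-1, ] + 1
  nb_sum[-nr, ] <- nb_sum[-nr, ] + z[-1, ]; deg[-nr, ] <- deg[-nr, ] + 1
  nb_sum[, -1] <- nb_sum[, -1] + z[, -nc]; deg[, -1] <- deg[, -1] + 1
  nb_sum[, -nc] <- nb_sum[, -nc] + z[, -1]; deg[, -nc] <- deg[, -nc] + 1
  # row-normalized weights: each row of W sums to 1, so sum(W) = n
  sum(z * nb_sum / deg) / ss
}

#' Entropy-based quality filter
#'
#' Retains maps whose Shannon entropy (under the configured mode, after the
#' configured smoothing) is strictly greater than the rejection threshold;
#' a map scoring exactly at the threshold is excluded. Order is preserved.
#'
#' @param maps list of `fibrosis_map` objects (possibly empty).
#' @param config a [spatial_stats_config()].
#' @return the retained sublist.
#' @export
filter_by_entropy <- function(maps, config = spatial_stats_config()) {
  if (length(maps) == 0) return(maps)
  se <- vapply(maps, shannon_entropy, numeric(1), config = config)
  maps[se > config$se_reject_threshold]
}
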