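#' Ablation strategies, in canonical order
#'
#' Four strategies are modeled: pulmonary-vein isolation alone and PVI plus
#' fibrosis ablation of the left atrium, the right atrium, or both. The
#' order is fixed package-wide and matches the four classifier outputs.
#'
#' @return character vector of the four strategy names.
#' @export
ablation_strategies <- function() {
  c("PVI", "PVI+LA", "PVI+RA", "PVI+LA+RA")
}

#' Tissue conductivity from local fibrosis intensity
#'
#' Piecewise-constant structural-remodeling rule: image intensity ratio is
#' binned into four conductivities calibrated against planar conduction
#' velocities of 0.81, 0.74, 0.71 and 0.58 m/s. Bins are left-closed /
#' right-open so the boundary values 0.9, 1.4 and 1.6 join the
#' higher-fibrosis bin.
#'
#' @param iir numeric vector/matrix of IIR values (>= 0).
#' @return conductivities in S/m, same shape as `iir`.
#' @export
conductivity_from_iir <- function(iir) {
  if (any(iir < 0)) abort("IIR values must be >= 0")
  out <- ifelse(iir < 0.9, 0.40,
    ifelse(iir < 1.4, 0.31, ifelse(iir < 1.6, 0.28, 0.19))
  )
  if (is.matrix(iir)) dim(out) <- dim(iir)
  out
}

#' Ionic conductance multipliers for remodeled tissue
#'
#' Composes up to three multiplicative layers on the baseline Courtemanche
#' maximal conductances:
#' \itemize{
#'   \item baseline calibration: \eqn{g_{Na} \times 2} (physiological
#'     upstroke velocity), \eqn{g_{K1} \times 0.8} (clinical restitution);
#'   \item AF electrical remodeling (when `af_remodeling_on`):
#'     \eqn{g_{to} \times 0.5}, \eqn{g_{Kur} \times 0.5},
#'     \eqn{g_{CaL} \times 0.3};
#'   \item fibrotic electrophysiological remodeling (when IIR exceeds
#'     `fibrotic_threshold`): \eqn{g_{K1} \times 0.5},
#'     \eqn{g_{Na} \times 0.6}, \eqn{g_{CaL} \times 0.5}.
#' }
#' Layers are pure multipliers, so their composition is order-independent.
#'
#' @param iir numeric vector of IIR values (>= 0).
#' @param af_remodeling_on logical; apply the AF remodeling layer.
#' @param fibrotic_threshold IIR above which the fibrotic layer applies
#'   (default 1.22, the ablation-mask threshold).
#' @return tibble with columns `g_na`, `g_k1`, `g_to`, `g_kur`, `g_cal`,
#'   one row per element of `iir`.
#' @export
ionic_scaling_for <- function(iir, af_remodeling_on = TRUE,
                              fibrotic_threshold = 1.22) {
  if (any(iir < 0)) abort("IIR values must be >= 0")
  n <- length(iir)
  out <- tibble(
    g_na = rep(2.0, n), g_k1 = rep(0.8, n), g_to = rep(1.0, n),
    g_kur = rep(1.0, n), g_cal = rep(1.0, n)
  )
  if (af_remodeling_on) {
    out$g_to <- out$g_to * 0.5
    out$g_kur <- out$g_kur * 0.5
    out$g_cal <- out$g_cal * 0.3
  }
  fib <- as.vector(iir) > fibrotic_threshold
  out$g_k1[fib] <- out$g_k1[fib] * 0.5
  out$g_na[fib] <- out$g_na[fib] * 0.6
  out$g_cal[fib] <- out$g_cal[fib] * 0.5
  out
}

#' Pulmonary-vein isolation ring geometry
#'
#' Ring placement on the unfolded LA sheet, in unit coordinates: two annuli
#' around the left and right PV antra. The antrum interior stays conducting
#' but is electrically isolated by the non-conducting ring.
#'
#' @param centers list of length-2 unit-coordinate centers (x, y).
#' @param radius ring radius in unit coordinates.
#' @param width_px ring thickness in grid pixels.
#' @param enabled logical; `FALSE` disables the rings (useful for toy
#'   geometries).
#' @return list of class `pvi_config`.
#' @export
pvi_config <- function(centers = list(c(0.2, 0.8), c(0.8, 0.8)),
                       radius = 0.12, width_px = 2, enabled = TRUE) {
  structure(list(
    centers = centers, radius = radius,
    width_px = width_px, enabled = enabled
  ), class = "pvi_config")
}

#' Binary PVI ring mask on a grid
#'
#' @param shape grid dimensions (rows, cols).
#' @param config a [pvi_config()].
#' @return logical matrix; `TRUE` marks non-conducting ring pixels.
#' @export
pvi_ring_mask <- function(shape, config = pvi_config()) {
  shape <- rep(as.integer(shape), length.out = 2)
  mask <- matrix(FALSE, shape[1], shape[2])
  if (!config$enabled) return(mask)
  x <- (col(mask) - 0.5) / shape[2]
  y <- (row(mask) - 0.5) / shape[1]
  rpx <- config$radius * min(shape)
  for (ct in config$centers) {
    d <- sqrt(((x - ct[1]) * shape[2])^2 + ((y - ct[2]) * shape[1])^2)
    mask <- mask | (abs(d - rpx) <= config$width_px / 2)
  }
  mask
}

#' Ablation masks for one strategy
#'
#' The LA mask always carries the PVI rings; when the strategy includes LA
#' fibrosis ablation, pixels with IIR above `threshold` are added. The RA
#' mask contains suprathreshold pixels when the strategy includes RA
#' ablation and is all zeros otherwise (there is no PVI lesion on the right
#' atrium).
#'
#' @param la_map,ra_map `fibrosis_map`s (or matrices) for the two atria.
#' @param strategy one of [ablation_strategies()].
#' @param threshold IIR threshold for fibrosis ablation (default 1.22).
#' @param pvi a [pvi_config()].
#' @return list with logical matrices `la` and `ra`.
#' @export
build_ablation_masks <- function(la_map, ra_map, strategy,
                                 threshold = 1.22, pvi = pvi_config()) {
  if (!strategy %in% ablation_strategies()) {
    abort(sprintf("unknown ablation strategy '%s'", strategy))
  }
  la <- pvi_ring_mask(dim(la_map), pvi)
  if (strategy %in% c("PVI+LA", "PVI+LA+RA")) {
    la <- la | (unclass(la_map) > threshold)
  }
  ra <- matrix(FALSE, nrow(ra_map), ncol(ra_map))
  if (strategy %in% c("PVI+RA", "PVI+LA+RA")) {
    ra <- unclass(ra_map) > threshold
  }
  list(la = la, ra = ra)
}
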