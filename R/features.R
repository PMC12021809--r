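# Classifier inputs are extracted from the pre-ablation episode (dominant
# frequency and phase-singularity density summarize where the AF drivers
# live) and termination labels from the post-ablation episodes.

split_by_sheet <- function(result, values) {
  dims <- result$sheet_meta$dims
  n_per <- prod(dims)
  out <- list()
  for (si in seq_along(result$sheet_meta$sheets)) {
    nm <- result$sheet_meta$sheets[si]
    out[[nm]] <- matrix(values[(si - 1) * n_per + seq_len(n_per)],
      dims[1], dims[2]
    )
  }
  out
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))

#' Dominant-frequency maps
#'
#' Per node: mean-removed, Hann-windowed power spectrum of the voltage
#' trace; the dominant frequency is the frequency of the maximal spectral
#' peak at or below `f_max` (peaks above 20 Hz are excluded as
#' non-physiological). Quiescent nodes (no suprathreshold upstroke) get
#' DF = 0. Maps are resampled to the feature grid.
#'
#' @param result a `simulation_result`.
#' @param f_max frequency cap in Hz (default 20).
#' @param f_min spectral floor in Hz; the trace must cover at least two
#'   periods of `f_min` (default 1 Hz).
#' @param out_dim feature-map resolution (default 96).
#' @return named list of DF matrices (Hz), one per sheet.
#' @export
dominant_frequency_map <- function(result, f_max = 20, f_min = 1,
                                   out_dim = 96) {
  v <- result$voltage
  fs <- 1000 / result$record_dt
  n_t <- ncol(v)
  if (n_t * result$record_dt < 2 * 1000 / f_min) {
    abort(sprintf(
      "trace of %.2f s is shorter than 2 periods at the %.2g Hz floor",
      n_t * result$record_dt / 1000, f_min
    ))
  }
  active <- result$upstrokes > 0
  df_node <- numeric(nrow(v))
  freqs <- (seq_len(n_t) - 1) * fs / n_t
  band <- which(freqs > 0 & freqs <= f_max)
  if (any(active)) {
    w <- hann_window(n_t)
    x <- t(v[active, , drop = FALSE])
    x <- (x - rep(colMeans(x), each = n_t)) * w
    pw <- Mod(stats::mvfft(x))^2
    df_node[active] <- freqs[band][apply(
      pw[band, , drop = FALSE],
      2, which.max
    )]
  }
  lapply(split_by_sheet(result, df_node), resample_grid, out_dim)
}

# analytic-signal phase of every node trace: angle of x + i H(x)
analytic_phase <- function(v) {
  n_t <- ncol(v)
  h <- numeric(n_t)
  if (n_t %% 2 == 0) {
    h[c(1, n_t / 2 + 1)] <- 1
    h[2:(n_t / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n_t + 1) / 2)] <- 2
  }
  x <- t(v)
  x <- x - rep(colMeans(x), each = n_t)
  z <- stats::mvfft(stats::mvfft(x) * h, inverse = TRUE) / n_t
  t(atan2(Im(z), Re(z)))
}

#' Detect phase singularities by plaquette winding number
#'
#' Integrates the wrapped phase difference around every 2x2 plaquette; a
#' winding of +-2 pi marks a singularity (rotor core) of charge +-1.
#'
#' @param phase matrix of phases in (-pi, pi\].
#' @return tibble with `x`, `y` (plaquette centers, in column/row pixel
#'   coordinates) and `charge` (+1 or -1).
#' @export
detect_phase_singularities <- function(phase) {
  wrap <- function(a) atan2(sin(a), cos(a))
  nr <- nrow(phase); nc <- ncol(phase)
  p00 <- phase[-nr, -nc]; p01 <- phase[-nr, -1]
  p11 <- phase[-1, -1]; p10 <- phase[-1, -nc]
  s <- wrap(p01 - p00) + wrap(p11 - p01) + wrap(p10 - p11) + wrap(p00 - p10)
  w <- round(s / (2 * pi))
  idx <- which(w != 0, arr.ind = TRUE)
  tibble(
    x = idx[, 2] + 0.5, y = idx[, 1] + 0.5,
    charge = as.integer(w[idx])
  )
}

#' Phase map and singularities at one frame
#'
#' Phase is the angle of the analytic signal (Hilbert transform) of each
#' node's mean-removed voltage trace.
#'
#' @param result a `simulation_result`.
#' @param frame frame index (1-based).
#' @return list with per-sheet `phase` matrices and a `singularities`
#'   tibble (`sheet`, `x`, `y`, `charge`).
#' @export
phase_and_singularities <- function(result, frame) {
  n_t <- ncol(result$voltage)
  if (frame < 1 || frame > n_t) abort("frame index out of range")
  ph <- analytic_phase(result$voltage)
  sheets <- split_by_sheet(result, ph[, frame])
  sing <- bind_rows(lapply(names(sheets), function(nm) {
    s <- detect_phase_singularities(sheets[[nm]])
    if (nrow(s) > 0) s$sheet <- nm else s$sheet <- character(0)
    s
  }))
  list(phase = sheets, singularities = sing)
}

#' Phase-singularity density maps
#'
#' Counts phase-singularity occurrences per pixel across all frames of the
#' episode, Gaussian-smooths the count field, and resamples to the feature
#' grid. The raw (pre-smoothing) counts are returned as well: their total
#' equals the number of detections, a conservation property used in tests.
#'
#' @param result a `simulation_result` (>= 10 frames).
#' @param smoothing_sigma Gaussian smoothing SD in pixels (0 disables).
#' @param frame_stride evaluate every k-th frame (default 1 = all frames).
#' @param out_dim feature-map resolution.
#' @return list with per-sheet `psd` (smoothed, resampled), `raw` counts
#'   (solver grid), and `n_detections`.
#' @export
psd_map <- function(result, smoothing_sigma = 2, frame_stride = 1,
                    out_dim = 96) {
  n_t <- ncol(result$voltage)
  if (n_t < 10) abort("need at least 10 frames for a PSD map")
  ph <- analytic_phase(result$voltage)
  dims <- result$sheet_meta$dims
  n_per <- prod(dims)
  counts <- lapply(result$sheet_meta$sheets, function(nm) {
    matrix(0, dims[1], dims[2])
  })
  names(counts) <- result$sheet_meta$sheets
  n_det <- 0L
  frames <- seq(1, n_t, by = frame_stride)
  for (fr in frames) {
    sheets <- split_by_sheet(result, ph[, fr])
    for (nm in names(sheets)) {
      s <- detect_phase_singularities(sheets[[nm]])
      if (nrow(s) > 0) {
        n_det <- n_det + nrow(s)
        ri <- pmin(dims[1], pmax(1, round(s$y)))
        ci <- pmin(dims[2], pmax(1, round(s$x)))
        for (k in seq_len(nrow(s))) {
          counts[[nm]][ri[k], ci[k]] <- counts[[nm]][ri[k], ci[k]] + 1
        }
      }
    }
  }
  psd <- lapply(counts, function(m) {
    if (smoothing_sigma > 0) m <- smooth_matrix(m, smoothing_sigma)
    resample_grid(m, out_dim)
  })
  list(psd = psd, raw = counts, n_detections = n_det)
}

# last local maximum above the threshold, per node; 0 if none
last_peak_frame <- function(v, threshold = -40) {
  n_t <- ncol(v)
  if (n_t < 3) return(rep(0L, nrow(v)))
  mid <- v[, 2:(n_t - 1), drop = FALSE]
  is_pk <- (mid > v[, 1:(n_t - 2), drop = FALSE]) &
    (mid >= v[, 3:n_t, drop = FALSE]) & (mid > threshold)
  out <- integer(nrow(v))
  any_pk <- rowSums(is_pk) > 0
  if (any(any_pk)) {
    out[any_pk] <- apply(is_pk[any_pk, , drop = FALSE], 1, function(r) {
      max(which(r))
    }) + 1L
  }
  out
}

#' Ground-truth termination labels from post-ablation episodes
#'
#' Per conducting node, the time of the last action-potential peak (local
#' maximum above -40 mV) as a fraction of the episode duration; fractions
#' are averaged over all conducting nodes of both atria. The episode counts
#' as terminated when the average lies within 0-60 percent of the duration
#' (the boundary value 0.6 is terminated: the range is read as closed).
#' Nodes that never activate contribute fraction 0.
#'
#' @param results_per_strategy named list of `simulation_result`s, one per
#'   strategy in [ablation_strategies()] order.
#' @param threshold peak detection floor in mV.
#' @return tibble with `strategy`, `terminated`,
#'   `mean_last_peak_fraction`.
#' @export
ground_truth_label <- function(results_per_strategy, threshold = -40) {
  missing <- setdiff(ablation_strategies(), names(results_per_strategy))
  if (length(missing) > 0) {
    abort(paste("missing strategy result:", paste(missing, collapse = ", ")))
  }
  rows <- lapply(ablation_strategies(), function(st) {
    res <- results_per_strategy[[st]]
    cond <- res$sheet_meta$conducting
    pk <- last_peak_frame(res$voltage[cond, , drop = FALSE], threshold)
    frac <- pk * res$record_dt / (res$duration * 1000)
    mlpf <- mean(frac)
    tibble(
      strategy = st, terminated = mlpf <= 0.6,
      mean_last_peak_fraction = mlpf
    )
  })
  bind_rows(rows)
}

#' Assemble the five-channel feature stack for one atrium pair
#'
#' Channel order (fixed): PVI mask, PVI-plus-fibrosis ablation mask, PSD,
#' DF, fibrosis. Masks are binary; PSD is scaled by its per-map maximum
#' (zero map if empty), DF by `f_max`, fibrosis by 2 (the IIR range). The
#' RA PVI channel is all zeros (no PVI lesion exists on the right atrium).
#'
#' @param pre_result pre-ablation `simulation_result` (bi-atrial).
#' @param la_map,ra_map the fibrosis maps.
#' @param threshold fibrosis-ablation IIR threshold.
#' @param pvi a [pvi_config()].
#' @param f_max DF cap in Hz.
#' @param out_dim feature grid (default 96).
#' @return list of class `feature_stack`: arrays `la` and `ra` of dimension
#'   `out_dim x out_dim x 5` plus `channels` names.
#' @export
feature_stack <- function(pre_result, la_map, ra_map, threshold = 1.22,
                          pvi = pvi_config(), f_max = 20, out_dim = 96) {
  df <- dominant_frequency_map(pre_result,
    f_max = f_max, out_dim = out_dim,
    f_min = 2000 / (pre_result$duration * 1000)
  )
  psd <- psd_map(pre_result, out_dim = out_dim)
  m_pvi <- build_ablation_masks(la_map, ra_map, "PVI", threshold, pvi)
  m_fib <- build_ablation_masks(la_map, ra_map, "PVI+LA+RA", threshold, pvi)
  norm_psd <- function(m) if (max(m) > 0) m / max(m) else m
  mk <- function(atr, fmap) {
    ch <- array(0, c(out_dim, out_dim, 5))
    ch[, , 1] <- resample_grid(m_pvi[[atr]] * 1, out_dim)
    ch[, , 2] <- resample_grid(m_fib[[atr]] * 1, out_dim)
    ch[, , 3] <- norm_psd(psd$psd[[atr]])
    ch[, , 4] <- df[[atr]] / f_max
    ch[, , 5] <- resample_grid(unclass(fmap), out_dim) / 2
    ch
  }
  structure(list(
    la = mk("la", la_map), ra = mk("ra", ra_map),
    channels = c("mask_pvi", "mask_pvi_fibrosis", "psd", "df", "fibrosis")
  ), class = "feature_stack")
}
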