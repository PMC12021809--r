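#' Default resting state of the atrial myocyte model
#'
#' @return named numeric vector of the 21 Courtemanche state variables
#'   (membrane potential in mV, gates dimensionless, concentrations in mM).
#' @export
courtemanche_rest <- function() {
  s <- courtemanche_rest_cpp()
  names(s) <- c(
    "V", "m", "h", "j", "oa", "oi", "ua", "ui", "xr", "xs", "d", "f",
    "fca", "u", "v", "w", "nai", "ki", "cai", "caup", "carel"
  )
  s
}

scaling_matrix <- function(iir_vec, af_remodeling_on = TRUE,
                           fibrotic_threshold = 1.22) {
  as.matrix(ionic_scaling_for(iir_vec, af_remodeling_on, fibrotic_threshold))
}

# lattice 4-neighbour edges among conducting nodes of one sheet
sheet_edges <- function(dims, conducting, d_node, offset = 0L) {
  nr <- dims[1]; nc <- dims[2]
  id <- matrix(seq_len(nr * nc), nr, nc)
  e_right <- cbind(as.vector(id[, -nc]), as.vector(id[, -1]))
  e_down <- cbind(as.vector(id[-nr, ]), as.vector(id[-1, ]))
  e <- rbind(e_right, e_down)
  keep <- conducting[e[, 1]] & conducting[e[, 2]]
  e <- e[keep, , drop = FALSE]
  w <- (d_node[e[, 1]] + d_node[e[, 2]]) / 2
  list(edges = e + offset, w = w)
}

#' Build a bi-atrial (or single-sheet) simulation domain
#'
#' Two flat 2D sheets stand in for the 3D bi-atrial geometry: fibrosis maps
#' are resampled to the solver lattice, conductivity and ionic scalings are
#' assigned per node from local IIR, ablated pixels become non-conducting,
#' and a few interatrial bridges couple the sheets electrically.
#'
#' @param la_map,ra_map fibrosis maps (matrices in IIR); `ra_map = NULL`
#'   builds a single sheet.
#' @param solver_dim lattice size per sheet (resampled from the map grid).
#' @param spacing node spacing in mm.
#' @param chi calibration product (surface-to-volume x capacitance);
#'   conductivity sigma maps to diffusivity sigma / chi in mm^2/ms. See
#'   [calibrate_chi()].
#' @param af_remodeling apply AF electrical remodeling.
#' @param masks optional list with logical matrices `la`, `ra` (map grid) of
#'   ablated pixels.
#' @param bridge_positions list of unit-coordinate (x, y) interatrial
#'   connection sites; `NULL` disables coupling.
#' @param fibrotic_threshold IIR for fibrotic EP remodeling.
#' @return a `tissue_sheet` object.
#' @export
tissue_sheet <- function(la_map, ra_map = NULL, solver_dim = 192,
                         spacing = 0.5, chi = NULL, af_remodeling = TRUE,
                         masks = NULL,
                         bridge_positions = list(
                           c(0.5, 0.95), c(0.12, 0.75), c(0.88, 0.75)
                         ),
                         fibrotic_threshold = 1.22) {
  if (is.null(chi)) chi <- default_chi()
  sheets <- list(la = unclass(la_map))
  if (!is.null(ra_map)) sheets$ra <- unclass(ra_map)
  dims <- c(solver_dim, solver_dim)
  n_per <- prod(dims)
  iir <- c(); cond <- c(); labels <- c()
  for (nm in names(sheets)) {
    ii <- resample_grid(sheets[[nm]], dims)
    mk <- if (!is.null(masks) && !is.null(masks[[nm]])) {
      resample_grid(masks[[nm]] * 1, dims) > 0.5
    } else {
      matrix(FALSE, dims[1], dims[2])
    }
    iir <- c(iir, as.vector(ii))
    cond <- c(cond, as.vector(!mk))
    labels <- c(labels, rep(nm, n_per))
  }
  sigma <- conductivity_from_iir(iir)
  d_node <- sigma / chi / spacing^2 # edge coupling, 1/ms
  edges <- NULL; ew <- NULL
  for (k in seq_along(sheets)) {
    off <- (k - 1L) * n_per
    se <- sheet_edges(dims, cond[off + seq_len(n_per)],
      d_node[off + seq_len(n_per)],
      offset = off
    )
    edges <- rbind(edges, se$edges)
    ew <- c(ew, se$w)
  }
  if (length(sheets) == 2 && length(bridge_positions) > 0) {
    for (bp in bridge_positions) {
      r <- pmin(dims[1], pmax(1, round(bp[2] * dims[1])))
      c_ <- pmin(dims[2], pmax(1, round(bp[1] * dims[2])))
      a <- (c_ - 1) * dims[1] + r
      b <- n_per + a
      if (cond[a] && cond[b]) {
        edges <- rbind(edges, c(a, b))
        ew <- c(ew, (d_node[a] + d_node[b]) / 2)
      }
    }
  }
  structure(list(
    n_nodes = length(iir), dims = dims, sheets = names(sheets),
    iir = iir, sigma = sigma, conducting = cond, labels = labels,
    scaling = scaling_matrix(iir, af_remodeling, fibrotic_threshold),
    edges = edges, edge_w = ew, spacing = spacing, chi = chi,
    af_remodeling = af_remodeling
  ), class = "tissue_sheet")
}

#' @export
print.tissue_sheet <- function(x, ...) {
  cat(sprintf(
    "<tissue_sheet> %d sheet(s) of %dx%d, %.1f%% conducting, h = %.2f mm\n",
    length(x$sheets), x$dims[1], x$dims[2],
    100 * mean(x$conducting), x$spacing
  ))
  invisible(x)
}

#' Integrate the monodomain equation on a tissue domain
#'
#' Operator-split explicit integration: Rush-Larsen reaction steps at `dt`
#' and an explicit diffusion step on the node graph every `n_sub` reaction
#' steps (automatically reduced when the diffusion step would violate the
#' explicit stability bound). Non-conducting nodes hold their initial
#' potential and take no part in diffusion or stimulation.
#'
#' @param sheet a [tissue_sheet()] (or strand geometry from the same
#'   constructor family).
#' @param duration episode length in seconds.
#' @param dt reaction time step in ms.
#' @param n_sub diffusion every `n_sub` reaction steps.
#' @param record_dt trace sampling interval in ms.
#' @param init initial state: `NULL` for rest, or a 21 x n_nodes matrix
#'   (e.g. from [initiate_spirals()] or a previous run's `final_state`).
#' @param stim optional stimulus: list with `nodes` (1-based), `start`,
#'   `dur`, `amp` (depolarizing, pA/pF), optional `period` (ms) and
#'   `count` for pacing trains.
#' @param act_threshold upstroke detection threshold in mV.
#' @param state_record_stride record the full state every this many frames
#'   (0 = off; used to harvest limit-cycle trajectories).
#' @param quiet_exit_ms stop integrating once every node has been below
#'   -60 mV and upstroke-free for this many ms (0 disables); the remaining
#'   trace is filled with the resting field. Deterministic runs cannot
#'   re-activate from quiescence, so this only skips dead time.
#' @return a `simulation_result`: voltage traces (nodes x frames),
#'   first/last activation times (ms, -1 if never), upstroke counts, final
#'   state, and the run metadata.
#' @export
run_monodomain <- function(sheet, duration = 2, dt = 0.02, n_sub = 5L,
                           record_dt = 1, init = NULL, stim = NULL,
                           act_threshold = -40, state_record_stride = 0L,
                           quiet_exit_ms = 0) {
  if (duration <= 0) abort("`duration` must be > 0 seconds")
  n <- sheet$n_nodes
  if (is.null(init)) {
    init <- equilibrated_sheet_state(sheet)
  }
  edges <- sheet$edges
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- matrix(0L, 0, 2); ew <- numeric(0)
  } else {
    ew <- sheet$edge_w
  }
  # explicit-diffusion stability: dt_dif * max node degree-weight < 1
  if (length(ew) > 0) {
    rs <- numeric(n)
    for (k in 1:2) {
      sums <- tapply(ew, edges[, k], sum)
      idx <- as.integer(names(sums))
      rs[idx] <- rs[idx] + as.numeric(sums)
    }
    lim <- 0.9 / max(rs)
    while (n_sub > 1 && dt * n_sub > lim) n_sub <- n_sub - 1L
    if (dt * n_sub > lim) {
      abort(sprintf(
        "diffusion step dt = %.3g ms exceeds the stability bound %.3g ms",
        dt * n_sub, lim
      ))
    }
  }
  if (is.null(stim)) {
    stim <- list(nodes = integer(0), start = 0, dur = 0, amp = 0)
  }
  res <- run_monodomain_cpp(
    init, sheet$scaling, sheet$conducting,
    edges - 1L, ew, dt, as.integer(n_sub), duration * 1000, record_dt,
    as.integer(stim$nodes) - 1L, stim$start, stim$dur,
    stim$period %||% 0, as.integer(stim$count %||% 1L), stim$amp,
    act_threshold, as.integer(state_record_stride), quiet_exit_ms
  )
  if (isTRUE(res$unstable)) {
    abort(sprintf(
      "monodomain integration unstable at step %d (t = %.2f ms, node %d)",
      res$bad_step, res$bad_step * dt, res$bad_node
    ))
  }
  structure(list(
    voltage = res$voltage, first_activation = res$first_activation,
    last_activation = res$last_activation, upstrokes = res$upstrokes,
    final_state = res$final_state,
    state_trace = res$state_trace, n_state_frames = res$n_state_frames,
    duration = duration, dt = dt, record_dt = record_dt,
    act_threshold = act_threshold, sheet_meta = sheet[c(
      "dims", "sheets", "conducting", "labels", "n_nodes", "spacing"
    )]
  ), class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "<simulation_result> %d nodes, %.2f s at %.0f ms sampling, %d frames\n",
    nrow(x$voltage), x$duration, x$record_dt, ncol(x$voltage)
  ))
  invisible(x)
}

the_rest_cache <- new.env(parent = emptyenv())

# steady state of one cell under a given conductance scaling: the published
# rest state belongs to the unmodified model, so each remodeling layer gets
# its own settled rest (cached)
equilibrated_rest <- function(scaling_row, seconds = 3, dt = 0.02) {
  key <- paste(signif(scaling_row, 8), collapse = "|")
  if (!is.null(the_rest_cache[[key]])) return(the_rest_cache[[key]])
  state <- matrix(courtemanche_rest_cpp(), 21, 1)
  res <- run_monodomain_cpp(
    state, matrix(scaling_row, 1, 5), TRUE,
    matrix(0L, 0, 2), numeric(0), dt, 1L, seconds * 1000, seconds * 1000,
    integer(0), 0, 0, 0, 0L, 0, -40, 0L, 0
  )
  the_rest_cache[[key]] <- res$final_state
  res$final_state
}

# per-node equilibrated rest for a whole sheet (one solve per distinct
# remodeling combination)
equilibrated_sheet_state <- function(sheet) {
  init <- matrix(0, 21, sheet$n_nodes)
  key <- apply(signif(sheet$scaling, 8), 1, paste, collapse = "|")
  for (k in unique(key)) {
    idx <- which(key == k)
    init[, idx] <- equilibrated_rest(sheet$scaling[idx[1], ])
  }
  init
}

strand_sheet <- function(n_nodes = 100, spacing = 0.25, sigma = 0.4,
                         chi = 1.6, af_remodeling = TRUE) {
  d_node <- rep(sigma / chi / spacing^2, n_nodes)
  edges <- if (n_nodes > 1) {
    cbind(seq_len(n_nodes - 1), seq_len(n_nodes - 1) + 1)
  } else {
    matrix(0L, 0, 2)
  }
  structure(list(
    n_nodes = n_nodes, dims = c(n_nodes, 1L), sheets = "strand",
    iir = rep(0, n_nodes), sigma = rep(sigma, n_nodes),
    conducting = rep(TRUE, n_nodes),
    labels = rep("strand", n_nodes),
    scaling = scaling_matrix(rep(0, n_nodes), af_remodeling),
    edges = edges, edge_w = (d_node[edges[, 1]] + d_node[edges[, 2]]) / 2,
    spacing = spacing, chi = chi, af_remodeling = af_remodeling
  ), class = "tissue_sheet")
}

#' Planar conduction velocity on a calibrated 1D strand
#'
#' Paces one end of a homogeneous strand and reads conduction velocity from
#' the activation-time difference between two interior probes well away
#' from the boundaries. Fibrotic electrophysiological remodeling is
#' disabled: the published conductivity/CV pairs are structural-remodeling
#' calibrations (a 40 percent g_Na reduction would depress CV far below
#' them).
#'
#' @param sigma tissue conductivity in S/m.
#' @param chi calibration product (see [calibrate_chi()]).
#' @param n_nodes,spacing strand geometry (default 100 nodes at 0.25 mm).
#' @param dt reaction time step (ms); the strand uses diffusion every step.
#' @param duration strand run length in seconds.
#' @return conduction velocity in m/s.
#' @export
measure_cv <- function(sigma, chi = NULL, n_nodes = 100, spacing = 0.25,
                       dt = 0.02, duration = 0.12) {
  if (is.null(chi)) chi <- default_chi()
  sheet <- strand_sheet(n_nodes, spacing, sigma, chi)
  res <- run_monodomain(sheet,
    duration = duration, dt = dt, n_sub = 1L,
    stim = list(nodes = 1:5, start = 1, dur = 2, amp = 40)
  )
  p1 <- round(n_nodes * 0.3); p2 <- round(n_nodes * 0.7)
  t1 <- res$first_activation[p1]; t2 <- res$first_activation[p2]
  if (t1 < 0 || t2 < 0 || t2 <= t1) {
    abort("conduction block: planar wave failed to reach the probes")
  }
  (p2 - p1) * spacing / (t2 - t1) # mm/ms = m/s
}

the_chi_cache <- new.env(parent = emptyenv())

#' Calibrate the monodomain scaling product
#'
#' The monodomain diffusivity is sigma / chi, with chi the product of the
#' surface-to-volume ratio and membrane capacitance. chi is not printed in
#' the calibration sources, so it is fitted once so that planar CV at
#' 0.40 S/m equals the anchor 0.81 m/s; CV scales as sqrt(1/chi), which the
#' fixed-point iteration exploits.
#'
#' @param target_cv anchor CV in m/s (default 0.81).
#' @param sigma anchor conductivity in S/m (default 0.40).
#' @param chi0 starting value.
#' @param iters fixed-point iterations.
#' @param ... passed to [measure_cv()].
#' @return calibrated chi.
#' @export
calibrate_chi <- function(target_cv = 0.81, sigma = 0.4, chi0 = 1.6,
                          iters = 4, ...) {
  chi <- chi0
  for (i in seq_len(iters)) {
    cv <- measure_cv(sigma, chi = chi, ...)
    chi <- chi * (cv / target_cv)^2
  }
  chi
}

#' @rdname calibrate_chi
#' @details `default_chi()` returns the cached calibration for the default
#'   strand protocol, computing it on first use.
#' @export
default_chi <- function() {
  if (is.null(the_chi_cache$chi)) {
    the_chi_cache$chi <- calibrate_chi()
  }
  the_chi_cache$chi
}

#' Archimedean spiral-wave initial condition
#'
#' Assigns every conducting node a phase
#' \eqn{\phi(x, y) = \mathrm{atan2}(y - y_c, x - x_c) - k r} relative to its
#' nearest spiral core, then maps phase onto a precomputed single-cell
#' limit-cycle trajectory (one paced AF-remodeled action-potential cycle),
#' producing `n_spirals` rotor cores distributed over the sheets (two per
#' sheet for the default four). Core locations are seeded-random within the
#' sheet interior unless given explicitly.
#'
#' @param sheet a [tissue_sheet()].
#' @param n_spirals total number of spiral cores (default 4).
#' @param seed integer seed for core placement.
#' @param k spiral wavenumber in radians per pixel (default `2*pi/40`).
#' @param cycle_ms pacing cycle length used for the trajectory.
#' @param cores optional list of explicit cores: each a list with `sheet`
#'   ("la"/"ra") and `xy` in node coordinates.
#' @return list with `state` (21 x n_nodes), `cores`, and per-sheet phase
#'   matrices `phase`.
#' @export
initiate_spirals <- function(sheet, n_spirals = 4, seed = 1,
                             k = 2 * pi / 40, cycle_ms = 250,
                             cores = NULL) {
  if (is.null(cores)) {
    if (n_spirals < 1) abort("`n_spirals` must be >= 1")
    n_sheets <- length(sheet$sheets)
    per <- rep(n_spirals %/% n_sheets, n_sheets)
    if (n_spirals %% n_sheets > 0) {
      per[seq_len(n_spirals %% n_sheets)] <- per[seq_len(n_spirals %% n_sheets)] + 1
    }
    cores <- with_seed(mix_seed(seed, "cores"), {
      out <- list()
      for (si in seq_along(sheet$sheets)) {
        for (j in seq_len(per[si])) {
          out[[length(out) + 1]] <- list(
            sheet = sheet$sheets[si],
            xy = c(
              runif(1, 0.25, 0.75) * sheet$dims[2],
              runif(1, 0.25, 0.75) * sheet$dims[1]
            )
          )
        }
      }
      out
    })
  }
  for (co in cores) {
    if (co$xy[1] < 1 || co$xy[1] > sheet$dims[2] ||
      co$xy[2] < 1 || co$xy[2] > sheet$dims[1]) {
      abort("spiral core outside the grid")
    }
  }
  traj <- limit_cycle_trajectory(cycle_ms = cycle_ms)
  n_fr <- ncol(traj)
  rest <- courtemanche_rest_cpp()
  n_per <- prod(sheet$dims)
  state <- matrix(rest, 21, sheet$n_nodes)
  phases <- list()
  for (si in seq_along(sheet$sheets)) {
    nm <- sheet$sheets[si]
    sheet_cores <- Filter(function(co) co$sheet == nm, cores)
    ph <- matrix(NA_real_, sheet$dims[1], sheet$dims[2])
    if (length(sheet_cores) > 0) {
      xx <- col(ph); yy <- row(ph)
      # superpose vortices of alternating chirality (continuous everywhere
      # except at the cores, so no spurious singularities at seams) and add
      # the Archimedean radial term for the distance to the nearest core
      ph[] <- 0
      best_d <- matrix(Inf, sheet$dims[1], sheet$dims[2])
      for (ci in seq_along(sheet_cores)) {
        co <- sheet_cores[[ci]]
        d <- sqrt((xx - co$xy[1])^2 + (yy - co$xy[2])^2)
        chir <- if (ci %% 2 == 1) 1 else -1
        ph <- ph + chir * atan2(yy - co$xy[2], xx - co$xy[1])
        best_d <- pmin(best_d, d)
      }
      ph <- ph - k * best_d
      frac <- (ph / (2 * pi)) %% 1
      idx <- 1L + as.integer(floor(frac * (n_fr - 1L)))
      off <- (si - 1L) * n_per
      state[, off + seq_len(n_per)] <- traj[, as.vector(idx)]
    }
    phases[[nm]] <- ph
  }
  ncond <- !sheet$conducting
  if (any(ncond)) state[, ncond] <- rest
  list(state = state, cores = cores, phase = phases)
}

the_traj_cache <- new.env(parent = emptyenv())

# one paced AF-remodeled action-potential cycle, full state at 1 ms
limit_cycle_trajectory <- function(cycle_ms = 250, n_beats = 3, dt = 0.02) {
  key <- sprintf("%g-%d-%g", cycle_ms, n_beats, dt)
  if (!is.null(the_traj_cache[[key]])) return(the_traj_cache[[key]])
  sheet <- structure(list(
    n_nodes = 1L, dims = c(1L, 1L), sheets = "cell",
    iir = 0, sigma = 0.4, conducting = TRUE, labels = "cell",
    scaling = scaling_matrix(0, TRUE), edges = NULL, edge_w = NULL,
    spacing = 1, chi = 1, af_remodeling = TRUE
  ), class = "tissue_sheet")
  dur_ms <- 5 + n_beats * cycle_ms
  res <- run_monodomain(sheet,
    duration = dur_ms / 1000, dt = dt, n_sub = 1L,
    record_dt = 1, state_record_stride = 1L,
    stim = list(
      nodes = 1, start = 5, dur = 2, amp = 40,
      period = cycle_ms, count = n_beats
    )
  )
  t_last <- 5 + (n_beats - 1) * cycle_ms
  frames <- (t_last + 1):(t_last + cycle_ms)
  st <- res$state_trace[, frames + 1, drop = FALSE] # frame 1 is t = 0
  the_traj_cache[[key]] <- st
  st
}

#' Sustained-AF test
#'
#' An episode counts as sustained when the latest suprathreshold upstroke
#' anywhere in the tissue occurs at or after `fraction` of the episode
#' duration (default 60 percent).
#'
#' @param result a `simulation_result`.
#' @param fraction sustainability fraction (default 0.6).
#' @return logical.
#' @export
is_sustained <- function(result, fraction = 0.6) {
  if (is.null(result$duration) || result$duration <= 0) {
    abort("zero-duration simulation result")
  }
  last <- max(result$last_activation)
  last >= 0 && last >= fraction * result$duration * 1000
}
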