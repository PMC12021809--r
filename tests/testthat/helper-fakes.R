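# Hand-built simulation_result objects for feature-extraction tests.
fake_result <- function(voltage, dims, sheets = "la", record_dt = 1,
                        conducting = NULL, upstrokes = NULL) {
  n <- nrow(voltage)
  structure(list(
    voltage = voltage,
    upstrokes = upstrokes %||% apply(
      voltage, 1,
      function(v) sum(v[-1] >= -40 & v[-length(v)] < -40)
    ),
    last_activation = rep(-1, n),
    duration = ncol(voltage) * record_dt / 1000,
    dt = 0.02, record_dt = record_dt, act_threshold = -40,
    sheet_meta = list(
      dims = dims, sheets = sheets,
      conducting = conducting %||% rep(TRUE, n),
      labels = rep(sheets, each = prod(dims)),
      n_nodes = n, spacing = 1
    )
  ), class = "simulation_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Synthetic, separable classifier cohort: the labels are a deterministic
# function of a mask-channel statistic that is then amplified in the input.
synth_case <- function(i, d = 32) {
  la <- array(runif(d * d * 5), c(d, d, 5))
  ra <- array(runif(d * d * 5), c(d, d, 5))
  flag_la <- mean(la[, , 2]) > 0.5
  flag_ra <- mean(ra[, , 2]) > 0.5
  # boolean functions of two bimodal per-atrium statistics, mirroring the
  # strategy structure: LA-only, either, RA-only, both
  labels <- as.numeric(c(
    flag_la, flag_la | flag_ra, flag_ra, flag_la && flag_ra
  ))
  la[, , 2] <- la[, , 2] * (1 + 3 * flag_la)
  ra[, , 2] <- ra[, , 2] * (1 + 3 * flag_ra)
  list(
    features = structure(list(la = la, ra = ra, channels = letters[1:5]),
      class = "feature_stack"
    ),
    labels = labels
  )
}
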