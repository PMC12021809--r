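# Plain-R right-hand side of the Courtemanche-Ramirez-Nattel atrial myocyte
# model, in deSolve layout. This is the reference implementation the
# compiled solver is validated against in the test suite: same equations,
# independent integration path (adaptive LSODA vs fixed-step Rush-Larsen).

#' Courtemanche model derivatives (reference implementation)
#'
#' Right-hand side of the 21-variable human atrial myocyte model for use
#' with an adaptive ODE integrator. Conductance scalings follow
#' [ionic_scaling_for()] semantics.
#'
#' @param t time (ms).
#' @param state named state vector (see [courtemanche_rest()]).
#' @param parms list with `scaling` (named: g_na, g_k1, g_to, g_kur, g_cal)
#'   and `stim(t)` returning the stimulus in pA/pF.
#' @return list with the derivative vector (deSolve convention).
#' @export
courtemanche_derivs <- function(t, state, parms) {
  s <- as.list(state)
  sc <- parms$scaling
  stim <- if (is.null(parms$stim)) 0 else parms$stim(t)
  R <- 8.3143; Temp <- 310; F <- 96.4867; Cm <- 100
  Vi <- 13668; Vup <- 1109.52; Vrel <- 96.48
  Ko <- 5.4; Nao <- 140; Cao <- 1.8
  V <- s$V
  rtf <- R * Temp / F
  ena <- rtf * log(Nao / s$nai)
  ek <- rtf * log(Ko / s$ki)
  eca <- rtf / 2 * log(Cao / s$cai)

  ina <- 7.8 * sc[["g_na"]] * s$m^3 * s$h * s$j * (V - ena)
  ik1 <- 0.09 * sc[["g_k1"]] * (V - ek) / (1 + exp(0.07 * (V + 80)))
  ito <- 0.1652 * sc[["g_to"]] * s$oa^3 * s$oi * (V - ek)
  gkur <- 0.005 + 0.05 / (1 + exp(-(V - 15) / 13))
  ikur <- sc[["g_kur"]] * gkur * s$ua^3 * s$ui * (V - ek)
  ikr <- 0.0294117647 * s$xr * (V - ek) / (1 + exp((V + 15) / 22.4))
  iks <- 0.12941176 * s$xs^2 * (V - ek)
  ical <- 0.12375 * sc[["g_cal"]] * s$d * s$f * s$fca * (V - 65)
  ipca <- 0.275 * s$cai / (0.0005 + s$cai)
  sig <- (exp(Nao / 67.3) - 1) / 7
  fnak <- 1 / (1 + 0.1245 * exp(-0.1 * F * V / (R * Temp)) +
    0.0365 * sig * exp(-F * V / (R * Temp)))
  inak <- 0.59933874 * fnak / (1 + (10 / s$nai)^1.5) * (Ko / (Ko + 1.5))
  fvrt <- F * V / (R * Temp)
  inaca <- 1600 * (exp(0.35 * fvrt) * s$nai^3 * Cao -
    exp(-0.65 * fvrt) * Nao^3 * s$cai) /
    ((87.5^3 + Nao^3) * (1.38 + Cao) * (1 + 0.1 * exp(-0.65 * fvrt)))
  ibna <- 0.0006744375 * (V - ena)
  ibca <- 0.001131 * (V - eca)

  gate <- function(y, inf, tau) (inf - y) / tau
  am <- if (abs(V + 47.13) < 1e-6) 3.2 else {
    0.32 * (V + 47.13) / (1 - exp(-0.1 * (V + 47.13)))
  }
  bm <- 0.08 * exp(-V / 11)
  if (V >= -40) {
    ah <- 0; bh <- 1 / (0.13 * (1 + exp(-(V + 10.66) / 11.1)))
    aj <- 0
    bj <- 0.3 * exp(-2.535e-7 * V) / (1 + exp(-0.1 * (V + 32)))
  } else {
    ah <- 0.135 * exp(-(V + 80) / 6.8)
    bh <- 3.56 * exp(0.079 * V) + 3.1e5 * exp(0.35 * V)
    aj <- (-1.2714e5 * exp(0.2444 * V) - 3.474e-5 * exp(-0.04391 * V)) *
      (V + 37.78) / (1 + exp(0.311 * (V + 79.23)))
    bj <- 0.1212 * exp(-0.01052 * V) / (1 + exp(-0.1378 * (V + 40.14)))
  }
  aoa <- 0.65 / (exp(-(V + 10) / 8.5) + exp(-(V - 30) / 59))
  boa <- 0.65 / (2.5 + exp((V + 82) / 17))
  aoi <- 1 / (18.53 + exp((V + 113.7) / 10.95))
  boi <- 1 / (35.56 + exp(-(V + 1.26) / 7.44))
  aua <- aoa; bua <- boa
  aui <- 1 / (21 + exp(-(V - 185) / 28))
  bui <- exp((V - 158) / 16)
  axr <- if (abs(V + 14.1) < 1e-6) 0.0015 else {
    0.0003 * (V + 14.1) / (1 - exp(-(V + 14.1) / 5))
  }
  bxr <- if (abs(V - 3.3328) < 1e-6) 3.7866e-4 else {
    7.3898e-5 * (V - 3.3328) / (exp((V - 3.3328) / 5.1237) - 1)
  }
  axs <- if (abs(V - 19.9) < 1e-6) 6.8e-4 else {
    4e-5 * (V - 19.9) / (1 - exp(-(V - 19.9) / 17))
  }
  bxs <- if (abs(V - 19.9) < 1e-6) 3.15e-4 else {
    3.5e-5 * (V - 19.9) / (exp((V - 19.9) / 9) - 1)
  }
  tau_d <- if (abs(V + 10) < 1e-6) 2.28937728938 else {
    (1 - exp(-(V + 10) / 6.24)) /
      (0.035 * (V + 10) * (1 + exp(-(V + 10) / 6.24)))
  }
  tau_f <- 9 / (0.0197 * exp(-0.0337^2 * (V + 10)^2) + 0.02)
  tau_w <- if (abs(V - 7.9) < 1e-6) 0.923076923 else {
    6 * (1 - exp(-(V - 7.9) / 5)) /
      ((1 + 0.3 * exp(-(V - 7.9) / 5)) * (V - 7.9))
  }

  irel <- 30 * s$u^2 * s$v * s$w * (s$carel - s$cai)
  itr <- (s$caup - s$carel) / 180
  iup <- 0.005 / (1 + 0.00092 / s$cai)
  iupleak <- 0.005 * s$caup / 15
  fn <- 1e-12 * Vrel * irel - (5e-13 / F) * (0.5 * ical * Cm - 0.2 * inaca * Cm)
  u_inf <- 1 / (1 + exp(-(fn - 3.4175e-13) / 13.67e-16))
  v_inf <- 1 - 1 / (1 + exp(-(fn - 6.835e-14) / 13.67e-16))
  tau_v <- 1.91 + 2.09 / (1 + exp(-(fn - 3.4175e-13) / 13.67e-16))

  b1 <- (2 * inaca - ipca - ical - ibca) * Cm / (2 * F * Vi) +
    (Vup * (iupleak - iup) + irel * Vrel) / Vi
  b2 <- 1 + 0.07 * 0.0005 / (s$cai + 0.0005)^2 +
    0.05 * 0.00238 / (s$cai + 0.00238)^2

  kq10 <- 3
  d_state <- c(
    V = -(ina + ik1 + ito + ikur + ikr + iks + ical + ipca + inak +
      inaca + ibna + ibca) + stim,
    m = gate(s$m, am / (am + bm), 1 / (am + bm)),
    h = gate(s$h, ah / (ah + bh), 1 / (ah + bh)),
    j = gate(s$j, aj / (aj + bj), 1 / (aj + bj)),
    oa = gate(s$oa, 1 / (1 + exp(-(V + 20.47) / 17.54)), 1 / ((aoa + boa) * kq10)),
    oi = gate(s$oi, 1 / (1 + exp((V + 43.1) / 5.3)), 1 / ((aoi + boi) * kq10)),
    ua = gate(s$ua, 1 / (1 + exp(-(V + 30.3) / 9.6)), 1 / ((aua + bua) * kq10)),
    ui = gate(s$ui, 1 / (1 + exp((V - 99.45) / 27.48)), 1 / ((aui + bui) * kq10)),
    xr = gate(s$xr, 1 / (1 + exp(-(V + 14.1) / 6.5)), 1 / (axr + bxr)),
    xs = gate(s$xs, 1 / sqrt(1 + exp(-(V - 19.9) / 12.7)), 0.5 / (axs + bxs)),
    d = gate(s$d, 1 / (1 + exp(-(V + 10) / 8)), tau_d),
    f = gate(s$f, 1 / (1 + exp((V + 28) / 6.9)), tau_f),
    fca = gate(s$fca, 1 / (1 + s$cai / 0.00035), 2),
    u = gate(s$u, u_inf, 8),
    v = gate(s$v, v_inf, tau_v),
    w = gate(s$w, 1 - 1 / (1 + exp(-(V - 40) / 17)), tau_w),
    nai = (-3 * inak - 3 * inaca - ibna - ina) * Cm / (F * Vi),
    ki = (2 * inak - ik1 - ito - ikur - ikr - iks) * Cm / (F * Vi),
    cai = b1 / b2,
    caup = iup - iupleak - itr * Vrel / Vup,
    carel = (itr - irel) / (1 + 10 * 0.8 / (s$carel + 0.8)^2)
  )
  list(d_state)
}
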