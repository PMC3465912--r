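#' Resting initial state of the whole-cell model
#'
#' Standard resting-state values of the human ventricular model (epicardial
#' variant): V = -86.2 mV, Cai = 7e-5 mM, Ca_SR = 1.3 mM, Nai = 7.67 mM,
#' Ki = 138.3 mM, gates at their resting values.
#'
#' The SR store can be set to a post-pacing level with `casr`: simulation
#' protocols start from the diastolic store of a myocyte paced to steady
#' state (control ~3.2 mM; failing ~15% lower, 2.7 mM) rather than the
#' never-paced reference rest (1.3 mM).
#'
#' @param p a [membrane_params()] object (unused fields reserved).
#' @param casr initial SR Ca2+ (mM); default the reference resting value.
#' @return named numeric vector of class state: `V, m, h, j, d, f, f2, fcass,
#'   r, s, xr1, xr2, xs, Nai, Ki, Cai, CaSS, CaSR`.
#' @export
cell_init <- function(p = membrane_params("control"), casr = 1.3) {
  c(V = -86.2, m = 0, h = 0.75, j = 0.75, d = 0, f = 1, f2 = 1, fcass = 1,
    r = 0, s = 1, xr1 = 0, xr2 = 1, xs = 0,
    Nai = 7.67, Ki = 138.3, Cai = 7e-5, CaSS = 7e-5, CaSR = casr)
}

#' Condition-specific post-pacing diastolic SR store
#'
#' The diastolic luminal Ca2+ of a myocyte paced to steady state: 3.2 mM for
#' control and 2.7 mM (~15% lower) in heart failure.  Used as the initial
#' store for all pacing/rest protocols.
#'
#' @param condition `"control"` or `"heart_failure"`.
#' @return initial SR Ca2+ (mM).
#' @export
paced_casr <- function(condition = c("control", "heart_failure")) {
  if (match_condition(condition) == "heart_failure") 2.7 else 3.2
}

#' Cellular release current from the subcellular flux total
#'
#' `J_rel = k_rel * J_sub_rel` (k_rel = 22.25): the constant multiplier that
#' converts the summed subcellular release flux (cytosolic mM/ms, see
#' [subrel_total()]) into the whole-cell model's SR release current.
#'
#' @param j_sub_rel whole-field release flux total (mM/ms), >= 0.
#' @param p a [release_params()] object.
#' @return release current J_rel (mM/ms) for [step_cell()].
#' @export
couple_release <- function(j_sub_rel, p) {
  stopifnot(inherits(p, "release_params"))
  if (any(j_sub_rel < 0)) stop("couple_release: J_sub_rel must be >= 0",
                               call. = FALSE)
  p$k_rel * j_sub_rel
}

#' All sarcolemmal currents at a given state
#'
#' @param state named state vector (see [cell_init()]).
#' @param p a [membrane_params()] object.
#' @return named vector of currents (pA/pF): `INa, ICaL, Ito, IKr, IKs, IK1,
#'   INaCa, INaK, IpCa, IpK, IbNa, IbCa`.
#' @export
cell_currents <- function(state, p) {
  V <- state[["V"]]; Nai <- state[["Nai"]]; Ki <- state[["Ki"]]
  Cai <- state[["Cai"]]; CaSS <- state[["CaSS"]]
  rtf <- p$Rgas * p$Temp / p$Faraday
  ENa <- rtf * log(p$Na_o / Nai)
  EK  <- rtf * log(p$K_o / Ki)
  EKs <- rtf * log((p$K_o + p$p_KNa * p$Na_o) / (Ki + p$p_KNa * Nai))
  ECa <- 0.5 * rtf * log(p$Ca_o / Cai)
  INa <- p$G_Na * state[["m"]]^3 * state[["h"]] * state[["j"]] * (V - ENa)
  z <- 2 * (V - 15) / rtf
  ez <- exp(z)
  drive <- if (abs(z) < 1e-7) {
    # L'Hopital limit of z/(e^z - 1) ~ 1 - z/2
    (0.25 * CaSS * ez - p$Ca_o) * (1 - z / 2)
  } else {
    (0.25 * CaSS * ez - p$Ca_o) * z / (ez - 1)
  }
  ICaL <- p$G_CaL * state[["d"]] * state[["f"]] * state[["f2"]] *
    state[["fcass"]] * 2 * p$Faraday * drive
  Ito <- p$G_to * state[["r"]] * state[["s"]] * (V - EK)
  IKr <- p$G_Kr * sqrt(p$K_o / 5.4) * state[["xr1"]] * state[["xr2"]] * (V - EK)
  IKs <- p$G_Ks * state[["xs"]]^2 * (V - EKs)
  ak1 <- 0.1 / (1 + exp(0.06 * (V - EK - 200)))
  bk1 <- (3 * exp(0.0002 * (V - EK + 100)) + exp(0.1 * (V - EK - 10))) /
    (1 + exp(-0.5 * (V - EK)))
  IK1 <- p$G_K1 * sqrt(p$K_o / 5.4) * ak1 / (ak1 + bk1) * (V - EK)
  efrac  <- exp(p$gamma * V / rtf)
  efrac1 <- exp((p$gamma - 1) * V / rtf)
  INaCa <- p$k_NaCa *
    (efrac * Nai^3 * p$Ca_o - efrac1 * p$Na_o^3 * Cai * p$alpha) /
    ((p$K_mNai^3 + p$Na_o^3) * (p$K_mCa + p$Ca_o) * (1 + p$k_sat * efrac1))
  INaK <- p$P_NaK * p$K_o * Nai /
    ((p$K_o + p$K_mK) * (Nai + p$K_mNa) *
       (1 + 0.1245 * exp(-0.1 * V / rtf) + 0.0353 * exp(-V / rtf)))
  IpCa <- p$G_pCa * Cai / (Cai + p$K_pCa)
  IpK  <- p$G_pK * (V - EK) / (1 + exp((25 - V) / 5.98))
  IbNa <- p$G_bNa * (V - ENa)
  IbCa <- p$G_bCa * (V - ECa)
  c(INa = INa, ICaL = ICaL, Ito = Ito, IKr = IKr, IKs = IKs, IK1 = IK1,
    INaCa = INaCa, INaK = INaK, IpCa = IpCa, IpK = IpK, IbNa = IbNa,
    IbCa = IbCa)
}

# steady-state values and time constants of the twelve gates at potential V
# (epicardial transient-outward kinetics); CaSS enters through fcass.
gate_rates <- function(V, CaSS) {
  minf <- 1 / (1 + exp((-56.86 - V) / 9.03))^2
  am <- 1 / (1 + exp((-60 - V) / 5))
  bm <- 0.1 / (1 + exp((V + 35) / 5)) + 0.1 / (1 + exp((V - 50) / 200))
  taum <- am * bm
  hinf <- 1 / (1 + exp((V + 71.55) / 7.43))^2
  if (V >= -40) {
    ah <- 0
    bh <- 0.77 / (0.13 * (1 + exp(-(V + 10.66) / 11.1)))
    aj <- 0
    bj <- 0.6 * exp(0.057 * V) / (1 + exp(-0.1 * (V + 32)))
  } else {
    ah <- 0.057 * exp(-(V + 80) / 6.8)
    bh <- 2.7 * exp(0.079 * V) + 3.1e5 * exp(0.3485 * V)
    aj <- (-2.5428e4 * exp(0.2444 * V) - 6.948e-6 * exp(-0.04391 * V)) *
      (V + 37.78) / (1 + exp(0.311 * (V + 79.23)))
    bj <- 0.02424 * exp(-0.01052 * V) / (1 + exp(-0.1378 * (V + 40.14)))
  }
  tauh <- 1 / (ah + bh)
  tauj <- 1 / (aj + bj)
  dinf <- 1 / (1 + exp((-8 - V) / 7.5))
  ad <- 1.4 / (1 + exp((-35 - V) / 13)) + 0.25
  bd <- 1.4 / (1 + exp((V + 5) / 5))
  gd <- 1 / (1 + exp((50 - V) / 20))
  taud <- ad * bd + gd
  finf <- 1 / (1 + exp((V + 20) / 7))
  tauf <- 1102.5 * exp(-((V + 27)^2) / 225) + 200 / (1 + exp((13 - V) / 10)) +
    180 / (1 + exp((V + 30) / 10)) + 20
  f2inf <- 0.67 / (1 + exp((V + 35) / 7)) + 0.33
  tauf2 <- 562 * exp(-((V + 27)^2) / 240) + 31 / (1 + exp((25 - V) / 10)) +
    80 / (1 + exp((V + 30) / 10))
  fcassinf <- 0.6 / (1 + (CaSS / 0.05)^2) + 0.4
  taufcass <- 80 / (1 + (CaSS / 0.05)^2) + 2
  rinf <- 1 / (1 + exp((20 - V) / 6))
  taur <- 9.5 * exp(-((V + 40)^2) / 1800) + 0.8
  sinf <- 1 / (1 + exp((V + 20) / 5))
  taus <- 85 * exp(-((V + 45)^2) / 320) + 5 / (1 + exp((V - 20) / 5)) + 3
  xr1inf <- 1 / (1 + exp((-26 - V) / 7))
  axr1 <- 450 / (1 + exp((-45 - V) / 10))
  bxr1 <- 6 / (1 + exp((V + 30) / 11.5))
  tauxr1 <- axr1 * bxr1
  xr2inf <- 1 / (1 + exp((V + 88) / 24))
  axr2 <- 3 / (1 + exp((-60 - V) / 20))
  bxr2 <- 1.12 / (1 + exp((V - 60) / 20))
  tauxr2 <- axr2 * bxr2
  xsinf <- 1 / (1 + exp((-5 - V) / 14))
  axs <- 1400 / sqrt(1 + exp((5 - V) / 6))
  bxs <- 1 / (1 + exp((V - 35) / 15))
  tauxs <- axs * bxs + 80
  list(
    inf = c(m = minf, h = hinf, j = hinf, d = dinf, f = finf, f2 = f2inf,
            fcass = fcassinf, r = rinf, s = sinf, xr1 = xr1inf, xr2 = xr2inf,
            xs = xsinf),
    tau = c(m = taum, h = tauh, j = tauj, d = taud, f = tauf, f2 = tauf2,
            fcass = taufcass, r = taur, s = taus, xr1 = tauxr1, xr2 = tauxr2,
            xs = tauxs)
  )
}

# analytic rapid-buffering update: new free concentration after adding d
# (total Ca change) to a pool with buffer Btot, dissociation constant K
buffer_root <- function(cfree, Btot, K, d) {
  bound <- Btot * cfree / (cfree + K)
  b <- Btot - bound - d - cfree + K
  cc <- K * (bound + d + cfree)
  (sqrt(b * b + 4 * cc) - b) / 2
}

#' Advance the whole-cell model by one time step
#'
#' Forward-Euler update of membrane potential and ionic concentrations with
#' Rush-Larsen integration of the twelve gating variables.  The reference
#' model's intrinsic SR release gating is removed: the release current is the
#' externally supplied `J_rel` (from [couple_release()]), entering the SR
#' balance directly and the dyadic subspace scaled by `V_sr/V_ss`, as in the
#' reference formulation.
#'
#' @param state named state vector (see [cell_init()]).
#' @param j_rel coupled SR release current (mM/ms), >= 0.
#' @param i_stim stimulus current (pA/pF); negative values depolarise.
#' @param p a [membrane_params()] object.
#' @param dt time step (ms).
#' @return the updated state vector, with attribute `"currents"` (the currents
#'   used for the step).
#' @export
step_cell <- function(state, j_rel = 0, i_stim = 0, p, dt) {
  stopifnot(dt > 0, j_rel >= 0)
  cur <- cell_currents(state, p)
  V <- state[["V"]]
  itot <- sum(cur) + i_stim
  g <- gate_rates(V, state[["CaSS"]])
  gn <- names(g$inf)
  state[gn] <- g$inf + (state[gn] - g$inf) * exp(-dt / g$tau)
  cm_vc_f  <- p$Cm / (p$V_c * p$Faraday)
  cm_2vcf  <- p$Cm / (2 * p$V_c * p$Faraday)
  cm_2vssf <- p$Cm / (2 * p$V_ss * p$Faraday)
  Ileak <- p$V_leak * (state[["CaSR"]] - state[["Cai"]])
  Iup <- p$V_max_pump / (1 + (p$K_up / state[["Cai"]])^2)
  Ixfer <- p$V_xfer * (state[["CaSS"]] - state[["Cai"]])
  d_casr <- dt * (Iup - j_rel - Ileak)
  state[["CaSR"]] <- buffer_root(state[["CaSR"]], p$Buf_sr, p$K_buf_sr, d_casr)
  d_cass <- dt * (-Ixfer * p$V_c / p$V_ss + j_rel * p$V_sr / p$V_ss -
                    cur[["ICaL"]] * cm_2vssf)
  state[["CaSS"]] <- buffer_root(state[["CaSS"]], p$Buf_ss, p$K_buf_ss, d_cass)
  d_cai <- dt * (-(cur[["IbCa"]] + cur[["IpCa"]] - 2 * cur[["INaCa"]]) * cm_2vcf -
                   (Iup - Ileak) * p$V_sr / p$V_c + Ixfer)
  state[["Cai"]] <- buffer_root(state[["Cai"]], p$Buf_c, p$K_buf_c, d_cai)
  state[["Nai"]] <- state[["Nai"]] - dt *
    (cur[["INa"]] + cur[["IbNa"]] + 3 * cur[["INaK"]] + 3 * cur[["INaCa"]]) * cm_vc_f
  state[["Ki"]] <- state[["Ki"]] - dt *
    (i_stim + cur[["IK1"]] + cur[["Ito"]] + cur[["IKr"]] + cur[["IKs"]] -
       2 * cur[["INaK"]] + cur[["IpK"]]) * cm_vc_f
  state[["V"]] <- V - dt * itot
  if (!all(is.finite(state)) || state[["V"]] < -120 || state[["V"]] > 80)
    stop(sprintf("step_cell: numerical failure (V = %.2f mV)", state[["V"]]),
         call. = FALSE)
  attr(state, "currents") <- cur
  state
}
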