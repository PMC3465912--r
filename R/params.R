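#' Parameters of the stochastic SR release system
#'
#' Constants governing Ca2+ release through RyR clusters and rogue (solitary)
#' RyR channels, and their luminal/cytosolic Ca2+ gating.  Release fluxes are
#' carried in pmol/ms; `V_cluster` is a conductance in pmol/(ms*mM) so that a
#' cluster facing a 2.5 mM SR-cytosol gradient releases ~5e-8 pmol/ms
#' (a ~10 pA spark current), while a rogue channel releases the fixed
#' `J_rogue_amp` (~0.64 pA, quark scale).
#'
#' The firing probability of a channel of kind j is
#' \deqn{P_j = \frac{P_{max}}{1 + (K_{mj}/Ca_{local})^{n_j}} \, k_{CaSR}, \quad
#'       k_{CaSR} = \frac{k_{max}}{1 + (D_{SR}/Ca_{SR})^{n_{SR}}}}
#' Heart failure sensitises both gates: `K_m` drops from 15 to 7.5 uM and
#' `D_SR` from 3.25 to 2.5 mM.
#'
#' @param condition `"control"` or `"heart_failure"`.
#' @param ... named overrides of individual fields.
#' @return an object of class `release_params` (named list).
#' @export
release_params <- function(condition = c("control", "heart_failure"), ...) {
  condition <- match_condition(condition)
  hf <- condition == "heart_failure"
  p <- list(
    V_cluster   = 1.97e-8,           # pmol/(ms*mM), max cluster conductance
    J_rogue_amp = 3.3166e-9,         # pmol/ms, fixed rogue channel flux
    P_max       = 0.3,               # /ms, maximal firing probability
    K_m_cluster = if (hf) 0.0075 else 0.015,  # mM, cytosolic sensitivity
    K_m_rogue   = if (hf) 0.0075 else 0.015,  # mM, = K_m_cluster by default
    n_cluster   = 1.6,               # Hill coefficient, clustered gating
    n_rogue     = 1.0,               # Hill coefficient, solitary gating
    k_max       = 2.0,               # max luminal amplification factor
    D_SR        = if (hf) 2.5 else 3.25,      # mM, luminal sensitivity
    n_SR        = 4.5,               # luminal Hill coefficient
    k_rel       = 22.25,             # cellular coupling multiplier
    t_open_cluster = 10,             # ms, fixed cluster open time
    t_open_rogue   = 5,              # ms, fixed rogue open time
    t_refractory   = 400,            # ms, refractory period (spark
                                     # restitution timescale; ~1 firing/beat)
    r_source    = 0.25,              # um, physical cluster release footprint
    gamma_dyad  = 0.005              # mM per pA/pF, dyadic Ca seen by clusters
                                     # per unit inward L-type current
  )
  p <- apply_overrides(p, list(...), "release_params")
  p$condition <- condition
  class(p) <- "release_params"
  validate_release_params(p)
  p
}

validate_release_params <- function(p) {
  num <- p[setdiff(names(p), "condition")]
  bad <- names(num)[!vapply(num, function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x > 0, TRUE)]
  # gamma_dyad may legitimately be zero (uncoupled field)
  bad <- setdiff(bad, if (identical(p$gamma_dyad, 0)) "gamma_dyad" else character())
  if (length(bad))
    stop("release_params: fields must be positive finite scalars: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (p$n_rogue >= p$n_cluster)
    stop("release_params: n_rogue must be < n_cluster (solitary channels gate less cooperatively)",
         call. = FALSE)
  invisible(p)
}

#' Parameters of the whole-cell ventricular membrane model
#'
#' The complete constant set of the human ventricular action-potential model
#' (epicardial variant) used at the cellular level, with the heart-failure
#' remodelling applied to eight entries: SERCA `V_max_pump` (-45%), `G_Ks`
#' (-50%), `G_K1` (-20%), `G_to` (to 64%), `G_Na` (8.902 nS/pF), `P_NaK`
#' (-42%), `G_bCa` (up with NCX), and `k_NaCa` (+65%).
#'
#' Units follow the reference model: potentials mV, time ms, concentrations mM,
#' currents pA/pF, conductances nS/pF.
#'
#' @inheritParams release_params
#' @return an object of class `membrane_params`.
#' @export
membrane_params <- function(condition = c("control", "heart_failure"), ...) {
  condition <- match_condition(condition)
  hf <- condition == "heart_failure"
  p <- list(
    Rgas = 8314.472, Temp = 310.0, Faraday = 96485.3415,
    Cm   = 0.185,                    # uF (cell capacitance, code convention)
    V_c  = 0.016404, V_sr = 0.001094, V_ss = 0.00005468,  # nL
    K_o  = 5.4, Na_o = 140.0, Ca_o = 2.0,                 # mM
    G_Na = if (hf) 8.902 else 14.838,
    G_K1 = if (hf) 4.324 else 5.405,
    G_to = if (hf) 0.185 else 0.294,
    G_Kr = 0.153,
    G_Ks = if (hf) 0.196 else 0.392,
    G_CaL = 3.98e-5,
    G_bNa = 0.00029,
    G_bCa = if (hf) 0.0009045 else 0.000592,
    G_pCa = 0.1238, K_pCa = 0.0005,
    G_pK  = 0.0146,
    P_NaK = if (hf) 1.57 else 2.724,
    K_mK = 1.0, K_mNa = 40.0,
    k_NaCa = if (hf) 1650 else 1000,
    K_mNai = 87.5, K_mCa = 1.38, k_sat = 0.1, gamma = 0.35, alpha = 2.5,
    p_KNa = 0.03,
    V_max_pump = if (hf) 0.0035 else 0.006375,  # mM/ms, SERCA
    K_up = 0.00025,
    V_leak = 0.00018,        # SR background leak, calibrated so paced-state
                             # stores match the stated control/failing levels
    V_xfer = 0.0038,
    Buf_c = 0.2, K_buf_c = 0.001,
    Buf_sr = 10.0, K_buf_sr = 0.3,
    Buf_ss = 0.4, K_buf_ss = 0.00025
  )
  p <- apply_overrides(p, list(...), "membrane_params")
  p$condition <- condition
  class(p) <- "membrane_params"
  validate_membrane_params(p)
  p
}

validate_membrane_params <- function(p) {
  num <- p[setdiff(names(p), "condition")]
  bad <- names(num)[!vapply(num, function(x) is.numeric(x) && length(x) == 1 && is.finite(x), TRUE)]
  if (length(bad))
    stop("membrane_params: non-numeric fields: ", paste(bad, collapse = ", "),
         call. = FALSE)
  nonneg <- c("G_Na", "G_K1", "G_to", "G_Kr", "G_Ks", "G_CaL", "G_bNa",
              "G_bCa", "G_pCa", "G_pK", "P_NaK", "k_NaCa", "V_max_pump",
              "V_leak", "V_xfer")
  bad <- nonneg[vapply(nonneg, function(f) p[[f]] < 0, TRUE)]
  if (length(bad))
    stop("membrane_params: conductances/pump rates must be >= 0: ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(p)
}

#' Geometry and numerics of the subcellular Ca2+ field
#'
#' Discretisation of the 2D longitudinal sheet (default 100 um x 20 um,
#' mesh 0.1 um, time step 0.01 ms), RyR cluster lattice spacings, diffusion
#' coefficients, indicator-dye and endogenous-buffer kinetics, and the field
#' SERCA pump / background leak.  Transport and buffering constants are named
#' defaults of the reference spark/wave reaction-diffusion formulation and can
#' all be overridden.
#'
#' The explicit scheme requires `dt * (D_x + D_y) / h^2 <= 0.5`; construction
#' fails otherwise.
#'
#' @param ... named overrides of individual fields.
#' @return an object of class `grid_params`.
#' @export
grid_params <- function(...) {
  p <- list(
    Lx = 100, Ly = 20,       # um, sheet size (longitudinal x, Z-line y)
    h  = 0.1,                # um, mesh spacing
    dt = 0.01,               # ms, time step
    l_x = 2.0, l_y = 1.0,    # um, cluster lattice spacings
    depth = 2.0,             # um, effective slab thickness of the 2D section;
                             # matches 3D point-source Ca at ~2 um distance
    D_x = 0.30, D_y = 0.15,  # um^2/ms, free Ca2+ diffusion
    D_dye = 0.02,            # um^2/ms, dye diffusion (free and bound)
    dye_total = 0.05,        # mM
    dye_kon = 80,            # /mM/ms
    dye_koff = 0.09,         # /ms  (Kd = 1.125 uM)
    buf_total = 0.123,       # mM, stationary endogenous buffer
    buf_kon = 100,           # /mM/ms
    buf_koff = 0.1,          # /ms  (Kd = 1 uM)
    pump_vmax = 2.08e-4,     # mM/ms, field SERCA
    pump_km = 1.84e-4,       # mM
    pump_hill = 4,           # integer Hill coefficient
    leak = NA_real_          # mM/ms; NA = balance pump at resting Ca
  )
  p <- apply_overrides(p, list(...), "grid_params")
  class(p) <- "grid_params"
  validate_grid_params(p)
  p
}

validate_grid_params <- function(p) {
  pos <- c("Lx", "Ly", "h", "dt", "l_x", "l_y", "depth", "dye_kon", "dye_koff",
           "buf_kon", "buf_koff", "pump_km")
  bad <- pos[vapply(pos, function(f) !(is.numeric(p[[f]]) && length(p[[f]]) == 1 &&
                                         is.finite(p[[f]]) && p[[f]] > 0), TRUE)]
  if (length(bad))
    stop("grid_params: fields must be positive: ", paste(bad, collapse = ", "),
         call. = FALSE)
  nonneg <- c("D_x", "D_y", "D_dye", "dye_total", "buf_total", "pump_vmax")
  bad <- nonneg[vapply(nonneg, function(f) p[[f]] < 0, TRUE)]
  if (length(bad))
    stop("grid_params: fields must be >= 0: ", paste(bad, collapse = ", "),
         call. = FALSE)
  cfl <- p$dt * (p$D_x + p$D_y) / p$h^2
  if (cfl > 0.5)
    stop(sprintf(
      "grid_params: explicit-scheme stability violated: dt*(D_x+D_y)/h^2 = %.3f > 0.5; reduce dt or coarsen h",
      cfl), call. = FALSE)
  cfl_dye <- p$dt * 2 * p$D_dye / p$h^2
  if (cfl_dye > 0.5)
    stop("grid_params: dye diffusion violates the stability bound; reduce dt",
         call. = FALSE)
  if (p$pump_hill != round(p$pump_hill) || p$pump_hill < 1)
    stop("grid_params: pump_hill must be a positive integer", call. = FALSE)
  invisible(p)
}

#' Build the full parameter bundle for one condition
#'
#' Pure function: returns the release, membrane and grid parameter sets for a
#' control or failing myocyte.  The failing bundle differs from control in
#' exactly ten entries (eight membrane constants plus the two release
#' sensitivities `K_m` and `D_SR`); the grid is condition-independent.
#'
#' @inheritParams release_params
#' @param release,membrane,grid named lists of field overrides applied on top
#'   of the condition defaults.
#' @return an object of class `ryr_params`: list with elements `release`,
#'   `membrane`, `grid`.
#' @examples
#' ctl <- make_params("control")
#' hf  <- make_params("heart_failure")
#' ctl$membrane$G_Na  # 14.838
#' hf$membrane$G_Na   # 8.902
#' @export
make_params <- function(condition = c("control", "heart_failure"),
                        release = list(), membrane = list(), grid = list()) {
  condition <- match_condition(condition)
  out <- list(
    release  = do.call(release_params, c(list(condition = condition), release)),
    membrane = do.call(membrane_params, c(list(condition = condition), membrane)),
    grid     = do.call(grid_params, grid),
    condition = condition
  )
  class(out) <- "ryr_params"
  out
}

match_condition <- function(condition) {
  if (!is.character(condition) || length(condition) < 1)
    stop("condition must be \"control\" or \"heart_failure\"", call. = FALSE)
  cond <- condition[1]
  if (!cond %in% c("control", "heart_failure"))
    stop(sprintf("unknown condition \"%s\" (expected \"control\" or \"heart_failure\")",
                 cond), call. = FALSE)
  cond
}

apply_overrides <- function(p, dots, what) {
  if (!length(dots)) return(p)
  if (is.null(names(dots)) || any(names(dots) == ""))
    stop(what, ": overrides must be named", call. = FALSE)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown))
    stop(what, ": unknown field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  p[names(dots)] <- dots
  p
}

#' @export
print.ryr_params <- function(x, ...) {
  cat("<ryr_params> condition:", x$condition, "\n")
  cat("  grid:", x$grid$Lx, "x", x$grid$Ly, "um, h =", x$grid$h,
      "um, dt =", x$grid$dt, "ms\n")
  cat("  release: K_m =", x$release$K_m_cluster * 1e3, "uM, D_SR =",
      x$release$D_SR, "mM, k_rel =", x$release$k_rel, "\n")
  cat("  membrane: G_Na =", x$membrane$G_Na, ", k_NaCa =", x$membrane$k_NaCa,
      ", V_max_pump =", x$membrane$V_max_pump, "\n")
  invisible(x)
}
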