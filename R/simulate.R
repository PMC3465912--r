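#' Run one pacing-then-rest protocol of the coupled model
#'
#' Executes a single Monte Carlo realisation: builds the parameter bundle and
#' RyR lattice for the scenario, then advances the coupled subcellular
#' field / whole-cell system with the compiled engine.  The protocol is
#' `pacing_n` stimuli at cycle length `pacing_cl` (first stimulus at t = 10
#' ms), followed by an unstimulated observation window of `rest_ms`.  With
#' `disable_ina_after_pacing`, G_Na is zeroed once the last stimulus ends, so
#' spontaneous depolarisations are observed without triggered upstrokes.
#'
#' @param cfg a [scenario_config()] object.
#' @param seed RNG seed for this repetition (defaults to `cfg$seed`); drives
#'   both rogue placement and channel gating.
#' @return an object of class `ryr_run`: list with `series` (data.frame of
#'   t_ms, Vm_mV, Cai_mM, CaSR_mM, CaSS_mM, INaCa_pApF, ICaL_pApF, Jrel_mMms,
#'   Ca_field_mM, n_open_clusters, n_open_rogues), `linescan` (nx x samples
#'   matrix of the central longitudinal row), `events` (see [detect_events()]),
#'   `manifest`, `final_state` and opening counts.
#' @export
run_protocol <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "scenario_config"))
  params <- make_params(cfg$condition, cfg$release, cfg$membrane, cfg$grid)
  grid <- params$grid
  lattice <- ryr_lattice(cfg$n_rogue, grid, params$release, seed)
  casr0 <- if (is.na(cfg$init_casr)) paced_casr(cfg$condition) else cfg$init_casr
  state0 <- cell_init(params$membrane, casr = casr0)
  ca0 <- state0[["Cai"]]

  t0 <- 10
  stim_start <- if (cfg$pacing_n > 0) t0 + (seq_len(cfg$pacing_n) - 1) * cfg$pacing_cl else numeric(0)
  rest_start <- if (cfg$pacing_n > 0) t0 + cfg$pacing_n * cfg$pacing_cl else 0
  t_end <- rest_start + cfg$rest_ms
  pacing_phys_end <- if (cfg$pacing_n > 0) stim_start[cfg$pacing_n] + cfg$pacing_dur else 0
  gna_zero_after <- if (cfg$disable_ina_after_pacing) pacing_phys_end else Inf

  eng <- engine_inputs(params, lattice, ca0)
  numerics <- list(
    dt = grid$dt,
    gating_every = max(1L, as.integer(round(cfg$gating_dt / grid$dt))),
    rec_every = max(1L, as.integer(round(cfg$record_dt / grid$dt))),
    linescan_row = as.integer(round((grid$Ly / 2) / grid$h)),
    stochastic = TRUE
  )
  protocol <- list(stim_start = stim_start, stim_dur = cfg$pacing_dur,
                   stim_amp = cfg$pacing_amp, t_end = t_end,
                   gna_zero_after = gna_zero_after)
  res <- .engine_run(eng$grid, eng$release, eng$membrane, eng$channels,
                     state0, protocol, numerics, as.double(seed))
  series <- as.data.frame(res$series)
  names(series) <- c("t_ms", "Vm_mV", "Cai_mM", "CaSR_mM", "CaSS_mM",
                     "INaCa_pApF", "ICaL_pApF", "Jrel_mMms", "Ca_field_mM",
                     "n_open_clusters", "n_open_rogues")
  manifest <- list(
    package = "rogueryr",
    version = as.character(utils::packageVersion("rogueryr")),
    condition = cfg$condition, n_rogue = cfg$n_rogue,
    pacing_n = cfg$pacing_n, pacing_cl = cfg$pacing_cl,
    pacing_dur = cfg$pacing_dur, pacing_amp = cfg$pacing_amp,
    rest_ms = cfg$rest_ms, record_dt = cfg$record_dt,
    gating_dt = cfg$gating_dt, seed = seed, init_casr = casr0,
    disable_ina_after_pacing = cfg$disable_ina_after_pacing,
    rest_start = rest_start, t_end = t_end,
    n_clusters = nrow(lattice$cluster_pos),
    n_rogues = nrow(lattice$rogue_pos),
    params = params
  )
  run <- list(series = series,
              linescan = res$linescan,
              linescan_x = (seq_len(nrow(res$linescan)) - 1) * grid$h,
              linescan_t = series$t_ms,
              linescan_y = numerics$linescan_row * grid$h,
              final_state = stats::setNames(as.numeric(res$final_state),
                                            names(state0)),
              ca_final = res$ca_final,
              n_cluster_openings = res$n_cluster_openings,
              n_rogue_openings = res$n_rogue_openings,
              manifest = manifest)
  class(run) <- "ryr_run"
  run$events <- detect_events(run)
  run
}

# Assemble the flat argument lists consumed by the compiled engine.
engine_inputs <- function(params, lattice, ca0,
                          force = NULL) {
  grid <- params$grid
  nx <- round(grid$Lx / grid$h) + 1L
  ny <- round(grid$Ly / grid$h) + 1L
  lin0 <- function(node) (node[, 2] - 1L) * nx + (node[, 1] - 1L)  # 0-based
  fp <- footprint_offsets(grid, params$release$r_source)
  ncl <- nrow(lattice$cluster_node)
  nfp <- nrow(fp)
  fp_idx <- integer(ncl * nfp)
  fp_w <- rep(fp$w, times = ncl)
  for (k in seq_len(ncl)) {
    ix <- pmin(nx, pmax(1L, lattice$cluster_node[k, 1] + fp$dx))
    iy <- pmin(ny, pmax(1L, lattice$cluster_node[k, 2] + fp$dy))
    fp_idx[((k - 1) * nfp + 1):(k * nfp)] <- (iy - 1L) * nx + (ix - 1L)
  }
  if (is.null(force))
    force <- list(kind = integer(0), idx = integer(0),
                  on = numeric(0), off = numeric(0))
  channels <- list(
    cluster_node = as.integer(lin0(lattice$cluster_node)),
    rogue_node = as.integer(if (nrow(lattice$rogue_node)) lin0(lattice$rogue_node) else integer(0)),
    fp_off = as.integer(seq(0L, ncl * nfp, by = nfp)),
    fp_idx = as.integer(fp_idx),
    fp_w = fp_w,
    force_kind = as.integer(force$kind),
    force_idx = as.integer(force$idx),
    force_on = as.numeric(force$on),
    force_off = as.numeric(force$off)
  )
  egrid <- unclass(grid)
  egrid$nx <- nx
  egrid$ny <- ny
  egrid$leak <- field_leak(grid, ca0)
  egrid$conv <- 1e6 / (grid$h^2 * grid$depth)
  egrid$ca0 <- ca0
  egrid$pump_hill <- as.integer(grid$pump_hill)
  list(grid = egrid,
       release = unclass(params$release),
       membrane = unclass(params$membrane),
       channels = channels)
}

#' @export
print.ryr_run <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<ryr_run> %s | N_rogue = %g | seed %s | %d beats @ %g ms | t_end %g ms\n",
              m$condition, m$n_rogue, format(m$seed), m$pacing_n, m$pacing_cl,
              m$t_end))
  if (!is.null(x$events)) {
    e <- x$events
    cat(sprintf("  delta_Vm = %.2f mV, delta_Ca = %.3g mM, T_peakVm = %s ms, triggered = %s\n",
                e$delta_Vm, e$delta_Ca, format(e$T_peakVm), e$triggered))
  }
  invisible(x)
}
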