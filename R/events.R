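#' Detect DAD / triggered-AP events in a simulated run
#'
#' Establishes the start of the quiescent stage (the last paced action
#' potential's return to within 2 mV of the diastolic potential, or t = 0 for
#' unpaced runs), a 100-ms pre-event baseline, and measures the spontaneous
#' depolarisation and Ca2+ transient relative to it:
#' `delta_Vm` / `delta_Ca` are the peak rises above baseline, `T_peakVm` /
#' `T_peakCa` the times from the end of the resting stage to the respective
#' peaks.  A run counts as *triggered* when the membrane potential crosses the
#' fast-Na activation threshold (-40 mV) with an upstroke velocity above
#' 10 mV/ms during the observation window.
#'
#' @param run an `ryr_run` object, or a data.frame with columns `t_ms`,
#'   `Vm_mV`, `Cai_mM` (then `rest_start` must be given).
#' @param rest_start nominal end of pacing (ms); taken from the run manifest
#'   by default.
#' @param baseline_ms length of the baseline window (ms).
#' @param ap_threshold triggered-AP potential threshold (mV).
#' @param upstroke_min minimal dV/dt for a triggered upstroke (mV/ms).
#' @param settle_mV return-to-rest tolerance for locating the end of the last
#'   paced beat (mV).
#' @return one-row data.frame: `delta_Ca` (mM), `delta_Vm` (mV), `T_peakCa`,
#'   `T_peakVm` (ms, `NA` when no peak exists), `triggered` (logical),
#'   `n_waves` (diagnostic count of distinct suprabaseline Vm excursions),
#'   `t_rest_start`, `baseline_Vm`, `baseline_Ca`.
#' @export
detect_events <- function(run, rest_start = NULL, baseline_ms = 100,
                          ap_threshold = -40, upstroke_min = 10,
                          settle_mV = 2) {
  if (inherits(run, "ryr_run")) {
    series <- run$series
    if (is.null(rest_start)) rest_start <- run$manifest$rest_start
  } else {
    series <- run
    if (is.null(rest_start))
      stop("detect_events: rest_start required for a bare series", call. = FALSE)
  }
  t <- series$t_ms; vm <- series$Vm_mV; ca <- series$Cai_mM
  if (max(t) - rest_start < 2 * baseline_ms)
    stop("detect_events: observation window too short to establish a baseline",
         call. = FALSE)

  # end of resting stage: last paced AP returned to within settle_mV of
  # diastole (diastole taken as the post-pacing minimum)
  post <- t >= rest_start
  v_dia <- min(vm[post])
  idx_settle <- which(post & vm <= v_dia + settle_mV)
  t0 <- if (length(idx_settle)) t[idx_settle[1]] else rest_start

  win <- t >= t0
  tw <- t[win]; vw <- vm[win]; cw <- ca[win]
  dvdt <- c(0, diff(vw) / diff(tw))

  # event onset: first sustained positive dV/dt above the noise floor after
  # the baseline window; baseline = mean over the 100 ms preceding onset
  floor_mVms <- 0.02
  onset_idx <- NA_integer_
  cand <- which(tw > t0 + baseline_ms & dvdt > floor_mVms)
  if (length(cand)) {
    # sustained: positive slope for at least 10 ms following the candidate
    for (i in cand) {
      ahead <- which(tw >= tw[i] & tw <= tw[i] + 10)
      if (length(ahead) && all(dvdt[ahead] > 0)) { onset_idx <- i; break }
    }
  }
  base_end <- if (!is.na(onset_idx)) tw[onset_idx] else t0 + baseline_ms
  base_win <- tw >= base_end - baseline_ms & tw <= base_end
  baseline_vm <- mean(vw[base_win])
  baseline_ca <- mean(cw[base_win])

  meas <- tw >= base_end
  delta_vm <- max(0, max(vw[meas]) - baseline_vm)
  delta_ca <- max(0, max(cw[meas]) - baseline_ca)
  t_peak_vm <- if (delta_vm > 0) tw[meas][which.max(vw[meas])] - t0 else NA_real_
  t_peak_ca <- if (delta_ca > 0) tw[meas][which.max(cw[meas])] - t0 else NA_real_

  triggered <- any(vw > ap_threshold & dvdt > upstroke_min)

  # diagnostic: distinct excursions of Vm more than 2 mV above baseline
  above <- vw > baseline_vm + 2
  n_waves <- sum(diff(c(FALSE, above)) == 1)

  data.frame(delta_Ca = delta_ca, delta_Vm = delta_vm,
             T_peakCa = t_peak_ca, T_peakVm = t_peak_vm,
             triggered = triggered, n_waves = n_waves,
             t_rest_start = t0, baseline_Vm = baseline_vm,
             baseline_Ca = baseline_ca)
}

#' Monte Carlo ensemble over rogue-RyR densities
#'
#' Repeats the protocol `reps` times for every density in `n_rogue_values`
#' (per-run seeds derived deterministically from the master seed), collects
#' the per-run event summaries, and computes per-group mean, SEM and n for
#' each metric, one-way ANOVA across groups, and the triggered-AP fraction
#' per group.  Failed repetitions are excluded with a warning; a group is
#' dropped when fewer than two repetitions survive.
#'
#' @param cfg a [scenario_config()] object (its `n_rogue` is overridden by the
#'   sweep values).
#' @param n_rogue_values numeric vector of rogue densities (/um^2).
#' @param reps repetitions per density (>= 2; default `cfg$n_reps`).
#' @return an object of class `ryr_ensemble`: list with `summaries` (per-run
#'   metrics), `stats` (group x metric mean/SEM/n), `anova` (metric, F, P),
#'   `triggered` (group, fraction, n), `seed`.
#' @export
ensemble <- function(cfg, n_rogue_values, reps = cfg$n_reps) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (length(n_rogue_values) < 1) stop("ensemble: empty density list", call. = FALSE)
  if (reps < 2) stop("ensemble: reps must be >= 2 for SEM", call. = FALSE)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(cfg$seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1, length(n_rogue_values) * reps),
                  nrow = reps)
  rows <- list()
  for (g in seq_along(n_rogue_values)) {
    for (r in seq_len(reps)) {
      cfg_g <- cfg
      cfg_g$n_rogue <- n_rogue_values[g]
      run <- tryCatch(run_protocol(cfg_g, seed = seeds[r, g]),
                      error = function(e) e)
      if (inherits(run, "error")) {
        warning(sprintf("ensemble: repetition %d at N_rogue = %g failed and was excluded: %s",
                        r, n_rogue_values[g], conditionMessage(run)))
        next
      }
      ev <- run$events
      ev$n_rogue <- n_rogue_values[g]
      ev$rep <- r
      ev$seed <- seeds[r, g]
      rows[[length(rows) + 1]] <- ev
    }
  }
  if (!length(rows)) stop("ensemble: all repetitions failed", call. = FALSE)
  summaries <- do.call(rbind, rows)
  out <- c(list(summaries = summaries), summarize_ensemble(summaries),
           list(seed = cfg$seed))
  class(out) <- "ryr_ensemble"
  out
}

#' Group statistics for a table of per-run event summaries
#'
#' Computes, for each rogue density: mean, SEM (= sample SD / sqrt(n)) and n
#' of every metric; one-way ANOVA (F, P) across densities; and the
#' triggered-AP fraction.  Groups with fewer than two rows are dropped with a
#' warning.
#'
#' @param summaries data.frame with columns `n_rogue`, `triggered` and the
#'   metric columns.
#' @param metrics metric column names to summarise.
#' @return list with `stats`, `anova` and `triggered` data.frames.
#' @export
summarize_ensemble <- function(summaries,
                               metrics = c("delta_Ca", "delta_Vm",
                                           "T_peakCa", "T_peakVm")) {
  keep <- vapply(split(seq_len(nrow(summaries)), summaries$n_rogue),
                 length, 0L) >= 2
  groups <- as.numeric(names(keep))[keep]
  if (any(!keep))
    warning("group(s) dropped with < 2 surviving repetitions: ",
            paste(names(keep)[!keep], collapse = ", "))
  kept <- summaries[summaries$n_rogue %in% groups, ]
  stats_rows <- list()
  for (m in metrics) {
    for (g in groups) {
      x <- kept[[m]][kept$n_rogue == g]
      x <- x[is.finite(x)]
      stats_rows[[length(stats_rows) + 1]] <- data.frame(
        n_rogue = g, metric = m, mean = mean(x),
        sem = stats::sd(x) / sqrt(length(x)), n = length(x))
    }
  }
  anova_rows <- lapply(metrics, function(m) {
    ok <- is.finite(kept[[m]])
    if (length(unique(kept$n_rogue[ok])) < 2)
      return(data.frame(metric = m, F = NA_real_, P = NA_real_))
    fit <- stats::aov(kept[[m]][ok] ~ factor(kept$n_rogue[ok]))
    s <- summary(fit)[[1]]
    data.frame(metric = m, F = s$`F value`[1], P = s$`Pr(>F)`[1])
  })
  trig <- do.call(rbind, lapply(groups, function(g) {
    x <- kept$triggered[kept$n_rogue == g]
    data.frame(n_rogue = g, fraction = mean(x), n = length(x))
  }))
  list(stats = do.call(rbind, stats_rows),
       anova = do.call(rbind, anova_rows),
       triggered = trig)
}

#' @export
print.ryr_ensemble <- function(x, ...) {
  cat("<ryr_ensemble> groups:", paste(unique(x$stats$n_rogue), collapse = ", "),
      "| master seed", x$seed, "\n")
  print(x$stats, row.names = FALSE)
  cat("triggered-AP fraction:\n")
  print(x$triggered, row.names = FALSE)
  invisible(x)
}

#' Linescan image of the subcellular Ca2+ field
#'
#' Position-vs-time matrix of cytosolic Ca2+ along the longitudinal (x)
#' direction.  Runs record the row at the domain mid-height; requesting any
#' other stored row raises an error, as does a row outside the domain.
#'
#' @param run an `ryr_run` object.
#' @param y transverse position of the requested row (um); default the
#'   recorded mid-height row.
#' @return matrix (x-nodes x time samples) with attributes `x` (um) and
#'   `t` (ms).
#' @export
linescan <- function(run, y = NULL) {
  stopifnot(inherits(run, "ryr_run"))
  Ly <- run$manifest$params$grid$Ly
  if (!is.null(y)) {
    if (y < 0 || y > Ly)
      stop(sprintf("linescan: row y = %g um outside the domain [0, %g]", y, Ly),
           call. = FALSE)
    if (abs(y - run$linescan_y) > run$manifest$params$grid$h / 2)
      stop(sprintf("linescan: only the mid-height row (y = %g um) was recorded",
                   run$linescan_y), call. = FALSE)
  }
  m <- run$linescan
  attr(m, "x") <- run$linescan_x
  attr(m, "t") <- run$linescan_t
  m
}
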