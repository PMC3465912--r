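#' Scenario configuration for a simulation run
#'
#' Bundles the experimental protocol: condition, rogue-RyR density, pacing
#' (cycle length, pulse duration and amplitude, number of beats), the
#' unstimulated observation window, Monte Carlo repetition count, RNG seed,
#' and the fast-Na-blockade flag used when measuring DAD amplitudes at high
#' rogue densities.
#'
#' @param condition `"control"` or `"heart_failure"`.
#' @param n_rogue rogue RyR density (channels/um^2), >= 0.
#' @param pacing_n number of paced beats before the rest window (>= 0).
#' @param pacing_cl pacing cycle length (ms); 1000 ms = 1 Hz.
#' @param pacing_dur stimulus pulse duration (ms).
#' @param pacing_amp stimulus amplitude (pA/pF, applied as inward current).
#' @param rest_ms unstimulated observation window after the last beat (ms).
#' @param n_reps Monte Carlo repetitions (>= 1).
#' @param seed RNG seed (integer), recorded in every output.
#' @param disable_ina_after_pacing if `TRUE`, G_Na is set to zero once the last
#'   stimulus has ended, so DADs are measured without triggered upstrokes.
#' @param init_casr initial SR Ca2+ store (mM); `NA` selects the
#'   condition-specific post-pacing value (see [paced_casr()]).
#' @param record_dt output sampling interval (ms).
#' @param gating_dt interval at which stochastic channel gating is evaluated
#'   (ms); must be a multiple of the field time step.
#' @param release,membrane,grid named lists of parameter overrides forwarded
#'   to [make_params()].
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(condition = c("control", "heart_failure"),
                            n_rogue = 0,
                            pacing_n = 3,
                            pacing_cl = 1000,
                            pacing_dur = 1,
                            pacing_amp = 52,
                            rest_ms = 1500,
                            n_reps = 10,
                            seed = 1L,
                            disable_ina_after_pacing = FALSE,
                            init_casr = NA_real_,
                            record_dt = 1,
                            gating_dt = 0.1,
                            release = list(), membrane = list(), grid = list()) {
  cfg <- list(
    condition = match_condition(condition),
    n_rogue = n_rogue, pacing_n = pacing_n, pacing_cl = pacing_cl,
    pacing_dur = pacing_dur, pacing_amp = pacing_amp, rest_ms = rest_ms,
    n_reps = n_reps, seed = as.integer(seed),
    disable_ina_after_pacing = isTRUE(disable_ina_after_pacing),
    init_casr = init_casr,
    record_dt = record_dt, gating_dt = gating_dt,
    release = release, membrane = membrane, grid = grid
  )
  class(cfg) <- "scenario_config"
  validate_scenario_config(cfg)
  cfg
}

validate_scenario_config <- function(cfg) {
  chk <- function(field, ok, msg) {
    if (!ok) stop("scenario_config: field `", field, "` ", msg, call. = FALSE)
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  chk("n_rogue", num1(cfg$n_rogue) && cfg$n_rogue >= 0, "must be >= 0")
  chk("pacing_n", num1(cfg$pacing_n) && cfg$pacing_n >= 0 &&
        cfg$pacing_n == round(cfg$pacing_n), "must be a non-negative integer")
  chk("pacing_cl", num1(cfg$pacing_cl) && cfg$pacing_cl > 0, "must be positive")
  chk("pacing_dur", num1(cfg$pacing_dur) && cfg$pacing_dur > 0, "must be positive")
  chk("pacing_amp", num1(cfg$pacing_amp) && cfg$pacing_amp > 0, "must be positive")
  chk("rest_ms", num1(cfg$rest_ms) && cfg$rest_ms >= 0, "must be >= 0")
  chk("n_reps", num1(cfg$n_reps) && cfg$n_reps >= 1 &&
        cfg$n_reps == round(cfg$n_reps), "must be an integer >= 1")
  chk("seed", is.integer(cfg$seed) && length(cfg$seed) == 1 && !is.na(cfg$seed),
      "must be an integer")
  chk("init_casr", (length(cfg$init_casr) == 1 && is.na(cfg$init_casr)) ||
        (num1(cfg$init_casr) && cfg$init_casr > 0),
      "must be positive or NA")
  chk("record_dt", num1(cfg$record_dt) && cfg$record_dt > 0, "must be positive")
  chk("gating_dt", num1(cfg$gating_dt) && cfg$gating_dt > 0, "must be positive")
  for (s in c("release", "membrane", "grid"))
    if (!is.list(cfg[[s]])) stop("scenario_config: `", s, "` must be a list",
                                 call. = FALSE)
  # constructing the bundle validates override names and parameter invariants
  invisible(make_params(cfg$condition, cfg$release, cfg$membrane, cfg$grid))
  invisible(cfg)
}

# Flat key = value configuration dialect with [section] headers.  Sections:
# [scenario] (fields of scenario_config) and [release]/[membrane]/[grid]
# (parameter overrides).  Unknown sections or keys are errors, protecting
# against silent typos.

scenario_fields <- c("condition", "n_rogue", "pacing_n", "pacing_cl",
                     "pacing_dur", "pacing_amp", "rest_ms", "n_reps", "seed",
                     "disable_ina_after_pacing", "init_casr", "record_dt",
                     "gating_dt")

#' Read a scenario configuration from a key-value file
#'
#' The file dialect is flat `key = value` pairs under `[section]` headers
#' (`[scenario]`, `[release]`, `[membrane]`, `[grid]`).  Omitted fields take
#' their defaults; unknown sections or keys raise an error naming the
#' offender.  A minimal file may contain only `condition` under `[scenario]`.
#'
#' @param path path to the configuration file.
#' @return a [scenario_config()] object.
#' @seealso [write_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  section <- NA_character_
  kv <- list(scenario = list(), release = list(), membrane = list(), grid = list())
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- sub("^\\[(.*)\\]$", "\\1", ln)
      if (!section %in% names(kv))
        stop("config: unknown section [", section, "]", call. = FALSE)
      next
    }
    if (is.na(section))
      stop("config: key outside of any [section]: ", ln, call. = FALSE)
    if (!grepl("=", ln, fixed = TRUE))
      stop("config: line is not `key = value`: ", ln, call. = FALSE)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    kv[[section]][[key]] <- val
  }
  sc <- kv$scenario
  unknown <- setdiff(names(sc), scenario_fields)
  if (length(unknown))
    stop("config: unknown [scenario] key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  parse_val <- function(key, val) {
    if (key == "condition") return(val)
    if (key == "disable_ina_after_pacing")
      return(tolower(val) %in% c("true", "yes", "1"))
    if (key == "init_casr" && tolower(val) %in% c("na", "auto"))
      return(NA_real_)
    x <- suppressWarnings(as.numeric(val))
    if (is.na(x)) stop("config: field `", key, "` is not numeric: ", val,
                       call. = FALSE)
    if (key == "seed") x <- as.integer(x)
    x
  }
  args <- lapply(stats::setNames(names(sc), names(sc)),
                 function(k) parse_val(k, sc[[k]]))
  for (s in c("release", "membrane", "grid")) {
    if (length(kv[[s]]))
      args[[s]] <- lapply(kv[[s]], function(v) parse_val("num", v))
  }
  cfg <- do.call(scenario_config, args)
  # constructing the parameter bundle validates override names and invariants
  invisible(make_params(cfg$condition, cfg$release, cfg$membrane, cfg$grid))
  defaults <- setdiff(scenario_fields, names(sc))
  if (length(defaults))
    message("config: defaults applied for: ", paste(defaults, collapse = ", "))
  cfg
}

#' Write a scenario configuration to a key-value file
#'
#' Round-trips through [load_config()] unchanged.
#'
#' @param cfg a [scenario_config()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "scenario_config"))
  fmt <- function(x) {
    if (length(x) == 1 && is.na(x)) return("auto")
    if (is.logical(x)) return(if (x) "true" else "false")
    if (is.character(x)) return(x)
    format(x, digits = 17, scientific = FALSE, trim = TRUE)
  }
  out <- c("[scenario]",
           vapply(scenario_fields, function(k) paste(k, "=", fmt(cfg[[k]])), ""))
  for (s in c("release", "membrane", "grid")) {
    if (length(cfg[[s]])) {
      out <- c(out, paste0("[", s, "]"),
               vapply(names(cfg[[s]]),
                      function(k) paste(k, "=", fmt(cfg[[s]][[k]])), ""))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>", x$condition,
      sprintf("| N_rogue = %g /um^2 | %d beats @ CL %g ms | rest %g ms | reps %d | seed %d\n",
              x$n_rogue, x$pacing_n, x$pacing_cl, x$rest_ms, x$n_reps, x$seed))
  if (x$disable_ina_after_pacing) cat("  I_Na disabled after pacing\n")
  invisible(x)
}
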