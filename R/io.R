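#' Write all artifacts of a run to a directory
#'
#' Writes the time-series table (`timeseries.tsv`), the linescan matrix
#' (`linescan.tsv`, rows = x-nodes, columns = samples) with an axis sidecar
#' (`linescan_axes.tsv`), the event summary (`events.tsv`) and a key-value
#' manifest (`manifest.txt`) from which the run can be regenerated.
#'
#' @param run an `ryr_run` object.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "ryr_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(run$series, file.path(dir, "timeseries.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(run$linescan, file.path(dir, "linescan.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  axes <- data.frame(axis = c(rep("x_um", length(run$linescan_x)),
                              rep("t_ms", length(run$linescan_t))),
                     value = c(run$linescan_x, run$linescan_t))
  utils::write.table(axes, file.path(dir, "linescan_axes.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(run$events, file.path(dir, "events.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  write_manifest(run$manifest, file.path(dir, "manifest.txt"))
  invisible(dir)
}

# Flatten the manifest (scenario fields + resolved parameter bundle) to
# key = value lines.
write_manifest <- function(manifest, path) {
  flat <- list()
  add <- function(prefix, x) {
    for (nm in names(x)) {
      v <- x[[nm]]
      key <- if (nzchar(prefix)) paste(prefix, nm, sep = ".") else nm
      if (is.list(v) && !inherits(v, "data.frame")) add(key, v)
      else if (is.numeric(v) || is.logical(v) || is.character(v))
        flat[[key]] <<- paste(format(v, digits = 17, trim = TRUE),
                              collapse = ",")
    }
  }
  m <- manifest
  m$params <- lapply(m$params[c("release", "membrane", "grid")], unclass)
  add("", m)
  writeLines(paste(names(flat), "=", unlist(flat)), path)
  invisible(path)
}

#' Write ensemble statistics tables
#'
#' Writes `run_summaries.tsv` (one row per repetition), `stats.tsv` (one row
#' per density x metric: mean, SEM, n), `anova.tsv` and `triggered.tsv`.
#'
#' @param ens an `ryr_ensemble` object.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_ensemble <- function(ens, dir) {
  stopifnot(inherits(ens, "ryr_ensemble"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(x, file.path(dir, f), sep = "\t",
                                          row.names = FALSE, quote = FALSE)
  wt(ens$summaries, "run_summaries.tsv")
  wt(ens$stats, "stats.tsv")
  wt(ens$anova, "anova.tsv")
  wt(ens$triggered, "triggered.tsv")
  invisible(dir)
}

cli_common_options <- function() {
  list(
    optparse::make_option("--condition", type = "character",
                          default = "heart_failure",
                          help = "control or heart_failure [default %default]"),
    optparse::make_option("--n-rogue", dest = "n_rogue", type = "double",
                          default = 0,
                          help = "rogue RyR density per um^2 [default %default]"),
    optparse::make_option("--seed", type = "integer", default = 1L,
                          help = "master RNG seed [default %default]"),
    optparse::make_option("--reps", type = "integer", default = 1L,
                          help = "Monte Carlo repetitions [default %default]"),
    optparse::make_option("--out-dir", dest = "out_dir", type = "character",
                          default = NULL, help = "output directory (required)"),
    optparse::make_option("--config", type = "character", default = NULL,
                          help = "optional key-value config file"),
    optparse::make_option("--disable-ina-after-pacing",
                          dest = "disable_ina", action = "store_true",
                          default = FALSE,
                          help = "zero G_Na after the last stimulus"),
    optparse::make_option("--pacing-n", dest = "pacing_n", type = "integer",
                          default = NULL, help = "number of paced beats"),
    optparse::make_option("--pacing-cl", dest = "pacing_cl", type = "double",
                          default = NULL, help = "pacing cycle length (ms)"),
    optparse::make_option("--rest-ms", dest = "rest_ms", type = "double",
                          default = NULL, help = "rest window (ms)"),
    optparse::make_option("--mesh-h", dest = "h", type = "double",
                          default = NULL, help = "mesh spacing (um)"),
    optparse::make_option("--dt", type = "double", default = NULL,
                          help = "time step (ms)")
  )
}

cli_build_config <- function(opt) {
  cfg <- if (!is.null(opt$config)) load_config(opt$config)
         else scenario_config(condition = opt$condition)
  cfg$condition <- match_condition(opt$condition)
  cfg$n_rogue <- opt$n_rogue
  cfg$seed <- opt$seed
  cfg$n_reps <- max(1L, opt$reps)
  cfg$disable_ina_after_pacing <- isTRUE(opt$disable_ina)
  for (f in c("pacing_n", "pacing_cl", "rest_ms"))
    if (!is.null(opt[[f]])) cfg[[f]] <- opt[[f]]
  if (!is.null(opt[["h"]])) cfg$grid$h <- opt[["h"]]
  if (!is.null(opt[["dt"]])) cfg$grid$dt <- opt[["dt"]]
  validate_scenario_config(cfg)
  cfg
}

#' Command-line entry point: simulate one scenario
#'
#' Runs one protocol (repeating `--reps` times with derived seeds) and writes
#' the full artifact set per repetition under `--out-dir`.  Used by the
#' `inst/cli/rogueryr` script; call directly with an argument vector for
#' programmatic use.
#'
#' @param args character vector of command-line arguments.
#' @return (invisibly) the list of run objects.
#' @export
cmd_simulate <- function(args = commandArgs(trailingOnly = TRUE)) {
  parser <- optparse::OptionParser(option_list = cli_common_options(),
                                   prog = "rogueryr simulate")
  opt <- optparse::parse_args(parser, args = args)
  if (is.null(opt$out_dir))
    stop("simulate: --out-dir is required", call. = FALSE)
  cfg <- cli_build_config(opt)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(cfg$seed)
  seeds <- sample.int(.Machine$integer.max - 1, cfg$n_reps)
  runs <- vector("list", cfg$n_reps)
  for (r in seq_len(cfg$n_reps)) {
    message(sprintf("[%s] rep %d/%d (seed %d)", format(Sys.time(), "%H:%M:%S"),
                    r, cfg$n_reps, seeds[r]))
    runs[[r]] <- run_protocol(cfg, seed = seeds[r])
    write_run(runs[[r]], file.path(opt$out_dir, sprintf("rep%03d", r)))
  }
  message("wrote ", cfg$n_reps, " repetition(s) to ", opt$out_dir)
  invisible(runs)
}

#' Command-line entry point: density sweep with ensemble statistics
#'
#' Runs the Monte Carlo ensemble over a comma-separated list of rogue
#' densities and writes the per-run summaries and the group statistics table
#' (mean, SEM, n, ANOVA P, triggered fraction).
#'
#' @param args character vector of command-line arguments; requires
#'   `--sweep d1,d2,...` and `--out-dir`.
#' @return (invisibly) the `ryr_ensemble`.
#' @export
cmd_sweep <- function(args = commandArgs(trailingOnly = TRUE)) {
  opts <- c(cli_common_options(),
            list(optparse::make_option("--sweep", type = "character",
                                       default = NULL,
                                       help = "comma-separated N_rogue list")))
  parser <- optparse::OptionParser(option_list = opts, prog = "rogueryr sweep")
  opt <- optparse::parse_args(parser, args = args)
  if (is.null(opt$out_dir)) stop("sweep: --out-dir is required", call. = FALSE)
  if (is.null(opt$sweep) || !nzchar(opt$sweep))
    stop("sweep: --sweep with a non-empty density list is required", call. = FALSE)
  dens <- as.numeric(strsplit(opt$sweep, ",", fixed = TRUE)[[1]])
  if (anyNA(dens)) stop("sweep: could not parse --sweep densities", call. = FALSE)
  cfg <- cli_build_config(opt)
  if (opt$reps < 2) stop("sweep: --reps must be >= 2", call. = FALSE)
  message(sprintf("[%s] sweep over {%s} x %d reps", format(Sys.time(), "%H:%M:%S"),
                  paste(dens, collapse = ", "), opt$reps))
  ens <- ensemble(cfg, dens, reps = opt$reps)
  write_ensemble(ens, opt$out_dir)
  cfg_manifest <- c(list(sweep = paste(dens, collapse = ",")),
                    cfg[scenario_fields])
  writeLines(paste(names(cfg_manifest), "=",
                   vapply(cfg_manifest, function(v) paste(format(v), collapse = ","), "")),
             file.path(opt$out_dir, "manifest.txt"))
  message("wrote ensemble statistics to ", opt$out_dir)
  invisible(ens)
}
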