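# Configuration files, run manifests, CSV outputs and the command-line
# front end.  All times are serialized as decimal minutes with three
# fractional digits for bit-stable CSV diffs.

fmt_min <- function(x) sprintf("%.3f", x)

#' Load a simulation configuration from YAML or JSON
#'
#' Schema: `strategy`, `n_days`, `seed` (or `seeds: {master}`), optional
#' `t_max` (required when strategy is `prio_maxwait`), optional `catalog`
#' (path to a catalog CSV), optional `operating_point` (preset name or CSV
#' path), optional `timing` (either synthetic parameter fields or
#' `arrival_csv`/`reporting_csv` histogram paths).  Omitted sections fall
#' back to the package defaults (bundled catalog, `lowFPR` preset,
#' calibrated synthetic timing).
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A [simulation_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(raw$strategy)) stop("config key 'strategy' is required")
  if (!raw$strategy %in% SIM_STRATEGIES)
    stop("unknown strategy '", raw$strategy, "' (config key 'strategy')")
  if (is.null(raw$n_days)) stop("config key 'n_days' is required")
  seed <- if (!is.null(raw$seed)) raw$seed
          else if (!is.null(raw$seeds$master)) raw$seeds$master
          else stop("config key 'seed' (or seeds: {master}) is required")
  if (raw$strategy == "prio_maxwait" && is.null(raw$t_max))
    stop("config key 't_max' is required for strategy prio_maxwait")
  catalog <- if (!is.null(raw$catalog)) read_catalog_csv(raw$catalog)
             else default_catalog()
  op <- NULL
  if (!is.null(raw$operating_point)) {
    op <- if (raw$operating_point %in% c("lowFPR", "lowFNR"))
      op_preset(raw$operating_point, catalog)
    else read_operating_point_csv(raw$operating_point)
  }
  timing <- default_timing_params()
  arrival_hist <- reporting_hist <- NULL
  if (!is.null(raw$timing)) {
    tm <- raw$timing
    if (!is.null(tm$arrival_csv) || !is.null(tm$reporting_csv)) {
      if (is.null(tm$arrival_csv) || is.null(tm$reporting_csv))
        stop("config keys 'timing.arrival_csv' and 'timing.reporting_csv' must be given together")
      arrival_hist <- read_histogram_csv(tm$arrival_csv)
      reporting_hist <- read_histogram_csv(tm$reporting_csv)
    } else {
      defaults <- default_timing_params()
      pick <- function(key) if (!is.null(tm[[key]])) tm[[key]] else defaults[[key]]
      timing <- timing_params(
        day_mean_arrival_delta = pick("day_mean_arrival_delta"),
        night_mean_arrival_delta = pick("night_mean_arrival_delta"),
        day_hours = unlist(pick("day_hours")),
        reporting_mean_delta = pick("reporting_mean_delta"),
        reporting_dispersion = pick("reporting_dispersion"),
        distribution_family = pick("distribution_family"))
    }
  }
  simulation_config(strategy = raw$strategy, n_days = raw$n_days, seed = seed,
                    catalog = catalog, operating_point = op,
                    t_max = raw$t_max, timing = timing,
                    arrival_hist = arrival_hist, reporting_hist = reporting_hist)
}

#' Serialize a configuration back to YAML
#'
#' Writes the resolved scalar parameters (strategy, days, seed, t_max and
#' synthetic timing) so that [load_config()] on the output reproduces the
#' configuration.
#' @param config a [simulation_config()].
#' @param path output `.yaml` path.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "simulation_config"))
  out <- list(strategy = config$strategy, n_days = config$n_days,
              seed = config$seed,
              timing = config$timing[c("day_mean_arrival_delta",
                                       "night_mean_arrival_delta", "day_hours",
                                       "reporting_mean_delta",
                                       "reporting_dispersion",
                                       "distribution_family")])
  if (!is.null(config$t_max)) out$t_max <- config$t_max
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Write the per-exam event log as CSV
#'
#' Columns `day,exam_id,acq_min,report_min,rtat_min,rank,promoted,
#' true_labels,pred_labels`; label sets are semicolon-joined finding names.
#' @param sim a `cxr_sim` result.
#' @param path output path.
#' @export
write_event_log <- function(sim, path) {
  r <- sim$records
  join <- function(m) {
    if (is.null(m)) return(rep("", nrow(r)))
    nm <- colnames(m)
    apply(m, 1L, function(row) paste(nm[row], collapse = ";"))
  }
  df <- data.frame(day = r$day, exam_id = r$exam_id,
                   acq_min = fmt_min(r$acq_min),
                   report_min = fmt_min(r$report_min),
                   rtat_min = fmt_min(r$rtat_min),
                   rank = r$rank, promoted = r$promoted,
                   true_labels = join(sim$true_labels),
                   pred_labels = join(sim$pred_labels))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a per-class RTAT summary as CSV
#'
#' Columns `strategy,class,n,mean_min,median_min,max_min`.
#' @param summary output of [summarize_rtat()].
#' @param strategy strategy label for the first column.
#' @param path output path.
#' @export
write_summary_csv <- function(summary, strategy, path) {
  df <- data.frame(strategy = strategy, class = summary$class, n = summary$n,
                   mean_min = fmt_min(summary$mean_min),
                   median_min = fmt_min(summary$median_min),
                   max_min = fmt_min(summary$max_min))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build a run manifest
#'
#' Captures everything needed to reproduce a run: the resolved scalar
#' configuration, package version, master seed and output paths.
#' @param config a [simulation_config()].
#' @param outputs named character vector of output file paths.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(config, outputs = character(0)) {
  structure(list(
    package = "triagesim",
    version = as.character(utils::packageVersion("triagesim")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config = list(strategy = config$strategy, n_days = config$n_days,
                  t_max = config$t_max,
                  timing = config$timing[c("day_mean_arrival_delta",
                                           "night_mean_arrival_delta",
                                           "day_hours", "reporting_mean_delta",
                                           "reporting_dispersion",
                                           "distribution_family")]),
    outputs = as.list(outputs)), class = "run_manifest")
}

#' @rdname run_manifest
#' @param manifest a `run_manifest`.
#' @param path output `.json` path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}

# --- minimal CLI ----------------------------------------------------------

parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- gsub("-", "_", substring(a, 3L))
    if (i == length(args) || startsWith(args[i + 1L], "--"))
      stop("missing value for --", key)
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  opts
}

cli_config <- function(opts, strategy = NULL) {
  if (!is.null(opts$config)) return(load_config(opts$config))
  simulation_config(
    strategy = if (!is.null(strategy)) strategy else opts$strategy %||% "fifo",
    n_days = as.integer(opts$days %||% 100L),
    seed = as.integer(opts$seed %||% 1L),
    t_max = if (!is.null(opts$t_max)) as.numeric(opts$t_max) else NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

cli_log <- function(verbose, ...) if (verbose) message(sprintf(...))

#' Command-line entry point
#'
#' Subcommands: `run` (simulate one strategy; writes `events.csv`,
#' `summary.csv`, `manifest.json`), `compare` (two strategies under common
#' seeds; writes `comparison.csv`), `sweep` (FPR sweep; writes
#' `sweep.csv`), `calibrate` (fit the reporting mean to a target RTAT;
#' writes `calibrated.yaml`), and `fixtures` (emit the bundled catalog,
#' operating points and synthetic histograms as CSVs).  Shared options:
#' `--days`, `--seed`, `--out DIR`, `--config FILE`, `--quiet true`.
#'
#' @param args character vector of arguments, e.g.
#'   `c("run", "--strategy", "fifo", "--days", "5", "--seed", "7",
#'      "--out", "out/")`.
#' @return Integer exit status, invisibly (0 on success); a wrapper script
#'   is installed at `system.file("cli", "triagesim", package = "triagesim")`.
#' @export
cli_run <- function(args) {
  status <- tryCatch({
    if (!length(args)) stop("usage: triagesim <run|compare|sweep|calibrate|fixtures> [--options]")
    cmd <- args[1L]
    opts <- parse_cli_opts(args[-1L])
    verbose <- is.null(opts$quiet)
    out_dir <- opts$out %||% "."
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    switch(cmd,
      run = {
        cfg <- cli_config(opts)
        cli_log(verbose, "running %s for %d day(s), seed %d",
                cfg$strategy, cfg$n_days, cfg$seed)
        sim <- run_simulation(cfg)
        cli_log(verbose, "simulated %d exams", nrow(sim$records))
        files <- c(events = file.path(out_dir, "events.csv"),
                   summary = file.path(out_dir, "summary.csv"),
                   manifest = file.path(out_dir, "manifest.json"))
        write_event_log(sim, files[["events"]])
        write_summary_csv(summarize_rtat(sim), cfg$strategy, files[["summary"]])
        write_manifest(run_manifest(cfg, files), files[["manifest"]])
      },
      compare = {
        a <- opts$a %||% stop("compare needs --a <strategy>")
        b <- opts$b %||% stop("compare needs --b <strategy>")
        sim_a <- run_simulation(cli_config(opts, a))
        sim_b <- run_simulation(cli_config(opts, b))
        cmp <- compare_strategies(sim_a, sim_b)
        utils::write.csv(cmp, file.path(out_dir, "comparison.csv"),
                         row.names = FALSE, quote = FALSE)
        cli_log(verbose, "compared %s vs %s over %d classes", a, b, nrow(cmp))
      },
      sweep = {
        cfg <- cli_config(opts, "prio")
        sw <- fpr_sweep(cfg)
        utils::write.csv(
          data.frame(fpr = sw$fpr, mean_rtat_rank1 = fmt_min(sw$mean_rtat_rank1)),
          file.path(out_dir, "sweep.csv"), row.names = FALSE, quote = FALSE)
        cli_log(verbose, "sweep argmin at FPR %.3f", attr(sw, "argmin_fpr"))
      },
      calibrate = {
        target <- as.numeric(opts$target %||% 80)
        p <- calibrate_reporting_mean(target,
                                      n_days = as.integer(opts$days %||% 100L),
                                      seed = as.integer(opts$seed %||% 1234L))
        yaml::write_yaml(unclass(p), file.path(out_dir, "calibrated.yaml"))
        cli_log(verbose, "calibrated reporting mean %.3f min (RTAT %.1f)",
                p$reporting_mean_delta, attr(p, "achieved_rtat"))
      },
      fixtures = {
        write_catalog_csv(default_catalog(), file.path(out_dir, "catalog.csv"))
        for (nm in c("lowFPR", "lowFNR")) {
          op <- op_preset(nm)
          utils::write.csv(op[, c("finding", "tpr", "fpr")],
                           file.path(out_dir, paste0("operating_point_", nm, ".csv")),
                           row.names = FALSE, quote = FALSE)
        }
        p <- default_timing_params()
        write_histogram_csv(synth_histogram(p, "arrival"),
                            file.path(out_dir, "arrival_hist.csv"))
        write_histogram_csv(synth_histogram(p, "reporting"),
                            file.path(out_dir, "reporting_hist.csv"))
        cli_log(verbose, "fixtures written to %s", out_dir)
      },
      stop("unknown subcommand: ", cmd))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
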