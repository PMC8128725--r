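# Event-driven Monte Carlo engine: couples the arrival process, label and
# prediction sampling, the worklist policy and the single-radiologist
# service process over repeated, independent 24-hour days.

SIM_STRATEGIES <- c("fifo", "prio", "prio_maxwait", "perfect")
DAY_MIN <- 1440

# Deterministic seed mixing (Lehmer-style) keeping values inside 32-bit
# range; used to expand one master seed into named per-stream, per-day
# substreams.
mix_seed <- function(a, b) ((a %% 2147483647) * 48271 + b + 1) %% 2147483647

stream_seed <- function(master, stream, day) {
  sid <- match(stream, c("arrival", "labels", "classifier", "service"))
  if (is.na(sid)) stop("unknown stream: ", stream)
  mix_seed(mix_seed(master, sid), day)
}

#' Assemble and validate a simulation configuration
#'
#' @param strategy worklist policy: `"fifo"` (chronological), `"prio"`
#'   (urgency order from classifier predictions), `"prio_maxwait"` (`prio`
#'   plus promotion of exams waiting longer than `t_max`), or `"perfect"`
#'   (urgency order from the true labels — the upper bound).
#' @param n_days number of independent simulated days (>= 1).
#' @param seed master integer seed; expanded deterministically into the
#'   four named streams (arrival, labels, classifier, service) so that
#'   strategies compared under one seed consume identical arrival, label
#'   and classifier randomness (common random numbers).
#' @param catalog a [finding_catalog()].
#' @param operating_point an [operating_point()]; used by `prio` and
#'   `prio_maxwait` (default: the `"lowFPR"` preset), ignored by `fifo`
#'   and `perfect`.
#' @param t_max maximum waiting time in minutes before promotion
#'   (`prio_maxwait` only; default 360).
#' @param timing a [timing_params()] object used to synthesize the arrival
#'   and reporting histograms, unless both histograms are given explicitly.
#' @param arrival_hist,reporting_hist optional [tod_histogram()] objects
#'   overriding the synthetic ones.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(strategy = c("fifo", "prio", "prio_maxwait", "perfect"),
                              n_days = 100L, seed = 1L,
                              catalog = default_catalog(),
                              operating_point = NULL, t_max = NULL,
                              timing = default_timing_params(),
                              arrival_hist = NULL, reporting_hist = NULL) {
  strategy <- match.arg(strategy)
  n_days <- as.integer(n_days)
  if (is.na(n_days) || n_days < 1L) stop("n_days must be >= 1")
  stopifnot(inherits(catalog, "finding_catalog"))
  if (strategy %in% c("prio", "prio_maxwait")) {
    if (is.null(operating_point)) operating_point <- op_preset("lowFPR", catalog)
    stopifnot(inherits(operating_point, "operating_point"))
    if (nrow(operating_point) != nrow(catalog))
      stop("operating point does not match catalog size")
  }
  if (strategy == "prio_maxwait") {
    if (is.null(t_max)) t_max <- 360
    if (t_max <= 0) stop("t_max must be > 0")
  }
  if (is.null(arrival_hist)) arrival_hist <- synth_histogram(timing, "arrival")
  if (is.null(reporting_hist)) reporting_hist <- synth_histogram(timing, "reporting")
  stopifnot(inherits(arrival_hist, "tod_histogram"),
            inherits(reporting_hist, "tod_histogram"))
  structure(list(strategy = strategy, n_days = n_days, seed = as.integer(seed),
                 catalog = catalog, operating_point = operating_point,
                 t_max = t_max, timing = timing,
                 arrival_hist = arrival_hist, reporting_hist = reporting_hist),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("<simulation_config> strategy=%s, n_days=%d, seed=%d\n",
              x$strategy, x$n_days, x$seed))
  if (!is.null(x$t_max)) cat(sprintf("  t_max=%g min\n", x$t_max))
  invisible(x)
}

#' Simulate one 24-hour day of worklist processing
#'
#' Arrivals accumulate from time 0 by sampled inter-arrival deltas and stop
#' at minute 1440; each exam receives true labels and, under the predictive
#' strategies, classifier predictions that determine its insertion rank.
#' One radiologist finalizes reports separated by sampled reporting deltas;
#' a completion that finds the worklist empty is discarded and the service
#' chain restarts with a fresh delta at the next arrival.  Completions are
#' processed before arrivals at equal clock times.  After minute 1440 no
#' exams arrive but service continues until the worklist is empty, so each
#' day is an independent replication.
#'
#' @param config a [simulation_config()].
#' @param day_index 1-based day number (selects the per-day substreams).
#' @return A list with per-exam vectors `acq`, `report`, `rank`,
#'   `promoted` and label matrices `true` (and `pred` unless fifo).
#' @export
run_day <- function(config, day_index) {
  stopifnot(inherits(config, "simulation_config"))
  K <- nrow(config$catalog)
  strategy <- config$strategy
  ah <- config$arrival_hist; rh <- config$reporting_hist

  # arrival stream: cumulative hour-conditioned deltas until the day ends
  set.seed(stream_seed(config$seed, "arrival", day_index))
  acq <- numeric(0)
  t <- 0
  repeat {
    t <- t + sample_delta(ah, t)
    if (t >= DAY_MIN) break
    acq[length(acq) + 1L] <- t
  }
  n <- length(acq)
  if (n == 0L)
    return(list(day = day_index, acq = numeric(0), report = numeric(0),
                rank = integer(0), promoted = logical(0),
                true = matrix(FALSE, 0L, K, dimnames = list(NULL, config$catalog$name)),
                pred = NULL))

  # label stream
  set.seed(stream_seed(config$seed, "labels", day_index))
  true <- sample_labels(config$catalog, n)

  # classifier stream (consumed only by the predictive strategies)
  pred <- NULL
  if (strategy %in% c("prio", "prio_maxwait")) {
    set.seed(stream_seed(config$seed, "classifier", day_index))
    pred <- sample_prediction(true, config$operating_point)
    ranks <- urgency_rank(pred, config$catalog)
  } else if (strategy == "perfect") {
    pred <- true
    ranks <- urgency_rank(true, config$catalog)
  } else {
    ranks <- rep.int(K + 1L, n)      # fifo: one uniform tier
  }

  # service stream drives the event loop
  set.seed(stream_seed(config$seed, "service", day_index))
  maxwait <- strategy == "prio_maxwait"
  report <- numeric(n); promoted_out <- logical(n)
  wl <- worklist()
  i <- 1L                  # next arrival
  done <- 0L
  next_completion <- Inf   # no service chain until the first arrival
  stalled <- TRUE
  while (done < n) {
    ta <- if (i <= n) acq[i] else Inf
    if (next_completion <= ta) {
      now <- next_completion
      if (maxwait) wl <- wl_promote_overdue(wl, now, config$t_max)
      if (!length(wl)) {
        next_completion <- Inf   # discard; restart chain at next arrival
        stalled <- TRUE
      } else {
        r <- wl_pop_head(wl)
        wl <- r$worklist
        report[r$item$id] <- now
        promoted_out[r$item$id] <- r$item$promoted
        done <- done + 1L
        next_completion <- now + sample_delta(rh, now)
      }
    } else {
      now <- ta
      wl <- if (strategy == "fifo") wl_fifo_insert(wl, i, now, ranks[i])
            else wl_insert(wl, i, now, ranks[i])
      if (maxwait) wl <- wl_promote_overdue(wl, now, config$t_max)
      if (stalled) {
        next_completion <- now + sample_delta(rh, now)
        stalled <- FALSE
      }
      i <- i + 1L
    }
  }
  list(day = day_index, acq = acq, report = report, rank = ranks,
       promoted = promoted_out, true = true,
       pred = if (strategy == "fifo") NULL else pred)
}

#' Run the full multi-day Monte Carlo simulation
#'
#' Concatenates independent [run_day()] replications; per-day substreams
#' are derived deterministically from the master seed, so results are
#' bit-for-bit reproducible and a two-day run equals the concatenation of
#' its two single-day runs.
#'
#' @param config a [simulation_config()].
#' @return An object of class `cxr_sim`: a list with `records` (data frame
#'   with one row per exam: `day`, `exam_id`, `acq_min`, `report_min`,
#'   `rtat_min`, `rank`, `promoted`), logical label matrices `true_labels`
#'   and `pred_labels` (NULL under fifo), the `catalog` and the `config`.
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  days <- lapply(seq_len(config$n_days), function(d) run_day(config, d))
  n_per <- vapply(days, function(d) length(d$acq), integer(1))
  day_col <- rep.int(seq_len(config$n_days), n_per)
  acq <- unlist(lapply(days, `[[`, "acq"), use.names = FALSE)
  report <- unlist(lapply(days, `[[`, "report"), use.names = FALSE)
  records <- data.frame(
    day = day_col,
    exam_id = seq_along(acq),
    acq_min = acq,
    report_min = report,
    rtat_min = report - acq,
    rank = unlist(lapply(days, `[[`, "rank"), use.names = FALSE),
    promoted = unlist(lapply(days, `[[`, "promoted"), use.names = FALSE))
  true_labels <- do.call(rbind, lapply(days, `[[`, "true"))
  pred_labels <- if (config$strategy == "fifo") NULL
                 else do.call(rbind, lapply(days, `[[`, "pred"))
  structure(list(records = records, true_labels = true_labels,
                 pred_labels = pred_labels, catalog = config$catalog,
                 config = config),
            class = "cxr_sim")
}

#' @export
print.cxr_sim <- function(x, ...) {
  r <- x$records
  cat(sprintf("<cxr_sim> strategy=%s: %d exams over %d day(s)\n",
              x$config$strategy, nrow(r), x$config$n_days))
  if (nrow(r))
    cat(sprintf("  RTAT mean %.1f / median %.1f / max %.1f min\n",
                mean(r$rtat_min), stats::median(r$rtat_min), max(r$rtat_min)))
  invisible(x)
}
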