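# Time-of-day-conditioned delta distributions driving the simulation clock.
#
# All simulation time is continuous minutes since the start of a day; the
# hour of day of a clock value t is floor(t/60) mod 24.  Delta histograms
# use 1-minute bins with integer edges and support (0, 150]: bin j covers
# the interval (j-1, j] and a draw from bin j returns j minutes.

#' Maximum delta retained in a timing histogram (minutes)
#'
#' Inter-arrival and inter-report deltas above this cutoff are treated as
#' outliers (machine downtime, overnight gaps) and discarded when building
#' histograms from timestamps.
#' @export
HIST_CUTOFF_MIN <- 150

hour_of <- function(clock) floor(clock / 60) %% 24

#' Construct a time-of-day delta histogram
#'
#' @param counts integer matrix, 24 rows (hour of day 0-23) by up to 150
#'   columns (delta bins of 1 minute; column j is the bin (j-1, j]).
#' @param kind `"arrival"` or `"reporting"`.
#' @return An object of class `tod_histogram` with precomputed per-hour and
#'   pooled cumulative distributions for fast sampling.
#' @export
tod_histogram <- function(counts, kind = c("arrival", "reporting")) {
  kind <- match.arg(kind)
  if (!is.matrix(counts) || nrow(counts) != 24L)
    stop("counts must be a 24-row matrix (one row per hour of day)")
  if (ncol(counts) < 1L || ncol(counts) > HIST_CUTOFF_MIN)
    stop("delta bins must lie within (0, ", HIST_CUTOFF_MIN, "] minutes")
  if (any(counts < 0) || any(counts != round(counts)) || any(!is.finite(counts)))
    stop("counts must be nonnegative integers")
  storage.mode(counts) <- "double"  # row sums can exceed .Machine$integer.max
  row_tot <- rowSums(counts)
  cum <- t(apply(counts, 1L, cumsum))
  occ <- row_tot > 0
  cum[occ, ] <- cum[occ, , drop = FALSE] / row_tot[occ]
  pooled <- colSums(counts)
  pooled_cum <- if (sum(pooled) > 0) cumsum(pooled) / sum(pooled) else NULL
  structure(
    list(kind = kind, counts = counts, delta = seq_len(ncol(counts)),
         row_total = row_tot, row_cum = cum, pooled_cum = pooled_cum),
    class = "tod_histogram")
}

#' @export
print.tod_histogram <- function(x, ...) {
  tot <- sum(x$row_total)
  cat(sprintf("<tod_histogram> kind=%s, %d delta bins, %s deltas\n",
              x$kind, length(x$delta), format(tot, big.mark = ",")))
  if (tot > 0) {
    m <- sum(x$delta * colSums(x$counts)) / tot
    cat(sprintf("  pooled mean delta: %.2f min; occupied hours: %d/24\n",
                m, sum(x$row_total > 0)))
  }
  invisible(x)
}

#' Build a delta histogram from an ordered series of event timestamps
#'
#' Consecutive timestamp pairs yield deltas (in minutes); each delta is
#' attributed to the hour of day of the *earlier* event, deltas greater than
#' `cutoff` are discarded as outliers, and the rest are binned at 1-minute
#' resolution (a delta d falls in bin `ceiling(d)`).
#'
#' @param timestamps strictly increasing `POSIXct` vector, or a numeric
#'   vector of minutes since some day's midnight.
#' @param kind `"arrival"` or `"reporting"`.
#' @param cutoff outlier cutoff in minutes, in (0, 150]; default 150
#'   (2 h 30 min).
#' @return A [tod_histogram()] whose total count equals the number of
#'   consecutive pairs minus the number of discarded deltas.
#' @export
build_histogram <- function(timestamps, kind = c("arrival", "reporting"),
                            cutoff = HIST_CUTOFF_MIN) {
  kind <- match.arg(kind)
  if (!(is.numeric(cutoff) && length(cutoff) == 1L && cutoff > 0 &&
        cutoff <= HIST_CUTOFF_MIN))
    stop("cutoff must be a single value in (0, ", HIST_CUTOFF_MIN, "] minutes")
  if (inherits(timestamps, "POSIXct")) {
    lt <- as.POSIXlt(timestamps)
    hours <- lt$hour
    mins <- as.numeric(timestamps) / 60
  } else if (is.numeric(timestamps)) {
    mins <- as.numeric(timestamps)
    hours <- hour_of(mins)
  } else {
    stop("timestamps must be POSIXct or numeric minutes")
  }
  if (length(mins) < 2L) stop("insufficient data: need at least 2 timestamps")
  deltas <- diff(mins)
  if (any(deltas <= 0)) stop("timestamps must be strictly increasing")
  hours <- hours[-length(hours)]         # hour of the earlier event (D4)
  keep <- deltas <= cutoff
  deltas <- deltas[keep]
  hours <- hours[keep]
  nb <- as.integer(ceiling(cutoff))
  counts <- matrix(0L, 24L, nb)
  if (length(deltas)) {
    bin <- as.integer(ceiling(deltas))
    for (i in seq_along(bin))
      counts[hours[i] + 1L, bin[i]] <- counts[hours[i] + 1L, bin[i]] + 1L
  }
  tod_histogram(counts, kind)
}

#' Draw delta values conditioned on the hour of the simulation clock
#'
#' Samples from the histogram row for `hour(clock)`; if that hour has no
#' observations the pooled all-hours distribution is used instead, so the
#' simulation clock can never stall on a sparse histogram.
#'
#' @param hist a [tod_histogram()].
#' @param clock current simulation time in minutes.
#' @param n number of draws.
#' @return Integer delta(s) in minutes, strictly positive, never above the
#'   histogram support. Uses the current R random stream.
#' @export
sample_delta <- function(hist, clock, n = 1L) {
  stopifnot(inherits(hist, "tod_histogram"))
  if (is.null(hist$pooled_cum)) stop("empty distribution")
  h <- hour_of(clock) + 1L
  cdf <- if (hist$row_total[h] > 0) hist$row_cum[h, ] else hist$pooled_cum
  u <- stats::runif(n)
  hist$delta[findInterval(u, cdf, left.open = TRUE) + 1L]
}

#' Parameters of the synthetic timing model
#'
#' Describes the stand-in generator for the hospital's (unpublished)
#' empirical inter-arrival and inter-report distributions: arrivals follow a
#' unit-coefficient-of-variation positive family whose mean gap switches
#' between a day and a night value, and reporting gaps share one mean across
#' all hours with a tunable dispersion.
#'
#' @param day_mean_arrival_delta mean minutes between exams during day hours.
#' @param night_mean_arrival_delta mean minutes between exams at night; must
#'   be at least the day value (fewer exams at night).
#' @param day_hours half-open hour interval `[from, to)` counted as daytime.
#' @param reporting_mean_delta mean minutes between consecutive report
#'   finalizations (includes pauses and interruptions, not just reading time).
#'   The default is the value calibrated so that a FIFO run reproduces the
#'   hospital's observed 80-minute average report turnaround time.
#' @param reporting_dispersion dispersion of the reporting family: the
#'   log-scale standard deviation for `"lognormal"`, the coefficient of
#'   variation for `"gamma"`.
#' @param distribution_family `"lognormal"` or `"gamma"`.
#' @export
timing_params <- function(day_mean_arrival_delta = 12,
                          night_mean_arrival_delta = 45,
                          day_hours = c(7L, 19L),
                          reporting_mean_delta = 13.266,
                          reporting_dispersion = 0.75,
                          distribution_family = c("lognormal", "gamma")) {
  distribution_family <- match.arg(distribution_family)
  if (day_mean_arrival_delta <= 0 || night_mean_arrival_delta <= 0 ||
      reporting_mean_delta <= 0)
    stop("all mean deltas must be > 0")
  if (night_mean_arrival_delta < day_mean_arrival_delta)
    stop("night_mean_arrival_delta must be >= day_mean_arrival_delta")
  if (reporting_dispersion <= 0) stop("reporting_dispersion must be > 0")
  if (length(day_hours) != 2L || day_hours[1] < 0 || day_hours[2] > 24 ||
      day_hours[1] >= day_hours[2])
    stop("day_hours must be an increasing pair within [0, 24]")
  structure(
    list(day_mean_arrival_delta = day_mean_arrival_delta,
         night_mean_arrival_delta = night_mean_arrival_delta,
         day_hours = as.integer(day_hours),
         reporting_mean_delta = reporting_mean_delta,
         reporting_dispersion = reporting_dispersion,
         distribution_family = distribution_family),
    class = "timing_params")
}

default_timing_params <- function() timing_params()

# Probability mass of the chosen family over 1-minute bins (0,150],
# truncated and renormalized.
family_bin_pmf <- function(mean, dispersion, family) {
  edges <- 0:HIST_CUTOFF_MIN
  if (family == "lognormal") {
    sdlog <- dispersion
    meanlog <- log(mean) - sdlog^2 / 2
    cdf <- stats::plnorm(edges, meanlog, sdlog)
  } else if (family == "gamma") {
    shape <- 1 / dispersion^2
    cdf <- stats::pgamma(edges, shape = shape, scale = mean / shape)
  } else stop("unknown distribution family: ", family)
  p <- diff(cdf)
  if (sum(p) <= 0) stop("family mass entirely beyond the cutoff")
  p / sum(p)
}

#' Synthesize a time-of-day histogram from parametric timing assumptions
#'
#' Emulates the shape of empirically observed per-hour delta distributions:
#' arrival rows carry the day mean inside `day_hours` and the night mean
#' outside (unit coefficient of variation), reporting rows share one mean
#' and dispersion across all hours.  Rows are the chosen family discretized
#' to 1-minute bins, truncated to (0, 150] and renormalized; counts are the
#' expected counts of 1e6 draws per hour, so construction is deterministic.
#'
#' @param params a [timing_params()] object.
#' @param kind `"arrival"` or `"reporting"`.
#' @return A [tod_histogram()].
#' @export
synth_histogram <- function(params, kind = c("arrival", "reporting")) {
  stopifnot(inherits(params, "timing_params"))
  kind <- match.arg(kind)
  counts <- matrix(0, 24L, HIST_CUTOFF_MIN)
  for (h in 0:23) {
    if (kind == "arrival") {
      m <- if (h >= params$day_hours[1] && h < params$day_hours[2])
        params$day_mean_arrival_delta else params$night_mean_arrival_delta
      disp <- if (params$distribution_family == "lognormal")
        sqrt(log(2)) else 1   # coefficient of variation 1 in either family
    } else {
      m <- params$reporting_mean_delta
      disp <- params$reporting_dispersion
    }
    counts[h + 1L, ] <- round(1e6 * family_bin_pmf(m, disp, params$distribution_family))
  }
  tod_histogram(counts, kind)
}

#' Calibrate the reporting mean so FIFO reproduces a target average RTAT
#'
#' Bisects on `reporting_mean_delta`: for each candidate, synthetic arrival
#' and reporting histograms are built and a FIFO simulation of `n_days` days
#' is run with a fixed evaluation seed; the candidate bracketing stops when
#' the simulated grand-mean report turnaround time is within `tol` of the
#' target (relative).  The returned parameters are verified to land within
#' 10% of the target.
#'
#' @param target_avg_rtat target grand-mean RTAT in minutes.
#' @param base_params starting [timing_params()]; only the reporting mean is
#'   searched.
#' @param n_days days per evaluation run (at least 100 recommended).
#' @param seed fixed evaluation seed.
#' @param bracket search interval for the reporting mean, minutes.
#' @param tol relative tolerance used as the bisection stopping rule.
#' @return Calibrated [timing_params()] with attribute `achieved_rtat`.
#' @export
calibrate_reporting_mean <- function(target_avg_rtat = 80,
                                     base_params = timing_params(),
                                     n_days = 100L, seed = 1234L,
                                     bracket = c(2, 30), tol = 0.02) {
  stopifnot(inherits(base_params, "timing_params"), target_avg_rtat > 0)
  eval_mean <- function(m) {
    p <- base_params
    p$reporting_mean_delta <- m
    cfg <- simulation_config(strategy = "fifo", n_days = n_days,
                             seed = seed, timing = p)
    mean(run_simulation(cfg)$records$rtat_min)
  }
  lo <- bracket[1]; hi <- bracket[2]
  f_lo <- eval_mean(lo); f_hi <- eval_mean(hi)
  if ((f_lo - target_avg_rtat) * (f_hi - target_avg_rtat) > 0)
    stop(sprintf(
      "calibration failed: target %.1f min outside bracket [%.1f, %.1f] -> RTAT [%.1f, %.1f]",
      target_avg_rtat, lo, hi, f_lo, f_hi))
  achieved <- NA_real_; mid <- (lo + hi) / 2
  for (it in seq_len(40L)) {
    mid <- (lo + hi) / 2
    f_mid <- eval_mean(mid)
    achieved <- f_mid
    if (abs(f_mid - target_avg_rtat) / target_avg_rtat <= tol) break
    if ((f_mid - target_avg_rtat) * (f_lo - target_avg_rtat) > 0) {
      lo <- mid; f_lo <- f_mid
    } else hi <- mid
    if (hi - lo < 1e-3) break
  }
  if (abs(achieved - target_avg_rtat) / target_avg_rtat > 0.10)
    stop(sprintf(
      "calibration failed: best reporting mean %.3f min gives RTAT %.1f, outside +/-10%% of %.1f",
      mid, achieved, target_avg_rtat))
  out <- base_params
  out$reporting_mean_delta <- mid
  attr(out, "achieved_rtat") <- achieved
  out
}

#' Write / read a histogram as a plain CSV of occupied cells
#'
#' Columns `kind,hour,delta_min,count`, one row per occupied (hour, delta)
#' cell.
#' @param hist a [tod_histogram()].
#' @param path file path.
#' @export
write_histogram_csv <- function(hist, path) {
  stopifnot(inherits(hist, "tod_histogram"))
  occ <- which(hist$counts > 0, arr.ind = TRUE)
  df <- data.frame(kind = hist$kind, hour = occ[, 1L] - 1L,
                   delta_min = hist$delta[occ[, 2L]],
                   count = hist$counts[occ])
  df <- df[order(df$hour, df$delta_min), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_histogram_csv
#' @export
read_histogram_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("kind", "hour", "delta_min", "count")
  if (!all(need %in% names(df)))
    stop("histogram CSV must have columns ", paste(need, collapse = ","))
  kind <- unique(df$kind)
  if (length(kind) != 1L) stop("histogram CSV must contain a single kind")
  counts <- matrix(0L, 24L, HIST_CUTOFF_MIN)
  counts[cbind(df$hour + 1L, df$delta_min)] <- df$count
  tod_histogram(counts, kind)
}

#' Read ISO-8601 timestamps, one per line
#'
#' @param path plain-text file of ISO-8601 timestamps (e.g.
#'   `2019-02-03T08:15:00`), one per line.
#' @return A `POSIXct` vector (UTC).
#' @export
read_timestamps <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x)]
  fmts <- c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
            "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M")
  ts <- as.POSIXct(rep(NA_real_, length(x)), tz = "UTC")
  for (f in fmts) {
    miss <- is.na(ts)
    if (!any(miss)) break
    ts[miss] <- as.POSIXct(strptime(x[miss], f, tz = "UTC"))
  }
  if (anyNA(ts)) stop("unparseable timestamp at line ", which(is.na(ts))[1])
  ts
}
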