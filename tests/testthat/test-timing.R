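# Time-of-day histogram building, sampling and the synthetic generator.

test_that("build_histogram bins consecutive deltas by the earlier event's hour and drops outliers", {
  # minutes 08:00, 08:10, 08:25, 11:00 -> deltas 10, 15, 155; 155 discarded
  h <- build_histogram(c(480, 490, 505, 660), "arrival", cutoff = 150)
  expect_equal(sum(h$counts), 2)
  expect_equal(h$counts[9, 10], 1)   # hour 8, delta 10
  expect_equal(h$counts[9, 15], 1)   # hour 8, delta 15
  expect_equal(sum(h$counts[-9, ]), 0)

  # POSIXct input: 10:00 and 10:05 -> one delta of 5 min in hour 10
  ts <- as.POSIXct("2020-01-01 10:00:00", tz = "UTC") + c(0, 300)
  h2 <- build_histogram(ts, "reporting")
  expect_equal(sum(h2$counts), 1)
  expect_equal(h2$counts[11, 5], 1)

  expect_error(build_histogram(c(100), "arrival"), "insufficient data")
  expect_error(build_histogram(c(100, 90), "arrival"), "strictly increasing")
  expect_error(build_histogram(c(100, 200), "arrival", cutoff = 0), "cutoff")
})

test_that("retained histogram mass equals an independent brute-force filter of the gap list", {
  set.seed(7)
  gaps <- stats::rexp(999, rate = 1 / 20)
  gaps <- pmax(gaps, 1e-6)
  ts <- cumsum(c(0, gaps)) + 1        # 1000 timestamps from 00:00
  h <- build_histogram(ts, "arrival", cutoff = 150)
  expect_equal(sum(h$counts), sum(gaps <= 150))
})

test_that("sample_delta draws from the hour-conditioned distribution", {
  # degenerate PMF: single occupied bin at hour 8, delta 10
  h <- hist_const(10, hours = 8, count = 5L)
  set.seed(1)
  expect_true(all(sample_delta(h, clock = 8 * 60 + 30, n = 50) == 10))

  # two-bin row with counts 1 and 3: frequencies within 3 sigma of 1/4, 3/4
  counts <- matrix(0L, 24, 150)
  counts[9, c(10, 20)] <- c(1L, 3L)
  h2 <- tod_histogram(counts, "arrival")
  set.seed(2)
  x <- sample_delta(h2, clock = 510, n = 10000)
  phat <- mean(x == 10)
  expect_lt(abs(phat - 0.25), 3 * sqrt(0.25 * 0.75 / 10000))

  # empty hour row falls back to the pooled distribution
  set.seed(3)
  y <- sample_delta(h2, clock = 3 * 60, n = 100)   # hour 3 has no mass
  expect_true(all(y %in% c(10, 20)))

  # an entirely empty histogram cannot be sampled
  h0 <- tod_histogram(matrix(0L, 24, 150), "arrival")
  expect_error(sample_delta(h0, 0), "empty distribution")
})

test_that("sampled deltas stay within the outlier cutoff and match row means", {
  h <- synth_histogram(timing_params(), "arrival")
  set.seed(4)
  x <- sample_delta(h, clock = 12 * 60, n = 1e5)
  expect_true(all(x >= 1 & x <= 150))

  # empirical mean within 3 standard errors of the row's analytic mean
  p <- h$counts[13, ] / sum(h$counts[13, ])
  mu <- sum(h$delta * p)
  sdv <- sqrt(sum(h$delta^2 * p) - mu^2)
  expect_lt(abs(mean(x) - mu), 3 * sdv / sqrt(1e5))
})

test_that("synth_histogram reflects day/night means and is deterministic", {
  p <- timing_params(day_mean_arrival_delta = 10, night_mean_arrival_delta = 30)
  h <- synth_histogram(p, "arrival")
  row_mean <- function(hst, hour) {
    w <- hst$counts[hour + 1, ]
    sum(hst$delta * w) / sum(w)
  }
  expect_lt(row_mean(h, 12), row_mean(h, 2))   # busier during the day

  # reporting rows share one mean; discretization bias stays below 5%
  pr <- timing_params(reporting_mean_delta = 15, reporting_dispersion = 0.5)
  hr <- synth_histogram(pr, "reporting")
  for (hour in c(0, 9, 23))
    expect_lt(abs(row_mean(hr, hour) - 15) / 15, 0.05)

  # deterministic construction: identical on repeated calls
  expect_identical(synth_histogram(p, "arrival"), synth_histogram(p, "arrival"))

  expect_error(timing_params(day_mean_arrival_delta = 20,
                             night_mean_arrival_delta = 10), "night")
  expect_error(timing_params(reporting_mean_delta = -1), "> 0")
})

test_that("gamma family rows hit the requested mean too", {
  p <- timing_params(reporting_mean_delta = 12, reporting_dispersion = 0.8,
                     distribution_family = "gamma")
  h <- synth_histogram(p, "reporting")
  w <- h$counts[1, ]
  expect_lt(abs(sum(h$delta * w) / sum(w) - 12) / 12, 0.05)
})

test_that("histogram CSV round-trips exactly", {
  h <- synth_histogram(timing_params(), "reporting")
  f <- withr::local_tempfile(fileext = ".csv")
  write_histogram_csv(h, f)
  h2 <- read_histogram_csv(f)
  expect_equal(h2$kind, h$kind)
  expect_equal(h2$counts, h$counts)
})

test_that("timestamp reader parses ISO-8601 lines", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("2020-01-01T08:00:00", "2020-01-01T08:05:30"), f)
  ts <- read_timestamps(f)
  expect_s3_class(ts, "POSIXct")
  expect_equal(as.numeric(diff(ts)), 5.5)
  writeLines(c("2020-01-01T08:00:00", "not-a-time"), f)
  expect_error(read_timestamps(f), "unparseable")
})

test_that("calibration hits the 80-minute hospital average and generalizes across seeds", {
  p <- calibrate_reporting_mean(80, n_days = 100, seed = 1234)
  expect_gte(attr(p, "achieved_rtat"), 72)
  expect_lte(attr(p, "achieved_rtat"), 88)

  # independent-seed rerun stays within 15% of the target
  cfg <- simulation_config("fifo", n_days = 100, seed = 987, timing = p)
  m <- mean(run_simulation(cfg)$records$rtat_min)
  expect_lt(abs(m - 80) / 80, 0.15)
})

test_that("calibration in the no-queue limit returns roughly the bare service time", {
  # arrivals far slower than service: turnaround ~ one service delta
  base <- timing_params(day_mean_arrival_delta = 120,
                        night_mean_arrival_delta = 140)
  p <- calibrate_reporting_mean(12, base_params = base, n_days = 60,
                                seed = 55, bracket = c(2, 30))
  expect_lt(abs(attr(p, "achieved_rtat") - 12) / 12, 0.10)
  # served on arrival: the calibrated service mean is close to the RTAT itself
  expect_lt(abs(p$reporting_mean_delta - 12), 4)
})

test_that("an unreachable calibration target reports a bracket failure", {
  expect_error(
    calibrate_reporting_mean(80, n_days = 20, seed = 9, bracket = c(1, 2)),
    "calibration failed")
})
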