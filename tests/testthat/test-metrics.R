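# RTAT summaries, Welch's t-test and the FPR sweep.

fake_sim <- function(rtat, labels, catalog = default_catalog()) {
  colnames(labels) <- catalog$name
  list(records = data.frame(rtat_min = rtat), true_labels = labels,
       catalog = catalog)
}

test_that("multi-finding exams contribute to every true class; label-free exams are normal", {
  cat <- default_catalog()
  lab <- matrix(FALSE, 1, 8)
  lab[1, c(1, 7)] <- TRUE                       # pneumothorax + mass
  s <- summarize_rtat(fake_sim(10, lab))
  expect_equal(s$n, c(1L, 0L, 0L, 0L, 0L, 0L, 1L, 0L, 0L))
  expect_equal(s$mean_min[c(1, 7)], c(10, 10))

  lab2 <- matrix(FALSE, 2, 8); lab2[, 3] <- TRUE
  s2 <- summarize_rtat(fake_sim(c(5, 15), lab2))
  i <- which(s2$class == "pleural_effusion")
  expect_equal(unlist(s2[i, c("mean_min", "median_min", "max_min")]),
               c(mean_min = 10, median_min = 10, max_min = 15))

  expect_error(summarize_rtat(fake_sim(numeric(0), matrix(FALSE, 0, 8))),
               "no exam records")
})

test_that("summaries equal an independent group-and-aggregate oracle", {
  set.seed(17)
  n <- 1000
  cat <- default_catalog()
  lab <- matrix(stats::runif(n * 8) < 0.25, n, 8)
  rtat <- stats::rexp(n, 1 / 50)
  s <- summarize_rtat(fake_sim(rtat, lab))
  for (k in 1:8) {
    x <- rtat[lab[, k]]
    expect_equal(s$n[k], length(x))
    expect_equal(s$mean_min[k], mean(x))
    expect_equal(s$median_min[k], stats::median(x))
    expect_equal(s$max_min[k], max(x))
  }
  # count conservation: classes overlap, normal counts the label-free exams
  expect_gte(sum(s$n), n)
  expect_equal(s$n[9], sum(rowSums(lab) == 0))
  expect_equal(sum(s$n), sum(lab) + sum(rowSums(lab) == 0))
})

test_that("welch_t matches the textbook formulas and stats::t.test", {
  w0 <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w0$t_statistic, 0)
  expect_equal(w0$p_value, 1)
  expect_false(w0$significant)

  a <- c(1, 2, 3, 4); b <- c(2, 4, 6, 8)
  w <- welch_t(a, b)
  # hand evaluation of the Welch formulas
  se2 <- var(a) / 4 + var(b) / 4
  t_ref <- (mean(a) - mean(b)) / sqrt(se2)
  df_ref <- se2^2 / ((var(a) / 4)^2 / 3 + (var(b) / 4)^2 / 3)
  expect_equal(w$t_statistic, t_ref)
  expect_equal(w$degrees_of_freedom, df_ref)
  expect_equal(w$p_value, 2 * stats::pt(-abs(t_ref), df_ref))

  expect_error(welch_t(1, c(1, 2)), "at least 2")

  set.seed(18)
  for (i in 1:100) {
    x <- stats::rnorm(sample(5:60, 1), sd = stats::runif(1, 0.5, 3))
    y <- stats::rnorm(sample(5:60, 1), mean = stats::runif(1, -1, 1))
    w <- welch_t(x, y)
    ref <- stats::t.test(x, y)      # Welch is t.test's default
    expect_equal(w$t_statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(w$degrees_of_freedom, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(w$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("welch_t p-values are uniform under the null", {
  set.seed(19)
  p <- replicate(200, welch_t(stats::rnorm(1e5), stats::rnorm(1e5))$p_value)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("an uninformative ROC model yields a flat sweep curve", {
  cat <- default_catalog()
  flat <- roc_model(cat$name, rep(0.5, 8))
  base <- simulation_config("prio", n_days = 60, seed = 23)
  sw <- fpr_sweep(base, roc = flat,
                  fpr_grid = c(0, 0.1, 0.5, 0.9, 1))
  # endpoints are exact FIFO; interior points differ only by sampling noise
  expect_equal(sw$mean_rtat_rank1[1], sw$mean_rtat_rank1[5])
  spread <- diff(range(sw$mean_rtat_rank1))
  expect_lt(spread / mean(sw$mean_rtat_rank1), 0.35)
})

test_that("sweep grids are validated", {
  base <- simulation_config("prio", n_days = 2, seed = 1)
  expect_error(fpr_sweep(base, fpr_grid = c(0, 0.5)), "endpoints")
  expect_error(fpr_sweep(base, fpr_grid = c(0, 0.5, 2)), "\\[0, 1\\]")
})
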