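# Report-turnaround-time summaries, Welch's t-test strategy comparisons,
# and the operating-point (FPR) sweep experiment.

#' Per-class report turnaround time summary
#'
#' An exam contributes to the class of every finding it truly carries (so
#' multi-finding exams appear in several rows); exams with no true finding
#' form the "normal" class.  Predictions never affect class membership.
#'
#' @param sim a `cxr_sim` result from [run_simulation()], or a list with a
#'   `records` data frame (column `rtat_min`) and a logical `true_labels`
#'   matrix.
#' @param catalog a [finding_catalog()]; defaults to the one in `sim`.
#' @return Data frame with one row per finding plus `"normal"`: columns
#'   `class`, `n`, `mean_min`, `median_min`, `max_min`.
#' @export
summarize_rtat <- function(sim, catalog = sim$catalog) {
  if (is.null(sim$records) || nrow(sim$records) == 0L)
    stop("no exam records to summarize")
  rtat <- sim$records$rtat_min
  labels <- sim$true_labels
  if (nrow(labels) != length(rtat)) stop("records and labels are not aligned")
  classes <- c(catalog$name, "normal")
  member <- cbind(labels, normal = rowSums(labels) == 0L)
  out <- data.frame(class = classes, n = integer(length(classes)),
                    mean_min = NA_real_, median_min = NA_real_,
                    max_min = NA_real_, stringsAsFactors = FALSE)
  for (j in seq_along(classes)) {
    x <- rtat[member[, j]]
    out$n[j] <- length(x)
    if (length(x)) {
      out$mean_min[j] <- mean(x)
      out$median_min[j] <- stats::median(x)
      out$max_min[j] <- max(x)
    }
  }
  out
}

#' Raw RTAT vectors per class
#'
#' Splits the turnaround times of a run by true class membership (one
#' vector per finding, plus `"normal"`), for paired strategy comparisons.
#' @inheritParams summarize_rtat
#' @return Named list of numeric vectors (minutes).
#' @export
rtat_by_class <- function(sim, catalog = sim$catalog) {
  rtat <- sim$records$rtat_min
  labels <- sim$true_labels
  out <- lapply(seq_len(nrow(catalog)), function(k) rtat[labels[, k]])
  names(out) <- catalog$name
  out$normal <- rtat[rowSums(labels) == 0L]
  out
}

#' Welch's unequal-variance two-sample t-test
#'
#' Location test for two independent samples without assuming equal
#' variances: `t = (mean_a - mean_b) / sqrt(s2_a/n_a + s2_b/n_b)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value.
#'
#' @param sample_a,sample_b numeric vectors of at least 2 values each, with
#'   nonzero variance in at least one.
#' @param alpha significance level for the `significant` flag.
#' @return An object of class `welch_result`: `t_statistic`,
#'   `degrees_of_freedom`, `p_value`, `significant`.
#' @export
welch_t <- function(sample_a, sample_b, alpha = 0.05) {
  na <- length(sample_a); nb <- length(sample_b)
  if (na < 2L || nb < 2L) stop("each sample needs at least 2 observations")
  va <- stats::var(sample_a); vb <- stats::var(sample_b)
  if (va == 0 && vb == 0 && mean(sample_a) != mean(sample_b))
    stop("both samples are degenerate with different means")
  se2 <- va / na + vb / nb
  if (se2 == 0) {
    t <- 0; df <- na + nb - 2; p <- 1
  } else {
    t <- (mean(sample_a) - mean(sample_b)) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    p <- 2 * stats::pt(-abs(t), df)
  }
  structure(list(t_statistic = t, degrees_of_freedom = df, p_value = p,
                 significant = p < alpha),
            class = "welch_result")
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("Welch t = %.4f, df = %.1f, p = %.4g%s\n",
              x$t_statistic, x$degrees_of_freedom, x$p_value,
              if (x$significant) " (significant)" else ""))
  invisible(x)
}

#' Per-class Welch comparison of two simulation runs
#'
#' @param sim_a,sim_b `cxr_sim` results sharing one catalog.
#' @return Data frame `class,t,df,p,significant`, one row per finding plus
#'   normal.
#' @export
compare_strategies <- function(sim_a, sim_b) {
  ca <- rtat_by_class(sim_a); cb <- rtat_by_class(sim_b)
  stopifnot(identical(names(ca), names(cb)))
  rows <- lapply(names(ca), function(cl) {
    w <- welch_t(ca[[cl]], cb[[cl]])
    data.frame(class = cl, t = w$t_statistic, df = w$degrees_of_freedom,
               p = w$p_value, significant = w$significant,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Default FPR grid for the operating-point sweep
#'
#' Log-ish spacing, denser near the low-FPR region where the optimum for
#' mean turnaround reduction sits.
#' @export
default_fpr_grid <- function()
  c(0, 0.01, 0.025, 0.05, 0.1, 0.2, 0.4, 0.6, 0.8, 1.0)

#' Sweep the common classifier FPR and measure most-urgent-class RTAT
#'
#' For each grid FPR, builds a common-FPR operating point from the ROC
#' surrogate, runs a `prio` simulation with the base configuration's seeds
#' (common random numbers across grid points), and records the mean RTAT of
#' exams truly carrying the rank-1 finding.  At FPR 0 every prediction is
#' negative and at FPR 1 every prediction is positive, so both endpoints
#' collapse to FIFO behavior.
#'
#' @param base_config a [simulation_config()]; its strategy is overridden
#'   to `"prio"` at each grid point.
#' @param roc a [roc_model()].
#' @param fpr_grid probabilities in [0, 1]; must include both endpoints 0
#'   and 1.
#' @return Data frame `fpr, mean_rtat_rank1, n` with attribute
#'   `argmin_fpr`, the grid FPR minimizing the mean.
#' @export
fpr_sweep <- function(base_config, roc = default_roc(base_config$catalog),
                      fpr_grid = default_fpr_grid()) {
  stopifnot(inherits(base_config, "simulation_config"), inherits(roc, "roc_model"))
  if (any(fpr_grid < 0 | fpr_grid > 1)) stop("fpr grid values must lie in [0, 1]")
  if (!(0 %in% fpr_grid && 1 %in% fpr_grid))
    stop("fpr grid must include the endpoints 0 and 1")
  fpr_grid <- sort(unique(fpr_grid))
  res <- lapply(fpr_grid, function(f) {
    cfg <- base_config
    cfg$strategy <- "prio"
    cfg$operating_point <- operating_point_from_fpr(roc, f)
    sim <- run_simulation(cfg)
    x <- rtat_by_class(sim)[[1L]]      # catalog is rank-ordered; rank-1 first
    c(mean = mean(x), n = length(x))
  })
  out <- data.frame(fpr = fpr_grid,
                    mean_rtat_rank1 = vapply(res, `[[`, numeric(1), "mean"),
                    n = vapply(res, `[[`, numeric(1), "n"))
  attr(out, "argmin_fpr") <- out$fpr[which.min(out$mean_rtat_rank1)]
  out
}
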