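# Stochastic model of the multi-label image classifier: per-finding binary
# predictions governed by (TPR, FPR) operating points, plus an
# equal-variance binormal ROC surrogate for operating-point sweeps.

#' Construct a per-finding operating point
#'
#' @param finding character vector of finding names (catalog order).
#' @param tpr,fpr per-finding true/false positive rates in [0, 1].
#' @return A data frame of class `operating_point` with derived `fnr`/`tnr`.
#' @export
operating_point <- function(finding, tpr, fpr) {
  if (length(finding) != length(tpr) || length(finding) != length(fpr))
    stop("finding, tpr and fpr must have equal length")
  if (any(tpr < 0 | tpr > 1 | fpr < 0 | fpr > 1))
    stop("rates must lie in [0, 1]")
  structure(data.frame(finding = as.character(finding), tpr = as.numeric(tpr),
                       fpr = as.numeric(fpr), fnr = 1 - tpr, tnr = 1 - fpr,
                       stringsAsFactors = FALSE),
            class = c("operating_point", "data.frame"))
}

# Published operating points of the classifier on the eight findings:
# "lowFPR" fixes FPR = 0.05 for every finding (the sweep optimum for mean
# turnaround), "lowFNR" fixes TPR = 0.95 (guards against missed urgent
# findings at the price of many false alarms).
op_preset_table <- function() {
  list(
    lowFPR = list(tpr = c(0.82, 0.71, 0.86, 0.75, 0.61, 0.75, 0.51, 0.51),
                  fpr = rep(0.05, 8L)),
    lowFNR = list(tpr = rep(0.95, 8L),
                  fpr = c(0.20, 0.24, 0.21, 0.27, 0.39, 0.18, 0.72, 0.78)))
}

#' Bundled classifier operating points
#'
#' @param name `"lowFPR"` (every finding thresholded at FPR 0.05) or
#'   `"lowFNR"` (every finding thresholded at TPR 0.95).
#' @param catalog the [finding_catalog()] the rates refer to (default
#'   catalog order).
#' @return An [operating_point()].
#' @export
op_preset <- function(name = c("lowFPR", "lowFNR"), catalog = default_catalog()) {
  name <- match.arg(name)
  tab <- op_preset_table()[[name]]
  if (nrow(catalog) != length(tab$tpr))
    stop("presets are defined for the default 8-finding catalog")
  operating_point(catalog$name, tab$tpr, tab$fpr)
}

#' Perfect classifier (upper bound on prioritization benefit)
#' @param catalog a [finding_catalog()].
#' @return An [operating_point()] with TPR 1 and FPR 0 for every finding.
#' @export
op_perfect <- function(catalog = default_catalog())
  operating_point(catalog$name, rep(1, nrow(catalog)), rep(0, nrow(catalog)))

#' Simulate classifier predictions for ground-truth labels
#'
#' Per finding, independently of other findings and of arrival time: a
#' truly positive finding is predicted positive with probability `tpr`, a
#' truly negative one with probability `fpr`.
#'
#' @param labels logical n-by-K truth matrix (or length-K vector).
#' @param op an [operating_point()] aligned with the label columns.
#' @return Logical matrix of predicted labels, same shape as `labels`.
#'   Uses the current R random stream.
#' @export
sample_prediction <- function(labels, op) {
  stopifnot(inherits(op, "operating_point"))
  if (is.vector(labels)) labels <- matrix(labels, nrow = 1L)
  if (ncol(labels) != nrow(op))
    stop("labels and operating point are not aligned")
  n <- nrow(labels)
  p <- matrix(op$fpr, n, nrow(op), byrow = TRUE)
  p[labels] <- matrix(op$tpr, n, nrow(op), byrow = TRUE)[labels]
  out <- matrix(stats::runif(length(p)), n, ncol(labels)) < p
  colnames(out) <- colnames(labels)
  out
}

#' TPR at a given FPR under the equal-variance binormal ROC model
#'
#' The surrogate ROC family is the equal-variance binormal curve
#' `tpr = pnorm(mu + qnorm(fpr))` with separation `mu = sqrt(2) * qnorm(auc)`,
#' the standard one-parameter curve matched to a scalar AUC.  Endpoints are
#' fixed at `tpr(0) = 0`, `tpr(1) = 1` by continuity.
#'
#' @param auc area under the ROC curve, in [0.5, 1].
#' @param fpr false positive rate(s), in [0, 1].
#' @return TPR value(s); vectorized over `fpr` and `auc`.
#' @export
tpr_at_fpr <- function(auc, fpr) {
  if (any(auc < 0.5 | auc > 1)) stop("auc must lie in [0.5, 1]")
  if (any(fpr < 0 | fpr > 1)) stop("fpr must lie in [0, 1]")
  mu <- sqrt(2) * stats::qnorm(auc)
  out <- stats::pnorm(mu + stats::qnorm(fpr))
  out[fpr == 0] <- 0
  out[fpr == 1] <- 1
  out
}

#' Per-finding ROC surrogate model
#'
#' @param finding character vector of finding names.
#' @param auc per-finding AUC values in [0.5, 1].
#' @return A data frame of class `roc_model`.
#' @export
roc_model <- function(finding, auc) {
  if (length(finding) != length(auc)) stop("finding and auc must have equal length")
  if (any(auc < 0.5 | auc > 1)) stop("auc must lie in [0.5, 1]")
  structure(data.frame(finding = as.character(finding), auc = as.numeric(auc),
                       stringsAsFactors = FALSE),
            class = c("roc_model", "data.frame"))
}

#' Default ROC model implied by the bundled operating points
#'
#' Each bundled preset pins one point of a finding's ROC curve.  Inverting
#' the equal-variance binormal model at both points gives two estimates of
#' the separation `mu = qnorm(tpr) - qnorm(fpr)`; their average is converted
#' back to an AUC via `auc = pnorm(mu / sqrt(2))`.  No AUC constants are
#' hard-coded: the model is derived from the operating-point tables.
#'
#' @param catalog a [finding_catalog()] (default 8-finding catalog).
#' @return A [roc_model()].
#' @export
default_roc <- function(catalog = default_catalog()) {
  tab <- op_preset_table()
  mu1 <- stats::qnorm(tab$lowFPR$tpr) - stats::qnorm(tab$lowFPR$fpr)
  mu2 <- stats::qnorm(tab$lowFNR$tpr) - stats::qnorm(tab$lowFNR$fpr)
  roc_model(catalog$name, stats::pnorm((mu1 + mu2) / 2 / sqrt(2)))
}

#' Operating point obtained by thresholding every finding at a common FPR
#'
#' Applies one FPR to all findings and derives each finding's TPR from its
#' AUC via [tpr_at_fpr()]; used by the FPR sweep experiment.
#'
#' @param roc a [roc_model()].
#' @param fpr common false positive rate in [0, 1].
#' @return An [operating_point()].
#' @export
operating_point_from_fpr <- function(roc, fpr) {
  stopifnot(inherits(roc, "roc_model"), length(fpr) == 1L)
  operating_point(roc$finding, tpr_at_fpr(roc$auc, fpr), rep(fpr, nrow(roc)))
}

#' Read an operating point / ROC model from CSV
#'
#' Operating-point files have columns `finding,tpr,fpr`; ROC files have
#' `finding,auc`.
#' @param path CSV file path.
#' @export
read_operating_point_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("finding", "tpr", "fpr") %in% names(df)))
    stop("operating-point CSV must have columns finding,tpr,fpr")
  operating_point(df$finding, df$tpr, df$fpr)
}

#' @rdname read_operating_point_csv
#' @export
read_roc_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("finding", "auc") %in% names(df)))
    stop("ROC CSV must have columns finding,auc")
  roc_model(df$finding, df$auc)
}
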