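# Per-subject slope summaries: rank-based inverse normal transformation,
# residualization against the predicted normal-aging slope, and diagnosis
# group contrasts.

#' Rank-based inverse normal transformation
#'
#' Maps values to normal quantiles through their ranks:
#' `qnorm((r - k) / (n - 2k + 1))` with offset `k` (Blom's 3/8 by default)
#' and average ranks for ties — deterministic and strictly monotone in the
#' input ranks. The standard normalization applied to the slope and age
#' phenotypes before association.
#'
#' @param values Numeric vector, at least 2 finite values. `NA`s are
#'   propagated; ranks are computed among non-missing values.
#' @param offset Rank offset `k` in `[0, 0.5]`.
#' @return Transformed vector of the same length.
#' @export
inverse_normal_transform <- function(values, offset = 3 / 8) {
  ok <- !is.na(values)
  x <- values[ok]
  if (length(x) < 2) stop_config("need at least 2 finite values")
  if (length(unique(x)) == 1)
    stop_config("all values identical: ranks are degenerate")
  n <- length(x)
  r <- rank(x, ties.method = "average")
  out <- values
  out[ok] <- stats::qnorm((r - offset) / (n - 2 * offset + 1))
  out
}

#' Accelerated cognitive decline slope as a regression residual
#'
#' Residualizes the (inverse-normal transformed) measured slope on the
#' transformed model-predicted normal-aging slope, plus optional covariates,
#' by ordinary least squares. What is left over — decline not explained by
#' normal aging — is the accelerated cognitive decline slope used as the
#' association phenotype. Residuals are orthogonal to every regressor.
#'
#' @param measured Per-subject median measured slopes, points/year.
#' @param predicted Per-subject median predicted aging slopes, points/year.
#' @param covariates Optional numeric matrix/data.frame of extra regressors.
#' @param transform Apply [inverse_normal_transform()] to both slope vectors
#'   first (default `TRUE`).
#' @return Numeric residual vector (transformed units when `transform`).
#' @export
accelerated_slope_residuals <- function(measured, predicted,
                                        covariates = NULL, transform = TRUE) {
  if (length(measured) != length(predicted))
    stop_config("measured and predicted lengths differ")
  y <- if (transform) inverse_normal_transform(measured) else measured
  p <- if (transform) inverse_normal_transform(predicted) else predicted
  X <- cbind(intercept = 1, predicted = p)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != length(measured))
      stop_config("covariates rows must match length of measured")
    X <- cbind(X, covariates)
  }
  qr_X <- qr(X)
  if (qr_X$rank < ncol(X)) stop_config("rank-deficient design matrix")
  as.numeric(stats::lm.fit(X, y)$residuals)
}

#' Per-diagnosis slope distributions and pairwise rank-sum tests
#'
#' Summarises a slope (or residual) by diagnosis group — median, IQR, n —
#' and runs a two-sided Wilcoxon rank-sum test for every group pair (exact
#' when sample sizes permit and there are no ties).
#'
#' @param values Numeric vector.
#' @param group Factor/character group labels aligned with `values`; groups
#'   with fewer than 2 records are an error.
#' @return List with `summary` (data.frame: group, n, median, q25, q75) and
#'   `tests` (data.frame: group1, group2, p).
#' @export
group_summaries <- function(values, group) {
  group <- as.character(group)
  stopifnot(length(values) == length(group))
  sp <- split(values, group)
  if (length(sp) < 2) stop_config("need at least 2 groups")
  ns <- vapply(sp, length, integer(1))
  if (any(ns < 2)) stop_config("every group needs at least 2 records")
  summ <- data.frame(
    group = names(sp), n = ns,
    median = vapply(sp, stats::median, numeric(1)),
    q25 = vapply(sp, function(v) unname(stats::quantile(v, 0.25)), numeric(1)),
    q75 = vapply(sp, function(v) unname(stats::quantile(v, 0.75)), numeric(1)),
    stringsAsFactors = FALSE)
  rownames(summ) <- NULL
  combos <- utils::combn(names(sp), 2)
  tests <- data.frame(
    group1 = combos[1, ], group2 = combos[2, ],
    p = apply(combos, 2, function(gg) {
      suppressWarnings(stats::wilcox.test(sp[[gg[1]]], sp[[gg[2]]],
                                          alternative = "two.sided")$p.value)
    }),
    stringsAsFactors = FALSE)
  list(summary = summ, tests = tests)
}

#' Assemble per-subject slope records
#'
#' Joins the median measured and median predicted pair slopes with subject
#' covariates and attaches the accelerated slope residual. This is the
#' phenotype table consumed by the association scan.
#'
#' @param predicted_pairs Pair frame with `predicted_slope` (output of
#'   [predict.siamese_net()]).
#' @param visits Visit table with `subject_id, sex, age_years, diagnosis`.
#' @param covariates Optional extra per-subject covariate matrix for the
#'   residualization (rows aligned with the retained subjects).
#' @return data.frame of class `slope_records`: `subject_id,
#'   median_measured_slope, median_predicted_slope, accelerated_slope, sex,
#'   median_age_years, diagnosis`.
#' @export
slope_records <- function(predicted_pairs, visits, covariates = NULL) {
  meas <- median_subject_slope(predicted_pairs, "slope")
  pred <- median_subject_slope(predicted_pairs, "predicted_slope")
  stopifnot(identical(meas$subject_id, pred$subject_id))
  vs <- split(visits, visits$subject_id)
  idx <- match(meas$subject_id, names(vs))
  if (anyNA(idx)) stop_config("pair subjects missing from visit table")
  out <- data.frame(
    subject_id = meas$subject_id,
    median_measured_slope = meas$median_slope,
    median_predicted_slope = pred$median_slope,
    sex = vapply(vs[idx], function(s) s$sex[1], numeric(1)),
    median_age_years = vapply(vs[idx], function(s) stats::median(s$age_years),
                              numeric(1)),
    diagnosis = vapply(vs[idx], function(s) s$diagnosis[1], character(1)),
    stringsAsFactors = FALSE)
  out$accelerated_slope <- accelerated_slope_residuals(
    out$median_measured_slope, out$median_predicted_slope,
    covariates = covariates)
  rownames(out) <- NULL
  class(out) <- c("slope_records", "data.frame")
  out
}
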