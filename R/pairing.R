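# Cohort pairing: link cognitive scores to scans, apply inclusion rules,
# enumerate longitudinal pairs with labels and measured slopes.

DX_LEVELS <- c("CN", "MCI", "AD")

#' Match cognitive assessments to imaging scans within a day window
#'
#' Each score row is linked to at most one scan of the same subject: the
#' nearest in time within `window_days` (default 45 days). Ties are broken in
#' favour of the earlier scan. Unmatched rows are dropped; their count is
#' attached as attribute `n_unmatched`.
#'
#' @param visits data.frame with at least `subject_id, visit_day, adas13`
#'   (plus any extra columns, carried through).
#' @param scans data.frame with `subject_id, scan_day, scan_id`.
#' @param window_days Maximum |score day - scan day| allowed.
#' @return The matched visit table with `scan_id, scan_day, match_gap_days`
#'   columns appended.
#' @export
match_scores_to_scans <- function(visits, scans, window_days = 45) {
  stopifnot(all(c("subject_id", "visit_day") %in% names(visits)),
            all(c("subject_id", "scan_day", "scan_id") %in% names(scans)))
  if (anyDuplicated(visits[c("subject_id", "visit_day")]))
    stop_config("duplicate (subject_id, visit_day) keys in visits")
  if (anyDuplicated(scans[c("subject_id", "scan_day")]))
    stop_config("duplicate (subject_id, scan_day) keys in scans")
  out <- visits
  out$scan_id <- NA_character_
  out$scan_day <- NA_real_
  out$match_gap_days <- NA_real_
  for (k in seq_len(nrow(visits))) {
    cand <- scans[scans$subject_id == visits$subject_id[k], , drop = FALSE]
    if (nrow(cand) == 0) next
    gap <- abs(cand$scan_day - visits$visit_day[k])
    ok <- gap <= window_days
    if (!any(ok)) next
    cand <- cand[ok, , drop = FALSE]
    gap <- gap[ok]
    # nearest scan; tie -> earlier scan day
    best <- order(gap, cand$scan_day)[1]
    out$scan_id[k] <- cand$scan_id[best]
    out$scan_day[k] <- cand$scan_day[best]
    out$match_gap_days[k] <- gap[best]
  }
  matched <- out[!is.na(out$scan_id), , drop = FALSE]
  rownames(matched) <- NULL
  attr(matched, "n_unmatched") <- nrow(out) - nrow(matched)
  matched
}

#' Apply the longitudinal inclusion rules
#'
#' Keeps subjects with at least `min_visits` matched visits (default 3, i.e.
#' "more than two data points") whose diagnosis sequence, in time order,
#' never moves backward along CN -> MCI -> AD (stable or forward transitions
#' only).
#'
#' @param matched Matched visit table (needs `subject_id, visit_day,
#'   diagnosis`).
#' @param min_visits Minimum matched visits per retained subject.
#' @param require_monotone_dx Enforce the forward-transition rule.
#' @return The retained subset, sorted by subject and day.
#' @export
filter_subjects <- function(matched, min_visits = 3, require_monotone_dx = TRUE) {
  stopifnot(all(c("subject_id", "visit_day", "diagnosis") %in% names(matched)))
  bad <- setdiff(unique(matched$diagnosis), DX_LEVELS)
  if (length(bad) > 0)
    stop_config("unknown diagnosis label(s): %s", paste(bad, collapse = ", "))
  m <- matched[order(matched$subject_id, matched$visit_day), , drop = FALSE]
  keep_subj <- vapply(split(m, m$subject_id), function(s) {
    if (nrow(s) < min_visits) return(FALSE)
    if (require_monotone_dx) {
      code <- match(s$diagnosis, DX_LEVELS)
      if (is.unsorted(code)) return(FALSE)
    }
    TRUE
  }, logical(1))
  out <- m[m$subject_id %in% names(keep_subj)[keep_subj], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enumerate longitudinal visit pairs within a time-gap window
#'
#' All ordered visit combinations (i < j) per subject, adjacent or not, whose
#' gap lies in `[min_gap_months, max_gap_months]` (inclusive; one month is
#' 30.4375 days). Output is sorted by (subject, first day, second day).
#'
#' @param matched Filtered matched visit table.
#' @param min_gap_months,max_gap_months Gap window in months.
#' @param change_threshold Absolute score change (points) at or above which a
#'   pair is labelled different-class (`label = 1`); see [label_pair()].
#' @return data.frame of class `visit_pairs`: `subject_id, day_i, day_j,
#'   scan_i, scan_j, score_i, score_j, dt_years, dscore, slope, label`.
#' @export
build_pairs <- function(matched, min_gap_months = 6, max_gap_months = 24,
                        change_threshold = 4) {
  if (min_gap_months >= max_gap_months)
    stop_config("min_gap_months must be < max_gap_months")
  m <- matched[order(matched$subject_id, matched$visit_day), , drop = FALSE]
  lo <- min_gap_months * DAYS_PER_MONTH
  hi <- max_gap_months * DAYS_PER_MONTH
  res <- lapply(split(m, m$subject_id), function(s) {
    nv <- nrow(s)
    if (nv < 2) return(NULL)
    ij <- which(upper.tri(matrix(0, nv, nv)), arr.ind = TRUE)
    gap <- s$visit_day[ij[, 2]] - s$visit_day[ij[, 1]]
    ok <- gap >= lo - 1e-9 & gap <= hi + 1e-9
    if (!any(ok)) return(NULL)
    ij <- ij[ok, , drop = FALSE]
    i <- ij[, 1]; j <- ij[, 2]
    dt <- (s$visit_day[j] - s$visit_day[i]) / DAYS_PER_YEAR
    ds <- s$adas13[j] - s$adas13[i]
    data.frame(
      subject_id = s$subject_id[1],
      day_i = s$visit_day[i], day_j = s$visit_day[j],
      scan_i = if ("scan_id" %in% names(s)) s$scan_id[i] else NA_character_,
      scan_j = if ("scan_id" %in% names(s)) s$scan_id[j] else NA_character_,
      score_i = s$adas13[i], score_j = s$adas13[j],
      dt_years = dt, dscore = ds, slope = ds / dt,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(subject_id = character(), day_i = numeric(),
                      day_j = numeric(), scan_i = character(),
                      scan_j = character(), score_i = numeric(),
                      score_j = numeric(), dt_years = numeric(),
                      dscore = numeric(), slope = numeric(),
                      stringsAsFactors = FALSE)
  out <- out[order(out$subject_id, out$day_i, out$day_j), , drop = FALSE]
  out$label <- label_pair(out$dscore, change_threshold)
  rownames(out) <- NULL
  class(out) <- c("visit_pairs", "data.frame")
  out
}

#' Same/different-class label for a pair from its score change
#'
#' `Y = 1` (different class, significant cognitive change) iff
#' `|delta_score| >= change_threshold`, else `Y = 0`. The default threshold of
#' 4 ADAS-Cog13 points is a commonly used clinically meaningful change.
#'
#' @param dscore Score change(s), second minus first visit.
#' @param change_threshold Non-negative threshold in points.
#' @return Integer vector of 0/1 labels.
#' @export
label_pair <- function(dscore, change_threshold = 4) {
  if (change_threshold < 0) stop_config("change_threshold must be >= 0")
  as.integer(abs(dscore) >= change_threshold)
}

#' Measured cognitive decline slope of a pair
#'
#' Score change divided by the time gap, in points per year.
#'
#' @param dscore Score change (points).
#' @param dt_years Positive time gap (years).
#' @return Slope(s), points/year.
#' @export
measured_slope <- function(dscore, dt_years) {
  if (any(dt_years <= 0)) stop_config("dt_years must be > 0")
  dscore / dt_years
}

#' Per-subject median of pair slopes
#'
#' The summary used as the association outcome: the median over a subject's
#' pair slopes, with the even-count median taken as the mean of the two
#' central values ([stats::median()] convention).
#'
#' @param values Numeric vector (at least one finite value), or a
#'   `visit_pairs` frame in which case medians are computed per subject.
#' @param column Which pair column to summarise when `values` is a frame.
#' @return A single median, or a data.frame `subject_id, median_slope`.
#' @export
median_subject_slope <- function(values, column = "slope") {
  if (is.data.frame(values)) {
    sp <- split(values[[column]], values$subject_id)
    out <- data.frame(subject_id = names(sp),
                      median_slope = vapply(sp, median_subject_slope, numeric(1)),
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    return(out)
  }
  if (length(values) < 1 || all(is.na(values)))
    stop_config("median_subject_slope needs at least one value")
  stats::median(values, na.rm = TRUE)
}
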