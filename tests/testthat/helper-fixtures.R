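# Shared fixtures and independent oracles used across test files.

# Visit table -> scan table (one scan per visit, same day).
scans_of <- function(visits) {
  data.frame(subject_id = visits$subject_id, scan_day = visits$visit_day,
             scan_id = visits$scan_id, stringsAsFactors = FALSE)
}

# Matched visit table straight from a simulated cohort.
matched_of <- function(cohort, window = 45) {
  v <- cohort$visits
  match_scores_to_scans(v[setdiff(names(v), "scan_id")], scans_of(v), window)
}

# Hand-built visit table from per-subject day/score/dx vectors.
visit_table <- function(days, scores = NULL, dx = "CN", subject = "S1") {
  scores <- scores %||% rep(10, length(days))
  data.frame(subject_id = subject, visit_day = days,
             age_years = 70 + days / 365.25, sex = 0,
             diagnosis = rep(dx, length.out = length(days)),
             adas13 = scores, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force pair enumeration oracle: all i < j with the gap predicate.
oracle_pairs <- function(visits, min_m = 6, max_m = 24) {
  lo <- min_m * 30.4375; hi <- max_m * 30.4375
  out <- list()
  for (sid in sort(unique(visits$subject_id))) {
    s <- visits[visits$subject_id == sid, ]
    s <- s[order(s$visit_day), ]
    n <- nrow(s)
    if (n < 2) next
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      gap <- s$visit_day[j] - s$visit_day[i]
      if (gap >= lo - 1e-9 && gap <= hi + 1e-9)
        out[[length(out) + 1]] <- data.frame(
          subject_id = sid, day_i = s$visit_day[i], day_j = s$visit_day[j],
          stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(subject_id = character(), day_i = numeric(),
                      day_j = numeric()))
  do.call(rbind, out)
}

# Brute-force subject filter oracle.
oracle_filter <- function(visits, min_visits = 3) {
  code <- c(CN = 1, MCI = 2, AD = 3)
  keep <- vapply(split(visits, visits$subject_id), function(s) {
    s <- s[order(s$visit_day), ]
    nrow(s) >= min_visits && !is.unsorted(code[s$diagnosis])
  }, logical(1))
  sort(names(keep)[keep])
}

# Random small cohort for pairing property tests: up to 12 visits on a random
# day grid, random diagnosis sequences (possibly non-monotone).
random_pairing_cohort <- function(n_subjects = 6) {
  rows <- lapply(seq_len(n_subjects), function(i) {
    nv <- sample(1:12, 1)
    days <- sort(sample(0:1500, nv))
    visit_table(days, scores = runif(nv, 0, 60),
                dx = sample(c("CN", "MCI", "AD"), nv, replace = TRUE),
                subject = sprintf("R%02d", i))
  })
  do.call(rbind, rows)
}

# Direct-formula HWE enumeration oracle (independent of the package's
# recursion-free implementation path).
oracle_hwe <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  na <- nAa + 2 * naa
  hets <- seq(na %% 2, min(na, 2 * n - na), by = 2)
  pr <- vapply(hets, function(h) {
    n2 <- (na - h) / 2; n0 <- n - h - n2
    exp(lfactorial(n) - lfactorial(n0) - lfactorial(h) - lfactorial(n2) +
          h * log(2) + lfactorial(na) + lfactorial(2 * n - na) -
          lfactorial(2 * n))
  }, numeric(1))
  pobs <- pr[match(nAa, hets)]
  min(1, sum(pr[pr <= pobs * (1 + 1e-12)]))
}

# Build a genotype_set from a raw dosage matrix.
gs_of <- function(D, chr = "1", pos = NULL, info = NULL) {
  m <- ncol(D)
  v <- data.frame(id = sprintf("v%04d", seq_len(m)), chr = chr,
                  pos = pos %||% (seq_len(m) * 1000L), ref = "A", alt = "G",
                  stringsAsFactors = FALSE)
  colnames(D) <- v$id
  if (is.null(rownames(D))) rownames(D) <- sprintf("I%04d", seq_len(nrow(D)))
  genotype_set(D, v, info = info)
}

# The noise-controlled recovery cohort and mini-training configuration used
# by the parameter-recovery checks.
recovery_rho <- function(seed, epochs = 30) {
  cfg <- sim_config(n_subjects = 60, score_noise_sd = 0, volume_noise_sd = 0,
                    acceleration_sd = 0, seed = seed)
  co <- simulate_cohort(cfg)
  pairs <- build_pairs(filter_subjects(matched_of(co)))
  ctl <- siamese_control(learning_rate = 1e-3, epochs = epochs,
                         decay_factor = 0.5,
                         seed = derive_seed(seed, "train"))
  fit <- fit_siamese(pairs, co$scans, ctl)
  preds <- predict(fit, pairs, co$scans)
  val <- preds[preds$subject_id %in% fit$split$val, ]
  med <- median_subject_slope(val, "predicted_slope")
  truth <- co$truth$subjects
  stats::cor(med$median_slope,
             truth$aging_slope[match(med$subject_id, truth$subject_id)],
             method = "spearman")
}
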