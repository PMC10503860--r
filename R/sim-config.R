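#' Configuration for the synthetic longitudinal cohort generator
#'
#' Bundles every knob of the simulator: cohort size and visit schedule,
#' phantom volume geometry and intensity encoding, cognitive-trajectory
#' parameters, and the genotype model. Defaults describe a compact cohort
#' (60 subjects, 32^3 phantoms) whose per-subject trajectories follow
#' `score(t) = baseline + (aging_slope + acceleration) * t + noise`, with
#' scores clipped to the 0-85 range of the ADAS-Cog13 battery and slopes in
#' points per year (time is stored in days; a year is 365.25 days).
#'
#' @param n_subjects Number of subjects.
#' @param visits_per_subject Integer range `c(min, max)`; each subject's visit
#'   count is drawn uniformly from it.
#' @param visit_interval_days Mean and jitter sd (days) between consecutive
#'   visits, as `c(mean, sd)`. Roughly semi-annual by default.
#' @param volume_shape Three positive integers, the phantom dimensions.
#' @param aging_region,disease_region Integer vectors of linear voxel indices.
#'   Must be disjoint. `NULL` places two disjoint default cuboids.
#' @param aging_slope_dist `c(mean, sd)` of the per-subject normal-aging slope,
#'   ADAS points per year.
#' @param acceleration_sd Residual sd (points/year) of the disease-acceleration
#'   component on top of genetic effects.
#' @param score_noise_sd Per-visit observation noise on the score, points.
#' @param volume_noise_sd Additive Gaussian intensity noise in the phantom.
#' @param baseline_dist `c(mean, sd)` of the baseline score, points.
#' @param age_range Baseline age range in years, drawn uniformly.
#' @param n_snps Number of simulated variants.
#' @param maf_range `c(lo, hi)`, minor-allele-frequency range, subset of
#'   (0, 0.5].
#' @param causal_snps List of `list(index =, beta =)` entries: variant index
#'   and its additive effect on the acceleration, points/year per ALT allele.
#' @param ld_block `c(length, copy_prob)`: variants come in consecutive blocks
#'   of `length`; within a block each haplotype allele is copied from the
#'   previous variant with probability `copy_prob`, inducing LD.
#' @param dx_cutpoints Two probabilities; tertile-style cut points of the true
#'   acceleration that assign CN / MCI / AD diagnoses in simulation.
#' @param intensity Named numeric vector with the phantom intensity encoding:
#'   `aging_intercept`, `aging_slope` (per score point), `disease_intercept`,
#'   `disease_slope`, `background`, `rim`. The phantom keeps near-0 air and a
#'   near-1 bright rim in every volume so per-volume min-max scaling is a
#'   near-identity map.
#' @param seed Integer; the single seed all stages derive from.
#' @return An object of class `sim_config`.
#' @seealso [simulate_cohort()], [render_volume()], [simulate_genotypes()]
#' @export
sim_config <- function(n_subjects = 60,
                       visits_per_subject = c(3, 6),
                       visit_interval_days = c(mean = 183, sd = 14),
                       volume_shape = c(32, 32, 32),
                       aging_region = NULL,
                       disease_region = NULL,
                       aging_slope_dist = c(mean = 1.5, sd = 1),
                       acceleration_sd = 1,
                       score_noise_sd = 1,
                       volume_noise_sd = 0.02,
                       baseline_dist = c(mean = 12, sd = 4),
                       age_range = c(55, 91),
                       n_snps = 100,
                       maf_range = c(0.05, 0.5),
                       causal_snps = list(),
                       ld_block = c(length = 1, copy_prob = 0),
                       dx_cutpoints = c(1 / 3, 2 / 3),
                       intensity = c(aging_intercept = 0.8,
                                     aging_slope = -0.006,
                                     disease_intercept = 0.6,
                                     disease_slope = -0.006,
                                     background = 0,
                                     rim = 1),
                       seed = 1L) {
  volume_shape <- as.integer(volume_shape)
  if (length(volume_shape) != 3 || any(volume_shape < 2))
    stop_config("volume_shape must be 3 integers >= 2")
  if (is.null(aging_region))
    aging_region <- cuboid_region(volume_shape, c(0.15, 0.40))
  if (is.null(disease_region))
    disease_region <- cuboid_region(volume_shape, c(0.60, 0.85))
  nvox <- prod(volume_shape)
  if (any(aging_region < 1 | aging_region > nvox) ||
      any(disease_region < 1 | disease_region > nvox))
    stop_config("region indices outside volume_shape")
  if (length(intersect(aging_region, disease_region)) > 0)
    stop_config("aging_region and disease_region must be disjoint")
  if (any(c(acceleration_sd, score_noise_sd, volume_noise_sd,
            aging_slope_dist[2], baseline_dist[2],
            visit_interval_days[2]) < 0))
    stop_config("standard deviations must be >= 0")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop_config("maf_range must lie within (0, 0.5]")
  if (length(visits_per_subject) != 2 ||
      visits_per_subject[1] < 1 ||
      visits_per_subject[1] > visits_per_subject[2])
    stop_config("visits_per_subject must be an increasing integer range")
  for (cs in causal_snps) {
    if (is.null(cs$index) || is.null(cs$beta) ||
        cs$index < 1 || cs$index > n_snps)
      stop_config("causal_snps entries need index (within 1..n_snps) and beta")
  }
  if (ld_block[["length"]] < 1 ||
      ld_block[["copy_prob"]] < 0 || ld_block[["copy_prob"]] > 1)
    stop_config("ld_block needs length >= 1 and copy_prob in [0, 1]")
  structure(list(
    n_subjects = as.integer(n_subjects),
    visits_per_subject = as.integer(visits_per_subject),
    visit_interval_days = visit_interval_days,
    volume_shape = volume_shape,
    aging_region = as.integer(aging_region),
    disease_region = as.integer(disease_region),
    aging_slope_dist = aging_slope_dist,
    acceleration_sd = acceleration_sd,
    score_noise_sd = score_noise_sd,
    volume_noise_sd = volume_noise_sd,
    baseline_dist = baseline_dist,
    age_range = age_range,
    n_snps = as.integer(n_snps),
    maf_range = maf_range,
    causal_snps = causal_snps,
    ld_block = ld_block,
    dx_cutpoints = dx_cutpoints,
    intensity = intensity,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Linear indices of an axis-aligned cuboid spanning the given fractional
# range of each dimension.
cuboid_region <- function(shape, frac) {
  rng <- lapply(shape, function(d) {
    lo <- max(2L, floor(frac[1] * d))
    hi <- min(d - 1L, ceiling(frac[2] * d))
    lo:hi
  })
  idx <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
  sort(as.integer((idx[, 3] - 1) * shape[1] * shape[2] +
                    (idx[, 2] - 1) * shape[1] + idx[, 1]))
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  subjects: %d, visits %d-%d every ~%.0f days\n",
              x$n_subjects, x$visits_per_subject[1], x$visits_per_subject[2],
              x$visit_interval_days[1]))
  cat(sprintf("  volumes: %s, aging region %d voxels, disease region %d voxels\n",
              paste(x$volume_shape, collapse = "x"),
              length(x$aging_region), length(x$disease_region)))
  cat(sprintf("  aging slope ~ N(%.2f, %.2f) pts/yr, acceleration sd %.2f\n",
              x$aging_slope_dist[1], x$aging_slope_dist[2], x$acceleration_sd))
  cat(sprintf("  genotypes: %d SNPs, MAF in [%.2f, %.2f], %d causal\n",
              x$n_snps, x$maf_range[1], x$maf_range[2], length(x$causal_snps)))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
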