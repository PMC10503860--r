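#' Simulate a longitudinal imaging-genetics cohort with known ground truth
#'
#' Generates, from one [sim_config()], (1) a visit table of cognitive scores
#' on a jittered visit schedule, (2) one phantom volume per visit whose
#' regional intensities linearly encode the aging and disease components of
#' the score, (3) Hardy-Weinberg genotypes with optional LD blocks and planted
#' causal variants, and (4) a truth table of the per-subject aging slope and
#' acceleration and the per-variant effect sizes.
#'
#' Each subject's trajectory is
#' `score(t) = baseline + (aging_slope + acceleration) * t + noise`, clipped
#' to `[0, 85]`; the acceleration is `sum(beta_k * g_k)` over causal variants
#' plus a normal residual. Diagnoses are assigned from the true acceleration
#' by the configured quantile cut points (CN / MCI / AD), constant across a
#' subject's visits. Fully deterministic given `config$seed`.
#'
#' @param config A [sim_config()] object.
#' @param render_volumes If `FALSE`, skip volume rendering (fast path for
#'   genotype/phenotype-only studies); the scan list is then empty.
#' @return A list of class `sim_cohort` with elements `visits` (data.frame:
#'   `subject_id, visit_day, age_years, sex, diagnosis, adas13, scan_id`),
#'   `scans` (named list of 3D arrays), `genotypes` (a [genotype_set()]), and
#'   `truth` (list with `subjects` and `variants` data.frames).
#' @export
simulate_cohort <- function(config, render_volumes = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_subjects
  ids <- sprintf("S%04d", seq_len(n))

  genotypes <- simulate_genotypes(
    n_samples = n, n_snps = config$n_snps, maf_range = config$maf_range,
    ld_block = config$ld_block, seed = derive_seed(config$seed, "genotypes"),
    sample_ids = ids)

  set.seed(derive_seed(config$seed, "subjects"))
  aging <- stats::rnorm(n, config$aging_slope_dist[1], config$aging_slope_dist[2])
  gen_eff <- rep(0, n)
  beta_true <- rep(0, config$n_snps)
  for (cs in config$causal_snps) {
    gen_eff <- gen_eff + cs$beta * genotypes$dosages[, cs$index]
    beta_true[cs$index] <- beta_true[cs$index] + cs$beta
  }
  accel <- gen_eff + stats::rnorm(n, 0, config$acceleration_sd)
  baseline <- pmax(0, stats::rnorm(n, config$baseline_dist[1], config$baseline_dist[2]))
  age0 <- stats::runif(n, config$age_range[1], config$age_range[2])
  sex <- stats::rbinom(n, 1, 0.5)
  cuts <- stats::quantile(accel, probs = config$dx_cutpoints, names = FALSE)
  if (anyDuplicated(cuts) || stats::var(accel) == 0) {
    dx <- rep("CN", n)  # degenerate (e.g. zero acceleration everywhere)
  } else {
    dx <- as.character(cut(accel, breaks = c(-Inf, cuts, Inf),
                           labels = c("CN", "MCI", "AD")))
  }

  set.seed(derive_seed(config$seed, "visits"))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    nv <- sample(seq(config$visits_per_subject[1], config$visits_per_subject[2]), 1)
    gaps <- pmax(30, stats::rnorm(nv - 1, config$visit_interval_days[1],
                                  config$visit_interval_days[2]))
    days <- round(c(0, cumsum(gaps)))
    t_yr <- days / DAYS_PER_YEAR
    noise <- if (config$score_noise_sd > 0)
      stats::rnorm(nv, 0, config$score_noise_sd) else numeric(nv)
    score <- clip(baseline[i] + (aging[i] + accel[i]) * t_yr + noise, 0, 85)
    rows[[i]] <- data.frame(
      subject_id = ids[i], visit_day = as.integer(days),
      age_years = age0[i] + t_yr, sex = sex[i], diagnosis = dx[i],
      adas13 = score,
      scan_id = sprintf("%s_d%05d", ids[i], days),
      stringsAsFactors = FALSE)
  }
  visits <- do.call(rbind, rows)
  rownames(visits) <- NULL

  scans <- list()
  if (render_volumes) {
    set.seed(derive_seed(config$seed, "volumes"))
    scans <- vector("list", nrow(visits))
    names(scans) <- visits$scan_id
    for (k in seq_len(nrow(visits))) {
      i <- match(visits$subject_id[k], ids)
      t_yr <- visits$visit_day[k] / DAYS_PER_YEAR
      scans[[k]] <- render_volume(
        aging_component = baseline[i] + aging[i] * t_yr,
        config = config,
        disease_component = accel[i] * t_yr)
    }
  }

  truth <- list(
    subjects = data.frame(
      subject_id = ids, aging_slope = aging, acceleration = accel,
      baseline = baseline, age_baseline = age0, sex = sex, diagnosis = dx,
      stringsAsFactors = FALSE),
    variants = data.frame(
      id = genotypes$variants$id, beta = beta_true,
      stringsAsFactors = FALSE))

  structure(list(visits = visits, scans = scans, genotypes = genotypes,
                 truth = truth, config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects, %d visits, %d volumes, %d SNPs\n",
              length(unique(x$visits$subject_id)), nrow(x$visits),
              length(x$scans), ncol(x$genotypes$dosages)))
  print(table(x$truth$subjects$diagnosis))
  invisible(x)
}

#' Render one phantom volume encoding the aging and disease score components
#'
#' Produces a 3D intensity array of shape `config$volume_shape`: an air
#' background, a bright rim on the first and last slice of the first axis
#' (fixed intensity anchors, so per-volume min-max normalization is almost the
#' identity), an aging region whose mean intensity decreases linearly with the
#' aging score component, and a disease region encoding the disease component
#' the same way. Gaussian noise of sd `config$volume_noise_sd` is added
#' everywhere. Draws from the current RNG stream.
#'
#' @param aging_component Aging part of the cognitive score, points (finite).
#' @param config A [sim_config()].
#' @param disease_component Disease part of the score, points.
#' @return A 3D numeric array.
#' @export
render_volume <- function(aging_component, config, disease_component = 0) {
  stopifnot(inherits(config, "sim_config"),
            is.finite(aging_component), is.finite(disease_component))
  shape <- config$volume_shape
  nvox <- prod(shape)
  if (any(config$aging_region > nvox) || any(config$disease_region > nvox))
    stop_config("region indices outside volume_shape")
  it <- config$intensity
  v <- rep(it[["background"]], nvox)
  dim(v) <- shape
  v[c(1, shape[1]), , ] <- it[["rim"]]
  v[config$aging_region] <- it[["aging_intercept"]] +
    it[["aging_slope"]] * aging_component
  v[config$disease_region] <- it[["disease_intercept"]] +
    it[["disease_slope"]] * disease_component
  if (config$volume_noise_sd > 0)
    v <- v + stats::rnorm(nvox, 0, config$volume_noise_sd)
  v
}

#' Simulate Hardy-Weinberg genotypes with optional LD blocks
#'
#' Dosages count ALT alleles. Per variant, a MAF is drawn uniformly from
#' `maf_range` and two haplotypes per sample are sampled as Bernoulli(MAF).
#' Variants fall in consecutive blocks of `ld_block["length"]`; within a
#' block, each haplotype allele is copied from the previous variant with
#' probability `ld_block["copy_prob"]` (1 gives perfect LD, 0 independence).
#'
#' @param n_samples Number of samples (>= 2).
#' @param n_snps Number of variants.
#' @param maf_range `c(lo, hi)` within (0, 0.5].
#' @param ld_block `c(length, copy_prob)`.
#' @param seed Integer seed (the generator is deterministic given it).
#' @param sample_ids Optional character ids; defaults to `S0001...`.
#' @param chr,pos_start,pos_spacing Variant coordinates: all variants on
#'   `chr`, positions `pos_start + (j-1) * pos_spacing` (1-based bp).
#' @return A [genotype_set()].
#' @export
simulate_genotypes <- function(n_samples, n_snps,
                               maf_range = c(0.05, 0.5),
                               ld_block = c(length = 1, copy_prob = 0),
                               seed = 1L,
                               sample_ids = NULL,
                               chr = "1", pos_start = 10000L,
                               pos_spacing = 5000L) {
  if (n_samples < 2) stop_config("n_samples must be >= 2")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop_config("maf_range must lie within (0, 0.5]")
  blk_len <- as.integer(ld_block[["length"]])
  copy_p <- ld_block[["copy_prob"]]
  set.seed(as.integer(seed))
  mafs <- stats::runif(n_snps, maf_range[1], maf_range[2])
  h1 <- matrix(0L, n_samples, n_snps)
  h2 <- matrix(0L, n_samples, n_snps)
  for (j in seq_len(n_snps)) {
    fresh1 <- stats::rbinom(n_samples, 1L, mafs[j])
    fresh2 <- stats::rbinom(n_samples, 1L, mafs[j])
    block_start <- ((j - 1L) %% blk_len) == 0L
    if (block_start || j == 1L) {
      h1[, j] <- fresh1; h2[, j] <- fresh2
    } else {
      keep1 <- stats::runif(n_samples) < copy_p
      keep2 <- stats::runif(n_samples) < copy_p
      h1[, j] <- ifelse(keep1, h1[, j - 1L], fresh1)
      h2[, j] <- ifelse(keep2, h2[, j - 1L], fresh2)
    }
  }
  dosages <- h1 + h2
  ids <- sample_ids %||% sprintf("S%04d", seq_len(n_samples))
  rownames(dosages) <- ids
  variants <- data.frame(
    id = sprintf("rs%07d", seq_len(n_snps)),
    chr = as.character(chr),
    pos = as.integer(pos_start + (seq_len(n_snps) - 1L) * pos_spacing),
    ref = "A", alt = "G",
    stringsAsFactors = FALSE)
  colnames(dosages) <- variants$id
  genotype_set(dosages, variants)
}
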