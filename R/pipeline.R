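# End-to-end pipeline: simulate -> pair -> train -> predict -> slopes ->
# gwas -> clump, with on-disk TSV/NIfTI/VCF artifacts and a provenance
# record, so stages can be run singly or chained.

#' Pipeline configuration
#'
#' Flat configuration covering every stage: cohort simulation, score-scan
#' matching and pairing, Siamese training, slope derivation, genotype QC and
#' the association scan with locus definition. Defaults mirror the stage
#' function defaults; every threshold is validated against its legal range.
#'
#' @param out_dir Output directory for all artifacts.
#' @param seed Global integer seed; all stages derive theirs from it.
#' @param n_subjects,n_snps,volume_shape,score_noise_sd,acceleration_sd,volume_noise_sd
#'   Cohort generator settings (see [sim_config()]).
#' @param causal_index,causal_beta Optional planted causal variant(s):
#'   parallel vectors of variant index and effect (points/year per allele).
#' @param write_volumes Write per-visit NIfTI volumes under
#'   `out_dir/volumes/` (needed when stages are run as separate processes).
#' @param match_window_days,min_visits,min_gap_months,max_gap_months,change_threshold
#'   Pairing-stage rules (see [match_scores_to_scans()], [filter_subjects()],
#'   [build_pairs()]).
#' @param epochs,learning_rate,margin,batch_size,hidden,embed_dim,split_fraction
#'   Training hyperparameters (see [siamese_control()]); the compact defaults
#'   here (30 epochs, lr 1e-3) suit the small default cohort.
#' @param qc_max_missing,qc_min_maf,qc_hwe_p,qc_min_info,kinship_threshold
#'   QC thresholds (see [filter_variants()], [remove_related()]).
#' @param ld_window,ld_step,ld_r2,n_pcs LD pruning and PC settings.
#' @param model Association model: 1 adjusts for the predicted aging slope,
#'   2 does not.
#' @param p_lead,r2_clump,r2_indep,merge_kb Locus-definition parameters (see
#'   [define_loci()]).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "neuroslope_run",
                            seed = 1L,
                            n_subjects = 60, n_snps = 200,
                            volume_shape = c(32, 32, 32),
                            score_noise_sd = 1, acceleration_sd = 1,
                            volume_noise_sd = 0.02,
                            causal_index = integer(), causal_beta = numeric(),
                            write_volumes = TRUE,
                            match_window_days = 45, min_visits = 3,
                            min_gap_months = 6, max_gap_months = 24,
                            change_threshold = 4,
                            epochs = 30, learning_rate = 1e-3, margin = 1,
                            batch_size = 4, hidden = 32, embed_dim = 16,
                            split_fraction = 0.7,
                            qc_max_missing = 0.02, qc_min_maf = 0.01,
                            qc_hwe_p = 1e-6, qc_min_info = 0.1,
                            kinship_threshold = 0.0884,
                            ld_window = 50, ld_step = 5, ld_r2 = 0.2,
                            n_pcs = 10,
                            model = 1,
                            p_lead = 1e-5, r2_clump = 0.6, r2_indep = 0.1,
                            merge_kb = 250) {
  # coerce list-valued fields as read back from YAML
  volume_shape <- as.integer(unlist(volume_shape))
  causal_index <- as.integer(unlist(causal_index))
  causal_beta <- as.numeric(unlist(causal_beta))
  hidden <- as.integer(unlist(hidden))
  seed <- as.integer(seed)
  if (min_gap_months >= max_gap_months)
    stop_config("min_gap_months must be < max_gap_months")
  if (length(causal_index) != length(causal_beta))
    stop_config("causal_index and causal_beta lengths differ")
  for (thr in c(qc_max_missing, qc_min_maf, qc_hwe_p, qc_min_info, ld_r2,
                r2_clump, r2_indep, split_fraction))
    if (thr < 0 || thr > 1) stop_config("threshold %g outside [0, 1]", thr)
  if (match_window_days < 0) stop_config("match_window_days must be >= 0")
  if (epochs < 1 || margin <= 0) stop_config("invalid training settings")
  cfg <- mget(names(formals(pipeline_config)), envir = environment())
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf("neuroslope pipeline config (seed %d): %d subjects, %d SNPs -> %s\n",
              x$seed, x$n_subjects, x$n_snps, x$out_dir))
  invisible(x)
}

stage_paths <- function(cfg) {
  d <- cfg$out_dir
  list(dir = d,
       visits = file.path(d, "visits.tsv"),
       truth_subjects = file.path(d, "truth_subjects.tsv"),
       truth_variants = file.path(d, "truth_variants.tsv"),
       genotypes = file.path(d, "genotypes.vcf"),
       volumes = file.path(d, "volumes"),
       pairs = file.path(d, "pairs.tsv"),
       checkpoint = file.path(d, "checkpoint.json"),
       predictions = file.path(d, "predictions.tsv"),
       slopes = file.path(d, "slopes.tsv"),
       assoc = file.path(d, "assoc.tsv"),
       loci = file.path(d, "loci.tsv"),
       qc_log = file.path(d, "qc_log.tsv"),
       provenance = file.path(d, "provenance.json"))
}

load_stage_volumes <- function(cfg, scan_ids) {
  p <- stage_paths(cfg)
  paths <- file.path(p$volumes, paste0(scan_ids, ".nii.gz"))
  miss <- !file.exists(paths)
  if (any(miss)) stop_config("input file not found: %s", paths[miss][1])
  vols <- lapply(paths, read_volume_nifti)
  names(vols) <- scan_ids
  vols
}

sim_config_of <- function(cfg) {
  causal <- mapply(function(i, b) list(index = i, beta = b),
                   cfg$causal_index, cfg$causal_beta, SIMPLIFY = FALSE)
  sim_config(n_subjects = cfg$n_subjects, n_snps = cfg$n_snps,
             volume_shape = cfg$volume_shape,
             score_noise_sd = cfg$score_noise_sd,
             acceleration_sd = cfg$acceleration_sd,
             volume_noise_sd = cfg$volume_noise_sd,
             causal_snps = causal, seed = cfg$seed)
}

#' Run the pipeline, in full or one stage at a time
#'
#' Stages: `simulate`, `pair`, `train`, `predict`, `slopes`, `gwas`, `clump`,
#' or `all` (the chain). Each stage reads its declared inputs from
#' `cfg$out_dir` (or from memory when chained), writes its declared outputs
#' there, and a machine-readable provenance record (config hash, seed,
#' package version, completed stages) is updated after every run. Rerunning
#' with the same config and seed reproduces every table byte for byte.
#'
#' @param cfg A [pipeline_config()] (or path to its YAML file).
#' @param stages Character vector of stage names, or `"all"`.
#' @return Invisibly, a list with the in-memory artifacts of the stages run.
#' @export
run_pipeline <- function(cfg, stages = "all") {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  all_stages <- c("simulate", "pair", "train", "predict", "slopes", "gwas",
                  "clump")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad) > 0)
    stop_config("unknown stage(s): %s", paste(bad, collapse = ", "))
  p <- stage_paths(cfg)
  dir.create(p$dir, showWarnings = FALSE, recursive = TRUE)
  art <- list()

  if ("simulate" %in% stages) {
    cohort <- simulate_cohort(sim_config_of(cfg))
    write_tsv_table(cohort$visits, p$visits)
    write_tsv_table(cohort$truth$subjects, p$truth_subjects)
    write_tsv_table(cohort$truth$variants, p$truth_variants)
    write_vcf_genotypes(cohort$genotypes, p$genotypes)
    if (cfg$write_volumes) {
      dir.create(p$volumes, showWarnings = FALSE)
      for (id in names(cohort$scans))
        write_volume_nifti(cohort$scans[[id]],
                           file.path(p$volumes, paste0(id, ".nii.gz")))
    }
    art$cohort <- cohort
  }

  get_visits <- function() art$cohort$visits %||% read_tsv_table(p$visits)
  get_pairs <- function() art$pairs %||% read_tsv_table(p$pairs)
  get_volumes <- function(scan_ids) {
    if (!is.null(art$cohort) && length(art$cohort$scans) > 0)
      art$cohort$scans[scan_ids]
    else load_stage_volumes(cfg, scan_ids)
  }

  if ("pair" %in% stages) {
    visits <- get_visits()
    scans <- data.frame(subject_id = visits$subject_id,
                        scan_day = visits$visit_day,
                        scan_id = visits$scan_id, stringsAsFactors = FALSE)
    matched <- match_scores_to_scans(visits[setdiff(names(visits), "scan_id")],
                                     scans, cfg$match_window_days)
    kept <- filter_subjects(matched, cfg$min_visits)
    pairs <- build_pairs(kept, cfg$min_gap_months, cfg$max_gap_months,
                         cfg$change_threshold)
    write_tsv_table(pairs, p$pairs)
    art$pairs <- pairs
  }

  if ("train" %in% stages) {
    pairs <- get_pairs()
    vols <- get_volumes(unique(c(pairs$scan_i, pairs$scan_j)))
    ctl <- siamese_control(margin = cfg$margin,
                           learning_rate = cfg$learning_rate,
                           batch_size = cfg$batch_size, epochs = cfg$epochs,
                           hidden = cfg$hidden, embed_dim = cfg$embed_dim,
                           seed = derive_seed(cfg$seed, "train"))
    fit <- fit_siamese(pairs, vols, ctl,
                       split_fraction = cfg$split_fraction)
    save_checkpoint(fit, p$checkpoint)
    art$fit <- fit
  }

  if ("predict" %in% stages) {
    fit <- art$fit %||% load_checkpoint(p$checkpoint)
    pairs <- get_pairs()
    vols <- get_volumes(unique(c(pairs$scan_i, pairs$scan_j)))
    preds <- predict(fit, pairs, vols)
    write_tsv_table(preds[, c("subject_id", "day_i", "day_j", "dt_years",
                              "slope", "predicted_slope", "npe")],
                    p$predictions)
    art$predictions <- preds
  }

  if ("slopes" %in% stages) {
    preds <- art$predictions %||% {
      tab <- read_tsv_table(p$predictions)
      tab
    }
    visits <- get_visits()
    records <- slope_records(preds, visits)
    write_tsv_table(records, p$slopes)
    art$slopes <- records
  }

  if ("gwas" %in% stages) {
    records <- art$slopes %||% read_tsv_table(p$slopes)
    G <- art$cohort$genotypes %||% read_vcf_genotypes(p$genotypes)
    Gq <- filter_variants(G, cfg$qc_max_missing, cfg$qc_min_maf,
                          cfg$qc_hwe_p, cfg$qc_min_info)
    write_tsv_table(attr(Gq, "qc_log"), p$qc_log)
    K <- kinship_matrix(Gq)
    unrelated <- remove_related(K, cfg$kinship_threshold)
    keep <- intersect(unrelated, records$subject_id)
    Gk <- subset_samples(Gq, match(keep, rownames(Gq$dosages)))
    rec <- records[match(keep, records$subject_id), , drop = FALSE]
    pruned_ids <- ld_prune(Gk, cfg$ld_window, cfg$ld_step, cfg$ld_r2)
    n_pcs <- min(cfg$n_pcs, nrow(Gk$dosages) - 2, length(pruned_ids) - 1)
    pcs <- compute_pcs(subset_variants(Gk, match(pruned_ids,
                                                 Gk$variants$id)), n_pcs)
    # Model 1/2 phenotype: INT of the median measured slope; Model 1 adds
    # the INT predicted aging slope as a covariate (via gwas_covariates).
    pheno <- inverse_normal_transform(rec$median_measured_slope)
    covar <- gwas_covariates(rec, pcs, model = cfg$model)
    res <- assoc_linear(pheno, Gk, covar)
    write_tsv_table(res, p$assoc)
    art$assoc <- res
    art$genotypes_qc <- Gk
  }

  if ("clump" %in% stages) {
    res <- art$assoc %||% read_tsv_table(p$assoc)
    G <- art$genotypes_qc %||% read_vcf_genotypes(p$genotypes)
    loci <- define_loci(res, G, cfg$p_lead, cfg$r2_clump, cfg$r2_indep,
                        cfg$merge_kb)
    write_tsv_table(loci, p$loci)
    art$loci <- loci
  }

  write_provenance(cfg, stages, p$provenance)
  invisible(art)
}

# Machine-readable provenance: config + hash + seed + package version.
write_provenance <- function(cfg, stages, path) {
  prev <- if (file.exists(path))
    jsonlite::read_json(path, simplifyVector = TRUE) else NULL
  done <- unique(c(prev$stages_completed, stages))
  rec <- list(
    package = "neuroslope",
    version = as.character(utils::packageVersion("neuroslope")),
    seed = cfg$seed,
    config_hash = fnv1a_hash(unclass(cfg)),
    config = unclass(cfg),
    stages_completed = done)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
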