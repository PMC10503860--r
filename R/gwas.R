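# Per-variant linear association for the (accelerated) cognitive-decline
# slope, LD-based lead-SNP clumping and locus merging, and the Bonferroni
# threshold utility.

#' Per-variant linear association scan
#'
#' Ordinary least squares of an inverse-normal-transformed phenotype on each
#' variant's ALT-dosage plus covariates. Model 1 includes the predicted
#' aging slope among the covariates; Model 2 omits it — the caller selects
#' the model simply through the covariate matrix it passes (see
#' [gwas_covariates()]). Two-sided p-values come from the t distribution
#' with residual degrees of freedom (finite-sample, not a normal
#' approximation).
#'
#' @param phenotype Numeric phenotype vector (already transformed), one entry
#'   per sample of `g`.
#' @param g A [genotype_set()].
#' @param covariates Numeric matrix of covariates (no intercept column; one
#'   is added). Typically 10 PCs, sex, INT median age, and for Model 1 the
#'   INT median predicted slope.
#' @param missing `"complete"` (default) drops samples missing the variant;
#'   `"impute"` mean-imputes missing dosages per variant.
#' @return data.frame of class `assoc_results`: variant metadata plus
#'   `beta, se, t, p, n` (per ALT allele, transformed-phenotype units) and a
#'   logical `flagged` column marking rank-deficient fits (their statistics
#'   are `NA`, never silently dropped).
#' @export
assoc_linear <- function(phenotype, g, covariates = NULL,
                         missing = c("complete", "impute")) {
  stopifnot(inherits(g, "genotype_set"))
  missing <- match.arg(missing)
  n <- nrow(g$dosages)
  if (length(phenotype) != n)
    stop_config("phenotype length %d != %d samples", length(phenotype), n)
  C <- cbind(intercept = rep(1, n))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) stop_config("covariates rows != samples")
    C <- cbind(C, covariates)
  }
  base_ok <- stats::complete.cases(C) & !is.na(phenotype)
  m <- ncol(g$dosages)
  beta <- se <- tval <- pval <- rep(NA_real_, m)
  nused <- integer(m)
  flagged <- logical(m)
  for (j in seq_len(m)) {
    gj <- g$dosages[, j]
    if (missing == "impute" && anyNA(gj))
      gj[is.na(gj)] <- mean(gj, na.rm = TRUE)
    ok <- base_ok & !is.na(gj)
    nj <- sum(ok)
    nused[j] <- nj
    X <- cbind(g = gj[ok], C[ok, , drop = FALSE])
    if (nj <= ncol(X)) { flagged[j] <- TRUE; next }
    fit <- stats::lm.fit(X, phenotype[ok])
    if (fit$rank < ncol(X) || is.na(fit$coefficients["g"])) {
      flagged[j] <- TRUE
      next
    }
    df <- nj - fit$rank
    rss <- sum(fit$residuals^2)
    XtX_inv <- chol2inv(fit$qr$qr[seq_len(fit$rank), seq_len(fit$rank),
                                  drop = FALSE])
    # column order after pivoting
    gpos <- match(1L, fit$qr$pivot)
    sigma2 <- rss / df
    beta[j] <- fit$coefficients["g"]
    se[j] <- sqrt(sigma2 * XtX_inv[gpos, gpos])
    tval[j] <- beta[j] / se[j]
    pval[j] <- 2 * stats::pt(-abs(tval[j]), df)
  }
  out <- cbind(g$variants,
               data.frame(beta = beta, se = se, t = tval, p = pval,
                          n = nused, flagged = flagged))
  rownames(out) <- NULL
  class(out) <- c("assoc_results", "data.frame")
  out
}

#' Build the standard GWAS covariate matrix
#'
#' Convenience assembly of the scan's two covariate designs on a
#' [slope_records()] table: principal components, binary sex, INT-transformed
#' median age, and — for Model 1 — the INT-transformed median predicted
#' aging slope.
#'
#' @param records A [slope_records()] frame (rows aligned with the genotype
#'   samples).
#' @param pcs Sample-by-PC score matrix from [compute_pcs()], or `NULL`.
#' @param model 1 (with predicted-slope covariate) or 2 (without).
#' @return Numeric covariate matrix.
#' @export
gwas_covariates <- function(records, pcs = NULL, model = 1) {
  if (!model %in% c(1, 2)) stop_config("model must be 1 or 2")
  C <- cbind(sex = records$sex,
             age_int = inverse_normal_transform(records$median_age_years))
  if (model == 1)
    C <- cbind(C, pred_slope_int =
                 inverse_normal_transform(records$median_predicted_slope))
  if (!is.null(pcs)) {
    pcs <- as.matrix(pcs)
    idx <- match(records$subject_id, rownames(pcs))
    if (anyNA(idx)) stop_config("records subjects missing from PC matrix")
    C <- cbind(C, pcs[idx, , drop = FALSE])
  }
  C
}

#' Squared dosage correlation between two variants
#'
#' LD r-squared: the squared Pearson correlation of ALT dosages over samples
#' non-missing in both variants. Sign-invariant (coding either allele gives
#' the same value).
#'
#' @param g1,g2 Dosage vectors of equal length (>= 2 overlapping non-missing
#'   samples required).
#' @return r-squared in `[0, 1]`, or `NA` (with a warning) when either vector
#'   has zero variance over the overlap.
#' @export
pairwise_r2 <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 2) stop_config("need >= 2 overlapping non-missing samples")
  if (stats::var(g1[ok]) == 0 || stats::var(g2[ok]) == 0) {
    warning("zero variance: r2 undefined")
    return(NA_real_)
  }
  stats::cor(g1[ok], g2[ok])^2
}

#' Lead-SNP clumping and locus definition
#'
#' Replays the locus-definition rules on a set of association results:
#' (1) candidates are variants with `p < p_lead`; (2) iteratively, the best
#' remaining candidate absorbs candidates with `r2 >= r2_clump` within
#' `ld_window_kb` on the same chromosome ("independent significant SNPs");
#' (3) those are re-pruned at `r2 >= r2_indep` to give the lead SNPs;
#' (4) loci on one chromosome whose boundary gap is below `merge_kb` are
#' merged. Deterministic; ties broken by (p, chr, pos), and the output does
#' not depend on input row order.
#'
#' @param results An [assoc_linear()] frame (needs `id, chr, pos, p`).
#' @param g The [genotype_set()] the LD is computed from (analysis samples).
#' @param p_lead Candidate p-value cutoff, default `1e-5`.
#' @param r2_clump r-squared at/above which nearby candidates join a clump
#'   (default 0.6).
#' @param r2_indep r-squared at/above which clump leads are themselves pruned
#'   (default 0.1).
#' @param merge_kb Locus merge distance, kb (default 250).
#' @param ld_window_kb LD window for clumping, kb (default 1000).
#' @return data.frame of class `loci`: one row per locus — `locus, lead_id,
#'   chr, start, end, lead_p, n_members, members` (semicolon-joined ids,
#'   including absorbed lead SNPs of merged loci).
#' @export
define_loci <- function(results, g, p_lead = 1e-5, r2_clump = 0.6,
                        r2_indep = 0.1, merge_kb = 250, ld_window_kb = 1000) {
  stopifnot(inherits(g, "genotype_set"))
  res <- as.data.frame(results)
  res <- res[!is.na(res$p) & res$p < p_lead, , drop = FALSE]
  empty <- data.frame(locus = integer(), lead_id = character(),
                      chr = character(), start = integer(), end = integer(),
                      lead_p = numeric(), n_members = integer(),
                      members = character(), stringsAsFactors = FALSE)
  class(empty) <- c("loci", "data.frame")
  if (nrow(res) == 0) return(empty)
  res <- res[order(res$p, res$chr, res$pos), , drop = FALSE]
  gidx <- match(res$id, g$variants$id)
  if (anyNA(gidx)) stop_config("results contain variants absent from g")

  r2_fun <- function(a, b) {
    v <- suppressWarnings(pairwise_r2(g$dosages[, gidx[a]],
                                      g$dosages[, gidx[b]]))
    if (is.na(v)) 0 else v
  }

  # step 2: greedy clumping -> independent significant SNPs
  remaining <- seq_len(nrow(res))
  clumps <- list()
  while (length(remaining) > 0) {
    lead <- remaining[1]
    near <- remaining[res$chr[remaining] == res$chr[lead] &
                        abs(res$pos[remaining] - res$pos[lead]) <=
                        ld_window_kb * 1000]
    others <- near[near != lead]
    absorbed <- others[vapply(others, r2_fun, numeric(1), b = lead) >=
                         r2_clump]
    clumps[[length(clumps) + 1]] <-
      list(lead = lead, members = c(lead, absorbed))
    remaining <- setdiff(remaining, c(lead, absorbed))
  }

  # step 3: prune the clump leads at r2_indep -> lead SNPs
  leads <- vapply(clumps, `[[`, integer(1), "lead")
  keep <- rep(TRUE, length(leads))
  for (a in seq_along(leads)) {
    if (!keep[a]) next
    for (b in seq_along(leads)) {
      if (b <= a || !keep[b]) next
      if (res$chr[leads[a]] != res$chr[leads[b]]) next
      if (abs(res$pos[leads[a]] - res$pos[leads[b]]) > ld_window_kb * 1000)
        next
      if (r2_fun(leads[a], leads[b]) >= r2_indep) {
        keep[b] <- FALSE  # a has the smaller p (sorted); b is absorbed
        clumps[[a]]$members <- union(clumps[[a]]$members,
                                     clumps[[b]]$members)
      }
    }
  }
  clumps <- clumps[keep]

  loci <- data.frame(
    lead_id = res$id[vapply(clumps, `[[`, integer(1), "lead")],
    chr = res$chr[vapply(clumps, `[[`, integer(1), "lead")],
    start = vapply(clumps, function(cl) min(res$pos[cl$members]), numeric(1)),
    end = vapply(clumps, function(cl) max(res$pos[cl$members]), numeric(1)),
    lead_p = res$p[vapply(clumps, `[[`, integer(1), "lead")],
    members = vapply(clumps, function(cl)
      paste(sort(res$id[cl$members]), collapse = ";"), character(1)),
    stringsAsFactors = FALSE)

  # step 4: merge loci separated by < merge_kb on one chromosome
  loci <- loci[order(loci$chr, loci$start), , drop = FALSE]
  merged <- list()
  for (k in seq_len(nrow(loci))) {
    cur <- loci[k, ]
    last <- if (length(merged) > 0) merged[[length(merged)]] else NULL
    if (!is.null(last) && last$chr == cur$chr &&
        (cur$start - last$end) < merge_kb * 1000) {
      last$end <- max(last$end, cur$end)
      last$start <- min(last$start, cur$start)
      last$members <- paste(sort(unique(c(
        strsplit(last$members, ";")[[1]],
        strsplit(cur$members, ";")[[1]]))), collapse = ";")
      if (cur$lead_p < last$lead_p) {
        last$lead_p <- cur$lead_p
        last$lead_id <- cur$lead_id
      }
      merged[[length(merged)]] <- last
    } else {
      merged[[length(merged) + 1]] <- cur
    }
  }
  out <- do.call(rbind, merged)
  out <- out[order(out$chr, out$start), , drop = FALSE]
  out$locus <- seq_len(nrow(out))
  out$n_members <- vapply(strsplit(out$members, ";"), length, integer(1))
  out <- out[, c("locus", "lead_id", "chr", "start", "end", "lead_p",
                 "n_members", "members")]
  rownames(out) <- NULL
  class(out) <- c("loci", "data.frame")
  out
}

#' Bonferroni significance threshold
#'
#' `alpha / n_tests`; e.g. a gene-level scan of 19,171 genes at alpha 0.05
#' gives 2.61e-6.
#'
#' @param alpha Family-wise error rate in (0, 1).
#' @param n_tests Number of tests (>= 1).
#' @return The per-test threshold.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (alpha <= 0 || alpha >= 1) stop_config("alpha must be in (0, 1)")
  if (n_tests < 1) stop_config("n_tests must be >= 1")
  alpha / n_tests
}
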