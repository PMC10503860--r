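# Variant and sample quality control: missingness/MAF/HWE filters,
# KING-robust kinship and greedy relatedness removal, sliding-window LD
# pruning, and principal components for stratification adjustment.

#' Variant-level quality-control filters
#'
#' Removes variants failing any rule, applied in order: imputation info
#' score, missingness, minor allele frequency, Hardy-Weinberg exact test.
#' MAF and HWE use observed (non-missing) genotypes only. Per-rule removal
#' counts are attached as attribute `qc_log` (a data.frame) and the filter is
#' idempotent.
#'
#' @param g A [genotype_set()].
#' @param max_missing Maximum per-variant missing-call rate (default 0.02).
#' @param min_maf Minimum minor allele frequency (default 0.01; exclusive, so
#'   monomorphic variants always fail).
#' @param hwe_p_min Minimum HWE exact-test p-value (default `1e-6`).
#' @param min_info Minimum imputation quality; only applied when the set
#'   carries info scores.
#' @return The filtered `genotype_set`.
#' @export
filter_variants <- function(g, max_missing = 0.02, min_maf = 0.01,
                            hwe_p_min = 1e-6, min_info = 0.1) {
  stopifnot(inherits(g, "genotype_set"))
  if (max_missing < 0 || max_missing > 1 || min_maf < 0 || min_maf > 1 ||
      hwe_p_min < 0 || hwe_p_min > 1 || min_info < 0 || min_info > 1)
    stop_config("thresholds must lie in [0, 1]")
  m <- ncol(g$dosages)
  alive <- rep(TRUE, m)
  log <- data.frame(rule = character(), removed = integer())
  drop_rule <- function(alive, fail, rule) {
    fail <- fail & alive
    log <<- rbind(log, data.frame(rule = rule, removed = sum(fail)))
    alive & !fail
  }
  if (!is.null(g$info))
    alive <- drop_rule(alive, g$info < min_info, "info")
  miss <- colMeans(is.na(g$dosages))
  alive <- drop_rule(alive, miss > max_missing, "missingness")
  maf <- variant_maf(g)
  alive <- drop_rule(alive, is.na(maf) | maf <= min_maf | maf == 0, "maf")
  hwe_p <- apply(g$dosages, 2, function(d) {
    d <- d[!is.na(d)]
    hwe_exact_test(sum(d == 0), sum(d == 1), sum(d == 2))
  })
  alive <- drop_rule(alive, hwe_p < hwe_p_min, "hwe")
  out <- subset_variants(g, alive)
  attr(out, "qc_log") <- log
  out
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test: given the observed allele counts, the p-value sums
#' the probabilities of all heterozygote counts whose conditional probability
#' does not exceed that of the observed configuration (Wigginton-style
#' two-sided exact test). Counts refer to one biallelic variant.
#'
#' @param n_AA,n_Aa,n_aa Non-negative genotype counts (total >= 1).
#' @return Exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop_config("counts must be >= 0")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop_config("total count must be >= 1")
  n_a <- n_Aa + 2 * min(n_AA, n_aa) + 0  # rare-allele copies, see below
  # work with the rarer allele for symmetry
  rare <- n_Aa + 2 * min(n_AA, n_aa)
  # possible heterozygote counts share the parity of the rare-allele count
  hets <- seq(rare %% 2, min(rare, 2 * n - rare), by = 2)
  # log probability of each het count under the conditional distribution:
  # P(n_Aa | n, rare) = C * rare! (2n-rare)! n! 2^n_Aa /
  #                     (n_AA! n_Aa! n_aa! (2n)!)
  logp <- vapply(hets, function(h) {
    hom_rare <- (rare - h) / 2
    hom_common <- n - h - hom_rare
    lgamma(n + 1) - lgamma(hom_rare + 1) - lgamma(h + 1) -
      lgamma(hom_common + 1) + h * log(2) +
      lgamma(rare + 1) + lgamma(2 * n - rare + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- match(n_Aa, hets)
  min(1, sum(p[p <= p[obs] * (1 + 1e-12)]))
}

#' KING-robust pairwise kinship matrix
#'
#' Between-family robust kinship from heterozygote concordance:
#' `phi = (N_Aa,Aa - 2 * N_AA,aa) / (N_Aa(i) + N_Aa(j))`, where `N_Aa,Aa`
#' counts variants heterozygous in both samples and `N_AA,aa` counts opposite
#' homozygotes, over variants observed in both samples. Self-kinship is 0.5
#' by this formula. Robust to population structure; a duplicate pair scores
#' about 0.5, parent-offspring about 0.25, second degree about 0.0884.
#'
#' @param g A [genotype_set()] (at least 2 samples; >= 50 variants
#'   recommended for stable estimates).
#' @return Symmetric sample-by-sample matrix of class `kinship_matrix`.
#' @export
kinship_matrix <- function(g) {
  stopifnot(inherits(g, "genotype_set"))
  X <- g$dosages
  n <- nrow(X)
  if (n < 2) stop_config("need at least 2 samples")
  if (any(rowSums(!is.na(X)) == 0))
    stop_config("sample(s) with all-missing genotypes")
  obs <- !is.na(X)
  Xh <- ifelse(obs & X == 1, 1, 0)        # heterozygous indicator
  X0 <- ifelse(obs & X == 0, 1, 0)
  X2 <- ifelse(obs & X == 2, 1, 0)
  het_het <- Xh %*% t(Xh)
  opp_hom <- X0 %*% t(X2) + X2 %*% t(X0)
  # per-pair heterozygote counts restricted to jointly observed variants
  het_i <- Xh %*% t(obs)                  # het in i, observed in j
  denom <- het_i + t(het_i)
  K <- (het_het - 2 * opp_hom) / pmax(denom, 1)
  dimnames(K) <- list(rownames(X), rownames(X))
  structure(K, class = c("kinship_matrix", "matrix"))
}

#' Greedy removal of related samples
#'
#' While any retained pair exceeds the kinship threshold (0.0884, the
#' second-degree cutoff, by default), drops the member involved in more
#' over-threshold pairs; ties are broken by higher genotype missingness, then
#' lexicographically by id. No retained pair exceeds the threshold.
#'
#' @param K A [kinship_matrix()].
#' @param threshold Kinship cutoff.
#' @param missingness Optional named per-sample missing rate for tie-breaks.
#' @return Character vector of retained sample ids (original order).
#' @export
remove_related <- function(K, threshold = 0.0884, missingness = NULL) {
  ids <- rownames(K)
  stopifnot(!is.null(ids))
  miss <- missingness[ids] %||% stats::setNames(rep(0, length(ids)), ids)
  miss[is.na(miss)] <- 0
  A <- K > threshold
  diag(A) <- FALSE
  alive <- rep(TRUE, length(ids))
  repeat {
    deg <- rowSums(A[, alive, drop = FALSE]) * alive
    if (all(deg == 0)) break
    worst <- which(deg == max(deg))
    if (length(worst) > 1)
      worst <- worst[order(-miss[worst], ids[worst])]
    alive[worst[1]] <- FALSE
  }
  ids[alive]
}

#' Sliding-window greedy LD pruning
#'
#' plink-style `--indep-pairwise`: within each window of `window` variants,
#' repeatedly removes one member of the retained pair with the highest
#' squared dosage correlation above `r2_max` until no such pair remains, then
#' advances the window by `step` variants. Removal is permanent across
#' windows. Of an offending pair, the lower-MAF member is removed (tie: the
#' later position).
#'
#' @param g A [genotype_set()], positions sorted within chromosome.
#' @param window Window size in variants (default 50).
#' @param step Window advance in variants (default 5; must be <= window).
#' @param r2_max Maximum allowed pairwise r-squared (default 0.2).
#' @return Character vector of retained variant ids.
#' @export
ld_prune <- function(g, window = 50, step = 5, r2_max = 0.2) {
  stopifnot(inherits(g, "genotype_set"))
  if (window < step) stop_config("window must be >= step")
  ids <- g$variants$id
  maf <- variant_maf(g)
  alive <- rep(TRUE, length(ids))
  for (ch in unique(g$variants$chr)) {
    vi <- which(g$variants$chr == ch)
    starts <- seq(1, max(1, length(vi) - 1), by = step)
    for (s in starts) {
      win <- vi[s:min(s + window - 1, length(vi))]
      repeat {
        act <- win[alive[win]]
        if (length(act) < 2) break
        R2 <- suppressWarnings(stats::cor(g$dosages[, act, drop = FALSE],
                                          use = "pairwise.complete.obs"))^2
        R2[!is.finite(R2)] <- 0
        diag(R2) <- 0
        mx <- max(R2)
        if (mx <= r2_max) break
        hit <- which(R2 == mx, arr.ind = TRUE)[1, ]
        pair <- act[hit]
        # drop the lower-MAF member; tie -> later position
        drop <- if (maf[pair[1]] < maf[pair[2]]) pair[1]
                else if (maf[pair[2]] < maf[pair[1]]) pair[2]
                else max(pair)
        alive[drop] <- FALSE
      }
    }
  }
  ids[alive]
}

#' Genotype principal components for stratification adjustment
#'
#' Classical-MDS-equivalent PCA on standardized dosages (per-variant mean
#' imputation of missing calls, centering, unit-variance scaling;
#' zero-variance variants dropped). Columns are ordered by decreasing
#' eigenvalue and each component's sign is fixed so its largest-magnitude
#' variant loading is positive.
#'
#' @param g An LD-pruned [genotype_set()].
#' @param n_components Number of components (default 10; needs at least
#'   `n_components + 1` samples).
#' @return Sample-by-component score matrix (rownames = sample ids), with the
#'   eigenvalues as attribute `eigenvalues`.
#' @export
compute_pcs <- function(g, n_components = 10) {
  stopifnot(inherits(g, "genotype_set"))
  X <- g$dosages
  if (ncol(X) < 2) stop_config("need at least 2 variants")
  if (nrow(X) < n_components + 1)
    stop_config("need at least n_components + 1 samples")
  for (j in seq_len(ncol(X))) {
    mj <- mean(X[, j], na.rm = TRUE)
    X[is.na(X[, j]), j] <- mj
  }
  X <- scale(X)
  X <- X[, apply(is.finite(X), 2, all), drop = FALSE]
  sv <- svd(X, nu = n_components, nv = n_components)
  k <- min(n_components, length(sv$d))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  for (j in seq_len(k)) {
    load <- sv$v[, j]
    if (load[which.max(abs(load))] < 0) scores[, j] <- -scores[, j]
  }
  dimnames(scores) <- list(rownames(g$dosages), paste0("PC", seq_len(k)))
  attr(scores, "eigenvalues") <- sv$d[seq_len(k)]^2 / (nrow(X) - 1)
  scores
}
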