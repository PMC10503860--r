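# Association scan, LD r2, locus definition, thresholds.

test_that("association statistics match the closed-form OLS + t oracle", {
  set.seed(81)
  n <- 20
  g <- simulate_genotypes(n, 6, maf_range = c(0.2, 0.5), seed = 82)
  y <- rnorm(n)
  C <- cbind(sex = rbinom(n, 1, 0.5), age = rnorm(n))
  res <- assoc_linear(y, g, C)
  expect_s3_class(res, "assoc_results")
  for (j in 1:6) {
    X <- cbind(1, g$dosages[, j], C)
    bhat <- solve(t(X) %*% X, t(X) %*% y)
    r <- y - X %*% bhat
    df <- n - ncol(X)
    vb <- solve(t(X) %*% X) * sum(r^2) / df
    expect_equal(res$beta[j], bhat[2], tolerance = 1e-8)
    expect_equal(res$se[j], sqrt(vb[2, 2]), tolerance = 1e-8)
    expect_equal(res$p[j], 2 * pt(-abs(bhat[2] / sqrt(vb[2, 2])), df),
                 tolerance = 1e-8)
    expect_equal(res$t[j], res$beta[j] / res$se[j])
  }
  expect_true(all(res$n == n))
})

test_that("adding a constant to the phenotype changes nothing", {
  set.seed(83)
  g <- simulate_genotypes(60, 8, seed = 84)
  y <- rnorm(60)
  a <- assoc_linear(y, g)
  b <- assoc_linear(y + 1000, g)
  expect_equal(a$beta, b$beta, tolerance = 1e-9)
  expect_equal(a$p, b$p, tolerance = 1e-9)
})

test_that("missing-genotype handling matches its declared modes", {
  set.seed(85)
  g <- simulate_genotypes(100, 4, seed = 86)
  D <- g$dosages
  D[1:10, 2] <- NA
  g2 <- genotype_set(D, g$variants)
  y <- rnorm(100)
  comp <- assoc_linear(y, g2)
  expect_equal(comp$n[2], 90)  # complete-case per variant
  imp <- assoc_linear(y, g2, missing = "impute")
  expect_equal(imp$n[2], 100)
  # oracle for the imputed fit
  d <- D[, 2]; d[is.na(d)] <- mean(d, na.rm = TRUE)
  o <- summary(lm(y ~ d))$coefficients[2, ]
  expect_equal(imp$beta[2], unname(o[1]), tolerance = 1e-10)
})

test_that("a collinear variant is flagged, not dropped", {
  set.seed(87)
  n <- 30
  g0 <- simulate_genotypes(n, 2, seed = 88)
  sexlike <- rbinom(n, 1, 0.5)
  D <- cbind(g0$dosages[, 1], sexlike * 2)  # variant 2 == 2 * covariate
  g <- gs_of(D)
  res <- assoc_linear(rnorm(n), g, cbind(sex = sexlike))
  expect_false(res$flagged[1])
  expect_true(res$flagged[2])
  expect_true(is.na(res$p[2]))
  expect_equal(nrow(res), 2)
})

test_that("model 1 and model 2 agree when the extra covariate is independent", {
  set.seed(89)
  n <- 400
  g <- simulate_genotypes(n, 30, seed = 90)
  y <- rnorm(n)
  indep <- rnorm(n)  # predicted-slope covariate unrelated to y and g
  m2 <- assoc_linear(y, g)
  m1 <- assoc_linear(y, g, cbind(pred = indep))
  # genotype effects agree within Monte-Carlo tolerance
  expect_lt(max(abs(m1$beta - m2$beta)), 0.05)
  expect_gt(cor(-log10(m1$p), -log10(m2$p)), 0.95)
})

test_that("type-I error is calibrated under a permuted-dosage phenotype", {
  g <- simulate_genotypes(300, 1000, maf_range = c(0.1, 0.5), seed = 91)
  set.seed(92)
  y <- sample(g$dosages[, 1])  # permuted copy of a dosage: pure null
  res <- assoc_linear(y, g)
  rate <- mean(res$p < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("r2 is symmetric, allele-coding invariant and near zero when independent", {
  g <- simulate_genotypes(2000, 2, maf_range = c(0.3, 0.5),
                          ld_block = c(length = 1, copy_prob = 0), seed = 93)
  d1 <- g$dosages[, 1]; d2 <- g$dosages[, 2]
  expect_equal(pairwise_r2(d1, d1), 1)
  expect_equal(pairwise_r2(d1, 2 - d1), 1)
  expect_lt(pairwise_r2(d1, d2), 0.01)
  expect_warning(r <- pairwise_r2(d1, rep(1, 2000)), "zero variance")
  expect_true(is.na(r))
  expect_error(pairwise_r2(c(1, NA), c(NA, 1)), "overlapping")
})

test_that("locus definition matches an exhaustive rule replay on a fixture", {
  # 15 variants: two LD blocks on chr 1 plus isolated variants on chr 2
  g <- simulate_genotypes(500, 15, maf_range = c(0.2, 0.5),
                          ld_block = c(length = 5, copy_prob = 0.95),
                          seed = 94, pos_spacing = 40000L)
  g$variants$chr[11:15] <- "2"
  set.seed(95)
  y <- 0.4 * g$dosages[, 2] - 0.45 * g$dosages[, 12] + rnorm(500)
  res <- assoc_linear(y, g)
  got <- define_loci(res, g, p_lead = 1e-5, r2_clump = 0.6, r2_indep = 0.1,
                     merge_kb = 250, ld_window_kb = 1000)

  # independent replay of the documented rules
  cand <- res[!is.na(res$p) & res$p < 1e-5, ]
  cand <- cand[order(cand$p, cand$chr, cand$pos), ]
  r2 <- function(a, b) cor(g$dosages[, a], g$dosages[, b])^2
  remaining <- cand$id
  clumps <- list()
  while (length(remaining) > 0) {
    lead <- remaining[1]
    li <- match(lead, g$variants$id)
    mem <- lead
    for (o in remaining[-1]) {
      oi <- match(o, g$variants$id)
      if (g$variants$chr[oi] == g$variants$chr[li] &&
          abs(g$variants$pos[oi] - g$variants$pos[li]) <= 1e6 &&
          r2(oi, li) >= 0.6) mem <- c(mem, o)
    }
    clumps[[length(clumps) + 1]] <- list(lead = lead, members = mem)
    remaining <- setdiff(remaining, mem)
  }
  keep <- rep(TRUE, length(clumps))
  for (a in seq_along(clumps)) for (b in seq_along(clumps)) {
    if (b <= a || !keep[a] || !keep[b]) next
    la <- match(clumps[[a]]$lead, g$variants$id)
    lb <- match(clumps[[b]]$lead, g$variants$id)
    if (g$variants$chr[la] == g$variants$chr[lb] &&
        abs(g$variants$pos[la] - g$variants$pos[lb]) <= 1e6 &&
        r2(la, lb) >= 0.1) {
      keep[b] <- FALSE
      clumps[[a]]$members <- union(clumps[[a]]$members, clumps[[b]]$members)
    }
  }
  clumps <- clumps[keep]
  # merge loci separated by < 250 kb on one chromosome
  ext <- lapply(clumps, function(cl) {
    mi <- match(cl$members, g$variants$id)
    list(lead = cl$lead, members = cl$members,
         chr = g$variants$chr[match(cl$lead, g$variants$id)],
         start = min(g$variants$pos[mi]), end = max(g$variants$pos[mi]),
         p = res$p[match(cl$lead, res$id)])
  })
  ext <- ext[order(vapply(ext, `[[`, character(1), "chr"),
                   vapply(ext, `[[`, numeric(1), "start"))]
  merged <- list()
  for (cl in ext) {
    last <- if (length(merged)) merged[[length(merged)]] else NULL
    if (!is.null(last) && last$chr == cl$chr &&
        (cl$start - last$end) < 250000) {
      last$end <- max(last$end, cl$end)
      last$members <- union(last$members, cl$members)
      if (cl$p < last$p) { last$p <- cl$p; last$lead <- cl$lead }
      merged[[length(merged)]] <- last
    } else merged[[length(merged) + 1]] <- cl
  }
  expect_equal(nrow(got), length(merged))
  expect_setequal(got$lead_id, vapply(merged, `[[`, character(1), "lead"))
  for (k in seq_len(nrow(got))) {
    cl <- merged[[match(got$lead_id[k], vapply(merged, `[[`, character(1),
                                               "lead"))]]
    expect_setequal(strsplit(got$members[k], ";")[[1]], cl$members)
  }
})

test_that("locus definition handles empty and singleton candidate sets", {
  g <- simulate_genotypes(200, 5, seed = 96)
  res <- assoc_linear(rnorm(200), g)
  res$p <- rep(0.5, 5)
  expect_equal(nrow(define_loci(res, g)), 0)
  res$p <- c(0.5, 1e-8, 0.5, 0.5, 0.5)
  one <- define_loci(res, g)
  expect_equal(nrow(one), 1)
  expect_equal(one$lead_id, g$variants$id[2])
  expect_equal(one$n_members, 1L)
})

test_that("locus definition is invariant to input row order", {
  g <- simulate_genotypes(300, 12, ld_block = c(length = 4, copy_prob = 0.9),
                          seed = 97, pos_spacing = 30000L)
  set.seed(98)
  y <- 0.5 * g$dosages[, 6] + rnorm(300)
  res <- assoc_linear(y, g)
  a <- define_loci(res, g)
  b <- define_loci(res[sample(nrow(res)), ], g)
  expect_identical(a, b)
})

test_that("nearby loci merge below the distance cutoff", {
  # two independent significant variants 200 kb apart on one chromosome
  D <- simulate_genotypes(400, 2, maf_range = c(0.3, 0.5), seed = 99)$dosages
  g <- gs_of(D, pos = c(1000000L, 1200000L))
  res <- data.frame(id = g$variants$id, chr = "1", pos = g$variants$pos,
                    ref = "A", alt = "G", p = c(1e-8, 1e-7))
  merged <- define_loci(res, g, merge_kb = 250)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$n_members, 2L)
  apart <- define_loci(res, g, merge_kb = 150)
  expect_equal(nrow(apart), 2)
})

test_that("Bonferroni thresholds follow from the scan sizes", {
  expect_equal(signif(bonferroni_threshold(0.05, 19171), 3), 2.61e-6)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(signif(bonferroni_threshold(0.05, 1419), 3), 3.52e-5)
  expect_error(bonferroni_threshold(0.05, 0), "n_tests")
  expect_error(bonferroni_threshold(1.2, 10), "alpha")
})
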