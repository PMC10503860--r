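# Dual-loss Siamese network: losses, embeddings, gradients, training,
# prediction.

test_that("contrastive loss matches the formula and its zero set", {
  expect_equal(contrastive_loss(0.5, 0), 0.25)
  expect_equal(contrastive_loss(1.5, 1, margin = 1), 0)
  expect_equal(contrastive_loss(0.2, 1, margin = 1), 0.64)
  expect_error(contrastive_loss(0.5, 2), "Y must be")
  # non-negative everywhere; zero iff (Y=0, D=0) or (Y=1, D>=m)
  for (m in c(0.5, 1, 2)) for (D in seq(0, 3, by = 0.1)) {
    l0 <- contrastive_loss(D, 0, m); l1 <- contrastive_loss(D, 1, m)
    expect_gte(l0, 0); expect_gte(l1, 0)
    expect_equal(l0 == 0, D == 0)
    expect_equal(l1 == 0, D >= m)
  }
})

test_that("regression loss is the batch MSE", {
  expect_equal(regression_loss(c(1, 3), c(0, 0)), 5)
  expect_equal(regression_loss(2, 5), 9)
  expect_equal(regression_loss(c(4, 4), c(4, 4)), 0)
  expect_error(regression_loss(numeric(), numeric()), "empty")
})

test_that("pair distance is the Euclidean norm, symmetric, zero iff equal", {
  expect_equal(pair_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(pair_distance(1:4, 1:4), 0)
  e1 <- rnorm(6); e2 <- rnorm(6)
  expect_equal(pair_distance(e1, e2), pair_distance(e2, e1))
  expect_error(pair_distance(1:3, 1:4), "length mismatch")
})

test_that("weight sharing: identical input gives identical embeddings", {
  net <- siamese_network(c(16, 16, 16),
                         siamese_control(pool = c(4, 4, 4), hidden = 8L,
                                         embed_dim = 4L, seed = 2))
  set.seed(1)
  v <- array(runif(16^3), c(16, 16, 16))
  e1 <- embed_volume(net, v)
  e2 <- embed_volume(net, v)
  expect_identical(e1, e2)
  expect_length(e1, 4)
  expect_true(all(is.finite(e1)))
  expect_error(embed_volume(net, array(0, c(8, 8, 8))), "shape")
})

test_that("zero encoder weights embed everything to the zero vector", {
  net <- siamese_network(c(8, 8, 8),
                         siamese_control(pool = c(2, 2, 2),
                                         hidden = integer(0), embed_dim = 3L))
  w <- network_weights(net)
  w$W[[1]][] <- 0
  network_weights(net) <- w
  expect_equal(embed_volume(net, array(runif(512), c(8, 8, 8))), rep(0, 3))
})

test_that("analytic gradients match finite differences", {
  ns <- asNamespace("neuroslope")
  ctl <- siamese_control(hidden = 5L, embed_dim = 3L, margin = 1)
  params <- ns$net_init(7, 5L, 3L, seed = 2)
  set.seed(3)
  X1 <- matrix(rnorm(4 * 7), 4); X2 <- matrix(rnorm(4 * 7), 4)
  y1 <- rnorm(4, 10); Y <- c(0, 1, 1, 0)
  lg <- ns$pair_loss_grad(params, X1, X2, y1, Y, ctl)
  eps <- 1e-6
  fd <- function(set) {
    (ns$pair_loss_grad(set(eps), X1, X2, y1, Y, ctl,
                       want_grad = FALSE)$total -
       ns$pair_loss_grad(set(-eps), X1, X2, y1, Y, ctl,
                         want_grad = FALSE)$total) / (2 * eps)
  }
  for (l in 1:2) for (k in sample(length(params$W[[l]]), 6)) {
    g <- fd(function(d) { p <- params; p$W[[l]][k] <- p$W[[l]][k] + d; p })
    expect_equal(lg$grad$W[[l]][k], g, tolerance = 1e-4)
  }
  for (k in seq_along(params$Wr)) {
    g <- fd(function(d) { p <- params; p$Wr[k] <- p$Wr[k] + d; p })
    expect_equal(lg$grad$Wr[k], g, tolerance = 1e-4)
  }
  g <- fd(function(d) { p <- params; p$br <- p$br + d; p })
  expect_equal(lg$grad$br, g, tolerance = 1e-4)
})

test_that("a gradient step on a close different-class pair increases distance", {
  ns <- asNamespace("neuroslope")
  # 2-parameter toy embedding: scalar weights on a 2-feature input
  ctl <- siamese_control(hidden = integer(0), embed_dim = 2L, margin = 1,
                         mse_weight = 0, contrastive_weight = 1)
  params <- list(W = list(diag(2)), b = list(c(0, 0)),
                 Wr = matrix(0, 2, 1), br = 0)
  X1 <- matrix(c(0.1, 0), 1); X2 <- matrix(c(0, 0.1), 1)
  d0 <- sqrt(sum((X1 - X2)^2))
  expect_lt(d0, 1)  # inside the margin
  lg <- ns$pair_loss_grad(params, X1, X2, 0, 1, ctl)
  params$W[[1]] <- params$W[[1]] - 0.1 * lg$grad$W[[1]]
  params$b[[1]] <- params$b[[1]] - 0.1 * lg$grad$b[[1]]
  e1 <- ns$net_forward(params, X1); e2 <- ns$net_forward(params, X2)
  d1 <- pair_distance(as.numeric(e1[[2]]), as.numeric(e2[[2]]))
  expect_gt(d1, d0)
})

test_that("the 70/30 subject split of 414 subjects gives 289/125", {
  sp <- split_subjects(sprintf("S%03d", 1:414), 0.7, seed = 1)
  expect_length(sp$train, 289)
  expect_length(sp$val, 125)
  expect_length(intersect(sp$train, sp$val), 0)
})

test_that("training selects epochs, logs losses, and rejects split overlap", {
  cfg <- sim_config(n_subjects = 10, volume_shape = c(16, 16, 16),
                    score_noise_sd = 0, volume_noise_sd = 0,
                    acceleration_sd = 0, seed = 8)
  co <- simulate_cohort(cfg)
  pairs <- build_pairs(filter_subjects(matched_of(co)))
  ctl <- siamese_control(pool = c(4, 4, 4), hidden = 8L, embed_dim = 4L,
                         epochs = 1, seed = 4)
  fit <- fit_siamese(pairs, co$scans, ctl)
  expect_equal(fit$selected_epoch, 1L)
  expect_equal(nrow(fit$log), 1)

  subj <- unique(pairs$subject_id)
  expect_error(
    fit_siamese(pairs, co$scans, ctl,
                split = list(train = subj, val = subj[1])),
    "overlap")
})

test_that("training beats the constant-mean predictor on noise-free data", {
  cfg <- sim_config(n_subjects = 24, volume_shape = c(16, 16, 16),
                    score_noise_sd = 0, volume_noise_sd = 0,
                    acceleration_sd = 0, seed = 9)
  co <- simulate_cohort(cfg)
  pairs <- build_pairs(filter_subjects(matched_of(co)))
  ctl <- siamese_control(pool = c(4, 4, 4), hidden = 16L, embed_dim = 8L,
                         learning_rate = 1e-3, decay_factor = 0.5,
                         epochs = 15, seed = 5)
  fit <- fit_siamese(pairs, co$scans, ctl)
  tr <- pairs[pairs$subject_id %in% fit$split$train, ]
  va <- pairs[pairs$subject_id %in% fit$split$val, ]
  baseline <- mean((va$score_i - mean(tr$score_i))^2)
  expect_lt(fit$log$val_mse[fit$selected_epoch], baseline)
})

test_that("training logs are exactly reproducible under a fixed seed", {
  cfg <- sim_config(n_subjects = 8, volume_shape = c(16, 16, 16), seed = 10)
  co <- simulate_cohort(cfg)
  pairs <- build_pairs(filter_subjects(matched_of(co)))
  ctl <- siamese_control(pool = c(4, 4, 4), hidden = 8L, embed_dim = 4L,
                         epochs = 3, seed = 6)
  f1 <- fit_siamese(pairs, co$scans, ctl)
  f2 <- fit_siamese(pairs, co$scans, ctl)
  expect_identical(f1$log, f2$log)
  expect_identical(f1$params, f2$params)
})

test_that("a hand-built linear head reads out the aging-region mean exactly", {
  # pool grid == volume shape: features are the (min-max scaled) voxels.
  cfg <- sim_config(volume_shape = c(8, 8, 8),
                    aging_region = neuroslope:::cuboid_region(c(8, 8, 8),
                                                              c(0.3, 0.6)),
                    disease_region = neuroslope:::cuboid_region(c(8, 8, 8),
                                                                c(0.8, 0.9)),
                    volume_noise_sd = 0)
  ctl <- siamese_control(pool = c(8, 8, 8), hidden = integer(0),
                         embed_dim = 1L)
  net <- siamese_network(c(8, 8, 8), ctl)
  w <- network_weights(net)
  w$W[[1]][] <- 0
  w$W[[1]][cfg$aging_region, 1] <- 1 / length(cfg$aging_region)
  w$b[[1]] <- 0
  w$Wr[] <- 1; w$br <- 0
  network_weights(net) <- w

  slope_int <- unname(cfg$intensity["aging_slope"])
  icpt <- unname(cfg$intensity["aging_intercept"])
  aging_slope <- 2.5  # points/year
  comp <- function(t) 10 + aging_slope * t
  vols <- list(a = render_volume(comp(0), cfg), b = render_volume(comp(1), cfg),
               c = render_volume(comp(2), cfg))
  # yhat equals the aging-region mean
  e <- embed_volume(net, vols$a)
  expect_equal(as.numeric(e %*% w$Wr + w$br), icpt + slope_int * comp(0),
               tolerance = 1e-10)
  pairs <- data.frame(subject_id = "S1", day_i = c(0, 0), day_j = c(365.25, 730.5),
                      scan_i = c("a", "a"), scan_j = c("b", "c"),
                      score_i = comp(0), score_j = c(comp(1), comp(2)),
                      dt_years = c(1, 2), dscore = NA, slope = NA,
                      label = c(0L, 0L), stringsAsFactors = FALSE)
  pr <- predict(net, pairs, vols)
  # predicted slope equals the encoded intensity slope x aging slope, exactly
  expect_equal(pr$predicted_slope[1], slope_int * aging_slope,
               tolerance = 1e-10)
  # doubling delta_t with the same endpoint images halves nothing here (the
  # second pair really spans 2 years); with fixed images it halves the slope
  pairs2 <- pairs[1, ]; pairs2$dt_years <- 2
  pr2 <- predict(net, pairs2, vols)
  expect_equal(pr2$predicted_slope, pr$predicted_slope[1] / 2)
  # identical images at both ends -> zero slope
  pairs3 <- pairs[1, ]; pairs3$scan_j <- "a"
  expect_equal(predict(net, pairs3, vols)$predicted_slope, 0)
})

test_that("untrained models refuse to predict", {
  net <- siamese_network(c(8, 8, 8), siamese_control(pool = c(2, 2, 2)))
  pairs <- data.frame(subject_id = "S1", scan_i = "a", scan_j = "a",
                      score_i = 1, dt_years = 1)
  expect_error(predict(net, pairs, list(a = array(0, c(8, 8, 8)))),
               "untrained")
})

test_that("normalized predicted error scales inversely with the time gap", {
  expect_equal(normalized_predicted_error(10, 10, 1), 0)
  expect_equal(normalized_predicted_error(12, 10, 1), 2)
  expect_equal(normalized_predicted_error(12, 10, 2), 1)
  expect_error(normalized_predicted_error(1, 1, 0), "dt_years")
})

test_that("checkpoints round-trip weights, log and predictions", {
  cfg <- sim_config(n_subjects = 8, volume_shape = c(16, 16, 16), seed = 12)
  co <- simulate_cohort(cfg)
  pairs <- build_pairs(filter_subjects(matched_of(co)))
  ctl <- siamese_control(pool = c(4, 4, 4), hidden = 8L, embed_dim = 4L,
                         epochs = 2, seed = 7)
  fit <- fit_siamese(pairs, co$scans, ctl)
  path <- tempfile(fileext = ".json")
  save_checkpoint(fit, path)
  back <- load_checkpoint(path)
  p1 <- predict(fit, pairs, co$scans)
  p2 <- predict(back, pairs, co$scans)
  expect_equal(p2$predicted_slope, p1$predicted_slope, tolerance = 1e-12)
  expect_equal(back$selected_epoch, fit$selected_epoch)
  unlink(path)
})
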