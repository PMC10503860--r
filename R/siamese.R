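# Dual-loss Siamese network: a shared-weight encoder maps each volume of a
# longitudinal pair to an embedding; a regression head predicts the
# first-visit cognitive score (MSE loss) and a contrastive head acts on the
# Euclidean distance between the two embeddings. All forward/backward passes
# are written in base R matrix algebra so training is deterministic on one
# CPU; gradients are validated against finite differences in the test suite.

#' Hyperparameters of the Siamese slope model
#'
#' @param margin Contrastive margin `m` (> 0): minimum embedding distance a
#'   different-class pair should attain. Default 1.
#' @param learning_rate Initial Adam learning rate. Default `1e-4`.
#' @param batch_size Mini-batch size (pairs). Default 4.
#' @param epochs Training epochs. Default 200.
#' @param decay_factor,decay_every Step learning-rate schedule:
#'   `lr * decay_factor^floor((epoch - 1) / decay_every)`; defaults 0.1 and 10.
#' @param mse_weight,contrastive_weight Weights of the two losses in the total
#'   training objective; default 1 and 1 (model selection always uses their
#'   unweighted sum).
#' @param pool Target grid of the fixed block-average-pooling front end; each
#'   volume dimension must be divisible by it. Default `c(8, 8, 8)`.
#' @param hidden Integer vector of hidden dense-layer widths of the shared
#'   encoder (ReLU); `integer(0)` gives a purely linear encoder. Default 32.
#' @param embed_dim Embedding length (linear output layer). Default 16.
#' @param seed Seed for weight initialization and batch shuffling.
#' @return A list of class `siamese_control`.
#' @export
siamese_control <- function(margin = 1, learning_rate = 1e-4, batch_size = 4,
                            epochs = 200, decay_factor = 0.1, decay_every = 10,
                            mse_weight = 1, contrastive_weight = 1,
                            pool = c(8, 8, 8), hidden = 32L, embed_dim = 16L,
                            seed = 1L) {
  if (margin <= 0) stop_config("margin must be > 0")
  if (decay_factor <= 0 || decay_factor > 1)
    stop_config("decay_factor must be in (0, 1]")
  if (epochs < 1) stop_config("epochs must be >= 1")
  if (batch_size < 1) stop_config("batch_size must be >= 1")
  structure(list(margin = margin, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 decay_factor = decay_factor,
                 decay_every = as.integer(decay_every),
                 mse_weight = mse_weight,
                 contrastive_weight = contrastive_weight,
                 pool = as.integer(pool), hidden = as.integer(hidden),
                 embed_dim = as.integer(embed_dim), seed = as.integer(seed)),
            class = "siamese_control")
}

## ---- volume front end -------------------------------------------------

# Average blocks along one axis of a 3D array.
pool_axis <- function(a, axis, p) {
  d <- dim(a)
  if (d[axis] %% p != 0)
    stop_config("volume dimension %d not divisible by pool size %d", d[axis], p)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(a, perm)
  dp <- dim(a)
  b <- dp[1] %/% p
  m <- colMeans(matrix(a, nrow = b))
  a <- array(m, c(p, dp[2], dp[3]))
  aperm(a, order(perm))
}

#' Pooled, intensity-normalized features of one volume
#'
#' The network's fixed front end: min-max scales the volume to `[0, 1]`
#' (constant volumes map to 0) and block-averages it down to the `pool` grid,
#' returned as a flat numeric vector.
#'
#' @param volume 3D numeric array.
#' @param pool Integer target grid, e.g. `c(8, 8, 8)`.
#' @return Numeric vector of length `prod(pool)`.
#' @export
volume_features <- function(volume, pool = c(8, 8, 8)) {
  stopifnot(length(dim(volume)) == 3)
  rng <- range(volume)
  v <- if (rng[2] > rng[1]) (volume - rng[1]) / (rng[2] - rng[1])
       else array(0, dim(volume))
  for (ax in 1:3) v <- pool_axis(v, ax, pool[ax])
  as.numeric(v)
}

## ---- network core ------------------------------------------------------

# Parameter container: list(W = list of weight matrices (d_prev x d_next),
# b = list of bias vectors) for the encoder (hidden layers ReLU, final layer
# linear -> embedding), plus regression head Wr (embed_dim x 1), br.
net_init <- function(d_in, hidden, embed_dim, seed) {
  set.seed(seed)
  dims <- c(d_in, hidden, embed_dim)
  W <- list(); b <- list()
  for (l in seq_len(length(dims) - 1)) {
    W[[l]] <- matrix(stats::rnorm(dims[l] * dims[l + 1], 0,
                                  sqrt(2 / dims[l])),
                     dims[l], dims[l + 1])
    b[[l]] <- rep(0, dims[l + 1])
  }
  list(W = W, b = b,
       Wr = matrix(stats::rnorm(embed_dim, 0, sqrt(1 / embed_dim)),
                   embed_dim, 1),
       br = 0)
}

# Forward pass of the shared encoder on a batch (rows = items).
# Returns activations for backprop: A[[1]] = input, A[[L+1]] = embedding.
net_forward <- function(params, X) {
  L <- length(params$W)
  A <- vector("list", L + 1)
  A[[1]] <- X
  for (l in seq_len(L)) {
    Z <- sweep(A[[l]] %*% params$W[[l]], 2, params$b[[l]], `+`)
    A[[l + 1]] <- if (l < L) pmax(Z, 0) else Z  # ReLU hidden, linear embed
  }
  A
}

net_predict_score <- function(params, E) {
  as.numeric(E %*% params$Wr + params$br)
}

# Backprop dL/dE through the encoder; returns gradients of W, b.
net_backward <- function(params, A, dE) {
  L <- length(params$W)
  gW <- vector("list", L); gb <- vector("list", L)
  delta <- dE
  for (l in rev(seq_len(L))) {
    if (l < L) delta <- delta * (A[[l + 1]] > 0)  # ReLU mask
    gW[[l]] <- crossprod(A[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1) delta <- delta %*% t(params$W[[l]])
  }
  list(W = gW, b = gb)
}

# Dual loss and its gradients for one mini-batch of pairs.
# X1, X2: batch x d feature matrices; y1: first-visit scores; Y: 0/1 labels.
pair_loss_grad <- function(params, X1, X2, y1, Y, control, want_grad = TRUE) {
  A1 <- net_forward(params, X1)
  A2 <- net_forward(params, X2)
  E1 <- A1[[length(A1)]]; E2 <- A2[[length(A2)]]
  yhat1 <- net_predict_score(params, E1)
  nb <- nrow(X1)
  diffE <- E1 - E2
  D <- sqrt(rowSums(diffE^2))
  mse <- mean((yhat1 - y1)^2)
  hinge <- pmax(0, control$margin - D)
  con <- mean((1 - Y) * D^2 + Y * hinge^2)
  total <- control$mse_weight * mse + control$contrastive_weight * con
  out <- list(total = total, mse = mse, contrastive = con)
  if (!want_grad) return(out)

  dyhat <- control$mse_weight * 2 * (yhat1 - y1) / nb         # dL/dyhat1
  gWr <- crossprod(E1, dyhat)
  gbr <- sum(dyhat)
  # dL/dE from regression head (first item only) + contrastive term.
  Dsafe <- pmax(D, 1e-12)
  ccoef <- control$contrastive_weight / nb *
    (2 * (1 - Y) - 2 * Y * hinge / Dsafe)                     # d/dE1 factor on diffE
  dE1 <- outer(dyhat, as.numeric(params$Wr)) + diffE * ccoef
  dE2 <- -diffE * ccoef
  g1 <- net_backward(params, A1, dE1)
  g2 <- net_backward(params, A2, dE2)
  gW <- mapply(`+`, g1$W, g2$W, SIMPLIFY = FALSE)
  gb <- mapply(`+`, g1$b, g2$b, SIMPLIFY = FALSE)
  out$grad <- list(W = gW, b = gb, Wr = gWr, br = gbr)
  out
}

# One Adam update over the full parameter list.
adam_init <- function(params) {
  zero_like <- function(p) if (is.list(p)) lapply(p, zero_like) else p * 0
  list(m = zero_like(params), v = zero_like(params), t = 0)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      res <- mapply(upd, p, g, m, v, SIMPLIFY = FALSE)
      return(list(p = lapply(res, `[[`, "p"),
                  m = lapply(res, `[[`, "m"),
                  v = lapply(res, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^state$t)
    vhat <- v / (1 - beta2^state$t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  res <- mapply(upd, params, grads, state$m, state$v, SIMPLIFY = FALSE)
  list(params = lapply(res, `[[`, "p"),
       state = list(m = lapply(res, `[[`, "m"),
                    v = lapply(res, `[[`, "v"), t = state$t))
}

## ---- user-facing loss / distance primitives ---------------------------

#' Contrastive loss on an embedding distance
#'
#' `L = (1 - Y) * D^2 + Y * max(0, m - D)^2`: same-class pairs (`Y = 0`) are
#' pulled together, different-class pairs (`Y = 1`) are pushed beyond the
#' margin `m`. Vectorized over pairs.
#'
#' @param D Non-negative embedding distance(s).
#' @param Y Pair label(s), 0 (same class) or 1 (different class).
#' @param margin Margin `m` > 0.
#' @return Loss value(s), non-negative.
#' @export
contrastive_loss <- function(D, Y, margin = 1) {
  if (!all(Y %in% c(0, 1))) stop_config("Y must be 0 or 1")
  if (any(D < 0)) stop_config("D must be >= 0")
  if (margin <= 0) stop_config("margin must be > 0")
  (1 - Y) * D^2 + Y * pmax(0, margin - D)^2
}

#' Mean squared error of predicted first-visit scores
#'
#' @param predicted,actual Finite numeric vectors of equal, positive length.
#' @return Mean of squared differences over the batch.
#' @export
regression_loss <- function(predicted, actual) {
  if (length(predicted) == 0) stop_config("empty batch")
  if (length(predicted) != length(actual)) stop_config("length mismatch")
  if (!all(is.finite(predicted)) || !all(is.finite(actual)))
    stop_config("inputs must be finite")
  mean((predicted - actual)^2)
}

#' Euclidean distance between two embeddings
#'
#' @param e1,e2 Numeric vectors of equal length.
#' @return `||e1 - e2||_2`.
#' @export
pair_distance <- function(e1, e2) {
  if (length(e1) != length(e2)) stop_config("embedding length mismatch")
  sqrt(sum((e1 - e2)^2))
}

#' Normalized predicted error
#'
#' Difference between predicted and actual cognitive scores divided by the
#' pair's time gap — the per-pair performance measure, aggregated as its mean
#' and sd over validation pairs.
#'
#' @param predicted,actual Scores (points).
#' @param dt_years Positive time gap(s), years.
#' @return Numeric vector of per-pair NPE values, points/year.
#' @export
normalized_predicted_error <- function(predicted, actual, dt_years) {
  if (any(dt_years <= 0)) stop_config("dt_years must be > 0")
  (predicted - actual) / dt_years
}

#' Subject-level train/validation split
#'
#' Deterministic 70/30-style split by subject (never by pair): the training
#' set gets `floor(n * fraction)` subjects of a seeded permutation, the rest
#' validate (414 subjects at 0.7 give 289 train / 125 validation).
#'
#' @param subject_ids Character vector (duplicates allowed; the unique set is
#'   split).
#' @param fraction Training fraction in (0, 1).
#' @param seed Integer seed for the permutation.
#' @return List with character vectors `train` and `val`.
#' @export
split_subjects <- function(subject_ids, fraction = 0.7, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) stop_config("fraction must be in (0, 1)")
  subj <- sort(unique(as.character(subject_ids)))
  set.seed(as.integer(seed))
  perm <- sample(subj)
  n_train <- floor(length(subj) * fraction)
  list(train = sort(perm[seq_len(n_train)]),
       val = sort(perm[-seq_len(n_train)]))
}

## ---- model object and fitting ------------------------------------------

new_siamese_net <- function(params, control, d_in, volume_shape,
                            trained = FALSE,
                            center = rep(0, d_in), scale = rep(1, d_in)) {
  structure(list(params = params, control = control, d_in = d_in,
                 volume_shape = as.integer(volume_shape), trained = trained,
                 center = center, scale = scale,
                 log = NULL, selected_epoch = NA_integer_, split = NULL),
            class = "siamese_net")
}

#' Initialize an untrained Siamese network
#'
#' @param volume_shape Input volume dimensions (each divisible by the pooling
#'   grid in `control`).
#' @param control A [siamese_control()].
#' @return An object of class `siamese_net` with randomly initialized shared
#'   weights. Use [fit_siamese()] to train, or [network_weights<-] to install
#'   weights directly.
#' @export
siamese_network <- function(volume_shape = c(32, 32, 32),
                            control = siamese_control()) {
  if (any(volume_shape %% control$pool != 0))
    stop_config("volume_shape must be divisible by control$pool")
  d_in <- prod(control$pool)
  params <- net_init(d_in, control$hidden, control$embed_dim, control$seed)
  new_siamese_net(params, control, d_in, volume_shape)
}

#' Read or replace the network weights
#'
#' The weight list has encoder matrices `W`/biases `b` and the regression
#' head `Wr`/`br`. Installing weights marks the network as trained (e.g. when
#' loading a checkpoint or constructing an analytic toy network).
#'
#' @param object A `siamese_net`.
#' @param value Replacement weight list with the same shapes.
#' @return The weight list, or the modified object.
#' @export
network_weights <- function(object) object$params

#' @rdname network_weights
#' @export
`network_weights<-` <- function(object, value) {
  stopifnot(inherits(object, "siamese_net"))
  old <- object$params
  same_shape <- function(a, b) identical(dim(a) %||% length(a),
                                         dim(b) %||% length(b))
  if (!all(mapply(same_shape, old$W, value$W)) ||
      !same_shape(old$Wr, value$Wr))
    stop_config("replacement weights have wrong shapes")
  object$params <- value
  object$trained <- TRUE
  object
}

#' Fit the dual-loss Siamese slope model
#'
#' Trains the shared encoder + regression head on longitudinal visit pairs
#' with total loss `mse_weight * MSE + contrastive_weight * L_contrastive`,
#' Adam optimization, mini-batches, and a step learning-rate schedule. The
#' split is by subject; the returned model is the checkpoint minimizing the
#' validation sum of MSE and contrastive loss. Training is exactly
#' reproducible for a fixed `control$seed` on a single CPU.
#'
#' @param pairs A `visit_pairs` frame from [build_pairs()] (needs `scan_i`,
#'   `scan_j`, `score_i`, `label`, `subject_id`).
#' @param volumes Named list of 3D arrays keyed by scan id, or a numeric
#'   matrix of precomputed [volume_features()] rows keyed by rownames.
#' @param control A [siamese_control()].
#' @param split_fraction Training fraction of subjects (default 0.7).
#' @param split Optional explicit list `list(train =, val =)` of subject ids;
#'   overlapping sets are an error.
#' @return An object of classes `siamese_fit`, `siamese_net` with elements
#'   `params` (best weights), `log` (per-epoch train/val MSE and contrastive
#'   losses and learning rate), `selected_epoch`, and `split`.
#' @export
fit_siamese <- function(pairs, volumes, control = siamese_control(),
                        split_fraction = 0.7, split = NULL) {
  stopifnot(is.data.frame(pairs), nrow(pairs) > 0)
  feats <- as_feature_matrix(volumes, control$pool)
  vshape <- attr(feats, "volume_shape")
  missing_scans <- setdiff(unique(c(pairs$scan_i, pairs$scan_j)),
                           rownames(feats))
  if (length(missing_scans) > 0)
    stop_config("pairs reference %d scans without volumes (e.g. %s)",
                length(missing_scans), missing_scans[1])
  if (is.null(split)) {
    split <- split_subjects(pairs$subject_id, split_fraction,
                            derive_seed(control$seed, "split"))
  }
  if (length(intersect(split$train, split$val)) > 0)
    stop_config("subjects overlap between train and validation splits")
  tr <- pairs[pairs$subject_id %in% split$train, , drop = FALSE]
  va <- pairs[pairs$subject_id %in% split$val, , drop = FALSE]
  if (nrow(tr) == 0 || nrow(va) == 0)
    stop_config("both splits need at least one pair")

  # Standardize features on the training scans (a fixed affine front-end
  # transform stored with the model); near-constant features get unit scale.
  tr_scans <- unique(c(tr$scan_i, tr$scan_j))
  center <- colMeans(feats[tr_scans, , drop = FALSE])
  scale <- apply(feats[tr_scans, , drop = FALSE], 2, stats::sd)
  scale[!is.finite(scale) | scale < 1e-8] <- 1
  feats <- sweep(sweep(feats, 2, center), 2, scale, `/`)

  batch_of <- function(p, idx) list(
    X1 = feats[p$scan_i[idx], , drop = FALSE],
    X2 = feats[p$scan_j[idx], , drop = FALSE],
    y1 = p$score_i[idx], Y = p$label[idx])
  tr_all <- batch_of(tr, seq_len(nrow(tr)))
  va_all <- batch_of(va, seq_len(nrow(va)))

  d_in <- ncol(feats)
  params <- net_init(d_in, control$hidden, control$embed_dim,
                     derive_seed(control$seed, "init"))
  params$br <- mean(tr_all$y1)  # start the head at the mean training score
  opt <- adam_init(params)
  set.seed(derive_seed(control$seed, "batches"))

  log <- data.frame(epoch = integer(), lr = numeric(),
                    train_mse = numeric(), train_contrastive = numeric(),
                    val_mse = numeric(), val_contrastive = numeric())
  best <- list(val = Inf, params = params, epoch = NA_integer_)
  n_tr <- nrow(tr)
  for (epoch in seq_len(control$epochs)) {
    lr <- control$learning_rate *
      control$decay_factor^((epoch - 1) %/% control$decay_every)
    ord <- sample.int(n_tr)
    starts <- seq(1, n_tr, by = control$batch_size)
    for (s in starts) {
      idx <- ord[s:min(s + control$batch_size - 1, n_tr)]
      b <- batch_of(tr, idx)
      lg <- pair_loss_grad(params, b$X1, b$X2, b$y1, b$Y, control)
      stepped <- adam_step(params, lg$grad, opt, lr)
      params <- stepped$params
      opt <- stepped$state
    }
    ltr <- pair_loss_grad(params, tr_all$X1, tr_all$X2, tr_all$y1, tr_all$Y,
                          control, want_grad = FALSE)
    lva <- pair_loss_grad(params, va_all$X1, va_all$X2, va_all$y1, va_all$Y,
                          control, want_grad = FALSE)
    log <- rbind(log, data.frame(
      epoch = epoch, lr = lr,
      train_mse = ltr$mse, train_contrastive = ltr$contrastive,
      val_mse = lva$mse, val_contrastive = lva$contrastive))
    sel <- lva$mse + lva$contrastive  # selection: unweighted sum
    if (sel < best$val) best <- list(val = sel, params = params, epoch = epoch)
  }

  fit <- new_siamese_net(best$params, control, d_in,
                         volume_shape = vshape,
                         trained = TRUE, center = center, scale = scale)
  fit$log <- log
  fit$selected_epoch <- best$epoch
  fit$split <- split
  class(fit) <- c("siamese_fit", "siamese_net")
  fit
}

# Accept either a named list of volumes or a precomputed feature matrix.
as_feature_matrix <- function(volumes, pool) {
  if (is.matrix(volumes)) {
    if (is.null(rownames(volumes)))
      stop_config("feature matrix needs scan ids as rownames")
    attr(volumes, "volume_shape") <- attr(volumes, "volume_shape") %||% NA
    return(volumes)
  }
  stopifnot(is.list(volumes), !is.null(names(volumes)))
  feats <- t(vapply(volumes, volume_features, numeric(prod(pool)),
                    pool = pool))
  rownames(feats) <- names(volumes)
  attr(feats, "volume_shape") <- dim(volumes[[1]])
  feats
}

#' Embed one volume with the shared encoder
#'
#' Weight sharing means the embedding does not depend on which pair slot the
#' volume occupies; evaluation is deterministic for fixed weights.
#'
#' @param object A `siamese_net` (trained or not).
#' @param volume 3D array matching the configured input shape, or a
#'   precomputed feature vector of length `object$d_in`.
#' @return Numeric embedding of length `control$embed_dim`.
#' @export
embed_volume <- function(object, volume) {
  stopifnot(inherits(object, "siamese_net"))
  x <- if (is.array(volume) && length(dim(volume)) == 3) {
    if (!all(is.na(object$volume_shape)) &&
        !identical(dim(volume), as.integer(object$volume_shape)))
      stop_config("volume shape %s does not match model input %s",
                  paste(dim(volume), collapse = "x"),
                  paste(object$volume_shape, collapse = "x"))
    volume_features(volume, object$control$pool)
  } else as.numeric(volume)
  if (length(x) != object$d_in)
    stop_config("feature length %d != model input %d", length(x), object$d_in)
  x <- (x - object$center) / object$scale
  A <- net_forward(object$params, matrix(x, 1))
  as.numeric(A[[length(A)]])
}

#' Predict pair slopes (and per-visit scores) from a trained model
#'
#' The shared regression head is applied to each image of a pair
#' independently; the predicted aging slope of the pair is
#' `(yhat_j - yhat_i) / dt_years`, points per year.
#'
#' @param object A trained `siamese_fit` / `siamese_net`.
#' @param pairs `visit_pairs` frame.
#' @param volumes Named volume list or feature matrix (see [fit_siamese()]).
#' @param ... Unused.
#' @return `pairs` with columns `yhat_i`, `yhat_j`, `predicted_slope`, and
#'   `npe` (normalized predicted error of the first-visit score) appended.
#' @export
predict.siamese_net <- function(object, pairs, volumes, ...) {
  if (!isTRUE(object$trained))
    stop_config("model is untrained; fit it or install weights first")
  feats <- as_feature_matrix(volumes, object$control$pool)
  feats <- sweep(sweep(feats, 2, object$center), 2, object$scale, `/`)
  A1 <- net_forward(object$params, feats[pairs$scan_i, , drop = FALSE])
  A2 <- net_forward(object$params, feats[pairs$scan_j, , drop = FALSE])
  y1 <- net_predict_score(object$params, A1[[length(A1)]])
  y2 <- net_predict_score(object$params, A2[[length(A2)]])
  out <- pairs
  out$yhat_i <- y1
  out$yhat_j <- y2
  out$predicted_slope <- (y2 - y1) / pairs$dt_years
  out$npe <- normalized_predicted_error(y1, pairs$score_i, pairs$dt_years)
  out
}

#' @export
print.siamese_net <- function(x, ...) {
  arch <- paste(c(x$d_in, x$control$hidden, x$control$embed_dim),
                collapse = "-")
  cat(sprintf("Siamese slope model (%s encoder, margin %.2f): %s\n", arch,
              x$control$margin,
              if (isTRUE(x$trained)) "trained" else "untrained"))
  if (!is.null(x$log)) {
    sel <- x$log[x$log$epoch == x$selected_epoch, ]
    cat(sprintf("  selected epoch %d/%d: val MSE %.4f + contrastive %.4f\n",
                x$selected_epoch, nrow(x$log), sel$val_mse,
                sel$val_contrastive))
  }
  invisible(x)
}

#' @export
summary.siamese_fit <- function(object, ...) {
  sel <- object$log[object$log$epoch == object$selected_epoch, ]
  structure(list(
    control = object$control,
    n_epochs = nrow(object$log),
    selected_epoch = object$selected_epoch,
    n_train_subjects = length(object$split$train),
    n_val_subjects = length(object$split$val),
    selected = sel,
    log = object$log), class = "summary.siamese_fit")
}

#' @export
print.summary.siamese_fit <- function(x, ...) {
  cat(sprintf("Dual-loss Siamese fit: %d epochs, %d/%d train/val subjects\n",
              x$n_epochs, x$n_train_subjects, x$n_val_subjects))
  cat(sprintf("  selected epoch %d: train MSE %.4f / contrastive %.4f; val MSE %.4f / contrastive %.4f\n",
              x$selected_epoch, x$selected$train_mse,
              x$selected$train_contrastive, x$selected$val_mse,
              x$selected$val_contrastive))
  invisible(x)
}

#' @export
coef.siamese_net <- function(object, ...) object$params

#' @export
plot.siamese_fit <- function(x, ...) {
  log <- x$log
  tot_tr <- log$train_mse + log$train_contrastive
  tot_va <- log$val_mse + log$val_contrastive
  graphics::plot(log$epoch, tot_tr, type = "l", xlab = "epoch",
                 ylab = "MSE + contrastive loss",
                 ylim = range(c(tot_tr, tot_va)), ...)
  graphics::lines(log$epoch, tot_va, lty = 2)
  graphics::abline(v = x$selected_epoch, col = "grey60", lty = 3)
  graphics::legend("topright", legend = c("train", "validation"),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}

#' Save or load a model checkpoint
#'
#' Plain-text JSON checkpoint holding weights, hyperparameters, the training
#' log and the subject split; numbers are written at full precision so a
#' round trip reproduces predictions exactly.
#'
#' @param object A `siamese_net`.
#' @param path File path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored model.
#' @export
save_checkpoint <- function(object, path) {
  stopifnot(inherits(object, "siamese_net"))
  payload <- list(
    control = unclass(object$control),
    d_in = object$d_in,
    volume_shape = object$volume_shape,
    trained = object$trained,
    selected_epoch = object$selected_epoch,
    split = object$split,
    log = object$log,
    center = object$center,
    scale = object$scale,
    params = list(W = lapply(object$params$W, as.numeric),
                  W_dims = lapply(object$params$W, dim),
                  b = object$params$b,
                  Wr = as.numeric(object$params$Wr),
                  br = object$params$br))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop_config("input file not found: %s", path)
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  ctl <- do.call(siamese_control, p$control[names(p$control) %in%
                                              names(formals(siamese_control))])
  W <- mapply(function(w, d) matrix(unlist(w), unlist(d)[1], unlist(d)[2]),
              raw$params$W, raw$params$W_dims, SIMPLIFY = FALSE)
  b <- lapply(raw$params$b, function(x) as.numeric(unlist(x)))
  params <- list(W = W, b = b,
                 Wr = matrix(unlist(raw$params$Wr), ncol = 1),
                 br = p$params$br)
  obj <- new_siamese_net(params, ctl, p$d_in, p$volume_shape,
                         trained = isTRUE(p$trained),
                         center = p$center %||% rep(0, p$d_in),
                         scale = p$scale %||% rep(1, p$d_in))
  obj$selected_epoch <- p$selected_epoch
  obj$split <- p$split
  obj$log <- p$log
  if (isTRUE(p$trained)) class(obj) <- c("siamese_fit", "siamese_net")
  obj
}
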