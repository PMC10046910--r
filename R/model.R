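#' KCS-FCnet model configuration
#'
#' Hyperparameters of the kernel cross-spectral functional connectivity
#' network. The architecture is: bias-free temporal convolution (`n_filters`
#' kernels of `kernel_length` samples, valid mode, stride 1), batch
#' normalization and ELU, Gaussian-kernel pairwise connectivity per filter,
#' average over the filter axis, batch normalization and ELU, dropout, and a
#' dense softmax readout over the vectorized upper-triangle connectivity.
#'
#' @param n_filters number of temporal convolution filters `Nf` (the grid
#'   search explores `{2, 3, 4}`).
#' @param kernel_length temporal kernel length in samples; `NULL` resolves to
#'   half the sampling rate at fit time (the kernel length is tied to the
#'   sampling frequency so its span is a fixed 0.5 s).
#' @param n_channels,n_times input dimensions `Nc`, `Nt`; filled in by
#'   [kcs_fit()] from the training set when `NULL`.
#' @param n_classes number of classes `Ny` (binary decoding: 2).
#' @param dropout_rate dropout probability before the readout.
#' @param conv_max_norm,dense_max_norm max-norm constraints re-projected
#'   after every update: Euclidean norm of each convolution kernel and of
#'   each readout column.
#' @param sigma_init `"median_heuristic"` (kernel scale from the median
#'   pairwise distance of the initial forward pass) or `"fixed"`.
#' @param sigma_value kernel scale used when `sigma_init = "fixed"`.
#' @param learning_rate,epochs full-batch Adam settings.
#' @param bn_eps,bn_momentum batch-normalization variance floor and running-
#'   statistics update rate.
#' @param seed RNG seed for initialization and dropout.
#' @return An object of class `kcs_config`.
#' @export
kcs_config <- function(n_filters = 2L, kernel_length = NULL,
                       n_channels = NULL, n_times = NULL, n_classes = 2L,
                       dropout_rate = 0.5, conv_max_norm = 2.0,
                       dense_max_norm = 0.5,
                       sigma_init = c("median_heuristic", "fixed"),
                       sigma_value = 1.0, learning_rate = 1e-3,
                       epochs = 500L, bn_eps = 1e-3, bn_momentum = 0.1,
                       seed = 1L) {
  sigma_init <- match.arg(sigma_init)
  stopifnot(n_filters >= 1L, n_classes >= 2L,
            dropout_rate >= 0, dropout_rate < 1,
            learning_rate > 0, epochs >= 1L, sigma_value > 0)
  if (!is.null(kernel_length) && !is.null(n_times) &&
      kernel_length >= n_times) {
    stop("kernel_length (", kernel_length, ") must be < n_times (",
         n_times, ")")
  }
  structure(
    list(n_filters = as.integer(n_filters),
         kernel_length = if (!is.null(kernel_length)) as.integer(kernel_length),
         n_channels = if (!is.null(n_channels)) as.integer(n_channels),
         n_times = if (!is.null(n_times)) as.integer(n_times),
         n_classes = as.integer(n_classes),
         dropout_rate = dropout_rate, conv_max_norm = conv_max_norm,
         dense_max_norm = dense_max_norm, sigma_init = sigma_init,
         sigma_value = sigma_value, learning_rate = learning_rate,
         epochs = as.integer(epochs), bn_eps = bn_eps,
         bn_momentum = bn_momentum, seed = as.integer(seed)),
    class = "kcs_config"
  )
}

#' Gaussian kernel between two filtered channel signals
#'
#' `exp(-||z - z'||^2 / (2 sigma^2))`: the positive-definite similarity whose
#' spectral representation grounds the cross-spectral reading of the
#' connectivity layer. Returns values in `(0, 1]`, with 1 iff `z == z'`.
#'
#' @param z,z_prime numeric vectors of equal length.
#' @param sigma positive scale (bandwidth).
#' @return Scalar kernel value in `(0, 1]`.
#' @examples
#' gaussian_kernel(1:4, 1:4, 2)           # 1
#' @export
gaussian_kernel <- function(z, z_prime, sigma) {
  if (length(z) != length(z_prime)) {
    stop("length mismatch: ", length(z), " vs ", length(z_prime))
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("'sigma' must be a positive scalar")
  }
  exp(-sum((z - z_prime)^2) / (2 * sigma^2))
}

#' Pairwise Gaussian-kernel connectivity of filtered channels
#'
#' For each temporal filter, evaluates the Gaussian kernel between every
#' unordered pair of filtered channel signals, returning the strict upper
#' triangle in the fixed lexicographic pair order of [channel_pairs()].
#'
#' @param filtered numeric array `Nf x Nc x T` of filtered channel signals.
#' @param sigma positive kernel scale.
#' @return Matrix `Nf x (Nc (Nc - 1) / 2)` of kernel values in `(0, 1]`.
#' @export
connectivity_block <- function(filtered, sigma) {
  stopifnot(is.array(filtered), length(dim(filtered)) == 3L)
  if (any(!is.finite(filtered))) stop("non-finite values in 'filtered'")
  if (sigma <= 0) stop("'sigma' must be positive")
  nf <- dim(filtered)[1L]
  nc <- dim(filtered)[2L]
  idx <- channel_pairs(nc)
  out <- matrix(0, nf, nrow(idx))
  for (f in seq_len(nf)) {
    Z <- filtered[f, , , drop = TRUE]
    if (is.null(dim(Z))) Z <- matrix(Z, nrow = nc)
    D <- sq_dists(Z)
    out[f, ] <- exp(-D[idx] / (2 * sigma^2))
  }
  out
}

# Pairwise squared Euclidean distances between the rows of Z (Nc x T),
# clamped at zero against cancellation error.
sq_dists <- function(Z) {
  G <- tcrossprod(Z)
  s <- diag(G)
  D <- outer(s, s, "+") - 2 * G
  D[D < 0] <- 0
  D
}

elu <- function(x) {
  neg <- x < 0
  x[neg] <- expm1(x[neg])
  x
}
elu_grad <- function(x) {
  g <- rep.int(1, length(x))
  neg <- x < 0
  g[neg] <- exp(x[neg])
  g
}

softmax_rows <- function(L) {
  L <- L - apply(L, 1L, max)
  E <- exp(L)
  E / rowSums(E)
}

# Lag-embedding of the trial tensor for the valid-mode temporal convolution:
# returns a (B*Nc*T) x dt matrix XL such that XL %*% t(W) stacks, for every
# filter, the cross-correlation C[b,c,t] = sum_tau W[f,tau] X[b,c,t+tau-1].
# Rows run over c fastest, then t, then b, so each trial occupies one
# contiguous block of nc*T rows (cheap per-trial slicing). Computed once per
# fit and reused across epochs.
lag_matrix <- function(X, dt) {
  d <- dim(X)
  B <- d[1L]; nc <- d[2L]; nt <- d[3L]
  Tt <- nt - dt + 1L
  Xp <- aperm(X, c(2L, 3L, 1L))                 # nc x nt x B
  XL <- matrix(0, nc * Tt * B, dt)
  for (tau in seq_len(dt)) {
    XL[, tau] <- as.vector(Xp[, tau:(tau + Tt - 1L), , drop = FALSE])
  }
  XL
}

#' Trainable-parameter count of a configuration
#'
#' Closed-form count implied by the architecture: `Nf * dt` convolution
#' weights (bias-free), `2 Nf` scale/shift pairs for the first batch
#' normalization, 2 for the second, `Nc (Nc - 1) / 2 * Ny + Ny` for the dense
#' readout, plus 1 for the kernel scale `sigma`. The count matches the
#' number of values updated by the optimizer in [kcs_fit()].
#'
#' @param config a [kcs_config()] with `n_channels`, `kernel_length` and
#'   `n_classes` resolved.
#' @return Integer parameter count.
#' @examples
#' count_parameters(kcs_config(n_filters = 4, kernel_length = 64,
#'                             n_channels = 64))   # 4301
#' @export
count_parameters <- function(config) {
  stopifnot(inherits(config, "kcs_config"))
  if (is.null(config$n_channels) || is.null(config$kernel_length)) {
    stop("config must have 'n_channels' and 'kernel_length' resolved")
  }
  nf <- config$n_filters
  dt <- config$kernel_length
  nc <- config$n_channels
  ny <- config$n_classes
  p <- (nc * (nc - 1L)) %/% 2L
  as.integer(nf * dt + 2L * nf + 2L + p * ny + ny + 1L)
}

# Number of values the optimizer actually updates in a params object.
n_trainable <- function(params) {
  length(params$W) + length(params$gamma1) + length(params$beta1) +
    length(params$gamma2) + length(params$beta2) +
    length(params$V) + length(params$b) + length(params$log_sigma)
}

#' Initialize model parameters
#'
#' Convolution and readout weights are drawn Glorot-uniform (seeded); batch
#' norm scales start at 1 and shifts at 0. The kernel scale is stored as
#' `log(sigma)` so positivity holds throughout training. Under the median
#' heuristic, `sigma^2` is set to half the median squared pairwise channel
#' distance observed on a forward pass of `sample_batch` through the initial
#' convolution stage, so the median kernel value starts at `exp(-1)`.
#'
#' @param config a [kcs_config()] with input dimensions resolved.
#' @param sample_batch an [eeg_trial_set()] used by the median heuristic.
#' @return An object of class `kcs_params`.
#' @export
init_params <- function(config, sample_batch) {
  stopifnot(inherits(config, "kcs_config"),
            inherits(sample_batch, "eeg_trial_set"))
  nf <- config$n_filters
  dt <- config$kernel_length
  nc <- config$n_channels
  ny <- config$n_classes
  p <- (nc * (nc - 1L)) %/% 2L
  stopifnot(!is.null(dt), !is.null(nc))

  lim_w <- sqrt(6 / (dt + nf))
  lim_v <- sqrt(6 / (p + ny))
  W <- matrix(stats::runif(nf * dt, -lim_w, lim_w), nf, dt)
  V <- matrix(stats::runif(p * ny, -lim_v, lim_v), p, ny)

  params <- list(
    W = W,
    gamma1 = rep(1, nf), beta1 = rep(0, nf),
    gamma2 = 1, beta2 = 0,
    log_sigma = 0,
    V = V, b = rep(0, ny),
    bn1_mean = rep(0, nf), bn1_var = rep(1, nf),
    bn2_mean = 0, bn2_var = 1
  )
  class(params) <- "kcs_params"

  if (config$sigma_init == "median_heuristic") {
    med <- median_sq_dist(sample_batch$data, params, config)
    if (!is.finite(med) || med <= 0) {
      warning("median heuristic degenerate (all pairwise distances zero); ",
              "falling back to sigma = 1")
      params$log_sigma <- 0
    } else {
      params$log_sigma <- log(sqrt(med / 2))
    }
  } else {
    params$log_sigma <- log(config$sigma_value)
  }
  params
}

# Median squared pairwise channel distance after convolution + batch-stat
# normalization + ELU with the initial weights. Drives the median heuristic.
median_sq_dist <- function(X, params, config) {
  d <- dim(X)
  B <- d[1L]; nc <- d[2L]; nt <- d[3L]
  dt <- config$kernel_length
  Tt <- nt - dt + 1L
  blk <- nc * Tt
  XL <- lag_matrix(X, dt)
  C <- XL %*% t(params$W)
  idx <- channel_pairs(nc)
  dists <- matrix(0, B * config$n_filters, nrow(idx))
  k <- 0L
  for (f in seq_len(config$n_filters)) {
    x <- C[, f]
    mu <- mean(x); v <- mean((x - mu)^2)
    act <- elu(params$gamma1[f] * (x - mu) / sqrt(v + config$bn_eps) +
                 params$beta1[f])
    for (b in seq_len(B)) {
      Zb <- matrix(act[((b - 1L) * blk + 1L):(b * blk)], nc, Tt)
      k <- k + 1L
      dists[k, ] <- sq_dists(Zb)[idx]
    }
  }
  stats::median(dists)
}

# Full forward pass. X: B x Nc x Nt. Returns probs (B x Ny), connectivity
# (B x P, the filter-averaged kernel values, pre readout-normalization), and
# when keep_cache = TRUE all intermediates needed by the backward pass.
# training = TRUE uses batch statistics in both normalizations and applies
# the supplied (or freshly drawn) inverted-dropout mask.
kcs_forward <- function(X, params, config, training = FALSE,
                        dropout_mask = NULL, keep_cache = FALSE, XL = NULL) {
  d <- dim(X)
  B <- d[1L]; nc <- d[2L]; nt <- d[3L]
  nf <- config$n_filters
  dt <- config$kernel_length
  if (!is.null(config$n_channels) && nc != config$n_channels) {
    stop("input has ", nc, " channels, config expects ", config$n_channels)
  }
  if (dt >= nt) stop("kernel_length ", dt, " must be < n_times ", nt)
  Tt <- nt - dt + 1L
  idx <- channel_pairs(nc)
  p <- nrow(idx)
  eps <- config$bn_eps
  sigma <- exp(params$log_sigma)

  if (is.null(XL)) XL <- lag_matrix(X, dt)
  C <- XL %*% t(params$W)                       # (nc*Tt*B) x nf, trial-blocked

  # stage-1 batch norm (per filter map) + ELU
  xhat1 <- matrix(0, nrow(C), nf)
  pre1 <- matrix(0, nrow(C), nf)
  mu1 <- numeric(nf); var1 <- numeric(nf)
  for (f in seq_len(nf)) {
    if (training) {
      mu1[f] <- mean(C[, f]); var1[f] <- mean((C[, f] - mu1[f])^2)
    } else {
      mu1[f] <- params$bn1_mean[f]; var1[f] <- params$bn1_var[f]
    }
    xhat1[, f] <- (C[, f] - mu1[f]) / sqrt(var1[f] + eps)
    pre1[, f] <- params$gamma1[f] * xhat1[, f] + params$beta1[f]
  }
  Z <- elu(pre1)

  # Gaussian-kernel connectivity per (trial, filter)
  blk <- nc * Tt
  K <- array(0, dim = c(B, p, nf))
  Dsq <- array(0, dim = c(B, p, nf))
  for (f in seq_len(nf)) {
    Zf <- Z[, f]
    for (b in seq_len(B)) {
      Zb <- matrix(Zf[((b - 1L) * blk + 1L):(b * blk)], nc, Tt)
      Dsq[b, , f] <- sq_dists(Zb)[idx]
    }
  }
  K[] <- exp(-Dsq / (2 * sigma^2))
  A <- matrix(rowSums(matrix(K, B * p, nf)), B, p) / nf   # filter average

  # stage-2 batch norm (single map) + ELU
  if (training) {
    mu2 <- mean(A); var2 <- mean((A - mu2)^2)
  } else {
    mu2 <- params$bn2_mean; var2 <- params$bn2_var
  }
  xhat2 <- (A - mu2) / sqrt(var2 + eps)
  pre2 <- params$gamma2 * xhat2 + params$beta2
  H0 <- elu(pre2)

  if (training && config$dropout_rate > 0) {
    if (is.null(dropout_mask)) {
      dropout_mask <- matrix(
        stats::rbinom(B * p, 1L, 1 - config$dropout_rate) /
          (1 - config$dropout_rate), B, p)
    }
    H <- H0 * dropout_mask
  } else {
    dropout_mask <- NULL
    H <- H0
  }

  logits <- H %*% params$V + matrix(params$b, B, config$n_classes,
                                    byrow = TRUE)
  probs <- softmax_rows(logits)

  out <- list(probs = probs, connectivity = A)
  if (keep_cache) {
    out$cache <- list(XL = XL, C = C, xhat1 = xhat1, pre1 = pre1, Z = Z,
                      K = K, Dsq = Dsq, A = A, xhat2 = xhat2, pre2 = pre2,
                      H0 = H0, H = H, dropout_mask = dropout_mask,
                      mu1 = mu1, var1 = var1, mu2 = mu2, var2 = var2,
                      sigma = sigma, B = B, nc = nc, Tt = Tt, idx = idx)
  }
  out
}

#' Forward pass of the connectivity network
#'
#' Maps a batch of trials to class probabilities and to the per-trial
#' functional connectivity vector (the Gaussian-kernel values averaged over
#' the temporal filters, before the readout normalization). Rows of `probs`
#' sum to one; connectivity values lie in `(0, 1]`.
#'
#' @param X numeric array `B x Nc x Nt`, or an [eeg_trial_set()].
#' @param params a `kcs_params` object.
#' @param config the matching [kcs_config()].
#' @param training logical; `TRUE` uses batch statistics in the
#'   normalizations and applies dropout (training mode), `FALSE` (default)
#'   runs deterministic inference with the stored running statistics.
#' @return List with `probs` (`B x Ny`) and `connectivity`
#'   (`B x Nc (Nc - 1) / 2`).
#' @export
kcs_predict <- function(X, params, config, training = FALSE) {
  if (inherits(X, "eeg_trial_set")) X <- X$data
  kcs_forward(X, params, config, training = training)[c("probs",
                                                        "connectivity")]
}

# Cross-entropy loss and full gradient for one training-mode forward pass.
# y: integer labels in {0, 1}. Returns loss, gradient list (same layout as
# the trainable entries of params), and the batch statistics for the
# running-average update.
kcs_backward <- function(X, y, params, config, dropout_mask = NULL,
                         XL = NULL) {
  fw <- kcs_forward(X, params, config, training = TRUE,
                    dropout_mask = dropout_mask, keep_cache = TRUE, XL = XL)
  ch <- fw$cache
  B <- ch$B; nc <- ch$nc; Tt <- ch$Tt; idx <- ch$idx
  nf <- config$n_filters
  p <- nrow(idx)
  eps <- config$bn_eps
  sigma <- ch$sigma

  Y <- matrix(0, B, config$n_classes)
  Y[cbind(seq_len(B), y + 1L)] <- 1
  eps_p <- 1e-12
  loss <- -mean(log(pmax(fw$probs[cbind(seq_len(B), y + 1L)], eps_p)))

  dlogits <- (fw$probs - Y) / B
  dV <- crossprod(ch$H, dlogits)
  db <- colSums(dlogits)
  dH <- dlogits %*% t(params$V)
  if (!is.null(ch$dropout_mask)) dH <- dH * ch$dropout_mask
  dpre2 <- dH * elu_grad(ch$pre2)

  # stage-2 batch-norm backward (single map over all B*p entries)
  n2 <- B * p
  dgamma2 <- sum(dpre2 * ch$xhat2)
  dbeta2 <- sum(dpre2)
  dxhat2 <- dpre2 * params$gamma2
  istd2 <- 1 / sqrt(ch$var2 + eps)
  dA <- (istd2 / n2) * (n2 * dxhat2 - sum(dxhat2) -
                          ch$xhat2 * sum(dxhat2 * ch$xhat2))

  # filter-average pooling and kernel backward
  dlog_sigma <- 0
  dZ <- matrix(0, B * nc * Tt, nf)
  for (f in seq_len(nf)) {
    dK_f <- dA / nf                              # B x p
    K_f <- ch$K[, , f]
    D_f <- ch$Dsq[, , f]
    if (is.null(dim(K_f))) { K_f <- matrix(K_f, B, p); D_f <- matrix(D_f, B, p) }
    dlog_sigma <- dlog_sigma + sum(dK_f * K_f * D_f) / sigma^2
    g <- -dK_f * K_f / (2 * sigma^2)             # dL/dD, B x p
    blk <- nc * Tt
    Zcol <- ch$Z[, f]
    dZcol <- numeric(B * blk)
    for (b in seq_len(B)) {
      Gm <- matrix(0, nc, nc)
      Gm[idx] <- g[b, ]
      Gm[idx[, c(2L, 1L)]] <- g[b, ]
      rows <- ((b - 1L) * blk + 1L):(b * blk)
      Zb <- matrix(Zcol[rows], nc, Tt)
      dZcol[rows] <- 2 * (rowSums(Gm) * Zb - Gm %*% Zb)
    }
    dZ[, f] <- dZcol
  }

  # stage-1 batch-norm backward per filter map
  n1 <- B * nc * Tt
  dgamma1 <- numeric(nf); dbeta1 <- numeric(nf)
  dC <- matrix(0, n1, nf)
  for (f in seq_len(nf)) {
    dpre1 <- dZ[, f] * elu_grad(ch$pre1[, f])
    dgamma1[f] <- sum(dpre1 * ch$xhat1[, f])
    dbeta1[f] <- sum(dpre1)
    dxhat <- dpre1 * params$gamma1[f]
    istd <- 1 / sqrt(ch$var1[f] + eps)
    dC[, f] <- (istd / n1) * (n1 * dxhat - sum(dxhat) -
                                ch$xhat1[, f] * sum(dxhat * ch$xhat1[, f]))
  }
  dW <- crossprod(dC, ch$XL)

  list(loss = loss,
       grads = list(W = dW, gamma1 = dgamma1, beta1 = dbeta1,
                    gamma2 = dgamma2, beta2 = dbeta2,
                    log_sigma = dlog_sigma, V = dV, b = db),
       batch_stats = list(mu1 = ch$mu1, var1 = ch$var1,
                          mu2 = ch$mu2, var2 = ch$var2),
       probs = fw$probs)
}

trainable_names <- c("W", "gamma1", "beta1", "gamma2", "beta2",
                     "log_sigma", "V", "b")

#' Fit the connectivity network by full-batch gradient descent
#'
#' Minimizes mean categorical cross-entropy over the whole training batch
#' with Adam, back-propagating through every stage including the kernel
#' scale `sigma` (trained in log space, hence positive throughout). After
#' every update the max-norm constraints are re-projected: each convolution
#' kernel onto the ball of radius `conv_max_norm`, each readout column onto
#' radius `dense_max_norm`. Training aborts with a diagnostic if the loss
#' becomes non-finite.
#'
#' @param train an [eeg_trial_set()] containing both classes.
#' @param config a [kcs_config()]; `n_channels`, `n_times` and (if `NULL`)
#'   `kernel_length = fs / 2` are resolved from `train`.
#' @return An object of class `kcs_fcnet`: list with `params`, `config` and
#'   `log` (a data frame with per-epoch `loss` and training `accuracy`).
#' @export
kcs_fit <- function(train, config = kcs_config()) {
  stopifnot(inherits(train, "eeg_trial_set"), inherits(config, "kcs_config"))
  if (length(unique(train$labels)) < 2L) {
    stop("training set must contain both classes")
  }
  config$n_channels <- n_channels(train)
  config$n_times <- n_times(train)
  if (is.null(config$kernel_length)) {
    config$kernel_length <- as.integer(round(train$fs / 2))
  }
  if (config$kernel_length >= config$n_times) {
    stop("kernel_length ", config$kernel_length, " must be < n_times ",
         config$n_times)
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  params <- init_params(config, train)
  X <- train$data
  y <- train$labels
  XL <- lag_matrix(X, config$kernel_length)   # fixed across epochs

  state <- list()   # Adam moments
  lr <- config$learning_rate
  beta_1 <- 0.9; beta_2 <- 0.999; adam_eps <- 1e-8
  log_loss <- numeric(config$epochs)
  log_acc <- numeric(config$epochs)

  for (epoch in seq_len(config$epochs)) {
    bk <- kcs_backward(X, y, params, config, XL = XL)
    if (!is.finite(bk$loss)) {
      stop("training diverged at epoch ", epoch, " (loss = ", bk$loss, ")")
    }
    log_loss[epoch] <- bk$loss
    pred <- max.col(bk$probs, ties.method = "first") - 1L
    log_acc[epoch] <- mean(pred == y)

    for (nm in trainable_names) {
      g <- bk$grads[[nm]]
      if (is.null(state[[nm]])) {
        state[[nm]] <- list(m = g * 0, v = g * 0)
      }
      st <- state[[nm]]
      st$m <- beta_1 * st$m + (1 - beta_1) * g
      st$v <- beta_2 * st$v + (1 - beta_2) * g^2
      state[[nm]] <- st
      mhat <- st$m / (1 - beta_1^epoch)
      vhat <- st$v / (1 - beta_2^epoch)
      params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + adam_eps)
    }

    # max-norm re-projection
    wn <- sqrt(rowSums(params$W^2))
    over <- wn > config$conv_max_norm
    if (any(over)) {
      params$W[over, ] <- params$W[over, , drop = FALSE] *
        (config$conv_max_norm / wn[over])
    }
    vn <- sqrt(colSums(params$V^2))
    overv <- vn > config$dense_max_norm
    if (any(overv)) {
      params$V[, overv] <- sweep(params$V[, overv, drop = FALSE], 2L,
                                 config$dense_max_norm / vn[overv], `*`)
    }

    # running statistics for inference-mode normalization
    mom <- config$bn_momentum
    params$bn1_mean <- (1 - mom) * params$bn1_mean + mom * bk$batch_stats$mu1
    params$bn1_var <- (1 - mom) * params$bn1_var + mom * bk$batch_stats$var1
    params$bn2_mean <- (1 - mom) * params$bn2_mean + mom * bk$batch_stats$mu2
    params$bn2_var <- (1 - mom) * params$bn2_var + mom * bk$batch_stats$var2
  }

  structure(
    list(params = params, config = config,
         log = data.frame(epoch = seq_len(config$epochs), loss = log_loss,
                          accuracy = log_acc)),
    class = "kcs_fcnet"
  )
}

#' @export
print.kcs_fcnet <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<kcs_fcnet> Nf=%d, kernel=%d samples, Nc=%d, Ny=%d; ",
                     "%d trainable parameters\n"),
              cfg$n_filters, cfg$kernel_length, cfg$n_channels,
              cfg$n_classes, count_parameters(cfg)))
  n <- nrow(x$log)
  cat(sprintf("  final loss %.4f, training accuracy %.3f (epoch %d), sigma %.4f\n",
              x$log$loss[n], x$log$accuracy[n], n, exp(x$params$log_sigma)))
  invisible(x)
}

#' Predicted class probabilities of a fitted network
#'
#' @param object a fitted `kcs_fcnet`.
#' @param newdata an [eeg_trial_set()] or `B x Nc x Nt` array.
#' @param ... ignored.
#' @return Matrix `B x Ny` of class probabilities (inference mode: dropout
#'   off, running normalization statistics).
#' @export
predict.kcs_fcnet <- function(object, newdata, ...) {
  kcs_predict(newdata, object$params, object$config)$probs
}

#' Extract trial-wise functional connectivity
#'
#' Runs the network in inference mode (dropout off, running statistics) and
#' returns the filter-averaged Gaussian-kernel connectivity of every trial:
#' one value in `(0, 1]` per unordered channel pair, in the lexicographic
#' order of [channel_pairs()]. The full symmetric connectivity matrix is
#' recoverable by mirroring since the kernel is symmetric in its arguments.
#'
#' @param model a fitted `kcs_fcnet` (an unfitted one is accepted with a
#'   warning: initial-state connectivity is legal).
#' @param trials an [eeg_trial_set()].
#' @return Object of class `connectivity_tensor`: list with `values`
#'   (`R x Nc (Nc - 1) / 2` matrix), `pair_index` (from [channel_pairs()]),
#'   `labels` and `channel_names` carried over from `trials`.
#' @export
extract_connectivity <- function(model, trials) {
  stopifnot(inherits(trials, "eeg_trial_set"))
  if (!inherits(model, "kcs_fcnet")) {
    warning("extracting connectivity from unfitted parameters")
  }
  params <- model$params
  config <- model$config
  conn <- kcs_predict(trials, params, config)$connectivity
  structure(
    list(values = conn, pair_index = channel_pairs(n_channels(trials)),
         labels = trials$labels, channel_names = trials$channel_names),
    class = "connectivity_tensor"
  )
}
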