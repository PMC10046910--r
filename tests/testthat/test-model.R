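test_that("gaussian_kernel matches its closed form and rejects bad input", {
  expect_equal(gaussian_kernel(1:8, 1:8, 0.5), 1)
  # squared distance exactly 2 sigma^2 gives exp(-1)
  sigma <- 1.3
  z <- c(sqrt(2) * sigma, 0)
  expect_equal(gaussian_kernel(z, c(0, 0), sigma), exp(-1), tolerance = 1e-12)

  set.seed(42)
  a <- stats::rnorm(32); b <- stats::rnorm(32)
  expect_equal(gaussian_kernel(a, b, 1.5),
               exp(-sum((a - b)^2) / (2 * 1.5^2)), tolerance = 1e-12)

  expect_error(gaussian_kernel(1:3, 1:4, 1), "mismatch")
  expect_error(gaussian_kernel(1:3, 1:3, 0), "positive")
})

test_that("connectivity_block equals the brute-force pair loop", {
  set.seed(7)
  filt <- array(stats::rnorm(2 * 8 * 49), dim = c(2, 8, 49))
  got <- connectivity_block(filt, 2)
  idx <- channel_pairs(8)
  want <- matrix(0, 2, nrow(idx))
  for (f in 1:2) {
    for (i in seq_len(nrow(idx))) {
      want[f, i] <- gaussian_kernel(filt[f, idx[i, 1L], ],
                                    filt[f, idx[i, 2L], ], 2)
    }
  }
  expect_lt(max(abs(got - want)), 1e-5)

  # identical channels within a filter give a row of ones
  same <- array(rep(stats::rnorm(30), each = 1), dim = c(1, 4, 30))
  for (c in 2:4) same[1, c, ] <- same[1, 1, ]
  expect_equal(as.numeric(connectivity_block(same, 1)), rep(1, 6))

  # pair ordering for Nc = 4 is lexicographic
  expect_equal(unname(channel_pairs(4)),
               cbind(c(1L, 1L, 1L, 2L, 2L, 3L), c(2L, 3L, 4L, 3L, 4L, 4L)))
  expect_error(connectivity_block(array(NaN, c(1, 2, 3)), 1), "finite")
})

test_that("forward pass is a softmax over the composed connectivity", {
  set.seed(21)
  nc <- 3L; nt <- 16L; dt <- 4L
  X <- array(stats::rnorm(nc * nt), dim = c(1, nc, nt))
  cfg <- kcs_config(n_filters = 1L, kernel_length = dt, n_channels = nc,
                    n_times = nt, dropout_rate = 0, sigma_init = "fixed",
                    sigma_value = 1.4, bn_eps = 0)
  set.seed(1)
  params <- init_params(cfg, eeg_trial_set(
    array(stats::rnorm(2 * nc * nt), dim = c(2, nc, nt)), c(0L, 1L), 16))
  # identity normalizations: scale 1, shift 0, running stats 0/1, eps 0
  params$V <- matrix(stats::rnorm(6), 3, 2)
  params$b <- c(0.2, -0.1)

  got <- kcs_predict(X, params, cfg)
  want <- forward_oracle(matrix(X[1, , ], nc, nt), params$W,
                         exp(params$log_sigma), params$V, params$b)
  expect_equal(as.numeric(got$probs), want, tolerance = 1e-6)

  # softmax contract and uniform readout
  expect_equal(rowSums(got$probs), 1, tolerance = 1e-6)
  params0 <- params
  params0$V[] <- 0; params0$b[] <- 0
  expect_equal(as.numeric(kcs_predict(X, params0, cfg)$probs), c(0.5, 0.5),
               tolerance = 1e-12)
})

test_that("parameter count follows the closed form and the live model", {
  expect_equal(count_parameters(kcs_config(n_filters = 4, kernel_length = 64,
                                           n_channels = 64)), 4301L)
  expect_equal(count_parameters(kcs_config(n_filters = 2, kernel_length = 64,
                                           n_channels = 64)), 4169L)
  expect_equal(count_parameters(kcs_config(n_filters = 1, kernel_length = 2,
                                           n_channels = 2)), 11L)
  ts <- tiny_trials()
  cfg <- tiny_config()
  fit <- kcs_fit(ts, cfg)
  expect_equal(count_parameters(fit$config),
               kcsfcnet:::n_trainable(fit$params))
})

test_that("sigma initialization follows the declared policies", {
  ts <- tiny_trials(seed = 5)
  cfg <- tiny_config(sigma_init = "fixed", sigma_value = 2.5)
  cfg$n_channels <- 4L; cfg$n_times <- 32L
  set.seed(2)
  p_fixed <- init_params(cfg, ts)
  expect_equal(exp(p_fixed$log_sigma), 2.5)

  cfg_mh <- tiny_config()
  cfg_mh$n_channels <- 4L; cfg_mh$n_times <- 32L
  set.seed(2)
  p1 <- init_params(cfg_mh, ts)
  set.seed(2)
  p2 <- init_params(cfg_mh, ts)
  expect_identical(p1, p2)   # deterministic under a fixed seed

  # median heuristic: sigma^2 equals half the median squared distance of the
  # initial activations, computed here by an independent composition
  Wm <- p1$W
  sig <- exp(p1$log_sigma)
  # gather raw conv outputs over all trials for the batch normalization
  conv_all <- c()
  filt_list <- list()
  for (r in seq_len(dim(ts)[1L])) {
    x <- matrix(ts$data[r, , ], 4, 32)
    Tt <- 25
    filt <- matrix(0, 4, Tt)
    for (c in 1:4) for (t in seq_len(Tt)) {
      filt[c, t] <- sum(Wm[1, ] * x[c, t:(t + 7)])
    }
    filt_list[[r]] <- filt
    conv_all <- c(conv_all, as.vector(filt))
  }
  mu <- mean(conv_all); v <- mean((conv_all - mu)^2)
  act <- lapply(filt_list, function(fm) {
    z <- (fm - mu) / sqrt(v + cfg_mh$bn_eps)
    ifelse(z > 0, z, exp(z) - 1)
  })
  d2 <- c()
  prs <- channel_pairs(4)
  for (fm in act) {
    for (i in seq_len(nrow(prs))) {
      d2 <- c(d2, sum((fm[prs[i, 1L], ] - fm[prs[i, 2L], ])^2))
    }
  }
  expect_equal(sig, sqrt(stats::median(d2) / 2), tolerance = 1e-8)

  # degenerate all-zero batch falls back to sigma = 1 with a warning
  zero_ts <- eeg_trial_set(array(0, dim = c(4, 4, 32)),
                           labels = c(0L, 1L, 0L, 1L), fs = 64)
  set.seed(2)
  expect_warning(pz <- init_params(cfg_mh, zero_ts), "degenerate")
  expect_equal(exp(pz$log_sigma), 1)
})

test_that("back-propagated gradients match finite differences", {
  set.seed(3)
  B <- 4L; nc <- 3L; nt <- 16L; dt <- 4L
  X <- array(stats::rnorm(B * nc * nt), dim = c(B, nc, nt))
  y <- c(0L, 1L, 0L, 1L)
  cfg <- kcs_config(n_filters = 2L, kernel_length = dt, n_channels = nc,
                    n_times = nt, dropout_rate = 0, sigma_init = "fixed",
                    sigma_value = 1.2)
  set.seed(5)
  params <- init_params(cfg, eeg_trial_set(X, y, 16))
  bk <- kcsfcnet:::kcs_backward(X, y, params, cfg)
  num_grad <- function(field, idx, h = 1e-5) {
    p1 <- params; p2 <- params
    p1[[field]][idx] <- p1[[field]][idx] + h
    p2[[field]][idx] <- p2[[field]][idx] - h
    (kcsfcnet:::kcs_backward(X, y, p1, cfg)$loss -
       kcsfcnet:::kcs_backward(X, y, p2, cfg)$loss) / (2 * h)
  }
  checks <- list(c("log_sigma", 1), c("W", 3), c("gamma1", 2), c("beta1", 1),
                 c("gamma2", 1), c("V", 4), c("b", 2))
  for (cs in checks) {
    ng <- num_grad(cs[1L], as.integer(cs[2L]))
    ag <- bk$grads[[cs[1L]]][as.integer(cs[2L])]
    expect_lt(abs(ag - ng) / max(abs(ng), 1e-8), 1e-4)
  }
})

test_that("fitting enforces constraints and fails loudly on bad input", {
  ts <- tiny_trials(seed = 9)
  fit <- kcs_fit(ts, tiny_config())
  expect_gt(exp(fit$params$log_sigma), 0)
  expect_true(all(sqrt(rowSums(fit$params$W^2)) <=
                    fit$config$conv_max_norm + 1e-6))
  expect_true(all(sqrt(colSums(fit$params$V^2)) <=
                    fit$config$dense_max_norm + 1e-6))
  expect_true(all(is.finite(fit$log$loss)))

  single <- ts
  single$labels <- rep(0L, length(single$labels))
  class(single) <- "eeg_trial_set"
  expect_error(kcs_fit(single, tiny_config()), "both classes")
})

test_that("fits are deterministic and learn an easy planted signal", {
  ts <- tiny_trials(seed = 13)
  cfg <- tiny_config(epochs = 60L)
  f1 <- kcs_fit(ts, cfg)
  f2 <- kcs_fit(ts, cfg)
  expect_identical(f1$params, f2$params)
  expect_gt(utils::tail(f1$log$accuracy, 1), 0.85)
})

test_that("extracted connectivity is bounded, symmetric-by-construction and
          stable in inference mode", {
  ts <- tiny_trials(seed = 17)
  fit <- kcs_fit(ts, tiny_config())
  conn <- extract_connectivity(fit, ts)
  expect_true(all(conn$values >= 0 & conn$values <= 1))
  expect_equal(dim(conn$values), c(20L, 6L))
  conn2 <- extract_connectivity(fit, ts)
  expect_identical(conn$values, conn2$values)

  # a trial whose channels are all identical maps to all-ones connectivity
  same <- ts
  for (c in 2:4) same$data[, c, ] <- same$data[, 1, ]
  conn_same <- extract_connectivity(fit, same)
  expect_equal(as.numeric(conn_same$values[1L, ]), rep(1, 6))
})
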