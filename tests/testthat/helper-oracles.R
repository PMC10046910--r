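# Independent oracles used across test files. Each is a deliberately naive
# reimplementation (loops, enumeration) kept separate from the package's
# computation path.

# Welch magnitude-squared coherence between two signals, averaged over the
# FFT bins inside [f_lo, f_hi] Hz. Hann window, 50% overlap. Cross- and
# auto-spectra must be averaged over segments (and, by the caller, trials)
# for coherence to be meaningful.
welch_csd <- function(x, y, fs, nseg = 64L) {
  step <- nseg %/% 2L
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  acc <- complex(nseg)
  for (s in starts) {
    fx <- stats::fft(x[s:(s + nseg - 1L)] * win)
    fy <- stats::fft(y[s:(s + nseg - 1L)] * win)
    acc <- acc + fx * Conj(fy)
  }
  acc / length(starts)
}

band_coherence <- function(trials_data, pair, fs, f_lo, f_hi, nseg = 64L) {
  # trials_data: list of Nc x Nt matrices (one per trial)
  sxy <- complex(nseg); sxx <- complex(nseg); syy <- complex(nseg)
  for (tr in trials_data) {
    x <- tr[pair[1L], ]; y <- tr[pair[2L], ]
    sxy <- sxy + welch_csd(x, y, fs, nseg)
    sxx <- sxx + welch_csd(x, x, fs, nseg)
    syy <- syy + welch_csd(y, y, fs, nseg)
  }
  freqs <- (seq_len(nseg) - 1L) * fs / nseg
  bins <- which(freqs >= f_lo & freqs <= f_hi & freqs <= fs / 2)
  coh <- Mod(sxy[bins])^2 / (Re(sxx[bins]) * Re(syy[bins]))
  mean(coh)
}

# Periodogram argmax frequency (Hz) of a real signal.
peak_frequency <- function(x, fs) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  half <- seq_len(floor(n / 2))
  (which.max(p[half + 1L])) * fs / n   # skip DC bin
}

# Periodogram power near a target frequency (max over +/- 1 bin).
power_at <- function(x, fs, f0) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n
  k <- round(f0 * n / fs)
  max(p[(k:(k + 2L))])   # bins k-1, k, k+1 in 1-based indexing
}

# AUC by exhaustive positive/negative pair counting, ties = 1/2.
auc_bruteforce <- function(y_true, y_prob) {
  pos <- y_prob[y_true == 1]
  neg <- y_prob[y_true == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Cohen's kappa from the explicit 2x2 contingency table.
kappa_contingency <- function(y_true, y_pred) {
  n <- length(y_true)
  tab <- table(factor(y_true, c(0, 1)), factor(y_pred, c(0, 1)))
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (p_e >= 1) 0 else (p_o - p_e) / (1 - p_e)
}

# Two-sample KS statistic by direct ECDF comparison.
ks_stat_direct <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  fa <- vapply(grid, function(g) mean(a <= g), numeric(1))
  fb <- vapply(grid, function(g) mean(b <= g), numeric(1))
  max(abs(fa - fb))
}

# Exact two-sided KS p-value by exhaustive enumeration of all C(n+m, n)
# assignments of the pooled sample (feasible for n + m <= 10).
ks_perm_oracle <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  d_obs <- ks_stat_direct(a, b)
  combos <- utils::combn(length(pooled), n)
  hits <- 0L
  for (j in seq_len(ncol(combos))) {
    ia <- combos[, j]
    d <- ks_stat_direct(pooled[ia], pooled[-ia])
    if (d >= d_obs - 1e-12) hits <- hits + 1L
  }
  hits / ncol(combos)
}

# Straight-line reimplementation of the full forward pass for one trial,
# one filter bank, identity normalizations (bn_eps = 0, running stats 0/1),
# dropout off. Composes: valid cross-correlation -> ELU -> pairwise
# Gaussian kernels -> mean over filters -> ELU -> affine -> softmax.
forward_oracle <- function(x_trial, W, sigma, V, bias) {
  nf <- nrow(W); dt <- ncol(W)
  nc <- nrow(x_trial); nt <- ncol(x_trial)
  Tt <- nt - dt + 1L
  elu1 <- function(v) ifelse(v > 0, v, exp(v) - 1)
  pairs <- list()
  for (i in 1:(nc - 1)) for (j in (i + 1):nc) pairs[[length(pairs) + 1]] <- c(i, j)
  kvals <- matrix(0, nf, length(pairs))
  for (f in seq_len(nf)) {
    filt <- matrix(0, nc, Tt)
    for (c in seq_len(nc)) {
      for (t in seq_len(Tt)) {
        filt[c, t] <- sum(W[f, ] * x_trial[c, t:(t + dt - 1L)])
      }
    }
    filt <- elu1(filt)
    for (pi in seq_along(pairs)) {
      pr <- pairs[[pi]]
      kvals[f, pi] <- exp(-sum((filt[pr[1], ] - filt[pr[2], ])^2) /
                            (2 * sigma^2))
    }
  }
  avg <- colMeans(kvals)
  h <- elu1(avg)
  logits <- as.numeric(h %*% V + bias)
  e <- exp(logits - max(logits))
  e / sum(e)
}

# Tiny already-preprocessed trial set + fast model config for integration
# tests that need real fits without real cost.
tiny_trials <- function(n_trials = 20L, n_channels = 4L, n_times = 32L,
                        fs = 64, seed = 1L, separable = TRUE) {
  set.seed(seed)
  labels <- rep(c(0L, 1L), length.out = n_trials)
  data <- array(stats::rnorm(n_trials * n_channels * n_times) * 0.5,
                dim = c(n_trials, n_channels, n_times))
  if (separable) {
    tt <- seq_len(n_times)
    for (r in which(labels == 1L)) {
      src <- sin(2 * pi * 8 * tt / fs + stats::runif(1, 0, 2 * pi)) * 1.5
      data[r, 1L, ] <- data[r, 1L, ] + src
      data[r, 2L, ] <- data[r, 2L, ] - src
    }
  }
  eeg_trial_set(data, labels, fs)
}

tiny_config <- function(...) {
  args <- list(n_filters = 1L, kernel_length = 8L, epochs = 30L,
               dropout_rate = 0, seed = 3L)
  args <- utils::modifyList(args, list(...))
  do.call(kcs_config, args)
}
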