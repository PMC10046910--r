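#' Specification of a synthetic motor-imagery EEG subject
#'
#' Describes a two-class synthetic EEG recording in which class information is
#' planted as band-limited coupling between designated channel pairs, on top
#' of independent 1/f ("pink") background noise. Every downstream stage of
#' the pipeline (band-pass filtering, the kernel connectivity model,
#' Kolmogorov-Smirnov pruning) can be exercised against this known ground
#' truth without external data.
#'
#' The defaults are the package's reference condition: 80 balanced trials of
#' 16 channels at 128 Hz lasting 3 s, with an alpha-band (8-13 Hz) coupling
#' planted between channels 1-2 for class 1 and a beta-band (18-24 Hz)
#' coupling between channels 3-4 for class 0, at a coupled-source to
#' background variance ratio (`snr`) of 2.
#'
#' @param n_trials even number of trials (classes are exactly balanced).
#' @param n_channels number of EEG channels.
#' @param fs sampling rate in Hz.
#' @param duration trial length in seconds.
#' @param couplings list of couplings; each a list with elements
#'   `pair` (two distinct 1-based channel indices), `band` (`c(low, high)` in
#'   Hz, inside `(0, fs/2)`), and `class` (0 or 1: which class carries the
#'   shared source).
#' @param snr ratio of coupled-source variance to background-noise variance
#'   on each affected channel. `snr = 0` plants no signal (negative control).
#' @param cue_onset cue time in seconds within the trial (passed through to
#'   the trial set).
#' @param seed integer seed; generation is bit-reproducible for a fixed seed.
#'
#' @return An object of class `synthetic_spec`.
#' @seealso [generate_subject()]
#' @export
synthetic_spec <- function(n_trials = 80L, n_channels = 16L, fs = 128,
                           duration = 3,
                           couplings = list(
                             list(pair = c(1L, 2L), band = c(8, 13), class = 1L),
                             list(pair = c(3L, 4L), band = c(18, 24), class = 0L)
                           ),
                           snr = 2, cue_onset = 0, seed = 1L) {
  n_trials <- as.integer(n_trials)
  n_channels <- as.integer(n_channels)
  if (n_trials < 2L || n_trials %% 2L != 0L) {
    stop("'n_trials' must be even and >= 2 (balanced classes)")
  }
  stopifnot(n_channels >= 2L, fs > 0, duration > 0, snr >= 0)
  for (cp in couplings) {
    pair <- as.integer(cp$pair)
    if (length(pair) != 2L || any(pair < 1L) || any(pair > n_channels)) {
      stop("coupling channel indices must lie in [1, n_channels]")
    }
    if (pair[1L] == pair[2L]) {
      stop("coupling pair must name two distinct channels")
    }
    band <- as.numeric(cp$band)
    if (length(band) != 2L || band[1L] <= 0 || band[2L] <= band[1L] ||
        band[2L] >= fs / 2) {
      stop("coupling band [", band[1L], ", ", band[2L],
           "] Hz must satisfy 0 < low < high < fs/2 = ", fs / 2)
    }
    if (!cp$class %in% c(0L, 1L)) stop("coupling class must be 0 or 1")
  }
  structure(
    list(n_trials = n_trials, n_channels = n_channels, fs = fs,
         duration = duration, couplings = couplings, snr = snr,
         cue_onset = cue_onset, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# 1/f-amplitude spectral shaping of white Gaussian noise, unit variance.
pink_noise <- function(n) {
  w <- stats::rnorm(n)
  x <- stats::fft(w)
  k <- seq_len(n) - 1L
  freq_idx <- pmin(k, n - k)          # symmetric bin distance from DC
  scale <- ifelse(freq_idx == 0, 0, 1 / sqrt(freq_idx))
  y <- Re(stats::fft(x * scale, inverse = TRUE)) / n
  y / stats::sd(y)
}

# White noise band-limited to [low, high] Hz by spectral masking, unit variance.
bandlimited_noise <- function(n, fs, low, high) {
  w <- stats::rnorm(n)
  x <- stats::fft(w)
  k <- seq_len(n) - 1L
  freq <- pmin(k, n - k) * fs / n
  mask <- as.numeric(freq >= low & freq <= high)
  y <- Re(stats::fft(x * mask, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s == 0) stop("band [", low, ", ", high, "] Hz contains no FFT bin at n = ", n)
  y / s
}

#' Generate a synthetic two-class EEG subject
#'
#' Draws balanced two-class multichannel EEG per a [synthetic_spec()]. Every
#' channel carries independent pink (1/f) noise of unit variance. For each
#' coupling entry, trials of the named class additionally receive one shared
#' band-limited Gaussian source, added at zero lag to both channels of the
#' pair with opposite polarity (an antiphase dipole projection) and scaled
#' so its variance on each channel equals `snr`. The shared source makes the
#' pair statistically dependent within the stated band for that class only —
#' and, because the polarities oppose, the dependence appears in the channel
#' difference itself, the quantity a stationary kernel connectivity measure
#' operates on. This is the ground truth the model and the
#' Kolmogorov-Smirnov pruning are expected to recover.
#'
#' All randomness flows from one RNG stream seeded with `spec$seed`, so the
#' output tensor is bitwise reproducible.
#'
#' @param spec a [synthetic_spec()].
#' @return An [eeg_trial_set()] with `spec$n_trials` trials, labels
#'   alternating 0, 1, 0, 1, ...
#' @examples
#' ts <- generate_subject(synthetic_spec(n_trials = 4, n_channels = 4,
#'                                       duration = 1, seed = 42))
#' dim(ts)
#' @export
generate_subject <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  nt <- round(spec$fs * spec$duration)
  R <- spec$n_trials
  nc <- spec$n_channels
  labels <- rep(c(0L, 1L), length.out = R)
  data <- array(0, dim = c(R, nc, nt))
  for (r in seq_len(R)) {
    for (c in seq_len(nc)) {
      data[r, c, ] <- pink_noise(nt)
    }
    if (spec$snr > 0) {
      for (cp in spec$couplings) {
        if (labels[r] == cp$class) {
          src <- bandlimited_noise(nt, spec$fs, cp$band[1L], cp$band[2L]) *
            sqrt(spec$snr)
          # antiphase dipole projection: the shared source enters both
          # channels at zero lag with opposite polarity, so the dependence
          # lives in the channel difference that a stationary kernel
          # kappa(x - x') measures (identical-sign addition would cancel
          # there and leave the planted pair invisible to it)
          data[r, cp$pair[1L], ] <- data[r, cp$pair[1L], ] + src
          data[r, cp$pair[2L], ] <- data[r, cp$pair[2L], ] - src
        }
      }
    }
  }
  eeg_trial_set(data, labels, spec$fs, cue_onset = spec$cue_onset)
}

# Save/restore the global RNG state so seeded generators do not clobber the
# caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
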