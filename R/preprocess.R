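#' Preprocessing configuration
#'
#' Raw-EEG conditioning applied before model fitting, in fixed order:
#' Fourier-method resampling to `fs_target`, Butterworth band-pass over
#' `band`, and clipping to the motor-imagery window. Defaults follow common
#' motor-imagery practice: downsample to 128 Hz, keep 4-40 Hz (theta through
#' beta rhythms) with a fifth-order Butterworth, and retain 0.5-2.5 s after
#' the cue.
#'
#' @param fs_target target sampling rate in Hz.
#' @param band `c(low, high)` band edges in Hz; must satisfy
#'   `0 < low < high < fs_target / 2`.
#' @param filter_order Butterworth design order (applied forward-backward by
#'   default, doubling the effective order).
#' @param window `c(t0, t1)` clip window in seconds relative to the cue
#'   onset; half-open `[t0, t1)` in samples.
#' @param zero_phase logical; forward-backward (zero group delay) filtering
#'   when `TRUE` (default), single-pass causal filtering when `FALSE`.
#' @param reject_threshold optional amplitude threshold: trials with any
#'   `|sample|` above it are dropped before filtering. `NULL` (default)
#'   disables rejection.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(fs_target = 128, band = c(4, 40),
                              filter_order = 5, window = c(0.5, 2.5),
                              zero_phase = TRUE, reject_threshold = NULL) {
  band <- as.numeric(band)
  window <- as.numeric(window)
  stopifnot(fs_target > 0, length(band) == 2L, length(window) == 2L,
            filter_order >= 1)
  if (!(0 < band[1L] && band[1L] < band[2L])) {
    stop("band edges must satisfy 0 < low < high")
  }
  if (band[2L] >= fs_target / 2) {
    stop("upper band edge ", band[2L], " Hz reaches the Nyquist frequency ",
         fs_target / 2, " Hz of the target rate")
  }
  if (window[1L] >= window[2L]) {
    stop("clip window must satisfy t0 < t1 (got [", window[1L], ", ",
         window[2L], "])")
  }
  structure(
    list(fs_target = fs_target, band = band,
         filter_order = as.integer(filter_order), window = window,
         zero_phase = isTRUE(zero_phase), reject_threshold = reject_threshold),
    class = "preprocess_config"
  )
}

#' Fourier-method resampling of a time series
#'
#' Downsamples by truncating the discrete Fourier spectrum to the bins
#' representable at the new rate and inverting, i.e. ideal low-pass
#' resampling rather than decimation. The output has
#' `round(length(x) * fs_out / fs_in)` samples; a DC (constant) input is
#' preserved exactly. When the output length is even, the folded Nyquist bin
#' is replaced by its real part so the result is real.
#'
#' @param x numeric vector sampled at `fs_in`.
#' @param fs_in,fs_out input and output sampling rates in Hz;
#'   `fs_out < fs_in` (upsampling is out of scope).
#' @return Numeric vector at rate `fs_out`.
#' @examples
#' length(resample_fourier(sin(2 * pi * 10 * (0:3583) / 512), 512, 128))
#' @export
resample_fourier <- function(x, fs_in, fs_out) {
  if (length(x) < 2L) stop("input must have at least 2 samples")
  if (fs_out >= fs_in) {
    stop("fs_out (", fs_out, ") must be lower than fs_in (", fs_in,
         "): only downsampling is supported")
  }
  n <- length(x)
  m <- round(n * fs_out / fs_in)
  if (m < 2L) stop("output would have fewer than 2 samples")
  X <- stats::fft(x)
  Y <- complex(m)
  hpos <- ceiling(m / 2) - 1L            # positive-frequency bins kept
  Y[1L] <- X[1L]
  if (hpos >= 1L) {
    Y[2L:(hpos + 1L)] <- X[2L:(hpos + 1L)]
    Y[(m - hpos + 1L):m] <- X[(n - hpos + 1L):n]
  }
  if (m %% 2L == 0L) {
    Y[m / 2 + 1L] <- Re(X[m / 2 + 1L])   # folded Nyquist bin, keep real
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Band-pass filter every channel of every trial
#'
#' Applies a Butterworth band-pass of order `cfg$filter_order` designed for
#' the trial set's sampling rate, identically and independently to each
#' channel of each trial. By default the filter runs forward and backward
#' (zero phase, effective order doubled), which leaves the motor-imagery
#' segment free of group-delay distortion.
#'
#' @param trials an [eeg_trial_set()].
#' @param cfg a [preprocess_config()].
#' @return An `eeg_trial_set` of identical shape with filtered data.
#' @export
bandpass_butterworth <- function(trials, cfg) {
  stopifnot(inherits(trials, "eeg_trial_set"),
            inherits(cfg, "preprocess_config"))
  fs <- trials$fs
  nyq <- fs / 2
  if (cfg$band[2L] >= nyq) {
    stop("upper band edge ", cfg$band[2L],
         " Hz reaches the Nyquist frequency ", nyq, " Hz")
  }
  nt <- n_times(trials)
  if (nt <= 3L * cfg$filter_order) {
    stop("trial length ", nt, " too short for filter order ",
         cfg$filter_order)
  }
  bf <- signal::butter(cfg$filter_order, cfg$band / nyq, type = "pass")
  apply_filt <- if (cfg$zero_phase) {
    function(x) signal::filtfilt(bf, x)
  } else {
    function(x) as.numeric(signal::filter(bf, x))
  }
  out <- trials
  for (r in seq_len(n_trials(trials))) {
    for (c in seq_len(n_channels(trials))) {
      out$data[r, c, ] <- apply_filt(trials$data[r, c, ])
    }
  }
  out
}

#' Clip trials to the motor-imagery window
#'
#' Retains the half-open window `[cue_onset + t0, cue_onset + t1)` of each
#' trial, so the output has exactly `round((t1 - t0) * fs)` samples and
#' sample 1 corresponds to `cue_onset + t0`. The cue onset of the returned
#' set is reset to `-t0`, i.e. the cue now sits `t0` seconds before the
#' first retained sample.
#'
#' @inheritParams bandpass_butterworth
#' @return An `eeg_trial_set` with the clipped time axis.
#' @export
clip_epoch <- function(trials, cfg) {
  stopifnot(inherits(trials, "eeg_trial_set"),
            inherits(cfg, "preprocess_config"))
  fs <- trials$fs
  t0 <- cfg$window[1L]
  t1 <- cfg$window[2L]
  start <- round((trials$cue_onset + t0) * fs)     # 0-based sample index
  m <- round((t1 - t0) * fs)
  nt <- n_times(trials)
  if (start < 0 || start + m > nt) {
    stop("clip window [", trials$cue_onset + t0, ", ", trials$cue_onset + t1,
         ") s falls outside the recorded trial (duration ", nt / fs, " s)")
  }
  out <- trials
  out$data <- trials$data[, , (start + 1L):(start + m), drop = FALSE]
  out$cue_onset <- -t0
  out
}

#' Full preprocessing pipeline: resample, filter, clip
#'
#' Applies the three conditioning stages in fixed order. Resampling is
#' skipped when the data already run at `fs_target`; data at a lower rate
#' are rejected (upsampling is out of scope). If `cfg$reject_threshold` is
#' set, trials whose absolute amplitude exceeds it are dropped before
#' filtering.
#'
#' @inheritParams bandpass_butterworth
#' @return A preprocessed `eeg_trial_set` at `cfg$fs_target`.
#' @export
preprocess <- function(trials, cfg = preprocess_config()) {
  stopifnot(inherits(trials, "eeg_trial_set"),
            inherits(cfg, "preprocess_config"))
  if (!is.null(cfg$reject_threshold)) {
    keep <- apply(abs(trials$data), 1L, max) <= cfg$reject_threshold
    if (!all(keep)) {
      message("rejecting ", sum(!keep), " trial(s) above |amplitude| ",
              cfg$reject_threshold)
      trials <- trials[keep]
    }
  }
  if (trials$fs > cfg$fs_target) {
    nt_new <- round(n_times(trials) * cfg$fs_target / trials$fs)
    data_new <- array(0, dim = c(n_trials(trials), n_channels(trials), nt_new))
    for (r in seq_len(n_trials(trials))) {
      for (c in seq_len(n_channels(trials))) {
        data_new[r, c, ] <- resample_fourier(trials$data[r, c, ],
                                             trials$fs, cfg$fs_target)
      }
    }
    trials$data <- data_new
    trials$fs <- cfg$fs_target
  } else if (trials$fs < cfg$fs_target) {
    stop("data at ", trials$fs, " Hz below target ", cfg$fs_target,
         " Hz: upsampling is not supported")
  }
  trials <- bandpass_butterworth(trials, cfg)
  clip_epoch(trials, cfg)
}
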