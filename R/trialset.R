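#' Epoched EEG trial set
#'
#' Container for a set of epoched, labelled EEG trials: a numeric tensor of
#' dimension trials x channels x samples together with binary class labels,
#' the sampling rate, channel names and (optionally) 2-D scalp coordinates.
#' This is the common currency of the package: the synthetic generator
#' produces one, the preprocessing stages map one to another, and the model
#' consumes one.
#'
#' @param data numeric array of dimension `R x Nc x Nt` (trials x channels x
#'   samples), microvolt-scale arbitrary units, finite throughout.
#' @param labels integer vector of length `R` with values in `{0, 1}`; both
#'   classes must be present.
#' @param fs sampling rate in Hz.
#' @param channel_names character vector of length `Nc`. Defaults to
#'   `"ch01"`, `"ch02"`, ...
#' @param channel_positions optional `Nc x 2` numeric matrix of scalp
#'   coordinates (for topographic exports).
#' @param cue_onset time of the task cue in seconds, measured from the start
#'   of each trial. Epoch clipping windows are relative to this instant.
#'
#' @return An object of class `eeg_trial_set`: a list with elements `data`,
#'   `labels`, `fs`, `channel_names`, `channel_positions`, `cue_onset`.
#' @export
eeg_trial_set <- function(data, labels, fs, channel_names = NULL,
                          channel_positions = NULL, cue_onset = 0) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("'data' must be a 3-d array (trials x channels x samples)")
  }
  if (any(!is.finite(data))) {
    bad <- which(apply(data, 1L, function(tr) any(!is.finite(tr))))
    stop("non-finite values in 'data' (trial ", paste(bad, collapse = ", "), ")")
  }
  dims <- dim(data)
  labels <- as.integer(labels)
  if (length(labels) != dims[1L]) {
    stop("length(labels) [", length(labels), "] != number of trials [",
         dims[1L], "]")
  }
  if (!all(labels %in% c(0L, 1L))) {
    stop("'labels' must contain only 0 and 1")
  }
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present in 'labels'")
  }
  if (is.null(channel_names)) {
    channel_names <- sprintf("ch%02d", seq_len(dims[2L]))
  }
  if (length(channel_names) != dims[2L]) {
    stop("length(channel_names) [", length(channel_names),
         "] != number of channels [", dims[2L], "]")
  }
  if (!is.null(channel_positions)) {
    channel_positions <- as.matrix(channel_positions)
    stopifnot(nrow(channel_positions) == dims[2L],
              ncol(channel_positions) == 2L)
  }
  stopifnot(is.numeric(fs), length(fs) == 1L, fs > 0)
  structure(
    list(data = data, labels = labels, fs = as.numeric(fs),
         channel_names = as.character(channel_names),
         channel_positions = channel_positions,
         cue_onset = as.numeric(cue_onset)),
    class = "eeg_trial_set"
  )
}

#' @export
print.eeg_trial_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_trial_set> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1L], d[2L], d[3L], x$fs))
  cat(sprintf("  classes: %d x class 0, %d x class 1; cue onset %g s\n",
              sum(x$labels == 0L), sum(x$labels == 1L), x$cue_onset))
  invisible(x)
}

#' @export
dim.eeg_trial_set <- function(x) dim(x$data)

#' Subset trials of an eeg_trial_set
#'
#' @param x an `eeg_trial_set`.
#' @param i trial indices (integer or logical).
#' @param ... ignored.
#' @return An `eeg_trial_set` with the selected trials (classes need not both
#'   survive the subset; downstream fitting re-validates).
#' @export
`[.eeg_trial_set` <- function(x, i, ...) {
  out <- x
  out$data <- x$data[i, , , drop = FALSE]
  out$labels <- x$labels[i]
  out
}

n_trials <- function(x) dim(x$data)[1L]
n_channels <- function(x) dim(x$data)[2L]
n_times <- function(x) dim(x$data)[3L]

#' Ordered channel-pair index of the strict upper triangle
#'
#' Functional connectivity between `Nc` channels is symmetric, so the model
#' stores only pairs `(c, c')` with `c < c'`, in lexicographic order
#' `(1,2), (1,3), ..., (1,Nc), (2,3), ...` This helper returns that fixed
#' ordering as a two-column matrix, the layout used by every connectivity
#' vector in the package.
#'
#' @param n_channels number of channels `Nc`.
#' @return Integer matrix with `Nc (Nc - 1) / 2` rows and columns `a`, `b`.
#' @export
channel_pairs <- function(n_channels) {
  stopifnot(n_channels >= 2L)
  a <- rep(seq_len(n_channels - 1L), times = (n_channels - 1L):1L)
  b <- unlist(lapply(seq_len(n_channels - 1L), function(i) (i + 1L):n_channels))
  cbind(a = a, b = b)
}
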