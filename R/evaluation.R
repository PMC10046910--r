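#' Classification metrics for one validation fold
#'
#' Computes accuracy, Cohen's kappa and the area under the ROC curve from
#' held-out labels and predicted class-1 probabilities. Predictions are the
#' argmax of the two class probabilities, with exact ties resolved toward
#' class 0 (lowest index). Kappa is the chance-corrected agreement
#' `(p_o - p_e) / (1 - p_e)` with the expected agreement from marginal
#' frequencies; AUC is the probability that a random positive outranks a
#' random negative, ties counting one half.
#'
#' @param y_true integer labels in `{0, 1}`.
#' @param y_prob class-1 probabilities in `[0, 1]`.
#' @return List with `accuracy`, `kappa`, `auc`. With a single-class
#'   `y_true`, `auc` is `NA` with a warning (kappa is 0 by convention when
#'   the chance agreement is 1).
#' @examples
#' compute_metrics(c(0, 0, 1, 1), c(0.1, 0.6, 0.4, 0.8))
#' @export
compute_metrics <- function(y_true, y_prob) {
  stopifnot(length(y_true) == length(y_prob))
  if (any(y_prob < 0 | y_prob > 1)) stop("'y_prob' must lie in [0, 1]")
  y_true <- as.integer(y_true)
  stopifnot(all(y_true %in% c(0L, 1L)))
  pred <- ifelse(y_prob > 0.5, 1L, 0L)    # argmax; tie -> lowest index
  acc <- mean(pred == y_true)

  # Cohen's kappa from the 2x2 contingency marginals
  p_o <- acc
  p_yes <- mean(y_true == 1L) * mean(pred == 1L)
  p_no <- mean(y_true == 0L) * mean(pred == 0L)
  p_e <- p_yes + p_no
  kappa <- if (p_e >= 1) 0 else (p_o - p_e) / (1 - p_e)

  if (length(unique(y_true)) < 2L) {
    warning("single-class fold: AUC undefined, reported as NA")
    auc <- NA_real_
  } else {
    auc <- as.numeric(pROC::auc(pROC::roc(
      response = y_true, predictor = y_prob,
      levels = c(0L, 1L), direction = "<", quiet = TRUE)))
  }
  list(accuracy = acc, kappa = kappa, auc = auc)
}

# Five shuffled 80/20 splits; resamples (seeded) any split whose training
# or held-out part lacks a class (fitting needs both in training; AUC needs
# both held out). Returns list of list(train = idx, test = idx).
make_cv_splits <- function(labels, n_folds = 5L, test_fraction = 0.2,
                           seed = 1L) {
  R <- length(labels)
  n_test <- max(1L, round(R * test_fraction))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  splits <- vector("list", n_folds)
  for (k in seq_len(n_folds)) {
    repeat {
      perm <- sample.int(R)
      test <- perm[seq_len(n_test)]
      train <- perm[-seq_len(n_test)]
      if (length(unique(labels[train])) == 2L &&
          (n_test < 2L || length(unique(labels[test])) == 2L)) break
      message("fold ", k, ": single-class split, resampling")
    }
    splits[[k]] <- list(train = sort(train), test = sort(test))
  }
  splits
}

#' Cross-validated performance of the connectivity network
#'
#' Standard five-fold 80-20 scheme: the trials are shuffled, 80% train the
#' model and the held-out 20% are scored, five times with independent
#' shuffles. Splitting is seeded and a split that leaves either portion
#' single-class is redrawn (the model needs both classes to train; AUC
#' needs both held out).
#'
#' @param trials an [eeg_trial_set()] (preprocessed).
#' @param config a [kcs_config()].
#' @param n_folds number of repetitions (default 5).
#' @param test_fraction held-out fraction per repetition (default 0.2).
#' @param seed split seed (model seeds derive from it per fold).
#' @param splits optional precomputed splits (as from the internal splitter);
#'   used by the grid search to share folds across candidates.
#' @return A data frame with one row per fold: `fold`, `accuracy`, `kappa`,
#'   `auc`.
#' @export
cross_validate <- function(trials, config = kcs_config(), n_folds = 5L,
                           test_fraction = 0.2, seed = 1L, splits = NULL) {
  stopifnot(inherits(trials, "eeg_trial_set"))
  if (n_trials(trials) < 10L) stop("need at least 10 trials for 5-fold CV")
  if (is.null(splits)) {
    splits <- make_cv_splits(trials$labels, n_folds, test_fraction, seed)
  }
  rows <- vector("list", length(splits))
  for (k in seq_along(splits)) {
    sp <- splits[[k]]
    cfg_k <- config
    cfg_k$seed <- config$seed + k
    model <- kcs_fit(trials[sp$train], cfg_k)
    probs <- predict(model, trials[sp$test])
    m <- compute_metrics(trials$labels[sp$test], probs[, 2L])
    rows[[k]] <- data.frame(fold = k, accuracy = m$accuracy,
                            kappa = m$kappa, auc = m$auc)
  }
  do.call(rbind, rows)
}

#' Grid search over the number of temporal filters
#'
#' Cross-validates each candidate filter count on the same shared folds
#' (identical splits across candidates, reducing selection variance) and
#' returns the candidate with the highest mean accuracy; ties break toward
#' the smaller filter count.
#'
#' @inheritParams cross_validate
#' @param candidates integer vector of filter counts to try.
#' @return List with `best_nf`, `mean_accuracy` (named per candidate) and
#'   `folds` (per-candidate fold data frames).
#' @export
grid_search_nf <- function(trials, config = kcs_config(),
                           candidates = c(2L, 3L, 4L), n_folds = 5L,
                           test_fraction = 0.2, seed = 1L) {
  stopifnot(length(candidates) >= 1L)
  candidates <- sort(as.integer(candidates))
  splits <- make_cv_splits(trials$labels, n_folds, test_fraction, seed)
  folds <- list()
  means <- numeric(length(candidates))
  for (i in seq_along(candidates)) {
    cfg <- config
    cfg$n_filters <- candidates[i]
    fm <- cross_validate(trials, cfg, splits = splits)
    folds[[as.character(candidates[i])]] <- fm
    means[i] <- mean(fm$accuracy)
  }
  names(means) <- candidates
  best <- candidates[which.max(means)]   # first max: smallest Nf on ties
  list(best_nf = best, mean_accuracy = means, folds = folds)
}

#' Build the bounded subject-by-score matrix
#'
#' Aggregates per-subject fold metrics into the six-column score matrix used
#' for subject stratification: mean accuracy, mean normalized kappa, mean
#' AUC, and the complements `1 - sd` of each, so that every entry lies in
#' `[0, 1]` and higher is better. Kappa is first mapped per fold to
#' `(kappa + 1) / 2`; standard deviations use the population (n-divisor)
#' form over folds.
#'
#' @param per_subject named list: subject id -> fold data frame as returned
#'   by [cross_validate()] (at least 2 folds each).
#' @return A data frame of class `score_matrix` with columns `subject`,
#'   `acc`, `kappa_n`, `auc`, `c_std_acc`, `c_std_kappa`, `c_std_auc`.
#' @export
build_score_matrix <- function(per_subject) {
  stopifnot(is.list(per_subject), length(per_subject) >= 1L)
  sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
  rows <- lapply(names(per_subject), function(id) {
    fm <- per_subject[[id]]
    stopifnot(nrow(fm) >= 2L)
    kn <- (fm$kappa + 1) / 2
    vals <- c(mean(fm$accuracy), mean(kn), mean(fm$auc),
              1 - sd_pop(fm$accuracy), 1 - sd_pop(kn), 1 - sd_pop(fm$auc))
    if (any(vals < -1e-9 | vals > 1 + 1e-9)) {
      stop("score-matrix entry outside [0, 1] for subject ", id)
    }
    vals <- pmin(pmax(vals, 0), 1)
    data.frame(subject = id, acc = vals[1L], kappa_n = vals[2L],
               auc = vals[3L], c_std_acc = vals[4L], c_std_kappa = vals[5L],
               c_std_auc = vals[6L])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("score_matrix", "data.frame")
  out
}

# Numeric 6-column matrix view of a score_matrix data frame.
score_values <- function(scores) {
  as.matrix(scores[, c("acc", "kappa_n", "auc", "c_std_acc", "c_std_kappa",
                       "c_std_auc")])
}
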