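#' Write an EEG trial set to disk
#'
#' Serializes the trial container (tensor, labels, sampling rate, channel
#' names/positions, cue onset) as a single RDS archive. [read_trials()]
#' round-trips it bit-exactly.
#'
#' @param trials an [eeg_trial_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  stopifnot(inherits(trials, "eeg_trial_set"))
  saveRDS(unclass(trials), path)
  invisible(path)
}

#' Read an EEG trial set from disk
#'
#' Loads a container written by [write_trials()] and re-validates it.
#' Missing fields are reported by name; non-finite samples are rejected with
#' the offending trial index. Labels that are not already `{0, 1}` but take
#' exactly two values are coerced, with the class map reported in a message.
#'
#' @param path file path.
#' @return A validated [eeg_trial_set()].
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readRDS(path)
  for (field in c("data", "labels", "fs")) {
    if (is.null(raw[[field]])) {
      stop("trial file is missing required field '", field, "'")
    }
  }
  labels <- raw$labels
  u <- sort(unique(labels))
  if (!all(u %in% c(0, 1))) {
    if (length(u) != 2L) {
      stop("labels must take exactly two values, got: ",
           paste(u, collapse = ", "))
    }
    message("coercing labels: ", u[1L], " -> 0, ", u[2L], " -> 1")
    labels <- as.integer(labels == u[2L])
  }
  eeg_trial_set(raw$data, labels, raw$fs,
                channel_names = raw$channel_names,
                channel_positions = raw$channel_positions,
                cue_onset = if (is.null(raw$cue_onset)) 0 else raw$cue_onset)
}

#' Assemble a full pipeline configuration
#'
#' Bundles the per-stage settings consumed by [run_pipeline()]. Every field
#' has the pipeline default; unknown names passed in `...` are rejected
#' rather than silently ignored.
#'
#' @param n_subjects number of synthetic subjects to simulate (ignored when
#'   `subject_paths` is given).
#' @param subject_paths optional character vector of trial files (from
#'   [write_trials()]); when given, simulation is skipped.
#' @param snr per-subject signal-to-noise ratios for simulation, recycled to
#'   `n_subjects`; a spread of values yields a spread of performance.
#' @param sim named list of [synthetic_spec()] overrides (e.g. `n_trials`,
#'   `n_channels`, `couplings`) applied to every simulated subject; `snr`
#'   and `seed` are controlled by the pipeline and cannot be set here.
#' @param preprocess a [preprocess_config()].
#' @param model a [kcs_config()].
#' @param grid_candidates filter counts for the grid search; `NULL` skips
#'   the search and uses `model$n_filters`.
#' @param n_folds,test_fraction cross-validation scheme.
#' @param alpha significance level for connection pruning.
#' @param percentile pooled percentile for the exported edge list.
#' @param k number of subject groups.
#' @param perplexity t-SNE perplexity (layout is skipped, with a note, when
#'   the subject count is too small for it).
#' @param seed root seed; every random stage derives its own stream from it.
#' @param out_dir output directory for artifacts.
#' @return Object of class `run_config`.
#' @export
run_config <- function(n_subjects = 3L, subject_paths = NULL, snr = 2,
                       sim = list(), preprocess = preprocess_config(),
                       model = kcs_config(), grid_candidates = NULL,
                       n_folds = 5L, test_fraction = 0.2, alpha = 0.05,
                       percentile = 99, k = 3L, perplexity = 10,
                       seed = 1L, out_dir = tempfile("kcsfcnet_run_")) {
  stopifnot(inherits(preprocess, "preprocess_config"),
            inherits(model, "kcs_config"),
            alpha > 0, alpha <= 1, percentile >= 0, percentile < 100)
  if (any(c("snr", "seed") %in% names(sim))) {
    stop("'sim' cannot set snr or seed; use the top-level fields")
  }
  snr <- as.numeric(unlist(snr))          # YAML sequences may arrive as lists
  if (!is.null(grid_candidates)) {
    grid_candidates <- as.integer(unlist(grid_candidates))
  }
  structure(
    list(n_subjects = as.integer(n_subjects), subject_paths = subject_paths,
         snr = snr, sim = sim, preprocess = preprocess, model = model,
         grid_candidates = grid_candidates, n_folds = as.integer(n_folds),
         test_fraction = test_fraction, alpha = alpha,
         percentile = percentile, k = as.integer(k),
         perplexity = perplexity, seed = as.integer(seed), out_dir = out_dir),
    class = "run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Accepts a YAML file whose top-level keys mirror the arguments of
#' [run_config()], with `preprocess` and `model` as nested mappings whose
#' keys mirror [preprocess_config()] and [kcs_config()]. Unknown keys at any
#' level fail fast with the offending name.
#'
#' @param path YAML file path.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  check_keys <- function(got, allowed, where) {
    bad <- setdiff(names(got), allowed)
    if (length(bad) > 0L) {
      stop("unknown ", where, " key(s): ", paste(bad, collapse = ", "))
    }
  }
  check_keys(raw, names(formals(run_config)), "config")
  if (!is.null(raw$preprocess)) {
    check_keys(raw$preprocess, names(formals(preprocess_config)), "preprocess")
    if (!is.null(raw$preprocess$band)) {
      raw$preprocess$band <- as.numeric(raw$preprocess$band)
    }
    if (!is.null(raw$preprocess$window)) {
      raw$preprocess$window <- as.numeric(raw$preprocess$window)
    }
    raw$preprocess <- do.call(preprocess_config, raw$preprocess)
  }
  if (!is.null(raw$model)) {
    check_keys(raw$model, names(formals(kcs_config)), "model")
    raw$model <- do.call(kcs_config, raw$model)
  }
  do.call(run_config, raw)
}

# Deterministic per-stage substreams derived from the root seed, kept well
# inside 32-bit integer range.
derive_seed <- function(root, offset) {
  as.integer((as.numeric(root) * 7919 + offset) %% .Machine$integer.max)
}

#' Run the full decoding and connectivity pipeline
#'
#' Executes, per subject: simulation (or loading), preprocessing, optional
#' grid search over the filter count, five-fold cross-validation, a final
#' fit on all trials, connectivity extraction and Kolmogorov-Smirnov
#' pruning. Across subjects it then builds the score matrix, clusters
#' subjects into performance groups, orders them along the first principal
#' component, computes per-subject quadratic Renyi entropies and channel
#' relevances, exports the pooled top-percentile edge list, and (when
#' enough subjects are present) a t-SNE layout. All artifacts are written
#' under `config$out_dir` (CSV/JSON) together with a machine-readable
#' `summary.json`; every random stage is seeded from `config$seed`.
#'
#' @param config a [run_config()].
#' @return The summary list, invisibly; side effect: artifact files.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(...) {
    cat(format(Sys.time(), "%H:%M:%S"), "|", sprintf(...), "\n",
        file = log_path, append = TRUE)
  }
  cfg_file <- tempfile()
  saveRDS(config, cfg_file)
  cfg_hash <- unname(tools::md5sum(cfg_file))
  unlink(cfg_file)
  logf("pipeline start: kcsfcnet %s (R %s), seed=%d, config md5=%s, subjects=%s",
       as.character(utils::packageVersion("kcsfcnet")),
       paste(R.version$major, R.version$minor, sep = "."),
       config$seed, cfg_hash,
       if (is.null(config$subject_paths)) config$n_subjects
       else length(config$subject_paths))

  # --- load or simulate subjects -------------------------------------------
  stage <- "simulate/load"
  subjects <- tryCatch({
    if (!is.null(config$subject_paths)) {
      lapply(config$subject_paths, read_trials)
    } else {
      snr <- rep(config$snr, length.out = config$n_subjects)
      lapply(seq_len(config$n_subjects), function(i) {
        spec <- do.call(synthetic_spec, c(
          config$sim,
          list(snr = snr[i], seed = derive_seed(config$seed, i))))
        generate_subject(spec)
      })
    }
  }, error = function(e) stop("stage '", stage, "' failed: ",
                              conditionMessage(e)))
  ids <- sprintf("S%02d", seq_along(subjects))
  names(subjects) <- ids

  # --- preprocess -----------------------------------------------------------
  stage <- "preprocess"
  subjects <- tryCatch(
    lapply(subjects, preprocess, cfg = config$preprocess),
    error = function(e) stop("stage '", stage, "' failed: ",
                             conditionMessage(e)))
  logf("preprocessed %d subjects to %d samples @ %g Hz", length(subjects),
       n_times(subjects[[1L]]), subjects[[1L]]$fs)

  # --- per-subject training and evaluation ----------------------------------
  stage <- "train/evaluate"
  per_subject <- list()
  models <- list()
  chosen_nf <- integer(length(subjects))
  for (i in seq_along(subjects)) {
    tr <- subjects[[i]]
    cv_seed <- derive_seed(config$seed, 100 + i)
    cfg <- config$model
    cfg$seed <- derive_seed(config$seed, 200 + i)
    res <- tryCatch({
      if (!is.null(config$grid_candidates)) {
        gs <- grid_search_nf(tr, cfg, candidates = config$grid_candidates,
                             n_folds = config$n_folds,
                             test_fraction = config$test_fraction,
                             seed = cv_seed)
        cfg$n_filters <- gs$best_nf
        list(folds = gs$folds[[as.character(gs$best_nf)]], cfg = cfg)
      } else {
        list(folds = cross_validate(tr, cfg, n_folds = config$n_folds,
                                    test_fraction = config$test_fraction,
                                    seed = cv_seed),
             cfg = cfg)
      }
    }, error = function(e) stop("stage '", stage, "' failed for ", ids[i],
                                ": ", conditionMessage(e)))
    per_subject[[ids[i]]] <- res$folds
    chosen_nf[i] <- res$cfg$n_filters
    models[[ids[i]]] <- kcs_fit(tr, res$cfg)
    logf("%s: Nf=%d, CV accuracy %.3f", ids[i], res$cfg$n_filters,
         mean(res$folds$accuracy))
  }

  # --- score matrix and grouping -------------------------------------------
  stage <- "group-level analysis"
  summary <- tryCatch({
    scores <- build_score_matrix(per_subject)
    utils::write.csv(scores, file.path(config$out_dir, "score_matrix.csv"),
                     row.names = FALSE)
    groups <- if (nrow(scores) >= config$k) {
      cluster_subjects(scores, k = config$k,
                       seed = derive_seed(config$seed, 300))
    } else NULL

    conns <- lapply(ids, function(id) {
      extract_connectivity(models[[id]], subjects[[id]])
    })
    names(conns) <- ids
    pmats <- lapply(conns, prune_connections, alpha = config$alpha)
    entropies <- vapply(pmats, renyi_entropy, numeric(1))
    relevance <- lapply(ids, function(id) {
      list(pvalues = channel_relevance("pvalues", pmat = pmats[[id]]),
           weights = channel_relevance(
             "weights", v = models[[id]]$params$V,
             pair_index = conns[[id]]$pair_index))
    })
    names(relevance) <- ids

    mean_conn <- do.call(rbind, lapply(conns, function(cn) colMeans(cn$values)))
    rownames(mean_conn) <- ids
    edges <- top_percentile_edges(mean_conn, conns[[1L]]$pair_index,
                                  q = config$percentile,
                                  channel_names = subjects[[1L]]$channel_names)
    utils::write.csv(edges, file.path(config$out_dir, "edges.csv"),
                     row.names = FALSE)

    layout <- NULL
    if (nrow(scores) > config$perplexity) {
      layout <- tsne_layout(scores, perplexity = config$perplexity,
                            seed = derive_seed(config$seed, 400))
      utils::write.csv(data.frame(subject = rownames(layout),
                                  x = layout[, 1L], y = layout[, 2L]),
                       file.path(config$out_dir, "tsne_layout.csv"),
                       row.names = FALSE)
    } else {
      logf("t-SNE skipped: %d subjects <= perplexity %g", nrow(scores),
           config$perplexity)
    }

    for (id in ids) {
      utils::write.csv(
        data.frame(channel = subjects[[id]]$channel_names,
                   relevance_pvalues = relevance[[id]]$pvalues,
                   relevance_weights = relevance[[id]]$weights),
        file.path(config$out_dir, paste0("relevance_", id, ".csv")),
        row.names = FALSE)
      utils::write.csv(pmats[[id]]$p,
                       file.path(config$out_dir, paste0("pvalues_", id, ".csv")),
                       row.names = FALSE)
    }

    list(
      seed = config$seed,
      subjects = ids,
      chosen_n_filters = as.list(stats::setNames(chosen_nf, ids)),
      fold_metrics = lapply(per_subject, function(fm)
        lapply(seq_len(nrow(fm)), function(j) as.list(fm[j, ]))),
      score_matrix = lapply(seq_len(nrow(scores)), function(j)
        as.list(scores[j, ])),
      groups = if (!is.null(groups))
        as.list(stats::setNames(as.character(groups$labels),
                                names(groups$labels))),
      pca_order = if (!is.null(groups)) groups$ordering,
      renyi_entropy_bits = as.list(entropies),
      n_significant_pairs = as.list(vapply(pmats, function(pm)
        sum(pm$mask[upper.tri(pm$mask)]), numeric(1)))
    )
  }, error = function(e) stop("stage '", stage, "' failed: ",
                              conditionMessage(e)))

  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logf("pipeline complete; artifacts in %s", config$out_dir)
  invisible(summary)
}
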