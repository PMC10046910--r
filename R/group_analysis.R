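#' Two-sample Kolmogorov-Smirnov test
#'
#' Statistic `D = sup |ECDF_a - ECDF_b|` with a two-sided p-value under the
#' null that both samples come from the same (unknown) distribution. The
#' exact null distribution is used when `length(a) + length(b) <= 25`,
#' the asymptotic Kolmogorov approximation otherwise.
#'
#' @param a,b numeric sample vectors, each of length >= 2.
#' @return List with `statistic` and `p_value`.
#' @examples
#' ks_two_sample(c(1, 2), c(3, 4))   # D = 1, p = 1/3
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("both samples need at least 2 observations")
  }
  use_exact <- (length(a) + length(b)) <= 25L
  res <- suppressWarnings(stats::ks.test(a, b, exact = use_exact))
  list(statistic = unname(res$statistic), p_value = unname(res$p.value))
}

#' Prune connections by class separability
#'
#' For every channel pair, the trial-wise connectivity values are split by
#' class label and compared with the two-sample Kolmogorov-Smirnov test; a
#' connection is kept (significant) when its p-value is at or below `alpha`.
#' No multiple-testing correction is applied: the mask is a raw per-pair
#' `p <= alpha` rule, so about `alpha` of truly null connections are
#' expected to survive by chance.
#'
#' @param conn a `connectivity_tensor` (see [extract_connectivity()]).
#' @param labels optional class labels (defaults to those stored in `conn`).
#' @param alpha significance level (default 0.05).
#' @return Object of class `pvalue_matrix`: list with `p` (symmetric
#'   `Nc x Nc`, diagonal 1), `mask` (logical, `p <= alpha` off-diagonal),
#'   `alpha`, and `channel_names`.
#' @export
prune_connections <- function(conn, labels = NULL, alpha = 0.05) {
  stopifnot(inherits(conn, "connectivity_tensor"))
  if (is.null(labels)) labels <- conn$labels
  labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(conn$values))
  if (sum(labels == 0L) < 2L || sum(labels == 1L) < 2L) {
    stop("both classes need at least 2 trials")
  }
  nc <- max(conn$pair_index)
  p <- matrix(1, nc, nc)
  for (i in seq_len(nrow(conn$pair_index))) {
    a <- conn$values[labels == 0L, i]
    b <- conn$values[labels == 1L, i]
    if (length(unique(c(a, b))) == 1L) {
      pv <- 1   # identical constant samples: no evidence against the null
    } else {
      pv <- ks_two_sample(a, b)$p_value
    }
    ci <- conn$pair_index[i, 1L]
    cj <- conn$pair_index[i, 2L]
    p[ci, cj] <- pv
    p[cj, ci] <- pv
  }
  mask <- p <= alpha
  diag(mask) <- FALSE
  structure(list(p = p, mask = mask, alpha = alpha,
                 channel_names = conn$channel_names),
            class = "pvalue_matrix")
}

#' Quadratic Renyi entropy of a pruned connectivity matrix
#'
#' Summarizes how many connections survive pruning and how evenly their
#' evidence is spread. Each significant pair `i` receives the weight
#' `w_i = 1 - p_i` (zero otherwise); the weights are normalized to a
#' probability vector `q` and the entropy is `H2 = -log2 sum(q_i^2)` bits.
#' `H2` is 0 when at most one pair is significant and reaches `log2(m)` for
#' `m` equally weighted significant pairs, so more retained, evenly spread
#' connections give higher entropy. The `"eigen"` method instead treats the
#' weight matrix (unit diagonal) as a kernel matrix `N = A / tr(A)` and
#' returns `-log2 tr(N^2)`, the matrix-based variant.
#'
#' @param pmat a `pvalue_matrix` from [prune_connections()].
#' @param method `"significance"` (default, weight-distribution form) or
#'   `"eigen"` (matrix-eigenvalue form).
#' @return Nonnegative scalar entropy in bits.
#' @export
renyi_entropy <- function(pmat, method = c("significance", "eigen")) {
  stopifnot(inherits(pmat, "pvalue_matrix"))
  method <- match.arg(method)
  idx <- channel_pairs(nrow(pmat$p))
  pv <- pmat$p[idx]
  sig <- pmat$mask[idx]
  if (method == "significance") {
    w <- ifelse(sig, 1 - pv, 0)
    s <- sum(w)
    if (s <= 0) return(0)
    q <- w / s
    -log2(sum(q^2))
  } else {
    A <- ifelse(pmat$mask, 1 - pmat$p, 0)
    diag(A) <- 1
    N <- A / sum(diag(A))
    -log2(sum(N * t(N)))   # tr(N^2), N symmetric
  }
}

#' Cluster subjects into performance groups
#'
#' Runs k-means (10 seeded restarts) on the six score columns and renames
#' the clusters "G I", "G II", "G III", ... in decreasing order of centroid
#' mean accuracy, so G I is always the best-performing group. A score
#' matrix whose rows are all identical is degenerate: every subject is
#' labelled G I with a warning.
#'
#' @param scores a `score_matrix` from [build_score_matrix()].
#' @param k number of groups (default 3: best, intermediate, worst).
#' @param seed RNG seed for the restarts.
#' @return Object of class `group_assignment`: list with `labels` (named
#'   factor), `centroids` (`k x 6`, ordered G I first), and `ordering`
#'   (subject permutation from [order_subjects()]).
#' @export
cluster_subjects <- function(scores, k = 3L, seed = 1L) {
  stopifnot(inherits(scores, "score_matrix"))
  X <- score_values(scores)
  if (nrow(X) < k) stop("need at least k = ", k, " subjects, got ", nrow(X))
  group_names <- paste("G", utils::as.roman(seq_len(k)))
  if (nrow(unique(X)) == 1L) {
    warning("all subjects have identical scores; assigning every subject to G I")
    labels <- factor(rep(group_names[1L], nrow(X)), levels = group_names)
    names(labels) <- scores$subject
    return(structure(list(labels = labels,
                          centroids = X[rep(1L, k), , drop = FALSE],
                          ordering = seq_len(nrow(X))),
                     class = "group_assignment"))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  ux <- unique(X)
  if (nrow(X) == k) {
    # as many groups as subjects: each subject is its own centroid
    cluster <- seq_len(nrow(X))
    centers <- X
  } else if (nrow(ux) <= k) {
    km <- stats::kmeans(X, centers = ux)
    cluster <- km$cluster; centers <- km$centers
  } else {
    km <- stats::kmeans(X, centers = k, nstart = 10L)
    cluster <- km$cluster; centers <- km$centers
  }
  ord <- order(centers[, 1L], decreasing = TRUE)  # by mean accuracy
  relabel <- integer(length(ord))
  relabel[ord] <- seq_along(ord)
  labels <- factor(group_names[relabel[cluster]], levels = group_names)
  names(labels) <- scores$subject
  centroids <- centers[ord, , drop = FALSE]
  rownames(centroids) <- group_names[seq_len(nrow(centroids))]
  structure(list(labels = labels, centroids = centroids,
                 ordering = order_subjects(scores)),
            class = "group_assignment")
}

#' Order subjects along the first principal component
#'
#' Projects the (column-centered) score rows on the first principal
#' component, with the sign chosen so the projection correlates positively
#' with the accuracy column, and returns the subject permutation in
#' descending projection order (best first).
#'
#' @param scores a `score_matrix`.
#' @return Integer permutation of the subject rows.
#' @export
order_subjects <- function(scores) {
  stopifnot(inherits(scores, "score_matrix"))
  X <- score_values(scores)
  if (nrow(X) < 2L) stop("need at least 2 subjects")
  if (all(apply(X, 2L, stats::var) == 0)) {
    warning("zero-variance score matrix; returning identity ordering")
    return(seq_len(nrow(X)))
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  proj <- pc$x[, 1L]
  if (stats::var(X[, 1L]) > 0) {
    s <- stats::cor(proj, X[, 1L])
    if (!is.na(s) && s < 0) proj <- -proj
  }
  order(proj, decreasing = TRUE)
}

#' Assign new subjects to previously fitted groups
#'
#' Nearest-centroid (Euclidean) assignment using the centroids of a fitted
#' [cluster_subjects()] model, without refitting; equidistant rows go to the
#' lowest-index (best) group. This is how subjects scored by one model are
#' placed into groups defined on another model's score matrix.
#'
#' @param fitted a `group_assignment`.
#' @param new_scores a `score_matrix` with the same six columns.
#' @return Named factor of group labels.
#' @export
transfer_labels <- function(fitted, new_scores) {
  stopifnot(inherits(fitted, "group_assignment"),
            inherits(new_scores, "score_matrix"))
  X <- score_values(new_scores)
  cen <- fitted$centroids
  if (ncol(X) != ncol(cen)) {
    stop("score matrix has ", ncol(X), " columns, centroids have ", ncol(cen))
  }
  d2 <- outer(rowSums(X^2), rowSums(cen^2), "+") - 2 * X %*% t(cen)
  idx <- apply(d2, 1L, which.min)          # first minimum: lowest index
  labels <- factor(rownames(cen)[idx], levels = levels(fitted$labels))
  names(labels) <- new_scores$subject
  labels
}

#' Strongest connections above a pooled percentile
#'
#' Min-max normalizes the supplied per-subject mean connectivity vectors
#' jointly (one normalization across all subjects, so strengths are
#' comparable between them) and returns, per subject, the channel pairs
#' whose normalized strength reaches the `q`-th percentile of the pooled
#' normalized values. This is the edge list behind connectogram displays of
#' the most significant connections.
#'
#' @param mean_conn matrix `subjects x Nc(Nc-1)/2` of per-pair mean
#'   connectivities (one row per subject), or a single vector.
#' @param pair_index pair ordering from [channel_pairs()].
#' @param q percentile in `(0, 100)`; `q = 0` returns all pairs.
#' @param channel_names optional channel names for the edge list.
#' @return Data frame with columns `subject`, `channel_a`, `channel_b`,
#'   `strength` (normalized). Constant connectivity (zero range) yields an
#'   empty edge list with a warning.
#' @export
top_percentile_edges <- function(mean_conn, pair_index, q = 99,
                                 channel_names = NULL) {
  if (is.vector(mean_conn)) mean_conn <- matrix(mean_conn, nrow = 1L)
  stopifnot(q >= 0, q < 100, ncol(mean_conn) == nrow(pair_index))
  if (is.null(rownames(mean_conn))) {
    rownames(mean_conn) <- paste0("S", seq_len(nrow(mean_conn)))
  }
  nc <- max(pair_index)
  if (is.null(channel_names)) channel_names <- sprintf("ch%02d", seq_len(nc))
  rng <- range(mean_conn)
  if (diff(rng) == 0) {
    warning("constant connectivity: no edges selected")
    return(data.frame(subject = character(0), channel_a = character(0),
                      channel_b = character(0), strength = numeric(0)))
  }
  norm <- (mean_conn - rng[1L]) / diff(rng)
  thr <- stats::quantile(as.vector(norm), q / 100, names = FALSE)
  rows <- list()
  for (s in seq_len(nrow(norm))) {
    keep <- which(norm[s, ] >= thr)
    if (length(keep) > 0L) {
      rows[[s]] <- data.frame(
        subject = rownames(mean_conn)[s],
        channel_a = channel_names[pair_index[keep, 1L]],
        channel_b = channel_names[pair_index[keep, 2L]],
        strength = unname(norm[s, keep]))
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(subject = character(0), channel_a = character(0),
                      channel_b = character(0), strength = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Per-channel relevance scores
#'
#' Collapses pairwise evidence to one score per channel for topographic
#' display. In `"pvalues"` mode a channel accumulates `1 - p` over its
#' significant connections; in `"weights"` mode it accumulates the absolute
#' readout weight `|v|` (averaged over classes) of every pair it belongs
#' to. Scores are normalized by their maximum (all-zero input stays
#' all-zero), so the most relevant channel scores 1.
#'
#' @param source `"pvalues"` or `"weights"`.
#' @param pmat a `pvalue_matrix` (pvalues mode).
#' @param v readout weight matrix `Nc(Nc-1)/2 x Ny` (weights mode).
#' @param pair_index pair ordering (weights mode; from [channel_pairs()]).
#' @return Numeric vector of per-channel relevances in `[0, 1]`.
#' @export
channel_relevance <- function(source = c("pvalues", "weights"),
                              pmat = NULL, v = NULL, pair_index = NULL) {
  source <- match.arg(source)
  if (source == "pvalues") {
    stopifnot(inherits(pmat, "pvalue_matrix"))
    contrib <- (1 - pmat$p) * pmat$mask
    rel <- rowSums(contrib)
  } else {
    stopifnot(is.matrix(v), !is.null(pair_index),
              nrow(v) == nrow(pair_index))
    wpair <- rowMeans(abs(v))
    nc <- max(pair_index)
    rel <- numeric(nc)
    for (i in seq_len(nrow(pair_index))) {
      rel[pair_index[i, 1L]] <- rel[pair_index[i, 1L]] + wpair[i]
      rel[pair_index[i, 2L]] <- rel[pair_index[i, 2L]] + wpair[i]
    }
  }
  m <- max(rel)
  if (m > 0) rel <- rel / m
  rel
}
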