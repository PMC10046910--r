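#' t-SNE layout of the subject score matrix
#'
#' Embeds the score-matrix rows in two dimensions with t-distributed
#' Stochastic Neighbor Embedding so that subjects with similar performance
#' profiles sit close together (the canvas on which per-subject p-value
#' matrices are displayed). This is the exact (non Barnes-Hut) algorithm:
#' Gaussian input affinities calibrated per point to the target perplexity
#' by bisection, Student-t low-dimensional affinities, gradient descent
#' with momentum and early exaggeration. Subject counts here are small
#' (tens), where the exact gradient is the appropriate choice.
#'
#' @param scores a `score_matrix`, or a numeric matrix of row vectors.
#' @param perplexity target perplexity (default 10). Must be smaller than
#'   the number of subjects; a warning is issued below the customary
#'   `3 * perplexity + 1` rows.
#' @param seed RNG seed (embedding is deterministic per seed).
#' @param n_iter gradient-descent iterations.
#' @return Numeric matrix `subjects x 2` of embedding coordinates.
#' @export
tsne_layout <- function(scores, perplexity = 10, seed = 1L, n_iter = 500L) {
  X <- if (inherits(scores, "score_matrix")) score_values(scores) else
    as.matrix(scores)
  n <- nrow(X)
  if (perplexity >= n) {
    stop("perplexity (", perplexity, ") must be below the number of subjects (",
         n, ")")
  }
  if (n <= 3 * perplexity) {
    warning("fewer than 3 * perplexity + 1 subjects; embedding may be unstable")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  D <- as.matrix(stats::dist(X))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1
    lo <- -Inf; hi <- Inf
    di <- D[i, -i]
    for (iter in seq_len(64L)) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { H <- 0 } else {
        pj <- w / sw
        H <- -sum(ifelse(pj > 0, pj * log(pj), 0))
      }
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    w <- exp(-di * beta)
    P[i, -i] <- if (sum(w) > 0) w / sum(w) else 1 / (n - 1)
  }
  P <- (P + t(P)) / (2 * n)
  P[P < 1e-12] <- 1e-12

  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2L)
  inc <- matrix(0, n, 2L)
  momentum <- 0.5
  eta <- 100
  exaggeration <- 4
  for (iter in seq_len(n_iter)) {
    Pe <- if (iter <= 100L) P * exaggeration else P
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- num / sum(num)
    Q[Q < 1e-12] <- 1e-12
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    if (iter == 20L) momentum <- 0.8
    inc <- momentum * inc - eta * grad
    Y <- Y + inc
    Y <- sweep(Y, 2L, colMeans(Y))
  }
  rownames(Y) <- if (inherits(scores, "score_matrix")) scores$subject else
    rownames(X)
  Y
}
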