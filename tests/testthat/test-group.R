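test_that("two-sample KS test matches closed cases and permutation oracle", {
  same <- ks_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  disj <- ks_two_sample(c(1, 2), c(3, 4))
  expect_equal(disj$statistic, 1)
  expect_equal(disj$p_value, 1 / 3, tolerance = 1e-12)  # 2 of C(4,2) splits

  set.seed(41)
  for (rep in 1:25) {
    n <- sample(2:5, 1); m <- sample(2:5, 1)
    a <- stats::rnorm(n); b <- stats::rnorm(m, mean = stats::runif(1, 0, 2))
    got <- ks_two_sample(a, b)
    expect_equal(got$statistic, ks_stat_direct(a, b), tolerance = 1e-12)
    expect_equal(got$p_value, ks_perm_oracle(a, b), tolerance = 1e-10)
  }
  expect_error(ks_two_sample(1, c(1, 2)), "at least 2")
})

make_conn <- function(values, labels, nc) {
  structure(list(values = values, pair_index = channel_pairs(nc),
                 labels = labels,
                 channel_names = sprintf("ch%02d", seq_len(nc))),
            class = "connectivity_tensor")
}

test_that("pruning keeps class-separable connections and only those", {
  set.seed(43)
  nc <- 5L
  p <- nrow(channel_pairs(nc))
  labels <- rep(c(0L, 1L), each = 20L)
  values <- matrix(stats::runif(40 * p), 40, p)
  values[labels == 1L, 1L] <- values[labels == 1L, 1L] + 2  # pair (1,2) shifts
  pm <- prune_connections(make_conn(values, labels, nc))
  expect_true(pm$mask[1L, 2L] && pm$mask[2L, 1L])
  expect_equal(diag(pm$p), rep(1, nc))
  expect_false(any(diag(pm$mask)))
  expect_equal(pm$p, t(pm$p))
  expect_true(all(pm$p >= 0 & pm$p <= 1))

  # identical connectivity across trials: nothing survives
  const <- matrix(0.5, 40, p)
  pm0 <- prune_connections(make_conn(const, labels, nc))
  expect_equal(pm0$p[upper.tri(pm0$p)], rep(1, p))
  expect_false(any(pm0$mask))

  expect_error(prune_connections(make_conn(values[1:3, ], c(0L, 0L, 1L), nc)),
               "at least 2")
})

make_pmat <- function(p_upper, nc, alpha = 0.05) {
  p <- matrix(1, nc, nc)
  idx <- channel_pairs(nc)
  p[idx] <- p_upper
  p[idx[, c(2L, 1L)]] <- p_upper
  mask <- p <= alpha
  diag(mask) <- FALSE
  structure(list(p = p, mask = mask, alpha = alpha,
                 channel_names = sprintf("ch%02d", seq_len(nc))),
            class = "pvalue_matrix")
}

test_that("Renyi entropy hits its closed forms", {
  nc <- 6L
  m_all <- nrow(channel_pairs(nc))

  expect_equal(renyi_entropy(make_pmat(rep(0.9, m_all), nc)), 0)      # none
  one <- rep(1, m_all); one[1L] <- 0.01
  expect_equal(renyi_entropy(make_pmat(one, nc)), 0)                  # one

  for (m in c(2L, 5L, m_all)) {
    pv <- rep(1, m_all); pv[seq_len(m)] <- 0.02
    expect_equal(renyi_entropy(make_pmat(pv, nc)), log2(m),
                 tolerance = 1e-12)
  }

  # arithmetic oracle: pairs at p = 0.01 and p = 0.03
  pv <- rep(1, m_all); pv[1L] <- 0.01; pv[2L] <- 0.03
  want <- -log2((0.99^2 + 0.97^2) / (0.99 + 0.97)^2)
  expect_equal(renyi_entropy(make_pmat(pv, nc)), want, tolerance = 1e-12)
  expect_equal(want, 0.99993, tolerance = 1e-4)

  # matrix-eigenvalue variant agrees with a direct eigendecomposition
  pv_mix <- rep(1, m_all); pv_mix[c(1L, 4L, 9L)] <- c(0.01, 0.02, 0.04)
  pm_mix <- make_pmat(pv_mix, nc)
  A <- ifelse(pm_mix$mask, 1 - pm_mix$p, 0)
  diag(A) <- 1
  lam <- eigen(A / sum(diag(A)), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(renyi_entropy(pm_mix, method = "eigen"), -log2(sum(lam^2)),
               tolerance = 1e-12)
})

make_scores <- function(acc, jitter = 0, seed = 1) {
  set.seed(seed)
  n <- length(acc)
  df <- data.frame(
    subject = sprintf("S%02d", seq_len(n)),
    acc = acc,
    kappa_n = pmin(pmax(acc + stats::rnorm(n, 0, jitter), 0), 1),
    auc = pmin(pmax(acc + stats::rnorm(n, 0, jitter), 0), 1),
    c_std_acc = 0.9, c_std_kappa = 0.9, c_std_auc = 0.9)
  class(df) <- c("score_matrix", "data.frame")
  df
}

test_that("k-means grouping orders clusters by accuracy and is stable", {
  acc <- c(0.95, 0.92, 0.93, 0.72, 0.70, 0.74, 0.52, 0.50, 0.55)
  sm <- make_scores(acc, jitter = 0.01)
  g1 <- cluster_subjects(sm, seed = 5)
  expect_equal(as.character(g1$labels),
               rep(c("G I", "G II", "G III"), each = 3L))
  expect_true(all(diff(g1$centroids[, 1L]) < 0))
  g2 <- cluster_subjects(sm, seed = 5)
  expect_identical(g1$labels, g2$labels)

  same <- make_scores(rep(0.8, 4))
  expect_warning(gd <- cluster_subjects(same), "identical")
  expect_true(all(gd$labels == "G I"))
  expect_error(cluster_subjects(make_scores(c(0.9, 0.5))), "at least")
})

test_that("PCA ordering tracks the dominant performance axis", {
  sm <- make_scores(c(0.6, 0.9, 0.3, 0.75))
  sm$kappa_n <- 0.5; sm$auc <- 0.5    # variance only in accuracy
  expect_equal(order_subjects(sm), c(2L, 4L, 1L, 3L))

  # reversing the rows reverses the permutation
  smr <- sm[nrow(sm):1, ]
  class(smr) <- c("score_matrix", "data.frame")
  expect_equal(order_subjects(smr), 5L - c(2L, 4L, 1L, 3L))

  two <- make_scores(c(0.4, 0.8))
  two$kappa_n <- 0.5; two$auc <- 0.5
  expect_equal(order_subjects(two), c(2L, 1L))

  flat <- make_scores(rep(0.7, 3))
  flat$kappa_n <- 0.7; flat$auc <- 0.7
  flat$c_std_acc <- 0.7; flat$c_std_kappa <- 0.7; flat$c_std_auc <- 0.7
  expect_warning(expect_equal(order_subjects(flat), 1:3), "zero-variance")
})

test_that("label transfer is idempotent, exact on centroids, ties to best", {
  sm <- make_scores(c(0.95, 0.93, 0.72, 0.70, 0.50, 0.52), jitter = 0.005)
  g <- cluster_subjects(sm, seed = 2)
  again <- transfer_labels(g, sm)
  expect_identical(unname(as.character(again)),
                   unname(as.character(g$labels)))

  cen_row <- make_scores(0.5)
  cen_row[1L, -1L] <- g$centroids[2L, ]
  expect_equal(as.character(transfer_labels(g, cen_row)), "G II")

  # a row equidistant from two centroids goes to the lowest-index group
  fake <- structure(
    list(labels = factor(c("G I", "G II"), levels = c("G I", "G II")),
         centroids = rbind("G I" = rep(0.75, 6), "G II" = rep(0.25, 6)),
         ordering = 1:2),
    class = "group_assignment")
  mid <- make_scores(0.5)
  mid[1L, -1L] <- rep(0.5, 6)   # dyadic values: distances exactly equal
  expect_equal(as.character(transfer_labels(fake, mid)), "G I")

  expect_error(transfer_labels(g, structure(data.frame(subject = "X"),
                                            class = c("score_matrix",
                                                      "data.frame"))),
               "columns")
})

test_that("percentile edge selection pools, normalizes and thresholds", {
  # 100 equally spaced pooled values, q = 99: exactly the single top value
  flat <- matrix(seq(0, 1, length.out = 100), nrow = 10, byrow = TRUE)
  idx10 <- channel_pairs(5L)
  edges <- top_percentile_edges(flat, idx10, q = 99)
  expect_equal(nrow(edges), 1L)
  expect_equal(edges$strength, 1)

  all_edges <- top_percentile_edges(flat, idx10, q = 0)
  expect_equal(nrow(all_edges), 100L)

  expect_warning(none <- top_percentile_edges(matrix(0.3, 2, 10), idx10),
                 "constant")
  expect_equal(nrow(none), 0L)
})

test_that("channel relevance aggregates pairwise evidence per endpoint", {
  nc <- 4L
  pv <- rep(1, 6L); pv[1L] <- 0   # only pair (1,2) significant, p = 0
  pm <- make_pmat(pv, nc)
  rel <- channel_relevance("pvalues", pmat = pm)
  expect_equal(rel, c(1, 1, 0, 0))

  idx <- channel_pairs(nc)
  expect_equal(channel_relevance("weights", v = matrix(0, 6, 2),
                                 pair_index = idx), rep(0, 4))

  set.seed(47)
  v <- matrix(stats::rnorm(12), 6, 2)
  got <- channel_relevance("weights", v = v, pair_index = idx)
  want <- numeric(nc)
  for (i in seq_len(6)) {
    w <- mean(abs(v[i, ]))
    want[idx[i, 1L]] <- want[idx[i, 1L]] + w
    want[idx[i, 2L]] <- want[idx[i, 2L]] + w
  }
  want <- want / max(want)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("t-SNE layout is deterministic and preserves gross separation", {
  set.seed(53)
  X <- rbind(matrix(stats::rnorm(40 * 3, mean = 0, sd = 0.05), 40),
             matrix(stats::rnorm(40 * 3, mean = 3, sd = 0.05), 40))
  y1 <- tsne_layout(X, perplexity = 10, seed = 8)
  expect_equal(dim(y1), c(80L, 2L))
  expect_true(all(is.finite(y1)))
  y2 <- tsne_layout(X, perplexity = 10, seed = 8)
  expect_identical(y1, y2)

  grp <- rep(1:2, each = 40)
  centers <- rbind(colMeans(y1[grp == 1, ]), colMeans(y1[grp == 2, ]))
  inter <- sqrt(sum((centers[1, ] - centers[2, ])^2))
  intra <- mean(c(sqrt(rowSums(sweep(y1[grp == 1, ], 2, centers[1, ])^2)),
                  sqrt(rowSums(sweep(y1[grp == 2, ], 2, centers[2, ])^2))))
  expect_gt(inter / intra, 1)

  expect_error(tsne_layout(X[1:5, ], perplexity = 10), "below the number")
  expect_warning(tsne_layout(X[1:12, ], perplexity = 5, n_iter = 50),
                 "unstable")
})
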