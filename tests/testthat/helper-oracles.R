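# Independent brute-force oracles used to pin down expected values.
# These deliberately share no code with the implementation: naive sums,
# explicit loops and solve() instead of log-sum-exp tricks, cached
# precisions or threshold sweeps.

bf_msp <- function(logits) {
  p <- exp(logits) / sum(exp(logits))
  max(p)
}

bf_energy <- function(logits, temperature = 1) {
  -temperature * log(sum(exp(logits / temperature)))
}

bf_mahalanobis <- function(x, means, covariance) {
  inv <- solve(covariance)
  d2 <- apply(means, 1L, function(mu) {
    diff <- matrix(x - mu, ncol = 1L)
    as.numeric(t(diff) %*% inv %*% diff)
  })
  -min(d2)
}

# Pooled within-class covariance by explicit scatter accumulation.
bf_pooled_covariance <- function(features, labels) {
  total <- matrix(0, ncol(features), ncol(features))
  n <- 0L
  for (cl in unique(labels)) {
    Xc <- features[labels == cl, , drop = FALSE]
    mu <- colMeans(Xc)
    for (i in seq_len(nrow(Xc))) {
      diff <- matrix(Xc[i, ] - mu, ncol = 1L)
      total <- total + diff %*% t(diff)
    }
    n <- n + nrow(Xc)
  }
  total / n
}

# Mann-Whitney AUROC: all pairs, half credit for ties.
bf_auroc <- function(conf_id, conf_ood) {
  wins <- 0
  for (s in conf_id) {
    for (t in conf_ood) {
      if (s > t) wins <- wins + 1 else if (s == t) wins <- wins + 0.5
    }
  }
  wins / (length(conf_id) * length(conf_ood))
}

# Exhaustive threshold enumeration for FPR at a TPR level: the largest
# threshold whose TPR reaches the level.
bf_fpr_at_tpr <- function(conf_id, conf_ood, level = 0.95) {
  thresholds <- c(Inf, sort(unique(c(conf_id, conf_ood)),
                            decreasing = TRUE), -Inf)
  for (t in thresholds) {
    if (mean(conf_id >= t) >= level) return(mean(conf_ood >= t))
  }
  stop("unreachable")
}

# Exhaustive Youden maximization with the tie-break toward higher TPR
# then higher threshold.
bf_best_threshold <- function(conf_id, conf_ood) {
  thresholds <- c(Inf, sort(unique(c(conf_id, conf_ood)),
                            decreasing = TRUE), -Inf)
  best <- NULL
  for (t in thresholds) {
    tpr <- mean(conf_id >= t)
    fpr <- mean(conf_ood >= t)
    cand <- list(threshold = t, tpr = tpr, fpr = fpr, j = tpr - fpr)
    if (is.null(best) ||
        cand$j > best$j + 1e-12 ||
        (abs(cand$j - best$j) <= 1e-12 && cand$tpr > best$tpr + 1e-12)) {
      best <- cand
    }
  }
  best
}

# Linear-interpolation quantile by hand (sorted order statistics).
bf_quantile7 <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Small labeled Gaussian fixture used across tests.
make_fixture_records <- function(n_classes = 3, dim = 2, n_per_class = 20,
                                 mean_scale = 4, seed = 101) {
  spec <- feature_space_spec(n_classes, dim, mean_scale = mean_scale,
                             within_cov = 1, seed = seed)
  generate_id_features(
    spec, make_class_size_profile("balanced", n_per_class * n_classes,
                                  n_classes))
}
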