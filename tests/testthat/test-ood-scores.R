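test_that("MSP matches hand evaluation and the softmax identities", {
  expect_equal(msp_confidence(c(0, 0, 0, 0)), 0.25)
  expect_equal(msp_confidence(c(log(2), 0, 0)), 0.5)
  # shift invariance, including shifts that would overflow a naive softmax
  l <- c(1.2, -0.7, 3.3)
  expect_equal(msp_confidence(l), msp_confidence(l + 1000))
  # range: [1/C, 1], 1/C iff constant logits
  set.seed(8)
  for (rep in 1:20) {
    l <- rnorm(5, sd = 3)
    s <- msp_confidence(l)
    expect_gte(s, 1 / 5)
    expect_lte(s, 1)
    expect_equal(s, bf_msp(l), tolerance = 1e-12)
  }
  expect_error(msp_confidence(c(1, NA, 2)), "finite")
  expect_error(msp_confidence(c(1)), "2 classes")
})

test_that("energy matches the free-energy formula and its bounds", {
  expect_equal(energy(c(0, 0, 0)), -log(3))
  expect_equal(energy(c(10, 0)), -log(exp(10) + 1))
  expect_equal(energy(c(10, 0)), -10.0000454, tolerance = 1e-6)
  expect_error(energy_config(0), "positive")
  # overflow safety: logits beyond exp() range
  expect_equal(energy(c(1000, 999)), -1000 - log(1 + exp(-1)))
  set.seed(9)
  for (rep in 1:20) {
    l <- rnorm(4, sd = 5)
    tt <- runif(1, 0.5, 3)
    e <- energy(l, energy_config(tt))
    expect_equal(e, bf_energy(l, tt), tolerance = 1e-9)
    expect_lte(e, -max(l))
    expect_gte(e, -max(l) - tt * log(4))
    expect_equal(energy_confidence(l, energy_config(tt)), -e)
  }
  # T -> 0: energy-confidence ranking converges to the max-logit ranking
  set.seed(10)
  L <- matrix(rnorm(50 * 6), 50, 6)
  conf <- energy_confidence(L, energy_config(1e-3))
  expect_identical(order(conf), order(apply(L, 1, max)))
})

test_that("Gaussian model fitting recovers means and pooled covariance", {
  # degenerate: two point-mass classes need regularization to invert
  X <- rbind(matrix(1, 3, 2), matrix(-1, 3, 2))
  y <- rep(1:2, each = 3)
  expect_error(fit_gaussian_model(X, y, reg_eps = 0), "singular")
  m <- fit_gaussian_model(X, y, reg_eps = 1e-6)
  expect_equal(m$means, rbind(c(1, 1), c(-1, -1)), ignore_attr = TRUE)
  expect_equal(m$covariance, diag(1e-6, 2), ignore_attr = TRUE)

  # pooled covariance equals the brute-force scatter average (6 points)
  X6 <- rbind(c(0, 0), c(2, 1), c(1, 3), c(5, 5), c(6, 7), c(7, 6))
  y6 <- rep(1:2, each = 3)
  m6 <- fit_gaussian_model(X6, y6, reg_eps = 0.5)
  expect_equal(m6$covariance, bf_pooled_covariance(X6, y6) + diag(0.5, 2),
               tolerance = 1e-12)
  expect_equal(m6$precision %*% m6$covariance, diag(2),
               tolerance = 1e-8, ignore_attr = TRUE)

  # parameter recovery: 3 classes x 50 samples from known 2-D Gaussians
  spec <- feature_space_spec(3, 2, mean_scale = 5, seed = 31)
  rec <- generate_id_features(spec,
                              make_class_size_profile("balanced", 150, 3))
  fit <- fit_gaussian_model(rec)
  mu <- class_means(spec)
  expect_lt(max(abs(fit$means - mu)), 3 / sqrt(50))

  expect_error(fit_gaussian_model(X6[1:4, ], c(1, 1, 1, 2)), "class")
  m_drop <- fit_gaussian_model(X6[1:4, ], c(1, 1, 1, 2),
                               drop_small = TRUE)
  expect_identical(m_drop$classes, 1L)
})

test_that("per-class covariance variant inverts each class separately", {
  set.seed(12)
  X <- rbind(matrix(rnorm(40, sd = 1), 20, 2),
             matrix(rnorm(40, sd = 3), 20, 2) + 10)
  y <- rep(1:2, each = 20)
  m <- fit_gaussian_model(X, y, tied = FALSE)
  expect_false(m$tied)
  expect_length(m$covariance, 2L)
  # class 2 has the larger spread
  expect_gt(mean(diag(m$covariance[[2]])), mean(diag(m$covariance[[1]])))
  conf <- mahalanobis_confidence(m$means[1, ], m)
  expect_equal(conf, 0)
})

test_that("Mahalanobis confidence is a negated nearest-class distance", {
  means <- rbind(c(0, 0), c(10, 0))
  model <- structure(list(means = means, covariance = diag(2),
                          precision = diag(2), reg_eps = 0,
                          classes = 1:2, tied = TRUE),
                     class = "gaussian_class_model")
  expect_equal(mahalanobis_confidence(c(0, 0), model), 0)
  expect_equal(mahalanobis_confidence(c(2, 0), model), -4)
  expect_equal(mahalanobis_confidence(c(6, 0), model), -16)  # nearest is c2
  # class order is irrelevant
  model_rev <- model
  model_rev$means <- means[2:1, ]
  x <- c(3.3, -1.2)
  expect_equal(mahalanobis_confidence(x, model),
               mahalanobis_confidence(x, model_rev))
  expect_error(mahalanobis_confidence(c(1, 2, 3), model), "dimension")
  # always <= 0 and equals the brute-force oracle
  set.seed(13)
  fit <- fit_gaussian_model(matrix(rnorm(60), 30, 2),
                            rep(1:3, each = 10), reg_eps = 1e-8)
  for (rep in 1:10) {
    x <- rnorm(2, sd = 3)
    got <- mahalanobis_confidence(x, fit)
    expect_lte(got, 0)
    expect_equal(got, bf_mahalanobis(x, fit$means, fit$covariance),
                 tolerance = 1e-9)
  }
})

test_that("score_dataset wires each method to the right adapter output", {
  rec <- make_fixture_records(n_classes = 3, dim = 2, n_per_class = 10)
  W <- matrix(rnorm(6), 3, 2)
  ad <- linear_adapter(W, rep(0, 3))
  model <- fit_gaussian_model(rec)

  empty <- score_dataset(rec[0, ], ad, "MSP")
  expect_identical(nrow(empty), 0L)

  msp <- score_dataset(rec, ad, "MSP")
  expect_equal(msp$score,
               as.numeric(msp_confidence(adapter_logits(ad,
                                                        feature_matrix(rec)))))
  expect_true(all(msp$method == "MSP"))

  mah <- score_dataset(rec, ad, "MAH", model = model)
  expect_equal(mah$score,
               as.numeric(mahalanobis_confidence(feature_matrix(rec),
                                                 model)))
  expect_error(score_dataset(rec, ad, "MAH"), "requires")

  # MSP and EBM take no fitting data: scores identical with/without model
  ebm <- score_dataset(rec, ad, "EBM")
  ebm2 <- score_dataset(rec, ad, "EBM", model = model)
  expect_identical(ebm$score, ebm2$score)
})
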