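test_that("ROC handles the separable, identical and tied textbook cases", {
  r <- roc_curve(c(3, 4), c(1, 2))
  expect_identical(r$auroc, 1)
  expect_identical(r$fpr95, 0)
  expect_identical(r$best_threshold, 3)
  expect_identical(c(r$best_tpr, r$best_fpr), c(1, 0))
  # curve endpoints and monotonicity
  expect_identical(r$tpr[1], 0)
  expect_identical(r$fpr[1], 0)
  expect_identical(utils::tail(r$tpr, 1), 1)
  expect_identical(utils::tail(r$fpr, 1), 1)
  expect_true(all(diff(r$tpr) >= 0))
  expect_true(all(diff(r$fpr) >= 0))

  # identical samples: the tie convention forces exactly 1/2
  expect_identical(roc_curve(c(1, 2, 3), c(1, 2, 3))$auroc, 0.5)

  # interleaved scores: pairwise oracle (3 wins, no ties, out of 6 pairs)
  expect_equal(roc_curve(c(1, 3, 5), c(2, 4))$auroc, 3 / 6)
  expect_equal(bf_auroc(c(1, 3, 5), c(2, 4)), 3 / 6)

  expect_error(roc_curve(numeric(0), 1), "non-empty")
  expect_error(roc_curve(c(1, Inf), c(0)), "finite")
})

test_that("trapezoidal AUROC equals the Mann-Whitney statistic exactly", {
  set.seed(17)
  for (rep in 1:25) {
    n1 <- sample(1:30, 1)
    n2 <- sample(1:30, 1)
    # integer scores force plenty of ties
    a <- sample(0:5, n1, replace = TRUE) + rnorm(n1, sd = 0.4 * (rep %% 2))
    b <- sample(0:5, n2, replace = TRUE) + rnorm(n2, sd = 0.4 * (rep %% 2))
    r <- roc_curve(a, b)
    expect_equal(r$auroc, bf_auroc(a, b), tolerance = 1e-12)
    # swapping the roles reflects about 1/2
    expect_equal(r$auroc + roc_curve(b, a)$auroc, 1, tolerance = 1e-12)
  }
})

test_that("AUROC is invariant under strictly increasing score transforms", {
  set.seed(18)
  a <- rnorm(40, 1)
  b <- rnorm(35)
  base <- roc_curve(a, b)$auroc
  expect_equal(roc_curve(exp(a), exp(b))$auroc, base, tolerance = 1e-12)
  expect_equal(roc_curve(3 * a + 7, 3 * b + 7)$auroc, base,
               tolerance = 1e-12)
})

test_that("cross-checks against an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(19)
  a <- rnorm(60, 0.8)
  b <- rnorm(50)
  ours <- roc_curve(a, b)$auroc
  ref <- as.numeric(pROC::auc(
    pROC::roc(response = rep(c(1, 0), c(60, 50)), predictor = c(a, b),
              direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("FPR95 follows the largest-threshold no-interpolation rule", {
  expect_identical(fpr_at_tpr(roc_curve(c(3, 4), c(1, 2))), 0)
  expect_error(fpr_at_tpr(roc_curve(c(3, 4), c(1, 2)), level = 0), "level")

  # identical distributions at large n: FPR95 is close to 0.95
  set.seed(20)
  a <- rnorm(5000)
  b <- rnorm(5000)
  expect_equal(fpr_at_tpr(roc_curve(a, b)), 0.95, tolerance = 0.02)

  # exhaustive enumeration oracle on 20 + 20 hand-sized sets
  for (rep in 1:10) {
    a <- round(rnorm(20), 1)
    b <- round(rnorm(20, -0.5), 1)
    r <- roc_curve(a, b)
    for (level in c(0.5, 0.8, 0.95, 1)) {
      expect_identical(fpr_at_tpr(r, level), bf_fpr_at_tpr(a, b, level))
    }
  }
})

test_that("the Youden threshold matches exhaustive maximization", {
  # identical ID and OOD: J = 0 everywhere, deterministic tie-break
  r_tie <- roc_curve(c(1, 2), c(1, 2))
  b_tie <- best_threshold(r_tie)
  expect_identical(b_tie, list(threshold = bf_best_threshold(c(1, 2),
                                                             c(1, 2))$threshold,
                               tpr = 1, fpr = 1))
  set.seed(21)
  for (rep in 1:10) {
    a <- rnorm(50, 0.8)
    b <- rnorm(50)
    got <- best_threshold(roc_curve(a, b))
    want <- bf_best_threshold(a, b)
    expect_identical(got$threshold, want$threshold)
    expect_identical(got$tpr, want$tpr)
    expect_identical(got$fpr, want$fpr)
  }
})

test_that("threshold accuracy counts decisions on both sides", {
  expect_identical(accuracy_at_threshold(c(3, 4), c(1, 2), 2.5), 1)
  expect_identical(accuracy_at_threshold(c(1, 3), c(2, 4), 2.5), 0.5)
  # threshold -Inf predicts everything ID
  expect_identical(accuracy_at_threshold(c(1, 3), c(2, 4, 5), -Inf),
                   2 / 5)
  # at the Youden point with equal set sizes, accuracy = (TPR + 1 - FPR)/2
  set.seed(22)
  a <- rnorm(80, 1)
  b <- rnorm(80)
  r <- roc_curve(a, b)
  expect_equal(accuracy_at_threshold(a, b, r$best_threshold),
               (r$best_tpr + 1 - r$best_fpr) / 2, tolerance = 1e-12)
})

test_that("five-number summaries follow the interpolation convention", {
  s <- five_number_summary(1:5)
  expect_equal(unclass(s), list(min = 1, q1 = 2, median = 3, q3 = 4,
                                max = 5))
  s7 <- five_number_summary(c(7, 7, 7))
  expect_true(all(unlist(s7) == 7))
  set.seed(23)
  x <- rnorm(10)
  s <- five_number_summary(x)
  expect_equal(s$q1, bf_quantile7(x, 0.25), tolerance = 1e-12)
  expect_equal(s$median, bf_quantile7(x, 0.5), tolerance = 1e-12)
  expect_equal(s$q3, bf_quantile7(x, 0.75), tolerance = 1e-12)
  expect_true(s$min <= s$q1 && s$q1 <= s$median &&
                s$median <= s$q3 && s$q3 <= s$max)
  expect_error(five_number_summary(numeric(0)), "non-empty")
})

test_that("size equalization subsamples only the larger set", {
  rec_a <- make_fixture_records(n_classes = 2, n_per_class = 50)
  rec_b <- make_fixture_records(n_classes = 2, n_per_class = 20, seed = 5)
  eq <- equalize_sizes(rec_a, rec_b, seed = 2)
  expect_identical(nrow(eq$a), 40L)
  expect_identical(eq$b, rec_b)  # smaller set untouched
  expect_true(all(eq$a$id %in% rec_a$id))
  # determinism and the equal-size identity case
  eq2 <- equalize_sizes(rec_a, rec_b, seed = 2)
  expect_identical(eq, eq2)
  same <- equalize_sizes(rec_b, rec_b, seed = 7)
  expect_identical(same$a, rec_b)
})
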