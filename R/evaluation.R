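#' ROC curve for ID-vs-OOD confidence scores
#'
#' Sweeps a decision threshold over the union of the observed scores plus
#' the two infinite endpoints; a sample is predicted ID iff its score is
#' `>= threshold` (ties go to ID). ID is the positive class, so TPR is
#' the fraction of ID samples above threshold and FPR the fraction of OOD
#' samples above it. AUROC is obtained by trapezoidal integration, which
#' under this tie convention equals the Mann-Whitney statistic
#' `P(s_ID > s_OOD) + 0.5 P(s_ID = s_OOD)`. FPR95 and the Youden-optimal
#' operating point are computed from the same sweep (see [fpr_at_tpr()]
#' and [best_threshold()]).
#'
#' @param conf_id numeric vector of confidence scores for ID samples, or
#'   a confidence set from [score_dataset()] (its `score` column is used).
#' @param conf_ood scores for OOD samples, likewise.
#' @return An object of class `roc_result` with fields `thresholds`
#'   (descending, `Inf` first), `tpr`, `fpr` (both non-decreasing along
#'   the sweep), `auroc`, `fpr95`, `best_threshold`, `best_tpr`,
#'   `best_fpr`.
#' @export
roc_curve <- function(conf_id, conf_ood) {
  conf_id <- score_vector(conf_id)
  conf_ood <- score_vector(conf_ood)
  if (length(conf_id) == 0L || length(conf_ood) == 0L) {
    stop("both score vectors must be non-empty", call. = FALSE)
  }
  check_finite(conf_id, "ID scores")
  check_finite(conf_ood, "OOD scores")
  thresholds <- c(Inf, sort(unique(c(conf_id, conf_ood)),
                            decreasing = TRUE), -Inf)
  sid <- sort(conf_id)
  sood <- sort(conf_ood)
  n_id <- length(sid)
  n_ood <- length(sood)
  # count of scores >= t, via #(scores < t)
  tpr <- (n_id - findInterval(thresholds, sid, left.open = TRUE)) / n_id
  fpr <- (n_ood - findInterval(thresholds, sood, left.open = TRUE)) / n_ood
  auroc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  res <- structure(list(thresholds = thresholds, tpr = tpr, fpr = fpr,
                        auroc = auroc),
                   class = "roc_result")
  res$fpr95 <- fpr_at_tpr(res, 0.95)
  best <- best_threshold(res)
  res$best_threshold <- best$threshold
  res$best_tpr <- best$tpr
  res$best_fpr <- best$fpr
  res
}

score_vector <- function(x) {
  if (is.data.frame(x)) as.numeric(x$score) else as.numeric(x)
}

#' FPR at a given TPR level (FPR95)
#'
#' The false-positive rate (OOD misclassified as ID) at the largest
#' threshold whose TPR reaches `level` — the step-function ROC value with
#' no interpolation.
#'
#' @param roc a [roc_curve()] result.
#' @param level required TPR, in (0, 1]; default 0.95.
#' @return FPR at that operating point.
#' @export
fpr_at_tpr <- function(roc, level = 0.95) {
  stopifnot(inherits(roc, "roc_result"))
  if (!is.numeric(level) || length(level) != 1L || is.na(level) ||
      level <= 0 || level > 1) {
    stop("level must lie in (0, 1]", call. = FALSE)
  }
  idx <- match(TRUE, roc$tpr >= level)
  roc$fpr[idx]
}

#' Youden-optimal threshold
#'
#' Selects the threshold maximizing Youden's J = TPR - FPR (the operating
#' point with minimum false positives and maximum true positives); ties
#' are broken toward higher TPR, then toward the higher threshold.
#'
#' @param roc a [roc_curve()] result.
#' @return `list(threshold, tpr, fpr)`.
#' @export
best_threshold <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  j <- roc$tpr - roc$fpr
  cand <- which(j >= max(j) - 1e-12)
  cand <- cand[roc$tpr[cand] >= max(roc$tpr[cand]) - 1e-12]
  idx <- cand[which.max(roc$thresholds[cand])]
  list(threshold = roc$thresholds[idx], tpr = roc$tpr[idx],
       fpr = roc$fpr[idx])
}

#' Detection accuracy at a fixed threshold
#'
#' Fraction of correct binary decisions when every sample with score
#' `>= threshold` is declared ID and every sample below it OOD:
#' `(#\{ID >= t\} + #\{OOD < t\}) / (n_ID + n_OOD)`.
#'
#' @inheritParams roc_curve
#' @param threshold decision threshold (may be infinite).
#' @return accuracy in `[0, 1]`.
#' @export
accuracy_at_threshold <- function(conf_id, conf_ood, threshold) {
  conf_id <- score_vector(conf_id)
  conf_ood <- score_vector(conf_ood)
  if (length(conf_id) == 0L || length(conf_ood) == 0L) {
    stop("both score vectors must be non-empty", call. = FALSE)
  }
  (sum(conf_id >= threshold) + sum(conf_ood < threshold)) /
    (length(conf_id) + length(conf_ood))
}

#' Five-number summary of a score distribution
#'
#' Minimum, lower quartile, median, upper quartile and maximum under the
#' linear-interpolation quantile convention (R type 7) — the boxplot-style
#' summary used to compare ID and OOD score distributions.
#'
#' @param scores non-empty finite numeric vector (or confidence set).
#' @return An object of class `five_number_summary`:
#'   `list(min, q1, median, q3, max)`.
#' @export
five_number_summary <- function(scores) {
  scores <- score_vector(scores)
  if (length(scores) == 0L) stop("scores must be non-empty", call. = FALSE)
  check_finite(scores, "scores")
  q <- unname(stats::quantile(scores, c(0, 0.25, 0.5, 0.75, 1), type = 7))
  structure(list(min = q[1], q1 = q[2], median = q[3], q3 = q[4],
                 max = q[5]),
            class = "five_number_summary")
}

#' Equalize the sizes of two sets by random subsampling
#'
#' Subsamples the larger of the two sets without replacement so both have
#' `min(|a|, |b|)` elements, deterministically given the seed. Used so ID
#' and OOD test sets are compared at equal size.
#'
#' @param set_a,set_b record tables (rows subsampled) or plain vectors.
#' @param seed integer seed.
#' @return `list(a, b)` of equal sizes.
#' @export
equalize_sizes <- function(set_a, set_b, seed = 1L) {
  size <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
  take <- function(x, i) {
    if (is.data.frame(x)) {
      out <- x[sort(i), , drop = FALSE]
      rownames(out) <- NULL
      out
    } else {
      x[sort(i)]
    }
  }
  n_a <- size(set_a)
  n_b <- size(set_b)
  if (n_a == 0L || n_b == 0L) stop("both sets must be non-empty",
                                   call. = FALSE)
  m <- min(n_a, n_b)
  with_seed(derive_seed(seed, 71L), {
    if (n_a > m) set_a <- take(set_a, sample.int(n_a, m))
    if (n_b > m) set_b <- take(set_b, sample.int(n_b, m))
  })
  list(a = set_a, b = set_b)
}
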