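#' Maximum softmax probability (MSP) confidence
#'
#' The baseline confidence score: the largest softmax output of the logit
#' vector. Computed overflow-safely by subtracting the row maximum before
#' exponentiating, so it is exactly invariant to constant shifts of the
#' logits. Higher values mean more ID-like; the score lives in
#' `[1/C, 1]`, attaining `1/C` iff the logits are constant.
#'
#' @param logits a logit vector (length C >= 2) or an `n x C` matrix.
#' @return numeric vector of MSP scores, one per row.
#' @examples
#' msp_confidence(c(0, 0, 0, 0))  # 0.25
#' @export
msp_confidence <- function(logits) {
  logits <- as_row_matrix(logits)
  if (ncol(logits) < 2L) stop("need at least 2 classes", call. = FALSE)
  check_finite(logits, "logits")
  p <- softmax_rows(logits)
  apply(p, 1L, max)
}

#' Energy-score configuration
#' @param temperature positive temperature `T` (default 1).
#' @return An object of class `energy_config`.
#' @export
energy_config <- function(temperature = 1) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      is.na(temperature) || temperature <= 0) {
    stop("temperature must be a positive scalar", call. = FALSE)
  }
  structure(list(temperature = temperature), class = "energy_config")
}

#' Helmholtz free energy of a logit vector
#'
#' `E(x) = -T * log(sum_i exp(f_i(x) / T))`, computed through an
#' overflow-safe log-sum-exp. Lower energy indicates ID; use
#' [energy_confidence()] for the "higher = more ID-like" orientation. It
#' always satisfies `-max(f) - T log C <= E(x) <= -max(f)`.
#'
#' @param logits a logit vector (length C >= 2) or an `n x C` matrix.
#' @param config an [energy_config()].
#' @return numeric vector of energies, one per row.
#' @examples
#' energy(c(0, 0, 0))  # -log(3)
#' @export
energy <- function(logits, config = energy_config()) {
  stopifnot(inherits(config, "energy_config"))
  logits <- as_row_matrix(logits)
  if (ncol(logits) < 2L) stop("need at least 2 classes", call. = FALSE)
  check_finite(logits, "logits")
  tt <- config$temperature
  z <- logits / tt
  m <- apply(z, 1L, max)
  -tt * (m + log(rowSums(exp(z - m))))
}

#' Energy confidence (negated energy)
#' @inheritParams energy
#' @return numeric vector; higher = more ID-like.
#' @export
energy_confidence <- function(logits, config = energy_config()) {
  -energy(logits, config)
}

#' Fit the class-conditional Gaussian model
#'
#' Estimates the parameters behind the Mahalanobis confidence score from
#' penultimate-layer features of the detector-fitting set (ID2): per-class
#' empirical means and, by default, a single tied covariance — the pooled
#' within-class covariance `sum_c S_c / N` where `S_c` is class `c`'s
#' scatter matrix about its own mean. A per-class covariance variant is
#' available via `tied = FALSE`. The covariance is regularized by adding
#' `reg_eps` to its diagonal before inversion; the default is scale-aware,
#' `1e-6 * trace(cov) / dim`, which keeps degenerate (zero-variance)
#' inputs usable.
#'
#' @param features `n x d` feature matrix (or a record table, from which
#'   features and labels are taken).
#' @param labels integer class labels, one per row; ignored when
#'   `features` is a record table.
#' @param reg_eps nonnegative diagonal regularizer; `NULL` for the
#'   scale-aware default.
#' @param tied use one pooled covariance across classes (default) rather
#'   than one covariance per class.
#' @param drop_small drop classes with fewer than 2 samples instead of
#'   raising an error. Starved classes carry too little information to
#'   estimate a mean and contribute nothing to a within-class scatter;
#'   experiments on severely imbalanced fitting sets use this.
#' @return An object of class `gaussian_class_model` with fields
#'   `means` (C x d), `covariance`, `precision`, `reg_eps`, `classes`,
#'   `tied`. With `tied = FALSE`, `covariance` and `precision` are lists
#'   indexed like `classes`.
#' @export
fit_gaussian_model <- function(features, labels = NULL, reg_eps = NULL,
                               tied = TRUE, drop_small = FALSE) {
  if (is.data.frame(features)) {
    labels <- features$label
    features <- feature_matrix(features)
  }
  features <- as.matrix(features)
  if (is.null(labels) || length(labels) != nrow(features)) {
    stop("labels must have one entry per feature row", call. = FALSE)
  }
  if (anyNA(labels)) stop("labels must not contain NA", call. = FALSE)
  classes <- sort(unique(labels))
  counts <- vapply(classes, function(cl) sum(labels == cl), integer(1))
  small <- counts < 2L
  if (any(small)) {
    if (!drop_small) {
      stop("class(es) ", paste(classes[small], collapse = ", "),
           " have fewer than 2 samples; cannot estimate a within-class ",
           "covariance (use drop_small = TRUE to exclude them)",
           call. = FALSE)
    }
    classes <- classes[!small]
    if (length(classes) == 0L) {
      stop("no class has >= 2 samples", call. = FALSE)
    }
  }
  d <- ncol(features)
  C <- length(classes)
  means <- matrix(0, C, d)
  scatters <- vector("list", C)
  n_used <- 0L
  for (k in seq_len(C)) {
    Xc <- features[labels == classes[k], , drop = FALSE]
    means[k, ] <- colMeans(Xc)
    centered <- sweep(Xc, 2L, means[k, ])
    scatters[[k]] <- crossprod(centered)
    n_used <- n_used + nrow(Xc)
  }

  regularized_inverse <- function(cov, eps) {
    cov_r <- cov + diag(eps, d)
    prec <- tryCatch(
      chol2inv(chol(cov_r)),
      error = function(e) {
        stop("covariance is singular (", conditionMessage(e),
             "); increase reg_eps", call. = FALSE)
      }
    )
    list(cov = cov_r, prec = prec)
  }

  if (tied) {
    cov <- Reduce(`+`, scatters) / n_used
    eps <- reg_eps %||% (1e-6 * sum(diag(cov)) / d)
    ri <- regularized_inverse(cov, eps)
    covariance <- ri$cov
    precision <- ri$prec
  } else {
    eps_list <- precision <- covariance <- vector("list", C)
    for (k in seq_len(C)) {
      cov_k <- scatters[[k]] / sum(labels == classes[k])
      eps_k <- reg_eps %||% (1e-6 * sum(diag(cov_k)) / d)
      ri <- regularized_inverse(cov_k, eps_k)
      covariance[[k]] <- ri$cov
      precision[[k]] <- ri$prec
      eps_list[[k]] <- eps_k
    }
    eps <- unlist(eps_list)
  }
  structure(list(means = means, covariance = covariance,
                 precision = precision, reg_eps = eps,
                 classes = as.integer(classes), tied = tied),
            class = "gaussian_class_model")
}

#' Mahalanobis confidence score
#'
#' The negated squared Mahalanobis distance from a penultimate feature
#' vector to the nearest class-conditional Gaussian:
#' `M(x) = max_c -(f(x) - mu_c)' P (f(x) - mu_c)` with `P` the
#' (regularized) precision. Always <= 0; equals 0 exactly when the
#' feature sits on a class mean; higher (closer to 0) = more ID-like.
#'
#' @param features a feature vector or `n x d` matrix.
#' @param model a [fit_gaussian_model()].
#' @return numeric vector of confidences, one per row.
#' @export
mahalanobis_confidence <- function(features, model) {
  stopifnot(inherits(model, "gaussian_class_model"))
  X <- as_row_matrix(features)
  d <- ncol(model$means)
  if (ncol(X) != d) {
    stop("feature dimension ", ncol(X), " does not match model dimension ",
         d, call. = FALSE)
  }
  C <- nrow(model$means)
  d2 <- matrix(0, nrow(X), C)
  for (k in seq_len(C)) {
    prec <- if (model$tied) model$precision else model$precision[[k]]
    centered <- sweep(X, 2L, model$means[k, ])
    d2[, k] <- rowSums((centered %*% prec) * centered)
  }
  # clamp tiny negative values from floating-point cancellation
  -pmax(apply(d2, 1L, min), 0)
}

#' Score a record table with one OOD method
#'
#' Wraps a confidence score around a classifier adapter: the Mahalanobis
#' score consumes the adapter's penultimate features (and requires a
#' fitted [fit_gaussian_model()]); MSP and the energy score consume the
#' adapter's logits and need no fitting data at all — which is exactly why
#' they are insensitive to the composition of the detector-fitting set.
#'
#' @param records a record table (ID and/or OOD rows).
#' @param adapter a [classifier_adapter()].
#' @param method one of `"MSP"`, `"MAH"`, `"EBM"`.
#' @param model a `gaussian_class_model`, required for `"MAH"`.
#' @param config an [energy_config()] for `"EBM"`.
#' @return A confidence set: `data.frame(id, domain, method, score)` with
#'   the convention higher = more ID-like.
#' @export
score_dataset <- function(records, adapter,
                          method = c("MSP", "MAH", "EBM"),
                          model = NULL, config = energy_config()) {
  method <- match.arg(method)
  if (nrow(records) == 0L) {
    return(data.frame(id = character(0), domain = character(0),
                      method = character(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  }
  X <- feature_matrix(records)
  score <- switch(
    method,
    "MSP" = msp_confidence(adapter_logits(adapter, X)),
    "EBM" = energy_confidence(adapter_logits(adapter, X), config),
    "MAH" = {
      if (is.null(model)) {
        stop("method 'MAH' requires a fitted gaussian_class_model",
             call. = FALSE)
      }
      mahalanobis_confidence(adapter_features(adapter, X), model)
    }
  )
  if (!all(is.finite(score))) {
    stop("non-finite confidence scores produced", call. = FALSE)
  }
  data.frame(id = records$id, domain = records$domain, method = method,
             score = as.numeric(score), stringsAsFactors = FALSE)
}
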