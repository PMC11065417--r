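#' Classifier adapter contract
#'
#' An adapter is how any trained classifier exposes the two quantities the
#' confidence scores consume: penultimate-layer ("pre-logit") features,
#' used by the Mahalanobis score, and logits, used by the softmax and
#' energy scores. Both accessors are pure: the same input always yields
#' the same output.
#'
#' @param features_fn function mapping an `n x p` input matrix to an
#'   `n x feature_dim` feature matrix.
#' @param logits_fn function mapping an `n x p` input matrix to an
#'   `n x n_classes` logit matrix.
#' @param n_classes number of classes the classifier distinguishes.
#' @param feature_dim dimension of the penultimate features.
#' @return An object of class `classifier_adapter`.
#' @export
classifier_adapter <- function(features_fn, logits_fn, n_classes,
                               feature_dim) {
  stopifnot(is.function(features_fn), is.function(logits_fn),
            n_classes >= 2L, feature_dim >= 1L)
  structure(list(features_fn = features_fn, logits_fn = logits_fn,
                 n_classes = as.integer(n_classes),
                 feature_dim = as.integer(feature_dim)),
            class = "classifier_adapter")
}

#' Penultimate features for a batch of inputs
#' @param adapter a [classifier_adapter()].
#' @param x input matrix (rows are samples) or a single vector.
#' @return `n x feature_dim` matrix.
#' @export
adapter_features <- function(adapter, x) {
  stopifnot(inherits(adapter, "classifier_adapter"))
  out <- as_row_matrix(adapter$features_fn(as_row_matrix(x)))
  if (ncol(out) != adapter$feature_dim) {
    stop("adapter returned features of width ", ncol(out),
         " but declares feature_dim = ", adapter$feature_dim, call. = FALSE)
  }
  out
}

#' Logits for a batch of inputs
#' @inheritParams adapter_features
#' @return `n x n_classes` matrix.
#' @export
adapter_logits <- function(adapter, x) {
  stopifnot(inherits(adapter, "classifier_adapter"))
  out <- as_row_matrix(adapter$logits_fn(as_row_matrix(x)))
  if (ncol(out) != adapter$n_classes) {
    stop("adapter returned logits of width ", ncol(out),
         " but declares n_classes = ", adapter$n_classes, call. = FALSE)
  }
  out
}

#' Linear reference adapter
#'
#' The adapter used for feature-level experiments: the input already is
#' the penultimate feature vector, so `features(x) = x` and
#' `logits(x) = W x + b`.
#'
#' @param weights `n_classes x feature_dim` weight matrix.
#' @param bias length-`n_classes` bias vector.
#' @return A [classifier_adapter()].
#' @export
linear_adapter <- function(weights, bias) {
  weights <- as.matrix(weights)
  if (length(bias) != nrow(weights)) {
    stop("bias length (", length(bias), ") must equal nrow(weights) (",
         nrow(weights), ")", call. = FALSE)
  }
  if (nrow(weights) < 2L) stop("need at least 2 classes", call. = FALSE)
  W <- weights
  b <- as.numeric(bias)
  out <- classifier_adapter(
    features_fn = function(x) x,
    logits_fn = function(x) {
      if (ncol(x) != ncol(W)) {
        stop("input has ", ncol(x), " columns but weights expect ",
             ncol(W), call. = FALSE)
      }
      sweep(x %*% t(W), 2L, b, "+")
    },
    n_classes = nrow(weights),
    feature_dim = ncol(weights)
  )
  out$weights <- W
  out$bias <- b
  out
}

#' Radial-softmax (Gaussian-discriminant) reference adapter
#'
#' Like [linear_adapter()] but with a shared radial term in the logit
#' map: `logits(x) = W x + b - ||x||^2 / 2`, the discriminant-function
#' vector of a Gaussian generative classifier with identity within-class
#' covariance (`w_c = mu_c`, `b_c = -||mu_c||^2/2 + log pi_c` recovers
#' the Bayes rule). The shared term cancels inside the softmax, so
#' posteriors, classification decisions and cross-entropy training are
#' identical to the linear head — but the logit scale retains density
#' information: inputs far from the data cloud get uniformly low logits,
#' the geometry deep classifiers exhibit and the one the energy score
#' relies on.
#'
#' @inheritParams linear_adapter
#' @return A [classifier_adapter()].
#' @export
radial_softmax_adapter <- function(weights, bias) {
  base <- linear_adapter(weights, bias)
  lin <- base$logits_fn
  out <- classifier_adapter(
    features_fn = base$features_fn,
    logits_fn = function(x) lin(x) - rowSums(x^2) / 2,
    n_classes = base$n_classes,
    feature_dim = base$feature_dim
  )
  out$weights <- base$weights
  out$bias <- base$bias
  out
}

#' Split specification for the ID1/ID2/ID3 protocol
#'
#' @param ratios three nonnegative fractions summing to 1: classifier
#'   training (ID1), detector fitting (ID2, used by the Mahalanobis score
#'   only) and testing (ID3). Default 70/15/15.
#' @param seed integer seed controlling the shuffle.
#' @param stratified split each class separately (default), guaranteeing
#'   every class is represented in each part up to rounding; prevents
#'   empty classes in the detector-fitting set.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(ratios = c(0.70, 0.15, 0.15), seed = 1L,
                       stratified = TRUE) {
  if (length(ratios) != 3L || any(ratios < 0) ||
      abs(sum(ratios) - 1) > 1e-9) {
    stop("ratios must be three nonnegative values summing to 1",
         call. = FALSE)
  }
  structure(list(ratios = as.numeric(ratios), seed = as.integer(seed),
                 stratified = isTRUE(stratified)),
            class = "split_spec")
}

# Apportion the indices `idx` (already shuffled) into three consecutive
# blocks sized by largest-remainder on `ratios`.
apportion_indices <- function(idx, ratios) {
  sizes <- largest_remainder(ratios * length(idx))
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  lapply(1:3, function(k) {
    if (sizes[k] == 0L) integer(0) else idx[starts[k]:ends[k]]
  })
}

#' Split ID records into ID1/ID2/ID3
#'
#' Partitions the in-distribution data into the classifier-training,
#' detector-fitting and test sets. The three parts are disjoint, their
#' union is the input, sizes match the ratios to within one record per
#' class (stratified) or overall, and the result is deterministic given
#' the seed.
#'
#' @param records a record table of ID samples.
#' @param spec a [split_spec()].
#' @return A named list `list(id1, id2, id3)` of record tables.
#' @export
split_dataset <- function(records, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"))
  if (is.null(records) || nrow(records) == 0L) {
    stop("cannot split an empty record table", call. = FALSE)
  }
  if (!all(records$domain == "ID")) {
    stop("split_dataset expects ID records only", call. = FALSE)
  }
  parts <- with_seed(derive_seed(spec$seed, 53L), {
    if (spec$stratified) {
      acc <- list(integer(0), integer(0), integer(0))
      for (cl in sort(unique(records$label))) {
        idx <- sample(which(records$label == cl))
        blocks <- apportion_indices(idx, spec$ratios)
        acc <- Map(c, acc, blocks)
      }
      acc
    } else {
      apportion_indices(sample(nrow(records)), spec$ratios)
    }
  })
  out <- lapply(parts, function(i) {
    part <- records[sort(i), , drop = FALSE]
    rownames(part) <- NULL
    part
  })
  names(out) <- c("id1", "id2", "id3")
  out
}

#' Classification accuracy of an adapter on labeled records
#' @param adapter a [classifier_adapter()].
#' @param records a labeled ID record table.
#' @return fraction of records whose arg-max logit matches the label.
#' @export
adapter_accuracy <- function(adapter, records) {
  if (nrow(records) == 0L) stop("no records to evaluate", call. = FALSE)
  logits <- adapter_logits(adapter, feature_matrix(records))
  mean(max.col(logits, ties.method = "first") == records$label)
}

# Numerically safe row-wise softmax.
softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Train the reference classifier
#'
#' A multinomial logistic-regression classifier trained with minibatch
#' AdamW on the cross-entropy loss (learning rate 1e-3, batch size 256 by
#' default). It serves two purposes: it provides real logits for the
#' softmax and energy scores in feature-level experiments, and its
#' per-epoch checkpoints give the sequence of classifiers of increasing
#' accuracy used by the accuracy-sweep experiment. Its penultimate
#' features are the inputs themselves (the model is a single linear
#' layer), matching the linear reference adapter.
#'
#' @param train_records labeled ID record table (at least 2 classes).
#' @param n_classes number of classes; defaults to `max(label)`.
#' @param epochs number of passes over the data; `epochs = 0` returns the
#'   seeded initialization with an empty checkpoint list.
#' @param learning_rate AdamW step size.
#' @param batch_size minibatch size.
#' @param seed integer seed for initialization and data order. Seeded
#'   initialization and ordering give statistical reproducibility of
#'   accuracies; exact bit-reproducibility across hardware is not
#'   promised.
#' @param holdout_records optional labeled records on which each epoch's
#'   checkpoint accuracy is measured; falls back to the training records
#'   (flagged in the checkpoint metadata).
#' @param weight_decay decoupled weight decay applied to the weight
#'   matrix (not the bias).
#' @param head output-layer parameterization: `"radial"` (default) gives
#'   a [radial_softmax_adapter()]; `"linear"` a plain [linear_adapter()].
#'   The two train identically (the radial term cancels in the softmax)
#'   and have identical accuracy and MSP scores; they differ only in the
#'   shared logit component the energy score reads.
#' @return A list of class `reference_classifier` with elements
#'   `adapter` (final [classifier_adapter()]), `checkpoints` (one per
#'   epoch: `epoch`, `adapter`, `accuracy`, `accuracy_on`) and `n_classes`.
#' @export
train_reference_classifier <- function(train_records, n_classes = NULL,
                                       epochs = 20L,
                                       learning_rate = 1e-3,
                                       batch_size = 256L, seed = 1L,
                                       holdout_records = NULL,
                                       weight_decay = 1e-2,
                                       head = c("radial", "linear")) {
  head <- match.arg(head)
  make_adapter <- switch(head, radial = radial_softmax_adapter,
                         linear = linear_adapter)
  if (nrow(train_records) == 0L) stop("no training records", call. = FALSE)
  if (!all(train_records$domain == "ID") || anyNA(train_records$label)) {
    stop("every training record must be a labeled ID sample", call. = FALSE)
  }
  y <- train_records$label
  n_classes <- as.integer(n_classes %||% max(y))
  if (length(unique(y)) < 2L) {
    stop("training data must contain at least 2 classes", call. = FALSE)
  }
  X <- feature_matrix(train_records)
  n <- nrow(X)
  d <- ncol(X)
  epochs <- as.integer(epochs)
  stopifnot(epochs >= 0L, learning_rate > 0, batch_size >= 1L)

  Y <- matrix(0, n, n_classes)
  Y[cbind(seq_len(n), y)] <- 1

  state <- with_seed(derive_seed(seed, 61L), {
    W <- matrix(stats::rnorm(n_classes * d, sd = 0.01), n_classes, d)
    b <- numeric(n_classes)
    mW <- vW <- matrix(0, n_classes, d)
    mb <- vb <- numeric(n_classes)
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    t_step <- 0L
    accuracy_on <- if (is.null(holdout_records)) "train" else "holdout"
    eval_records <- holdout_records %||% train_records
    checkpoints <- vector("list", epochs)

    for (epoch in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        Xb <- X[idx, , drop = FALSE]
        P <- softmax_rows(sweep(Xb %*% t(W), 2L, b, "+"))
        G <- P - Y[idx, , drop = FALSE]            # d(loss)/d(logits)
        gW <- t(G) %*% Xb / length(idx)
        gb <- colMeans(G)
        if (!all(is.finite(gW)) || !all(is.finite(gb))) {
          stop("non-finite gradient at epoch ", epoch,
               "; reduce the learning rate or rescale the features",
               call. = FALSE)
        }
        t_step <- t_step + 1L
        mW <- beta1 * mW + (1 - beta1) * gW
        vW <- beta2 * vW + (1 - beta2) * gW^2
        mb <- beta1 * mb + (1 - beta1) * gb
        vb <- beta2 * vb + (1 - beta2) * gb^2
        corr1 <- 1 - beta1^t_step
        corr2 <- 1 - beta2^t_step
        W <- W - learning_rate *
          ((mW / corr1) / (sqrt(vW / corr2) + eps) + weight_decay * W)
        b <- b - learning_rate * (mb / corr1) / (sqrt(vb / corr2) + eps)
      }
      ck_adapter <- make_adapter(W, b)
      checkpoints[[epoch]] <- list(
        epoch = epoch,
        adapter = ck_adapter,
        accuracy = adapter_accuracy(ck_adapter, eval_records),
        accuracy_on = accuracy_on
      )
    }
    list(W = W, b = b, checkpoints = checkpoints)
  })

  structure(list(adapter = make_adapter(state$W, state$b),
                 checkpoints = state$checkpoints,
                 n_classes = n_classes),
            class = "reference_classifier")
}

#' Write a checkpoint manifest
#'
#' Serializes each checkpoint's weights to a CSV file and records epoch,
#' held-out accuracy and seed in a JSON manifest.
#'
#' @param classifier a `reference_classifier`.
#' @param out_dir output directory (created if missing).
#' @param seed the training seed, logged in the manifest.
#' @return the manifest path, invisibly.
#' @export
write_checkpoint_manifest <- function(classifier, out_dir, seed = NA) {
  stopifnot(inherits(classifier, "reference_classifier"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(classifier$checkpoints, function(ck) {
    file <- sprintf("checkpoint_epoch_%03d.csv", ck$epoch)
    utils::write.csv(cbind(bias = ck$adapter$bias, ck$adapter$weights),
                     file.path(out_dir, file),
                     row.names = FALSE)
    list(epoch = ck$epoch, accuracy = ck$accuracy,
         accuracy_on = ck$accuracy_on, file = file)
  })
  manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(list(seed = seed, checkpoints = entries), manifest,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
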