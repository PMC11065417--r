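#' Feature-space specification for synthetic in-distribution data
#'
#' Describes a population of `n_classes` classes whose penultimate-layer
#' features are class-conditional multivariate Gaussian with a shared
#' within-class covariance — the structure the Mahalanobis confidence
#' score assumes. Class means are drawn i.i.d. from
#' `N(0, mean_scale^2 I)` as a deterministic function of `seed`.
#'
#' @param n_classes number of ID classes (>= 2).
#' @param dim feature dimension (>= 1).
#' @param mean_scale standard deviation of the class-mean cloud
#'   (feature-space units).
#' @param within_cov within-class covariance: a scalar isotropic variance
#'   or a symmetric positive semi-definite `dim x dim` matrix.
#' @param seed integer seed; this object plus its seed fully determine
#'   every dataset generated from it.
#' @return An object of class `feature_space_spec`.
#' @export
feature_space_spec <- function(n_classes, dim, mean_scale = 1,
                               within_cov = 1, seed = 1L) {
  n_classes <- as.integer(n_classes)
  dim <- as.integer(dim)
  if (is.na(n_classes) || n_classes < 2L) {
    stop("n_classes must be an integer >= 2", call. = FALSE)
  }
  if (is.na(dim) || dim < 1L) stop("dim must be an integer >= 1",
                                   call. = FALSE)
  if (!is.numeric(mean_scale) || length(mean_scale) != 1L || mean_scale < 0) {
    stop("mean_scale must be a nonnegative scalar", call. = FALSE)
  }
  if (is.matrix(within_cov)) {
    if (nrow(within_cov) != dim || ncol(within_cov) != dim) {
      stop("within_cov matrix must be dim x dim", call. = FALSE)
    }
    if (max(abs(within_cov - t(within_cov))) > 1e-8) {
      stop("within_cov must be symmetric", call. = FALSE)
    }
    ev <- eigen(within_cov, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1)) {
      stop("within_cov must be positive semi-definite", call. = FALSE)
    }
    cov <- (within_cov + t(within_cov)) / 2
  } else {
    if (!is.numeric(within_cov) || length(within_cov) != 1L ||
        within_cov < 0) {
      stop("scalar within_cov must be a nonnegative variance", call. = FALSE)
    }
    cov <- diag(within_cov, dim)
  }
  structure(
    list(n_classes = n_classes, dim = dim, mean_scale = mean_scale,
         within_cov = cov, seed = as.integer(seed)),
    class = "feature_space_spec"
  )
}

#' Class means implied by a feature-space specification
#'
#' @param spec a [feature_space_spec()].
#' @return `n_classes x dim` matrix of class means, a pure function of
#'   `spec$seed`.
#' @export
class_means <- function(spec) {
  stopifnot(inherits(spec, "feature_space_spec"))
  with_seed(derive_seed(spec$seed, 11L), {
    matrix(stats::rnorm(spec$n_classes * spec$dim, sd = spec$mean_scale),
           nrow = spec$n_classes, ncol = spec$dim)
  })
}

#' OOD shift specification
#'
#' Operationalizes the near/far OOD spectrum as a single nonnegative
#' scalar `delta`. Under `mode = "mean-shift"` (default), OOD samples are
#' drawn from Gaussians whose means are ID class means displaced by
#' Euclidean distance `delta` along a seed-determined unit direction
#' (one direction per class). `"covariance-inflation"` keeps the ID means
#' but scales the covariance by `(1 + delta)^2`; `"mixture"` draws each
#' sample from one of the two mechanisms with equal probability.
#'
#' @param delta nonnegative displacement in feature-space units
#'   (`delta = 0` under mean-shift reproduces the ID mixture exactly).
#' @param n_samples number of OOD samples to draw (>= 0).
#' @param mode one of `"mean-shift"`, `"covariance-inflation"`,
#'   `"mixture"`.
#' @return An object of class `ood_shift_spec`.
#' @export
ood_shift_spec <- function(delta, n_samples,
                           mode = c("mean-shift", "covariance-inflation",
                                    "mixture")) {
  mode <- match.arg(mode)
  if (!is.numeric(delta) || length(delta) != 1L || is.na(delta) ||
      delta < 0) {
    stop("delta must be a nonnegative scalar", call. = FALSE)
  }
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 0L) {
    stop("n_samples must be a nonnegative integer", call. = FALSE)
  }
  structure(list(delta = delta, n_samples = n_samples, mode = mode),
            class = "ood_shift_spec")
}

#' Class-size profile for the detector-fitting set
#'
#' Builds the per-class sample counts used in the imbalance experiment.
#' Three kinds are supported: `"balanced"` (counts as equal as
#' divisibility allows, remainder to the lowest-indexed classes),
#' `"unbalanced-empirical"` (counts proportional to supplied weights,
#' emulating an empirical corpus distribution), and
#' `"unbalanced-uniform"` (counts proportional to independent
#' Uniform(0, 1) draws). All kinds conserve the total exactly via
#' largest-remainder rounding.
#'
#' @param kind profile kind.
#' @param n_total total number of samples across classes.
#' @param n_classes number of classes.
#' @param seed integer seed (used by `"unbalanced-uniform"`).
#' @param empirical_weights nonnegative weights of length `n_classes`,
#'   required for `"unbalanced-empirical"`.
#' @return An object of class `class_size_profile` with fields `kind`,
#'   `counts`, `n_total`, `n_classes`.
#' @examples
#' p <- make_class_size_profile("balanced", n_total = 58362, n_classes = 142)
#' unique(p$counts)  # 411
#' @export
make_class_size_profile <- function(kind = c("balanced",
                                             "unbalanced-empirical",
                                             "unbalanced-uniform"),
                                    n_total, n_classes, seed = 1L,
                                    empirical_weights = NULL) {
  kind <- match.arg(kind)
  n_total <- as.integer(n_total)
  n_classes <- as.integer(n_classes)
  if (is.na(n_total) || n_total < 1L) stop("n_total must be positive",
                                           call. = FALSE)
  if (is.na(n_classes) || n_classes < 1L) stop("n_classes must be positive",
                                               call. = FALSE)
  counts <- switch(
    kind,
    "balanced" = {
      if (n_total < n_classes) {
        stop("balanced profile requires n_total >= n_classes ",
             "(at least one sample per class)", call. = FALSE)
      }
      base <- rep(n_total %/% n_classes, n_classes)
      rem <- n_total %% n_classes
      if (rem > 0) base[seq_len(rem)] <- base[seq_len(rem)] + 1L
      as.integer(base)
    },
    "unbalanced-empirical" = {
      if (is.null(empirical_weights)) {
        stop("kind 'unbalanced-empirical' requires empirical_weights",
             call. = FALSE)
      }
      if (length(empirical_weights) != n_classes ||
          any(empirical_weights < 0) || sum(empirical_weights) <= 0) {
        stop("empirical_weights must be nonnegative, length n_classes, ",
             "with positive sum", call. = FALSE)
      }
      largest_remainder(empirical_weights / sum(empirical_weights) * n_total)
    },
    "unbalanced-uniform" = {
      w <- with_seed(derive_seed(seed, 23L), stats::runif(n_classes))
      largest_remainder(w / sum(w) * n_total)
    }
  )
  stopifnot(sum(counts) == n_total)
  structure(list(kind = kind, counts = counts, n_total = n_total,
                 n_classes = n_classes),
            class = "class_size_profile")
}

# Draw `n` rows from N(mu, Sigma); handles n = 0/1 and a zero covariance.
draw_gaussian <- function(n, mu, sigma) {
  if (n == 0L) return(matrix(numeric(0), nrow = 0L, ncol = length(mu)))
  as_row_matrix(MASS::mvrnorm(n, mu = mu, Sigma = sigma))
}

#' Generate in-distribution feature records
#'
#' Draws `profile$counts[c]` samples for each class `c` from
#' `N(mu_c, within_cov)` where the `mu_c` are the seed-determined class
#' means of `spec`. The output is byte-identical across runs with the
#' same spec and profile.
#'
#' @param spec a [feature_space_spec()].
#' @param profile a [make_class_size_profile()] whose length matches
#'   `spec$n_classes`.
#' @return A record table (see [feature_records()]) with `domain = "ID"`
#'   and integer labels `1..n_classes`.
#' @export
generate_id_features <- function(spec, profile) {
  stopifnot(inherits(spec, "feature_space_spec"),
            inherits(profile, "class_size_profile"))
  if (profile$n_classes != spec$n_classes) {
    stop("profile describes ", profile$n_classes, " classes but spec has ",
         spec$n_classes, call. = FALSE)
  }
  mu <- class_means(spec)
  feats <- with_seed(derive_seed(spec$seed, 31L), {
    do.call(rbind, lapply(seq_len(spec$n_classes), function(c) {
      draw_gaussian(profile$counts[c], mu[c, ], spec$within_cov)
    }))
  })
  labels <- rep(seq_len(spec$n_classes), times = profile$counts)
  feature_records(
    id = sprintf("id-%06d", seq_len(nrow(feats))),
    domain = rep("ID", nrow(feats)),
    label = labels,
    features = feats
  )
}

#' Generate out-of-distribution feature records
#'
#' Emits `shift$n_samples` unlabeled OOD records at a controllable
#' distributional distance from the ID population of `spec`; see
#' [ood_shift_spec()] for the shift mechanisms. Each sample picks one of
#' the ID classes uniformly at random as its anchor, so at
#' `delta = 0` (mean-shift) the OOD distribution equals the balanced ID
#' mixture.
#'
#' @param spec the [feature_space_spec()] describing the ID population.
#' @param shift an [ood_shift_spec()].
#' @param seed optional integer seed for the OOD draws; defaults to a
#'   stream derived from `spec$seed`, independent of the ID draws.
#' @return A record table with `domain = "OOD"` and `NA` labels.
#' @export
generate_ood_features <- function(spec, shift, seed = NULL) {
  stopifnot(inherits(spec, "feature_space_spec"),
            inherits(shift, "ood_shift_spec"))
  d <- spec$dim
  if (shift$n_samples == 0L) {
    return(feature_records(id = character(0), domain = character(0),
                           label = integer(0),
                           features = matrix(numeric(0), 0L, d)))
  }
  mu <- class_means(spec)
  seed <- seed %||% derive_seed(spec$seed, 47L)
  feats <- with_seed(seed, {
    # one seed-determined unit displacement direction per class
    u <- matrix(stats::rnorm(spec$n_classes * d), spec$n_classes, d)
    u <- u / sqrt(rowSums(u^2))
    shifted <- mu + shift$delta * u
    anchor <- sample.int(spec$n_classes, shift$n_samples, replace = TRUE)
    inflated <- spec$within_cov * (1 + shift$delta)^2
    use_shift <- switch(shift$mode,
                        "mean-shift" = rep(TRUE, shift$n_samples),
                        "covariance-inflation" = rep(FALSE, shift$n_samples),
                        "mixture" = stats::runif(shift$n_samples) < 0.5)
    out <- matrix(0, shift$n_samples, d)
    for (c in sort(unique(anchor))) {
      i_s <- which(anchor == c & use_shift)
      i_c <- which(anchor == c & !use_shift)
      if (length(i_s)) {
        out[i_s, ] <- draw_gaussian(length(i_s), shifted[c, ],
                                    spec$within_cov)
      }
      if (length(i_c)) {
        out[i_c, ] <- draw_gaussian(length(i_c), mu[c, ], inflated)
      }
    }
    out
  })
  feature_records(
    id = sprintf("ood-%06d", seq_len(nrow(feats))),
    domain = rep("OOD", nrow(feats)),
    features = feats
  )
}
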