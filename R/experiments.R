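#' Experiment configuration
#'
#' Collects every tunable of the three experiment axes (classifier
#' accuracy, degree of out-of-domainness, class imbalance of the
#' detector-fitting set) plus the shared synthetic-population settings.
#' All randomness downstream is a pure function of this configuration and
#' the seeds it lists.
#'
#' @param methods subset of `c("MSP", "MAH", "EBM")`.
#' @param seeds integer vector of replicate seeds.
#' @param n_classes,dim,mean_scale,within_cov ID feature population (see
#'   [feature_space_spec()]).
#' @param n_per_class ID samples generated per class before the
#'   70/15/15 split.
#' @param ood_n OOD test samples generated per condition.
#' @param shift_grid nonnegative deltas for the out-of-domainness sweep.
#' @param shift_mode shift mechanism (see [ood_shift_spec()]).
#' @param epochs,learning_rate,batch_size reference-classifier training.
#' @param checkpoint_epochs epochs whose checkpoints enter the accuracy
#'   sweep; the default is a 15-point sequence spanning undertrained to
#'   converged, giving a series of classifiers of increasing accuracy;
#'   `NULL` = every epoch.
#' @param accuracy_sweep_delta,imbalance_delta the fixed OOD shift used
#'   by the accuracy sweep and the imbalance experiment.
#' @param profile_kinds class-size profiles compared by the imbalance
#'   experiment; all share `id2_n_total`.
#' @param id2_n_total total size of each detector-fitting profile.
#' @param empirical_weights weights for the `"unbalanced-empirical"`
#'   profile; default is a geometric decay across classes, emulating the
#'   long-tailed class-frequency distribution of field image corpora.
#' @param temperature energy-score temperature.
#' @param reg_eps Mahalanobis covariance regularizer (`NULL` =
#'   scale-aware default).
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(methods = c("MSP", "MAH", "EBM"),
                              seeds = 1:5,
                              n_classes = 10L, dim = 16L, mean_scale = 3,
                              within_cov = 1, n_per_class = 100L,
                              ood_n = 200L,
                              shift_grid = c(0, 1, 2, 4, 8),
                              shift_mode = "mean-shift",
                              epochs = 60L, learning_rate = 1e-3,
                              batch_size = 256L,
                              checkpoint_epochs = c(1:8, 10, 12, 15, 20,
                                                    30, 45, 60),
                              accuracy_sweep_delta = 4,
                              imbalance_delta = 4,
                              profile_kinds = c("balanced",
                                                "unbalanced-empirical",
                                                "unbalanced-uniform"),
                              id2_n_total = 150L,
                              empirical_weights = NULL,
                              temperature = 1,
                              reg_eps = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (length(methods) == 0L || length(seeds) == 0L) {
    stop("methods and seeds must be non-empty", call. = FALSE)
  }
  if (any(shift_grid < 0)) stop("shift grid must be nonnegative",
                                call. = FALSE)
  profile_kinds <- match.arg(profile_kinds,
                             c("balanced", "unbalanced-empirical",
                               "unbalanced-uniform"), several.ok = TRUE)
  empirical_weights <- empirical_weights %||% 0.7^(seq_len(n_classes) - 1L)
  structure(list(
    methods = methods, seeds = as.integer(seeds),
    n_classes = as.integer(n_classes), dim = as.integer(dim),
    mean_scale = mean_scale, within_cov = within_cov,
    n_per_class = as.integer(n_per_class), ood_n = as.integer(ood_n),
    shift_grid = as.numeric(shift_grid), shift_mode = shift_mode,
    epochs = as.integer(epochs), learning_rate = learning_rate,
    batch_size = as.integer(batch_size),
    checkpoint_epochs = checkpoint_epochs,
    accuracy_sweep_delta = accuracy_sweep_delta,
    imbalance_delta = imbalance_delta,
    profile_kinds = profile_kinds, id2_n_total = as.integer(id2_n_total),
    empirical_weights = empirical_weights,
    temperature = temperature, reg_eps = reg_eps
  ), class = "experiment_config")
}

#' Read an experiment configuration from a YAML file
#' @param path YAML file whose keys are [experiment_config()] arguments.
#' @return An `experiment_config`.
#' @export
experiment_config_from_yaml <- function(path) {
  args <- yaml::read_yaml(path)
  do.call(experiment_config, args)
}

new_experiment_rows <- function(experiment, factor_name, factor_value,
                                method, metric, value, seed) {
  data.frame(experiment = experiment, factor_name = factor_name,
             factor_value = as.character(factor_value), method = method,
             metric = metric, value = as.numeric(value),
             seed = as.integer(seed), stringsAsFactors = FALSE)
}

# Shared per-seed preparation: ID population, 70/15/15 split, trained
# reference classifier (checkpoints kept), Gaussian model on ID2.
prepare_run <- function(config, seed) {
  spec <- feature_space_spec(config$n_classes, config$dim,
                             mean_scale = config$mean_scale,
                             within_cov = config$within_cov,
                             seed = derive_seed(seed, 101L))
  profile <- make_class_size_profile("balanced",
                                     config$n_per_class * config$n_classes,
                                     config$n_classes)
  id <- generate_id_features(spec, profile)
  parts <- split_dataset(id, split_spec(seed = derive_seed(seed, 103L)))
  classifier <- train_reference_classifier(
    parts$id1, n_classes = config$n_classes, epochs = config$epochs,
    learning_rate = config$learning_rate, batch_size = config$batch_size,
    seed = derive_seed(seed, 107L), holdout_records = parts$id2
  )
  list(spec = spec, parts = parts, classifier = classifier)
}

score_methods <- function(config, test_records, adapter, model) {
  cfg <- energy_config(config$temperature)
  sets <- lapply(config$methods, function(m) {
    score_dataset(test_records, adapter, method = m,
                  model = if (m == "MAH") model, config = cfg)
  })
  names(sets) <- config$methods
  sets
}

metric_rows_for <- function(sets, experiment, factor_name, factor_value,
                            seed, metrics = c("auroc", "fpr95")) {
  do.call(rbind, lapply(names(sets), function(m) {
    s <- sets[[m]]
    roc <- roc_curve(s$score[s$domain == "ID"],
                     s$score[s$domain == "OOD"])
    vals <- c(auroc = roc$auroc, fpr95 = roc$fpr95)
    new_experiment_rows(experiment, factor_name, factor_value, m,
                        metrics, vals[metrics], seed)
  }))
}

#' Accuracy-sweep experiment
#'
#' Measures, for a sequence of classifier checkpoints of increasing
#' held-out accuracy, the AUROC of each OOD method on an equalized
#' ID3/OOD test set. The Mahalanobis model is refit on ID2 features from
#' each checkpoint.
#'
#' @param config an [experiment_config()].
#' @return A tidy `data.frame(experiment, factor_name, factor_value,
#'   method, metric, value, seed)`.
#' @export
run_accuracy_sweep <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  out <- list()
  for (seed in config$seeds) {
    run <- prepare_run(config, seed)
    cks <- run$classifier$checkpoints
    keep <- config$checkpoint_epochs %||%
      vapply(cks, `[[`, integer(1), "epoch")
    cks <- Filter(function(ck) ck$epoch %in% keep, cks)
    if (length(cks) < 2L) {
      stop("accuracy sweep needs at least 2 checkpoints", call. = FALSE)
    }
    shift <- ood_shift_spec(config$accuracy_sweep_delta, config$ood_n,
                            config$shift_mode)
    ood <- generate_ood_features(run$spec, shift,
                                 seed = derive_seed(seed, 113L))
    eq <- equalize_sizes(run$parts$id3, ood, seed = derive_seed(seed, 127L))
    test <- rbind(eq$a, eq$b)
    for (ck in cks) {
      if (is.null(ck$accuracy)) {
        stop("checkpoint at epoch ", ck$epoch, " lacks accuracy metadata",
             call. = FALSE)
      }
      model <- if ("MAH" %in% config$methods) {
        fit_gaussian_model(adapter_features(ck$adapter,
                                            feature_matrix(run$parts$id2)),
                           run$parts$id2$label, reg_eps = config$reg_eps)
      }
      sets <- score_methods(config, test, ck$adapter, model)
      out[[length(out) + 1L]] <- metric_rows_for(
        sets, "accuracy_sweep", "classifier_accuracy",
        format(ck$accuracy, digits = 6), seed, metrics = "auroc")
    }
  }
  do.call(rbind, out)
}

#' Out-of-domainness sweep
#'
#' For each shift `delta` in the grid, generates OOD data at that
#' distance from the ID population, equalizes test-set sizes, and records
#' AUROC and FPR95 for each method. Emulates testing a detector against
#' OOD datasets spanning a near-to-far spectrum.
#'
#' @param config an [experiment_config()] with at least 2 grid values.
#' @return A tidy experiment table (see [run_accuracy_sweep()]).
#' @export
run_oodness_sweep <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  if (length(config$shift_grid) < 2L) {
    stop("the shift grid needs at least 2 delta values", call. = FALSE)
  }
  out <- list()
  for (seed in config$seeds) {
    run <- prepare_run(config, seed)
    model <- if ("MAH" %in% config$methods) {
      fit_gaussian_model(run$parts$id2, reg_eps = config$reg_eps)
    }
    for (delta in config$shift_grid) {
      shift <- ood_shift_spec(delta, config$ood_n, config$shift_mode)
      ood <- generate_ood_features(run$spec, shift,
                                   seed = derive_seed(seed, 131L))
      eq <- equalize_sizes(run$parts$id3, ood,
                           seed = derive_seed(seed, 137L))
      sets <- score_methods(config, rbind(eq$a, eq$b),
                            run$classifier$adapter, model)
      out[[length(out) + 1L]] <- metric_rows_for(
        sets, "oodness_sweep", "delta", delta, seed)
    }
  }
  do.call(rbind, out)
}

#' Class-imbalance experiment
#'
#' Holds the classifier and a test set fixed and varies only the class
#' composition of the detector-fitting set (ID2) across the configured
#' profiles at one common total size. The Mahalanobis model is refit per
#' profile (classes starved below 2 samples are dropped from the fit);
#' MSP and the energy score take no fitting data, so their scores are
#' bit-identical across profiles — the mechanism behind their
#' insensitivity to imbalance.
#'
#' @param config an [experiment_config()].
#' @return A tidy experiment table; the attribute `score_sets` holds the
#'   per-profile confidence sets (named `profile.method`) so the
#'   invariance can be checked exactly.
#' @export
run_imbalance_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  out <- list()
  score_sets <- list()
  for (seed in config$seeds) {
    run <- prepare_run(config, seed)
    shift <- ood_shift_spec(config$imbalance_delta, config$ood_n,
                            config$shift_mode)
    ood <- generate_ood_features(run$spec, shift,
                                 seed = derive_seed(seed, 139L))
    eq <- equalize_sizes(run$parts$id3, ood, seed = derive_seed(seed, 149L))
    test <- rbind(eq$a, eq$b)
    # dedicated ID2 pool large enough to realize any profile
    pool_per_class <- max(config$id2_n_total, 2L * config$n_classes)
    pool <- generate_id_features(
      feature_space_spec(config$n_classes, config$dim,
                         mean_scale = config$mean_scale,
                         within_cov = config$within_cov,
                         seed = run$spec$seed),
      make_class_size_profile("balanced",
                              pool_per_class * config$n_classes,
                              config$n_classes))
    for (kind in config$profile_kinds) {
      profile <- make_class_size_profile(
        kind, config$id2_n_total, config$n_classes,
        seed = derive_seed(seed, 151L),
        empirical_weights = config$empirical_weights)
      if (profile$n_total != config$id2_n_total) {
        stop("profiles must share one total size", call. = FALSE)
      }
      id2 <- subsample_profile(pool, profile,
                               seed = derive_seed(seed, 157L))
      model <- if ("MAH" %in% config$methods) {
        fit_gaussian_model(id2, reg_eps = config$reg_eps,
                           drop_small = TRUE)
      }
      sets <- score_methods(config, test, run$classifier$adapter, model)
      for (m in names(sets)) {
        score_sets[[paste(seed, kind, m, sep = ".")]] <- sets[[m]]
      }
      out[[length(out) + 1L]] <- metric_rows_for(
        sets, "imbalance", "profile", kind, seed, metrics = "auroc")
    }
  }
  tab <- do.call(rbind, out)
  attr(tab, "score_sets") <- score_sets
  tab
}

# Draw profile$counts[c] samples of each class c from a labeled pool,
# without replacement, deterministically given the seed.
subsample_profile <- function(pool, profile, seed = 1L) {
  with_seed(derive_seed(seed, 163L), {
    idx <- unlist(lapply(seq_len(profile$n_classes), function(cl) {
      avail <- which(pool$label == cl)
      want <- profile$counts[cl]
      if (want > length(avail)) {
        stop("pool has only ", length(avail), " samples of class ", cl,
             " but the profile asks for ", want, call. = FALSE)
      }
      sample(avail, want)
    }))
    out <- pool[sort(idx), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Run the full experiment report
#'
#' Executes the configured experiments end-to-end and writes the tidy
#' result table (`results.csv`), a per-method headline summary
#' (`summary.json`: AUROC, FPR95, Youden threshold and operating point,
#' accuracy at that threshold on equalized sets, and ID/OOD five-number
#' score summaries at the first seed and the largest configured shift),
#' and `run.log` recording seeds and the package version. A failing
#' experiment is recorded in the log and the remaining experiments still
#' run.
#'
#' @param config an [experiment_config()].
#' @param out_dir output directory.
#' @param experiments which of the three experiments to run.
#' @return Invisibly, `list(results, summary, failures)`.
#' @export
run_full_report <- function(config, out_dir,
                            experiments = c("accuracy_sweep",
                                            "oodness_sweep",
                                            "imbalance")) {
  stopifnot(inherits(config, "experiment_config"))
  experiments <- match.arg(experiments, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  runners <- list(accuracy_sweep = run_accuracy_sweep,
                  oodness_sweep = run_oodness_sweep,
                  imbalance = run_imbalance_experiment)
  tables <- list()
  failures <- character(0)
  log_lines <- c(
    paste0("oodeval version: ",
           as.character(utils::packageVersion("oodeval"))),
    paste0("seeds: ", paste(config$seeds, collapse = ", ")),
    paste0("methods: ", paste(config$methods, collapse = ", ")),
    paste0("experiments: ", paste(experiments, collapse = ", "))
  )
  for (ex in experiments) {
    res <- tryCatch(runners[[ex]](config), error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, ex)
      log_lines <- c(log_lines,
                     paste0("FAILED ", ex, ": ", conditionMessage(res)))
    } else {
      attr(res, "score_sets") <- NULL
      tables[[ex]] <- res
      log_lines <- c(log_lines, paste0("completed ", ex, ": ",
                                       nrow(res), " rows"))
    }
  }
  results <- do.call(rbind, c(tables, list(make.row.names = FALSE)))
  if (!is.null(results)) {
    utils::write.csv(results, file.path(out_dir, "results.csv"),
                     row.names = FALSE)
  }
  summary <- headline_summary(config)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(list(results = results, summary = summary,
                 failures = failures))
}

# Headline per-method evaluation at the first seed and the largest
# configured shift: the ROC operating point, threshold-based accuracy and
# the ID/OOD score-distribution summaries.
headline_summary <- function(config) {
  seed <- config$seeds[1]
  run <- prepare_run(config, seed)
  delta <- max(config$shift_grid)
  shift <- ood_shift_spec(delta, config$ood_n, config$shift_mode)
  ood <- generate_ood_features(run$spec, shift,
                               seed = derive_seed(seed, 167L))
  eq <- equalize_sizes(run$parts$id3, ood, seed = derive_seed(seed, 173L))
  test <- rbind(eq$a, eq$b)
  model <- if ("MAH" %in% config$methods) {
    fit_gaussian_model(run$parts$id2, reg_eps = config$reg_eps)
  }
  sets <- score_methods(config, test, run$classifier$adapter, model)
  out <- lapply(names(sets), function(m) {
    s <- sets[[m]]
    cid <- s$score[s$domain == "ID"]
    cood <- s$score[s$domain == "OOD"]
    roc <- roc_curve(cid, cood)
    list(method = m,
         auroc = roc$auroc,
         fpr95 = roc$fpr95,
         best_threshold = roc$best_threshold,
         best_tpr = roc$best_tpr,
         best_fpr = roc$best_fpr,
         accuracy = accuracy_at_threshold(cid, cood, roc$best_threshold),
         id_summary = unclass(five_number_summary(cid)),
         ood_summary = unclass(five_number_summary(cood)))
  })
  names(out) <- names(sets)
  list(seed = seed, delta = delta, n_test_per_domain = nrow(eq$a),
       methods = out)
}
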