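#' Labeled feature records
#'
#' The tabular exchange format used throughout the pipeline: one row per
#' sample carrying an identifier, a domain tag (`"ID"` or `"OOD"`), a class
#' label (ID rows only; `NA` for OOD rows), a feature vector `f_1..f_d`
#' (e.g. penultimate-layer activations) and optionally a logit vector
#' `l_1..l_k`.
#'
#' @param id character vector of unique sample identifiers.
#' @param domain character vector, each element `"ID"` or `"OOD"`.
#' @param label integer class labels for ID rows; `NA` for OOD rows. OOD
#'   samples never carry a class label so they cannot leak into fitting.
#' @param features numeric matrix, one row per sample.
#' @param logits optional numeric matrix of classifier logits, one row per
#'   sample.
#' @return A `data.frame` with columns `id`, `domain`, `label`,
#'   `f_1..f_d` and optionally `l_1..l_k`.
#' @export
feature_records <- function(id, domain, label = NULL, features,
                            logits = NULL) {
  features <- as_row_matrix(features)
  n <- nrow(features)
  if (length(id) != n || length(domain) != n) {
    stop("id, domain and features must describe the same number of samples",
         call. = FALSE)
  }
  if (!all(domain %in% c("ID", "OOD"))) {
    stop("domain must be 'ID' or 'OOD'", call. = FALSE)
  }
  if (is.null(label)) label <- rep(NA_integer_, n)
  label <- as.integer(label)
  if (length(label) != n) {
    stop("label must have one entry per sample", call. = FALSE)
  }
  if (any(domain == "OOD" & !is.na(label))) {
    stop("OOD records must not carry a class label", call. = FALSE)
  }
  if (any(domain == "ID" & is.na(label))) {
    stop("every ID record must carry a class label", call. = FALSE)
  }
  check_finite(features, "features")
  colnames(features) <- paste0("f_", seq_len(ncol(features)))
  out <- data.frame(id = as.character(id), domain = domain, label = label,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(features))
  if (!is.null(logits)) {
    logits <- as_row_matrix(logits)
    if (nrow(logits) != n) {
      stop("logits must have one row per sample", call. = FALSE)
    }
    check_finite(logits, "logits")
    colnames(logits) <- paste0("l_", seq_len(ncol(logits)))
    out <- cbind(out, as.data.frame(logits))
  }
  rownames(out) <- NULL
  out
}

feature_cols <- function(records) {
  grep("^f_[0-9]+$", names(records), value = TRUE)
}

logit_cols <- function(records) {
  grep("^l_[0-9]+$", names(records), value = TRUE)
}

#' Extract the feature matrix from a record table
#' @param records a record table from [feature_records()].
#' @return numeric matrix, one row per sample.
#' @export
feature_matrix <- function(records) {
  cols <- feature_cols(records)
  if (length(cols) == 0L) stop("records carry no feature columns",
                               call. = FALSE)
  as.matrix(records[, cols, drop = FALSE])
}

#' Extract the logit matrix from a record table
#' @param records a record table from [feature_records()].
#' @return numeric matrix, one row per sample.
#' @export
logit_matrix <- function(records) {
  cols <- logit_cols(records)
  if (length(cols) == 0L) stop("records carry no logit columns",
                               call. = FALSE)
  as.matrix(records[, cols, drop = FALSE])
}

#' Write a record table to delimited text
#'
#' Header layout is `id,domain,label,f_1..f_d[,l_1..l_k]`; OOD rows have an
#' empty label field.
#'
#' @param records a record table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a record table written by [write_feature_table()]
#' @param path file path.
#' @return a record table `data.frame`.
#' @export
read_feature_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  out$id <- as.character(out$id)
  out$label <- as.integer(out$label)
  out
}
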