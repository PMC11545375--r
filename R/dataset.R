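# Labeled feature tables and holdout partitioning.  The selector operates on
# a samples x features matrix with binary stenosis labels (1 = positive).

#' Construct a labeled dataset
#'
#' @param features numeric matrix, `n_samples x n_features`, no missing
#'   values.
#' @param labels binary vector (`0`/`1`), length `n_samples`; `1` marks a
#'   positive stenosis case.
#' @param feature_names optional character vector of unique column names;
#'   defaults to the matrix column names.
#' @return An object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(features, labels, feature_names = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (anyNA(features) || any(!is.finite(features))) {
    stop_ssfs("feature matrix contains missing or non-finite values",
              class = "dataset_error")
  }
  labels <- as.integer(labels)
  if (length(labels) != nrow(features)) {
    stop_ssfs("labels length %d != number of samples %d",
              length(labels), nrow(features), class = "dataset_error")
  }
  if (!all(labels %in% c(0L, 1L))) {
    stop_ssfs("labels must contain only 0 and 1", class = "dataset_error")
  }
  feature_names <- feature_names %||% colnames(features) %||%
    sprintf("F%03d", seq_len(ncol(features)))
  if (length(feature_names) != ncol(features)) {
    stop_ssfs("feature_names length %d != number of features %d",
              length(feature_names), ncol(features), class = "dataset_error")
  }
  if (anyDuplicated(feature_names)) {
    stop_ssfs("duplicate feature name(s): %s",
              paste(unique(feature_names[duplicated(feature_names)]),
                    collapse = ", "),
              class = "dataset_error")
  }
  colnames(features) <- feature_names
  structure(list(features = features, labels = labels,
                 feature_names = feature_names),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset %d samples x %d features, %d positive>\n",
              nrow(x$features), ncol(x$features), sum(x$labels)))
  invisible(x)
}

#' Load a delimited feature table
#'
#' Reads a delimited text file with a header row into a [labeled_dataset()].
#'
#' @param path path to a CSV/TSV file.
#' @param label_column name of the label column (values coercible to 0/1).
#' @param delim field delimiter; `","` by default, use `"\t"` for TSV.
#' @return A [labeled_dataset()]; feature column order follows the file.
#' @export
load_feature_table <- function(path, label_column = "label", delim = ",") {
  tab <- utils::read.table(path, header = TRUE, sep = delim,
                           check.names = FALSE, stringsAsFactors = FALSE)
  nm <- names(tab)
  if (anyDuplicated(nm)) {
    stop_ssfs("duplicate column name(s): %s",
              paste(unique(nm[duplicated(nm)]), collapse = ", "),
              class = "dataset_error")
  }
  if (!label_column %in% nm) {
    stop_ssfs("label column '%s' not found", label_column,
              class = "dataset_error")
  }
  labels <- tab[[label_column]]
  feat <- tab[nm != label_column]
  bad <- names(feat)[!vapply(feat, is.numeric, logical(1))]
  if (length(bad)) {
    stop_ssfs("non-numeric feature column(s): %s",
              paste(bad, collapse = ", "), class = "dataset_error")
  }
  labeled_dataset(as.matrix(feat), labels, names(feat))
}

#' Write a feature table
#'
#' Inverse of [load_feature_table()] (round-trip safe at full precision).
#'
#' @param ds a [labeled_dataset()].
#' @param path output path.
#' @param label_column name for the label column.
#' @param delim field delimiter.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ds, path, label_column = "label",
                                delim = ",") {
  stopifnot(inherits(ds, "labeled_dataset"))
  tab <- as.data.frame(ds$features, check.names = FALSE)
  tab[[label_column]] <- ds$labels
  utils::write.table(tab, path, sep = delim, row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Partition a dataset into train/validation/test index sets
#'
#' The reference database partitions its 608 patches as 458 training, 50
#' validation and 100 test instances.  Stratified assignment (the default)
#' preserves the class balance within each split to plus/minus one sample.
#'
#' @param ds a [labeled_dataset()].
#' @param counts integer vector `c(train, validation, test)` summing to the
#'   number of samples; all three must be positive.
#' @param seed integer seed; splits are deterministic given the seed.
#' @param stratified preserve class proportions per split (default `TRUE`).
#' @return An object of class `partition_spec` with fields `train_idx`,
#'   `validation_idx`, `test_idx`.
#' @export
split_dataset <- function(ds, counts, seed, stratified = TRUE) {
  stopifnot(inherits(ds, "labeled_dataset"))
  counts <- as.integer(counts)
  if (length(counts) != 3L) {
    stop_ssfs("counts must be c(train, validation, test)",
              class = "partition_error")
  }
  n <- nrow(ds$features)
  if (sum(counts) != n) {
    stop_ssfs("counts sum to %d but dataset has %d samples",
              sum(counts), n, class = "partition_error")
  }
  if (any(counts < 1L)) {
    stop_ssfs("every split must receive at least one sample",
              class = "partition_error")
  }
  idx <- with_seed(seed, {
    if (stratified) {
      pos <- sample(which(ds$labels == 1L))
      neg <- sample(which(ds$labels == 0L))
      # largest-remainder apportionment of each class across the three splits
      take <- function(cls_idx, quota) {
        out <- vector("list", 3L)
        start <- 1L
        for (k in 1:3) {
          out[[k]] <- if (quota[k] > 0L) {
            cls_idx[start:(start + quota[k] - 1L)]
          } else integer(0)
          start <- start + quota[k]
        }
        out
      }
      apportion <- function(n_cls) {
        exact <- counts * n_cls / n
        base <- floor(exact)
        rem <- n_cls - sum(base)
        if (rem > 0L) {
          extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
          base[extra] <- base[extra] + 1L
        }
        as.integer(base)
      }
      qp <- apportion(length(pos))
      qn <- counts - qp
      if (any(qn < 0L)) { qp <- qp + pmin(qn, 0L); qn <- counts - qp }
      if (length(pos) && any(qp == 0L) || length(neg) && any(qn == 0L)) {
        stop_ssfs(
          "a split would receive zero samples of one class under stratification",
          class = "partition_error")
      }
      p <- take(pos, qp); q <- take(neg, qn)
      lapply(1:3, function(k) sort(c(p[[k]], q[[k]])))
    } else {
      perm <- sample.int(n)
      list(sort(perm[seq_len(counts[1])]),
           sort(perm[counts[1] + seq_len(counts[2])]),
           sort(perm[counts[1] + counts[2] + seq_len(counts[3])]))
    }
  })
  structure(list(train_idx = idx[[1]], validation_idx = idx[[2]],
                 test_idx = idx[[3]]),
            class = "partition_spec")
}

#' @export
print.partition_spec <- function(x, ...) {
  cat(sprintf("<partition_spec train=%d validation=%d test=%d>\n",
              length(x$train_idx), length(x$validation_idx),
              length(x$test_idx)))
  invisible(x)
}
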