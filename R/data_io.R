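# Reading and writing feature tables, feature-set definitions and replicate
# result tables, plus validation of feature-set references against a dataset.

#' Construct a labeled dataset
#'
#' A labeled dataset couples a numeric sample-by-feature matrix with a binary
#' class label per sample.  It is the container every other module consumes.
#'
#' @param x numeric matrix, samples in rows, features in columns.
#' @param labels vector of class labels, one per row; at most two distinct
#'   values.  A single-level label vector is accepted but flagged degenerate.
#' @param sample_ids optional character vector of unique sample identifiers;
#'   defaults to rownames of `x` or `s1..sn`.
#' @param feature_names optional character vector of unique feature names;
#'   defaults to colnames of `x` or `f1..fP`.
#' @return an object of class `labeled_dataset` with fields `matrix`,
#'   `labels` (factor), `sample_ids` and `feature_names`.
#' @export
labeled_dataset <- function(x, labels, sample_ids = NULL, feature_names = NULL) {
  if (!is.matrix(x) || !is.numeric(x)) {
    fss_abort("invalid_matrix", "`x` must be a numeric matrix")
  }
  feature_names <- feature_names %||% colnames(x) %||% paste0("f", seq_len(ncol(x)))
  sample_ids <- sample_ids %||% rownames(x) %||% paste0("s", seq_len(nrow(x)))
  if (length(feature_names) != ncol(x)) {
    fss_abort("invalid_matrix", "feature_names length must equal the number of columns")
  }
  if (anyDuplicated(feature_names)) {
    dup <- unique(feature_names[duplicated(feature_names)])
    fss_abort("duplicate_feature", paste0("duplicate feature name(s): ", paste(dup, collapse = ", ")))
  }
  if (length(labels) != nrow(x)) {
    fss_abort("invalid_labels", "labels length must equal the number of rows")
  }
  if (anyDuplicated(sample_ids)) {
    fss_abort("invalid_labels", "sample_ids must be unique")
  }
  lv <- unique(as.character(labels))
  if (length(lv) > 2) {
    fss_abort("invalid_labels", paste0("expected at most two label levels, found ", length(lv)))
  }
  dimnames(x) <- list(sample_ids, feature_names)
  structure(
    list(matrix = x, labels = factor(as.character(labels), levels = sort(lv)),
         sample_ids = sample_ids, feature_names = feature_names),
    degenerate = length(lv) < 2L,
    class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("<labeled_dataset> ", nrow(x$matrix), " samples x ", ncol(x$matrix), " features; labels: ",
      paste(sprintf("%s=%d", levels(x$labels), tabulate(x$labels, nlevels(x$labels))), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Dataset dimensions
#' @param d a [labeled_dataset()].
#' @return sample or feature count.
#' @export
n_samples <- function(d) nrow(d$matrix)

#' @rdname n_samples
#' @export
n_features <- function(d) ncol(d$matrix)

# Delimiter chosen by file extension: tab for .tsv/.tab/.txt, comma otherwise.
delim_for <- function(path) {
  if (grepl("\\.(tsv|tab|txt)$", tolower(path))) "\t" else ","
}

#' Read a delimited feature table into a labeled dataset
#'
#' The file must have a header row naming every feature column plus one label
#' column.  The label column is removed from the returned matrix; sample order
#' follows file row order.
#'
#' @param path path to a CSV/TSV file (delimiter auto-detected by extension).
#' @param label_column name of the class label column.
#' @return a [labeled_dataset()].
#' @export
read_feature_table <- function(path, label_column = "class") {
  if (!file.exists(path)) fss_abort("missing_file", paste0("file not found: ", path))
  sep <- delim_for(path)
  header <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  header <- gsub('^"|"$', "", header)
  if (!label_column %in% header) {
    fss_abort("missing_label_column",
              paste0("label column '", label_column, "' not found in ", path))
  }
  feats <- setdiff(header, label_column)
  if (anyDuplicated(header)) {
    dup <- unique(header[duplicated(header)])
    fss_abort("duplicate_feature", paste0("duplicate feature name(s) in header: ",
                                          paste(dup, collapse = ", ")))
  }
  dt <- data.table::fread(path, sep = sep, header = TRUE, check.names = FALSE,
                          data.table = FALSE, showProgress = FALSE)
  labels <- dt[[label_column]]
  xdf <- dt[feats]
  bad <- names(xdf)[!vapply(xdf, is.numeric, logical(1))]
  if (length(bad)) {
    fss_abort("nonnumeric_feature",
              paste0("non-numeric value(s) in feature column(s): ", paste(bad, collapse = ", ")))
  }
  labeled_dataset(as.matrix(xdf), labels, feature_names = feats)
}

#' Write a labeled dataset as a delimited feature table
#'
#' Inverse of [read_feature_table()]: feature columns first, label column last.
#' @param dataset a [labeled_dataset()].
#' @param path output path (delimiter by extension).
#' @param label_column name for the label column.
#' @export
write_feature_table <- function(dataset, path, label_column = "class") {
  df <- as.data.frame(dataset$matrix, check.names = FALSE)
  df[[label_column]] <- as.character(dataset$labels)
  data.table::fwrite(df, path, sep = delim_for(path))
  invisible(path)
}

#' Construct a feature-set collection
#'
#' An ordered, named collection of feature groups: the search space of the
#' feature set selector.  Collection order is meaningful (subset index i in the
#' golden-ratio allocation used by the simulator).
#'
#' @param set_names character vector of unique set names.
#' @param features list of character vectors, one per set, each without
#'   duplicates.
#' @return an object of class `feature_set_collection`.
#' @export
feature_set_collection <- function(set_names, features) {
  if (length(set_names) != length(features)) {
    fss_abort("invalid_sets", "set_names and features must have equal length")
  }
  if (anyDuplicated(set_names)) {
    fss_abort("duplicate_set", paste0("duplicate set name(s): ",
                                      paste(unique(set_names[duplicated(set_names)]), collapse = ", ")))
  }
  for (i in seq_along(features)) {
    if (length(features[[i]]) == 0) {
      fss_abort("empty_set", paste0("set '", set_names[i], "' has an empty feature list"))
    }
    if (anyDuplicated(features[[i]])) {
      fss_abort("duplicate_feature", paste0("duplicate feature name(s) within set '", set_names[i], "'"))
    }
  }
  names(features) <- set_names
  structure(list(set_names = as.character(set_names), features = features),
            class = "feature_set_collection")
}

#' @export
print.feature_set_collection <- function(x, ...) {
  cat("<feature_set_collection> ", length(x$set_names), " sets; sizes: ",
      paste(utils::head(lengths(x$features), 10), collapse = ", "),
      if (length(x$set_names) > 10) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Read a feature-set definition file
#'
#' Expected format: delimited text with header `Subset,Size,Features`, one row
#' per set, `Features` a `;`-joined list of feature names.  The `Size` column
#' is a checksum: it must equal the parsed feature count.
#'
#' @param path path to the definition file.
#' @return a [feature_set_collection()] preserving file row order.
#' @export
read_feature_sets <- function(path) {
  if (!file.exists(path)) fss_abort("missing_file", paste0("file not found: ", path))
  dt <- data.table::fread(path, sep = delim_for(path), header = TRUE,
                          colClasses = "character", data.table = FALSE, showProgress = FALSE)
  need <- c("Subset", "Size", "Features")
  if (!all(need %in% names(dt))) {
    fss_abort("invalid_sets", paste0("feature-set file must have columns ",
                                     paste(need, collapse = ", ")))
  }
  feats <- lapply(dt$Features, function(s) {
    out <- strsplit(s, ";", fixed = TRUE)[[1]]
    out[nzchar(out)]
  })
  sizes <- suppressWarnings(as.integer(dt$Size))
  mism <- which(is.na(sizes) | sizes != lengths(feats))
  if (length(mism)) {
    fss_abort("size_mismatch",
              paste0("declared size disagrees with feature count for set(s): ",
                     paste(dt$Subset[mism], collapse = ", ")))
  }
  feature_set_collection(dt$Subset, feats)
}

#' Write a feature-set collection to its definition file format
#' @param collection a [feature_set_collection()].
#' @param path output path.
#' @export
write_feature_sets <- function(collection, path) {
  df <- data.frame(Subset = collection$set_names,
                   Size = lengths(collection$features),
                   Features = vapply(collection$features, paste, character(1), collapse = ";"))
  data.table::fwrite(df, path, sep = delim_for(path))
  invisible(path)
}

#' Bind a feature-set collection to a dataset
#'
#' Resolves every feature name in the collection to a column index of the
#' dataset.  Under the default `strict` policy any name absent from the dataset
#' is an error listing the offenders; under `drop` such names are removed with
#' a warning (sets emptied entirely are dropped).  Binding never reorders
#' features within a set and is idempotent.
#'
#' @param collection a [feature_set_collection()].
#' @param dataset a [labeled_dataset()].
#' @param policy `"strict"` or `"drop"`.
#' @return the collection with an added `indices` field (per-set integer column
#'   indices into the dataset) and attribute `bound = TRUE`.
#' @export
bind_feature_sets <- function(collection, dataset, policy = c("strict", "drop")) {
  policy <- match.arg(policy)
  keep_names <- collection$set_names
  feats <- collection$features
  unknown <- lapply(feats, function(f) setdiff(f, dataset$feature_names))
  n_unknown <- sum(lengths(unknown))
  if (n_unknown > 0) {
    if (policy == "strict") {
      offenders <- unique(unlist(unknown))
      fss_abort("unknown_feature",
                paste0(n_unknown, " feature name(s) not present in the dataset, e.g.: ",
                       paste(utils::head(offenders, 10), collapse = ", ")))
    }
    warning(sprintf("dropping %d feature name(s) not present in the dataset", n_unknown),
            call. = FALSE)
    feats <- lapply(feats, function(f) f[f %in% dataset$feature_names])
    nonempty <- lengths(feats) > 0
    feats <- feats[nonempty]
    keep_names <- keep_names[nonempty]
  }
  out <- feature_set_collection(keep_names, feats)
  out$indices <- lapply(out$features, function(f) match(f, dataset$feature_names))
  attr(out, "bound") <- TRUE
  out
}

replicate_table_columns <- c("replicate", "method", "selected_subset",
                             "cv_accuracy", "holdout_accuracy", "seed")

validate_replicate_table <- function(table) {
  if (!is.data.frame(table) || !identical(names(table), replicate_table_columns)) {
    fss_abort("invalid_table", paste0("replicate table must have columns exactly: ",
                                      paste(replicate_table_columns, collapse = ", ")))
  }
  acc <- c(table$cv_accuracy, table$holdout_accuracy)
  if (any(!is.na(acc) & (acc < 0 | acc > 1))) {
    fss_abort("invalid_table", "accuracies must lie in [0, 1]")
  }
  if (anyDuplicated(table[c("replicate", "method")])) {
    fss_abort("invalid_table", "one row per (replicate, method) expected")
  }
  invisible(table)
}

#' Write replicate benchmark results
#'
#' Columns are exactly `replicate,method,selected_subset,cv_accuracy,
#' holdout_accuracy,seed`.  Numeric values are written with 17 significant
#' digits so that [read_replicate_results()] reproduces the table exactly.
#'
#' @param table a replicate-results data frame.
#' @param path output CSV path.
#' @export
write_replicate_results <- function(table, path) {
  validate_replicate_table(table)
  out <- table
  for (col in c("cv_accuracy", "holdout_accuracy")) {
    out[[col]] <- ifelse(is.na(table[[col]]), "", formatC(table[[col]], digits = 17, format = "g"))
  }
  con <- tryCatch(file(path, "w"), error = function(e) {
    fss_abort("unwritable_path", paste0("cannot open for writing: ", path))
  })
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read replicate benchmark results written by [write_replicate_results()]
#' @param path CSV path.
#' @return a data frame with the canonical replicate-table columns.
#' @export
read_replicate_results <- function(path) {
  if (!file.exists(path)) fss_abort("missing_file", paste0("file not found: ", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(replicate = "integer", method = "character",
                                       selected_subset = "character",
                                       cv_accuracy = "character",
                                       holdout_accuracy = "character", seed = "integer"))
  if (nrow(df)) {
    df$selected_subset[df$selected_subset == ""] <- NA_character_
    df$cv_accuracy <- as.numeric(ifelse(df$cv_accuracy == "", NA, df$cv_accuracy))
    df$holdout_accuracy <- as.numeric(ifelse(df$holdout_accuracy == "", NA, df$holdout_accuracy))
  } else {
    df$selected_subset <- character(0)
    df$cv_accuracy <- numeric(0)
    df$holdout_accuracy <- numeric(0)
  }
  validate_replicate_table(df)
  df
}
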