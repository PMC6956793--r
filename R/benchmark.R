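# Replicate benchmark harness: stratified train/holdout splitting, the
# three-method comparison (selector-guided search, whole-matrix search, tuned
# gradient-boosting single-classifier search), subset-selection frequency
# summaries and Welch one-sided tests.

#' Stratified train/holdout split
#'
#' Allocates per class with floor + largest-remainder correction so the train
#' partition totals exactly `round(train_fraction * n)`; the union of the two
#' partitions is the input and their intersection empty.
#'
#' @param dataset a [labeled_dataset()].
#' @param train_fraction fraction in (0, 1), 0.75 by default.
#' @param seed integer seed.
#' @return list with `train` and `holdout` [labeled_dataset()]s.
#' @export
stratified_split <- function(dataset, train_fraction = 0.75, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    fss_abort("invalid_fraction", "train_fraction must lie strictly between 0 and 1")
  }
  labels <- dataset$labels
  n <- length(labels)
  target_total <- round(train_fraction * n)
  counts <- tabulate(labels, nlevels(labels))
  base <- floor(train_fraction * counts)
  remainder <- train_fraction * counts - base
  extra <- target_total - sum(base)
  take <- base
  if (extra > 0) {
    give <- order(-remainder, seq_along(counts))[seq_len(extra)]
    take[give] <- take[give] + 1L
  }
  if (any(take == 0) || any(take == counts)) {
    fss_abort("class_starvation",
              "a class would receive zero samples in the train or holdout partition")
  }
  set.seed(seed)
  train_idx <- integer(0)
  for (li in seq_along(levels(labels))) {
    idx <- which(as.integer(labels) == li)
    train_idx <- c(train_idx, sample(idx)[seq_len(take[li])])
  }
  train_idx <- sort(train_idx)
  hold_idx <- setdiff(seq_len(n), train_idx)
  slice <- function(idx) {
    labeled_dataset(dataset$matrix[idx, , drop = FALSE], dataset$labels[idx],
                    sample_ids = dataset$sample_ids[idx],
                    feature_names = dataset$feature_names)
  }
  list(train = slice(train_idx), holdout = slice(hold_idx))
}

#' Define a benchmark method
#'
#' @param label unique method label.
#' @param template template string defining the method's pipeline shape
#'   (e.g. `"FeatureSetSelector-Transformer-Classifier"`, or a single
#'   classifier name for a tuned-baseline search).
#' @param overrides named list of [gp_config()] fields to override for this
#'   method.
#' @return a `method_spec` object.
#' @export
method_spec <- function(label, template, overrides = list()) {
  structure(list(label = label, template = template, overrides = overrides),
            class = "method_spec")
}

#' The study's standard three-method roster
#'
#' Selector-guided search (`FSS`), whole-matrix search without the selector
#' (`noFSS`), and a tuned gradient-boosting baseline realized as a
#' single-classifier template searched by the same engine (so all three share
#' the percentile selection rule).
#' @return list of three [method_spec()]s.
#' @export
standard_methods <- function() {
  list(method_spec("FSS", "FeatureSetSelector-Transformer-Classifier"),
       method_spec("noFSS", "Transformer-Classifier"),
       method_spec("XGB", "GradientBoostingClassifier"))
}

selected_subset_of <- function(pipeline) {
  node <- pipeline$nodes[[1]]
  if (identical(node$op, "FeatureSetSelector")) node$hp$subset else NA_character_
}

#' Run the replicate benchmark
#'
#' Per replicate: derive a seed from `(master seed, replicate index)`, split
#' the data 75/25 (stratified), run every method's search on the train part,
#' select each method's optimal pipeline by the percentile rule, refit it on
#' the full train part and score it on the untouched holdout part.  Method
#' seeds derive from the replicate seed and the method label, never from
#' method order, so rows are exchangeable under method reordering.
#'
#' @param dataset a [labeled_dataset()].
#' @param collection bound feature sets for selector methods.
#' @param methods list of [method_spec()]s (default [standard_methods()]).
#' @param n_replicates number of replicates (>= 1).
#' @param seed master seed.
#' @param registry operator registry.
#' @param base_config baseline [gp_config()]; per-method overrides apply on
#'   top of it.
#' @param train_fraction stratified split fraction.
#' @param verbose print one progress line per replicate/method.
#' @return a replicate table: one row per (replicate, method) with the
#'   selected subset (if any), CV accuracy of the chosen pipeline, holdout
#'   accuracy and the method seed.
#' @export
run_replicates <- function(dataset, collection = NULL, methods = standard_methods(),
                           n_replicates = 20L, seed = 1L,
                           registry = default_registry(),
                           base_config = gp_config(), train_fraction = 0.75,
                           verbose = FALSE) {
  if (n_replicates < 1) fss_abort("invalid_replicates", "n_replicates must be >= 1")
  labels <- vapply(methods, `[[`, character(1), "label")
  if (anyDuplicated(labels)) fss_abort("duplicate_method", "method labels must be unique")
  rows <- vector("list", n_replicates * length(methods))
  ri <- 0L
  for (r in seq_len(n_replicates)) {
    rep_seed <- derive_seed(seed, r)
    split <- stratified_split(dataset, train_fraction, rep_seed)
    for (m in methods) {
      m_seed <- derive_seed(rep_seed, m$label)
      cfg <- base_config
      for (nm in names(m$overrides)) cfg[[nm]] <- m$overrides[[nm]]
      cfg$seed <- m_seed
      res <- run_search(split$train, collection, m$template, registry, cfg)
      opt <- res$optimal
      fitted <- fit_pipeline(opt$pipeline, split$train, registry_with_sets(registry, collection),
                             collection, seed = derive_seed(m_seed, "refit"))
      hacc <- if (inherits(fitted, "pipeline_failure")) {
        NA_real_
      } else {
        accuracy(stats::predict(fitted, split$holdout), split$holdout$labels)
      }
      ri <- ri + 1L
      rows[[ri]] <- data.frame(replicate = r, method = m$label,
                               selected_subset = selected_subset_of(opt$pipeline),
                               cv_accuracy = opt$cv_accuracy,
                               holdout_accuracy = hacc, seed = m_seed)
      if (verbose) {
        message(sprintf("replicate %d method %s seed %d: subset=%s cv=%.3f holdout=%.3f",
                        r, m$label, m_seed, selected_subset_of(opt$pipeline),
                        opt$cv_accuracy, hacc))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  validate_replicate_table(out)
  out
}

#' Subset-selection frequency summary for a selector method
#'
#' Counts how often each subset was chosen across replicates and the mean
#' holdout accuracy of the pipelines that chose it.  Subsets with zero
#' inclusions are reported with count 0 when the subset universe is supplied.
#'
#' @param table a replicate table from [run_replicates()].
#' @param fss_method_label label of the selector method in the table.
#' @param subset_names optional character vector of all subset names.
#' @return data frame `(subset, n_selected, mean_holdout_accuracy)` sorted by
#'   descending count.
#' @export
subset_selection_summary <- function(table, fss_method_label, subset_names = NULL) {
  validate_replicate_table(table)
  sub <- table[table$method == fss_method_label, , drop = FALSE]
  if (nrow(sub) == 0) {
    fss_abort("unknown_method", paste0("no rows for method label '", fss_method_label, "'"))
  }
  chosen <- ifelse(is.na(sub$selected_subset), "none", sub$selected_subset)
  universe <- unique(c(subset_names %||% character(0), chosen))
  counts <- vapply(universe, function(s) sum(chosen == s), integer(1))
  means <- vapply(universe, function(s) {
    acc <- sub$holdout_accuracy[chosen == s]
    if (length(acc) == 0) NA_real_ else mean(acc, na.rm = TRUE)
  }, numeric(1))
  out <- data.frame(subset = universe, n_selected = counts,
                    mean_holdout_accuracy = means)
  out <- out[order(-out$n_selected, out$subset), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Welch two-sample one-sided t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a one-sided p-value in the stated direction (delegates to
#' [stats::t.test()]).
#'
#' @param a,b numeric samples, each with at least two finite values.
#' @param direction `"greater"` tests mean(a) > mean(b); `"less"` the reverse.
#' @return a `welch_result`: `t`, `df`, `p_value`, `direction`.
#' @export
welch_one_sided <- function(a, b, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (length(a) < 2 || length(b) < 2 || anyNA(a) || anyNA(b)) {
    fss_abort("undersized_sample", "each sample needs at least two finite values")
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    fss_abort("zero_variance", "both samples have zero variance")
  }
  ht <- stats::t.test(a, b, alternative = direction, var.equal = FALSE)
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value, direction = direction),
            class = "welch_result")
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("<welch_result> t = %.4f, df = %.2f, one-sided p (%s) = %.3g\n",
              x$t, x$df, x$direction, x$p_value))
  invisible(x)
}
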