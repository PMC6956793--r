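# Pipeline operator registry: the feature set selector, feature transformers
# and classifiers, each with a typed contract and a finite hyperparameter grid.
#
# Concrete learner internals delegate to established implementations (ranger
# for tree ensembles and single greedy trees, xgboost for gradient boosting);
# this module owns the uniform fit/transform/predict surface, the grids and
# the pipeline execution semantics.

operator_types <- c("FeatureSetSelector", "Selector", "Transformer", "Classifier", "Regressor")

#' Define an operator specification
#'
#' @param name unique operator name.
#' @param type one of the five major operator types: `FeatureSetSelector`,
#'   `Selector`, `Transformer`, `Classifier`, `Regressor`.
#' @param grid named list of finite ordered hyperparameter value sets (may be
#'   empty for parameter-free operators, but no individual grid may be empty).
#' @param fit for transformers: `function(x, hp, seed)`; for classifiers:
#'   `function(x, y, hp, seed)`.  Returns a fitted model object.
#' @param apply for transformers: `function(model, x)` returning a matrix; for
#'   classifiers: `function(model, x)` returning predicted labels.
#' @return an `operator_spec` object.
#' @export
operator_spec <- function(name, type, grid, fit, apply) {
  type <- match.arg(type, operator_types)
  if (any(lengths(grid) == 0)) {
    fss_abort("empty_grid", paste0("operator '", name, "' has an empty hyperparameter grid"))
  }
  structure(list(name = name, type = type, grid = grid, fit = fit, apply = apply),
            class = "operator_spec")
}

# --- internal learner wrappers -------------------------------------------
# Classifiers receive a numeric matrix; columns are renamed v1..vP so learner
# backends never choke on user feature names.  ranger is markedly faster on
# wide data when handed a data.frame, so conversion happens here once.

as_learn_df <- function(x) {
  df <- as.data.frame(x)
  names(df) <- paste0("v", seq_len(ncol(x)))
  df
}

fit_extra_trees <- function(x, y, hp, seed) {
  # mtry scales with sqrt(P), the classification-forest convention
  mtry <- min(ncol(x), max(1L, as.integer(round(hp$mtry_factor * sqrt(ncol(x))))))
  m <- ranger::ranger(x = as_learn_df(x), y = y,
                      num.trees = hp$n_estimators, mtry = mtry,
                      min.node.size = hp$min_samples_leaf,
                      splitrule = "extratrees", num.random.splits = 1,
                      num.threads = 1, seed = seed, verbose = FALSE)
  list(model = m, levels = levels(y))
}

predict_ranger <- function(model, x) {
  colnames(x) <- paste0("v", seq_len(ncol(x)))  # matrix input: fast predict path
  # fixed seed: vote ties must break identically on every call (pure predict)
  stats::predict(model$model, data = x, num.threads = 1, seed = 1L)$predictions
}

fit_decision_tree <- function(x, y, hp, seed) {
  # a single greedy tree: all features considered at every split, no bagging
  m <- ranger::ranger(x = as_learn_df(x), y = y, num.trees = 1,
                      mtry = ncol(x), max.depth = hp$max_depth,
                      min.node.size = hp$min_samples_split,
                      replace = FALSE, sample.fraction = 1,
                      num.threads = 1, seed = seed, verbose = FALSE)
  list(model = m, levels = levels(y))
}

fit_gradient_boosting <- function(x, y, hp, seed) {
  yl <- as.integer(y) - 1L
  dm <- xgboost::xgb.DMatrix(x, label = yl, nthread = 1)
  params <- list(objective = "binary:logistic", max_depth = hp$max_depth,
                 eta = hp$learning_rate, tree_method = "hist", max_bin = 32,
                 nthread = 1, seed = seed)
  m <- xgboost::xgb.train(params, dm, nrounds = hp$n_estimators, verbose = 0)
  list(model = m, levels = levels(y))
}

predict_gradient_boosting <- function(model, x) {
  p <- stats::predict(model$model, xgboost::xgb.DMatrix(x, nthread = 1))
  factor(model$levels[ifelse(p > 0.5, 2L, 1L)], levels = model$levels)
}

fit_one_hot <- function(x, hp, seed) {
  n_distinct <- vapply(seq_len(ncol(x)), function(j) length(unique(x[, j])), integer(1))
  cat_cols <- which(n_distinct <= hp$max_levels)
  levels_of <- lapply(cat_cols, function(j) sort(unique(x[, j])))
  list(cat_cols = cat_cols, levels_of = levels_of, p = ncol(x))
}

apply_one_hot <- function(model, x) {
  if (length(model$cat_cols) == 0) return(x)
  pieces <- vector("list", ncol(x))
  k <- 0L
  for (j in seq_len(ncol(x))) {
    idx <- match(j, model$cat_cols)
    if (is.na(idx)) {
      pieces[[j]] <- x[, j, drop = FALSE]
    } else {
      levs <- model$levels_of[[idx]]
      ind <- outer(x[, j], levs, FUN = "==") * 1
      colnames(ind) <- paste0(colnames(x)[j] %||% paste0("x", j), "=", levs)
      pieces[[j]] <- ind
    }
  }
  do.call(cbind, pieces)
}

# Exact principal components via the n x n Gram matrix (n << P here, so this
# is far cheaper than an SVD of the full matrix).
fit_pca <- function(x, hp, seed) {
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu, "-")
  gram <- tcrossprod(xc)
  eg <- eigen(gram, symmetric = TRUE)
  keep <- which(eg$values > max(eg$values, 0) * 1e-10)
  keep <- keep[seq_len(min(length(keep), hp$n_components))]
  if (length(keep) == 0) fss_abort("degenerate_pca", "input has no variance")
  # right singular vectors: V = X'U / sqrt(lambda)
  rot <- crossprod(xc, eg$vectors[, keep, drop = FALSE]) %*%
    diag(1 / sqrt(eg$values[keep]), nrow = length(keep))
  list(mu = mu, rotation = rot)
}

apply_pca <- function(model, x) {
  out <- sweep(x, 2, model$mu, "-") %*% model$rotation
  colnames(out) <- paste0("pc", seq_len(ncol(out)))
  out
}

fit_scaler <- function(x, hp, seed) {
  n <- nrow(x)
  mu <- colMeans(x)
  sdv <- if (n > 1) sqrt(pmax(colSums(x^2) - n * mu^2, 0) / (n - 1)) else rep(0, ncol(x))
  sdv[sdv == 0 | is.na(sdv)] <- 1
  list(mu = mu, sd = sdv)
}

apply_scaler <- function(model, x) {
  sweep(sweep(x, 2, model$mu, "-"), 2, model$sd, "/")
}

kernel_block <- function(x, landmarks, kernel, gamma) {
  switch(kernel,
    linear = tcrossprod(x, landmarks),
    rbf = {
      d2 <- outer(rowSums(x^2), rowSums(landmarks^2), "+") - 2 * tcrossprod(x, landmarks)
      exp(-gamma * pmax(d2, 0))
    },
    sigmoid = tanh(gamma * tcrossprod(x, landmarks) + 1),
    fss_abort("unknown_kernel", paste0("unknown kernel: ", kernel)))
}

# Landmark-based low-rank kernel feature map (Nystroem approximation):
# K ~ K_nm K_mm^{-1} K_mn, realized as phi(x) = k(x, L) U diag(ev^{-1/2}).
fit_nystroem <- function(x, hp, seed) {
  set.seed(seed)
  m <- min(hp$n_components, nrow(x))
  landmarks <- x[sample.int(nrow(x), m), , drop = FALSE]
  gamma <- hp$gamma_scale / ncol(x)
  kmm <- kernel_block(landmarks, landmarks, hp$kernel, gamma)
  eg <- eigen((kmm + t(kmm)) / 2, symmetric = TRUE)
  keep <- eg$values > max(eg$values, 0) * 1e-10
  if (!any(keep)) fss_abort("degenerate_kernel", "kernel matrix has no positive spectrum")
  map <- eg$vectors[, keep, drop = FALSE] %*% diag(1 / sqrt(eg$values[keep]),
                                                  nrow = sum(keep))
  list(landmarks = landmarks, kernel = hp$kernel, gamma = gamma, map = map)
}

apply_nystroem <- function(model, x) {
  out <- kernel_block(x, model$landmarks, model$kernel, model$gamma) %*% model$map
  colnames(out) <- paste0("phi", seq_len(ncol(out)))
  out
}

#' Default operator registry
#'
#' The registry holds one feature set selector, three transformers (one-hot
#' encoder for low-cardinality columns with continuous pass-through, a
#' landmark-based kernel-approximation feature map with rbf/linear/sigmoid
#' kernels, and a standard scaler) and three classifiers (extremely randomized
#' tree ensemble, single decision tree, gradient tree boosting).  Grids are
#' finite and deliberately desk-scale.
#'
#' The feature set selector's `subset` grid is populated from a bound
#' feature-set collection, either here via `feature_sets` or later by the
#' search engine.
#'
#' @param feature_sets optional [feature_set_collection()] whose set names
#'   become the selector's grid.
#' @return a named list of [operator_spec()]s, class `operator_registry`.
#' @export
default_registry <- function(feature_sets = NULL) {
  reg <- list(
    OneHotEncoder = operator_spec(
      "OneHotEncoder", "Transformer",
      grid = list(max_levels = 10L),
      fit = fit_one_hot, apply = apply_one_hot),
    KernelApproximator = operator_spec(
      "KernelApproximator", "Transformer",
      grid = list(kernel = c("rbf", "linear", "sigmoid"),
                  gamma_scale = 1,
                  n_components = 25L),
      fit = fit_nystroem, apply = apply_nystroem),
    StandardScaler = operator_spec(
      "StandardScaler", "Transformer",
      grid = list(),
      fit = fit_scaler, apply = apply_scaler),
    PCA = operator_spec(
      "PCA", "Transformer",
      grid = list(n_components = c(10L, 25L)),
      fit = fit_pca, apply = apply_pca),
    ExtraTreesClassifier = operator_spec(
      "ExtraTreesClassifier", "Classifier",
      grid = list(n_estimators = c(50L, 100L),
                  mtry_factor = 2,
                  min_samples_leaf = 1L),
      fit = fit_extra_trees, apply = predict_ranger),
    DecisionTreeClassifier = operator_spec(
      "DecisionTreeClassifier", "Classifier",
      grid = list(max_depth = c(3L, 6L), min_samples_split = 2L),
      fit = fit_decision_tree, apply = predict_ranger),
    GradientBoostingClassifier = operator_spec(
      "GradientBoostingClassifier", "Classifier",
      grid = list(n_estimators = c(10L, 20L),
                  max_depth = c(2L, 3L),
                  learning_rate = c(0.1, 0.3)),
      fit = fit_gradient_boosting, apply = predict_gradient_boosting)
  )
  reg <- structure(reg, class = "operator_registry")
  registry_with_sets(reg, feature_sets)
}

# Install (or rebind) the feature set selector whose subset grid is the bound
# collection's set names.  Without a collection the selector is absent, so a
# template demanding one is unsatisfiable -- the legality rules surface that.
registry_with_sets <- function(registry, collection) {
  if (is.null(collection)) return(registry)
  registry$FeatureSetSelector <- operator_spec(
    "FeatureSetSelector", "FeatureSetSelector",
    grid = list(subset = collection$set_names),
    fit = NULL, apply = NULL)
  registry
}

ops_of_type <- function(registry, type) {
  names(registry)[vapply(registry, function(o) o$type == type, logical(1))]
}

#' Slice a dataset to one named feature subset
#'
#' The feature set selector's core operation: restrict the dataset to the
#' subset's columns (in subset order), leaving sample order and labels
#' untouched.  Idempotent when re-applied with the same subset.
#'
#' @param dataset a [labeled_dataset()].
#' @param collection a bound [feature_set_collection()] (see
#'   [bind_feature_sets()]).
#' @param subset_name name of the subset to keep.
#' @return the sliced [labeled_dataset()].
#' @export
apply_fss <- function(dataset, collection, subset_name) {
  if (!subset_name %in% collection$set_names) {
    fss_abort("unknown_subset", paste0("unknown subset: ", subset_name))
  }
  feats <- collection$features[[subset_name]]
  missing <- setdiff(feats, dataset$feature_names)
  if (length(missing)) {
    fss_abort("unknown_feature", paste0("subset '", subset_name, "' references feature(s) ",
                                        "absent from the dataset: ",
                                        paste(utils::head(missing, 5), collapse = ", ")))
  }
  labeled_dataset(dataset$matrix[, feats, drop = FALSE], dataset$labels,
                  sample_ids = dataset$sample_ids, feature_names = feats)
}

#' Fit a pipeline on training data
#'
#' Nodes are fitted in order, each consuming the previous node's output.  A
#' feature set selector node, when present, must be first.  Learner failures
#' on degenerate input are captured and returned as a `pipeline_failure`
#' object rather than raised.
#'
#' @param pipeline a `pipeline_individual` (see [sample_pipeline()]).
#' @param train a [labeled_dataset()].
#' @param registry an [default_registry()]-style operator registry.
#' @param collection bound feature sets (required when the pipeline has a
#'   selector node).
#' @param seed integer seed for any stochastic node internals.
#' @return a `fitted_pipeline`, or a `pipeline_failure` carrying the error
#'   message.
#' @export
fit_pipeline <- function(pipeline, train, registry, collection = NULL, seed = 1L) {
  res <- tryCatch({
    x <- train$matrix
    y <- train$labels
    used <- train$feature_names
    fitted_nodes <- vector("list", length(pipeline$nodes))
    for (i in seq_along(pipeline$nodes)) {
      node <- pipeline$nodes[[i]]
      op <- registry[[node$op]]
      if (is.null(op)) fss_abort("unknown_operator", paste0("unknown operator: ", node$op))
      node_seed <- derive_seed(seed, i, node$op)
      if (op$type == "FeatureSetSelector") {
        if (i != 1L) fss_abort("invalid_pipeline", "feature set selector must be the first node")
        if (is.null(collection)) {
          fss_abort("unbound_sets", "pipeline has a selector node but no feature sets were supplied")
        }
        sliced <- apply_fss(labeled_dataset(x, y, train$sample_ids, colnames(x)),
                            collection, node$hp$subset)
        x <- sliced$matrix
        used <- sliced$feature_names
        fitted_nodes[[i]] <- list(kind = "fss", subset = node$hp$subset, features = used)
      } else if (op$type %in% c("Transformer", "Selector")) {
        m <- op$fit(x, node$hp, node_seed)
        x <- op$apply(m, x)
        fitted_nodes[[i]] <- list(kind = "transform", op = node$op, model = m)
      } else if (op$type == "Classifier") {
        if (nlevels(droplevels(y)) < 2) {
          fss_abort("degenerate_labels", "classifier requires two label levels in training data")
        }
        m <- op$fit(x, y, node$hp, node_seed)
        fitted_nodes[[i]] <- list(kind = "classify", op = node$op, model = m)
      } else {
        fss_abort("unsupported_type", paste0("no primitives registered for type ", op$type))
      }
    }
    structure(list(pipeline = pipeline, nodes = fitted_nodes, registry = registry,
                   input_features = train$feature_names, used_features = used,
                   levels = levels(train$labels), seed = seed),
              class = "fitted_pipeline")
  }, error = function(e) {
    structure(list(pipeline = pipeline, message = conditionMessage(e)),
              class = "pipeline_failure")
  })
  res
}

#' @export
print.fitted_pipeline <- function(x, ...) {
  cat("<fitted_pipeline> ", pipeline_signature(x$pipeline), "\n", sep = "")
  invisible(x)
}

#' Predict labels with a fitted pipeline
#'
#' A pure function of the fitted state and the input: repeated calls return
#' identical predictions.  The input must contain every feature the pipeline
#' requires (the selected subset for selector pipelines, all training features
#' otherwise); columns are matched by name, so column order is irrelevant.
#'
#' @param object a `fitted_pipeline`.
#' @param data a [labeled_dataset()] or numeric matrix with named columns.
#' @param ... unused.
#' @return factor of predicted labels, one per sample.
#' @export
predict.fitted_pipeline <- function(object, data, ...) {
  x <- if (inherits(data, "labeled_dataset")) data$matrix else data
  has_fss <- length(object$nodes) > 0 && identical(object$nodes[[1]]$kind, "fss")
  required <- if (has_fss) object$used_features else object$input_features
  missing <- setdiff(required, colnames(x))
  if (length(missing)) {
    fss_abort("missing_features", paste0(length(missing), " required feature(s) missing, e.g.: ",
                                         paste(utils::head(missing, 5), collapse = ", ")))
  }
  x <- x[, if (has_fss) object$used_features else object$input_features, drop = FALSE]
  for (node in object$nodes) {
    if (node$kind == "fss") next  # slicing already done via used_features
    op <- object$registry[[node$op]]
    if (node$kind == "transform") {
      x <- op$apply(node$model, x)
    } else {
      return(op$apply(node$model, x))
    }
  }
  fss_abort("invalid_pipeline", "pipeline has no classifier node")
}

#' Permutation feature importance of a fitted pipeline
#'
#' Importance of a feature is the baseline accuracy minus the mean accuracy
#' over `n_repeats` evaluations in which only that feature's column is
#' permuted.  Features never passed beyond the selector node are reported with
#' importance exactly 0 without evaluation (their column is never read).
#'
#' @param fitted a `fitted_pipeline`.
#' @param data a [labeled_dataset()] to evaluate on (typically holdout data).
#' @param n_repeats permutations per feature (>= 1).
#' @param seed integer seed for the permutations.
#' @return data frame `(feature, importance, n_repeats)` sorted descending by
#'   importance.
#' @export
permutation_importance <- function(fitted, data, n_repeats = 10L, seed = 1L) {
  if (n_repeats < 1) fss_abort("invalid_repeats", "n_repeats must be >= 1")
  set.seed(seed)
  truth <- data$labels
  baseline <- accuracy(stats::predict(fitted, data), truth)
  used <- fitted$used_features
  imp <- numeric(length(data$feature_names))
  names(imp) <- data$feature_names
  n <- nrow(data$matrix)
  for (f in data$feature_names) {
    if (!f %in% used) next  # never read by the pipeline: importance exactly 0
    drops <- numeric(n_repeats)
    for (r in seq_len(n_repeats)) {
      xp <- data$matrix
      xp[, f] <- xp[sample.int(n), f]
      drops[r] <- accuracy(stats::predict(fitted, xp), truth)
    }
    imp[f] <- baseline - mean(drops)
  }
  out <- data.frame(feature = names(imp), importance = unname(imp),
                    n_repeats = n_repeats)
  out[order(-out$importance, out$feature), , drop = FALSE]
}

#' Write an importance table to CSV (descending by importance)
#' @param table output of [permutation_importance()].
#' @param path output CSV path.
#' @param top_k optional number of top rows to keep (e.g. 20).
#' @export
write_importance <- function(table, path, top_k = NULL) {
  if (!is.null(top_k)) table <- utils::head(table, top_k)
  data.table::fwrite(table, path)
  invisible(path)
}
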