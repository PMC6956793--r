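test_that("the default registry covers the required operator types with finite grids", {
  sim <- small_sim()
  reg <- default_registry(sim$subsets)
  types <- vapply(reg, function(o) o$type, character(1))
  expect_setequal(unique(types), c("FeatureSetSelector", "Transformer", "Classifier"))
  for (op in reg) {
    expect_true(all(lengths(op$grid) >= 1), info = op$name)
    expect_true(all(vapply(op$grid, function(v) is.atomic(v) && all(is.finite(v) | is.character(v)),
                           logical(1))), info = op$name)
  }
  # without bound feature sets there is no selector to sample
  expect_false("FeatureSetSelector" %in% names(default_registry()))
})

test_that("feature set slicing keeps order, labels and idempotence", {
  ds <- make_noise_dataset(n = 8, p = 5)
  fs <- bind_feature_sets(feature_set_collection(c("A", "all"),
                                                 list(c("f2", "f4"), paste0("f", 1:5))), ds)
  sliced <- apply_fss(ds, fs, "A")
  expect_identical(sliced$feature_names, c("f2", "f4"))
  expect_identical(sliced$matrix, ds$matrix[, c("f2", "f4")])
  expect_identical(sliced$labels, ds$labels)
  # idempotent re-application and identity slice
  expect_identical(apply_fss(sliced, fs, "A")$matrix, sliced$matrix)
  expect_identical(apply_fss(ds, fs, "all")$matrix, ds$matrix)
  expect_error(apply_fss(ds, fs, "nope"), class = "fsspipe_error_unknown_subset")
})

test_that("the one-hot encoder expands low-cardinality columns and passes continuous through", {
  x <- cbind(cat = rep(c(0, 1, 2), 4), cont = rnorm(12))
  m <- fsspipe:::fit_one_hot(x, list(max_levels = 3L), seed = 1)
  out <- fsspipe:::apply_one_hot(m, x)
  expect_equal(ncol(out), 4L)  # 3 indicators + 1 pass-through
  expect_true(all(rowSums(out[, 1:3]) == 1))
  expect_identical(out[, 4], x[, "cont"])
  # all-continuous input is returned unchanged
  xc <- matrix(rnorm(40), 10, 4)
  mc <- fsspipe:::fit_one_hot(xc, list(max_levels = 3L), seed = 1)
  expect_identical(fsspipe:::apply_one_hot(mc, xc), xc)
})

test_that("the kernel feature map reproduces the exact kernel at full rank", {
  set.seed(8)
  x <- matrix(rnorm(60), 12, 5)
  # exact reconstruction holds for the positive semi-definite kernels
  for (kern in c("rbf", "linear")) {
    m <- fsspipe:::fit_nystroem(x, list(kernel = kern, gamma_scale = 1, n_components = 12L), seed = 2)
    phi <- fsspipe:::apply_nystroem(m, x)
    k_exact <- fsspipe:::kernel_block(x, x, kern, 1 / ncol(x))
    expect_equal(tcrossprod(phi), k_exact, tolerance = 1e-6, ignore_attr = TRUE)
  }
  # the sigmoid kernel is indefinite: its negative spectrum is clipped, so we
  # require only a finite map of the requested rank or less
  ms <- fsspipe:::fit_nystroem(x, list(kernel = "sigmoid", gamma_scale = 1, n_components = 12L), seed = 2)
  phis <- fsspipe:::apply_nystroem(ms, x)
  expect_true(all(is.finite(phis)))
  expect_lte(ncol(phis), 12L)
  expect_equal(nrow(phis), 12L)
})

test_that("pipelines fit, predict purely, and refuse missing features", {
  ds <- make_separable_dataset(n = 20)
  reg <- default_registry()
  pipe <- manual_pipeline(list("StandardScaler", list()),
                          list("DecisionTreeClassifier", list(max_depth = 6L, min_samples_split = 2L)))
  fitted <- fit_pipeline(pipe, ds, reg, seed = 5)
  expect_s3_class(fitted, "fitted_pipeline")
  expect_equal(accuracy(predict(fitted, ds), ds$labels), 1)  # separable: memorized
  expect_identical(predict(fitted, ds), predict(fitted, ds))  # purity
  # column order outside the required set is irrelevant; missing columns error
  shuffled <- ds$matrix[, rev(ds$feature_names)]
  expect_identical(predict(fitted, shuffled), predict(fitted, ds))
  expect_error(predict(fitted, ds$matrix[, 1:2]), class = "fsspipe_error_missing_features")
})

test_that("selector pipelines only read their subset and tolerate outside noise", {
  sim <- small_sim()
  bound <- bind_feature_sets(sim$subsets, sim$train)
  reg <- default_registry(bound)
  pipe <- manual_pipeline(list("FeatureSetSelector", list(subset = "S1")),
                          list("ExtraTreesClassifier",
                               list(n_estimators = 25L, mtry_factor = 1, min_samples_leaf = 1L)))
  fitted <- fit_pipeline(pipe, sim$train, reg, bound, seed = 9)
  expect_identical(fitted$used_features, bound$features$S1)
  # predictions only require the subset columns
  preds <- predict(fitted, sim$test$matrix[, bound$features$S1])
  expect_identical(preds, predict(fitted, sim$test))
  # perturbing a column outside the subset changes nothing
  perturbed <- sim$test$matrix
  outside <- setdiff(sim$test$feature_names, bound$features$S1)[1]
  perturbed[, outside] <- 99
  expect_identical(predict(fitted, perturbed), preds)
})

test_that("degenerate training inputs surface as failures, not crashes", {
  ds <- make_noise_dataset(n = 6, p = 2)
  one_class <- labeled_dataset(ds$matrix, rep("a", 6))
  pipe <- manual_pipeline(list("DecisionTreeClassifier", list(max_depth = 3L, min_samples_split = 2L)))
  res <- fit_pipeline(pipe, one_class, default_registry(), seed = 1)
  expect_s3_class(res, "pipeline_failure")
  expect_match(res$message, "label")
})

test_that("permutation importance is zero outside the selected subset and tracks signal", {
  sim <- small_sim()
  bound <- bind_feature_sets(sim$subsets, sim$train)
  reg <- default_registry(bound)
  pipe <- manual_pipeline(list("FeatureSetSelector", list(subset = "S2")),
                          list("DecisionTreeClassifier", list(max_depth = 6L, min_samples_split = 2L)))
  fitted <- fit_pipeline(pipe, sim$train, reg, bound, seed = 3)
  imp <- permutation_importance(fitted, sim$test, n_repeats = 2, seed = 4)
  outside <- setdiff(sim$test$feature_names, bound$features$S2)
  expect_true(all(imp$importance[match(outside, imp$feature)] == 0))
  expect_identical(nrow(imp), n_features(sim$test))

  # a single perfectly predictive feature on balanced labels: permuting it
  # drives accuracy to chance, so importance approaches baseline - 0.5
  sep <- make_separable_dataset(n = 40, p = 3)
  fs <- bind_feature_sets(feature_set_collection("A", list(c("f1", "f2"))), sep)
  p2 <- manual_pipeline(list("FeatureSetSelector", list(subset = "A")),
                        list("DecisionTreeClassifier", list(max_depth = 3L, min_samples_split = 2L)))
  f2 <- fit_pipeline(p2, sep, default_registry(fs), fs, seed = 6)
  imp2 <- permutation_importance(f2, sep, n_repeats = 20, seed = 7)
  expect_lt(abs(imp2$importance[imp2$feature == "f1"] - 0.5), 0.1)
  # top-k view for reporting
  expect_identical(nrow(utils::head(imp2, 2)), 2L)
})
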