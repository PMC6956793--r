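test_that("cross-validation evaluation records folds, means and caches fits", {
  sep <- make_separable_dataset(n = 30)
  reg <- default_registry()
  pipe <- manual_pipeline(list("DecisionTreeClassifier", list(max_depth = 6L, min_samples_split = 2L)))
  cache <- fsspipe:::new_eval_cache()
  rec <- evaluate_cv(pipe, sep, reg, k = 5, seed = 3, cache = cache)
  expect_length(rec$fold_accuracies, 5L)
  expect_equal(rec$cv_accuracy, mean(rec$fold_accuracies))
  expect_equal(rec$cv_accuracy, 1)  # trivially separable
  expect_equal(rec$complexity, 1L)
  expect_false(rec$cached)
  # second evaluation of the same signature must come from the cache
  n_fits <- fsspipe:::cache_fit_count(cache)
  rec2 <- evaluate_cv(pipe, sep, reg, k = 5, seed = 3, cache = cache)
  expect_true(rec2$cached)
  expect_identical(fsspipe:::cache_fit_count(cache), n_fits)

  # constant features on balanced labels: every fold predicts the majority tie
  # class, giving fold accuracy exactly 1/2 on balanced folds
  const <- labeled_dataset(matrix(1, 20, 2), rep(c("a", "b"), 10))
  rec3 <- evaluate_cv(pipe, const, reg, k = 5, seed = 3)
  expect_equal(rec3$cv_accuracy, 0.5)

  expect_error(evaluate_cv(pipe, sep, reg, k = 30, seed = 1),
               class = "fsspipe_error_invalid_folds")
})

test_that("stratified folds balance classes and respect the minority bound", {
  labels <- factor(rep(c("a", "b"), c(12, 8)))
  fold <- make_folds(labels, 4, seed = 9)
  expect_identical(sort(unique(fold)), 1:4)
  per_fold <- table(fold, labels)
  expect_true(all(per_fold[, "a"] == 3))
  expect_true(all(per_fold[, "b"] == 2))
  expect_error(make_folds(labels, 9, seed = 1), class = "fsspipe_error_invalid_folds")
})

test_that("mutation touches nodes uniformly and respects singleton degeneracy", {
  sim <- small_sim()
  reg <- default_registry(sim$subsets)
  tpl <- parse_template("FeatureSetSelector-Transformer-Classifier", reg)
  set.seed(12)
  base <- sample_pipeline(tpl, reg)
  altered <- integer(3)
  n <- 3000
  for (i in seq_len(n)) {
    m <- mutate_pipeline(base, tpl, reg)
    for (j in 1:3) {
      if (!identical(m$nodes[[j]], base$nodes[[j]])) altered[j] <- altered[j] + 1L
    }
  }
  # each node is picked ~ n/3 times; some picks resample the same value, so
  # observed alteration rates sit at or below 1/3 but well above 0
  expect_true(all(altered / n > 0.1))
  expect_true(all(altered / n < 1 / 3 + 0.03))

  # a registry with one operator and singleton grids leaves mutation identity
  reg1 <- singleton_registry()
  tpl1 <- parse_template("Classifier", reg1)
  p1 <- sample_pipeline(tpl1, reg1)
  expect_identical(mutate_pipeline(p1, tpl1, reg1), p1)
})

test_that("suffix crossover splices at the cut and preserves identical parents", {
  sim <- small_sim()
  reg <- default_registry(sim$subsets)
  tpl <- parse_template("FeatureSetSelector-Transformer-Classifier", reg)
  set.seed(13)
  p <- sample_pipeline(tpl, reg)
  q <- p
  q$nodes[[3]] <- list(op = "DecisionTreeClassifier",
                       hp = list(max_depth = 3L, min_samples_split = 2L))
  # parents differing only at node 3: any cut swaps exactly that node
  for (i in 1:20) {
    kids <- crossover_pipelines(p, q)
    expect_setequal(c(pipeline_signature(kids[[1]]), pipeline_signature(kids[[2]])),
                    c(pipeline_signature(p), pipeline_signature(q)))
  }
  kids_same <- crossover_pipelines(p, p)
  expect_identical(pipeline_signature(kids_same[[1]]), pipeline_signature(p))

  other <- sample_pipeline(parse_template("Transformer-Classifier", reg), reg)
  expect_error(crossover_pipelines(p, other), class = "fsspipe_error_template_mismatch")
})

make_record <- function(acc, cx, gen = 0L, sig = NULL) {
  structure(list(signature = sig %||% paste0("r", acc, "_", cx),
                 pipeline = NULL, fold_accuracies = acc, cv_accuracy = acc,
                 complexity = cx, generation = gen, failed = FALSE),
            class = "evaluation_record")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

brute_force_front <- function(obj) {
  n <- nrow(obj)
  dominated <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && obj[j, 1] >= obj[i, 1] && obj[j, 2] <= obj[i, 2] &&
          (obj[j, 1] > obj[i, 1] || obj[j, 2] < obj[i, 2])) {
        dominated[i] <- TRUE
        break
      }
    }
  }
  which(!dominated)
}

test_that("non-dominated sorting equals brute-force dominance on random instances", {
  # fixed worked example
  recs <- list(make_record(0.9, 3), make_record(0.8, 2), make_record(0.7, 1),
               make_record(0.85, 3))
  fronts <- nondominated_sort(recs)
  expect_setequal(fronts[[1]], 1:3)
  expect_identical(fronts[[2]], 4L)
  expect_identical(nondominated_sort(list(make_record(0.5, 1))), list(1L))
  same <- replicate(4, make_record(0.6, 2, sig = paste0("s", sample(1e6, 1))), simplify = FALSE)
  expect_length(nondominated_sort(same)[[1]], 4L)

  set.seed(77)
  for (trial in 1:40) {
    n <- sample(2:200, 1)
    recs <- lapply(seq_len(n), function(i) {
      make_record(round(runif(1), 2), sample(1:4, 1), sig = paste0("x", i))
    })
    obj <- cbind(vapply(recs, `[[`, numeric(1), "cv_accuracy"),
                 vapply(recs, `[[`, numeric(1), "complexity"))
    expect_setequal(nondominated_sort(recs)[[1]], brute_force_front(obj))
  }
})

test_that("NSGA-II survivors fill by front then crowding, keeping boundary points", {
  recs <- c(lapply(list(c(0.9, 3), c(0.8, 2), c(0.7, 1)),
                   function(v) make_record(v[1], v[2])),
            lapply(list(c(0.85, 3), c(0.75, 2), c(0.65, 1), c(0.6, 1)),
                   function(v) make_record(v[1], v[2])))
  surv <- nsga2_survivors(recs, 5)
  sigs <- vapply(surv, `[[`, character(1), "signature")
  # all of front 0 survives
  expect_true(all(vapply(recs[1:3], `[[`, character(1), "signature") %in% sigs))
  expect_length(surv, 5L)
  # boundary points of the second front have infinite crowding distance
  cd <- crowding_distance(recs[4:7])
  expect_identical(which(is.infinite(cd)), c(1L, 3L, 4L))

  expect_identical(length(nsga2_survivors(recs, 7)), 7L)
  expect_error(nsga2_survivors(recs, 8), class = "fsspipe_error_invalid_target")
})

test_that("the percentile rule selects by nearest accuracy with stated tie-breaks", {
  # hand-computed: 90th percentile of {0.5..0.9} under linear interpolation is
  # 0.86, so the 0.9 record is nearest
  recs <- lapply(seq(0.5, 0.9, by = 0.1), function(a) make_record(a, 2))
  expect_equal(select_optimal(recs, 90)$cv_accuracy, 0.9)
  # single record returns itself
  expect_identical(select_optimal(recs[3], 90)$cv_accuracy, 0.7)
  # equidistant records break ties toward lower complexity (0.5 and 1.0 are
  # both exactly 0.25 from their midpoint in binary floating point)
  tie <- list(make_record(0.5, 3, sig = "hi_cx"), make_record(1, 2, sig = "lo_cx"))
  expect_identical(select_optimal(tie, 50)$signature, "lo_cx")
  # failures are excluded, and all-failed errors
  failed <- make_record(0.99, 1, sig = "bad")
  failed$failed <- TRUE
  expect_identical(select_optimal(c(recs, list(failed)), 90)$cv_accuracy, 0.9)
  expect_error(select_optimal(list(failed), 90), class = "fsspipe_error_no_successful_records")
})

test_that("the search is reproducible, cached, and closed over its template", {
  sim <- small_sim()
  bound <- bind_feature_sets(sim$subsets, sim$train)
  cfg <- gp_config(population = 8, generations = 2, seed = 21)
  reg <- default_registry()
  res1 <- run_search(sim$train, bound, "FeatureSetSelector-Transformer-Classifier", reg, cfg)
  res2 <- run_search(sim$train, bound, "FeatureSetSelector-Transformer-Classifier", reg, cfg)
  expect_identical(serialize(res1, NULL), serialize(res2, NULL))
  # archive holds unique signatures only, and the fit counter agrees
  sigs <- vapply(res1$records, `[[`, character(1), "signature")
  expect_identical(anyDuplicated(sigs), 0L)
  expect_identical(res1$n_evaluations, length(res1$records))
  # the optimal pipeline is one of the records
  expect_true(res1$optimal$signature %in% sigs)
  # every evaluated pipeline validates against the template
  tpl <- parse_template("FeatureSetSelector-Transformer-Classifier", default_registry(bound))
  for (r in res1$records) {
    expect_length(validate_pipeline(r$pipeline, tpl, default_registry(bound)), 0L)
  }
  # fixed-length template: complexity is constant, so the front is a single point set
  cx <- vapply(res1$records, `[[`, numeric(1), "complexity")
  expect_true(all(cx == 3))
  ok <- Filter(function(r) !r$failed, res1$records)
  best <- max(vapply(ok, `[[`, numeric(1), "cv_accuracy"))
  front_accs <- vapply(ok[vapply(ok, `[[`, character(1), "signature") %in% res1$front],
                       `[[`, numeric(1), "cv_accuracy")
  expect_true(all(front_accs == best))
})

test_that("a registry admitting a single pipeline yields exactly one record", {
  sep <- make_separable_dataset(n = 24)
  reg <- singleton_registry()
  res <- run_search(sep, NULL, "Transformer-Classifier", reg,
                    gp_config(population = 4, generations = 2, seed = 5))
  expect_length(res$records, 1L)
  expect_identical(res$optimal$signature, res$records[[1]]$signature)
})
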