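# Evolutionary pipeline search: cross-validated fitness, template-legal
# mutation and crossover, NSGA-II survivor selection over (accuracy,
# complexity), and the 90th-percentile optimal-pipeline rule.

#' Search engine configuration
#'
#' @param population population size (>= 2); the offspring count per
#'   generation equals the population size (mu + lambda scheme).
#' @param generations number of generations after initialization.
#' @param mutation_rate,crossover_rate per-offspring probabilities of mutation
#'   and crossover, each in `[0, 1]` with sum at most 1 (the remainder
#'   reproduces a parent unchanged).  The 0.9/0.1 defaults are the
#'   conventional setting for this family of pipeline-search systems.
#' @param cv_folds number of stratified cross-validation folds k (>= 2).
#' @param percentile percentile of the cross-validation accuracy used by
#'   [select_optimal()].
#' @param seed integer seed; every random draw of a search derives from it.
#' @param max_evaluations optional cap on unique pipeline evaluations; the
#'   generational loop stops early once reached.
#' @return a `gp_config` object.
#' @export
gp_config <- function(population = 20L, generations = 5L,
                      mutation_rate = 0.9, crossover_rate = 0.1,
                      cv_folds = 5L, percentile = 90, seed = 1L,
                      max_evaluations = NULL) {
  if (population < 2) fss_abort("invalid_config", "population must be >= 2")
  if (generations < 0) fss_abort("invalid_config", "generations must be >= 0")
  for (r in c(mutation_rate, crossover_rate)) {
    if (r < 0 || r > 1) fss_abort("invalid_config", "rates must lie in [0, 1]")
  }
  if (mutation_rate + crossover_rate > 1 + 1e-12) {
    fss_abort("invalid_config", "mutation_rate + crossover_rate must not exceed 1")
  }
  if (cv_folds < 2) fss_abort("invalid_config", "cv_folds must be >= 2")
  if (percentile < 0 || percentile > 100) {
    fss_abort("invalid_config", "percentile must lie in [0, 100]")
  }
  structure(list(population = as.integer(population), generations = as.integer(generations),
                 mutation_rate = mutation_rate, crossover_rate = crossover_rate,
                 cv_folds = as.integer(cv_folds), percentile = percentile,
                 seed = as.integer(seed),
                 max_evaluations = if (is.null(max_evaluations)) NULL else as.integer(max_evaluations)),
            class = "gp_config")
}

#' Stratified cross-validation fold assignment
#'
#' Shuffles within each class and deals samples round-robin over k folds, so
#' folds are balanced to within one sample per class.
#'
#' @param labels factor of class labels.
#' @param k number of folds; must not exceed the minority-class count.
#' @param seed integer seed.
#' @return integer fold id (1..k) per sample.
#' @export
make_folds <- function(labels, k, seed) {
  labels <- as.factor(labels)
  counts <- tabulate(labels, nlevels(labels))
  if (k > min(counts)) {
    fss_abort("invalid_folds", sprintf("k = %d exceeds the minority class count (%d)",
                                       k, min(counts)))
  }
  set.seed(seed)
  fold <- integer(length(labels))
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

new_eval_cache <- function() {
  cache <- new.env(parent = emptyenv())
  assign(".fit_count", 0L, envir = cache)
  cache
}

cache_fit_count <- function(cache) get(".fit_count", envir = cache)

#' Evaluate a pipeline by stratified k-fold cross-validation
#'
#' Computes per-fold accuracies and their mean.  Results are cached by
#' pipeline signature: the same signature is never refitted within a run
#' (cache hits return the stored record with `cached = TRUE`).  A learner
#' failure is recorded as a failed evaluation, not raised.
#'
#' @param pipeline a `pipeline_individual`.
#' @param train training [labeled_dataset()].
#' @param registry operator registry.
#' @param collection bound feature sets (or NULL).
#' @param k number of folds.
#' @param seed integer seed: fixes the fold assignment and, combined with the
#'   pipeline signature, the per-fold fit seeds, so evaluation order cannot
#'   change results.
#' @param cache optional environment created by the engine; pass the same one
#'   to share evaluations.
#' @param generation generation tag stored in the record.
#' @return an `evaluation_record`: signature, pipeline, fold accuracies, mean
#'   CV accuracy, complexity, generation first seen and a failure flag.
#' @export
evaluate_cv <- function(pipeline, train, registry, collection = NULL,
                        k = 5L, seed = 1L, cache = NULL, generation = 0L) {
  sig <- pipeline_signature(pipeline)
  if (!is.null(cache) && exists(sig, envir = cache, inherits = FALSE)) {
    rec <- get(sig, envir = cache, inherits = FALSE)
    rec$cached <- TRUE
    return(rec)
  }
  if (nlevels(droplevels(train$labels)) < 2) {
    fss_abort("degenerate_labels", "cross-validation requires two label levels")
  }
  # Fold slices depend only on (labels, k, seed), so within a run they are
  # built once and shared across every evaluation through the cache.
  splits_key <- ".splits"
  splits <- if (!is.null(cache) && exists(splits_key, envir = cache, inherits = FALSE)) {
    get(splits_key, envir = cache, inherits = FALSE)
  } else {
    fold <- make_folds(train$labels, k, derive_seed(seed, "folds"))
    sp <- lapply(seq_len(k), function(f) {
      tr_idx <- which(fold != f)
      va_idx <- which(fold == f)
      list(train = labeled_dataset(train$matrix[tr_idx, , drop = FALSE],
                                   train$labels[tr_idx],
                                   sample_ids = train$sample_ids[tr_idx],
                                   feature_names = train$feature_names),
           val_x = train$matrix[va_idx, , drop = FALSE],
           val_y = train$labels[va_idx])
    })
    if (!is.null(cache)) assign(splits_key, sp, envir = cache)
    sp
  }
  accs <- rep(NA_real_, k)
  failed <- FALSE
  msg <- NULL
  for (f in seq_len(k)) {
    fitted <- fit_pipeline(pipeline, splits[[f]]$train, registry, collection,
                           seed = derive_seed(seed, string_hash(sig), f))
    if (inherits(fitted, "pipeline_failure")) {
      failed <- TRUE
      msg <- fitted$message
      break
    }
    pred <- stats::predict(fitted, splits[[f]]$val_x)
    accs[f] <- accuracy(pred, splits[[f]]$val_y)
  }
  rec <- structure(list(signature = sig, pipeline = pipeline,
                        fold_accuracies = accs,
                        cv_accuracy = if (failed) NA_real_ else mean(accs),
                        complexity = pipeline_complexity(pipeline),
                        generation = generation, failed = failed,
                        message = msg, cached = FALSE),
                   class = "evaluation_record")
  if (!is.null(cache)) {
    assign(sig, rec, envir = cache)
    assign(".fit_count", cache_fit_count(cache) + 1L, envir = cache)
  }
  rec
}

#' Mutate a pipeline under template legality
#'
#' One uniformly chosen node is altered: with probability 1/2 one of its
#' hyperparameters is resampled from its grid, otherwise its operator is
#' replaced by a different compatible one with fresh random hyperparameters.
#' When no alternative operator exists the mutation falls back to
#' hyperparameter resampling; the output always validates.
#'
#' @param pipeline a valid `pipeline_individual`.
#' @param template its template.
#' @param registry operator registry.
#' @return a mutated `pipeline_individual`.
#' @export
mutate_pipeline <- function(pipeline, template, registry) {
  i <- sample.int(length(pipeline$nodes), 1)
  node <- pipeline$nodes[[i]]
  slot_ops <- if (is_free_template(template)) {
    free_slot_ops(i, length(pipeline$nodes), registry)
  } else {
    compatible_operators(template$constraints[[i]], registry)
  }
  alternatives <- setdiff(slot_ops, node$op)
  alternatives <- alternatives[vapply(alternatives, function(o)
    all(lengths(registry[[o]]$grid) > 0), logical(1))]
  resample_hp <- stats::runif(1) < 0.5 || length(alternatives) == 0
  if (resample_hp) {
    grid <- registry[[node$op]]$grid
    if (length(grid) > 0) {
      h <- names(grid)[sample.int(length(grid), 1)]
      node$hp[[h]] <- grid[[h]][[sample.int(length(grid[[h]]), 1)]]
    } else if (length(alternatives) > 0) {
      op <- alternatives[[sample.int(length(alternatives), 1)]]
      node <- list(op = op, hp = sample_hp(registry[[op]]$grid))
    }
  } else {
    op <- alternatives[[sample.int(length(alternatives), 1)]]
    node <- list(op = op, hp = sample_hp(registry[[op]]$grid))
  }
  pipeline$nodes[[i]] <- node
  pipeline
}

#' One-point suffix crossover of two template-mates
#'
#' A cut position is chosen uniformly; the node suffixes from that position on
#' are exchanged.  Both parents must follow the same template, so both
#' children validate by construction.  Under a free (variable-length)
#' template each parent gets its own cut, so children may change length; cut
#' pairs whose children would exceed the length bound are redrawn.
#'
#' @param p1,p2 `pipeline_individual`s sharing a template (or both from the
#'   same free mode).
#' @param max_length length bound for free-mode children (taken from the
#'   template by [run_search()]).
#' @return list of two children.
#' @export
crossover_pipelines <- function(p1, p2, max_length = NULL) {
  if (!identical(p1$template_text, p2$template_text)) {
    fss_abort("template_mismatch", "crossover requires parents from the same template")
  }
  n1 <- length(p1$nodes)
  n2 <- length(p2$nodes)
  if (is.null(max_length)) {
    if (n1 != n2) {
      fss_abort("template_mismatch", "crossover requires parents from the same template")
    }
    cut <- sample.int(n1, 1)
    idx <- cut:n1
    c1 <- p1
    c2 <- p2
    c1$nodes[idx] <- p2$nodes[idx]
    c2$nodes[idx] <- p1$nodes[idx]
    return(list(c1, c2))
  }
  # free mode: independent cuts; suffixes always end in the classifier node
  for (try in 1:20) {
    cut1 <- sample.int(n1, 1)
    cut2 <- sample.int(n2, 1)
    len1 <- (cut1 - 1) + (n2 - cut2 + 1)
    len2 <- (cut2 - 1) + (n1 - cut1 + 1)
    if (len1 <= max_length && len2 <= max_length) {
      c1 <- p1
      c2 <- p2
      c1$nodes <- c(p1$nodes[seq_len(cut1 - 1)], p2$nodes[cut2:n2])
      c2$nodes <- c(p2$nodes[seq_len(cut2 - 1)], p1$nodes[cut1:n1])
      return(list(c1, c2))
    }
  }
  list(p1, p2)
}

record_objectives <- function(records) {
  cbind(acc = vapply(records, `[[`, numeric(1), "cv_accuracy"),
        cx = vapply(records, `[[`, numeric(1), "complexity"))
}

# a dominates b: accuracy >=, complexity <=, at least one strict
dominates <- function(oa, ob) {
  oa[1] >= ob[1] && oa[2] <= ob[2] && (oa[1] > ob[1] || oa[2] < ob[2])
}

#' Fast non-dominated sorting over (CV accuracy, complexity)
#'
#' Dominance maximizes accuracy and minimizes complexity.  Records with
#' missing objectives (failed evaluations) must be excluded by the caller.
#'
#' @param records list of `evaluation_record`s.
#' @return list of integer index vectors, one per front, front 1 first.
#' @export
nondominated_sort <- function(records) {
  n <- length(records)
  if (n == 0) return(list())
  obj <- record_objectives(records)
  dominated_by <- integer(n)       # how many dominate i
  dominates_set <- vector("list", n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (dominates(obj[i, ], obj[j, ])) {
        dominates_set[[i]] <- c(dominates_set[[i]], j)
      } else if (dominates(obj[j, ], obj[i, ])) {
        dominated_by[i] <- dominated_by[i] + 1L
      }
    }
  }
  fronts <- list()
  current <- which(dominated_by == 0L)
  while (length(current)) {
    fronts[[length(fronts) + 1L]] <- current
    nxt <- integer(0)
    for (i in current) {
      for (j in dominates_set[[i]]) {
        dominated_by[j] <- dominated_by[j] - 1L
        if (dominated_by[j] == 0L) nxt <- c(nxt, j)
      }
    }
    current <- sort(unique(nxt))
  }
  fronts
}

#' Crowding distance of records within one front
#' @param records list of `evaluation_record`s forming one front.
#' @return numeric distances (boundary points are `Inf`).
#' @export
crowding_distance <- function(records) {
  n <- length(records)
  if (n <= 2) return(rep(Inf, n))
  obj <- record_objectives(records)
  dist <- numeric(n)
  for (m in 1:2) {
    ord <- order(obj[, m])
    rng <- obj[ord[n], m] - obj[ord[1], m]
    dist[ord[c(1, n)]] <- Inf
    if (rng > 0) {
      for (i in 2:(n - 1)) {
        dist[ord[i]] <- dist[ord[i]] + (obj[ord[i + 1], m] - obj[ord[i - 1], m]) / rng
      }
    }
  }
  dist
}

#' NSGA-II survivor selection
#'
#' Fills the next population by ascending front rank; the last partially
#' admitted front is broken by descending crowding distance, with signature
#' order as the deterministic tie-break.
#'
#' @param records combined parent and offspring `evaluation_record`s (no
#'   failures).
#' @param target number of survivors (`<= length(records)`).
#' @return list of surviving records.
#' @export
nsga2_survivors <- function(records, target) {
  if (target > length(records)) {
    fss_abort("invalid_target", "target exceeds the number of candidate records")
  }
  fronts <- nondominated_sort(records)
  chosen <- integer(0)
  for (front in fronts) {
    if (length(chosen) + length(front) <= target) {
      chosen <- c(chosen, front)
    } else {
      need <- target - length(chosen)
      if (need > 0) {
        cd <- crowding_distance(records[front])
        sigs <- vapply(records[front], `[[`, character(1), "signature")
        keep <- front[order(-cd, sigs)][seq_len(need)]
        chosen <- c(chosen, keep)
      }
      break
    }
  }
  records[chosen]
}

#' Select the optimal pipeline by the percentile rule
#'
#' Computes the given percentile (linear interpolation between order
#' statistics) of the mean CV accuracy over all unique non-failed records and
#' returns the record whose accuracy is closest to it; ties are broken by
#' lower complexity, then earlier generation, then signature.  Preferring a
#' near-90th-percentile pipeline over the top scorer guards against selecting
#' an overfitted pipeline.
#'
#' @param records list of `evaluation_record`s.
#' @param percentile percentile in `[0, 100]`.
#' @return the selected `evaluation_record`.
#' @export
select_optimal <- function(records, percentile = 90) {
  ok <- Filter(function(r) !isTRUE(r$failed), records)
  if (length(ok) == 0) fss_abort("no_successful_records", "no successful evaluation records")
  accs <- vapply(ok, `[[`, numeric(1), "cv_accuracy")
  q <- stats::quantile(accs, percentile / 100, type = 7, names = FALSE)
  d <- abs(accs - q)
  cx <- vapply(ok, `[[`, numeric(1), "complexity")
  gen <- vapply(ok, `[[`, numeric(1), "generation")
  sigs <- vapply(ok, `[[`, character(1), "signature")
  ok[[order(d, cx, gen, sigs)[1]]]
}

#' Run the evolutionary pipeline search
#'
#' mu + lambda generational loop: initialize a template-legal population,
#' evaluate by stratified k-fold CV, vary by the configured mutation and
#' crossover rates, and select survivors by NSGA-II over (accuracy,
#' complexity).  All unique evaluations are retained; the optimal pipeline is
#' chosen by the percentile rule over that full archive.  Reproducible given
#' `config$seed`.
#'
#' @param train training [labeled_dataset()].
#' @param collection bound feature sets (required if the template contains a
#'   selector).
#' @param template a `pipeline_template` or template string.
#' @param registry operator registry.
#' @param config a [gp_config()].
#' @return an `optimization_result`: `records` (all unique evaluation
#'   records), `front` (signatures of the final non-dominated set), `optimal`
#'   (the selected record), `config` and `seed`.
#' @export
run_search <- function(train, collection = NULL, template, registry = default_registry(),
                       config = gp_config()) {
  registry <- registry_with_sets(registry, collection)
  if (is.character(template)) template <- parse_template(template, registry)
  set.seed(config$seed)
  eval_seed <- derive_seed(config$seed, "cv")
  cache <- new_eval_cache()
  archive <- new.env(parent = emptyenv())
  archive_order <- character(0)

  note <- function(rec) {
    if (!exists(rec$signature, envir = archive, inherits = FALSE)) {
      assign(rec$signature, rec, envir = archive)
      archive_order <<- c(archive_order, rec$signature)
    }
  }
  eval_all <- function(pipes, gen) {
    lapply(pipes, function(p) {
      rec <- evaluate_cv(p, train, registry, collection, k = config$cv_folds,
                         seed = eval_seed, cache = cache, generation = gen)
      note(rec)
      rec
    })
  }

  population <- replicate(config$population, sample_pipeline(template, registry),
                          simplify = FALSE)
  pop_records <- eval_all(population, 0L)

  # Binary crowded tournament over the current population's records, as
  # NSGA-II prescribes for mating selection: lower front rank wins, ties go to
  # the larger crowding distance.
  tournament_order <- function(recs) {
    fronts <- nondominated_sort(recs)
    rank <- integer(length(recs))
    crowd <- numeric(length(recs))
    for (fi in seq_along(fronts)) {
      rank[fronts[[fi]]] <- fi
      crowd[fronts[[fi]]] <- crowding_distance(recs[fronts[[fi]]])
    }
    list(rank = rank, crowd = crowd)
  }
  pick_parent <- function(ord) {
    cand <- sample.int(length(ord$rank), 2, replace = TRUE)
    a <- cand[1]
    b <- cand[2]
    if (ord$rank[a] < ord$rank[b]) return(a)
    if (ord$rank[b] < ord$rank[a]) return(b)
    if (ord$crowd[a] >= ord$crowd[b]) a else b
  }

  for (gen in seq_len(config$generations)) {
    if (!is.null(config$max_evaluations) &&
        cache_fit_count(cache) >= config$max_evaluations) break
    ok_pop <- !vapply(pop_records, `[[`, logical(1), "failed")
    sel_records <- if (any(ok_pop)) pop_records[ok_pop] else pop_records
    sel_population <- population[ok_pop | !any(ok_pop)]
    ord <- tournament_order(sel_records)
    offspring <- vector("list", config$population)
    for (j in seq_len(config$population)) {
      parents <- list(sel_population[[pick_parent(ord)]],
                      sel_population[[pick_parent(ord)]])
      r <- stats::runif(1)
      child <- if (r < config$crossover_rate) {
        crossover_pipelines(parents[[1]], parents[[2]],
                            max_length = if (is_free_template(template)) template$max_length)[[1]]
      } else if (r < config$crossover_rate + config$mutation_rate) {
        mutate_pipeline(parents[[1]], template, registry)
      } else {
        parents[[1]]
      }
      offspring[[j]] <- child
    }
    off_records <- eval_all(offspring, gen)
    combined <- c(pop_records, off_records)
    ok <- Filter(function(r) !isTRUE(r$failed), combined)
    if (length(ok) >= config$population) {
      survivors <- nsga2_survivors(ok, config$population)
    } else {
      survivors <- c(ok, combined[vapply(combined, `[[`, logical(1), "failed")])[seq_len(config$population)]
    }
    pop_records <- survivors
    population <- lapply(survivors, `[[`, "pipeline")
  }

  records <- lapply(archive_order, function(s) get(s, envir = archive, inherits = FALSE))
  ok <- Filter(function(r) !isTRUE(r$failed), records)
  front_sigs <- if (length(ok)) {
    vapply(ok[nondominated_sort(ok)[[1]]], `[[`, character(1), "signature")
  } else {
    character(0)
  }
  # The percentile rule is applied to the records the evolutionary process
  # itself certifies -- the final population (unique signatures) -- not to the
  # full evaluation archive, whose accuracy distribution is dominated by
  # early random pipelines at desk-scale generation counts.
  final_sigs <- unique(vapply(pop_records, `[[`, character(1), "signature"))
  final_records <- Filter(function(r) !isTRUE(r$failed),
                          lapply(final_sigs, function(s) get(s, envir = archive, inherits = FALSE)))
  if (length(final_records) == 0) final_records <- records
  structure(list(records = records, front = front_sigs,
                 optimal = select_optimal(final_records, config$percentile),
                 n_evaluations = cache_fit_count(cache),
                 config = config, seed = config$seed),
            class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  cat("<optimization_result> ", length(x$records), " unique pipelines evaluated; optimal: ",
      x$optimal$signature, " (cv accuracy ", round(x$optimal$cv_accuracy, 4), ")\n", sep = "")
  invisible(x)
}

#' Tidy table of evaluation records
#' @param result an `optimization_result`.
#' @return data frame with signature, per-fold accuracies, mean CV accuracy,
#'   complexity, generation and failure flag.
#' @export
records_table <- function(result) {
  recs <- result$records
  k <- max(vapply(recs, function(r) length(r$fold_accuracies), integer(1)))
  folds <- t(vapply(recs, function(r) {
    out <- rep(NA_real_, k)
    out[seq_along(r$fold_accuracies)] <- r$fold_accuracies
    out
  }, numeric(k)))
  colnames(folds) <- paste0("fold", seq_len(k))
  data.frame(signature = vapply(recs, `[[`, character(1), "signature"),
             folds,
             cv_accuracy = vapply(recs, `[[`, numeric(1), "cv_accuracy"),
             complexity = vapply(recs, `[[`, integer(1), "complexity"),
             generation = vapply(recs, function(r) as.integer(r$generation), integer(1)),
             failed = vapply(recs, `[[`, logical(1), "failed"))
}
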