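# Programmatic fixtures shared across test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small two-class dataset with a hard linear separation on feature f1.
make_separable_dataset <- function(n = 20, p = 4, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  labels <- rep(c("a", "b"), length.out = n)
  x[, 1] <- ifelse(labels == "a", 5, -5) + rnorm(n, sd = 0.1)
  labeled_dataset(x, labels, feature_names = paste0("f", seq_len(p)))
}

# Pure-noise dataset (no class signal anywhere).
make_noise_dataset <- function(n = 24, p = 6, seed = 2) {
  set.seed(seed)
  labeled_dataset(matrix(rnorm(n * p), n, p), rep(c("a", "b"), length.out = n),
                  feature_names = paste0("f", seq_len(p)))
}

# Tiny simulated interaction dataset with module structure, shared across
# files through a memoised store to keep the suite fast.
.fixture_store <- new.env(parent = emptyenv())

small_sim <- function(rho = 0.8, seed = 7) {
  key <- paste0("sim_", rho, "_", seed)
  if (!exists(key, envir = .fixture_store)) {
    cfg <- simulation_config(n_samples = 60, n_features = 300, functional_fraction = 0.04,
                             n_background = 288, gamma_shape = 2, gamma_scale = 40,
                             rho = rho, seed = seed)
    assign(key, simulate_interaction_dataset(cfg), envir = .fixture_store)
  }
  get(key, envir = .fixture_store)
}

# Registry stripped to a single deterministic pipeline per template slot.
singleton_registry <- function() {
  reg <- default_registry()
  reg$KernelApproximator <- NULL
  reg$OneHotEncoder <- NULL
  reg$PCA <- NULL
  reg$ExtraTreesClassifier <- NULL
  reg$GradientBoostingClassifier <- NULL
  reg$DecisionTreeClassifier$grid <- list(max_depth = 6L, min_samples_split = 2L)
  reg
}

# A concrete pipeline built by hand from (operator, hyperparameters) pairs.
manual_pipeline <- function(..., template_text = "manual") {
  nodes <- lapply(list(...), function(spec) list(op = spec[[1]], hp = spec[[2]]))
  structure(list(nodes = nodes, template_text = template_text),
            class = "pipeline_individual")
}
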