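# fsspipe

Feature-set-guided evolutionary search for machine-learning pipelines on
high-dimensional omics data.

## The problem

Classifying subjects from expression data (hundreds of samples, thousands of
transcripts) defeats naive automated machine-learning search: candidate
evaluations are expensive and flexible learners overfit the thousands of
uninformative features. When the features are already organized into groups —
gene co-expression modules, pathways — a search whose first step commits to
*one group* can be both faster and better. `fsspipe` is for computational
biologists and methodologists who want that mechanism as a reproducible,
desk-scale R package.

## The method

`fsspipe` searches linear pipelines

```
FeatureSetSelector  →  Transformer  →  Classifier
```

by strongly typed genetic programming. A **Template** constrains the shape of
every candidate (each slot is a major operator type or a specific operator);
the **Feature Set Selector (FSS)** slices the data to one named feature
group; candidates are scored by mean stratified k-fold cross-validation
accuracy (k = 5); **NSGA-II** (non-dominated sorting + crowding distance,
binary crowded tournament mating) trades accuracy against pipeline
complexity (operator count); and the final pipeline is the one whose CV
accuracy is nearest the **90th percentile** of the final population's
accuracies — an anti-overfitting rule analogous to the one-standard-error
rule in regularized regression.

The package also ships:

* a **simulator** of module-structured differential co-expression: subset
  sizes are gamma-distributed; each of the 200 functional features (4% of
  P = 5000) joins subset *i* with golden-ratio probability ∝ 1.618^(−i);
  within each subset the functional features share a latent factor of
  strength ρ among controls, and case values are permuted per feature, so
  the class signal is pure differential co-expression with no main effects;
* a **replicate benchmark** comparing the FSS search against a whole-matrix
  search (no selector) and a tuned gradient-boosting baseline, with 75/25
  stratified splits and Welch one-sided t-tests on holdout accuracies.

## Worked example

```r
library(fsspipe)

# Module-structured simulated cohort: 200 samples x 5000 features,
# 200 functional features spread over ~20 subsets, S1 richest.
sim <- simulate_interaction_dataset(simulation_config(seed = 42))
sim
#> <simulated_data> train 200x5000; 200 functional features over 19 subsets (rho = 0.22)
head(sim$functional_counts, 5)
#> S1 S2 S3 S4 S5
#> 78 48 31 22  5

bound <- bind_feature_sets(sim$subsets, sim$train)
res <- run_search(sim$train, bound,
                  template = "FeatureSetSelector-Transformer-Classifier",
                  config = gp_config(population = 20, generations = 5, seed = 7))
res
#> <optimization_result> 81 unique pipelines evaluated; optimal:
#>   FeatureSetSelector(subset=S2)|PCA(n_components=10)|DecisionTreeClassifier(max_depth=3,min_samples_split=2)
#>   (cv accuracy 0.705)

fitted <- fit_pipeline(res$optimal$pipeline, sim$train,
                       default_registry(bound), bound, seed = 1)
mean(predict(fitted, sim$test) == sim$test$labels)
#> [1] 0.62
```

From the module labels alone the search selected S2 — one of the
signal-bearing subsets (48 of its features are functional) — and the
pipeline generalizes to the independent test set at 0.62, well above the
~0.5 a whole-matrix learner achieves on the same data (the simulated signal
is invisible without slicing: no feature has a main effect, and the
per-module latent factors are buried in the full 5000-feature spectrum).
Individual short searches are noisy; across the 20-replicate benchmark the
signal-richest subset S1 is the modal selection and carries the best mean
holdout accuracy.

A command-line wrapper with `simulate`, `optimize`, `benchmark` and
`importance` subcommands is installed at `inst/cli/fsspipe`:

```sh
Rscript inst/cli/fsspipe simulate --seed 7 --out data/
Rscript inst/cli/fsspipe optimize --train data/train.csv --subsets data/subsets.csv \
    --template FeatureSetSelector-Transformer-Classifier --seed 7 --out run/
```

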