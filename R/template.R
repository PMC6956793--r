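# Templates: linear pipeline structure constraints realized as strongly typed
# GP legality rules.  Every candidate pipeline must satisfy its template
# node-for-node, and the genetic operators are closed over that legality.

#' Parse a template string
#'
#' A template is a hyphen-separated sequence of tokens, each either one of the
#' five major operator types (`FeatureSetSelector`, `Selector`, `Transformer`,
#' `Classifier`, `Regressor`) or the exact (case-sensitive) name of a
#' registered operator.  A selector token may appear only in first position;
#' the final token must resolve to a classifier.
#'
#' @param text template string, e.g. `"FeatureSetSelector-Transformer-Classifier"`.
#' @param registry operator registry used to resolve specific-operator tokens.
#' @return a `pipeline_template` object.
#' @export
parse_template <- function(text, registry = default_registry()) {
  if (!is.character(text) || length(text) != 1 || !nzchar(text)) {
    fss_abort("invalid_template", "template must be a nonempty string")
  }
  tokens <- strsplit(text, "-", fixed = TRUE)[[1]]
  constraints <- lapply(tokens, function(tok) {
    if (tok %in% operator_types) {
      list(token = tok, kind = "type", type = tok)
    } else if (tok %in% names(registry)) {
      list(token = tok, kind = "op", type = registry[[tok]]$type)
    } else {
      fss_abort("unknown_token", paste0("unknown template token: '", tok, "'"))
    }
  })
  types <- vapply(constraints, `[[`, character(1), "type")
  if (any(types[-1] == "FeatureSetSelector")) {
    fss_abort("invalid_template", "a feature set selector may appear only at position 1")
  }
  if (types[length(types)] != "Classifier") {
    fss_abort("invalid_template", "the final template token must resolve to a classifier")
  }
  structure(list(text = text, constraints = constraints), class = "pipeline_template")
}

#' @export
print.pipeline_template <- function(x, ...) {
  cat("<pipeline_template> ", x$text, "\n", sep = "")
  invisible(x)
}

#' Template-free variable-length search mode
#'
#' Instead of a fixed node sequence, candidates are linear chains of one up
#' to `max_length` nodes: zero or more transformers followed by a classifier.
#' Under this mode pipeline complexity genuinely varies, so the NSGA-II
#' complexity objective is non-trivial.  The feature set selector is not
#' available here — it enters pipelines through an explicit template.
#'
#' @param max_length maximum chain length (>= 1), 3 by default.
#' @return a `pipeline_template` in free mode.
#' @export
free_template <- function(max_length = 3L) {
  if (max_length < 1) fss_abort("invalid_template", "max_length must be >= 1")
  structure(list(text = paste0("<free, max length ", max_length, ">"),
                 constraints = NULL, max_length = as.integer(max_length)),
            class = "pipeline_template")
}

is_free_template <- function(template) is.null(template$constraints)

template_length <- function(template) length(template$constraints)

# Compatible operator names for position i of a length-L free-mode chain.
free_slot_ops <- function(i, L, registry) {
  if (i == L) ops_of_type(registry, "Classifier") else ops_of_type(registry, "Transformer")
}

# Registered operator names compatible with one template constraint.
compatible_operators <- function(constraint, registry) {
  if (constraint$kind == "op") constraint$token else ops_of_type(registry, constraint$type)
}

sample_hp <- function(grid) {
  lapply(grid, function(v) v[[sample.int(length(v), 1)]])
}

#' Sample a random pipeline satisfying a template
#'
#' For each template node, a compatible operator is chosen uniformly, then
#' each of its hyperparameters uniformly from its grid.  Uses the current RNG
#' state.
#'
#' @param template a [parse_template()] result.
#' @param registry operator registry.
#' @return a `pipeline_individual`: ordered nodes of
#'   `(operator name, hyperparameter assignment)`; its complexity is the node
#'   count.
#' @export
sample_pipeline <- function(template, registry) {
  if (is_free_template(template)) {
    L <- sample.int(template$max_length, 1)
    nodes <- lapply(seq_len(L), function(i) {
      ops <- free_slot_ops(i, L, registry)
      if (length(ops) == 0) {
        fss_abort("unsatisfiable", "free mode needs at least one transformer and one classifier")
      }
      op <- ops[[sample.int(length(ops), 1)]]
      list(op = op, hp = sample_hp(registry[[op]]$grid))
    })
    return(new_pipeline(nodes, template))
  }
  nodes <- lapply(template$constraints, function(con) {
    ops <- compatible_operators(con, registry)
    ops <- ops[vapply(ops, function(o) all(lengths(registry[[o]]$grid) > 0), logical(1))]
    if (length(ops) == 0) {
      fss_abort("unsatisfiable", paste0("no registered operator satisfies template token '",
                                        con$token, "'"))
    }
    op <- ops[[sample.int(length(ops), 1)]]
    list(op = op, hp = sample_hp(registry[[op]]$grid))
  })
  new_pipeline(nodes, template)
}

new_pipeline <- function(nodes, template) {
  structure(list(nodes = nodes, template_text = template$text),
            class = "pipeline_individual")
}

#' Pipeline complexity: the total number of operators
#' @param pipeline a `pipeline_individual`.
#' @return integer node count.
#' @export
pipeline_complexity <- function(pipeline) length(pipeline$nodes)

#' Canonical signature string of a pipeline
#'
#' Uniquely identifies an (operator, hyperparameter) chain; used as the
#' evaluation cache key.
#' @param pipeline a `pipeline_individual`.
#' @return character scalar like `"Op1(a=1)|Op2(b=x,c=2)"`.
#' @export
pipeline_signature <- function(pipeline) {
  paste(vapply(pipeline$nodes, function(node) {
    if (length(node$hp) == 0) return(node$op)
    paste0(node$op, "(", paste(names(node$hp), unlist(lapply(node$hp, format)),
                               sep = "=", collapse = ","), ")")
  }, character(1)), collapse = "|")
}

#' @export
print.pipeline_individual <- function(x, ...) {
  cat("<pipeline_individual> ", pipeline_signature(x), "\n", sep = "")
  invisible(x)
}

#' Validate a pipeline against a template and registry
#'
#' Never throws: returns a character vector of violations, empty when the
#' pipeline is valid.  Checks length, per-node operator compatibility and
#' hyperparameter grid membership.
#'
#' @param pipeline a `pipeline_individual`.
#' @param template a `pipeline_template`.
#' @param registry operator registry.
#' @return character vector of violation messages (length 0 = valid).
#' @export
validate_pipeline <- function(pipeline, template, registry) {
  violations <- character(0)
  n <- length(pipeline$nodes)
  if (is_free_template(template)) {
    if (n < 1 || n > template$max_length) {
      return(sprintf("pipeline has %d node(s); free mode allows 1..%d",
                     n, template$max_length))
    }
  } else {
    if (n != template_length(template)) {
      return(sprintf("pipeline has %d node(s) but template requires %d",
                     n, template_length(template)))
    }
  }
  for (i in seq_len(n)) {
    node <- pipeline$nodes[[i]]
    if (is_free_template(template)) {
      ok_ops <- free_slot_ops(i, n, registry)
      token <- if (i == n) "Classifier" else "Transformer"
    } else {
      con <- template$constraints[[i]]
      ok_ops <- compatible_operators(con, registry)
      token <- con$token
    }
    if (!node$op %in% ok_ops) {
      violations <- c(violations, sprintf("node %d: operator '%s' violates constraint '%s'",
                                          i, node$op, token))
      next
    }
    grid <- registry[[node$op]]$grid
    if (!setequal(names(node$hp), names(grid))) {
      violations <- c(violations, sprintf("node %d: hyperparameter set differs from the grid of '%s'",
                                          i, node$op))
      next
    }
    for (h in names(grid)) {
      if (!node$hp[[h]] %in% grid[[h]]) {
        violations <- c(violations, sprintf("node %d: value '%s' of parameter '%s' is off-grid",
                                            i, format(node$hp[[h]]), h))
      }
    }
  }
  violations
}
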