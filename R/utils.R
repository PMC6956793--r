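# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signal a classed error
#'
#' All user-facing errors in the package carry a condition class of the form
#' `fsspipe_error_<name>` plus the umbrella class `fsspipe_error`, so callers
#' can catch specific failure modes.
#' @noRd
fss_abort <- function(class, msg, call. = FALSE) {
  stop(errorCondition(msg, class = c(paste0("fsspipe_error_", class), "fsspipe_error", "fssError")))
}

#' Derive a reproducible child seed
#'
#' Deterministically maps a parent seed plus any number of labels (integers or
#' strings) onto a positive 32-bit integer seed.  Used so every source of
#' randomness in a run flows from one master seed while remaining independent
#' of evaluation order: a component's seed depends only on its labels, never on
#' how many random draws happened before it.
#'
#' @param seed integer parent seed.
#' @param ... labels (character or numeric) identifying the child stream.
#' @return a single integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, "folds")
#' derive_seed(42, 3, "refit")
derive_seed <- function(seed, ...) {
  parts <- unlist(lapply(list(...), function(p) {
    if (is.character(p)) {
      vapply(p, function(s) sum(utf8ToInt(s) * seq_len(nchar(s))), numeric(1))
    } else {
      as.numeric(p)
    }
  }), use.names = FALSE)
  m <- 2147483647  # 2^31 - 1, Mersenne prime modulus
  x <- as.numeric(seed) %% m
  for (p in c(parts, 0)) {
    # affine mix; all intermediates stay below 2^53 so doubles are exact
    x <- (x * 69069 + (p %% m) * 40692 + 1013904223) %% m
  }
  as.integer(x %% (m - 2)) + 1L
}

# Short deterministic integer hash of a string (for per-signature fit seeds).
string_hash <- function(s) {
  sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 97 + 1)) %% 2147483647
}

#' Classification accuracy of predicted vs true labels
#' @param pred,truth label vectors of equal length (factor or character).
#' @return fraction of agreeing positions.
#' @export
accuracy <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  mean(as.character(pred) == as.character(truth))
}
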