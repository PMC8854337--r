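# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code under a temporary RNG seed
#'
#' Thin wrapper over [withr::with_seed()] used so that every stochastic
#' operation in the package is reproducible from an explicit integer seed and
#' leaves the caller's RNG state untouched. `seed = NULL` runs the code with
#' the current RNG state.
#' @param seed integer seed or `NULL`.
#' @param code code to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

# Derive n reproducible sub-seeds from one master seed. Used so that cohorts,
# trials and GA runs each consume an independent, named random stream.
derive_seeds <- function(seed, n) {
  with_seed_(seed, sample.int(.Machine$integer.max - 1L, n))
}

stop_input <- function(...) stop(..., call. = FALSE)

assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_input(sprintf("`%s` must be a single positive finite number", name))
  }
  invisible(x)
}

# Matrix coercion for model inputs: keeps column names, rejects non-finite
# values early with a pointed error.
as_feature_matrix <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop_input("features contain non-finite values")
  x
}

as_binary_labels <- function(y) {
  y <- as.integer(as.character(y))
  if (any(is.na(y)) || !all(y %in% c(0L, 1L))) {
    stop_input("labels must be binary 0/1")
  }
  y
}
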