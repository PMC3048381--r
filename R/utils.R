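#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed locally, evaluates `expr`, and restores the caller's RNG
#' state, so seeded operations do not perturb the global random stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("gssa_config_error", "gssa_error")))
}

stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("gssa_format_error", "gssa_error")))
}

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("gssa_validation_error", "gssa_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
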