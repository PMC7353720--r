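#' Evaluate an expression under a fixed RNG seed, restoring the caller's state
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

stop_config <- function(...) stop(errorCondition(paste0(...), class = c("admixepi_config_error", "error")))
stop_data <- function(...) stop(errorCondition(paste0(...), class = c("admixepi_data_error", "error")))
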