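#' @keywords internal
"_PACKAGE"

#' @import methods
NULL

## Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
## All stochastic generators in the package flow through this one gate so that
## every simulation is a pure function of (config, seed).
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

stop_poebias <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "poebias_error")))
}

## percent sanity check used across modules
check_percent <- function(x, what, lo = 0, hi = 100) {
  bad <- !is.na(x) & (x < lo | x > hi)
  if (any(bad)) {
    stop_poebias(what, " outside [", lo, ", ", hi, "]: ",
                 paste(utils::head(x[bad], 3L), collapse = ", "),
                 class = "poebias_domain_error")
  }
  invisible(x)
}
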