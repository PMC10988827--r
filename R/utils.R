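#' @importFrom rlang abort warn %||%
#' @importFrom dplyr %>%
NULL

# Classed conditions so callers can distinguish bad input from bad structure
# from bad configuration.
lc_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(paste0("latcohort_", class), "latcohort_error"), ...)
}

lc_assert <- function(cond, message, class = "error_input") {
  if (!isTRUE(cond)) lc_abort(message, class)
  invisible(TRUE)
}

# Deterministic RNG scope: runs `code` under `seed` and restores the caller's
# RNG state afterwards.
with_seed <- function(seed, code) {
  lc_assert(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
            "`seed` must be a single finite number.")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
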