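# Internal helpers shared across modules.

REGION_LABELS <- c("forehead", "right_cheek", "left_cheek", "cheeks_nose", "lips")
CHANNEL_LABELS <- c("R", "G", "B", "Gy", "IR")
COLOUR_CHANNELS <- c("R", "G", "B", "Gy")

#' Run code with a locally seeded RNG
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so package functions are deterministic given their
#' `seed` argument without disturbing the global stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_local_seed <- function(seed, expr) {
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
  expr
}

# Index of the element of `haystack` nearest to each element of `needles`.
nearest_index <- function(needles, haystack) {
  stopifnot(length(haystack) >= 1)
  vapply(needles, function(x) which.min(abs(haystack - x)), integer(1))
}

stop_validation <- function(...) {
  stop(structure(
    class = c("rppg_validation_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

stop_format <- function(...) {
  stop(structure(
    class = c("rppg_format_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_validation(name, " must be a single finite number")
  }
  invisible(x)
}
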