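#' Define a bounded Likert rating scale
#'
#' A Likert scale is described by its lowest and highest integer categories.
#' Two derived quantities are carried along because the Aiken's V machinery
#' needs them constantly: the number of categories `c = highest - lowest + 1`
#' and the span `k = c - 1`, the number of scale steps (the effective number
#' of "trials" per judge in the score-interval view of V).
#'
#' @param lowest Integer, lowest scale category (e.g. 1).
#' @param highest Integer, highest scale category (e.g. 5).
#'
#' @return An object of class `likert_scale`: a list with elements `lowest`,
#'   `highest`, `n_categories` and `span`.
#' @examples
#' likert_scale(1, 5)
#' @export
likert_scale <- function(lowest = 1L, highest = 5L) {
  if (length(lowest) != 1L || length(highest) != 1L ||
      !is.numeric(lowest) || !is.numeric(highest) ||
      lowest != as.integer(lowest) || highest != as.integer(highest)) {
    stop("`lowest` and `highest` must be single integers", call. = FALSE)
  }
  lowest <- as.integer(lowest)
  highest <- as.integer(highest)
  if (highest <= lowest) {
    stop("`highest` must exceed `lowest`", call. = FALSE)
  }
  structure(
    list(
      lowest = lowest,
      highest = highest,
      n_categories = highest - lowest + 1L,
      span = highest - lowest
    ),
    class = "likert_scale"
  )
}

#' @export
print.likert_scale <- function(x, ...) {
  cat(sprintf(
    "<likert_scale> %d..%d (%d categories, span %d)\n",
    x$lowest, x$highest, x$n_categories, x$span
  ))
  invisible(x)
}

is_likert_scale <- function(x) inherits(x, "likert_scale")

assert_scale <- function(scale) {
  if (!is_likert_scale(scale)) {
    stop("`scale` must be a likert_scale object", call. = FALSE)
  }
  invisible(scale)
}
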