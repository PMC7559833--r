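#' Panel descriptive statistics
#'
#' Mean and sample standard deviation (n - 1 denominator) of the judges'
#' career experience, the figures a validation report quotes as
#' "mean +/- SD years".
#'
#' @param profiles A data frame of judge profiles with a numeric
#'   `career_years` column (as returned by [load_fixture()]).
#' @return A list of class `panel_descriptives` with `n_experts`,
#'   `mean_career_years` and `sd_career_years`.
#' @examples
#' panel_descriptives(load_fixture("physicians")$profiles)
#' @export
panel_descriptives <- function(profiles) {
  if (!is.data.frame(profiles) || is.null(profiles$career_years)) {
    stop("`profiles` must be a data frame with a `career_years` column", call. = FALSE)
  }
  years <- profiles$career_years
  if (length(years) < 2L) {
    stop("panel descriptives need at least 2 profiles", call. = FALSE)
  }
  if (any(years < 0)) stop("career_years must be non-negative", call. = FALSE)
  structure(
    list(
      n_experts = length(years),
      mean_career_years = mean(years),
      sd_career_years = stats::sd(years)
    ),
    class = "panel_descriptives"
  )
}

#' @export
print.panel_descriptives <- function(x, ...) {
  cat(sprintf(
    "<panel_descriptives> %d experts, career experience %.1f +/- %.1f years\n",
    x$n_experts, x$mean_career_years, x$sd_career_years
  ))
  invisible(x)
}
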