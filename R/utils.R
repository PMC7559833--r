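# Display rounding. Statistics are computed and stored at full precision;
# these helpers exist only at the rendering boundary. Two conventions are
# needed because published validation tables commonly truncate coefficient
# columns (0.925 -> "0.92") while descriptives round half-up (11.757 ->
# "11.8"). A small epsilon absorbs binary-representation error so that e.g.
# 0.85 (stored as the nearest double) truncates to 0.85, not 0.84.

.round_eps <- 1e-8

#' Round half-up to a number of decimals
#'
#' Unlike [round()] (round-half-to-even), halves move away from zero:
#' `round_half_up(0.845, 2)` is 0.85.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + .round_eps) / p
}

#' Truncate (round toward zero) to a number of decimals
#'
#' @inheritParams round_half_up
#' @return Truncated numeric vector.
#' @export
trunc_dec <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + .round_eps) / p
}

# Apply a display policy ("truncate", "half-up", "none") and format with a
# fixed number of decimals (full precision under "none").
format_display <- function(x, policy = c("truncate", "half-up", "none"), digits = 2) {
  policy <- match.arg(policy)
  switch(policy,
    "truncate" = sprintf(paste0("%.", digits, "f"), trunc_dec(x, digits)),
    "half-up"  = sprintf(paste0("%.", digits, "f"), round_half_up(x, digits)),
    "none"     = format(x, digits = 15, trim = TRUE)
  )
}
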