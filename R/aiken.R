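#' Rating frequencies per scale category
#'
#' @param r Integer vector of ratings.
#' @param scale A [likert_scale()].
#' @return Named integer vector of counts, one per category `lowest..highest`,
#'   summing to `length(r)`.
#' @examples
#' rating_frequencies(c(5, 5, 4, 5), likert_scale(1, 5))
#' @export
rating_frequencies <- function(r, scale = likert_scale(1, 5)) {
  assert_scale(scale)
  if (length(r) && (any(r != trunc(r)) || any(r < scale$lowest | r > scale$highest))) {
    stop("ratings outside the declared scale", call. = FALSE)
  }
  counts <- tabulate(r - scale$lowest + 1L, nbins = scale$n_categories)
  stats::setNames(as.integer(counts), as.character(scale$lowest:scale$highest))
}

#' Aiken's V content-validity coefficient
#'
#' For n judges rating an item on an integer scale from l to h, Aiken's V is
#' the rank sum S = sum(r_i - l) rescaled to \[0, 1\]:
#' V = S / (n * k) with k = h - l. Equivalently, V is the mean rating mapped
#' linearly from \[l, h\] onto \[0, 1\]: V = (mean - l) / k.
#'
#' @param r Integer vector of ratings (length >= 1).
#' @param scale A [likert_scale()].
#' @return A list with `n`, `S` (integer rank sum), `V` and `mean_rating`,
#'   all at full precision.
#' @examples
#' aiken_v(c(4, 4, rep(5, 8)), likert_scale(1, 5))  # V = 0.95
#' @export
aiken_v <- function(r, scale = likert_scale(1, 5)) {
  assert_scale(scale)
  if (!length(r)) stop("cannot compute Aiken's V of an empty rating set", call. = FALSE)
  if (any(r != trunc(r)) || any(r < scale$lowest | r > scale$highest)) {
    stop("ratings outside the declared scale", call. = FALSE)
  }
  n <- length(r)
  S <- sum(r) - n * scale$lowest
  list(
    n = n,
    S = as.integer(S),
    V = S / (n * scale$span),
    mean_rating = mean(r)
  )
}

#' Score-method confidence interval for Aiken's V
#'
#' Treats `V` as a proportion over `n * k` effective trials (n judges, k
#' scale steps each) and inverts the normal score test, the Wilson-type
#' interval. Both endpoints p solve `(V - p)^2 = z^2 p (1 - p) / (n k)`:
#'
#' `L, U = (2 n k V + z^2 -/+ z * sqrt(4 n k V (1 - V) + z^2)) / (2 (n k + z^2))`
#'
#' By default `z = 1.96` at 95% confidence (the convention of the usual
#' desktop implementation of this interval, rather than the exact normal
#' quantile); any other confidence level uses the exact quantile unless `z`
#' is supplied.
#'
#' @param V Aiken's V, in \[0, 1\].
#' @param n Number of judges.
#' @param k Scale span (categories minus 1).
#' @param confidence Two-sided confidence level, default 0.95.
#' @param z Normal quantile override; default 1.96 when `confidence` is 0.95.
#' @return A list with `ci_low`, `ci_high`, `confidence`, `z`;
#'   `0 <= ci_low <= V <= ci_high <= 1`.
#' @examples
#' score_ci(0.95, n = 10, k = 4)  # about (0.835, 0.987)
#' @export
score_ci <- function(V, n, k, confidence = 0.95, z = NULL) {
  if (V < 0 || V > 1) stop("V must lie in [0, 1]", call. = FALSE)
  if (n * k < 1) stop("n * k must be at least 1", call. = FALSE)
  if (confidence <= 0 || confidence >= 1) stop("confidence must be in (0, 1)", call. = FALSE)
  if (is.null(z)) {
    z <- if (isTRUE(all.equal(confidence, 0.95))) 1.96 else stats::qnorm(1 - (1 - confidence) / 2)
  }
  nk <- n * k
  disc <- z * sqrt(4 * nk * V * (1 - V) + z^2)
  denom <- 2 * (nk + z^2)
  L <- (2 * nk * V + z^2 - disc) / denom
  U <- (2 * nk * V + z^2 + disc) / denom
  list(ci_low = max(0, min(L, V)), ci_high = min(1, max(U, V)),
       confidence = confidence, z = z)
}

#' Item validity decision
#'
#' An item is content-valid when its (unrounded) Aiken's V reaches the
#' threshold; the comparison is inclusive, so `V = threshold` passes.
#'
#' @param V Aiken's V in \[0, 1\].
#' @param threshold Minimum acceptable V, default 0.75.
#' @return Logical.
#' @export
validate_item <- function(V, threshold = 0.75) {
  if (any(V < 0 | V > 1)) stop("V must lie in [0, 1]", call. = FALSE)
  V >= threshold
}

#' Per-item Aiken's V analysis of a panel
#'
#' Computes, for every item of a rating matrix, the category frequencies,
#' mean rating, rank sum S, Aiken's V, its score-method confidence interval
#' and the validity decision. This is the per-item table a content-validation
#' report prints.
#'
#' @param x A [rating_matrix()] (normally the final, screened panel).
#' @param confidence Confidence level for the score interval.
#' @param z Normal quantile override (see [score_ci()]).
#' @param threshold Validity threshold on unrounded V, default 0.75.
#' @return A tibble with one row per item: `item_id`, `n`, one `freq_<cat>`
#'   column per scale category, `mean_rating`, `S`, `V`, `ci_low`, `ci_high`,
#'   `valid`.
#' @examples
#' fx <- load_fixture("physicians")
#' aiken_items(subset_experts(fx$matrix, fx$profiles$expert_id))
#' @export
aiken_items <- function(x, confidence = 0.95, z = NULL, threshold = 0.75) {
  stopifnot(inherits(x, "rating_matrix"))
  sc <- rating_scale(x)
  rows <- lapply(item_ids(x), function(item) {
    r <- x$ratings[, item]
    av <- aiken_v(r, sc)
    ci <- score_ci(av$V, av$n, sc$span, confidence, z)
    freq <- rating_frequencies(r, sc)
    out <- c(
      list(item_id = item, n = av$n),
      stats::setNames(as.list(as.integer(freq)), paste0("freq_", names(freq))),
      list(
        mean_rating = av$mean_rating, S = av$S, V = av$V,
        ci_low = ci$ci_low, ci_high = ci$ci_high,
        valid = validate_item(av$V, threshold)
      )
    )
    tibble::as_tibble(out)
  })
  do.call(rbind, rows)
}

#' Questionnaire-level summary of per-item validity
#'
#' Mean, sample SD (n - 1), minimum and maximum of the unrounded per-item V
#' values, and whether every item passed the validity threshold.
#'
#' @param items A per-item tibble from [aiken_items()].
#' @return A list of class `questionnaire_summary`: `n_items`, `mean_V`,
#'   `sd_V`, `min_V`, `max_V`, `all_valid`.
#' @export
summarize_questionnaire <- function(items) {
  if (!is.data.frame(items) || !nrow(items)) {
    stop("`items` must be a non-empty per-item result table", call. = FALSE)
  }
  v <- items$V
  structure(
    list(
      n_items = nrow(items),
      mean_V = mean(v),
      sd_V = if (length(v) > 1L) stats::sd(v) else 0,
      min_V = min(v),
      max_V = max(v),
      all_valid = all(items$valid)
    ),
    class = "questionnaire_summary"
  )
}

#' @export
print.questionnaire_summary <- function(x, ...) {
  cat(sprintf(
    "<questionnaire_summary> %d items: mean V %.3f (SD %.3f), range %.3f-%.3f; %s\n",
    x$n_items, x$mean_V, x$sd_V, x$min_V, x$max_V,
    if (x$all_valid) "all items valid" else "some items below threshold"
  ))
  invisible(x)
}
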