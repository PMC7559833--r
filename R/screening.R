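#' Deviance policy for screening discordant judges
#'
#' The screening rule flags a judge's answer when it sits too far from the
#' consensus of the other judges in the screening pool, and excludes the
#' judge once enough answers are flagged. The default policy — an answer at
#' least 3 scale points from the leave-one-out mean, in 2 or more items — is
#' the rule used in the embedded validation study; it reproduces exactly the
#' flagged cells that study reports. An alternative `sd_multiple` mode flags
#' answers at least `deviance_threshold` leave-one-out sample SDs from the
#' leave-one-out mean; it does not reproduce the study's flags and is kept
#' only as a configurable variant.
#'
#' @param deviance_threshold Positive number `d`: scale points
#'   (`absolute_points` mode) or SD multiples (`sd_multiple` mode). Default 3.
#' @param min_flagged_items Integer `m >= 1`: flags needed to exclude a
#'   judge. Default 2.
#' @param mode `"absolute_points"` (default) or `"sd_multiple"`.
#' @param inclusive Logical; `TRUE` (default) flags differences equal to the
#'   threshold ("at least"), `FALSE` requires strict excess.
#' @return A list of class `deviance_policy`.
#' @export
deviance_policy <- function(deviance_threshold = 3, min_flagged_items = 2L,
                            mode = c("absolute_points", "sd_multiple"),
                            inclusive = TRUE) {
  mode <- match.arg(mode)
  if (!is.numeric(deviance_threshold) || length(deviance_threshold) != 1L ||
      deviance_threshold <= 0) {
    stop("`deviance_threshold` must be a positive number", call. = FALSE)
  }
  if (!is.numeric(min_flagged_items) || length(min_flagged_items) != 1L ||
      min_flagged_items < 1 || min_flagged_items != trunc(min_flagged_items)) {
    stop("`min_flagged_items` must be an integer >= 1", call. = FALSE)
  }
  structure(
    list(
      deviance_threshold = deviance_threshold,
      min_flagged_items = as.integer(min_flagged_items),
      mode = mode,
      inclusive = isTRUE(inclusive)
    ),
    class = "deviance_policy"
  )
}

#' @export
print.deviance_policy <- function(x, ...) {
  cat(sprintf(
    "<deviance_policy> |rating - LOO mean| %s %g %s; exclude at >= %d flags\n",
    if (x$inclusive) ">=" else ">", x$deviance_threshold,
    if (x$mode == "absolute_points") "points" else "LOO SDs",
    x$min_flagged_items
  ))
  invisible(x)
}

check_pool <- function(x, pool) {
  missing <- setdiff(pool, expert_ids(x))
  if (length(missing)) {
    stop(sprintf("pool contains unknown expert(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  if (length(pool) < 2L) stop("screening pool needs at least 2 experts", call. = FALSE)
  if (anyDuplicated(pool)) stop("duplicate expert in pool", call. = FALSE)
  pool
}

#' Leave-one-out mean rating
#'
#' Mean rating of an item over the screening pool excluding one judge — the
#' consensus that judge's answer is compared against.
#'
#' @param x A [rating_matrix()].
#' @param expert Expert label (must be in `pool`).
#' @param item Item label.
#' @param pool Character vector of expert labels forming the screening pool;
#'   defaults to all experts.
#' @return The arithmetic mean of the other pool members' ratings.
#' @export
loo_mean <- function(x, expert, item, pool = expert_ids(x)) {
  check_pool(x, pool)
  if (!expert %in% pool) stop(sprintf("expert '%s' is not in the pool", expert), call. = FALSE)
  if (!item %in% item_ids(x)) stop(sprintf("unknown item '%s'", item), call. = FALSE)
  others <- setdiff(pool, expert)
  mean(x$ratings[others, item])
}

# Leave-one-out means/SDs for every (pool expert, item) cell at once.
# With column sums s_j over the pool, the LOO mean for cell (i, j) is
# (s_j - r_ij) / (p - 1); the LOO sample variance follows from the pooled
# sums of squares.
loo_stats <- function(x, pool) {
  r <- x$ratings[pool, , drop = FALSE]
  p <- nrow(r)
  s <- matrix(colSums(r), nrow = p, ncol = ncol(r), byrow = TRUE)
  loo_mean <- (s - r) / (p - 1)
  loo_sd <- NULL
  if (p >= 3L) {
    ss <- matrix(colSums(r^2), nrow = p, ncol = ncol(r), byrow = TRUE)
    loo_var <- (ss - r^2 - (p - 1) * loo_mean^2) / (p - 2)
    loo_var[loo_var < 0] <- 0  # guard tiny negative round-off
    loo_sd <- sqrt(loo_var)
  }
  list(ratings = r, loo_mean = loo_mean, loo_sd = loo_sd)
}

#' Flag deviant answers by leave-one-out comparison
#'
#' Compares every pool judge's rating of every item with the mean of the
#' other pool judges and flags the cells that meet the policy threshold.
#'
#' @inheritParams loo_mean
#' @param policy A [deviance_policy()].
#' @return A tibble with one row per flagged answer, in matrix order
#'   (expert, then item): `expert_id`, `item_id`, `rating`, `loo_mean`,
#'   `abs_difference`.
#' @export
flag_deviant_answers <- function(x, pool = expert_ids(x), policy = deviance_policy()) {
  check_pool(x, pool)
  st <- loo_stats(x, pool)
  diff <- abs(st$ratings - st$loo_mean)
  eps <- 1e-9  # treat float-exact threshold hits as equal
  if (policy$mode == "absolute_points") {
    cut <- policy$deviance_threshold
  } else {
    if (is.null(st$loo_sd)) {
      stop("sd_multiple mode needs a pool of at least 3 experts", call. = FALSE)
    }
    cut <- policy$deviance_threshold * st$loo_sd
  }
  hit <- if (policy$inclusive) diff >= cut - eps else diff > cut + eps
  idx <- which(t(hit))  # transpose so flags come out expert-major
  if (!length(idx)) {
    return(tibble::tibble(
      expert_id = character(0), item_id = character(0), rating = integer(0),
      loo_mean = numeric(0), abs_difference = numeric(0)
    ))
  }
  j <- ((idx - 1L) %% ncol(st$ratings)) + 1L
  i <- ((idx - 1L) %/% ncol(st$ratings)) + 1L
  tibble::tibble(
    expert_id = rownames(st$ratings)[i],
    item_id = colnames(st$ratings)[j],
    rating = st$ratings[cbind(i, j)],
    loo_mean = st$loo_mean[cbind(i, j)],
    abs_difference = diff[cbind(i, j)]
  )
}

#' Screen a panel for discordant judges
#'
#' Applies [flag_deviant_answers()] and excludes every judge whose flag count
#' reaches the policy's `min_flagged_items`. All judges meeting the criterion
#' are excluded; retained judges keep their original order.
#'
#' @inheritParams flag_deviant_answers
#' @param verbose If `TRUE`, message each flagged cell and exclusion.
#' @return A list of class `screening_result`: `policy`, `flags` (tibble),
#'   `flag_count_per_expert` (named integer over the pool), `excluded_experts`,
#'   `retained_expert_ids`.
#' @export
screen_experts <- function(x, pool = expert_ids(x), policy = deviance_policy(),
                           verbose = FALSE) {
  check_pool(x, pool)
  flags <- flag_deviant_answers(x, pool, policy)
  counts <- table(factor(flags$expert_id, levels = pool))
  counts <- stats::setNames(as.integer(counts), pool)
  excluded <- pool[counts >= policy$min_flagged_items]
  retained <- setdiff(pool, excluded)
  if (verbose) {
    for (i in seq_len(nrow(flags))) {
      message(sprintf(
        "flag: expert %s, item %s: rating %d vs leave-one-out mean %.3f (|diff| = %.3f)",
        flags$expert_id[i], flags$item_id[i], flags$rating[i],
        flags$loo_mean[i], flags$abs_difference[i]
      ))
    }
    for (e in excluded) {
      message(sprintf("excluded: expert %s (%d flagged items)", e, counts[[e]]))
    }
  }
  structure(
    list(
      policy = policy,
      flags = flags,
      flag_count_per_expert = counts,
      excluded_experts = excluded,
      retained_expert_ids = retained
    ),
    class = "screening_result"
  )
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf(
    "<screening_result> %d flagged answer(s); excluded: %s; %d expert(s) retained\n",
    nrow(x$flags),
    if (length(x$excluded_experts)) paste(x$excluded_experts, collapse = ", ") else "none",
    length(x$retained_expert_ids)
  ))
  invisible(x)
}

#' Assemble the final panel after screening
#'
#' Drops excluded judges and appends replacement judges (already present in
#' the matrix but outside the screening pool) to the retained set.
#'
#' @param x The full [rating_matrix()] (pool and replacement experts).
#' @param screening A `screening_result` from [screen_experts()].
#' @param replacements Character vector of replacement expert labels; must
#'   not overlap the screened pool.
#' @return A [rating_matrix()] over retained + replacement experts, items
#'   untouched.
#' @export
assemble_final_panel <- function(x, screening, replacements = character(0)) {
  pool <- names(screening$flag_count_per_expert)
  overlap <- intersect(replacements, pool)
  if (length(overlap)) {
    stop(sprintf("replacement expert(s) %s are in the screening pool",
                 paste(overlap, collapse = ", ")), call. = FALSE)
  }
  keep <- c(screening$retained_expert_ids, replacements)
  if (length(keep) < 2L) {
    stop("final panel would have fewer than 2 experts", call. = FALSE)
  }
  subset_experts(x, keep)
}
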