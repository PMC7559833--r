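#' Configuration for the synthetic panel generator
#'
#' The generator emulates the situation the screening and validity machinery
#' is built for: a small expert panel rating many items on a bounded Likert
#' scale with high consensus, optionally contaminated by discordant judges
#' whose answers sit far below the consensus on a random subset of items.
#'
#' Each rating starts from a latent item relevance `mu_j`, perturbed by a
#' symmetric continuous noise term (Gaussian by default) with SD `sigma`,
#' then rounded to the nearest integer (round-half-to-even) and clamped to
#' the scale. A deviant expert's answer to an item is, with probability
#' `p_dev`, replaced by `round(mu_j - delta)` clamped to the scale — low-ball
#' deviance, mirroring the observed pattern where discordant judges score 1
#' against a 4-5 consensus. Defaults reproduce the study conditions: 10
#' experts, 30 items, 1-5 scale, item relevances uniform on \[4, 5\],
#' `sigma = 0.5`, one deviant expert with `delta = 3` and `p_dev = 0.3`.
#'
#' @param n_experts Number of experts (default 10).
#' @param n_items Number of items (default 30).
#' @param scale A [likert_scale()].
#' @param mu Latent item relevance: a vector of length `n_items`, or a range
#'   `c(lo, hi)` to draw uniformly per item. Default `c(4, 5)`.
#' @param sigma SD of the latent rating noise, in scale points (default 0.5).
#' @param n_deviant Number of injected discordant experts (default 1).
#' @param delta Points subtracted from `mu_j` on a deviant answer (default 3).
#' @param p_dev Per-item probability a deviant expert answers deviantly
#'   (default 0.3).
#' @param noise `"gaussian"` (default) or `"uniform"` (symmetric, SD `sigma`).
#' @param seed Integer seed; the generator is deterministic given it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_experts = 10L, n_items = 30L,
                              scale = likert_scale(1, 5),
                              mu = c(4, 5), sigma = 0.5,
                              n_deviant = 1L, delta = 3, p_dev = 0.3,
                              noise = c("gaussian", "uniform"),
                              seed = 1L) {
  noise <- match.arg(noise)
  assert_scale(scale)
  if (n_experts < 1 || n_items < 1) stop("need at least 1 expert and 1 item", call. = FALSE)
  if (sigma < 0) stop("`sigma` must be non-negative", call. = FALSE)
  if (p_dev < 0 || p_dev > 1) stop("`p_dev` must be in [0, 1]", call. = FALSE)
  if (n_deviant < 0 || n_deviant > n_experts) {
    stop("`n_deviant` must be between 0 and n_experts", call. = FALSE)
  }
  if (delta <= 0) stop("`delta` must be positive", call. = FALSE)
  if (!(length(mu) %in% c(2L, n_items)) ||
      any(mu < scale$lowest | mu > scale$highest)) {
    stop("`mu` must be a range c(lo, hi) or one value per item, within the scale",
         call. = FALSE)
  }
  structure(
    list(
      n_experts = as.integer(n_experts), n_items = as.integer(n_items),
      scale = scale, mu = mu, sigma = sigma,
      n_deviant = as.integer(n_deviant), delta = delta, p_dev = p_dev,
      noise = noise, seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

clamp_scale <- function(x, scale) pmin(pmax(x, scale$lowest), scale$highest)

#' Simulate a rating panel with known discordant experts
#'
#' Draws a panel under a [simulation_config()], recording which experts were
#' injected as deviant and which cells were actually replaced — the ground
#' truth a recovery study scores the screening rule against.
#'
#' The random draws happen in a fixed order (item relevances, then the noise
#' matrix, then deviant-expert selection, then per-cell deviance coin flips),
#' so two configs differing only in `n_deviant`/`p_dev` share the same
#' underlying clean panel at the same seed. This is what
#' [screening_operating_characteristics()] relies on to measure the V bias
#' that screening leaves relative to the uncontaminated panel.
#'
#' @param config A [simulation_config()].
#' @return A list of class `simulated_panel`: `matrix` (a [rating_matrix()]),
#'   `clean_matrix` (the same panel before deviance injection),
#'   `true_deviants` (character labels), `realized_deviant_cells` (tibble
#'   with `expert_id`, `item_id`).
#' @examples
#' sim <- simulate_panel(simulation_config(seed = 42))
#' sim$true_deviants
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_experts
  J <- config$n_items
  sc <- config$scale
  mu <- if (length(config$mu) == J) config$mu else stats::runif(J, config$mu[1], config$mu[2])
  eps <- switch(config$noise,
    gaussian = stats::rnorm(n * J, 0, config$sigma),
    # uniform on +/- sigma*sqrt(3) has SD sigma
    uniform = stats::runif(n * J, -config$sigma * sqrt(3), config$sigma * sqrt(3))
  )
  latent <- matrix(mu, nrow = n, ncol = J, byrow = TRUE) + matrix(eps, n, J)
  clean <- clamp_scale(round(latent), sc)
  dimnames(clean) <- list(as.character(seq_len(n)), as.character(seq_len(J)))

  ratingm <- clean
  deviants <- character(0)
  cells <- tibble::tibble(expert_id = character(0), item_id = character(0))
  if (config$n_deviant > 0L) {
    deviants <- as.character(sort(sample.int(n, config$n_deviant)))
    hit <- matrix(stats::runif(config$n_deviant * J) < config$p_dev,
                  nrow = config$n_deviant, ncol = J)
    dev_value <- clamp_scale(round(mu - config$delta), sc)
    for (i in seq_along(deviants)) {
      ratingm[deviants[i], hit[i, ]] <- dev_value[hit[i, ]]
    }
    idx <- which(hit, arr.ind = TRUE)
    cells <- tibble::tibble(
      expert_id = deviants[idx[, 1]],
      item_id = colnames(ratingm)[idx[, 2]]
    )
    cells <- cells[order(as.integer(cells$expert_id), as.integer(cells$item_id)), ]
  }
  structure(
    list(
      matrix = rating_matrix(ratingm, sc, panel_id = "simulated"),
      clean_matrix = rating_matrix(clean, sc, panel_id = "simulated-clean"),
      true_deviants = deviants,
      realized_deviant_cells = cells
    ),
    class = "simulated_panel"
  )
}

#' @export
print.simulated_panel <- function(x, ...) {
  cat(sprintf(
    "<simulated_panel> %d experts x %d items; %d deviant expert(s), %d deviant cell(s)\n",
    n_experts(x$matrix), n_items(x$matrix),
    length(x$true_deviants), nrow(x$realized_deviant_cells)
  ))
  invisible(x)
}

#' Operating characteristics of the screening rule
#'
#' Monte-Carlo estimate of how the leave-one-out exclusion rule behaves under
#' a known generative model: sensitivity (fraction of injected deviant
#' experts excluded), specificity (fraction of clean experts retained) and
#' the mean per-item bias in Aiken's V that the screened panel retains
#' relative to the uncontaminated panel.
#'
#' Replicate `r` runs [simulate_panel()] at seed `config$seed + r - 1`, so
#' enlarging `R` extends the replicate set without perturbing earlier draws.
#'
#' @param config A [simulation_config()].
#' @param policy A [deviance_policy()].
#' @param R Number of replicates (>= 1).
#' @return A list of class `operating_characteristics`: `R`, `sensitivity`
#'   (`NaN` when `n_deviant = 0`), `specificity`, `mean_V_bias`,
#'   `exclusion_rate` (fraction of replicates excluding at least one expert).
#' @examples
#' screening_operating_characteristics(
#'   simulation_config(n_deviant = 0, seed = 7), R = 20
#' )$specificity
#' @export
screening_operating_characteristics <- function(config, policy = deviance_policy(),
                                                R = 100L) {
  stopifnot(inherits(config, "simulation_config"))
  if (R < 1) stop("`R` must be at least 1", call. = FALSE)
  sens_num <- 0; sens_den <- 0
  spec_num <- 0; spec_den <- 0
  v_bias <- numeric(R)
  any_excl <- logical(R)
  for (r in seq_len(R)) {
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    sim <- simulate_panel(cfg)
    scr <- screen_experts(sim$matrix, policy = policy)
    excluded <- scr$excluded_experts
    any_excl[r] <- length(excluded) > 0
    clean_experts <- setdiff(expert_ids(sim$matrix), sim$true_deviants)
    sens_num <- sens_num + sum(sim$true_deviants %in% excluded)
    sens_den <- sens_den + length(sim$true_deviants)
    spec_num <- spec_num + sum(!clean_experts %in% excluded)
    spec_den <- spec_den + length(clean_experts)
    keep <- if (length(scr$retained_expert_ids) >= 2L) scr$retained_expert_ids
            else expert_ids(sim$matrix)
    # V = (mean rating - lowest) / span, so per-item V comes straight from
    # column means; avoids building a full per-item table per replicate
    sc <- rating_scale(sim$matrix)
    v_screened <- (colMeans(ratings(sim$matrix)[keep, , drop = FALSE]) - sc$lowest) / sc$span
    v_clean <- (colMeans(ratings(sim$clean_matrix)) - sc$lowest) / sc$span
    v_bias[r] <- mean(v_screened - v_clean)
  }
  structure(
    list(
      R = as.integer(R),
      sensitivity = if (sens_den > 0) sens_num / sens_den else NaN,
      specificity = if (spec_den > 0) spec_num / spec_den else NaN,
      mean_V_bias = mean(v_bias),
      exclusion_rate = mean(any_excl)
    ),
    class = "operating_characteristics"
  )
}

#' @export
print.operating_characteristics <- function(x, ...) {
  cat(sprintf(
    "<operating_characteristics> R = %d: sensitivity %.3f, specificity %.3f, mean V bias %+.4f\n",
    x$R, x$sensitivity, x$specificity, x$mean_V_bias
  ))
  invisible(x)
}
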