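#' Configuration for a validation run
#'
#' Bundles everything [run_validation()] needs: the data source (a ratings
#' file or an embedded fixture), the scale, the screening pool and policy,
#' and the Aiken's V parameters. Exactly one of `ratings_path` or `fixture`
#' must be given.
#'
#' @param ratings_path Path to a CSV/TSV rating matrix (see [read_ratings()]).
#' @param fixture `"physicians"` or `"nurses"` to use an embedded panel.
#' @param fixture_variant `"verbatim"` or `"reconciled"` (nurses only; see
#'   [load_fixture()]).
#' @param scale A [likert_scale()].
#' @param pool Screening pool: character vector of expert labels, or `NULL`
#'   for "all experts except `replacements`".
#' @param replacements Replacement experts appended to the final panel after
#'   screening. For fixtures, defaults to the profiles' replacement flag.
#' @param policy A [deviance_policy()].
#' @param screen If `FALSE`, skip screening (pre-cleaned panels).
#' @param confidence Confidence level for the score interval.
#' @param z Normal quantile override (see [score_ci()]).
#' @param threshold Validity threshold on unrounded V.
#' @param rounding Display policy for rendered V/CI columns: `"truncate"`
#'   (default, matching the convention of published validation tables),
#'   `"half-up"` or `"none"`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(ratings_path = NULL, fixture = NULL,
                       fixture_variant = "verbatim",
                       scale = likert_scale(1, 5),
                       pool = NULL, replacements = NULL,
                       policy = deviance_policy(), screen = TRUE,
                       confidence = 0.95, z = NULL, threshold = 0.75,
                       rounding = c("truncate", "half-up", "none")) {
  rounding <- match.arg(rounding)
  if (is.null(ratings_path) == is.null(fixture)) {
    stop("give exactly one of `ratings_path` or `fixture`", call. = FALSE)
  }
  assert_scale(scale)
  if (threshold <= 0 || threshold > 1) stop("`threshold` must be in (0, 1]", call. = FALSE)
  if (confidence <= 0 || confidence >= 1) stop("`confidence` must be in (0, 1)", call. = FALSE)
  structure(
    list(
      ratings_path = ratings_path, fixture = fixture,
      fixture_variant = fixture_variant, scale = scale,
      pool = pool, replacements = replacements,
      policy = policy, screen = isTRUE(screen),
      confidence = confidence, z = z, threshold = threshold,
      rounding = rounding
    ),
    class = "run_config"
  )
}

#' Run the full content-validation pipeline
#'
#' Load the panel, screen the pool for discordant judges, assemble the final
#' panel (retained + replacements), compute the per-item Aiken's V table on
#' the final panel only, and summarise. Deterministic given the config and
#' input.
#'
#' @param config A [run_config()].
#' @param verbose Passed to [screen_experts()].
#' @return A list of class `validation_report`: `config`, `descriptives`
#'   (fixture runs only, else `NULL`), `screening` (`NULL` when screening is
#'   off), `final_panel` (character vector of expert labels), `items` (the
#'   [aiken_items()] tibble), `summary` (a [summarize_questionnaire()]
#'   result), `provenance`.
#' @examples
#' rep <- run_validation(run_config(fixture = "physicians"))
#' rep$summary
#' @export
run_validation <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  descriptives <- NULL
  if (!is.null(config$fixture)) {
    fx <- load_fixture(config$fixture, config$fixture_variant)
    m <- fx$matrix
    descriptives <- panel_descriptives(fx$profiles)
    replacements <- config$replacements
    if (is.null(replacements)) {
      replacements <- fx$profiles$expert_id[fx$profiles$replacement]
    }
  } else {
    m <- read_ratings(config$ratings_path, config$scale)
    replacements <- if (is.null(config$replacements)) character(0) else config$replacements
  }
  pool <- config$pool
  if (is.null(pool)) pool <- setdiff(expert_ids(m), replacements)

  screening <- NULL
  if (config$screen) {
    screening <- screen_experts(m, pool, config$policy, verbose = verbose)
    final <- assemble_final_panel(m, screening, replacements)
  } else {
    final <- subset_experts(m, c(pool, replacements))
  }
  items <- aiken_items(final, config$confidence, config$z, config$threshold)
  structure(
    list(
      config = config,
      descriptives = descriptives,
      screening = screening,
      final_panel = expert_ids(final),
      items = items,
      summary = summarize_questionnaire(items),
      provenance = list(
        package = "panelval",
        version = as.character(utils::packageVersion("panelval"))
      )
    ),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %d-expert final panel, %d items\n",
              length(x$final_panel), nrow(x$items)))
  if (!is.null(x$screening)) print(x$screening)
  print(x$summary)
  invisible(x)
}

report_item_lines <- function(report, rounding) {
  it <- report$items
  freq_cols <- grep("^freq_", names(it), value = TRUE)
  vapply(seq_len(nrow(it)), function(i) {
    paste(
      c(
        it$item_id[i],
        as.character(unlist(it[i, freq_cols])),
        format_display(it$mean_rating[i], "half-up"),
        sprintf("%s (%s-%s)",
                format_display(it$V[i], rounding),
                format_display(it$ci_low[i], rounding),
                format_display(it$ci_high[i], rounding))
      ),
      collapse = "\t"
    )
  }, character(1))
}

#' Render a validation report
#'
#' `"table"` emits one tab-separated row per item — frequencies, mean and
#' `"V (L-U)"` — under the configured display rounding. `"csv"` and `"json"`
#' carry the unrounded per-item values so downstream consumers never inherit
#' display truncation; the JSON form round-trips via
#' [jsonlite::fromJSON()].
#'
#' @param report A `validation_report`.
#' @param format `"table"`, `"csv"` or `"json"`.
#' @param rounding Display policy for the `"table"` format; defaults to the
#'   report's config.
#' @return A character vector of lines (`"table"`, `"csv"`) or a JSON string
#'   (`"json"`).
#' @export
render_report <- function(report, format = c("table", "csv", "json"),
                          rounding = NULL) {
  stopifnot(inherits(report, "validation_report"))
  format <- match.arg(format)
  if (is.null(rounding)) rounding <- report$config$rounding
  if (format == "table") {
    freq_cols <- grep("^freq_", names(report$items), value = TRUE)
    header <- paste(c("Item", sub("^freq_", "", freq_cols), "Mean", "Aiken's V (95% CI)"),
                    collapse = "\t")
    summ <- report$summary
    total <- sprintf("Total\tmean V %s (SD %s), range %s-%s, all valid: %s",
                     format_display(summ$mean_V, rounding),
                     format_display(summ$sd_V, rounding),
                     format_display(summ$min_V, rounding),
                     format_display(summ$max_V, rounding),
                     ifelse(summ$all_valid, "yes", "no"))
    c(header, report_item_lines(report, rounding), total)
  } else if (format == "csv") {
    df <- as.data.frame(report$items)
    tc <- textConnection("out", "w", local = TRUE)
    utils::write.csv(df, tc, row.names = FALSE, quote = FALSE)
    close(tc)
    out
  } else {
    body <- list(
      final_panel = report$final_panel,
      screening = if (is.null(report$screening)) NULL else list(
        policy = unclass(report$screening$policy),
        flags = as.data.frame(report$screening$flags),
        flag_count_per_expert = as.list(report$screening$flag_count_per_expert),
        excluded_experts = report$screening$excluded_experts,
        retained_expert_ids = report$screening$retained_expert_ids
      ),
      descriptives = if (is.null(report$descriptives)) NULL else unclass(report$descriptives),
      items = as.data.frame(report$items),
      summary = unclass(report$summary),
      provenance = report$provenance
    )
    jsonlite::toJSON(body, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  }
}

#' Write a rendered report to a file
#'
#' @param report A `validation_report`.
#' @param path Output path.
#' @param format Passed to [render_report()].
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path, format = c("table", "csv", "json")) {
  format <- match.arg(format)
  out <- render_report(report, format)
  writeLines(as.character(out), path, useBytes = TRUE)
  invisible(path)
}
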