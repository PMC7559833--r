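# Embedded panel fixtures: expert ratings from a published content validation
# of two 30-item questionnaires on physical activity on prescription (PAP) in
# primary healthcare, one judged by 11 sports medicine physicians and one by
# 11 nurses, each item scored 1-5 (5 = highest relevance). In each panel ten
# judges are the original panel and one ("replacement") was recruited after a
# discordant original judge was dropped.
#
# Ratings are stored item-by-item in the published column order; the loader
# transposes to the package convention (experts as rows).

.fixture_physicians_experts <- c("1", "2", "11", "4", "5", "6", "7", "8", "9", "10", "3")

.fixture_physicians_ratings <- c(
  5, 5, 5, 4, 4, 5, 5, 5, 5, 5, 5,
  5, 5, 4, 2, 4, 5, 5, 5, 5, 4, 5,
  5, 4, 3, 4, 3, 5, 5, 5, 5, 3, 3,
  5, 5, 4, 5, 3, 4, 5, 5, 5, 5, 4,
  4, 5, 5, 5, 3, 5, 5, 5, 5, 5, 5,
  5, 5, 3, 4, 4, 5, 5, 4, 5, 5, 4,
  4, 5, 5, 4, 4, 3, 5, 5, 5, 5, 5,
  4, 5, 5, 4, 4, 5, 5, 5, 5, 5, 3,
  3, 4, 3, 3, 4, 5, 5, 4, 5, 5, 4,
  3, 4, 3, 3, 4, 5, 5, 5, 5, 5, 4,
  4, 3, 3, 4, 4, 4, 5, 4, 5, 5, 4,
  4, 3, 4, 3, 4, 5, 5, 5, 5, 4, 1,
  3, 4, 5, 5, 4, 5, 5, 5, 5, 5, 3,
  4, 3, 5, 5, 4, 5, 5, 4, 5, 4, 4,
  3, 3, 5, 5, 4, 5, 5, 5, 5, 4, 1,
  3, 3, 5, 5, 4, 5, 5, 5, 5, 5, 3,
  3, 4, 4, 5, 4, 5, 5, 5, 5, 5, 4,
  3, 4, 3, 5, 4, 5, 5, 4, 5, 5, 3,
  3, 4, 5, 5, 4, 5, 5, 5, 5, 5, 5,
  3, 4, 5, 4, 4, 5, 5, 5, 5, 5, 3,
  4, 3, 3, 4, 4, 5, 5, 5, 5, 4, 4,
  3, 3, 4, 4, 4, 5, 5, 5, 5, 4, 3,
  3, 4, 3, 4, 4, 5, 5, 5, 5, 4, 3,
  4, 4, 3, 4, 3, 5, 5, 5, 5, 5, 2,
  4, 4, 3, 4, 3, 5, 5, 5, 5, 5, 3,
  3, 4, 3, 4, 3, 5, 5, 5, 5, 5, 3,
  4, 4, 5, 5, 4, 5, 5, 3, 5, 5, 1,
  3, 4, 4, 4, 4, 5, 5, 4, 5, 5, 1,
  3, 5, 4, 4, 4, 5, 5, 5, 3, 4, 2,
  4, 4, 4, 5, 4, 5, 5, 5, 5, 4, 4
)

.fixture_nurses_experts <- c("1", "2", "3", "4", "5", "6", "11", "8", "9", "10", "7")

.fixture_nurses_ratings <- c(
  5, 4, 5, 4, 4, 5, 4, 5, 5, 5, 2,
  5, 4, 3, 3, 4, 5, 4, 4, 4, 5, 1,
  5, 5, 3, 5, 4, 5, 4, 5, 3, 5, 5,
  4, 5, 4, 4, 4, 5, 4, 5, 5, 5, 4,
  5, 4, 5, 5, 5, 5, 4, 4, 4, 5, 1,
  5, 4, 3, 4, 4, 5, 3, 5, 5, 5, 4,
  5, 4, 4, 5, 4, 5, 4, 3, 5, 5, 4,
  5, 4, 5, 5, 5, 5, 3, 4, 5, 5, 3,
  5, 4, 4, 5, 5, 5, 3, 5, 5, 5, 5,
  5, 4, 4, 5, 4, 5, 4, 4, 3, 5, 5,
  5, 4, 5, 4, 5, 5, 4, 5, 5, 5, 4,
  4, 4, 4, 5, 5, 5, 3, 5, 3, 4, 2,
  4, 5, 5, 5, 5, 5, 3, 5, 5, 5, 4,
  5, 5, 4, 5, 5, 5, 4, 5, 5, 5, 2,
  5, 5, 4, 5, 5, 5, 3, 5, 4, 4, 2,
  5, 5, 5, 5, 5, 5, 3, 5, 4, 5, 4,
  5, 5, 5, 4, 5, 5, 4, 5, 5, 5, 5,
  5, 5, 5, 5, 5, 5, 4, 5, 5, 5, 5,
  2, 5, 5, 5, 5, 5, 4, 5, 5, 5, 5,
  5, 5, 5, 5, 5, 5, 4, 5, 5, 5, 5,
  4, 5, 4, 5, 5, 5, 4, 5, 5, 5, 5,
  5, 5, 5, 5, 5, 5, 5, 5, 5, 5, 5,
  5, 5, 5, 5, 5, 5, 4, 5, 5, 5, 5,
  2, 4, 4, 4, 5, 5, 3, 5, 4, 5, 5,
  5, 5, 4, 5, 5, 5, 4, 5, 5, 5, 5,
  2, 5, 2, 4, 5, 5, 3, 5, 4, 5, 5,
  3, 5, 2, 4, 5, 5, 4, 1, 5, 5, 3,
  5, 5, 3, 4, 5, 5, 4, 2, 5, 5, 4,
  4, 4, 5, 5, 5, 5, 4, 5, 5, 5, 5,
  5, 5, 5, 5, 5, 5, 4, 5, 5, 5, 5
)

# Judge metadata as published: the ten final-panel members per group (the
# dropped original judge has no published profile).
.fixture_physicians_profiles <- list(
  expert_id    = c("1", "2", "11", "4", "5", "6", "7", "8", "9", "10"),
  age_range    = c("51-55", "51-55", "56-60", "56-60", ">60", "56-60", ">60", ">60", ">60", "51-55"),
  sex          = c("Female", "Female", "Male", "Male", "Female", "Male", "Male", "Female", "Male", "Female"),
  career_years = c(20, 25, 36, 31, 36, 30, 30, 25, 25, 26),
  replacement  = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE)
)

.fixture_nurses_profiles <- list(
  expert_id    = c("1", "2", "3", "4", "5", "6", "11", "8", "9", "10"),
  age_range    = c("56-60", "46-50", "41-45", "36-40", "41-45", "41-45", "36-40", "46-50", "36-40", "51-55"),
  sex          = c("Female", "Male", "Female", "Female", "Male", "Female", "Female", "Female", "Male", "Female"),
  career_years = c(35, 28, 19, 10, 20, 3, 4, 9, 5, 30),
  replacement  = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE)
)

#' Load an embedded expert-panel fixture
#'
#' Returns one of the two published 11-expert, 30-item rating panels together
#' with the published judge profiles. Each panel contains the ten original
#' judges plus one replacement judge (`replacement = TRUE` in the profiles)
#' recruited when screening dropped a discordant original.
#'
#' Two readings of the nurses panel are available. `"verbatim"` is the
#' published rating table as printed. `"reconciled"` corrects two cells
#' (expert 3 at item 26: 2 to 3; expert 8 at item 27: 1 to 3) whose printed
#' values are inconsistent with the published per-item frequency summary;
#' only under this reading do all 30 nurse items reach the 0.75 validity
#' threshold. The physicians panel is identical under both variants.
#'
#' @param panel `"physicians"` or `"nurses"`.
#' @param variant `"verbatim"` (default) or `"reconciled"`; see Details.
#' @return A list with elements `matrix` (a [rating_matrix()], 11 experts x
#'   30 items) and `profiles` (a tibble of judge metadata with columns
#'   `expert_id`, `role`, `age_range`, `sex`, `career_years`, `replacement`).
#' @examples
#' fx <- load_fixture("physicians")
#' fx$matrix
#' @export
load_fixture <- function(panel = c("physicians", "nurses"),
                         variant = c("verbatim", "reconciled")) {
  panel <- match.arg(panel)
  variant <- match.arg(variant)
  if (panel == "physicians") {
    experts <- .fixture_physicians_experts
    vals <- .fixture_physicians_ratings
    prof <- .fixture_physicians_profiles
    role <- "physician"
  } else {
    experts <- .fixture_nurses_experts
    vals <- .fixture_nurses_ratings
    prof <- .fixture_nurses_profiles
    role <- "nurse"
  }
  # vals are item-major (one published row of 11 expert scores per item);
  # reshape to the package convention, experts x items
  m <- t(matrix(as.integer(vals), nrow = 30L, ncol = 11L, byrow = TRUE))
  dimnames(m) <- list(experts, as.character(1:30))
  if (panel == "nurses" && variant == "reconciled") {
    m["3", "26"] <- 3L
    m["8", "27"] <- 3L
  }
  profiles <- tibble::tibble(
    expert_id = prof$expert_id,
    role = role,
    age_range = prof$age_range,
    sex = prof$sex,
    career_years = as.integer(prof$career_years),
    replacement = prof$replacement
  )
  list(
    matrix = rating_matrix(m, likert_scale(1, 5), panel_id = panel),
    profiles = profiles
  )
}

#' Original (screening-pool) and replacement experts of a fixture
#'
#' Convenience split used by the default pipeline: screening runs over the
#' ten original judges; the replacement joins only when the final panel is
#' assembled.
#'
#' @param fixture A list as returned by [load_fixture()].
#' @return A list with character vectors `pool` (originals, matrix order) and
#'   `replacements`.
#' @export
fixture_pool <- function(fixture) {
  reps <- fixture$profiles$expert_id[fixture$profiles$replacement]
  list(
    pool = setdiff(expert_ids(fixture$matrix), reps),
    replacements = reps
  )
}

#' Export the embedded fixtures as CSV files
#'
#' Writes each panel's rating matrix (and its reconciled variant for the
#' nurses) plus the judge profiles to a directory, in the dialect
#' [read_ratings()] accepts.
#'
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
export_fixtures <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (panel in c("physicians", "nurses")) {
    fx <- load_fixture(panel)
    p <- file.path(dir, paste0(panel, "_ratings.csv"))
    write_ratings(fx$matrix, p)
    pp <- file.path(dir, paste0(panel, "_profiles.csv"))
    utils::write.csv(as.data.frame(fx$profiles), pp, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p, pp)
  }
  fx <- load_fixture("nurses", variant = "reconciled")
  p <- file.path(dir, "nurses_ratings_reconciled.csv")
  write_ratings(fx$matrix, p)
  invisible(c(paths, p))
}
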