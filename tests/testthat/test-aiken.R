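sc5 <- likert_scale(1, 5)

final_panel <- function(panel, variant = "verbatim") {
  fx <- load_fixture(panel, variant)
  pl <- fixture_pool(fx)
  scr <- screen_experts(fx$matrix, pl$pool)
  assemble_final_panel(fx$matrix, scr, pl$replacements)
}

test_that("rating frequencies count categories in scale order", {
  phys <- final_panel("physicians")
  expect_equal(
    unname(rating_frequencies(ratings(phys)[, "1"], sc5)),
    c(0L, 0L, 0L, 2L, 8L)
  )
  nurs <- final_panel("nurses")
  expect_equal(
    unname(rating_frequencies(ratings(nurs)[, "19"], sc5)),
    c(0L, 1L, 0L, 1L, 8L)
  )
  expect_equal(unname(rating_frequencies(integer(0), sc5)), rep(0L, 5))
  expect_error(rating_frequencies(c(1, 6), sc5), "outside")
})

test_that("Aiken's V equals the rescaled rank sum and the rescaled mean", {
  av <- aiken_v(c(4, 4, rep(5, 8)), sc5)
  expect_equal(av$S, 38L)
  expect_equal(av$V, 0.95)
  expect_equal(av$mean_rating, 4.80)

  expect_equal(aiken_v(rep(1, 7), sc5)$V, 0)
  expect_equal(aiken_v(rep(5, 7), sc5)$V, 1)
  expect_equal(aiken_v(rep(5, 10), sc5)$mean_rating, 5)
  expect_error(aiken_v(integer(0), sc5), "empty")

  set.seed(11)
  for (rep in 1:100) {
    sc <- likert_scale(sample(0:2, 1), sample(3:7, 1))
    r <- sample(sc$lowest:sc$highest, sample(1:15, 1), replace = TRUE)
    av <- aiken_v(r, sc)
    expect_gte(av$V, 0); expect_lte(av$V, 1)
    expect_equal(av$V, (av$mean_rating - sc$lowest) / sc$span)
  }
})

test_that("V from raw ratings equals V recomputed from frequencies on random panels", {
  set.seed(12)
  for (rep in 1:1000) {
    sc <- likert_scale(1, sample(3:7, 1))
    r <- sample(sc$lowest:sc$highest, sample(1:12, 1), replace = TRUE)
    expect_equal(
      aiken_v(r, sc)$V,
      v_from_frequencies(rating_frequencies(r, sc), sc)
    )
  }
})

test_that("score interval matches published bounds and hand evaluations", {
  ci <- score_ci(0.95, 10, 4)
  expect_equal(ci$ci_low, 0.8349, tolerance = 1e-4)
  expect_equal(trunc_dec(ci$ci_low, 2), 0.83)
  expect_equal(trunc_dec(ci$ci_high, 2), 0.98)

  ci2 <- score_ci(0.85, 10, 4)
  expect_equal(ci2$ci_low, 0.70930, tolerance = 1e-4)
  expect_equal(ci2$ci_high, 0.92939, tolerance = 1e-4)

  # closed-form collapse at the boundary: the +/- term cancels z^2 exactly
  expect_equal(score_ci(1, 10, 4)$ci_high, 1)
  expect_equal(score_ci(1, 3, 6)$ci_high, 1)
  expect_equal(score_ci(0, 10, 4)$ci_low, 0)
  expect_error(score_ci(1.2, 10, 4), "\\[0, 1\\]")
})

test_that("both score-interval endpoints satisfy the defining score equation", {
  set.seed(13)
  for (rep in 1:200) {
    n <- sample(1:30, 1); k <- sample(1:8, 1)
    V <- sample(0:(n * k), 1) / (n * k)
    ci <- score_ci(V, n, k)
    z <- ci$z
    for (p in c(ci$ci_low, ci$ci_high)) {
      expect_lt(abs((V - p)^2 - z^2 * p * (1 - p) / (n * k)), 1e-9)
    }
    expect_lte(ci$ci_low, V); expect_gte(ci$ci_high, V)
    expect_gte(ci$ci_low, 0); expect_lte(ci$ci_high, 1)
  }
})

test_that("interval width shrinks strictly as n*k grows, at fixed V", {
  for (V in c(0.1, 0.5, 0.75, 0.95)) {
    widths <- vapply(c(4, 10, 40, 100, 400), function(nk) {
      ci <- score_ci(V, n = nk, k = 1)
      ci$ci_high - ci$ci_low
    }, numeric(1))
    expect_true(all(diff(widths) < 0))
  }
})

test_that("V and its interval are invariant to shifting the scale", {
  r <- c(2, 3, 5, 4, 4)
  for (shift in c(-1, 1, 3)) {
    a <- aiken_v(r, sc5)
    b <- aiken_v(r + shift, likert_scale(1 + shift, 5 + shift))
    expect_equal(a$V, b$V)
    expect_equal(
      score_ci(a$V, a$n, 4)[c("ci_low", "ci_high")],
      score_ci(b$V, b$n, 4)[c("ci_low", "ci_high")]
    )
  }
})

test_that("non-default confidence levels use the exact normal quantile", {
  ci <- score_ci(0.8, 10, 4, confidence = 0.90)
  expect_equal(ci$z, qnorm(0.95))
  expect_lt(ci$ci_high - ci$ci_low, score_ci(0.8, 10, 4)$ci_high - score_ci(0.8, 10, 4)$ci_low)
  expect_equal(score_ci(0.8, 10, 4, z = 2)$z, 2)
})

test_that("validity decisions are inclusive and use unrounded V", {
  expect_true(validate_item(0.775))
  expect_true(validate_item(0.75))
  expect_false(validate_item(0.7499))
  expect_false(validate_item(0.749999, threshold = 0.75))
  expect_error(validate_item(1.1), "\\[0, 1\\]")
})

test_that("the per-item table carries frequencies, V, CI and decision consistently", {
  phys <- final_panel("physicians")
  it <- aiken_items(phys)
  expect_equal(nrow(it), 30L)
  expect_equal(it$n, rep(10L, 30))
  expect_equal(rowSums(it[, paste0("freq_", 1:5)]), rep(10, 30), ignore_attr = TRUE)
  expect_equal(it$V, (it$mean_rating - 1) / 4)
  expect_equal(it$valid, it$V >= 0.75)
  # spot anchors
  expect_equal(it$V[it$item_id == "1"], 0.95)
  expect_equal(it$S[it$item_id == "1"], 38L)
})

test_that("questionnaire summary reproduces the published headline values", {
  nurs <- summarize_questionnaire(aiken_items(final_panel("nurses")))
  expect_equal(round_half_up(nurs$mean_V, 2), 0.89)

  nurs_rec <- summarize_questionnaire(aiken_items(final_panel("nurses", "reconciled")))
  expect_equal(round_half_up(nurs_rec$mean_V, 2), 0.89)
  expect_equal(trunc_dec(nurs_rec$min_V, 2), 0.77)
  expect_equal(nurs_rec$max_V, 1.00)
  expect_true(nurs_rec$all_valid)

  phys <- summarize_questionnaire(aiken_items(final_panel("physicians")))
  expect_equal(trunc_dec(phys$mean_V, 2), 0.84)
  expect_equal(trunc_dec(phys$min_V, 2), 0.77)
  expect_equal(trunc_dec(phys$max_V, 2), 0.95)
  expect_true(phys$all_valid)

  one <- summarize_questionnaire(aiken_items(final_panel("physicians"))[5, ])
  expect_equal(one$sd_V, 0)
  expect_equal(one$mean_V, one$min_V)
})

test_that("the verbatim nurses reading leaves one item below the threshold", {
  it <- aiken_items(final_panel("nurses"))
  expect_equal(it$V[it$item_id == "27"], 0.725)
  expect_false(it$valid[it$item_id == "27"])
  expect_equal(it$V[it$item_id == "26"], 0.75)
  expect_true(it$valid[it$item_id == "26"])  # inclusive threshold
})
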