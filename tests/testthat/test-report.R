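test_that("display rounding implements truncation and half-up with float guards", {
  expect_equal(trunc_dec(0.925, 2), 0.92)
  expect_equal(trunc_dec(0.9293891, 2), 0.92)
  expect_equal(trunc_dec(0.85, 2), 0.85)   # binary representation must not leak
  expect_equal(trunc_dec(0.975, 2), 0.97)
  expect_equal(round_half_up(11.757, 1), 11.8)
  expect_equal(round_half_up(0.845, 2), 0.85)
  expect_equal(round_half_up(5.147, 1), 5.1)
  expect_equal(round_half_up(-0.845, 2), -0.85)
  expect_equal(format_display(0.8475, "truncate"), "0.84")
  expect_equal(format_display(0.8475, "half-up"), "0.85")
})

test_that("run_validation on the physicians fixture reproduces the published anchors", {
  rep <- run_validation(run_config(fixture = "physicians"))
  expect_equal(length(rep$final_panel), 10L)
  expect_equal(rep$screening$excluded_experts, "3")
  it1 <- rep$items[rep$items$item_id == "1", ]
  expect_equal(unlist(it1[paste0("freq_", 1:5)]), c(0, 0, 0, 2, 8), ignore_attr = TRUE)
  expect_equal(it1$mean_rating, 4.80)
  expect_equal(it1$V, 0.95)
  expect_equal(round_half_up(rep$descriptives$mean_career_years, 1), 28.4)
})

test_that("run_validation works without screening and on tiny external files", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("expert,q1", "a,4", "b,5"), path)
  rep <- run_validation(run_config(ratings_path = path, screen = FALSE))
  expect_null(rep$screening)
  expect_equal(nrow(rep$items), 1L)
  expect_equal(rep$items$V, 0.875)

  rep2 <- run_validation(run_config(ratings_path = path))
  expect_equal(rep2$final_panel, c("a", "b"))
})

test_that("config validation rejects contradictory or incomplete setups", {
  expect_error(run_config(), "exactly one")
  expect_error(run_config(fixture = "physicians", ratings_path = "x.csv"), "exactly one")
  expect_error(run_config(fixture = "physicians", threshold = 0), "threshold")
  expect_error(run_config(fixture = "physicians", confidence = 1), "confidence")
})

test_that("table rendering matches the published layout and rounding convention", {
  rep <- run_validation(run_config(fixture = "physicians"))
  lines <- render_report(rep, "table")
  expect_match(lines[3], "^2\t0\t1\t0\t3\t6\t4\\.40\t0\\.85 \\(0\\.70-0\\.92\\)$")
  nrep <- run_validation(run_config(fixture = "nurses"))
  nlines <- render_report(nrep, "table")
  expect_match(nlines[23], "^22\t0\t0\t0\t0\t10\t5\\.00\t1\\.00 \\(0\\.91-1\\.00\\)$")
  # half-up policy prints 0.85's upper bound as 0.93 instead
  hu <- render_report(rep, "table", rounding = "half-up")
  expect_match(hu[3], "0\\.85 \\(0\\.71-0\\.93\\)$")
})

test_that("json rendering round-trips the per-item values at full precision", {
  rep <- run_validation(run_config(fixture = "nurses"))
  parsed <- jsonlite::fromJSON(render_report(rep, "json"))
  expect_equal(parsed$items$V, rep$items$V)
  expect_equal(parsed$items$ci_low, rep$items$ci_low)
  expect_equal(parsed$summary$mean_V, rep$summary$mean_V)
  expect_equal(parsed$screening$excluded_experts, "7")
  expect_equal(parsed$final_panel, rep$final_panel)
})

test_that("identical configs render byte-identical reports", {
  r1 <- run_validation(run_config(fixture = "nurses"))
  r2 <- run_validation(run_config(fixture = "nurses"))
  expect_identical(render_report(r1, "csv"), render_report(r2, "csv"))
  expect_identical(as.character(render_report(r1, "json")),
                   as.character(render_report(r2, "json")))
})

test_that("csv output excludes display truncation (unrounded values survive)", {
  rep <- run_validation(run_config(fixture = "physicians"))
  csv <- render_report(rep, "csv")
  df <- utils::read.csv(text = csv)
  expect_equal(df$V, rep$items$V)
  expect_equal(df$ci_low, rep$items$ci_low, tolerance = 1e-12)
})

test_that("report V values can be recomputed from the report's own frequency rows", {
  for (panel in c("physicians", "nurses")) {
    rep <- run_validation(run_config(fixture = panel))
    sc <- likert_scale(1, 5)
    freq <- as.matrix(rep$items[, paste0("freq_", 1:5)])
    v_again <- apply(freq, 1, v_from_frequencies, scale = sc)
    expect_equal(unname(v_again), rep$items$V)
  }
})

test_that("the CLI runs, writes outputs and signals validity via exit status", {
  skip_if_not_installed("optparse")
  out_json <- withr::local_tempfile(fileext = ".json")
  out_csv <- withr::local_tempfile(fileext = ".csv")
  status <- suppressMessages(panelval_cli(c(
    "run", "--fixture", "physicians", "--quiet",
    "--out-json", out_json, "--out-csv", out_csv
  )))
  expect_equal(status, 0L)
  parsed <- jsonlite::fromJSON(out_json)
  expect_equal(parsed$summary$n_items, 30L)
  expect_equal(nrow(utils::read.csv(out_csv)), 30L)

  # verbatim nurses data leave item 27 below threshold -> status 3
  status3 <- suppressMessages(panelval_cli(c("run", "--fixture", "nurses", "--quiet")))
  expect_equal(status3, 3L)
  status0 <- suppressMessages(panelval_cli(c(
    "run", "--fixture", "nurses", "--fixture-variant", "reconciled", "--quiet"
  )))
  expect_equal(status0, 0L)

  expect_equal(
    suppressWarnings(suppressMessages(
      panelval_cli(c("run", "--ratings", "/nonexistent.csv", "--quiet"))
    )),
    1L
  )
  expect_equal(suppressMessages(panelval_cli(c("run", "--quiet"))), 2L)
  expect_equal(suppressMessages(panelval_cli("frobnicate")), 2L)
})

test_that("the CLI simulate and fixtures subcommands write loadable files", {
  skip_if_not_installed("optparse")
  dir <- withr::local_tempdir()
  out <- file.path(dir, "sim.csv")
  truth <- file.path(dir, "truth.json")
  status <- panelval_cli(c("simulate", "--seed", "5", "--out", out, "--truth", truth))
  expect_equal(status, 0L)
  m <- read_ratings(out)
  expect_equal(n_experts(m), 10L)
  expect_equal(n_items(m), 30L)
  tr <- jsonlite::fromJSON(truth)
  expect_equal(length(tr$true_deviants), 1L)

  status <- panelval_cli(c("fixtures", "--export", dir))
  expect_equal(status, 0L)
  expect_true(file.exists(file.path(dir, "nurses_ratings.csv")))
})

test_that("a YAML config file supplies options without overriding explicit flags", {
  skip_if_not_installed("optparse")
  skip_if_not_installed("yaml")
  cfg <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("fixture: nurses", "fixture-variant: reconciled"), cfg)
  expect_equal(suppressMessages(panelval_cli(c("run", "--config", cfg, "--quiet"))), 0L)
  # explicit flag wins over the file
  expect_equal(suppressMessages(panelval_cli(c(
    "run", "--config", cfg, "--fixture-variant", "verbatim", "--quiet"
  ))), 3L)
})
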