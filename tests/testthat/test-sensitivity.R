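test_that("a 1x1 grid equals running the stages by hand with the derived cell seed", {
  corpus <- simulate_corpus(corpus_config(seed = 21))
  grid <- suppressMessages(run_grid(
    corpus,
    policies = policy_presets()["munday_mid"],
    rulesets = preset_rulesets()["munday_screened"],
    boot_reps = 15, seed = 123
  ))
  cell <- grid$cells[["munday_mid|munday_screened"]]

  screened <- screen_corpus(corpus, "munday_screened")
  eff <- compute_lnrr(screened, "munday_mid")
  manual <- suppressMessages(loess_trend(
    eff, boot_reps = 15, seed = derive_seed(123, "munday_mid|munday_screened")
  ))
  expect_equal(cell$trend$curve, manual$curve)
  expect_equal(cell$trend$metrics, manual$metrics)
  expect_equal(cell$yearly, manual$yearly)
})

test_that("without bounded-scale zeros the policy dimension collapses", {
  fx <- make_fixture("no_zeros_flat")
  grid <- suppressMessages(run_grid(fx$corpus, boot_reps = 0,
                                    rulesets = preset_rulesets()["munday_screened"]))
  cmp <- tidy(grid)
  expect_identical(length(unique(round(cmp$decline_ratio, 12))), 1L)
  expect_identical(length(unique(round(cmp$weighted_slope, 12))), 1L)
})

test_that("on a zero-rich corpus the tiniest replacement constant shows the steepest decline", {
  fx <- make_fixture("early_zeros_constant_effect", seed = 4)
  grid <- suppressMessages(run_grid(
    fx$corpus, boot_reps = 0,
    policies = policy_presets()[c("clements", "munday_whole")],
    rulesets = preset_rulesets()["munday_screened"]
  ))
  cmp <- tidy(grid)
  dr <- setNames(cmp$decline_ratio, cmp$policy)
  expect_gt(dr[["clements"]], dr[["munday_whole"]])
  expect_identical(cmp$policy[cmp$steepest_decline], "clements")
})

test_that("permuting the grid's cell order leaves every cell identical", {
  corpus <- simulate_corpus(corpus_config(seed = 31))
  fwd <- suppressMessages(run_grid(corpus, boot_reps = 10, seed = 7,
                                   policies = policy_presets()[c("clements", "munday_whole")],
                                   rulesets = preset_rulesets()["munday_screened"]))
  rev <- suppressMessages(run_grid(corpus, boot_reps = 10, seed = 7,
                                   policies = policy_presets()[c("munday_whole", "clements")],
                                   rulesets = preset_rulesets()["munday_screened"]))
  for (nm in names(fwd$cells)) {
    expect_equal(fwd$cells[[nm]]$trend$curve, rev$cells[[nm]]$trend$curve)
    expect_equal(fwd$cells[[nm]]$trend$metrics, rev$cells[[nm]]$trend$metrics)
  }
})

test_that("cells that empty or starve the corpus are degenerate, not fatal", {
  all_sham <- purrr::map_dfr(1:12, ~ make_record(record_id = paste0("s", .x),
                                                 is_sham = TRUE))
  grid <- suppressMessages(run_grid(
    all_sham, boot_reps = 0,
    policies = policy_presets()["munday_mid"],
    rulesets = list(screened = preset_rulesets("munday_screened"),
                    open = screening_rules(name = "open"))
  ))
  cmp <- tidy(grid)
  expect_true(cmp$degenerate[cmp$ruleset == "screened"]) # empty after screening
  expect_true(cmp$degenerate[cmp$ruleset == "open"])     # 12 effects but 1 year
  expect_identical(nrow(cmp), 2L)

  grid_files <- withr::local_tempdir()
  corpus <- simulate_corpus(corpus_config(seed = 2))
  g <- suppressMessages(run_grid(corpus, boot_reps = 0,
                                 policies = policy_presets()["munday_mid"],
                                 rulesets = preset_rulesets()["munday_screened"],
                                 outdir = grid_files))
  expect_true(file.exists(file.path(grid_files, "comparison.csv")))
  expect_true(file.exists(file.path(grid_files, "munday_mid_munday_screened_effects.csv")))
})
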