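line_effects <- function(slope = -0.2, intercept = NULL, years = 2009:2019, per_year = 2) {
  if (is.null(intercept)) intercept <- -slope * max(years) + 1 # keep values positive
  tibble::tibble(
    record_id = paste0("e", seq_len(length(years) * per_year)),
    year = rep(years, each = per_year),
    lnrr = slope * rep(years, each = per_year) + intercept,
    variance = 1
  )
}

test_that("constant effects give a flat curve and zero slope", {
  eff <- line_effects(slope = 0, intercept = 1.7)
  tr <- suppressMessages(loess_trend(eff, boot_reps = 0))
  expect_equal(tr$curve$fitted, rep(1.7, nrow(tr$curve)), tolerance = 1e-8)
  expect_equal(tr$metrics$weighted_slope, 0, tolerance = 1e-10)
  expect_equal(tr$metrics$decline_ratio, 1, tolerance = 1e-10)
})

test_that("noiseless linear effects recover the slope by weighted least squares", {
  eff <- line_effects(slope = -0.2)
  tr <- suppressMessages(loess_trend(eff, boot_reps = 0, response = "signed"))
  expect_equal(tr$metrics$weighted_slope, -0.2, tolerance = 1e-10)
  # degree-1 loess reproduces a straight line
  expect_equal(tr$curve$fitted, -0.2 * tr$curve$year + (0.2 * 2019 + 1), tolerance = 1e-6)
  expect_gt(tr$metrics$decline_ratio, 1)
})

test_that("the trend is reproducible from the seed and bounds behave sensibly", {
  corpus <- simulate_corpus(corpus_config(seed = 8))
  eff <- compute_lnrr(corpus, "munday_mid")
  t1 <- suppressMessages(loess_trend(eff, boot_reps = 40, seed = 99))
  t2 <- suppressMessages(loess_trend(eff, boot_reps = 40, seed = 99))
  expect_identical(t1$curve, t2$curve)
  expect_identical(t1$metrics, t2$metrics)

  # percentile bounds bracket the fitted curve at nearly all grid points
  inside <- mean(t1$curve$ci_low <= t1$curve$fitted & t1$curve$fitted <= t1$curve$ci_high)
  expect_gte(inside, 0.9)

  # bands narrow (on average) as the corpus grows
  big <- simulate_corpus(corpus_config(studies_per_year = 40, seed = 8))
  eff_big <- compute_lnrr(big, "munday_mid")
  t3 <- suppressMessages(loess_trend(eff_big, boot_reps = 40, seed = 99))
  expect_lt(mean(t3$curve$ci_high - t3$curve$ci_low),
            mean(t1$curve$ci_high - t1$curve$ci_low))
})

test_that("trend preconditions are enforced with informative errors", {
  few <- line_effects(years = 2009:2011, per_year = 1)
  expect_error(suppressMessages(loess_trend(few)), "at least 10 effects")
  two_years <- line_effects(years = 2009:2010, per_year = 6)
  expect_error(suppressMessages(loess_trend(two_years)), "3 distinct years")
  ok <- line_effects()
  expect_error(suppressMessages(loess_trend(ok, span = 1.5)), "span")
  expect_error(suppressMessages(loess_trend(ok, span = 0)), "span")
})

test_that("compare_trends aligns configurations and flags the steepest decline", {
  eff_steep <- line_effects(slope = -0.3)
  eff_flat <- line_effects(slope = -0.05)
  t_steep <- suppressMessages(loess_trend(eff_steep, boot_reps = 0, response = "signed"))
  t_flat <- suppressMessages(loess_trend(eff_flat, boot_reps = 0, response = "signed"))

  cmp <- compare_trends(list(steep = t_steep, flat = t_flat))
  expect_identical(cmp$summary$name[cmp$summary$steepest_decline], "steep")
  expect_identical(names(cmp$yearly), c("year", "steep", "flat"))

  # identical inputs: all deltas zero
  cmp2 <- compare_trends(list(a = t_flat, b = t_flat))
  expect_equal(cmp2$summary$decline_ratio[1], cmp2$summary$decline_ratio[2])
  expect_equal(cmp2$yearly$a, cmp2$yearly$b)

  # disjoint / single-overlap year ranges are an error
  t_early <- suppressMessages(loess_trend(line_effects(years = 2009:2011, per_year = 4),
                                          boot_reps = 0))
  t_late <- suppressMessages(loess_trend(line_effects(years = 2011:2013, per_year = 4),
                                         boot_reps = 0))
  expect_error(compare_trends(list(a = t_early, b = t_late)), "at least two")
  expect_error(compare_trends(list(a = t_early)), "at least two lnrr_trend")
})
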