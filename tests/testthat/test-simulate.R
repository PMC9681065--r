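test_that("the generator is deterministic and its records always satisfy the invariants", {
  cfg <- corpus_config(seed = 17)
  expect_identical(simulate_corpus(cfg), simulate_corpus(cfg))

  configs <- list(
    corpus_config(seed = 1),
    corpus_config(effect_schedule = schedule_constant(0.5),
                  zero_schedule = schedule_constant(0.3), seed = 2),
    corpus_config(scale_mix = c(percentage = 1, proportion = 0, continuous = 0),
                  cv_range = c(0.1, 0.9), n_range = c(2L, 8L), seed = 3),
    corpus_config(years = 2012:2015, studies_per_year = 3,
                  flag_rates = c(sham = 0.3, fluctuating_co2 = 0.3,
                                 procedural = 0.3, opposite = 0.3), seed = 4),
    corpus_config(effect_schedule = function(y) 0.5 + 0.1 * (y - 2009),
                  sampling_noise = TRUE, seed = 5)
  )
  for (cfg in configs) {
    corpus <- simulate_corpus(cfg)
    expect_silent(validate_corpus(corpus, year_range = range(cfg$years)))
    expect_gt(nrow(corpus), 0)
  }
})

test_that("a zero-prevalence of zero yields no bound values on any scale", {
  fx <- make_fixture("no_zeros_flat")
  bound <- ifelse(fx$corpus$scale_type == "percentage", 100,
                  ifelse(fx$corpus$scale_type == "proportion", 1, Inf))
  expect_true(all(fx$corpus$control_mean > 0 & fx$corpus$control_mean < bound))
  expect_true(all(fx$corpus$treatment_mean > 0 & fx$corpus$treatment_mean < bound))
})

test_that("the early-zeros schedule makes floor records more common early than late", {
  zero_frac <- function(corpus, years) {
    sel <- corpus$year %in% years & corpus$scale_type != "continuous"
    mean(corpus$control_mean[sel] == 0 | corpus$treatment_mean[sel] == 0)
  }
  early <- late <- numeric(0)
  for (s in 1:5) {
    fx <- make_fixture("early_zeros_constant_effect", seed = s)
    early <- c(early, zero_frac(fx$corpus, 2009:2010))
    late <- c(late, zero_frac(fx$corpus, 2018:2019))
  }
  expect_gt(mean(early), mean(late))
})

test_that("non-zero unflagged records track the latent effect schedule", {
  cfg <- corpus_config(effect_schedule = schedule_constant(1),
                       zero_schedule = schedule_constant(0.3),
                       flag_rates = c(sham = 0, fluctuating_co2 = 0,
                                      procedural = 0, opposite = 0),
                       seed = 99)
  corpus <- simulate_corpus(cfg)
  clean <- corpus[corpus$control_mean > 0 & corpus$treatment_mean > 0, ]
  lnrr <- log(clean$treatment_mean / clean$control_mean)
  expect_equal(mean(lnrr), 1, tolerance = 4 * 0.3 / sqrt(nrow(clean)) + 0.02)

  # the gentle-decline default: early latent effects larger than late ones
  dec <- simulate_corpus(corpus_config(zero_schedule = schedule_constant(0),
                                       flag_rates = c(sham = 0, fluctuating_co2 = 0,
                                                      procedural = 0, opposite = 0),
                                       seed = 100))
  l <- log(dec$treatment_mean / dec$control_mean)
  expect_gt(mean(l[dec$year <= 2010]), mean(l[dec$year >= 2018]))
})

test_that("sham and fluctuating-CO2 records carry damped latent effects", {
  cfg <- corpus_config(effect_schedule = schedule_constant(1.5),
                       zero_schedule = schedule_constant(0),
                       flag_rates = c(sham = 0.4, fluctuating_co2 = 0.4,
                                      procedural = 0, opposite = 0),
                       seed = 55)
  corpus <- simulate_corpus(cfg)
  l <- log(corpus$treatment_mean / corpus$control_mean)
  expect_lt(mean(abs(l[corpus$is_sham])), 0.2)
  plain <- !corpus$is_sham & !corpus$is_fluctuating_co2
  fluct <- !corpus$is_sham & corpus$is_fluctuating_co2
  expect_lt(mean(l[fluct]), 0.7 * mean(l[plain]))
})

test_that("fixtures expose their contract and reject unknown names", {
  expect_error(make_fixture("bogus"), "worked_example")
  fx <- make_fixture("worked_example")
  expect_identical(nrow(fx$corpus), 1L)
  for (i in seq_len(nrow(fx$expected))) {
    got <- compute_lnrr(fx$corpus, fx$expected$policy[i])$lnrr
    expect_equal(got, fx$expected$lnrr[i])
    expect_equal(signif(got, 2), signif(fx$expected$printed[i], 2))
  }
})

test_that("infeasibly large latent effects abort after bounded resampling", {
  cfg <- corpus_config(effect_schedule = schedule_constant(12),
                       tau_true = 0, max_retries = 3,
                       scale_mix = c(percentage = 1, proportion = 0, continuous = 0),
                       seed = 1)
  expect_error(simulate_corpus(cfg), "bounds")
})
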