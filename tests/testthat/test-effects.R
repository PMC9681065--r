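test_that("bound-symmetric replacement moves only bound values, with provenance", {
  rec <- make_record(control_mean = 0, treatment_mean = 100,
                     control_sd = 0, treatment_sd = 0)
  adj <- apply_replacement(rec, "munday_whole")
  expect_equal(adj$control_mean, 1)
  expect_equal(adj$treatment_mean, 99)
  expect_true(adj$control_adjusted && adj$treatment_adjusted)

  interior <- make_record(control_mean = 37.5, treatment_mean = 62.5)
  for (p in policy_presets()) {
    out <- apply_replacement(interior, p)
    expect_equal(out$control_mean, 37.5)
    expect_equal(out$treatment_mean, 62.5)
    expect_false(out$control_adjusted || out$treatment_adjusted)
  }

  both_zero <- make_record(scale_type = "proportion", control_mean = 0,
                           treatment_mean = 0, control_sd = 0, treatment_sd = 0)
  adj2 <- apply_replacement(both_zero, replacement_policy(0.1, 0.001))
  expect_equal(adj2$control_mean, 0.001)
  expect_equal(adj2$treatment_mean, 0.001)
})

test_that("a continuous-scale record with a zero mean cannot be replaced", {
  rec <- make_record(scale_type = "continuous", control_mean = 0, treatment_mean = 12)
  expect_error(apply_replacement(rec, "clements"), "continuous")
  expect_error(compute_lnrr(rec, "clements"), "continuous")
})

test_that("the worked 0% vs 100% contrast reproduces 4.6, 6.9 and 13.8", {
  rec <- make_record(control_mean = 0, treatment_mean = 100,
                     control_sd = 0, treatment_sd = 0)
  expect_equal(compute_lnrr(rec, "munday_whole")$lnrr, log(99 / 1))
  expect_equal(compute_lnrr(rec, "munday_mid")$lnrr, log(99.9 / 0.1))
  expect_equal(compute_lnrr(rec, "clements")$lnrr, log(99.9999 / 0.0001))
  expect_equal(signif(compute_lnrr(rec, "munday_whole")$lnrr, 2), 4.6)
  expect_equal(signif(compute_lnrr(rec, "munday_mid")$lnrr, 2), 6.9)
  expect_equal(signif(compute_lnrr(rec, "clements")$lnrr, 3), 13.8)
})

test_that("lnRR identity, antisymmetry and policy-invariance hold on interior records", {
  equal_means <- make_record(control_mean = 40, treatment_mean = 40)
  expect_equal(compute_lnrr(equal_means, "clements")$lnrr, 0)

  recs <- random_interior_records(40, seed = 202)
  swapped <- recs
  swapped$control_mean <- recs$treatment_mean
  swapped$treatment_mean <- recs$control_mean
  swapped$control_sd <- recs$treatment_sd
  swapped$treatment_sd <- recs$control_sd
  swapped$control_n <- recs$treatment_n
  swapped$treatment_n <- recs$control_n
  for (p in policy_presets()) {
    a <- compute_lnrr(recs, p)
    b <- compute_lnrr(swapped, p)
    expect_equal(b$lnrr, -a$lnrr)
    expect_equal(b$variance, a$variance)
  }

  # no bound values anywhere => every policy yields the identical table
  tables <- lapply(policy_presets(), function(p) {
    out <- compute_lnrr(recs, p)
    out$policy <- NULL
    out
  })
  expect_identical(tables[[1]], tables[[2]])
  expect_identical(tables[[2]], tables[[3]])
})

test_that("the delta-method variance matches its formula case and a finite-difference oracle", {
  rec <- make_record(scale_type = "continuous",
                     control_mean = 10, treatment_mean = 20,
                     control_sd = 2, treatment_sd = 2,
                     control_n = 5L, treatment_n = 5L)
  expect_equal(compute_lnrr(rec, "clements")$variance, 0.010)

  # independent oracle: numeric gradient of ln(t/c), combined with the
  # per-arm squared standard errors
  fd_variance <- function(mc, mt, sdc, sdt, nc, nt, h = 1e-6) {
    f <- function(c0, t0) log(t0 / c0)
    gc <- (f(mc + h, mt) - f(mc - h, mt)) / (2 * h)
    gt <- (f(mc, mt + h) - f(mc, mt - h)) / (2 * h)
    gc^2 * sdc^2 / nc + gt^2 * sdt^2 / nt
  }
  recs <- random_interior_records(50, seed = 77)
  eff <- compute_lnrr(recs, "clements")
  v_oracle <- mapply(fd_variance, recs$control_mean, recs$treatment_mean,
                     recs$control_sd, recs$treatment_sd,
                     recs$control_n, recs$treatment_n)
  expect_equal(eff$variance, unname(v_oracle), tolerance = 1e-4)

  # both SDs zero: variance 0, unusable for weighting
  degen <- make_record(control_sd = 0, treatment_sd = 0)
  out <- compute_lnrr(degen, "clements")
  expect_equal(out$variance, 0)
  expect_false(out$usable_weight)
})

test_that("|lnRR| of a zero-control record is strictly decreasing in the replacement constant", {
  rec <- make_record(control_mean = 0, treatment_mean = 100,
                     control_sd = 0, treatment_sd = 0)
  cs <- c(10, 5, 1, 0.5, 0.1, 0.001, 0.0001)
  mags <- vapply(cs, function(cc) {
    compute_lnrr(rec, replacement_policy(cc, cc / 100))$magnitude
  }, numeric(1))
  expect_true(all(diff(mags) > 0))
})

test_that("the inflation curve matches direct evaluation and is monotone in the control value", {
  curve <- inflation_curve(100, c(5, 1, 0.1, 0.0001))
  expect_equal(curve$control, c(5, 1, 0.1, 0.0001)) # descending order
  expect_equal(curve$lnrr, log((100 - curve$control) / curve$control))
  expect_true(all(diff(curve$lnrr) > 0))
  expect_equal(signif(curve$lnrr[curve$control == 0.0001], 3), 13.8)

  flat <- inflation_curve(50, 50)
  expect_equal(flat$lnrr, 0)

  expect_error(inflation_curve(100, c(-1, 2)), "positive")
  expect_error(inflation_curve(100, c(2, 150)), "below 100")
})
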