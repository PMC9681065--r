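# Quick single-record constructor for unit tests.
make_record <- function(record_id = "r1", scale_type = "percentage",
                        control_mean = 40, treatment_mean = 60,
                        control_sd = 5, treatment_sd = 5,
                        control_n = 10L, treatment_n = 10L,
                        year = 2012L, co2_uatm = 1000,
                        is_sham = FALSE, is_fluctuating_co2 = FALSE,
                        is_procedural_control = FALSE, direction_opposite = FALSE) {
  tibble::tibble(
    record_id = record_id, study_id = paste0("study_", record_id),
    year_online = as.integer(year), year_print = as.integer(year),
    scale_type = scale_type,
    control_mean = control_mean, treatment_mean = treatment_mean,
    control_sd = control_sd, treatment_sd = treatment_sd,
    control_n = as.integer(control_n), treatment_n = as.integer(treatment_n),
    co2_uatm = co2_uatm, year = as.integer(year),
    species = "species_01", life_stage = "larva",
    cue_type = "predator_cue", behaviour_metric = "pct_time_in_cue_arm",
    is_sham = is_sham, is_fluctuating_co2 = is_fluctuating_co2,
    is_procedural_control = is_procedural_control,
    direction_opposite = direction_opposite
  )
}

# Random interior-valued records (no bound values), for invariance and
# oracle properties.
random_interior_records <- function(n, seed) {
  withr::with_seed(seed, {
    scale <- sample(c("percentage", "proportion", "continuous"), n, replace = TRUE)
    bound <- unname(c(percentage = 100, proportion = 1, continuous = Inf)[scale])
    ctrl <- runif(n, 0.05, 0.95) * pmin(bound, 100)
    trt <- runif(n, 0.05, 0.95) * pmin(bound, 100)
    recs <- purrr::map_dfr(seq_len(n), function(i) {
      make_record(
        record_id = paste0("r", i), scale_type = scale[i],
        control_mean = ctrl[i], treatment_mean = trt[i],
        control_sd = runif(1, 0.05, 0.3) * ctrl[i],
        treatment_sd = runif(1, 0.05, 0.3) * trt[i],
        control_n = sample(5:30, 1), treatment_n = sample(5:30, 1),
        year = sample(2009:2019, 1)
      )
    })
    recs
  })
}

# Random effects table for pooling tests.
random_effects <- function(n, seed, years = 2009:2012) {
  withr::with_seed(seed, tibble::tibble(
    record_id = paste0("e", seq_len(n)),
    year = years[sample.int(length(years), n, replace = TRUE)],
    lnrr = rnorm(n, 1, 1),
    variance = runif(n, 0.01, 0.5)
  ))
}

# Independent brute-force inverse-variance pooling oracle.
oracle_fixed <- function(y, v) {
  w <- 1 / v
  list(mean = sum(w * y) / sum(w), se = sqrt(1 / sum(w)))
}
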