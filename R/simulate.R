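#' Schedules for year-varying generator parameters
#'
#' A schedule maps publication year to a parameter value (latent true
#' effect, zero prevalence). `schedule_constant()` is flat;
#' `schedule_linear()` interpolates linearly from the first to the last
#' year of the simulated range. A plain function of year is also accepted
#' wherever a schedule is.
#'
#' @param value Constant value.
#' @param from,to Values at the first and last simulated year.
#' @return A `sim_schedule` object.
#' @examples
#' schedule_linear(0.4, 0.02) # zeros common early, rare late
#' @export
schedule_constant <- function(value) {
  structure(list(type = "constant", value = value), class = "sim_schedule")
}

#' @rdname schedule_constant
#' @export
schedule_linear <- function(from, to) {
  structure(list(type = "linear", from = from, to = to), class = "sim_schedule")
}

resolve_schedule <- function(schedule, years) {
  yr_range <- range(years)
  if (is.function(schedule)) return(vapply(years, schedule, numeric(1)))
  if (inherits(schedule, "sim_schedule")) {
    return(switch(schedule$type,
      constant = rep(schedule$value, length(years)),
      linear = {
        if (yr_range[1] == yr_range[2]) rep(schedule$from, length(years))
        else schedule$from + (schedule$to - schedule$from) *
          (years - yr_range[1]) / (yr_range[2] - yr_range[1])
      }
    ))
  }
  if (is.numeric(schedule) && length(schedule) == 1) return(rep(schedule, length(years)))
  abort("Schedules must be sim_schedule objects, plain functions of year, or single numbers.")
}

#' Configure the synthetic study-corpus generator
#'
#' Defines the data-generating situation the analysis assumes: a decade of
#' experiments whose latent true log response ratio follows a configurable
#' schedule, with between-study heterogeneity, delta-method-consistent
#' sampling noise, and bounded-scale floor/ceiling records (exact 0% and
#' 100% means) that are more common in early years than late ones.
#'
#' The defaults emulate the field being modelled: publication years
#' 2009-2019; a gentle latent decline from 2.5 to 0.8 (strong early effects
#' on naive species and cues, weaker later ones); zero prevalence falling
#' linearly from 0.4 in the first year to 0.02 in the last; and a mix of
#' percentage, proportion and continuous outcome scales.
#'
#' @param years Inclusive integer range of publication years.
#' @param studies_per_year Studies published per year (scalar or one value
#'   per year).
#' @param records_per_study Inclusive integer range of contrasts per study.
#' @param effect_schedule Schedule for the latent true lnRR magnitude
#'   `mu(year)` ([schedule_constant()], [schedule_linear()], or a function).
#' @param zero_schedule Schedule for the probability that a bounded-scale
#'   record is a floor record (its smaller mean forced to exactly 0).
#' @param bound_prob Given a floor record, probability the larger mean is
#'   likewise forced to the full bound (a 0% vs 100% contrast).
#' @param tau_true SD of between-study heterogeneity around `mu(year)`.
#' @param scale_mix Named probabilities over
#'   `c(percentage, proportion, continuous)`.
#' @param baseline_range Range (percent of bound) from which the geometric
#'   mean of the two arms is drawn on bounded scales; default 10-90 keeps
#'   typical ratios moderate and tiny non-zero means rare.
#' @param continuous_baseline Range for continuous-scale control means.
#' @param n_range Inclusive range of per-arm sample sizes.
#' @param cv_range Range of per-arm coefficients of variation generating
#'   SDs.
#' @param flag_rates Named probabilities for `sham`, `fluctuating_co2`,
#'   `procedural` (applied only in 2009-2010) and `opposite`.
#' @param attenuation_fluctuating Multiplier applied to the latent effect of
#'   fluctuating-CO2 records (daily CO2 cycles attenuate behavioural
#'   effects).
#' @param sham_sd SD of the near-zero latent effect of sham records.
#' @param co2_levels Treatment CO2 partial pressures (µatm) sampled
#'   uniformly.
#' @param sampling_noise Optionally perturb reported means with
#'   multiplicative lognormal noise whose log-scale SD matches the per-arm
#'   delta-method term `sd/(sqrt(n) * mean)`. Default `FALSE`: reported arm
#'   means are the latent arm means, so each record's lnRR equals its
#'   latent effect exactly and the delta-method variance is carried by the
#'   SD/n fields. Enabling noise makes records scatter around their latent
#'   effect but couples the recomputed variance estimates to the errors
#'   (the small-denominator weight instability the package exists to
#'   study), which degrades the calibration of downstream pooling.
#' @param max_retries Resampling attempts when a drawn latent effect cannot
#'   fit inside the scale bounds before a hard error.
#' @param seed Default seed used by [simulate_corpus()] when none is given.
#' @return A `corpus_config` object.
#' @export
corpus_config <- function(years = 2009:2019,
                          studies_per_year = 10,
                          records_per_study = c(1L, 3L),
                          effect_schedule = schedule_linear(2.5, 0.8),
                          zero_schedule = schedule_linear(0.4, 0.02),
                          bound_prob = 0.5,
                          tau_true = 0.3,
                          scale_mix = c(percentage = 0.6, proportion = 0.2, continuous = 0.2),
                          baseline_range = c(10, 90),
                          continuous_baseline = c(5, 50),
                          n_range = c(6L, 30L),
                          cv_range = c(0.2, 0.6),
                          flag_rates = c(sham = 0.05, fluctuating_co2 = 0.05,
                                         procedural = 0.05, opposite = 0.05),
                          attenuation_fluctuating = 0.3,
                          sham_sd = 0.05,
                          co2_levels = c(600, 750, 850, 1000, 1300),
                          sampling_noise = FALSE,
                          max_retries = 100L,
                          seed = 20221122) {
  years <- sort(as.integer(years))
  studies_per_year <- rep_len(as.integer(studies_per_year), length(years))
  stopifnot(
    length(years) >= 1, all(studies_per_year >= 1),
    length(records_per_study) == 2, records_per_study[1] >= 1,
    records_per_study[1] <= records_per_study[2],
    all(names(scale_mix) %in% SCALE_TYPES), abs(sum(scale_mix) - 1) < 1e-8,
    length(n_range) == 2, n_range[1] >= 2,
    length(cv_range) == 2, cv_range[1] >= 0,
    tau_true >= 0, bound_prob >= 0, bound_prob <= 1,
    all(flag_rates >= 0 & flag_rates <= 1),
    all(c("sham", "fluctuating_co2", "procedural", "opposite") %in% names(flag_rates)),
    baseline_range[1] > 0, baseline_range[2] < 100,
    baseline_range[1] <= baseline_range[2],
    all(co2_levels > 0), max_retries >= 1
  )
  zp <- resolve_schedule(zero_schedule, years)
  if (any(zp < 0 | zp > 1)) abort("Zero-prevalence schedule must stay in [0, 1] over the year range.")
  structure(
    list(years = years, studies_per_year = studies_per_year,
         records_per_study = as.integer(records_per_study),
         effect_schedule = effect_schedule, zero_schedule = zero_schedule,
         bound_prob = bound_prob, tau_true = tau_true, scale_mix = scale_mix,
         baseline_range = baseline_range, continuous_baseline = continuous_baseline,
         n_range = as.integer(n_range), cv_range = cv_range,
         flag_rates = flag_rates,
         attenuation_fluctuating = attenuation_fluctuating, sham_sd = sham_sd,
         co2_levels = co2_levels, sampling_noise = sampling_noise,
         max_retries = as.integer(max_retries), seed = seed),
    class = "corpus_config"
  )
}

SPECIES_POOL <- sprintf("species_%02d", 1:12)
LIFE_STAGES <- c("larva", "juvenile", "adult")
CUE_TYPES <- c("predator_cue", "alarm_cue", "habitat_cue", "none")
METRICS <- c("pct_time_in_cue_arm", "activity_level", "lateralization",
             "feeding_strikes", "boldness_score")

#' Simulate a synthetic study corpus
#'
#' Draws a full record table from a [corpus_config()]. For each record the
#' generator: assigns year, study, outcome scale, per-arm sample sizes and
#' CO2 level; draws a latent true lnRR from the effect schedule plus
#' `N(0, tau_true^2)` heterogeneity (sham records get a near-zero latent
#' effect, fluctuating-CO2 records an attenuated one); places the two arm
#' means symmetrically around a baseline so their log-ratio equals the
#' latent effect, resampling when the effect cannot fit inside the scale
#' bounds; derives SDs from per-arm coefficients of variation (binomial-
#' shaped `cv * sqrt(m (bound - m))` on bounded scales); and, with
#' the year's zero prevalence, converts bounded-scale records into floor
#' records (smaller mean exactly 0, SD 0; with probability `bound_prob` the
#' larger mean sits on the full bound).
#'
#' The same config and seed always produce the identical corpus.
#'
#' @param config A [corpus_config()].
#' @param seed Integer seed; defaults to the config's own.
#' @return A record tibble satisfying [validate_corpus()].
#' @examples
#' corpus <- simulate_corpus(corpus_config(seed = 42))
#' dplyr::count(corpus, scale_type)
#' @export
simulate_corpus <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "corpus_config"))
  with_local_seed(seed, simulate_corpus_impl(config))
}

simulate_corpus_impl <- function(config) {
  years <- config$years
  mu_by_year <- setNames(resolve_schedule(config$effect_schedule, years), years)
  zp_by_year <- setNames(resolve_schedule(config$zero_schedule, years), years)

  # one row per record slot
  slots <- purrr::map2_dfr(years, config$studies_per_year, function(yr, n_st) {
    n_rec <- sample(seq(config$records_per_study[1], config$records_per_study[2]),
                    n_st, replace = TRUE)
    tibble::tibble(
      year = yr,
      study = rep(seq_len(n_st), n_rec)
    )
  })
  n <- nrow(slots)
  slots$record_id <- sprintf("r%05d", seq_len(n))
  slots$study_id <- sprintf("s%d_%02d", slots$year, slots$study)

  scale_type <- sample(names(config$scale_mix), n, replace = TRUE,
                       prob = config$scale_mix)
  bound <- scale_bound(scale_type)
  n_c <- sample(seq(config$n_range[1], config$n_range[2]), n, replace = TRUE)
  n_t <- sample(seq(config$n_range[1], config$n_range[2]), n, replace = TRUE)
  cv_c <- runif(n, config$cv_range[1], config$cv_range[2])
  cv_t <- runif(n, config$cv_range[1], config$cv_range[2])
  co2 <- sample(config$co2_levels, n, replace = TRUE)

  is_sham <- runif(n) < config$flag_rates[["sham"]]
  is_fluct <- runif(n) < config$flag_rates[["fluctuating_co2"]]
  is_proc <- (slots$year <= min(years) + 1) &
    (runif(n) < config$flag_rates[["procedural"]])
  opposite <- runif(n) < config$flag_rates[["opposite"]]

  draw_latent <- function(idx) {
    l <- mu_by_year[as.character(slots$year[idx])] +
      rnorm(length(idx), 0, config$tau_true)
    l[is_sham[idx]] <- rnorm(sum(is_sham[idx]), 0, config$sham_sd)
    l[is_fluct[idx] & !is_sham[idx]] <-
      l[is_fluct[idx] & !is_sham[idx]] * config$attenuation_fluctuating
    unname(l)
  }
  latent <- draw_latent(seq_len(n))

  # Bounded scales: place the arms symmetrically about a geometric-mean
  # baseline g so treatment/control = exp(latent); resample latent draws
  # whose spread cannot fit below the bound.
  g_hi_for <- function(l, b) pmin(config$baseline_range[2] * b / 100,
                                  0.99 * b / exp(abs(l) / 2))
  bounded <- is_bounded_scale(scale_type)
  g_lo <- config$baseline_range[1] * bound / 100
  tries <- 0L
  repeat {
    infeasible <- bounded & (g_hi_for(latent, bound) < g_lo)
    if (!any(infeasible)) break
    tries <- tries + 1L
    if (tries > config$max_retries) {
      abort(sprintf(
        "Could not fit %d latent effect(s) inside the scale bounds after %d retries; shrink the effect schedule or the baseline range.",
        sum(infeasible), config$max_retries
      ))
    }
    latent[infeasible] <- draw_latent(which(infeasible))
  }

  control <- treatment <- numeric(n)
  bidx <- which(bounded)
  g <- runif(length(bidx), g_lo[bidx],
             g_hi_for(latent[bidx], bound[bidx]))
  control[bidx] <- g * exp(-latent[bidx] / 2)
  treatment[bidx] <- g * exp(latent[bidx] / 2)
  cont <- !bounded
  control[cont] <- runif(sum(cont), config$continuous_baseline[1],
                         config$continuous_baseline[2])
  treatment[cont] <- control[cont] * exp(latent[cont])

  sd_for <- function(m, cv) ifelse(bounded, cv * sqrt(pmax(m * (bound - m), 0)), cv * m)
  control_sd <- sd_for(control, cv_c)
  treatment_sd <- sd_for(treatment, cv_t)

  if (config$sampling_noise) {
    noisy <- function(m, s, nn) {
      sdlog <- pmin(s / (sqrt(nn) * m), 0.5) # cap: reported means of bounded assays are not arbitrarily dispersed
      out <- m * exp(rnorm(n, 0, sdlog))
      ifelse(bounded, pmin(out, bound * (1 - 1e-9)), out)
    }
    control <- noisy(control, control_sd, n_c)
    treatment <- noisy(treatment, treatment_sd, n_t)
  }

  # floor/ceiling records on bounded scales, per the year's zero prevalence
  zp <- unname(zp_by_year[as.character(slots$year)])
  make_zero <- bounded & (runif(n) < zp)
  also_bound <- make_zero & (runif(n) < config$bound_prob)
  if (any(make_zero)) {
    ctrl_smaller <- control <= treatment
    z_ctrl <- make_zero & ctrl_smaller
    z_trt <- make_zero & !ctrl_smaller
    control[z_ctrl] <- 0; control_sd[z_ctrl] <- 0
    treatment[z_trt] <- 0; treatment_sd[z_trt] <- 0
    b_ctrl <- also_bound & !ctrl_smaller
    b_trt <- also_bound & ctrl_smaller
    control[b_ctrl] <- bound[b_ctrl]; control_sd[b_ctrl] <- 0
    treatment[b_trt] <- bound[b_trt]; treatment_sd[b_trt] <- 0
  }

  year_print <- pmin(slots$year + (runif(n) < 0.3), max(years))

  tibble::tibble(
    record_id = slots$record_id,
    study_id = slots$study_id,
    year_online = slots$year,
    year_print = as.integer(year_print),
    scale_type = scale_type,
    control_mean = control,
    treatment_mean = treatment,
    control_sd = control_sd,
    treatment_sd = treatment_sd,
    control_n = n_c,
    treatment_n = n_t,
    co2_uatm = co2,
    year = slots$year,
    species = sample(SPECIES_POOL, n, replace = TRUE),
    life_stage = sample(LIFE_STAGES, n, replace = TRUE),
    cue_type = sample(CUE_TYPES, n, replace = TRUE),
    behaviour_metric = sample(METRICS, n, replace = TRUE),
    is_sham = is_sham,
    is_fluctuating_co2 = is_fluct,
    is_procedural_control = is_proc,
    direction_opposite = opposite
  )
}
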