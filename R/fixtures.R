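#' Canonical fixture corpora with their expected behaviour
#'
#' Three named fixtures exercise the pipeline's load-bearing claims:
#' \describe{
#'   \item{`worked_example`}{a single percentage-scale record with control
#'     mean 0% and treatment mean 100%. Its expected lnRR under the three
#'     preset policies is attached: ln(99/1) = 4.6 (c = 1),
#'     ln(99.9/0.1) = 6.9 (c = 0.1), ln(99.9999/0.0001) = 13.8
#'     (c = 0.0001).}
#'   \item{`no_zeros_flat`}{a simulated corpus with constant latent effect
#'     1, zero prevalence 0 and no curation flags — every replacement policy
#'     must yield an identical effects table on it.}
#'   \item{`early_zeros_constant_effect`}{the artifact-demonstration corpus:
#'     constant latent effect 1 but zero prevalence falling from 0.4 to
#'     0.02 across 2009-2019. Tiny replacement constants manufacture a
#'     decline here even though the truth is flat.}
#' }
#'
#' @param name Fixture name (see above).
#' @param seed Seed for the simulated fixtures.
#' @return A list with `corpus` (record tibble), `config` (the generator
#'   config, `NULL` for the hand-built fixture) and `expected` (tibble of
#'   expected quantities, where the fixture pins any).
#' @examples
#' fx <- make_fixture("worked_example")
#' fx$expected
#' @export
make_fixture <- function(name = c("worked_example", "no_zeros_flat",
                                  "early_zeros_constant_effect"),
                         seed = 20221122) {
  valid <- c("worked_example", "no_zeros_flat", "early_zeros_constant_effect")
  if (!is.character(name) || length(name) != 1 || !name %in% valid) {
    abort(sprintf("Unknown fixture '%s'. Valid names: %s.",
                  paste(name, collapse = ", "), paste(valid, collapse = ", ")))
  }

  if (name == "worked_example") {
    corpus <- tibble::tibble(
      record_id = "worked_example", study_id = "s_worked",
      year_online = 2009L, year_print = 2009L, scale_type = "percentage",
      control_mean = 0, treatment_mean = 100,
      control_sd = 0, treatment_sd = 0,
      control_n = 10L, treatment_n = 10L, co2_uatm = 1000,
      year = 2009L,
      species = NA_character_, life_stage = NA_character_,
      cue_type = NA_character_, behaviour_metric = NA_character_,
      is_sham = FALSE, is_fluctuating_co2 = FALSE,
      is_procedural_control = FALSE, direction_opposite = FALSE
    )
    expected <- tibble::tibble(
      policy = c("munday_whole", "munday_mid", "clements"),
      percentage_c = c(1, 0.1, 0.0001),
      lnrr = c(log(99 / 1), log(99.9 / 0.1), log(99.9999 / 0.0001)),
      printed = c(4.6, 6.9, 13.8)
    )
    return(list(corpus = corpus, config = NULL, expected = expected))
  }

  flat_flags <- c(sham = 0, fluctuating_co2 = 0, procedural = 0, opposite = 0)
  config <- switch(name,
    no_zeros_flat = corpus_config(
      effect_schedule = schedule_constant(1),
      zero_schedule = schedule_constant(0),
      flag_rates = flat_flags, seed = seed
    ),
    early_zeros_constant_effect = corpus_config(
      effect_schedule = schedule_constant(1),
      zero_schedule = schedule_linear(0.4, 0.02),
      flag_rates = flat_flags, seed = seed
    )
  )
  corpus <- simulate_corpus(config, seed = seed)
  expected <- switch(name,
    no_zeros_flat = tibble::tibble(
      property = "policy_invariance",
      detail = "all replacement policies yield identical effects tables"
    ),
    early_zeros_constant_effect = tibble::tibble(
      property = "artifact_reproduction",
      detail = "decline_ratio under c = 0.0001 exceeds decline_ratio under c = 1 despite constant truth"
    )
  )
  list(corpus = corpus, config = config, expected = expected)
}
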