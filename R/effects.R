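#' Compute lnRR effect sizes and delta-method sampling variances
#'
#' For each record, applies the zero-replacement policy ([apply_replacement()])
#' and computes the log response ratio
#' \deqn{\mathrm{lnRR} = \ln(\bar{x}_T / \bar{x}_C)}
#' together with its delta-method sampling variance
#' \deqn{v = \frac{s_T^2}{n_T \bar{x}_T^2} + \frac{s_C^2}{n_C \bar{x}_C^2},}
#' evaluated at the replacement-adjusted means. Records whose SDs are zero in
#' both arms (typical for 0% vs 100% contrasts) get `variance = 0` and are
#' flagged `usable_weight = FALSE`; downstream pooling applies a variance
#' floor to them (see [yearly_weighted_means()]).
#'
#' @param records A validated record tibble ([read_corpus()],
#'   [simulate_corpus()]).
#' @param policy A [replacement_policy()] or preset name.
#' @param year_source Which year column to carry as the analysis year when
#'   the corpus has no precomputed `year` column: `"online"` or `"print"`.
#' @return A tibble with one row per record: `record_id`, `year`, `lnrr`
#'   (signed), `variance`, `magnitude` (`|lnrr|`), `usable_weight`, the
#'   policy name, and the replacement provenance flags.
#' @examples
#' rec <- tibble::tibble(
#'   record_id = "r1", scale_type = "percentage",
#'   control_mean = 0, treatment_mean = 100,
#'   control_sd = 0, treatment_sd = 0, control_n = 10L, treatment_n = 10L,
#'   year = 2009L
#' )
#' compute_lnrr(rec, "munday_whole")$lnrr # log(99/1) = 4.595
#' @export
compute_lnrr <- function(records, policy, year_source = c("online", "print")) {
  policy <- as_policy(policy)
  records <- tibble::as_tibble(records)
  if (!"year" %in% names(records)) {
    year_source <- match.arg(year_source)
    ycol <- paste0("year_", year_source)
    if (!ycol %in% names(records)) abort(sprintf("No 'year' or '%s' column in records.", ycol))
    records$year <- records[[ycol]]
  }
  adj <- apply_replacement(records, policy)
  if (any(adj$control_mean <= 0 | adj$treatment_mean <= 0)) {
    abort("Adjusted mean <= 0 after replacement: the policy is misconfigured for this corpus.")
  }
  lnrr <- log(adj$treatment_mean / adj$control_mean)
  variance <- adj$treatment_sd^2 / (adj$treatment_n * adj$treatment_mean^2) +
    adj$control_sd^2 / (adj$control_n * adj$control_mean^2)
  tibble::tibble(
    record_id = adj$record_id,
    year = as.integer(adj$year),
    lnrr = lnrr,
    variance = variance,
    magnitude = abs(lnrr),
    usable_weight = variance > 0,
    policy = policy$name,
    control_adjusted = adj$control_adjusted,
    treatment_adjusted = adj$treatment_adjusted
  )
}

#' Analytic inflation curve: lnRR as a function of the control value
#'
#' Shows how |lnRR| blows up as the denominator shrinks below 1 on a
#' percentage scale. For each treatment value and each control value in the
#' grid, computes `lnrr = ln(treatment_adj / control)`, where a treatment
#' sitting on the upper bound (100) is adjusted symmetrically to
#' `100 - control` — the control value plays the role of the replacement
#' constant, so the curve traces exactly the worked series
#' ln(99/1) = 4.6, ln(99.9/0.1) = 6.9, ln(99.9999/0.0001) = 13.8.
#'
#' @param treatments Treatment means in percent (default `c(50, 100)`).
#' @param control_grid Control values strictly inside (0, 100), interpreted
#'   as candidate replacement values for a true control of 0. Default: a
#'   log-spaced grid from 0.0001 to 5.
#' @return A tibble `(treatment, control, lnrr)`, ordered by treatment then
#'   descending control.
#' @examples
#' curve <- inflation_curve(100, c(5, 1, 0.1, 0.0001))
#' curve$lnrr # strictly increasing as the control shrinks
#' @export
inflation_curve <- function(treatments = c(50, 100),
                            control_grid = 10^seq(log10(1e-4), log10(5), length.out = 200)) {
  if (any(control_grid <= 0)) abort("Control grid values must be strictly positive.")
  if (any(control_grid >= 100)) abort("Control grid values must be strictly below 100.")
  if (any(treatments <= 0 | treatments > 100)) abort("Treatments must lie in (0, 100].")
  grid <- tidyr::expand_grid(
    treatment = sort(treatments),
    control = sort(control_grid, decreasing = TRUE)
  )
  grid$lnrr <- log(
    ifelse(grid$treatment == 100, 100 - grid$control, grid$treatment) / grid$control
  )
  grid
}
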