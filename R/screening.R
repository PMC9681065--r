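#' Define an inclusion/exclusion rule set for corpus screening
#'
#' Screening operates on curation flags carried by each record (the flags
#' encode expert judgements that cannot be recomputed from the numbers):
#' sham treatments (procedural stimuli expected to show no effect),
#' fluctuating-CO2 treatments (daily CO2 cycles that attenuate behavioural
#' effects), procedural controls, opposite-direction results, and a minimum
#' CO2 exposure threshold.
#'
#' @param exclude_sham Drop records flagged `is_sham`?
#' @param exclude_fluctuating_co2 Drop records flagged `is_fluctuating_co2`?
#' @param exclude_procedural_controls Drop records flagged
#'   `is_procedural_control`?
#' @param include_opposite_direction Retain records whose treatment response
#'   direction differs from the control's? When `FALSE` such records are
#'   excluded (these are often the strongest treatment effects, so excluding
#'   them biases pooled effects downward).
#' @param min_co2_uatm Minimum CO2 partial pressure (µatm) for a record to
#'   count as a strong-exposure contrast, or `NA` for no floor.
#' @param name Label carried through reports and comparison tables.
#' @return An object of class `screening_rules`.
#' @seealso [preset_rulesets()], [screen_corpus()].
#' @export
screening_rules <- function(exclude_sham = FALSE,
                            exclude_fluctuating_co2 = FALSE,
                            exclude_procedural_controls = FALSE,
                            include_opposite_direction = TRUE,
                            min_co2_uatm = NA_real_,
                            name = "custom") {
  stopifnot(
    is.logical(exclude_sham), is.logical(exclude_fluctuating_co2),
    is.logical(exclude_procedural_controls), is.logical(include_opposite_direction)
  )
  if (!is.na(min_co2_uatm) && min_co2_uatm < 0) abort("`min_co2_uatm` must be >= 0.")
  structure(
    list(exclude_sham = exclude_sham,
         exclude_fluctuating_co2 = exclude_fluctuating_co2,
         exclude_procedural_controls = exclude_procedural_controls,
         include_opposite_direction = include_opposite_direction,
         min_co2_uatm = min_co2_uatm,
         name = name),
    class = "screening_rules"
  )
}

#' @export
print.screening_rules <- function(x, ...) {
  on <- c(
    if (x$exclude_sham) "exclude sham",
    if (x$exclude_fluctuating_co2) "exclude fluctuating CO2",
    if (x$exclude_procedural_controls) "exclude procedural controls",
    if (!x$include_opposite_direction) "exclude opposite-direction",
    if (!is.na(x$min_co2_uatm)) sprintf("CO2 >= %g uatm", x$min_co2_uatm)
  )
  cat(sprintf("<screening_rules '%s'> %s\n", x$name,
              if (length(on)) paste(on, collapse = "; ") else "no exclusions"))
  invisible(x)
}

#' Named screening rule sets for the reanalysis contrast
#'
#' \describe{
#'   \item{`munday_screened`}{Excludes sham and fluctuating-CO2 treatments,
#'     retains opposite-direction results, no CO2 floor — the corrected
#'     screening.}
#'   \item{`munday_high_co2`}{As above, restricted to contrasts at
#'     >= 800 µatm CO2.}
#'   \item{`clements_like`}{Keeps sham and fluctuating-CO2 treatments,
#'     excludes opposite-direction results, and drops procedural controls —
#'     mirrors the inclusions/exclusions the reanalysis critiques.}
#' }
#'
#' @param name Optional single preset name; omit to get all presets.
#' @return A named list of [screening_rules()], or one rule set when `name`
#'   is given.
#' @examples
#' preset_rulesets("munday_high_co2")$min_co2_uatm
#' @export
preset_rulesets <- function(name = NULL) {
  presets <- list(
    munday_screened = screening_rules(
      exclude_sham = TRUE, exclude_fluctuating_co2 = TRUE,
      exclude_procedural_controls = FALSE, include_opposite_direction = TRUE,
      min_co2_uatm = NA_real_, name = "munday_screened"
    ),
    munday_high_co2 = screening_rules(
      exclude_sham = TRUE, exclude_fluctuating_co2 = TRUE,
      exclude_procedural_controls = FALSE, include_opposite_direction = TRUE,
      min_co2_uatm = 800, name = "munday_high_co2"
    ),
    clements_like = screening_rules(
      exclude_sham = FALSE, exclude_fluctuating_co2 = FALSE,
      exclude_procedural_controls = TRUE, include_opposite_direction = FALSE,
      min_co2_uatm = NA_real_, name = "clements_like"
    )
  )
  if (is.null(name)) return(presets)
  if (!name %in% names(presets)) {
    abort(sprintf("Unknown ruleset preset '%s'. Valid presets: %s.",
                  name, paste(names(presets), collapse = ", ")))
  }
  presets[[name]]
}

as_ruleset <- function(rules) {
  if (inherits(rules, "screening_rules")) return(rules)
  if (is.character(rules) && length(rules) == 1) return(preset_rulesets(rules))
  abort("`rules` must be a screening_rules object or a preset name.")
}

#' Screen a corpus against a rule set, with an audit trail
#'
#' A record is excluded iff it trips an enabled rule. For the audit report
#' each exclusion is attributed to the **first** matching rule in the fixed
#' order sham -> fluctuating CO2 -> procedural control -> CO2 threshold ->
#' opposite direction, so the per-rule counts always sum to
#' `n_input - n_included`.
#'
#' @param records A record tibble.
#' @param rules A [screening_rules()] object or preset name.
#' @return The included records, with attribute `"screening_report"` (class
#'   `screening_report`: totals, per-rule exclusion counts, excluded ids
#'   grouped by triggering rule), retrievable via [screening_report()].
#' @examples
#' corpus <- simulate_corpus(corpus_config(seed = 1))
#' kept <- screen_corpus(corpus, "munday_screened")
#' screening_report(kept)
#' @export
screen_corpus <- function(records, rules) {
  rules <- as_ruleset(rules)
  records <- tibble::as_tibble(records)

  rule_hits <- list(
    sham = rules$exclude_sham & records$is_sham,
    fluctuating_co2 = rules$exclude_fluctuating_co2 & records$is_fluctuating_co2,
    procedural_control = rules$exclude_procedural_controls & records$is_procedural_control,
    co2_threshold = if (is.na(rules$min_co2_uatm)) rep(FALSE, nrow(records))
                    else records$co2_uatm < rules$min_co2_uatm,
    opposite_direction = (!rules$include_opposite_direction) & records$direction_opposite
  )

  attributed <- rep(NA_character_, nrow(records))
  for (rule in names(rule_hits)) {
    hit <- rule_hits[[rule]] & is.na(attributed)
    attributed[hit] <- rule
  }
  keep <- is.na(attributed)

  excluded_ids <- split(records$record_id[!keep], attributed[!keep])
  per_rule <- tibble::tibble(
    rule = names(rule_hits),
    n_excluded = unname(vapply(names(rule_hits),
                               function(r) sum(attributed == r, na.rm = TRUE),
                               integer(1)))
  )
  report <- structure(
    list(ruleset = rules$name, n_input = nrow(records), n_included = sum(keep),
         per_rule = per_rule, excluded_ids = excluded_ids),
    class = "screening_report"
  )
  included <- records[keep, , drop = FALSE]
  attr(included, "screening_report") <- report
  included
}

#' Retrieve the audit report attached by [screen_corpus()]
#' @param screened A tibble returned by [screen_corpus()].
#' @return The `screening_report` object.
#' @export
screening_report <- function(screened) attr(screened, "screening_report")

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("<screening_report '%s'> %d input, %d included, %d excluded\n",
              x$ruleset, x$n_input, x$n_included, x$n_input - x$n_included))
  shown <- x$per_rule[x$per_rule$n_excluded > 0, ]
  if (nrow(shown)) print(shown)
  invisible(x)
}

#' @export
tidy.screening_report <- function(x, ...) x$per_rule
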