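#' Define a zero-replacement policy for bounded outcome scales
#'
#' lnRR = ln(treatment mean / control mean) is undefined when either mean is
#' exactly zero, which happens routinely for behavioural outcomes recorded as
#' percentages or proportions (floor and ceiling effects). A replacement
#' policy substitutes a small positive constant `c` for zeros — and, when
#' `symmetric_upper = TRUE`, substitutes `bound - c` for means sitting on the
#' upper bound (100 for percentages, 1 for proportions). The choice of `c`
#' is consequential: the smaller it is, the more |lnRR| is inflated for
#' bound-valued records.
#'
#' @param percentage_c Replacement constant for zeros on the 0-100 scale;
#'   must lie in (0, 50).
#' @param proportion_c Replacement constant for zeros on the 0-1 scale;
#'   must lie in (0, 0.5).
#' @param symmetric_upper Also replace upper-bound means by `bound - c`?
#'   Default `TRUE`, matching the arithmetic convention in which a 0% vs 100%
#'   contrast becomes, e.g., 1 vs 99.
#' @param name Label carried through result tables.
#' @return An object of class `replacement_policy`.
#' @seealso [policy_presets()] for the named policies compared in the
#'   sensitivity analysis, [apply_replacement()], [compute_lnrr()].
#' @examples
#' replacement_policy(percentage_c = 0.1, proportion_c = 0.001)
#' @export
replacement_policy <- function(percentage_c, proportion_c,
                               symmetric_upper = TRUE, name = "custom") {
  stopifnot(is.numeric(percentage_c), length(percentage_c) == 1,
            is.numeric(proportion_c), length(proportion_c) == 1,
            is.logical(symmetric_upper), length(symmetric_upper) == 1)
  if (!(percentage_c > 0 && percentage_c < 50)) {
    abort("`percentage_c` must lie in (0, 50): a ratio with a zero (or a negative control) is undefined.")
  }
  if (!(proportion_c > 0 && proportion_c < 0.5)) {
    abort("`proportion_c` must lie in (0, 0.5).")
  }
  structure(
    list(percentage_c = percentage_c, proportion_c = proportion_c,
         symmetric_upper = symmetric_upper, name = name),
    class = "replacement_policy"
  )
}

#' @export
print.replacement_policy <- function(x, ...) {
  cat(sprintf(
    "<replacement_policy '%s'>  percentage c = %g, proportion c = %g, symmetric upper bound: %s\n",
    x$name, x$percentage_c, x$proportion_c, x$symmetric_upper
  ))
  invisible(x)
}

#' Named zero-replacement policies compared in the sensitivity analysis
#'
#' Three conventions for replacing bound values on percentage (0-100) and
#' proportion (0-1) scales:
#' \describe{
#'   \item{`clements`}{c = 0.0001 on both scales — the tiny four-decimal
#'     replacement that inflates |lnRR| most strongly.}
#'   \item{`munday_mid`}{c = 0.1 for percentages, 0.001 for proportions —
#'     a moderate correction.}
#'   \item{`munday_whole`}{c = 1 for percentages, 0.01 for proportions —
#'     the smallest whole number on the percentage scale.}
#' }
#' All presets replace the upper bound symmetrically (`bound - c`).
#'
#' @param name Optional single preset name; omit to get all presets.
#' @return A named list of [replacement_policy()] objects, or a single policy
#'   when `name` is given.
#' @examples
#' policy_presets("clements")
#' names(policy_presets())
#' @export
policy_presets <- function(name = NULL) {
  presets <- list(
    clements     = replacement_policy(0.0001, 0.0001, TRUE, name = "clements"),
    munday_mid   = replacement_policy(0.1, 0.001, TRUE, name = "munday_mid"),
    munday_whole = replacement_policy(1, 0.01, TRUE, name = "munday_whole")
  )
  if (is.null(name)) return(presets)
  if (!name %in% names(presets)) {
    abort(sprintf("Unknown policy preset '%s'. Valid presets: %s.",
                  name, paste(names(presets), collapse = ", ")))
  }
  presets[[name]]
}

as_policy <- function(policy) {
  if (inherits(policy, "replacement_policy")) return(policy)
  if (is.character(policy) && length(policy) == 1) return(policy_presets(policy))
  abort("`policy` must be a replacement_policy object or a preset name.")
}

policy_c <- function(policy, scale_type) {
  ifelse(scale_type == "percentage", policy$percentage_c,
         ifelse(scale_type == "proportion", policy$proportion_c, NA_real_))
}

#' Apply a zero-replacement policy to study records
#'
#' Moves bound-valued means off the bounds of their scale: a mean of exactly
#' 0 becomes `c`, and (when the policy is bound-symmetric) a mean of exactly
#' 100 (percentage) or 1 (proportion) becomes `bound - c`. Continuous-scale
#' records pass through untouched; interior values on bounded scales are
#' never modified. Standard deviations are left as recorded — the policy
#' adjusts means only.
#'
#' @param records A study-record data frame (see [read_corpus()] or
#'   [simulate_corpus()] for the column contract).
#' @param policy A [replacement_policy()] or preset name.
#' @return The records tibble with adjusted means and two provenance columns,
#'   `control_adjusted` and `treatment_adjusted`, marking which arms were
#'   moved off a bound.
#' @examples
#' rec <- tibble::tibble(
#'   record_id = "r1", scale_type = "percentage",
#'   control_mean = 0, treatment_mean = 100
#' )
#' apply_replacement(rec, policy_presets("munday_whole"))
#' @export
apply_replacement <- function(records, policy) {
  policy <- as_policy(policy)
  records <- tibble::as_tibble(records)
  stopifnot(all(c("scale_type", "control_mean", "treatment_mean") %in% names(records)))

  bad_cont <- is_zero_continuous(records)
  if (any(bad_cont)) {
    abort(paste0(
      "lnRR is undefined for continuous-scale records with a mean of exactly 0 ",
      "(records: ", paste(head(records$record_id[bad_cont], 5), collapse = ", "),
      "). Replacement policies apply to bounded scales only; screen these records out."
    ))
  }

  bound <- scale_bound(records$scale_type)
  cval <- policy_c(policy, records$scale_type)
  bounded <- is_bounded_scale(records$scale_type)

  adj_arm <- function(mean) {
    at_zero <- bounded & mean == 0
    at_top <- bounded & policy$symmetric_upper & mean == bound
    adj <- mean
    adj[at_zero] <- cval[at_zero]
    adj[at_top] <- bound[at_top] - cval[at_top]
    list(mean = adj, touched = at_zero | at_top)
  }

  ctrl <- adj_arm(records$control_mean)
  trt <- adj_arm(records$treatment_mean)
  records$control_mean <- ctrl$mean
  records$treatment_mean <- trt$mean
  records$control_adjusted <- ctrl$touched
  records$treatment_adjusted <- trt$touched
  records
}

is_zero_continuous <- function(records) {
  records$scale_type == "continuous" &
    (records$control_mean == 0 | records$treatment_mean == 0)
}
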