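# Scale bounds for the two bounded outcome scales.
scale_bound <- function(scale_type) {
  dplyr::case_match(scale_type,
    "percentage" ~ 100,
    "proportion" ~ 1,
    "continuous" ~ NA_real_
  )
}

is_bounded_scale <- function(scale_type) scale_type %in% c("percentage", "proportion")

#' Derive a reproducible integer seed from a master seed and a label
#'
#' Deterministically mixes a character label into a master seed so that
#' independent analysis cells (for example the policy-by-ruleset cells of a
#' sensitivity grid) each get their own stream, and adding a new cell never
#' perturbs the seeds of existing ones.
#'
#' @param master_seed Integer master seed.
#' @param label Character string identifying the cell/stream.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @examples
#' derive_seed(1, "clements|munday_screened")
#' @export
derive_seed <- function(master_seed, label) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1, is.character(label))
  m <- 2147483647 # 2^31 - 1, keeps products < 2^53 in double arithmetic
  h <- 0
  for (code in utf8ToInt(label)) h <- (h * 31 + code) %% m
  as.integer((abs(master_seed) + h) %% m)
}

# Evaluate a schedule (constant or function of year) at given years.
eval_schedule <- function(schedule, years) {
  if (is.function(schedule)) {
    vapply(years, schedule, numeric(1))
  } else {
    rep_len(as.numeric(schedule), length(years))
  }
}

# Run an expression with a local RNG state: seeds deterministically,
# restores the caller's .Random.seed afterwards.
with_local_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  force(code)
}
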