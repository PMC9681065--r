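# Floor zero sampling variances at the smallest positive variance in the
# set (0% vs 100% contrasts typically carry sd = 0 in both arms; an exact
# zero variance would get infinite weight).
floor_variances <- function(effects, quiet = FALSE) {
  v <- effects$variance
  if (any(!is.finite(v))) abort("Non-finite sampling variance in effects table.")
  zero <- v <= 0
  if (any(zero)) {
    pos <- v[v > 0]
    if (!length(pos)) abort("All effects have zero sampling variance; nothing to floor against.")
    effects$variance[zero] <- min(pos)
    if (!quiet) {
      inform(sprintf("Variance floor applied to %d effect(s) at v = %.3g.",
                     sum(zero), min(pos)))
    }
  }
  attr(effects, "n_floored") <- sum(zero)
  effects
}

# Inverse-variance pooling of a single group of effects.
# model "fixed": weights 1/v. model "random_dl": DerSimonian-Laird moment
# estimator tau2 = max(0, (Q - df) / (sum(w) - sum(w^2)/sum(w))) with
# w = 1/v, then weights 1/(v + tau2).
pool_effects <- function(y, v, model = c("random_dl", "fixed")) {
  model <- match.arg(model)
  stopifnot(length(y) == length(v), length(y) >= 1, all(v > 0))
  w <- 1 / v
  mu_fe <- sum(w * y) / sum(w)
  tau2 <- 0
  if (model == "random_dl" && length(y) > 1) {
    q <- sum(w * (y - mu_fe)^2)
    df <- length(y) - 1
    denom <- sum(w) - sum(w^2) / sum(w)
    if (denom > 0) tau2 <- max(0, (q - df) / denom)
  }
  w_star <- 1 / (v + tau2)
  mu <- sum(w_star * y) / sum(w_star)
  se <- sqrt(1 / sum(w_star))
  list(mean = mu, se = se, tau2 = tau2, k = length(y))
}

#' Variance-weighted mean effect sizes by publication year
#'
#' Pools the signed lnRR values within each analysis year using
#' inverse-variance weights, so experiments with smaller sampling variance
#' get greater weight. Two pooling models:
#' \describe{
#'   \item{`fixed`}{weights \eqn{w_i = 1/v_i}; pooled mean
#'     \eqn{\sum w_i y_i / \sum w_i}, SE \eqn{\sqrt{1/\sum w_i}}.}
#'   \item{`random_dl`}{(default) DerSimonian-Laird random-effects: the
#'     between-study variance \eqn{\tau^2} is estimated by the moment
#'     estimator from the heterogeneity statistic Q (truncated at 0) and
#'     weights become \eqn{1/(v_i + \tau^2)}.}
#' }
#' 95% confidence limits are `mean +/- 1.96 * se`. Effects with zero
#' sampling variance are floored at the smallest positive variance in the
#' input (logged). Years with no effects are omitted, not emitted as zeros.
#'
#' @param effects An effects tibble from [compute_lnrr()] (columns `year`,
#'   `lnrr`, `variance`; a `magnitude` column is used when
#'   `response = "magnitude"`).
#' @param model `"random_dl"` (default) or `"fixed"`.
#' @param response Pool the `"signed"` lnRR (default) or its `"magnitude"`.
#' @return A tibble with one row per observed year: `year`, `k`,
#'   `pooled_mean`, `pooled_se`, `ci_low`, `ci_high`, `tau2`, `model`.
#' @examples
#' eff <- tibble::tibble(year = c(2009L, 2009L), lnrr = c(1, 3),
#'                       variance = c(1, 1), magnitude = c(1, 3))
#' yearly_weighted_means(eff, model = "fixed")
#' @export
yearly_weighted_means <- function(effects, model = c("random_dl", "fixed"),
                                  response = c("signed", "magnitude")) {
  model <- match.arg(model)
  response <- match.arg(response)
  stopifnot(all(c("year", "lnrr", "variance") %in% names(effects)))
  if (nrow(effects) == 0) {
    return(tibble::tibble(year = integer(), k = integer(), pooled_mean = double(),
                          pooled_se = double(), ci_low = double(), ci_high = double(),
                          tau2 = double(), model = character()))
  }
  effects <- floor_variances(tibble::as_tibble(effects))
  y <- if (response == "magnitude") abs(effects$lnrr) else effects$lnrr
  z <- qnorm(0.975)
  dat <- tibble::tibble(year = as.integer(effects$year), y = y, v = effects$variance)
  out <- purrr::map_dfr(split(dat, dat$year), function(g) {
    p <- pool_effects(g$y, g$v, model)
    tibble::tibble(year = g$year[1], k = p$k, pooled_mean = p$mean,
                   pooled_se = p$se, ci_low = p$mean - z * p$se,
                   ci_high = p$mean + z * p$se, tau2 = p$tau2, model = model)
  })
  dplyr::arrange(out, .data$year)
}
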