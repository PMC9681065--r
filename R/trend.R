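#' Loess trend of effect sizes over publication year, with decline metrics
#'
#' Fits a locally weighted regression (degree 1) of effect-size magnitude
#' (or signed lnRR) on publication year, with 95% confidence bounds obtained
#' by a percentile bootstrap over records. Alongside the smooth curve it
#' reports the decline diagnostics used to compare replacement policies:
#' \describe{
#'   \item{`early_mean` / `late_mean`}{variance-weighted pooled effect over
#'     the first two and last two observed years;}
#'   \item{`decline_ratio`}{`early_mean / late_mean` — values above 1
#'     indicate a decline;}
#'   \item{`weighted_slope`}{slope of the inverse-variance-weighted linear
#'     regression of the response on year.}
#' }
#'
#' @param effects Effects tibble from [compute_lnrr()]; at least 10 effects
#'   spanning at least 3 distinct years.
#' @param span Loess span in (0, 1]; default 0.75.
#' @param boot_reps Bootstrap resamples for the confidence band; default
#'   1000. Use 0 to skip the band (curve and metrics only).
#' @param seed Integer seed making the bootstrap reproducible; default
#'   20221122.
#' @param response Trend the `"magnitude"` (default) or the `"signed"` lnRR.
#' @param model Pooling model for the yearly summaries and the early/late
#'   means ([yearly_weighted_means()]).
#' @param grid_points Number of evaluation points across the year range.
#' @return An object of class `lnrr_trend`: list with `curve` (tibble of
#'   `year`, `fitted`, `ci_low`, `ci_high`), `yearly` (the
#'   [yearly_weighted_means()] table), `metrics` (one-row tibble of the
#'   decline diagnostics) and `params`. Supports [tidy()], [glance()],
#'   [autoplot()].
#' @examples
#' corpus <- simulate_corpus(corpus_config(seed = 7))
#' eff <- compute_lnrr(corpus, "munday_mid")
#' tr <- loess_trend(eff, boot_reps = 25)
#' glance(tr)
#' @export
loess_trend <- function(effects, span = 0.75, boot_reps = 1000,
                        seed = 20221122,
                        response = c("magnitude", "signed"),
                        model = c("random_dl", "fixed"),
                        grid_points = 80) {
  response <- match.arg(response)
  model <- match.arg(model)
  if (!(span > 0 && span <= 1)) abort("`span` must lie in (0, 1].")
  effects <- floor_variances(tibble::as_tibble(effects))
  n_years <- dplyr::n_distinct(effects$year)
  if (nrow(effects) < 10 || n_years < 3) {
    abort(sprintf(
      "Loess trend needs at least 10 effects over at least 3 distinct years (got %d effects, %d years).",
      nrow(effects), n_years
    ))
  }

  y <- if (response == "magnitude") abs(effects$lnrr) else effects$lnrr
  dat <- tibble::tibble(year = as.numeric(effects$year), y = y, v = effects$variance)
  grid <- seq(min(dat$year), max(dat$year), length.out = grid_points)

  fit_curve <- function(d) {
    fit <- suppressWarnings(
      loess(y ~ year, data = d, span = span, degree = 1,
            family = "gaussian", surface = "direct")
    )
    as.numeric(predict(fit, newdata = data.frame(year = grid)))
  }
  fitted <- fit_curve(dat)

  ci_low <- ci_high <- rep(NA_real_, length(grid))
  n_boot_failed <- 0L
  if (boot_reps > 0) {
    boot <- with_local_seed(seed, {
      replicate(boot_reps, {
        idx <- sample.int(nrow(dat), replace = TRUE)
        tryCatch(fit_curve(dat[idx, ]), error = function(e) rep(NA_real_, length(grid)))
      })
    })
    n_boot_failed <- sum(apply(boot, 2, function(col) all(is.na(col))))
    ci_low <- apply(boot, 1, quantile, probs = 0.025, na.rm = TRUE)
    ci_high <- apply(boot, 1, quantile, probs = 0.975, na.rm = TRUE)
  }

  yearly <- yearly_weighted_means(effects, model = model, response = response)
  years_obs <- sort(unique(as.integer(effects$year)))
  early_years <- head(years_obs, 2)
  late_years <- tail(years_obs, 2)
  pool_span <- function(yrs) {
    sel <- as.integer(effects$year) %in% yrs
    p <- pool_effects(y[sel], effects$variance[sel], model)
    p$mean
  }
  early_mean <- pool_span(early_years)
  late_mean <- pool_span(late_years)
  wfit <- lm(y ~ year, data = dat, weights = 1 / dat$v)

  structure(
    list(
      curve = tibble::tibble(year = grid, fitted = fitted,
                             ci_low = ci_low, ci_high = ci_high),
      yearly = yearly,
      metrics = tibble::tibble(
        early_mean = early_mean, late_mean = late_mean,
        decline_ratio = early_mean / late_mean,
        weighted_slope = unname(coef(wfit)[["year"]]),
        n_effects = nrow(effects), n_years = n_years
      ),
      params = list(span = span, boot_reps = boot_reps, seed = seed,
                    response = response, model = model,
                    early_years = early_years, late_years = late_years,
                    n_boot_failed = n_boot_failed)
    ),
    class = "lnrr_trend"
  )
}

#' @export
print.lnrr_trend <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "<lnrr_trend> %d effects over %d years (%s response, %s pooling)\n",
    m$n_effects, m$n_years, x$params$response, x$params$model
  ))
  cat(sprintf(
    "  early mean %.3f (years %s), late mean %.3f (years %s)\n  decline ratio %.3f, weighted slope %.4f / year\n",
    m$early_mean, paste(x$params$early_years, collapse = "-"),
    m$late_mean, paste(x$params$late_years, collapse = "-"),
    m$decline_ratio, m$weighted_slope
  ))
  invisible(x)
}

#' @export
tidy.lnrr_trend <- function(x, ...) x$curve

#' @export
glance.lnrr_trend <- function(x, ...) x$metrics

#' Compare decline diagnostics across fitted trends
#'
#' Places two or more [loess_trend()] results side by side: one row per
#' configuration with its early/late pooled means, decline ratio and
#' weighted slope (the configuration with the largest decline ratio is
#' flagged `steepest_decline`), plus a wide table of yearly pooled means
#' over the shared year range.
#'
#' @param results A named list of `lnrr_trend` objects covering a common
#'   range of at least two years.
#' @return An object of class `trend_comparison`: list with `summary` and
#'   `yearly` tibbles. `tidy()` returns the summary.
#' @export
compare_trends <- function(results) {
  if (!is.list(results) || length(results) < 2 ||
      !all(vapply(results, inherits, logical(1), "lnrr_trend"))) {
    abort("`results` must be a named list of at least two lnrr_trend objects.")
  }
  if (is.null(names(results)) || any(!nzchar(names(results)))) {
    abort("Every element of `results` must be named.")
  }
  shared_years <- Reduce(intersect, lapply(results, function(r) r$yearly$year))
  if (length(shared_years) < 2) {
    abort("Trends must share at least two analysis years to be comparable.")
  }
  summary <- purrr::imap_dfr(results, function(r, nm) {
    dplyr::bind_cols(tibble::tibble(name = nm), r$metrics)
  })
  summary$steepest_decline <- summary$decline_ratio == max(summary$decline_ratio)
  yearly <- purrr::imap_dfr(results, function(r, nm) {
    d <- r$yearly[r$yearly$year %in% shared_years, c("year", "pooled_mean")]
    d$name <- nm
    d
  })
  yearly <- tidyr::pivot_wider(yearly, names_from = "name", values_from = "pooled_mean")
  structure(list(summary = summary, yearly = dplyr::arrange(yearly, .data$year)),
            class = "trend_comparison")
}

#' @export
print.trend_comparison <- function(x, ...) {
  cat("<trend_comparison>\n")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.trend_comparison <- function(x, ...) x$summary
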