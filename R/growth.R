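# Growth-rate estimation from dry-weight time series.

#' Fit an exponential growth rate by semi-log regression
#'
#' Ordinary least squares of `ln(dry_weight)` on `day`, pooling replicates
#' (all points enter the regression rather than being averaged first, so the
#' fit uses all variance information).
#'
#' @param series data frame with columns `day`, `dry_weight` (mg per 10
#'   seedlings) and optionally `replicate`.
#' @return list with `rate` (1/day), `intercept` (ln mg), `r_squared`, and the
#'   fitted `lm` object as `fit`.
#' @export
fit_growth_rate <- function(series) {
  if (!all(c("day", "dry_weight") %in% names(series))) {
    sphingo_abort("format", "growth series needs columns day, dry_weight")
  }
  if (any(!is.finite(series$dry_weight)) || any(series$dry_weight <= 0)) {
    sphingo_abort("domain", "dry weights must be positive and finite")
  }
  if (length(unique(series$day)) < 2L) {
    sphingo_abort("insufficient_data", "need >= 2 distinct time points to fit a growth rate")
  }
  fit <- stats::lm(log(dry_weight) ~ day, data = series)
  # summary() warns on numerically exact fits; the slope is still what we want
  s <- suppressWarnings(summary(fit))
  list(rate = unname(stats::coef(fit)[["day"]]),
       intercept = unname(stats::coef(fit)[["(Intercept)"]]),
       r_squared = s$r.squared,
       fit = fit)
}
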