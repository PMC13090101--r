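## Cumulative incubation-period survival: the probability a nest survives a
## full 27-day incubation, estimated by a weather bootstrap with mean
## re-centering.

#' Probability of surviving a window of consecutive days
#'
#' @param dsr_series vector of daily survival rates.
#' @param start index of the first day of the window.
#' @param length window length in days (27 for lapwing incubation).
#' @return Product of the daily survival rates over the window.
#' @export
window_survival <- function(dsr_series, start, length = 27) {
  if (start < 1 || start + length - 1 > base::length(dsr_series))
    stop("survival window [", start, ", ", start + length - 1,
         "] outside the series (length ", base::length(dsr_series), ")")
  prod(dsr_series[start:(start + length - 1)])
}

#' Window survival for every admissible start day of a season
#'
#' Predicts the daily survival series from the group's fixed factor levels
#' and the season's daily weather, then evaluates [window_survival()] at
#' every start day from the beginning of the season to `length - 1` days
#' before its end.
#'
#' @param model a converged [dsr_fit()].
#' @param weather data frame of daily weather rows (one row per day, in
#'   season order, with lag columns).
#' @param group named list/vector of fixed factor levels (e.g. `region`,
#'   `method`, and any other categorical term in the model).
#' @param length window length in days.
#' @return List with `start_survival` (one value per admissible start day),
#'   `mean` (their mean), and `dsr` (the predicted daily series).
#' @export
season_mean_survival <- function(model, weather, group, length = 27) {
  if (nrow(weather) < length)
    stop("weather series shorter than one ", length, "-day window")
  newdata <- cbind(weather, as.data.frame(as.list(group),
                                          stringsAsFactors = FALSE))
  s <- predict(model, newdata)
  starts <- seq_len(nrow(weather) - length + 1)
  vals <- vapply(starts, function(st) window_survival(s, st, length),
                 numeric(1))
  list(start_survival = vals, mean = mean(vals), dsr = s)
}

#' Bootstrap estimate of incubation-period survival
#'
#' Each replicate resamples the group's observed daily weather records with
#' replacement (whole days, preserving within-day covariate pairs), rebuilds
#' the 1-day lag columns from the resampled sequence, and recomputes the
#' season-mean window survival. The replicate distribution is re-centred so
#' its mean equals the expected value implied by the mean daily survival
#' rate over the observed days, `mean(DSR)^length`: the difference between
#' that expectation and the raw replicate mean is subtracted from every
#' replicate. The point estimate is the corrected mean, the SE is the
#' replicate SD, and the 95% CI the 2.5/97.5 percentiles of the corrected
#' replicates. Corrected values falling outside [0, 1] are clamped and
#' counted.
#'
#' @param model a converged [dsr_fit()].
#' @param weather observed daily weather rows for the group (all observed
#'   nest-days of the group's region and seasons).
#' @param group named fixed factor levels for the group.
#' @param n_reps number of bootstrap replicates.
#' @param seed integer seed; the result is reproducible bit for bit.
#' @param length incubation length in days.
#' @return A `dsr_period_survival` object: `estimate`, `se`, `ci` (2.5% and
#'   97.5%), `expected_mean`, `raw_means`, `corrected_means`, `n_clamped`,
#'   `n_reps`, `seed`, `group`.
#' @export
bootstrap_period_survival <- function(model, weather, group,
                                      n_reps = 1000, seed = 1,
                                      length = 27) {
  stopifnot(inherits(model, "dsr_fit"))
  if (!model$converged)
    stop("period survival requires a converged model (",
         model$diagnostic, ")")
  if (nrow(weather) < length)
    stop("weather series shorter than one ", length, "-day window")
  obs <- cbind(weather, as.data.frame(as.list(group),
                                      stringsAsFactors = FALSE))
  expected_mean <- mean(predict(model, obs))^length
  set.seed(seed)
  n <- nrow(weather)
  raw <- vapply(seq_len(n_reps), function(rep) {
    idx <- sample.int(n, n, replace = TRUE)
    w <- weather[idx, , drop = FALSE]
    ## lags follow the resampled ordering; the first day keeps its own value
    w$soil_temp_mean_lag1 <- c(w$soil_temp_mean[1],
                               w$soil_temp_mean[-n])
    w$wind_mean_lag1 <- c(w$wind_mean[1], w$wind_mean[-n])
    season_mean_survival(model, w, group, length)$mean
  }, numeric(1))
  corrected <- raw + (expected_mean - mean(raw))
  n_clamped <- sum(corrected < 0 | corrected > 1)
  clamped <- pmin(pmax(corrected, 0), 1)
  structure(list(
    group = group,
    estimate = mean(corrected),
    se = stats::sd(corrected),
    ci = stats::quantile(clamped, c(0.025, 0.975), names = TRUE),
    expected_mean = expected_mean,
    raw_means = raw,
    corrected_means = corrected,
    n_clamped = n_clamped,
    n_reps = n_reps,
    seed = seed,
    length = length), class = "dsr_period_survival")
}

#' @export
print.dsr_period_survival <- function(x, ...) {
  cat(sprintf(
    "%d-day incubation survival [%s]: %.4f (SE %.4f, 95%% CI %.4f-%.4f)\n",
    x$length, paste(names(x$group), unlist(x$group), sep = "=",
                    collapse = ", "),
    x$estimate, x$se, x$ci[[1]], x$ci[[2]]))
  if (x$n_clamped > 0)
    cat("  ", x$n_clamped, "corrected replicate(s) clamped to [0, 1]\n")
  invisible(x)
}
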