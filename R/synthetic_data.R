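## Synthetic weather and nest observation histories.
##
## The generator emulates the statistical structure the survival analysis
## assumes: regionally contrasted daily weather with first-order
## autocorrelation, a logit-linear true daily survival rate, nest initiation
## and discovery, and a roughly weekly visit cadence that produces the
## interval-censored i/j/k encounter histories.

#' Weather-generator parameters for one region
#'
#' Defaults reproduce the regional contrasts observed at the study sites:
#' mean daily soil-surface temperature 17.2 C (Alsace) vs 15.5 C
#' (Hauts-de-France), mean near-surface wind speed 0.3 vs 0.6 m/s, 69% wet
#' days with regional mean daily rainfall 2.6 vs 2.2 mm, mean daily solar
#' irradiance 217 vs 223 W/m2. Daily SDs are not reported at daily
#' resolution and are set to field-realistic values (soil temperature 4 C,
#' wind 0.10/0.15 m/s, irradiance 60 W/m2). All series share an AR(1)
#' autocorrelation `phi` (default 0.5). Wind and irradiance are truncated at
#' 0; the wind SDs keep the truncation bias negligible relative to the
#' regional means.
#'
#' @param region `"Alsace"` or `"HautsDeFrance"`.
#' @param soil_temp_mean,soil_temp_sd daily mean soil-surface temperature, C.
#' @param wind_mean,wind_sd daily mean near-surface wind speed, m/s.
#' @param phi shared AR(1) autocorrelation, in `[0, 1)`.
#' @param rain_wet_prob probability a day is wet.
#' @param rain_wet_mean mean rainfall on a wet day, mm.
#' @param irradiance_mean,irradiance_sd daily solar irradiance, W/m2.
#' @param soil_temp_trend,wind_trend,irradiance_trend linear day-of-season
#'   slopes, centred on the season midpoint; defaults 0.
#' @return A `weather_params` list.
#' @export
weather_params <- function(region = c("Alsace", "HautsDeFrance"),
                           soil_temp_mean = NULL, soil_temp_sd = 4,
                           wind_mean = NULL, wind_sd = NULL,
                           phi = 0.5,
                           rain_wet_prob = 0.69, rain_wet_mean = NULL,
                           irradiance_mean = NULL, irradiance_sd = 60,
                           soil_temp_trend = 0, wind_trend = 0,
                           irradiance_trend = 0) {
  region <- match.arg(region)
  defaults <- list(
    Alsace = list(soil = 17.2, wind = 0.3, wind_sd = 0.10,
                  rain_mm = 2.6, irr = 217),
    HautsDeFrance = list(soil = 15.5, wind = 0.6, wind_sd = 0.15,
                         rain_mm = 2.2, irr = 223))[[region]]
  if (is.null(soil_temp_mean)) soil_temp_mean <- defaults$soil
  if (is.null(wind_mean)) wind_mean <- defaults$wind
  if (is.null(wind_sd)) wind_sd <- defaults$wind_sd
  if (is.null(rain_wet_mean)) rain_wet_mean <- defaults$rain_mm / rain_wet_prob
  if (is.null(irradiance_mean)) irradiance_mean <- defaults$irr
  if (phi < 0 || phi >= 1) stop("phi must be in [0, 1)")
  stopifnot(soil_temp_sd >= 0, wind_sd >= 0, irradiance_sd >= 0,
            rain_wet_prob >= 0, rain_wet_prob <= 1, rain_wet_mean >= 0)
  structure(list(
    region = region,
    soil_temp_mean = soil_temp_mean, soil_temp_sd = soil_temp_sd,
    wind_mean = wind_mean, wind_sd = wind_sd, phi = phi,
    rain_wet_prob = rain_wet_prob, rain_wet_mean = rain_wet_mean,
    irradiance_mean = irradiance_mean, irradiance_sd = irradiance_sd,
    soil_temp_trend = soil_temp_trend, wind_trend = wind_trend,
    irradiance_trend = irradiance_trend), class = "weather_params")
}

## stationary AR(1) deviations with marginal SD sigma
.ar1 <- function(n, phi, sigma) {
  if (sigma == 0) return(numeric(n))
  e <- numeric(n)
  e[1] <- stats::rnorm(1, 0, sigma)
  if (n > 1) {
    innov <- stats::rnorm(n - 1, 0, sigma * sqrt(1 - phi^2))
    for (t in 2:n) e[t] <- phi * e[t - 1] + innov[t - 1]
  }
  e
}

#' Simulate a daily weather series for one region
#'
#' Gaussian AR(1) series for soil temperature, wind speed and irradiance
#' (wind and irradiance floored at 0), Bernoulli-exponential rainfall, and
#' optional linear seasonal trends centred mid-season. Lag-1 columns are
#' derived from the series itself (an extra pre-season day is simulated so
#' day 1 has a well-defined lag).
#'
#' @param params a [weather_params] object.
#' @param n_days season length in days (>= 2).
#' @param seed integer seed; the same seed reproduces the series exactly.
#' @return Data frame with one row per day: `day`, `soil_temp_mean`,
#'   `wind_mean`, their `_lag1` companions, `rain`, `irradiance`,
#'   `day_of_season`.
#' @export
simulate_weather <- function(params, n_days, seed = NULL) {
  stopifnot(inherits(params, "weather_params"), n_days >= 2)
  if (!is.null(seed)) set.seed(seed)
  n <- n_days + 1L   # day 0 supplies the lag for day 1
  dos <- seq_len(n) - 1L
  centred <- dos - (n_days + 1) / 2
  soil <- params$soil_temp_mean + params$soil_temp_trend * centred +
    .ar1(n, params$phi, params$soil_temp_sd)
  wind <- pmax(0, params$wind_mean + params$wind_trend * centred +
                 .ar1(n, params$phi, params$wind_sd))
  irr <- pmax(0, params$irradiance_mean + params$irradiance_trend * centred +
                .ar1(n, params$phi, params$irradiance_sd))
  wet <- stats::rbinom(n, 1, params$rain_wet_prob)
  rain <- wet * stats::rexp(n, rate = 1 / max(params$rain_wet_mean, 1e-12))
  if (params$rain_wet_mean == 0) rain <- numeric(n)
  keep <- 2:n
  data.frame(
    day = dos[keep],
    soil_temp_mean = soil[keep],
    wind_mean = wind[keep],
    soil_temp_mean_lag1 = soil[keep - 1L],
    wind_mean_lag1 = wind[keep - 1L],
    rain = rain[keep],
    irradiance = irr[keep],
    day_of_season = dos[keep])
}

#' True data-generating model for nest simulations
#'
#' Holds the logit-scale coefficient map of the true daily survival rate,
#' the cause-of-failure mixture conditional on failure (per region), the
#' discovery-lag and visit-interval distributions, and the per-region camera
#' assignment probability. Defaults are the study conditions: the
#' best-supported model's point estimates (region, monitoring method, their
#' interaction, same-day and previous-day wind speed and their interaction),
#' the observed regional fate mixtures, a 0-6 day discovery lag, visit
#' intervals with median 7 (IQR 6-7), and the observed camera shares.
#'
#' @param coef named logit-scale coefficient vector; names must match design
#'   columns (`(Intercept)`, `regionHautsDeFrance`, `methodcamera`,
#'   `wind_mean`, `wind_mean_lag1`, `regionHautsDeFrance:methodcamera`,
#'   `wind_mean:wind_mean_lag1`, ...).
#' @param terms model terms corresponding to `coef` (see [dsr_spec()]).
#' @param fate_mix named list per region of probabilities over the five
#'   failure causes; each must sum to 1.
#' @param discovery_lags integer vector of equally likely discovery lags.
#' @param visit_intervals,visit_probs visit-gap distribution (days >= 1).
#' @param p_camera named per-region probability a nest gets a camera.
#' @param incubation_days incubation length; 27 days.
#' @return A `true_model` list.
#' @export
true_model <- function(coef = NULL, terms = NULL, fate_mix = NULL,
                       discovery_lags = 0:6,
                       visit_intervals = c(6, 7, 8),
                       visit_probs = c(0.3, 0.6, 0.1),
                       p_camera = c(Alsace = 20 / 37,
                                    HautsDeFrance = 72 / 108),
                       incubation_days = 27) {
  if (is.null(terms))
    terms <- c("region", "method", "wind_mean", "wind_mean_lag1",
               "region:method", "wind_mean:wind_mean_lag1")
  if (is.null(coef))
    coef <- c("(Intercept)" = -1.013,
              "regionHautsDeFrance" = 1.700,
              "methodcamera" = 1.931,
              "wind_mean" = 1.905,
              "wind_mean_lag1" = 7.732,
              "regionHautsDeFrance:methodcamera" = -1.708,
              "wind_mean:wind_mean_lag1" = -5.741)
  if (is.null(fate_mix))
    fate_mix <- list(
      Alsace = c(agriculture = 11, abandoned = 5, flooded = 1,
                 depredated = 6, unknown_failure = 1) / 24,
      HautsDeFrance = c(agriculture = 5, abandoned = 7, flooded = 1,
                        depredated = 5, unknown_failure = 8) / 26)
  for (mx in fate_mix) {
    stopifnot(abs(sum(mx) - 1) < 1e-8, all(mx >= 0),
              setequal(names(mx), FAILURE_FATES))
  }
  stopifnot(all(visit_intervals >= 1), length(visit_intervals) ==
              length(visit_probs), abs(sum(visit_probs) - 1) < 1e-8,
            all(discovery_lags >= 0), incubation_days >= 1)
  structure(list(coef = coef, terms = terms, fate_mix = fate_mix,
                 discovery_lags = as.integer(discovery_lags),
                 visit_intervals = as.integer(visit_intervals),
                 visit_probs = visit_probs, p_camera = p_camera,
                 incubation_days = as.integer(incubation_days)),
            class = "true_model")
}

#' Simulate nest encounter histories from a true model
#'
#' For each nest: an initiation day is drawn uniformly so the full
#' incubation window fits in the weather series; the true daily survival
#' S_t = inverse-logit(x_t' beta) is evaluated on the region's weather; the
#' true failure day is drawn day by day (survival through all
#' `incubation_days` days means the nest hatches); a discovery lag and a
#' visit schedule are drawn; and the censored i/j/k triple is emitted: i =
#' the discovery visit (nest active), j = last visit with the nest active,
#' k = first visit at which the fate was ascertained (hatched nests are
#' confirmed on the hatch day, so j = k). Nests that fail before discovery
#' are redrawn within the same per-nest substream, so they never enter the
#' sample -- the likelihood conditions on being active at i. Per-nest
#' substreams are derived from the master seed, so increasing `n` leaves
#' earlier nests unchanged.
#'
#' In the latent truth table, `failure_day` is the first day the nest was no
#' longer active (the failure happened during the previous day); hatched
#' nests have `failure_day = NA`.
#'
#' @param model a [true_model].
#' @param weather named list of per-region weather data frames from
#'   [simulate_weather()] (names `Alsace`, `HautsDeFrance`), or a single
#'   data frame used for every region.
#' @param n_nests data frame with columns `region`, `method`, `n`; or a
#'   single integer, in which case regions and methods are drawn from the
#'   study shares. Default: the study cell counts (20/17/72/36).
#' @param seed master integer seed.
#' @param p_year1 probability a nest belongs to the first season (affects
#'   only the `year` label).
#' @return List with `nests` (a [nest_records] data frame), `covariates`
#'   (day-level rows for every at-risk day), `truth` (latent truth per
#'   nest), and `n_resampled` (nests redrawn because they failed before
#'   discovery or did not fit the season).
#' @export
simulate_nests <- function(model, weather, n_nests = NULL, seed = 1,
                           p_year1 = 40 / 145) {
  stopifnot(inherits(model, "true_model"))
  if (is.data.frame(weather))
    weather <- list(Alsace = weather, HautsDeFrance = weather)
  if (is.null(n_nests))
    n_nests <- data.frame(
      region = rep(REGION_LEVELS, each = 2),
      method = rep(METHOD_LEVELS[c(2, 1)], 2),
      n = c(20, 17, 72, 36))
  if (is.numeric(n_nests) && length(n_nests) == 1) {
    plan_region <- plan_method <- NULL
    n_total <- as.integer(n_nests)
  } else {
    plan_region <- rep(as.character(n_nests$region), n_nests$n)
    plan_method <- rep(as.character(n_nests$method), n_nests$n)
    n_total <- length(plan_region)
  }
  set.seed(seed)
  nest_seeds <- sample.int(.Machine$integer.max - 1L, n_total)
  inc <- model$incubation_days
  logit_cache <- new.env(parent = emptyenv())

  cell_logit <- function(region, method, habitat, clutch, year) {
    key <- paste(region, method, habitat, clutch, year, sep = "|")
    if (!is.null(logit_cache[[key]])) return(logit_cache[[key]])
    w <- weather[[region]]
    df <- data.frame(
      region = factor(region, REGION_LEVELS),
      method = factor(method, METHOD_LEVELS),
      habitat = factor(habitat, HABITAT_LEVELS),
      clutch_class = factor(clutch, CLUTCH_LEVELS),
      year = factor(year),
      w, check.names = FALSE)
    X <- dsr_design(model$terms, df)
    miss <- setdiff(names(model$coef), colnames(X))
    if (length(miss))
      stop("true-model coefficients not in design: ",
           paste(miss, collapse = ", "))
    lp <- drop(X[, names(model$coef), drop = FALSE] %*% model$coef)
    logit_cache[[key]] <- lp
    lp
  }

  rec <- vector("list", n_total)
  truth <- vector("list", n_total)
  covs <- vector("list", n_total)
  n_resampled <- 0L
  sample1 <- function(x, prob = NULL)
    if (length(x) == 1L) x else sample(x, 1, prob = prob)

  for (r in seq_len(n_total)) {
    set.seed(nest_seeds[r])
    if (is.null(plan_region)) {
      region <- sample(REGION_LEVELS, 1, prob = c(37, 108))
      method <- if (stats::runif(1) < model$p_camera[[region]])
        "camera" else "visits"
    } else {
      region <- plan_region[r]; method <- plan_method[r]
    }
    year <- if (stats::runif(1) < p_year1) 2021L else 2022L
    habitat <- sample(HABITAT_LEVELS, 1, prob = c(0.9, 0.1))
    clutch <- sample(CLUTCH_LEVELS, 1, prob = c(0.2, 0.8))
    w <- weather[[region]]
    n_days <- nrow(w)
    if (n_days < inc + 1)
      stop("weather series for ", region,
           " shorter than one incubation window")
    lp <- cell_logit(region, method, habitat, clutch, year)

    placed <- FALSE
    for (attempt in 1:1000) {
      init <- sample.int(n_days - inc, 1)   # window [init, init+inc-1]
      s <- stats::plogis(lp[init:(init + inc - 1)])
      u <- stats::runif(inc)
      fail_idx <- which(u > s)
      failed <- length(fail_idx) > 0
      ## day the nest stopped being active during; dead from fail_during + 1
      fail_during <- if (failed) init + fail_idx[1] - 1L else NA_integer_
      lag <- sample1(model$discovery_lags)
      d_disc <- init + lag
      if (failed && d_disc > fail_during) { n_resampled <- n_resampled + 1L
                                            next }
      if (!failed && d_disc > init + inc - 1L) { n_resampled <- n_resampled + 1L
                                                 next }
      if (!failed) {
        i <- d_disc
        j <- k <- init + inc           # hatch confirmed on the hatch day
        fate <- "hatched"
      } else {
        i <- d_disc
        visits <- i
        while (visits[length(visits)] <= fail_during)
          visits <- c(visits,
                      visits[length(visits)] +
                        sample1(model$visit_intervals,
                                prob = model$visit_probs))
        j <- max(visits[visits <= fail_during])
        k <- visits[visits > fail_during][1]
        fate <- sample(names(model$fate_mix[[region]]), 1,
                       prob = model$fate_mix[[region]])
      }
      if (k > n_days) { n_resampled <- n_resampled + 1L; next }
      placed <- TRUE
      break
    }
    if (!placed)
      stop("could not place nest ", r, " in the weather series")
    id <- sprintf("N%04d", r)
    rec[[r]] <- data.frame(
      nest_id = id, region = region, year = year, method = method,
      habitat = habitat, clutch_class = clutch, fate = fate,
      day_found = i, day_last_active = j, day_fate_confirmed = k,
      stringsAsFactors = FALSE)
    truth[[r]] <- data.frame(
      nest_id = id, region = region, method = method,
      init_day = init,
      failure_day = if (failed) fail_during + 1L else NA_integer_,
      hatched = !failed,
      true_window_survival = prod(stats::plogis(
        lp[init:(init + inc - 1)])),
      stringsAsFactors = FALSE)
    days <- i:(k - 1L)
    covs[[r]] <- data.frame(nest_id = id, day = days,
                            w[match(days, w$day),
                              setdiff(names(w), "day"), drop = FALSE],
                            row.names = NULL)
  }
  nests <- nest_records(do.call(rbind, rec))
  list(nests = nests,
       covariates = do.call(rbind, covs),
       truth = do.call(rbind, truth),
       n_resampled = n_resampled)
}
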