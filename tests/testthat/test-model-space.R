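test_that("AICc matches the closed form and its small-sample limit", {
  # null-model check at the study's effective sample size
  expect_equal(aicc(-197.431, 1, 2087), 396.863, tolerance = 0.01)
  # minimal K with perfect likelihood
  n <- 50
  expect_equal(aicc(0, 1, n), 2 + 4 / (n - 2), tolerance = 1e-12)
  # correction vanishes as n grows
  expect_equal(aicc(-10, 3, 1e9), -2 * (-10) + 2 * 3, tolerance = 1e-6)
  expect_error(aicc(-10, 3, 4), "n must exceed")
})

test_that("Akaike weights renormalize exp(-delta/2)", {
  expect_equal(akaike_weights(100), 1)
  w <- akaike_weights(c(100, 102))
  expect_equal(w, c(exp(0), exp(-1)) / (exp(0) + exp(-1)),
               tolerance = 1e-12)
  expect_equal(w, c(0.7311, 0.2689), tolerance = 1e-4)
  expect_equal(akaike_weights(c(5, 5, 5)), rep(1 / 3, 3))
  expect_equal(sum(akaike_weights(rnorm(20, 300, 10))), 1,
               tolerance = 1e-12)
})

test_that("collinearity screen drops the lower-priority member of correlated pairs", {
  set.seed(11)
  n <- 10000
  dt <- data.frame(wind_mean = rnorm(n), soil_temp_mean = rnorm(n),
                   rain = rexp(n), irradiance = rnorm(n, 200, 30))
  dt$wind_mean_lag1 <- dt$wind_mean          # duplicated column, |r| = 1
  sc <- screen_collinearity(dt, c("wind_mean", "soil_temp_mean",
                                  "wind_mean_lag1", "rain", "irradiance"))
  expect_true("wind_mean" %in% sc$retained)
  expect_false("wind_mean_lag1" %in% sc$retained)
  expect_identical(
    sc$report$dropped[sc$report$var_a == "wind_mean" &
                        sc$report$var_b == "wind_mean_lag1"],
    "wind_mean_lag1")

  # independent columns are all retained
  sc2 <- screen_collinearity(dt, c("wind_mean", "soil_temp_mean", "rain",
                                   "irradiance"))
  expect_setequal(sc2$retained, c("wind_mean", "soil_temp_mean", "rain",
                                  "irradiance"))

  # the rule is strict: |r| exactly at the threshold is retained
  dt2 <- data.frame(a = c(1, 2, 3, 4, 5), b = c(1, 3, 2, 5, 4))
  r_ab <- abs(cor(dt2$a, dt2$b))
  sc3 <- screen_collinearity(dt2, c("a", "b"), threshold = r_ab)
  expect_setequal(sc3$retained, c("a", "b"))
  sc4 <- screen_collinearity(dt2, c("a", "b"),
                             threshold = r_ab - 1e-9)
  expect_identical(sc4$retained, "a")

  dt$flat <- 1
  expect_warning(screen_collinearity(dt, c("wind_mean", "flat", "rain")),
                 "zero-variance")
})

test_that("model enumeration respects interaction hierarchy", {
  expect_length(enumerate_models(character(0)), 1)
  ms <- enumerate_models(c("region", "method", "region:method"))
  keys <- vapply(ms, function(s) paste(unclass(s), collapse = "+"),
                 character(1))
  expect_setequal(keys, c("", "region", "method", "region+method",
                          "region+method+region:method"))

  # brute-force oracle: filter all subsets of the global terms by the
  # hierarchy predicate and compare as sets
  global <- dsr_spec(c("habitat", "year", "clutch_class", "rain",
                       "irradiance", "soil_temp_mean", "wind_mean",
                       "soil_temp_mean_lag1", "wind_mean_lag1", "region",
                       "method", "day_of_season", "soil_temp_mean:wind_mean",
                       "region:wind_mean",
                       "soil_temp_mean:soil_temp_mean_lag1",
                       "wind_mean:wind_mean_lag1", "region:method"))
  terms <- as.character(global)
  p <- length(terms)
  brute <- character(0)
  for (mask in 0:(2^p - 1)) {
    sel <- terms[bitwAnd(mask, 2^(seq_len(p) - 1)) > 0]
    ints <- grep(":", sel, value = TRUE)
    ok <- all(vapply(ints, function(tm)
      all(strsplit(tm, ":", fixed = TRUE)[[1]] %in% sel), logical(1)))
    if (ok) brute <- c(brute, paste(sort(sel), collapse = "+"))
  }
  enum <- vapply(enumerate_models(global), function(s)
    paste(sort(as.character(s)), collapse = "+"), character(1))
  expect_identical(anyDuplicated(enum), 0L)
  expect_setequal(enum, brute)
})

test_that("balance filter applies the small-cell and chi-square rules", {
  counts <- list(Alsace_camera = 20, Alsace_visits = 17,
                 HautsDeFrance_camera = 72, HautsDeFrance_visits = 36)
  build <- function(counts) {
    rows <- do.call(rbind, lapply(names(counts), function(g) {
      parts <- strsplit(g, "_")[[1]]
      data.frame(region = parts[1], method = parts[2],
                 n = counts[[g]], stringsAsFactors = FALSE)
    }))
    df <- rows[rep(seq_len(nrow(rows)), rows$n), ]
    nest_records(data.frame(
      nest_id = sprintf("N%03d", seq_len(nrow(df))), region = df$region,
      year = 2021L, method = df$method, habitat = "crop",
      clutch_class = "eq4", fate = "hatched", day_found = 1L,
      day_last_active = 10L, day_fate_confirmed = 10L))
  }
  spec <- dsr_spec(c("region", "method", "region:method"))
  # the study's cell counts pass (all cells > 5, proportions comparable)
  expect_true(balance_filter(spec, build(counts))$admissible)
  # any cell of exactly 5 nests fails the small-cell rule
  counts$Alsace_visits <- 5
  bf <- balance_filter(spec, build(counts))
  expect_false(bf$admissible)
  expect_identical(bf$reason, "small-group")
  # perfectly balanced 2x2 is admissible (chi-square statistic 0)
  bf0 <- balance_filter(spec, build(list(Alsace_camera = 50,
                                         Alsace_visits = 50,
                                         HautsDeFrance_camera = 50,
                                         HautsDeFrance_visits = 50)))
  expect_true(bf0$admissible)
  # strongly unbalanced combinations are rejected by the chi-square rule
  bfu <- balance_filter(spec, build(list(Alsace_camera = 60,
                                         Alsace_visits = 8,
                                         HautsDeFrance_camera = 8,
                                         HautsDeFrance_visits = 60)))
  expect_false(bfu$admissible)
  expect_identical(bfu$reason, "unbalanced")
  # a single categorical factor faces only the small-cell rule
  one <- balance_filter(dsr_spec("region"),
                        build(list(Alsace_camera = 6,
                                   HautsDeFrance_camera = 100)))
  expect_true(one$admissible)
  # no categorical terms: always admissible
  expect_true(balance_filter(dsr_spec("wind_mean"),
                             build(counts))$admissible)
})

test_that("uninformative-parameter screen excludes all-overlapping candidates", {
  fake_fit <- function(est, se, terms, converged = TRUE) {
    names(est) <- c("(Intercept)", terms)
    structure(list(spec = dsr_spec(terms), coefficients = est,
                   vcov = diag(se^2, length(est)), converged = converged,
                   diagnostic = if (converged) "ok" else "boundary",
                   K = length(est), xlevels = list()), class = "dsr_fit")
  }
  fits <- list(
    null = fake_fit(2.5, 0.1, character(0)),
    weak = fake_fit(c(2.5, 0.05), c(0.1, 0.08), "wind_mean"),
    strong = fake_fit(c(2.5, 0.3, 0.01), c(0.1, 0.05, 0.5),
                      c("wind_mean", "rain")),
    bad = fake_fit(c(2.5, 1), c(0.1, 0.2), "rain", converged = FALSE))
  reasons <- informative_screen(fits)
  expect_identical(unname(reasons),
                   c(NA_character_, "all-uninformative", NA_character_,
                     "nonconverged"))
})

test_that("single-covariate models with a null effect are excluded at the nominal rate", {
  # under a true intercept-only model the 95% CI of a superfluous covariate
  # covers 0 with probability ~0.95, so the screen excludes ~95% of fits
  w <- simulate_weather(weather_params("Alsace"), 100, seed = 55)
  tm <- true_model(coef = c("(Intercept)" = 2.5), terms = character(0))
  plan <- data.frame(region = "Alsace", method = "visits", n = 150)
  n_seeds <- 200
  excluded <- logical(n_seeds)
  for (s in seq_len(n_seeds)) {
    sim <- simulate_nests(tm, list(Alsace = w), plan, seed = 1000 + s)
    dt <- join_covariates(sim$nests, sim$covariates)
    fit <- dsr_fit("wind_mean", dt)
    excluded[s] <- !is.na(informative_screen(list(fit))[1])
  }
  expect_lt(abs(mean(excluded) - 0.95), 0.05)
})

test_that("selection recovers a strong generating model and keeps the null close when true", {
  wA <- simulate_weather(weather_params("Alsace"), 120, seed = 61)
  wH <- simulate_weather(weather_params("HautsDeFrance"), 120, seed = 62)
  weather <- list(Alsace = wA, HautsDeFrance = wH)
  plan <- data.frame(region = rep(c("Alsace", "HautsDeFrance"), each = 2),
                     method = rep(c("camera", "visits"), 2),
                     n = c(150, 150, 150, 150))
  # strong region and method effects
  tm <- true_model(coef = c("(Intercept)" = 1.6,
                            "regionHautsDeFrance" = 1.4,
                            "methodcamera" = 1.2),
                   terms = c("region", "method"))
  sim <- simulate_nests(tm, weather, plan, seed = 71)
  sel <- select_dsr_models(c("region", "method", "region:method", "rain"),
                           sim$nests, sim$covariates)
  expect_s3_class(sel, "dsr_selection")
  retained <- sel[!sel$excluded, ]
  expect_equal(retained$delta_aicc[1], 0)
  expect_equal(sum(retained$weight), 1, tolerance = 1e-12)
  # the generating terms appear in some model within 2 AICc of the top
  top_set <- retained$model[retained$delta_aicc <= 2]
  expect_true(any(vapply(top_set, function(m)
    all(c("region", "method") %in% strsplit(m, " \\+ ")[[1]]),
    logical(1))))

  # all-null truth: the intercept-only model stays within 2 AICc of the top
  tm0 <- true_model(coef = c("(Intercept)" = 2.6), terms = character(0))
  sim0 <- simulate_nests(tm0, weather, plan, seed = 72)
  sel0 <- select_dsr_models(c("region", "method", "rain"),
                            sim0$nests, sim0$covariates)
  ret0 <- sel0[!sel0$excluded, ]
  expect_lte(ret0$delta_aicc[ret0$model == "(null)"], 2)

  # selection is invariant to nest-row permutation
  set.seed(5)
  perm <- sample(nrow(sim$nests))
  sel_perm <- select_dsr_models(
    c("region", "method", "region:method", "rain"),
    nest_records(as.data.frame(sim$nests)[perm, ]), sim$covariates)
  expect_identical(sel_perm$model, sel$model)
  expect_equal(sel_perm$AICc, sel$AICc, tolerance = 1e-6)
  expect_equal(sel_perm$weight, sel$weight, tolerance = 1e-6)
})
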