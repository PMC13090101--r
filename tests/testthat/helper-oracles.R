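# Independent oracles and fixture builders used across the suite.

# Quick nest-record constructor with sensible defaults.
make_nests <- function(n = 1, fate = "hatched", i = 1L, j = 5L, k = NULL,
                       region = "Alsace", method = "visits", year = 2021L,
                       habitat = "crop", clutch_class = "eq4",
                       nest_id = NULL) {
  if (is.null(k)) k <- ifelse(fate == "hatched", j, j + 2L)
  df <- data.frame(
    nest_id = if (is.null(nest_id)) sprintf("T%03d", seq_len(n)) else nest_id,
    region = region, year = year, method = method, habitat = habitat,
    clutch_class = clutch_class, fate = fate,
    day_found = i, day_last_active = j, day_fate_confirmed = k,
    stringsAsFactors = FALSE)
  nest_records(df)
}

# Constant covariate rows for the days [from, to] of given nests.
make_covariates <- function(nests, soil = 16, wind = 0.5, rain = 1,
                            irr = 220) {
  rows <- do.call(rbind, lapply(seq_len(nrow(nests)), function(r) {
    days <- nests$day_found[r]:(max(nests$day_fate_confirmed[r] - 1L,
                                    nests$day_found[r]))
    data.frame(nest_id = nests$nest_id[r], day = days,
               soil_temp_mean = soil, wind_mean = wind,
               soil_temp_mean_lag1 = soil, wind_mean_lag1 = wind,
               rain = rain, irradiance = irr, day_of_season = days,
               stringsAsFactors = FALSE)
  }))
  rows
}

# Exhaustive-path likelihood oracle: enumerate every daily outcome sequence
# consistent with the censored (i, j, k, fate) record and sum probabilities.
# s_by_day: daily survival values indexed by day-of-season.
enum_nest_lik <- function(i, j, k, failed, s_by_day) {
  days <- i:(k - 1)                       # at-risk days
  n <- length(days)
  total <- 0
  for (code in 0:(2^n - 1)) {
    surv <- bitwAnd(code, 2^(seq_len(n) - 1)) > 0
    first_dead <- if (all(surv)) Inf else which(!surv)[1]
    # canonical path: once dead, stays dead (count each outcome once)
    if (is.finite(first_dead) && first_dead < n &&
        any(surv[(first_dead + 1):n])) next
    # consistency with the record
    alive_span <- if (j > i) all(surv[days < j]) else TRUE
    ok <- if (failed) alive_span && is.finite(first_dead) &&
            days[first_dead] >= j else alive_span && !is.finite(first_dead)
    if (!ok) next
    # probability of the path up to and including the first death
    upto <- if (is.finite(first_dead)) first_dead else n
    p <- 1
    for (t in seq_len(upto)) {
      st <- s_by_day[days[t]]
      p <- p * if (t == upto && is.finite(first_dead)) (1 - st) else st
    }
    total <- total + p
  }
  log(total)
}

# Conditional-MLE odds ratio oracle: maximize the noncentral hypergeometric
# likelihood over log(psi) by golden-section search.
cmle_or_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; kk <- a + c
  support <- max(0, kk - n):min(kk, m)
  if (a == min(support) && a == max(support)) return(NA_real_)
  loglik <- function(lpsi) {
    lw <- lchoose(m, support) + lchoose(n, kk - support) + support * lpsi
    (lchoose(m, a) + lchoose(n, kk - a) + a * lpsi) -
      (max(lw) + log(sum(exp(lw - max(lw)))))
  }
  if (a == min(support)) return(0)
  if (a == max(support)) return(Inf)
  exp(stats::optimize(loglik, c(-30, 30), maximum = TRUE,
                      tol = 1e-10)$maximum)
}

# Two-sided Fisher exact p oracle for a 2x2 table: sum hypergeometric
# probabilities of all tables (fixed margins) no more probable than observed.
fisher_p_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; kk <- a + c
  support <- max(0, kk - n):min(kk, m)
  pr <- stats::dhyper(support, m, n, kk)
  sum(pr[pr <= pr[support == a] * (1 + 1e-7)])
}

# Nest records realizing given fate counts per region (for contingency
# fixtures built from printed tables).
nests_from_fate_counts <- function(counts) {
  # counts: matrix rows = region levels, cols = fate levels
  recs <- list()
  id <- 0
  for (r in rownames(counts)) for (f in colnames(counts)) {
    nf <- counts[r, f]
    if (nf == 0) next
    ids <- sprintf("%s_%s_%02d", substr(r, 1, 2), substr(f, 1, 3),
                   seq_len(nf))
    j <- 10L
    k <- if (f == "hatched") 10L else 12L
    recs[[length(recs) + 1]] <- data.frame(
      nest_id = ids, region = r, year = 2021L,
      method = "visits", habitat = "crop", clutch_class = "eq4",
      fate = f, day_found = 1L, day_last_active = j,
      day_fate_confirmed = k, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, recs)
  df$nest_id <- sprintf("N%03d", seq_len(nrow(df)))
  nest_records(df)
}

# Observed fate counts by region (printed study table; rows Alsace, HdF).
TABLE4_COUNTS <- matrix(
  c(13, 11, 5, 1, 6, 1,
    82, 5, 7, 1, 5, 8), nrow = 2, byrow = TRUE,
  dimnames = list(c("Alsace", "HautsDeFrance"),
                  c("hatched", "agriculture", "abandoned", "flooded",
                    "depredated", "unknown_failure")))
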