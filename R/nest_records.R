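## Nest encounter histories and daily covariates.
##
## A nest record is one monitored nesting attempt summarised by three
## day-of-season dates: i = day found with >= 1 egg, j = last day known
## active, k = day the fate was confirmed. Hatched nests have j == k; failed
## nests have j < k and the failure happened during (j, k]. Day t denotes the
## interval from the midnight starting day t to the next midnight; a nest
## "survived day t" if it was still active at the following midnight.

REGION_LEVELS  <- c("Alsace", "HautsDeFrance")
METHOD_LEVELS  <- c("visits", "camera")
HABITAT_LEVELS <- c("crop", "other")
CLUTCH_LEVELS  <- c("lt4", "eq4")
FATE_LEVELS    <- c("hatched", "agriculture", "abandoned", "flooded",
                    "depredated", "unknown_failure", "undetermined")
FAILURE_FATES  <- c("agriculture", "abandoned", "flooded", "depredated",
                    "unknown_failure")

NEST_COLUMNS <- c("nest_id", "region", "year", "method", "habitat",
                  "clutch_class", "fate", "day_found", "day_last_active",
                  "day_fate_confirmed")

COVARIATE_COLUMNS <- c("nest_id", "day", "soil_temp_mean", "wind_mean",
                       "soil_temp_mean_lag1", "wind_mean_lag1", "rain",
                       "irradiance", "day_of_season")

#' Construct and validate a collection of nest records
#'
#' Validates the encounter-history invariants: `day_found <= day_last_active
#' <= day_fate_confirmed`; hatched nests have `day_last_active ==
#' day_fate_confirmed`; failed nests have `day_last_active <
#' day_fate_confirmed`. Records with fate `"undetermined"` are retained in
#' the collection but are excluded from every analysis.
#'
#' @param df data frame with columns `nest_id`, `region` (`"Alsace"` or
#'   `"HautsDeFrance"`), `year`, `method` (`"camera"`/`"visits"`), `habitat`
#'   (`"crop"`/`"other"`), `clutch_class` (`"lt4"`/`"eq4"`), `fate`, and the
#'   integer day-of-season dates `day_found`, `day_last_active`,
#'   `day_fate_confirmed`.
#' @return A `nest_records` data frame with factor columns at canonical
#'   levels (region baseline Alsace, method baseline visits).
#' @export
nest_records <- function(df) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(NEST_COLUMNS, names(df))
  if (length(missing_cols))
    stop("nest table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  out <- df[NEST_COLUMNS]
  out$nest_id <- as.character(out$nest_id)
  if (anyDuplicated(out$nest_id))
    stop("duplicated nest_id: ",
         paste(unique(out$nest_id[duplicated(out$nest_id)]), collapse = ", "))
  for (fc in c("region", "method", "habitat", "clutch_class", "fate")) {
    lev <- switch(fc, region = REGION_LEVELS, method = METHOD_LEVELS,
                  habitat = HABITAT_LEVELS, clutch_class = CLUTCH_LEVELS,
                  fate = FATE_LEVELS)
    vals <- as.character(out[[fc]])
    bad <- !is.na(vals) & !(vals %in% lev)
    if (any(bad))
      stop("unknown ", fc, " level(s): ",
           paste(unique(vals[bad]), collapse = ", "))
    if (anyNA(vals)) stop("missing values in column '", fc, "'")
    out[[fc]] <- factor(vals, levels = lev)
  }
  out$year <- as.integer(out$year)
  for (dc in c("day_found", "day_last_active", "day_fate_confirmed")) {
    if (anyNA(out[[dc]]) || any(out[[dc]] != round(out[[dc]])))
      stop("column '", dc, "' must be integer day-of-season")
    out[[dc]] <- as.integer(out[[dc]])
  }
  i <- out$day_found; j <- out$day_last_active; k <- out$day_fate_confirmed
  bad <- which(i > j | j > k)
  if (length(bad))
    stop("day ordering i <= j <= k violated for nest(s): ",
         paste(out$nest_id[bad], collapse = ", "))
  hatched <- out$fate == "hatched"
  bad <- which(hatched & j != k)
  if (length(bad))
    stop("hatched nests must have j == k; violated for: ",
         paste(out$nest_id[bad], collapse = ", "))
  failed <- out$fate %in% FAILURE_FATES
  bad <- which(failed & j >= k)
  if (length(bad))
    stop("failed nests must have j < k (nonempty failure window); violated for: ",
         paste(out$nest_id[bad], collapse = ", "))
  rownames(out) <- NULL
  class(out) <- c("nest_records", "data.frame")
  out
}

#' Read a nest encounter-history table from CSV
#'
#' The three date columns may be integer day-of-season values or ISO-8601
#' calendar dates. Calendar dates are converted so that occasion 1 is the
#' earliest `day_found` in the file, unless `season_origin` names the
#' calendar date of occasion 1 explicitly.
#'
#' @param path CSV file with a header naming every nest-record field.
#' @param season_origin optional ISO-8601 date (string or `Date`) mapped to
#'   day-of-season 1 when the file carries calendar dates.
#' @return A validated [nest_records] data frame.
#' @export
read_nest_table <- function(path, season_origin = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(NEST_COLUMNS, names(df))
  if (length(missing_cols))
    stop("nest table ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  date_cols <- c("day_found", "day_last_active", "day_fate_confirmed")
  if (nrow(df) && !all(vapply(df[date_cols], is.numeric, logical(1)))) {
    dates <- lapply(df[date_cols], as.Date)
    if (anyNA(unlist(dates)))
      stop("date columns must be integers or ISO-8601 dates")
    origin <- if (is.null(season_origin)) min(dates$day_found)
              else as.Date(season_origin)
    for (dc in date_cols)
      df[[dc]] <- as.integer(dates[[dc]] - origin) + 1L
  }
  nest_records(df)
}

#' Write nest records to CSV
#'
#' @param nests a [nest_records] data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_nest_table <- function(nests, path) {
  stopifnot(inherits(nests, "nest_records"))
  utils::write.csv(as.data.frame(nests), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Exposure-day accounting for nest records
#'
#' `observed_alive_days` is j - i (days the nest was known to survive);
#' `failure_window_days` is k - j (the interval-censored window in which a
#' failed nest was lost; 0 for hatched nests). The per-nest exposure tally
#' used in summaries is k - i, all days under observation at risk.
#'
#' @param nests a [nest_records] data frame; fates must not be undetermined.
#' @return Data frame with columns `nest_id`, `observed_alive_days`,
#'   `failure_window_days`, `exposure_days`.
#' @export
exposure_days <- function(nests) {
  stopifnot(inherits(nests, "nest_records"))
  if (any(nests$fate == "undetermined"))
    stop("exposure_days is undefined for undetermined-fate records; ",
         "drop them first")
  data.frame(
    nest_id = nests$nest_id,
    observed_alive_days = nests$day_last_active - nests$day_found,
    failure_window_days = nests$day_fate_confirmed - nests$day_last_active,
    exposure_days = nests$day_fate_confirmed - nests$day_found,
    stringsAsFactors = FALSE)
}

#' Group-wise exposure summary
#'
#' @param nests a [nest_records] data frame (undetermined fates are dropped).
#' @param by character vector of grouping columns, default region and method.
#' @return Data frame with one row per group: group labels, `n_nests`,
#'   `exposure_days` (sum of per-nest k - i).
#' @export
exposure_summary <- function(nests, by = c("region", "method")) {
  stopifnot(inherits(nests, "nest_records"))
  nests <- nests[nests$fate != "undetermined", , drop = FALSE]
  expo <- nests$day_fate_confirmed - nests$day_found
  groups <- interaction(nests[by], drop = FALSE, lex.order = TRUE)
  out <- do.call(rbind, lapply(levels(groups), function(g) {
    sel <- groups == g
    lab <- strsplit(g, "\\.")[[1]]
    row <- as.data.frame(as.list(setNames(lab, by)),
                         stringsAsFactors = FALSE)
    row$n_nests <- sum(sel)
    row$exposure_days <- sum(expo[sel])
    row
  }))
  rownames(out) <- NULL
  out
}

#' Read / validate a daily covariate table
#'
#' One row per nest per calendar day with the weather covariates used by the
#' survival model, including 1-day lagged soil temperature and wind speed.
#'
#' @param path CSV file with the covariate columns.
#' @return Validated covariate data frame.
#' @export
read_covariate_table <- function(path) {
  validate_covariates(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_covariate_table
#' @param covariates covariate data frame to validate in place.
#' @export
validate_covariates <- function(covariates) {
  missing_cols <- setdiff(COVARIATE_COLUMNS, names(covariates))
  if (length(missing_cols))
    stop("covariate table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  cv <- covariates[COVARIATE_COLUMNS]
  cv$nest_id <- as.character(cv$nest_id)
  cv$day <- as.integer(cv$day)
  num <- c("soil_temp_mean", "wind_mean", "soil_temp_mean_lag1",
           "wind_mean_lag1", "rain", "irradiance")
  for (nc in num) {
    if (!all(is.finite(cv[[nc]])))
      stop("non-finite values in covariate '", nc, "'")
  }
  if (any(cv$rain < 0)) stop("rain must be >= 0")
  if (any(cv$irradiance < 0)) stop("irradiance must be >= 0")
  if (any(cv$wind_mean < 0)) stop("wind_mean must be >= 0")
  if (anyDuplicated(cv[c("nest_id", "day")]))
    stop("duplicated (nest_id, day) rows in covariate table")
  ## lag fields must restate the previous day's values where that day exists
  ord <- order(cv$nest_id, cv$day)
  cv <- cv[ord, , drop = FALSE]
  prev <- c(NA_integer_, cv$day[-nrow(cv)])
  same <- c(FALSE, cv$nest_id[-nrow(cv)] == cv$nest_id[-1]) &
    !is.na(prev) & prev == cv$day - 1L
  for (v in c("soil_temp_mean", "wind_mean")) {
    lagv <- paste0(v, "_lag1")
    prev_val <- c(NA_real_, cv[[v]][-nrow(cv)])
    bad <- same & abs(cv[[lagv]] - prev_val) > 1e-8
    if (any(bad, na.rm = TRUE))
      stop("lagged covariate ", lagv,
           " inconsistent with previous-day values for nest(s): ",
           paste(unique(cv$nest_id[which(bad)]), collapse = ", "))
  }
  rownames(cv) <- NULL
  cv
}

#' @rdname read_covariate_table
#' @param covariates covariate data frame.
#' @export
write_covariate_table <- function(covariates, path) {
  utils::write.csv(covariates, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build the day-level analysis table
#'
#' Expands each non-undetermined nest into one row per at-risk day t in
#' `[i, k)`, joined with that day's covariates and the nest's grouping
#' factors. The `alive` marker is `TRUE` for days in `[i, j)` (the nest is
#' known to have survived the day) and `FALSE` for days in `[j, k)` (the
#' failure window of a failed nest). Rows are ordered by (nest_id, day).
#'
#' @param nests a [nest_records] data frame.
#' @param covariates covariate data frame covering every day in `[i, k)` for
#'   every included nest.
#' @return A `dsr_day_table` data frame; attribute `"nests"` retains the
#'   contributing nest records.
#' @export
join_covariates <- function(nests, covariates) {
  stopifnot(inherits(nests, "nest_records"))
  covariates <- validate_covariates(covariates)
  nests <- nests[nests$fate != "undetermined", , drop = FALSE]
  if (!nrow(nests)) stop("no nests with determined fate to analyse")
  n_days <- nests$day_fate_confirmed - nests$day_found
  idx <- rep(seq_len(nrow(nests)), n_days)
  day <- unlist(lapply(seq_len(nrow(nests)), function(r)
    seq(nests$day_found[r], length.out = n_days[r])), use.names = FALSE)
  tab <- data.frame(
    nest_id = nests$nest_id[idx],
    day = as.integer(day),
    alive = day < nests$day_last_active[idx],
    failed = (nests$fate[idx] %in% FAILURE_FATES),
    region = nests$region[idx],
    year = factor(nests$year[idx]),
    method = nests$method[idx],
    habitat = nests$habitat[idx],
    clutch_class = nests$clutch_class[idx],
    stringsAsFactors = FALSE)
  key_t <- paste(tab$nest_id, tab$day)
  key_c <- paste(covariates$nest_id, covariates$day)
  pos <- match(key_t, key_c)
  if (anyNA(pos)) {
    gaps <- tab[is.na(pos), c("nest_id", "day")]
    stop("missing covariate rows for (nest_id, day): ",
         paste(utils::head(paste0(gaps$nest_id, ":", gaps$day), 20),
               collapse = ", "),
         if (nrow(gaps) > 20) " ..." else "")
  }
  cov_cols <- setdiff(COVARIATE_COLUMNS, c("nest_id", "day"))
  tab[cov_cols] <- covariates[pos, cov_cols]
  ord <- order(tab$nest_id, tab$day)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "nests") <- nests
  class(tab) <- c("dsr_day_table", "data.frame")
  tab
}
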