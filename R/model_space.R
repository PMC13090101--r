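## Constrained AICc selection over every hierarchical submodel of a global
## model: collinearity screen, enumeration, balance filter, fitting,
## uninformative-parameter screen, AICc ranking and Akaike weights.

#' Small-sample corrected Akaike Information Criterion
#'
#' `-2 logLik + 2K + 2K(K+1)/(n - K - 1)`. The effective sample size `n` for
#' nest-survival models is the total number of exposure days.
#'
#' @param logLik model log-likelihood.
#' @param K number of estimated parameters (> 0).
#' @param n effective sample size; must exceed `K + 1`.
#' @return The AICc score.
#' @export
aicc <- function(logLik, K, n) {
  stopifnot(K >= 1)
  if (any(n <= K + 1))
    stop("AICc undefined: n must exceed K + 1")
  -2 * logLik + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' Akaike weights
#'
#' `w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2)` with
#' `Delta_i = AICc_i - min(AICc)`.
#'
#' @param aicc_values numeric vector of AICc scores.
#' @return Weights summing to 1.
#' @export
akaike_weights <- function(aicc_values) {
  stopifnot(length(aicc_values) >= 1, all(is.finite(aicc_values)))
  d <- aicc_values - min(aicc_values)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Screen numeric covariates for collinearity
#'
#' Pairwise Pearson correlations are computed over all analysis rows; for
#' every pair with `|r|` strictly greater than the threshold, the member
#' lower in the priority list is dropped. Zero-variance covariates are
#' dropped with a warning.
#'
#' @param day_table day-level table (or any data frame of analysis rows).
#' @param covariates numeric covariate columns to screen, in priority order
#'   (earlier = more ecologically relevant, kept on conflict).
#' @param threshold exclusion threshold on `|r|` (strict inequality).
#' @return List with `retained` (character vector) and `report` (one row per
#'   pair: the two covariates, r, and the decision).
#' @export
screen_collinearity <- function(day_table,
                                covariates = c("wind_mean",
                                               "soil_temp_mean",
                                               "wind_mean_lag1",
                                               "soil_temp_mean_lag1",
                                               "rain", "irradiance",
                                               "day_of_season"),
                                threshold = 0.65) {
  stopifnot(length(covariates) >= 2)
  zero_var <- covariates[vapply(covariates, function(v)
    stats::sd(day_table[[v]]) == 0, logical(1))]
  if (length(zero_var)) {
    warning("zero-variance covariate(s) dropped: ",
            paste(zero_var, collapse = ", "))
    covariates <- setdiff(covariates, zero_var)
  }
  retained <- covariates
  pairs <- utils::combn(covariates, 2)
  report <- data.frame(var_a = pairs[1, ], var_b = pairs[2, ],
                       r = NA_real_, dropped = NA_character_,
                       stringsAsFactors = FALSE)
  for (p in seq_len(ncol(pairs))) {
    a <- pairs[1, p]; b <- pairs[2, p]
    r <- stats::cor(day_table[[a]], day_table[[b]])
    report$r[p] <- r
    if (abs(r) > threshold) {
      drop <- if (match(a, covariates) < match(b, covariates)) b else a
      if (drop %in% retained) retained <- setdiff(retained, drop)
      report$dropped[p] <- drop
    }
  }
  list(retained = retained, report = report)
}

#' Enumerate every hierarchical submodel of a global model
#'
#' All term subsets of the global specification in which every interaction
#' is accompanied by both its main effects, each including the intercept.
#' The intercept-only (null) model is always included. Order is
#' deterministic: by number of terms, then lexicographically by the
#' canonical term string.
#'
#' @param global a [dsr_spec] (or character vector) satisfying hierarchy.
#' @return List of `dsr_spec` objects.
#' @export
enumerate_models <- function(global) {
  global <- dsr_spec(global)
  mains <- setdiff(as.character(global), grep(":", global, value = TRUE))
  ints <- grep(":", as.character(global), value = TRUE)
  specs <- list()
  for (imask in seq_len(2^length(ints)) - 1L) {
    sel_int <- ints[bitwAnd(imask, 2^(seq_along(ints) - 1)) > 0]
    required <- unique(unlist(strsplit(sel_int, ":", fixed = TRUE)))
    free <- setdiff(mains, required)
    for (fmask in seq_len(2^length(free)) - 1L) {
      sel_free <- free[bitwAnd(fmask, 2^(seq_along(free) - 1)) > 0]
      specs[[length(specs) + 1L]] <-
        dsr_spec(c(required, sel_free, sel_int))
    }
  }
  key <- vapply(specs, function(s) paste(unclass(s), collapse = "+"),
                character(1))
  stopifnot(!anyDuplicated(key))
  ord <- order(lengths(specs), key)
  specs[ord]
}

#' Balance filter for categorical model terms
#'
#' A candidate model is inadmissible if cross-tabulating the nests over its
#' categorical factors yields any cell with 5 or fewer nests, or (with two
#' or more factors) a Pearson chi-square test of independence rejects at
#' `alpha` (pairwise tests, no continuity correction). Models with at most
#' one categorical factor face only the small-cell rule.
#'
#' @param spec a [dsr_spec].
#' @param nests a [nest_records] data frame (undetermined fates ignored).
#' @param min_cell smallest admissible cell count (cells `<= min_cell` fail).
#' @param alpha chi-square significance level.
#' @return List with `admissible` (flag) and `reason` (`NA`, `"small-group"`
#'   or `"unbalanced"`).
#' @export
balance_filter <- function(spec, nests, min_cell = 5, alpha = 0.05) {
  spec <- dsr_spec(spec)
  nests <- nests[nests$fate != "undetermined", , drop = FALSE]
  mains <- setdiff(as.character(spec), grep(":", spec, value = TRUE))
  cats <- intersect(mains, DSR_CATEGORICAL)
  if (!length(cats)) return(list(admissible = TRUE, reason = NA_character_))
  tab <- table(lapply(nests[cats], factor))
  if (any(tab <= min_cell))
    return(list(admissible = FALSE, reason = "small-group"))
  if (length(cats) >= 2) {
    pr <- utils::combn(cats, 2)
    for (p in seq_len(ncol(pr))) {
      ct <- table(factor(nests[[pr[1, p]]]), factor(nests[[pr[2, p]]]))
      pv <- suppressWarnings(
        stats::chisq.test(ct, correct = FALSE)$p.value)
      if (is.finite(pv) && pv < alpha)
        return(list(admissible = FALSE, reason = "unbalanced"))
    }
  }
  list(admissible = TRUE, reason = NA_character_)
}

#' Uninformative-parameter screen
#'
#' A fitted candidate (other than the null model) is excluded when every
#' non-intercept coefficient's confidence interval overlaps 0; candidates
#' with at least one informative coefficient are retained. Non-converged
#' candidates are excluded with reason `"nonconverged"`.
#'
#' @param fits list of [dsr_fit()] objects.
#' @param level confidence level for the Wald intervals.
#' @return Character vector per candidate: `NA` (retained),
#'   `"all-uninformative"` or `"nonconverged"`.
#' @export
informative_screen <- function(fits, level = 0.95) {
  vapply(fits, function(f) {
    if (!f$converged) return("nonconverged")
    if (f$K == 1) return(NA_character_)     # null model is always retained
    ci <- wald_ci(f, level)
    ci <- ci[ci$term != "(Intercept)", , drop = FALSE]
    if (!any(ci$informative)) "all-uninformative" else NA_character_
  }, character(1))
}

#' Constrained AICc model selection
#'
#' Runs the full pipeline: enumerate all hierarchical submodels of the
#' global model, apply the balance filter, fit the admissible candidates,
#' apply the uninformative-parameter screen, rank the retained candidates by
#' AICc and attach Akaike weights (computed over retained candidates).
#' Excluded candidates stay in the table with their exclusion reason.
#'
#' @param global global model, a [dsr_spec] or character vector of terms.
#' @param nests a [nest_records] data frame.
#' @param covariates daily covariate table.
#' @param level confidence level for the informative screen.
#' @param min_cell,alpha balance-filter settings (see [balance_filter()]).
#' @param verbose print progress.
#' @return A `dsr_selection` data frame sorted by AICc (retained models
#'   first): `model` (term string), `K`, `logLik`, `AICc`, `delta_aicc`,
#'   `weight`, `excluded`, `reason`. Attribute `"fits"` holds the fitted
#'   models keyed by term string.
#' @export
select_dsr_models <- function(global, nests, covariates, level = 0.95,
                              min_cell = 5, alpha = 0.05, verbose = FALSE) {
  day_table <- join_covariates(nests, covariates)
  specs <- enumerate_models(global)
  keys <- vapply(specs, function(s)
    if (length(s)) paste(unclass(s), collapse = " + ") else "(null)",
    character(1))
  n <- length(specs)
  K <- ll <- rep(NA_real_, n)
  reason <- rep(NA_character_, n)
  fits <- setNames(vector("list", n), keys)
  for (m in seq_len(n)) {
    bal <- balance_filter(specs[[m]], nests, min_cell, alpha)
    if (!bal$admissible) { reason[m] <- bal$reason; next }
    fit <- try(dsr_fit(specs[[m]], day_table), silent = TRUE)
    if (inherits(fit, "try-error")) { reason[m] <- "nonconverged"; next }
    fits[[m]] <- fit
    K[m] <- fit$K
    ll[m] <- fit$logLik
    if (verbose)
      message(sprintf("[%d/%d] %s  logLik %.3f", m, n, keys[m], ll[m]))
  }
  fitted_idx <- which(!vapply(fits, is.null, logical(1)))
  if (length(fitted_idx)) {
    scr <- informative_screen(fits[fitted_idx], level)
    reason[fitted_idx] <- ifelse(is.na(reason[fitted_idx]), scr,
                                 reason[fitted_idx])
  }
  aic_vals <- ifelse(is.na(ll), NA_real_,
                     aicc(ll, K, nrow(day_table)))
  excluded <- !is.na(reason)
  retained <- which(!excluded)
  if (!length(retained)) stop("no candidate model was retained")
  delta <- weight <- rep(NA_real_, n)
  delta[retained] <- aic_vals[retained] - min(aic_vals[retained])
  weight[retained] <- akaike_weights(aic_vals[retained])
  out <- data.frame(model = keys, K = K, logLik = ll, AICc = aic_vals,
                    delta_aicc = delta, weight = weight,
                    excluded = excluded, reason = reason,
                    stringsAsFactors = FALSE)
  ord <- order(excluded, aic_vals)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  attr(out, "n_effective") <- nrow(day_table)
  class(out) <- c("dsr_selection", "data.frame")
  out
}

#' @export
print.dsr_selection <- function(x, n = 10, ...) {
  cat("DSR model selection over", nrow(x), "candidates;",
      sum(!x$excluded), "retained\n")
  show <- utils::head(as.data.frame(x), n)
  show[c("logLik", "AICc", "delta_aicc")] <-
    lapply(show[c("logLik", "AICc", "delta_aicc")], round, 3)
  show$weight <- round(show$weight, 4)
  print(show, row.names = FALSE)
  invisible(x)
}
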