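## Interval-censored known-fate daily survival model.
##
## A nest found on day i, last known active on day j and with fate confirmed
## on day k contributes
##
##   sum_{t=i}^{j-1} log S_t  +  [failed] * log(1 - prod_{t=j}^{k-1} S_t)
##
## to the log-likelihood, where S_t = inverse-logit(x_t' beta) is the daily
## survival rate under that day's covariates. Hatched nests (j == k) have no
## failure window; failed nests were lost on exactly one (unknown) day in
## [j, k).

DSR_MAIN_TERMS <- c("habitat", "year", "clutch_class", "region", "method",
                    "rain", "irradiance", "soil_temp_mean", "wind_mean",
                    "soil_temp_mean_lag1", "wind_mean_lag1",
                    "day_of_season")
DSR_INTERACTIONS <- c("soil_temp_mean:wind_mean", "region:wind_mean",
                      "soil_temp_mean:soil_temp_mean_lag1",
                      "wind_mean:wind_mean_lag1", "region:method")
DSR_CATEGORICAL <- c("habitat", "year", "clutch_class", "region", "method")

#' Specify a candidate daily-survival model
#'
#' A model specification is an ordered set of terms drawn from the global
#' model: the grouping factors (`habitat`, `year`, `clutch_class`, `region`,
#' `method`), the daily covariates (`rain`, `irradiance`, `soil_temp_mean`,
#' `wind_mean`, their 1-day lags, `day_of_season`) and the five candidate
#' interactions. An intercept is always included. Interactions require both
#' main effects (hierarchy).
#'
#' @param terms character vector of term names; `character(0)` gives the
#'   intercept-only (null) model. Interaction terms are written `"a:b"` in
#'   either order.
#' @return A `dsr_spec` object (canonically ordered character vector).
#' @export
dsr_spec <- function(terms = character(0)) {
  if (inherits(terms, "dsr_spec")) return(terms)
  terms <- as.character(terms)
  universe <- c(DSR_MAIN_TERMS, DSR_INTERACTIONS)
  canon <- function(tm) {
    if (!grepl(":", tm, fixed = TRUE)) return(tm)
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    paste(parts[order(match(parts, DSR_MAIN_TERMS))], collapse = ":")
  }
  terms <- vapply(terms, canon, character(1), USE.NAMES = FALSE)
  bad <- setdiff(terms, universe)
  if (length(bad))
    stop("unknown model term(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(terms))
    stop("duplicated model term(s): ",
         paste(unique(terms[duplicated(terms)]), collapse = ", "))
  ints <- terms[grepl(":", terms, fixed = TRUE)]
  for (tm in ints) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    miss <- setdiff(parts, terms)
    if (length(miss))
      stop("interaction ", tm, " requires main effect(s): ",
           paste(miss, collapse = ", "))
  }
  terms <- terms[order(match(terms, universe))]
  structure(terms, class = "dsr_spec")
}

#' @export
print.dsr_spec <- function(x, ...) {
  cat("DSR model: S ~",
      if (length(x)) paste(unclass(x), collapse = " + ") else "1", "\n")
  invisible(x)
}

## Design matrix for a term set on a day-level table. `xlev` carries the
## factor levels of the fitting data into prediction.
dsr_design <- function(terms, data, xlev = NULL) {
  terms <- as.character(terms)
  f <- if (length(terms)) stats::reformulate(terms) else ~ 1
  mf <- stats::model.frame(f, data, xlev = xlev, na.action = stats::na.fail)
  for (v in names(mf))
    if (is.factor(mf[[v]]) && nlevels(mf[[v]]) < 2)
      stop("factor '", v, "' has a single level; term is aliased")
  stats::model.matrix(f, mf)
}

## Fast likelihood core. X: design; alive: logical marker; win_id: for
## rows with alive == FALSE, an integer id grouping the failure-window rows
## of each failed nest.
.dsr_loglik <- function(beta, X, alive, win_id) {
  lin <- drop(X %*% beta)
  log_s <- stats::plogis(lin, log.p = TRUE)
  ll <- sum(log_s[alive])
  if (any(!alive)) {
    sw <- rowsum(log_s[!alive], win_id)   # per-nest sum log S over window
    ll <- ll + sum(log(-expm1(sw)))
  }
  ll
}

.dsr_score <- function(beta, X, alive, win_id) {
  lin <- drop(X %*% beta)
  s <- stats::plogis(lin)
  w <- numeric(length(lin))
  w[alive] <- 1 - s[alive]
  if (any(!alive)) {
    log_s <- stats::plogis(lin, log.p = TRUE)
    sw <- rowsum(log_s[!alive], win_id)
    p <- exp(sw)                           # P(survive whole window)
    fac <- -p / (-expm1(sw))               # -P / (1 - P)
    w[!alive] <- fac[match(win_id, rownames(sw))] * (1 - s[!alive])
  }
  drop(crossprod(X, w))
}

.day_table_parts <- function(spec, day_table) {
  stopifnot(inherits(day_table, "data.frame"))
  need <- c("nest_id", "alive", "failed")
  miss <- setdiff(need, names(day_table))
  if (length(miss))
    stop("day table missing column(s): ", paste(miss, collapse = ", "))
  X <- dsr_design(spec, day_table)
  if (!all(is.finite(X))) stop("non-finite covariate values in design")
  alive <- day_table$alive
  failed_nests <- unique(day_table$nest_id[day_table$failed])
  ## every failed nest must carry a nonempty failure window
  no_window <- setdiff(failed_nests, day_table$nest_id[!alive])
  if (length(no_window))
    stop("failed nest(s) with empty failure window (k == j): ",
         paste(no_window, collapse = ", "))
  win_id <- day_table$nest_id[!alive]
  list(X = X, alive = alive, win_id = win_id,
       n_failed = length(failed_nests))
}

#' Interval-censored known-fate log-likelihood
#'
#' @param beta coefficient vector on the logit scale, aligned with the
#'   design columns of `spec` (intercept first).
#' @param spec a [dsr_spec] or character vector of terms.
#' @param day_table day-level analysis table from [join_covariates()].
#' @return The log-likelihood (a scalar).
#' @export
nest_log_likelihood <- function(beta, spec, day_table) {
  parts <- .day_table_parts(dsr_spec(spec), day_table)
  if (length(beta) != ncol(parts$X))
    stop("beta has length ", length(beta), ", design has ",
         ncol(parts$X), " columns")
  .dsr_loglik(beta, parts$X, parts$alive, parts$win_id)
}

#' Fit a daily-survival model by maximum likelihood
#'
#' Maximizes the interval-censored known-fate likelihood by L-BFGS-B with an
#' analytic gradient, starting from the Mayfield-informed intercept (logit of
#' 1 - failures/exposure-days) with all other coefficients 0. Covariates
#' enter raw (unstandardized), so coefficients are directly interpretable on
#' their natural units. Coefficients are box-bounded at +-25 on the logit
#' scale; an estimate at the bound, a data set with no failures, or an
#' optimizer failure is reported through `converged = FALSE` with a
#' diagnostic, never silently.
#'
#' @param spec a [dsr_spec] or character vector of terms.
#' @param day_table day-level table from [join_covariates()].
#' @param bound box bound on |coefficients| (logit scale).
#' @param control passed to [stats::optim()] (L-BFGS-B); the default demands
#'   a relative log-likelihood tolerance of about 1e-8.
#' @return An object of class `dsr_fit`: coefficients, covariance from the
#'   inverse of the numerically differentiated observed information,
#'   log-likelihood, parameter count `K`, effective sample size
#'   `n_effective` (total exposure days, the number of day-table rows),
#'   convergence flag and diagnostic.
#' @seealso [wald_ci()], [predict.dsr_fit()], [aicc()]
#' @export
dsr_fit <- function(spec, day_table, bound = 25,
                    control = list(factr = 1e7, pgtol = 1e-10,
                                   maxit = 1000)) {
  spec <- dsr_spec(spec)
  parts <- .day_table_parts(spec, day_table)
  X <- parts$X
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  n_eff <- nrow(day_table)
  n_failed <- parts$n_failed
  s0 <- min(max(1 - n_failed / n_eff, 0.5), 1 - 1e-4)
  start <- c(stats::qlogis(s0), numeric(ncol(X) - 1))
  negll <- function(b) -.dsr_loglik(b, X, parts$alive, parts$win_id)
  neggr <- function(b) -.dsr_score(b, X, parts$alive, parts$win_id)
  opt <- stats::optim(start, negll, neggr, method = "L-BFGS-B",
                      lower = -bound, upper = bound, control = control)
  beta <- setNames(opt$par, colnames(X))
  at_bound <- any(abs(beta) >= bound - 1e-6)
  converged <- opt$convergence == 0 && !at_bound && n_failed > 0
  diagnostic <- if (n_failed == 0) "complete survival"
    else if (at_bound) "boundary"
    else if (opt$convergence != 0) paste0("optim: ", opt$message)
    else "ok"
  vc <- matrix(NA_real_, length(beta), length(beta),
               dimnames = list(names(beta), names(beta)))
  if (converged) {
    hess <- stats::optimHess(opt$par, negll, neggr)
    vc_try <- try(solve(hess), silent = TRUE)
    if (inherits(vc_try, "try-error") || any(diag(vc_try) < 0)) {
      converged <- FALSE
      diagnostic <- "singular observed information"
    } else {
      vc <- vc_try
      dimnames(vc) <- list(names(beta), names(beta))
    }
  }
  structure(list(
    spec = spec,
    coefficients = beta,
    vcov = vc,
    logLik = -opt$value,
    K = length(beta),
    n_effective = n_eff,
    n_nests = length(unique(day_table$nest_id)),
    n_failed = n_failed,
    converged = converged,
    diagnostic = diagnostic,
    xlevels = .dsr_xlevels(spec, day_table),
    optim = opt[c("convergence", "counts", "message")]),
    class = "dsr_fit")
}

.dsr_xlevels <- function(spec, data) {
  vars <- unique(unlist(strsplit(as.character(spec), ":", fixed = TRUE)))
  vars <- intersect(vars, DSR_CATEGORICAL)
  out <- lapply(vars, function(v) levels(factor(data[[v]])))
  setNames(out, vars)
}

#' @export
print.dsr_fit <- function(x, ...) {
  cat("Known-fate daily survival model\n")
  print(x$spec)
  cat(sprintf("  %d nests, %d failed, %d exposure days\n",
              x$n_nests, x$n_failed, x$n_effective))
  cat(sprintf("  logLik %.3f   K %d   AICc %.3f   converged: %s (%s)\n",
              x$logLik, x$K, aicc(x$logLik, x$K, x$n_effective),
              x$converged, x$diagnostic))
  cat("Coefficients (logit scale):\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.dsr_fit <- function(object, ...) object$coefficients

#' @export
vcov.dsr_fit <- function(object, ...) object$vcov

#' @export
logLik.dsr_fit <- function(object, ...)
  structure(object$logLik, df = object$K, nobs = object$n_effective,
            class = "logLik")

#' Wald confidence intervals and the informative-parameter flag
#'
#' Intervals are `beta +- z * SE` on the logit scale. A coefficient is
#' flagged `informative` when its interval excludes 0; a model whose
#' non-intercept coefficients are all uninformative is screened out during
#' model selection.
#'
#' @param model a converged [dsr_fit()].
#' @param level confidence level (default 0.95).
#' @return Data frame with columns `term`, `estimate`, `se`, `lower`,
#'   `upper`, `informative`.
#' @export
wald_ci <- function(model, level = 0.95) {
  stopifnot(inherits(model, "dsr_fit"))
  if (!model$converged)
    stop("Wald intervals are undefined for a non-converged fit (",
         model$diagnostic, ")")
  z <- stats::qnorm((1 + level) / 2)
  se <- sqrt(diag(model$vcov))
  est <- model$coefficients
  data.frame(term = names(est), estimate = unname(est), se = unname(se),
             lower = unname(est - z * se), upper = unname(est + z * se),
             informative = unname(est - z * se > 0 | est + z * se < 0),
             stringsAsFactors = FALSE)
}

#' @export
confint.dsr_fit <- function(object, parm, level = 0.95, ...) {
  ci <- wald_ci(object, level)
  m <- cbind(lower = ci$lower, upper = ci$upper)
  rownames(m) <- ci$term
  if (!missing(parm)) m <- m[parm, , drop = FALSE]
  m
}

#' @export
summary.dsr_fit <- function(object, level = 0.95, ...) {
  out <- object[c("spec", "logLik", "K", "n_effective", "n_nests",
                  "n_failed", "converged", "diagnostic")]
  out$aicc <- aicc(object$logLik, object$K, object$n_effective)
  out$coef_table <- if (object$converged) wald_ci(object, level) else NULL
  class(out) <- "summary.dsr_fit"
  out
}

#' @export
print.summary.dsr_fit <- function(x, ...) {
  print(x$spec)
  cat(sprintf("%d nests, %d failed, %d exposure days\n",
              x$n_nests, x$n_failed, x$n_effective))
  cat(sprintf("logLik %.3f   K %d   AICc %.3f\n", x$logLik, x$K, x$aicc))
  if (is.null(x$coef_table)) {
    cat("fit did not converge:", x$diagnostic, "\n")
  } else {
    tab <- x$coef_table
    tab[2:5] <- lapply(tab[2:5], round, 4)
    print(tab, row.names = FALSE)
  }
  invisible(x)
}

#' Predict daily survival rates
#'
#' @param object a `dsr_fit`.
#' @param newdata data frame carrying every covariate named in the model's
#'   terms (factor columns may be characters; fitting levels are applied).
#' @param ... unused.
#' @return Vector of daily survival probabilities in (0, 1).
#' @export
predict.dsr_fit <- function(object, newdata, ...) {
  X <- dsr_design(object$spec, newdata, xlev = object$xlevels)
  drop(stats::plogis(X %*% object$coefficients[colnames(X)]))
}

#' @rdname predict.dsr_fit
#' @param model a `dsr_fit`.
#' @export
predict_dsr <- function(model, newdata) predict(model, newdata)

#' @export
plot.dsr_fit <- function(x, day_table, covariate = "wind_mean", ...) {
  s <- predict(x, day_table)
  plot(day_table[[covariate]], s, xlab = covariate,
       ylab = "predicted daily survival rate", ylim = c(0, 1), ...)
  invisible(x)
}

#' Serialize / restore a fitted model as JSON
#'
#' @param model a `dsr_fit`.
#' @param path JSON file path.
#' @return `path` (write) or a reconstructed `dsr_fit` (read).
#' @export
dsr_fit_to_json <- function(model, path) {
  stopifnot(inherits(model, "dsr_fit"))
  obj <- list(terms = as.character(model$spec),
              beta = as.list(model$coefficients),
              vcov = model$vcov, logLik = model$logLik, K = model$K,
              n_effective = model$n_effective, n_nests = model$n_nests,
              n_failed = model$n_failed, converged = model$converged,
              diagnostic = model$diagnostic, xlevels = model$xlevels)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname dsr_fit_to_json
#' @export
dsr_fit_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  beta <- unlist(obj$beta)
  vc <- matrix(unlist(obj$vcov), length(beta), length(beta),
               dimnames = list(names(beta), names(beta)))
  structure(list(spec = dsr_spec(obj$terms), coefficients = beta,
                 vcov = vc, logLik = obj$logLik, K = obj$K,
                 n_effective = obj$n_effective, n_nests = obj$n_nests,
                 n_failed = obj$n_failed, converged = obj$converged,
                 diagnostic = obj$diagnostic,
                 xlevels = lapply(obj$xlevels, as.character),
                 optim = NULL),
            class = "dsr_fit")
}
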