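## Nest-fate contingency analysis: Fisher exact tests, conditional-MLE odds
## ratios (noncentral hypergeometric), and Holm-Bonferroni adjusted
## fate-by-fate comparisons.

#' Cross-tabulate nest fates
#'
#' @param nests a [nest_records] data frame; undetermined fates are
#'   excluded.
#' @param row_factor grouping column (`"region"` or `"method"`).
#' @return A `fate_table` object: integer count matrix (rows = factor
#'   levels, columns = fate categories) with row-percentage and totals
#'   attributes.
#' @export
fate_table <- function(nests, row_factor = "region") {
  stopifnot(inherits(nests, "nest_records"),
            row_factor %in% c("region", "method", "year", "habitat",
                              "clutch_class"))
  nests <- nests[nests$fate != "undetermined", , drop = FALSE]
  if (!nrow(nests)) stop("no nests with determined fate")
  counts <- table(factor(nests[[row_factor]]),
                  factor(nests$fate, levels = setdiff(FATE_LEVELS,
                                                      "undetermined")))
  m <- unclass(counts)
  structure(m,
            row_factor = row_factor,
            row_totals = rowSums(m),
            col_totals = colSums(m),
            percent = round(100 * m / rowSums(m)),
            class = c("fate_table", "matrix"))
}

#' @export
print.fate_table <- function(x, ...) {
  m <- unclass(x)
  attributes(m)[c("row_factor", "row_totals", "col_totals",
                  "percent")] <- NULL
  pct <- attr(x, "percent")
  disp <- matrix(sprintf("%d (%d%%)", m, pct), nrow(m),
                 dimnames = dimnames(m))
  cat("Nest fates by", attr(x, "row_factor"), "\n")
  print(disp, quote = FALSE)
  invisible(x)
}

#' Fisher's exact test for an r x c contingency table
#'
#' Two-sided p-value summing the probabilities of all tables with the
#' observed margins that are no more probable than the observed table
#' (hypergeometric / multivariate hypergeometric null). Larger tables are
#' evaluated by the exact network algorithm; `simulate_p` switches to Monte
#' Carlo with a fixed seed when exhaustive evaluation is infeasible.
#'
#' @param counts integer matrix of counts (r, c >= 2).
#' @param simulate_p use Monte-Carlo p-value estimation.
#' @param B number of Monte-Carlo tables when `simulate_p = TRUE`.
#' @param seed seed for the Monte-Carlo path.
#' @return List with `p_value` and `method`.
#' @export
fisher_exact <- function(counts, simulate_p = FALSE, B = 1e6, seed = 1) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts")
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stop("contingency table must be at least 2 x 2")
  if (simulate_p) {
    set.seed(seed)
    ft <- stats::fisher.test(counts, simulate.p.value = TRUE, B = B)
    list(p_value = ft$p.value, method = sprintf("monte-carlo (B = %g)", B))
  } else {
    ft <- stats::fisher.test(counts, workspace = 2e7)
    list(p_value = ft$p.value, method = "exact")
  }
}

#' Conditional maximum-likelihood odds ratio for a 2 x 2 table
#'
#' The odds ratio maximizing the noncentral hypergeometric likelihood of the
#' table conditional on all margins -- the estimate reported by exact 2 x 2
#' tests. A zero cell drives the estimate to the likelihood limit 0 or
#' infinity.
#'
#' @param counts 2 x 2 integer matrix `rbind(c(a, b), c(c, d))`, or `a` with
#'   `b`, `c`, `d` given separately.
#' @param b,c,d individual cell counts when `counts` is scalar `a`.
#' @return The conditional MLE of the odds ratio.
#' @export
conditional_mle_or <- function(counts, b = NULL, c = NULL, d = NULL) {
  if (!is.null(b))   # cells filled column-wise: rbind(c(a, b), c(c, d))
    counts <- matrix(base::c(counts, c, b, d), 2, 2)
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == 2), all(counts >= 0),
            all(counts == round(counts)))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("conditional odds ratio undefined: empty table margin")
  unname(stats::fisher.test(counts)$estimate)
}

#' Holm-Bonferroni step-down adjustment
#'
#' @param p vector of raw p-values (one family).
#' @return Adjusted p-values: sorted ascending, `p_(i)` multiplied by
#'   `m - i + 1`, enforced monotone, capped at 1.
#' @export
holm_adjust <- function(p) stats::p.adjust(p, method = "holm")

#' Fate-by-fate comparisons with Holm-Bonferroni adjustment
#'
#' For each fate category, collapses the fate table to a 2 x 2 (that fate
#' vs. all others, by the row factor), computes the Fisher exact p-value and
#' the conditional-MLE odds ratio, then Holm-adjusts the family of p-values.
#'
#' @param tab a [fate_table()] with exactly two rows.
#' @param level family-wise significance level for the `significant` flag.
#' @return Data frame: `fate`, the four 2 x 2 cell counts, `odds_ratio`,
#'   `p_raw`, `p_adj`, `significant`.
#' @export
rowwise_fate_tests <- function(tab, level = 0.05) {
  stopifnot(inherits(tab, "fate_table"))
  m <- unclass(tab)
  if (nrow(m) != 2)
    stop("fate-by-fate comparisons need a two-level row factor")
  fates <- colnames(m)
  res <- lapply(fates, function(f) {
    two <- cbind(m[, f], rowSums(m) - m[, f])
    or <- if (all(rowSums(two) > 0) && all(colSums(two) > 0))
      conditional_mle_or(two) else NA_real_
    data.frame(fate = f,
               n_1 = two[1, 1], rest_1 = two[1, 2],
               n_2 = two[2, 1], rest_2 = two[2, 2],
               odds_ratio = or,
               p_raw = fisher_exact(two)$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- holm_adjust(out$p_raw)
  out$significant <- out$p_adj < level
  rownames(out) <- NULL
  out
}
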