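#' Pearson chi-square test of independence
#'
#' Computes \eqn{\sum (O-E)^2/E} over all cells with expected counts
#' \eqn{E = row \cdot col / N}, without continuity correction, and refers the
#' statistic to the chi-square upper tail on \eqn{(r-1)(c-1)} degrees of
#' freedom.  Used for the crude association screen of categorical stressors
#' against the depression indicator.
#'
#' @param counts non-negative integer matrix of cell counts (r x c).
#' @return list of class `assoc_test`: `method = "pearson_chi2"`,
#'   `statistic`, `df`, `p_value`, `expected`.
#' @export
pearson_chi_square <- function(counts) {
  counts <- check_table(counts)
  E <- expected_counts(counts)
  if (any(E <= 0)) stop("degenerate table: zero row or column margin")
  stat <- sum((counts - E)^2 / E)
  df <- (nrow(counts) - 1L) * (ncol(counts) - 1L)
  structure(list(method = "pearson_chi2", statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 expected = E),
            class = "assoc_test")
}

#' Fisher exact test by enumeration
#'
#' Enumerates every table with the observed margins, assigns each its
#' multivariate hypergeometric probability, and returns the two-sided
#' probability-mass p-value: the sum of probabilities of all tables no more
#' probable than the observed one (ties admitted within `tie_tol`).  This is
#' the rule most statistical packages apply for r x c exact tests, and the
#' test the screening tables fall back to when any expected cell count is
#' below 5.
#'
#' @param counts non-negative integer matrix; enumeration is guarded by
#'   `max_tables` and signals an error (fall back to [pearson_chi_square()])
#'   when the margin space is too large.
#' @param tie_tol relative tolerance for probability ties.
#' @param max_tables enumeration guard.
#' @return an `assoc_test` with `method = "fisher_exact"`, `p_value`, and
#'   `n_tables` enumerated; `statistic` and `df` are `NA`.
#' @export
fisher_exact <- function(counts, tie_tol = 1e-12, max_tables = 2e6) {
  counts <- check_table(counts)
  rs <- rowSums(counts); cs <- colSums(counts); N <- sum(counts)
  if (any(rs == 0) || any(cs == 0)) {
    # a zero margin leaves a single possible table
    return(structure(list(method = "fisher_exact", statistic = NA_real_,
                          df = NA_integer_, p_value = 1, n_tables = 1L),
                     class = "assoc_test"))
  }
  # log-probability of a table under the fixed-margins null:
  #   log P = sum lgamma(r_i+1) + sum lgamma(c_j+1) - lgamma(N+1) - sum lgamma(n_ij+1)
  const <- sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(N + 1)
  logp_obs <- const - sum(lgamma(counts + 1))
  env <- new.env(parent = emptyenv())
  env$p <- 0; env$count <- 0L
  r <- nrow(counts); c <- ncol(counts)
  cell <- matrix(0L, r, c)
  recurse <- function(i, j, row_left, col_left) {
    env$count <- env$count + 1L
    if (env$count > max_tables) {
      stop("table too large to enumerate; fall back to pearson_chi2")
    }
    if (i == r) {
      # last row forced entirely by the remaining column margins
      if (sum(col_left) != row_left[r]) return(invisible())
      cell[r, ] <<- col_left
      logp <- const - sum(lgamma(cell + 1))
      if (logp <= logp_obs + abs(logp_obs) * tie_tol + 1e-12) {
        env$p <- env$p + exp(logp)
      }
      return(invisible())
    }
    if (j == c) {
      # last cell of this row forced by the row margin
      v <- row_left[i]
      if (v > col_left[j]) return(invisible())
      cell[i, j] <<- v
      rl <- row_left; rl[i] <- 0L
      cl <- col_left; cl[j] <- cl[j] - v
      recurse(i + 1L, 1L, rl, cl)
      return(invisible())
    }
    hi <- min(row_left[i], col_left[j])
    for (v in 0:hi) {
      cell[i, j] <<- v
      rl <- row_left; rl[i] <- rl[i] - v
      cl <- col_left; cl[j] <- cl[j] - v
      recurse(i, j + 1L, rl, cl)
    }
    cell[i, j] <<- 0L
    invisible()
  }
  recurse(1L, 1L, rs, cs)
  structure(list(method = "fisher_exact", statistic = NA_real_,
                 df = NA_integer_, p_value = min(env$p, 1), n_tables = env$count),
            class = "assoc_test")
}

#' Choose between Pearson and Fisher tests
#'
#' Returns `"fisher_exact"` when any expected cell count is below 5,
#' otherwise `"pearson_chi2"` -- the rule footnoted under the screening
#' tables.
#'
#' @param counts contingency matrix.
#' @return method label.
#' @export
choose_test <- function(counts) {
  counts <- check_table(counts)
  E <- expected_counts(counts)
  if (any(E <= 0)) stop("degenerate table: zero margin")
  if (any(E < 5)) "fisher_exact" else "pearson_chi2"
}

#' Run the table-appropriate association test
#'
#' @param counts contingency matrix.
#' @return an `assoc_test` from [pearson_chi_square()] or [fisher_exact()]
#'   according to [choose_test()]; falls back to Pearson when enumeration is
#'   infeasible.
#' @export
test_association <- function(counts) {
  method <- choose_test(counts)
  if (method == "fisher_exact") {
    out <- tryCatch(fisher_exact(counts), error = function(e) NULL)
    if (!is.null(out)) return(out)
  }
  pearson_chi_square(counts)
}

#' Exact binomial prevalence with Clopper-Pearson interval
#'
#' Proportion `numerator/denominator` with the exact equal-tailed interval in
#' beta-quantile form: lower bound \eqn{B(\alpha/2; k, n-k+1)}, upper bound
#' \eqn{B(1-\alpha/2; k+1, n-k)}, with the conventional closures at k = 0 and
#' k = n.
#'
#' @param numerator,denominator integer counts, `0 <= k <= n`, `n >= 1`.
#' @param level confidence level (default 0.95).
#' @return list of class `prevalence_estimate` with `proportion`, `ci_low`,
#'   `ci_high`, `level`, `method`, and `percent` fields rounded to one
#'   decimal for reporting.
#' @export
prevalence <- function(numerator, denominator, level = 0.95) {
  k <- numerator; n <- denominator
  if (length(k) != 1L || length(n) != 1L || is.na(k) || is.na(n) ||
      n < 1 || k < 0 || k > n || k != round(k) || n != round(n)) {
    stop("need integer counts with 0 <= numerator <= denominator, denominator >= 1")
  }
  alpha <- 1 - level
  lo <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  hi <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  structure(list(numerator = k, denominator = n, proportion = k / n,
                 ci_low = lo, ci_high = hi, level = level,
                 method = "clopper_pearson",
                 percent = round(100 * k / n, 1),
                 percent_ci = round(100 * c(lo, hi), 1)),
            class = "prevalence_estimate")
}

#' @export
print.prevalence_estimate <- function(x, ...) {
  cat(sprintf("%d/%d = %.1f%% (%d%% CI: %.1f, %.1f%%) [%s]\n",
              x$numerator, x$denominator, 100 * x$proportion,
              round(100 * x$level), 100 * x$ci_low, 100 * x$ci_high,
              x$method))
  invisible(x)
}

#' Numeric summary: mean, SD, median, quartiles
#'
#' SD uses the sample (n-1) convention; quartiles are type-7 order
#' statistics, reported as a `(q1, q3)` pair in the style "median (IQR)".
#'
#' @param values numeric vector, at least one non-missing value.
#' @return list with `n`, `mean`, `sd`, `median`, `q1`, `q3`.
#' @export
summarize_numeric <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("no non-missing values to summarize")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE)
  list(n = length(values), mean = mean(values),
       sd = if (length(values) > 1) stats::sd(values) else 0,
       median = q[2], q1 = q[1], q3 = q[3])
}

#' Fleiss two-proportion sample size with continuity correction
#'
#' Unexposed-to-exposed allocation `r:1`; the exposed-group proportion is
#' derived from the unexposed proportion and `effect`, read either as a risk
#' ratio or as an absolute difference.  Group sizes are rounded up after the
#' continuity correction; `attrition` inflates the total for expected losses.
#'
#' @param alpha two-sided type-I error.
#' @param power target power.
#' @param ratio_unexposed_to_exposed allocation ratio r (unexposed per exposed).
#' @param p_unexposed outcome proportion among unexposed.
#' @param effect effect size linking the two proportions.
#' @param effect_type `"risk_ratio"` (default) or `"absolute_difference"`.
#' @param attrition proportion added for losses (e.g. 0.2), applied by
#'   [inflate_for_attrition()]; 0 disables.
#' @return list with `n_exposed`, `n_unexposed`, `n_total`,
#'   `n_total_inflated`, `p_exposed`.
#' @export
sample_size_two_proportions <- function(alpha, power, ratio_unexposed_to_exposed,
                                        p_unexposed, effect,
                                        effect_type = c("risk_ratio",
                                                        "absolute_difference"),
                                        attrition = 0) {
  effect_type <- match.arg(effect_type)
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1,
            p_unexposed > 0, p_unexposed < 1,
            ratio_unexposed_to_exposed > 0)
  p2 <- p_unexposed
  p1 <- switch(effect_type,
               risk_ratio = p2 * effect,
               absolute_difference = p2 + effect)
  if (p1 <= 0 || p1 >= 1) stop("implied exposed proportion outside (0,1)")
  if (abs(p1 - p2) < 1e-12) {
    stop("exposed and unexposed proportions equal: required n is unbounded")
  }
  r <- ratio_unexposed_to_exposed
  z_a <- stats::qnorm(1 - alpha / 2)
  z_b <- stats::qnorm(power)
  pbar <- (p1 + r * p2) / (1 + r)
  qbar <- 1 - pbar
  d <- abs(p1 - p2)
  n1 <- (z_a * sqrt((r + 1) / r * pbar * qbar) +
         z_b * sqrt(p1 * (1 - p1) + p2 * (1 - p2) / r))^2 / d^2
  # Fleiss continuity correction on the exposed group
  n1c <- n1 / 4 * (1 + sqrt(1 + 2 * (r + 1) / (n1 * r * d)))^2
  n_exp <- ceiling(n1c)
  n_unexp <- ceiling(r * n1c)
  total <- n_exp + n_unexp
  list(n_exposed = n_exp, n_unexposed = n_unexp, n_total = total,
       n_total_inflated = inflate_for_attrition(total, attrition),
       p_exposed = p1)
}

#' Inflate a sample size for expected attrition
#'
#' @param n base sample size.
#' @param attrition proportion added (0.2 adds 20%).
#' @return inflated size, rounded up.
#' @export
inflate_for_attrition <- function(n, attrition) {
  stopifnot(attrition >= 0, attrition < 1)
  as.integer(ceiling(n * (1 + attrition)))
}

#' Cross-tabulate a cohort variable against the depression indicator
#'
#' Builds the screening-table row for one categorical variable: counts and
#' column percentages by depression status plus the p-value from
#' [test_association()].
#'
#' @param cohort scored analysis-set data frame.
#' @param variable name of a categorical column.
#' @param flag name of the logical depression indicator column (default
#'   `"depressed"`, EPDS 12--16 within the analysis set).
#' @return list with `table` (counts), `percent`, `test`.
#' @export
crosstab_depression <- function(cohort, variable, flag = "depressed") {
  if (is.null(cohort[[variable]])) stop("no such column: ", variable)
  if (is.null(cohort[[flag]])) stop("no such column: ", flag)
  tab <- table(cohort[[variable]], factor(cohort[[flag]], levels = c(TRUE, FALSE),
                                          labels = c("depressed", "not_depressed")))
  counts <- matrix(as.integer(tab), nrow = nrow(tab),
                   dimnames = dimnames(tab))
  pct <- sweep(counts, 2L, colSums(counts), function(x, s) ifelse(s > 0, 100 * x / s, 0))
  list(table = counts, percent = round(pct, 1), test = test_association(counts))
}

# ---- internal ---------------------------------------------------------------

check_table <- function(counts) {
  counts <- as.matrix(counts)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (sum(counts) < 1) stop("empty table")
  storage.mode(counts) <- "integer"
  counts
}

expected_counts <- function(counts) {
  outer(rowSums(counts), colSums(counts)) / sum(counts)
}
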