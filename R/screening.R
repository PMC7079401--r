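#' Random-intercept linear mixed model for variable screening
#'
#' Fits `outcome ~ predictors + (1 | cluster)` by maximum likelihood
#' (ML, not REML, since screening compares fixed effects across models)
#' via `lme4::lmer`, and returns Wald (normal) p-values for the fixed
#' effects.  With fewer than two clusters the random intercept is
#' unidentifiable and the model degenerates to ordinary least squares,
#' which is returned with zero cluster variance.
#'
#' @param outcome numeric response vector.
#' @param predictors data frame or matrix of predictors (columns named).
#' @param cluster cluster identifier vector.
#' @return list of class `mixed_fit`: `fixed_effects` data frame
#'   (`term`, `estimate`, `se`, `p`), `random_intercept_variance`,
#'   `residual_variance`, `log_likelihood`, `converged`.
#' @export
fit_random_intercept <- function(outcome, predictors, cluster) {
  predictors <- as.data.frame(predictors)
  if (nrow(predictors) != length(outcome) ||
      length(cluster) != length(outcome)) {
    stop("outcome, predictors and cluster must have equal length")
  }
  dat <- cbind(.y = outcome, predictors, .cluster = factor(cluster))
  rhs <- paste(sprintf("`%s`", names(predictors)), collapse = " + ")
  n_cl <- length(unique(cluster))
  if (n_cl < 2L) {
    fit <- stats::lm(stats::as.formula(paste(".y ~", rhs)), data = dat)
    sm <- summary(fit)$coefficients
    fe <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                     p = 2 * stats::pnorm(-abs(sm[, 1] / sm[, 2])),
                     row.names = NULL, stringsAsFactors = FALSE)
    return(structure(list(fixed_effects = fe, random_intercept_variance = 0,
                          residual_variance = mean(stats::residuals(fit)^2),
                          log_likelihood = as.numeric(stats::logLik(fit)),
                          converged = TRUE, n_clusters = n_cl),
                     class = "mixed_fit"))
  }
  form <- stats::as.formula(paste(".y ~", rhs, "+ (1 | .cluster)"))
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(form, data = dat, REML = FALSE)))
  sm <- summary(fit)$coefficients
  vc <- lme4::VarCorr(fit)
  msgs <- fit@optinfo$conv$lme4$messages
  fe <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                   p = 2 * stats::pnorm(-abs(sm[, 3])),
                   row.names = NULL, stringsAsFactors = FALSE)
  structure(list(fixed_effects = fe,
                 random_intercept_variance = as.numeric(vc$.cluster[1, 1]),
                 residual_variance = attr(vc, "sc")^2,
                 log_likelihood = as.numeric(stats::logLik(fit)),
                 converged = is.null(msgs), n_clusters = n_cl),
            class = "mixed_fit")
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat("random-intercept fit:", x$n_clusters, "clusters; var(u) =",
      signif(x$random_intercept_variance, 4), " var(e) =",
      signif(x$residual_variance, 4), "\n")
  y <- x$fixed_effects
  y[, -1] <- round(y[, -1], 4)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Two-stage variable screen on the depression score
#'
#' Stage 1 fits one bivariate random-intercept model per candidate and
#' retains those with Wald p < `alpha`; stage 2 fits a single multivariable
#' model on the retained set and returns the candidates still at
#' p < `alpha`.  Deterministic given the input.
#'
#' @param cohort scored cohort data frame with a `cluster_id` column.
#' @param candidates character vector of candidate predictor columns.
#' @param outcome outcome column (default the continuous EPDS total; set
#'   to a binary indicator column to screen on the classification instead).
#' @param alpha retention threshold (default 0.05).
#' @return list with `selected` (character), `bivariate` (per-candidate
#'   p-values), `multivariable` (`mixed_fit` or NULL when nothing passes
#'   stage 1).
#' @export
screen_variables <- function(cohort, candidates, outcome = "epds_total",
                             alpha = 0.05) {
  if (!length(candidates)) stop("empty candidate list")
  missing_cols <- setdiff(c(candidates, outcome, "cluster_id"), names(cohort))
  if (length(missing_cols)) stop("missing columns: ",
                                 paste(missing_cols, collapse = ", "))
  y <- cohort[[outcome]]
  biv_p <- vapply(candidates, function(v) {
    f <- fit_random_intercept(y, cohort[v], cohort$cluster_id)
    min(f$fixed_effects$p[f$fixed_effects$term != "(Intercept)"])
  }, numeric(1))
  stage1 <- candidates[biv_p < alpha]
  if (!length(stage1)) {
    message("no candidate passed the bivariate screen")
    return(list(selected = character(0),
                bivariate = data.frame(candidate = candidates, p = biv_p,
                                       row.names = NULL),
                multivariable = NULL))
  }
  multi <- fit_random_intercept(y, cohort[stage1], cohort$cluster_id)
  fe <- multi$fixed_effects
  fe <- fe[fe$term != "(Intercept)", ]
  # map coefficient terms back to source columns (factors expand to dummies)
  sel <- stage1[vapply(stage1, function(v) {
    any(fe$p[startsWith(gsub("`", "", fe$term), v)] < alpha)
  }, logical(1))]
  list(selected = sel,
       bivariate = data.frame(candidate = candidates, p = biv_p,
                              row.names = NULL),
       multivariable = multi)
}
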