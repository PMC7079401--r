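#' Run the full stress-process analysis pipeline
#'
#' Orchestrates score -> eligibility -> descriptives -> screening ->
#' parceling -> SEM fit -> robust fit assessment -> effect decomposition on
#' one cohort, and (optionally) writes the result artifacts: the scored
#' cohort, per-variable cross-tabs with test results, a prevalence block,
#' the selected-variable list, the fit summary and the effect table.
#'
#' The model-modification loop is deliberately manual: the pipeline fits
#' the specification it is given and reports the fit verdict against the
#' conventional thresholds (robust chi-square p > 0.05, CFI/TLI >= 0.90,
#' RMSEA <= 0.08) so alternative topologies can be iterated via the
#' `spec` argument.
#'
#' @param cohort raw cohort data frame (e.g. from [generate_cohort()] or
#'   [read_cohort()]).
#' @param spec a `sem_spec`; default [default_sem_spec()].
#' @param crosstab_vars categorical columns to cross-tabulate against the
#'   depression indicator.
#' @param screen_candidates candidate columns for [screen_variables()];
#'   `NULL` skips screening.
#' @param out_dir directory for artifacts; `NULL` (default) writes nothing.
#' @param seed recorded in the bundle for provenance.
#' @return list of class `pipeline_result`: `counts` (input/excluded/
#'   analysis sizes), `prevalence`, `crosstabs`, `screening`, `fit`, `sb`,
#'   `indices`, `r2`, `effects`, `verdict`.
#' @export
run_pipeline <- function(cohort,
                         spec = default_sem_spec(),
                         crosstab_vars = c("food_access_difficulty",
                                           "pregnancy_intention",
                                           "fear_of_birth", "history_cmd",
                                           "marital_agreement",
                                           "partner_support"),
                         screen_candidates = NULL,
                         out_dir = NULL, seed = NA_integer_) {
  n_input <- nrow(cohort)
  scored <- score_cohort(cohort)
  parts <- apply_eligibility(scored)
  analysis <- parts$analysis
  n_excluded <- nrow(parts$excluded)
  analysis$depressed <- analysis$epds_total >= 12

  prev <- prevalence(sum(analysis$depressed), nrow(analysis))

  crosstabs <- lapply(crosstab_vars, function(v) {
    tryCatch(crosstab_depression(analysis, v), error = function(e) NULL)
  })
  names(crosstabs) <- crosstab_vars

  screening <- if (!is.null(screen_candidates)) {
    screen_variables(analysis, screen_candidates)
  } else NULL

  analysis <- parcel_cohort(analysis)
  model_dat <- prepare_model_data(analysis)
  fit <- fit_ml(spec, model_dat)
  sb <- if (fit$df > 0) satorra_bentler(fit) else NULL
  idx <- fit_indices(fit, sb = sb)
  r2 <- r_squared(fit)
  effects <- decompose_effects(fit, "dep")

  verdict <- list(
    sb_p_gt_05 = !is.null(sb) && sb$p_value > 0.05,
    cfi_ge_90 = idx$sb$cfi >= 0.90,
    tli_ge_90 = idx$sb$tli >= 0.90,
    rmsea_le_08 = idx$sb$rmsea <= 0.08)
  verdict$acceptable <- all(unlist(verdict))

  result <- structure(list(
    counts = list(input = n_input, excluded = n_excluded,
                  analysis = nrow(analysis),
                  referral = nrow(parts$referral)),
    prevalence = prev, crosstabs = crosstabs, screening = screening,
    fit = fit, sb = sb, indices = idx, r2 = r2, effects = effects,
    verdict = verdict, seed = seed), class = "pipeline_result")

  if (!is.null(out_dir)) write_pipeline_artifacts(result, analysis, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  cat(sprintf("  cohort: %d input, %d excluded (EPDS >= 17), %d analysed, %d flagged for referral\n",
              x$counts$input, x$counts$excluded, x$counts$analysis,
              x$counts$referral))
  cat("  prevalence: "); print(x$prevalence)
  if (!is.null(x$sb)) {
    cat(sprintf("  chi2_ml = %.2f, chi2_sb = %.2f (c = %.3f) on df = %d, p_sb = %.3f\n",
                x$fit$chi2_ml, x$sb$chi2_sb, x$sb$scaling_c, x$fit$df,
                x$sb$p_value))
  }
  cat(sprintf("  RMSEA = %.3f, CFI = %.3f, TLI = %.3f, SRMR = %.3f (robust variants)\n",
              x$indices$sb$rmsea, x$indices$sb$cfi, x$indices$sb$tli,
              x$indices$srmr))
  cat(sprintf("  R2(dep) = %.3f; fit verdict: %s\n",
              x$r2[["dep"]],
              if (x$verdict$acceptable) "acceptable" else "NOT acceptable"))
  cat("  standardized effects on dep:\n")
  print(x$effects, digits = 2)
  invisible(x)
}

write_pipeline_artifacts <- function(result, analysis, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(analysis, file.path(out_dir, "scored_cohort.csv"),
                   row.names = FALSE)
  eff <- as.data.frame(result$effects)
  num <- vapply(eff, is.numeric, logical(1))
  eff[num] <- lapply(eff[num], function(x) round(x, 6))
  utils::write.csv(eff, file.path(out_dir, "effect_table.csv"),
                   row.names = FALSE)
  for (v in names(result$crosstabs)) {
    ct <- result$crosstabs[[v]]
    if (is.null(ct)) next
    tab <- data.frame(level = rownames(ct$table), ct$table,
                      pct_depressed = ct$percent[, 1],
                      pct_not = ct$percent[, 2],
                      method = ct$test$method, p_value = ct$test$p_value,
                      row.names = NULL)
    utils::write.csv(tab, file.path(out_dir, paste0("crosstab_", v, ".csv")),
                     row.names = FALSE)
  }
  summary_json <- list(
    seed = result$seed,
    counts = result$counts,
    prevalence = list(numerator = result$prevalence$numerator,
                      denominator = result$prevalence$denominator,
                      percent = result$prevalence$percent,
                      ci_percent = result$prevalence$percent_ci),
    chi2_ml = result$fit$chi2_ml,
    chi2_sb = if (!is.null(result$sb)) result$sb$chi2_sb else NULL,
    scaling_c = if (!is.null(result$sb)) result$sb$scaling_c else NULL,
    df = result$fit$df,
    indices = list(rmsea = result$indices$sb$rmsea,
                   cfi = result$indices$sb$cfi,
                   tli = result$indices$sb$tli,
                   srmr = result$indices$srmr, cd = result$indices$cd),
    r2 = as.list(result$r2),
    estimates = as.list(result$fit$theta),
    se = as.list(result$fit$se),
    selected = if (!is.null(result$screening)) result$screening$selected
    else NULL,
    verdict = result$verdict)
  jsonlite::write_json(summary_json, file.path(out_dir, "fit_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}
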