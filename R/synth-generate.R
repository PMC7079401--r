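#' Generate a synthetic antenatal cohort
#'
#' Draws a cohort with the statistical structure the analysis pipeline
#' assumes: correlated binary stressors from thresholded latent normals at
#' the configured prevalences; ordinal mediators (marital agreement 1--4,
#' partner support 1--5, social-support total 3--14) as discretized linear
#' functions of the standardized upstream scores, with attenuation-corrected
#' propensity coefficients so the standardized effects on the *observed*
#' ordinal scores match the calibrated path matrix; a unit-variance latent
#' depression score from the structural equation plus a cluster (kebele)
#' random intercept; ten EPDS items 0--3 from the latent via a common
#' loading and item thresholds; and sociodemographic covariates from
#' documented marginal distributions.  Deterministic given the seed.
#'
#' @param config a [default_config()]-style `synth_config`.
#' @param seed integer override of `config$seed`.
#' @param n override of `config$n`.
#' @return data frame of one row per subject; includes the true latent
#'   score as `latent_dep` (for recovery experiments; drop for blinded use).
#' @export
generate_cohort <- function(config = default_config(), seed = config$seed,
                            n = config$n) {
  validate_config(config)
  plan <- generation_plan(config)
  set.seed(seed)
  prev <- config$stressor_prevalences

  cluster_id <- sample.int(config$n_clusters, n, replace = TRUE)
  # cluster effects are standardized across the drawn clusters so every
  # cohort carries exactly the configured between-cluster variance (with a
  # handful of clusters, raw draws would leave a large shared mean shift)
  u_cluster <- stats::rnorm(config$n_clusters)
  u_cluster <- if (config$n_clusters > 1L) {
    as.numeric(scale(u_cluster)) * config$cluster_sd
  } else rep(0, config$n_clusters)

  # latent normals for the four stressors (oriented toward the adverse
  # condition), exchangeable correlation rho
  rho <- config$stressor_latent_rho
  R <- matrix(rho, 4, 4); diag(R) <- 1
  Z <- matrix(stats::rnorm(n * 4), n, 4) %*% chol(R)
  p_adverse <- c(prev[["food_difficulty"]],
                 prev[["untimed"]] + prev[["unintended"]],
                 prev[["fear_of_birth"]], prev[["history_cmd"]])
  adverse <- sweep(Z, 2, stats::qnorm(1 - p_adverse), `>`)
  food_difficulty <- as.integer(adverse[, 1])
  unplanned <- as.integer(adverse[, 2])
  fear_birth <- as.integer(adverse[, 3])
  history_cmd <- as.integer(adverse[, 4])
  p_unint_given_unplanned <- prev[["unintended"]] /
    (prev[["untimed"]] + prev[["unintended"]])
  intention <- ifelse(unplanned == 0L, "planned",
                      ifelse(stats::runif(n) < p_unint_given_unplanned,
                             "unintended", "untimed"))

  std_bin <- function(x, p) (x - p) / sqrt(p * (1 - p))
  z <- list(
    food_adequate = std_bin(1L - food_difficulty, plan$p_model[["food_adequate"]]),
    unplanned = std_bin(unplanned, plan$p_model[["unplanned"]]),
    fear_birth = std_bin(fear_birth, plan$p_model[["fear_birth"]]),
    history_cmd = std_bin(history_cmd, plan$p_model[["history_cmd"]]))

  med_threshold <- list(
    marital_agreement = probs_to_thresholds(config$marital_probs),
    partner_support = probs_to_thresholds(config$partner_probs),
    social_support = (3:13 + 0.5 - config$social_mean) / config$social_sd)
  med_codes <- list(marital_agreement = 1:4, partner_support = 1:5,
                    social_support = 3:14)
  med_raw <- list()
  for (v in plan$mediators) {
    cc <- plan$prop_coef[[v]]
    lin <- rep(0, n)
    for (w in names(cc)) if (cc[[w]] != 0) lin <- lin + cc[[w]] * z[[w]]
    prop <- lin + sqrt(plan$resid_var[[v]]) * stats::rnorm(n)
    code <- med_codes[[v]][findInterval(prop, med_threshold[[v]]) + 1L]
    med_raw[[v]] <- code
    dm <- plan$med_disc[[v]]
    z[[v]] <- (code - dm$mean) / sqrt(dm$var)
  }

  b_dep <- plan$B["dep", ]
  lin <- rep(0, n)
  for (w in names(b_dep)) if (b_dep[[w]] != 0) lin <- lin + b_dep[[w]] * z[[w]]
  dep <- lin + u_cluster[cluster_id] +
    sqrt(plan$resid_var[["dep"]]) * stats::rnorm(n)

  # items load on the standardized latent, so the item calibration is
  # independent of the R^2-derived latent scale
  l <- config$epds_loading
  dep_std <- dep / plan$sd_dep
  epds <- matrix(0L, n, 10)
  for (i in 1:10) {
    pr <- l * dep_std + sqrt(1 - l^2) * stats::rnorm(n)
    epds[, i] <- findInterval(pr, config$epds_thresholds)
  }
  colnames(epds) <- paste0("epds_", 1:10)

  osss3 <- allocate_osss3(med_raw$social_support)
  pci <- matrix(0L, n, 4)
  g <- stats::rnorm(n)
  pci_thr <- probs_to_thresholds(config$pci_probs)
  for (i in 1:4) {
    pr <- config$pci_loading * g +
      sqrt(1 - config$pci_loading^2) * stats::rnorm(n)
    pci[, i] <- findInterval(pr, pci_thr)
  }
  colnames(pci) <- paste0("pci4_", 1:4)

  trimester2 <- stats::runif(n) < 0.37
  gestational_weeks <- ifelse(trimester2,
                              sample(13:27, n, replace = TRUE),
                              sample(28:42, n, replace = TRUE))
  age_years <- pmin(pmax(round(stats::rnorm(n, 26.5, 4.5)), 18), 45)
  income <- round(stats::rlnorm(n, meanlog = 7.888, sdlog = 0.736))
  income_category <- cut(income, c(-Inf, stats::quantile(income, c(0.49, 0.898))
                                   , Inf),
                         labels = c("low", "medium", "high"))
  education <- sample(c("no_formal", "grade_1_8", "grade_9_12",
                        "diploma_plus"), n, replace = TRUE,
                      prob = c(0.129, 0.256, 0.378, 0.237))
  occupation <- sample(c("home_duties", "student", "government", "self_employed"),
                       n, replace = TRUE, prob = c(0.714, 0.016, 0.141, 0.129))
  religion <- sample(c("orthodox", "muslim", "protestant"), n, replace = TRUE,
                     prob = c(0.801, 0.189, 0.010))
  marital_status <- sample(c("single", "married", "divorced", "separated"),
                           n, replace = TRUE,
                           prob = c(0.018, 0.961, 0.004, 0.017))
  parity <- sample(1:8, n, replace = TRUE,
                   prob = c(0.381, 0.314, 0.15, 0.08, 0.04, 0.02, 0.01, 0.005))
  muac_cm <- round(pmin(pmax(stats::rnorm(n, 24.1, 1.7), 18), 31), 1)

  out <- data.frame(
    subject_id = sprintf("S%05d", seq_len(n)),
    cluster_id = cluster_id,
    epds, osss3, pci,
    marital_agreement = med_raw$marital_agreement,
    partner_support = med_raw$partner_support,
    food_access_difficulty = food_difficulty,
    pregnancy_intention = intention,
    fear_of_birth = fear_birth,
    history_cmd = history_cmd,
    gestational_weeks = gestational_weeks,
    muac_cm = muac_cm,
    age_years = age_years, income = income,
    income_category = as.character(income_category),
    education = education, occupation = occupation, religion = religion,
    marital_status = marital_status, parity = parity,
    latent_dep = dep,
    stringsAsFactors = FALSE)
  out
}

# split a social-support total (3..14) into OSSS-3 items: item 1 in 1..4,
# items 2-3 in 1..5, drawn uniformly over the valid item triples for each
# total (the 100 possible triples are enumerated once)
allocate_osss3 <- function(total) {
  combos <- expand.grid(osss3_1 = 1:4, osss3_2 = 1:5, osss3_3 = 1:5)
  combo_total <- rowSums(combos)
  idx <- vapply(total, function(t) {
    cand <- which(combo_total == t)
    if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
  }, integer(1))
  items <- as.matrix(combos[idx, , drop = FALSE])
  dimnames(items) <- list(NULL, paste0("osss3_", 1:3))
  storage.mode(items) <- "integer"
  items
}

#' Assemble the observed-variable table for the default SEM
#'
#' Scores and parcels a raw cohort (if not already done) and derives the
#' model coding: `food_adequate = 1 - food_access_difficulty`, `unplanned`
#' pooling un-timed and unintended pregnancies, `social_support` as the
#' OSSS-3 total.
#'
#' @param cohort a cohort data frame.
#' @return data frame with the ten observed model variables.
#' @export
prepare_model_data <- function(cohort) {
  if (is.null(cohort$epds_total)) cohort <- score_cohort(cohort)
  if (is.null(cohort$parcel_1)) cohort <- parcel_cohort(cohort)
  data.frame(
    parcel_1 = cohort$parcel_1, parcel_2 = cohort$parcel_2,
    parcel_3 = cohort$parcel_3,
    marital_agreement = cohort$marital_agreement,
    partner_support = cohort$partner_support,
    social_support = cohort$osss3_total,
    food_adequate = 1L - cohort$food_access_difficulty,
    unplanned = as.integer(cohort$pregnancy_intention != "planned"),
    fear_birth = cohort$fear_of_birth,
    history_cmd = cohort$history_cmd)
}

#' The packaged stress-process SEM specification
#'
#' Measurement: a single depression factor with the three fixed EPDS
#' parcels as indicators (first loading fixed to 1).  Structural: the
#' [default_topology()] paths, all free; the four stressors are exogenous
#' and freely correlated.
#'
#' @return a `sem_spec` with 10 observed variables and 22 df.
#' @export
default_sem_spec <- function() {
  topo <- default_topology()
  topo$fixed <- NA_real_
  build_spec(
    measurement = list(dep = c("parcel_1", "parcel_2", "parcel_3")),
    structural = topo)
}

#' Simulate multivariate-normal data from a fitted or specified model
#'
#' Draws `n` observations from N(0, Sigma(theta)); used for calibration
#' checks of the robust chi-square under exact normality.
#'
#' @param spec a `sem_spec`.
#' @param theta parameter vector.
#' @param n sample size.
#' @param seed optional seed.
#' @return data frame with the observed variables.
#' @export
simulate_from_spec <- function(spec, theta, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Sigma <- implied_covariance(spec, theta)
  L <- chol(Sigma)
  X <- matrix(stats::rnorm(n * nrow(Sigma)), n) %*% L
  colnames(X) <- spec$observed_vars
  as.data.frame(X)
}

#' Parameter-recovery experiment for the SEM engine
#'
#' For each replicate: generate a cohort, score, parcel, fit the default
#' specification, standardize, and decompose effects.  Reports per-path
#' mean estimate, bias, RMSE and 95% CI coverage of the standardized
#' structural coefficients against their generating values, the convergence
#' rate, and the average direct/indirect/total effect table.
#'
#' @param config generator configuration.
#' @param reps number of replicates (>= 2).
#' @param n cohort size per replicate.
#' @param seed base seed; replicate r uses `seed + r`.
#' @return list of class `recovery_report`.
#' @export
recovery_experiment <- function(config = default_config(), reps = 100,
                                n = config$n, seed = config$seed) {
  stopifnot(reps >= 2)
  spec <- default_sem_spec()
  gen_B <- generation_plan(config)$B_std
  path_labels <- grep("^beta:", spec$parameter_labels, value = TRUE)
  gen_for_label <- vapply(path_labels, function(lab) {
    ft <- strsplit(sub("^beta:", "", lab), "->", fixed = TRUE)[[1]]
    gen_B[ft[2], ft[1]]
  }, numeric(1))
  est <- matrix(NA_real_, reps, length(path_labels),
                dimnames = list(NULL, path_labels))
  sem <- matrix(NA_real_, reps, length(path_labels),
                dimnames = list(NULL, path_labels))
  eff_acc <- NULL
  converged <- logical(reps)
  failures <- 0L
  t0 <- proc.time()[["elapsed"]]
  for (r in seq_len(reps)) {
    res <- tryCatch({
      cohort <- generate_cohort(config, seed = seed + r, n = n)
      dat <- prepare_model_data(cohort)
      fit <- fit_ml(spec, dat)
      std <- standardize(fit)
      se_std <- standardized_se(fit)
      eff <- decompose_effects(fit, "dep")
      list(fit = fit, std = std, se_std = se_std, eff = eff)
    }, error = function(e) NULL)
    if (is.null(res)) { failures <- failures + 1L; next }
    converged[r] <- res$fit$converged
    est[r, ] <- res$std$estimates[path_labels]
    sem[r, ] <- res$se_std[path_labels]
    eff_num <- as.matrix(res$eff[, c("direct", "indirect", "total")])
    eff_acc <- if (is.null(eff_acc)) eff_num else eff_acc + eff_num
  }
  ok <- converged & !is.na(est[, 1])
  mean_est <- colMeans(est[ok, , drop = FALSE])
  bias <- mean_est - gen_for_label
  rmse <- sqrt(colMeans(sweep(est[ok, , drop = FALSE], 2, gen_for_label)^2))
  cover <- colMeans(abs(sweep(est[ok, , drop = FALSE], 2, gen_for_label)) <=
                      1.96 * sem[ok, , drop = FALSE])
  eff_mean <- eff_acc / sum(ok)
  paths <- data.frame(parameter = path_labels,
                      generating = gen_for_label, mean_estimate = mean_est,
                      bias = bias, rmse = rmse, coverage = cover,
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(paths = paths,
                 effects_mean = data.frame(
                   source = decompose_sources(spec), eff_mean,
                   stringsAsFactors = FALSE, row.names = NULL),
                 convergence_rate = sum(converged) / max(reps - failures, 1L),
                 n_converged = sum(ok), reps = reps, n = n,
                 failures = failures,
                 runtime_s = proc.time()[["elapsed"]] - t0),
            class = "recovery_report")
}

decompose_sources <- function(spec) {
  setdiff(structural_variables(spec), "dep")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("recovery_report:", x$n_converged, "/", x$reps,
      "converged replicates at n =", x$n,
      sprintf("(%.1f s)\n", x$runtime_s))
  y <- x$paths
  y[, -1] <- round(y[, -1], 3)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Delta-method standard errors of the standardized free parameters
#'
#' @param fit a `sem_fit`.
#' @return named numeric vector aligned with `spec$parameter_labels`.
#' @export
standardized_se <- function(fit) {
  spec <- fit$spec
  f <- function(theta) std_solution(spec, theta)$estimates
  J <- num_jacobian(f, fit$theta)
  se <- sqrt(pmax(diag(J %*% fit$acov %*% t(J)), 0))
  names(se) <- spec$parameter_labels
  se
}
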