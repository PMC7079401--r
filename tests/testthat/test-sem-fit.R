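test_that("just-identified triad reproduces the closed-form solution", {
  set.seed(31)
  sp <- triad_spec()
  # simulate from a known single-factor model
  n <- 2000
  f <- rnorm(n)
  dat <- data.frame(y1 = f + rnorm(n, 0, sqrt(0.5)),
                    y2 = 0.8 * f + rnorm(n, 0, sqrt(0.5)),
                    y3 = 0.6 * f + rnorm(n, 0, sqrt(0.5)))
  fit <- fit_ml(sp, dat)
  expect_true(fit$converged)
  # df = 0: perfect reproduction of S, chi2 = 0
  expect_equal(fit$F_ML, 0, tolerance = 1e-8)
  expect_equal(fit$chi2_ml, 0, tolerance = 1e-5)
  cf <- triad_closed_form(fit$S_sample)
  expect_equal(unname(fit$theta["lambda:y2"]), cf$lambda[2], tolerance = 1e-5)
  expect_equal(unname(fit$theta["lambda:y3"]), cf$lambda[3], tolerance = 1e-5)
  expect_equal(unname(fit$theta["psi:f"]), cf$psi, tolerance = 1e-5)
  expect_equal(unname(fit$theta[c("psi:y1", "psi:y2", "psi:y3")]),
               unname(cf$theta), tolerance = 1e-5)
})

test_that("saturated model attains zero discrepancy", {
  set.seed(32)
  # x -> y, x -> z with the y~~z residual covariance free: 6 moments,
  # 6 free parameters, df = 0
  sp <- build_spec(
    measurement = list(),
    structural = data.frame(from = c("x", "x"), to = c("y", "z")),
    covariances = data.frame(a = "y", b = "z"))
  expect_equal(sp$df, 0)
  dat <- as.data.frame(matrix(rnorm(300), 100, 3))
  names(dat) <- c("x", "y", "z")
  fit <- fit_ml(sp, dat)
  expect_equal(fit$chi2_ml, 0, tolerance = 1e-6)
  expect_equal(unname(fit$Sigma_hat), unname(fit$S_sample), tolerance = 1e-6)
})

test_that("parameters are recovered from data simulated off the default spec", {
  set.seed(33)
  spec <- default_sem_spec()
  cfg <- default_config()
  coh <- generate_cohort(cfg, seed = 40, n = 5000)
  fit0 <- fit_ml(spec, prepare_model_data(coh))
  # draw exact multivariate-normal data from the fitted model and refit
  dat <- simulate_from_spec(spec, fit0$theta, n = 60000, seed = 41)
  fit <- fit_ml(spec, dat)
  expect_true(fit$converged)
  expect_equal(unname(fit$theta), unname(fit0$theta), tolerance = 0.08)
  # standard errors: z-residuals of free parameters should be O(1)
  z <- (fit$theta - fit0$theta) / fit$se
  expect_lt(max(abs(z)), 5)
})

test_that("Satorra-Bentler scaling approaches 1 under exact normality", {
  set.seed(34)
  spec <- triad_spec()
  theta <- c(0.8, 0.6, 0.5, 0.4, 0.6, 1.0)
  # over-identify by adding a 4th indicator
  sp4 <- build_spec(measurement = list(f = c("y1", "y2", "y3", "y4")),
                    structural = data.frame(from = character(0),
                                            to = character(0)))
  th4 <- c(0.8, 0.6, 0.7, 0.5, 0.4, 0.6, 0.5, 1.0)
  dat <- simulate_from_spec(sp4, th4, n = 5000, seed = 35)
  fit <- fit_ml(sp4, dat)
  sb <- satorra_bentler(fit)
  expect_lt(abs(sb$scaling_c - 1), 0.05)
  expect_equal(sb$chi2_sb * sb$scaling_c, fit$chi2_ml, tolerance = 1e-10)
  expect_error(satorra_bentler(fit_ml(spec,
                                      dat[, 1:3])), "df = 0")
})

test_that("weight and fourth-moment matrices agree with brute-force builds", {
  set.seed(36)
  X <- matrix(rnorm(600), 200, 3)
  # brute-force Gamma: explicit loop over vech pairs
  p <- 3
  Xc <- scale(X, center = TRUE, scale = FALSE)
  pairs <- list(c(1, 1), c(2, 1), c(3, 1), c(2, 2), c(3, 2), c(3, 3))
  D <- sapply(pairs, function(ij) Xc[, ij[1]] * Xc[, ij[2]])
  G_brute <- crossprod(scale(D, center = TRUE, scale = FALSE)) / nrow(X)
  expect_equal(stressproc:::fourth_moment_gamma(X), G_brute,
               tolerance = 1e-10, ignore_attr = TRUE)

  # normal-theory weight: W = Gamma_NT^{-1} with
  # Gamma_NT[ij,kl] = sigma_ik sigma_jl + sigma_il sigma_jk
  S <- cov(X)
  G_NT <- matrix(0, 6, 6)
  for (a in 1:6) for (b in 1:6) {
    i <- pairs[[a]][1]; j <- pairs[[a]][2]
    k <- pairs[[b]][1]; l <- pairs[[b]][2]
    G_NT[a, b] <- S[i, k] * S[j, l] + S[i, l] * S[j, k]
  }
  W <- stressproc:::normal_theory_weight(solve(S))
  expect_equal(solve(W), G_NT, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("fit indices follow their defining arithmetic", {
  set.seed(37)
  sp4 <- build_spec(measurement = list(f = c("y1", "y2", "y3", "y4")),
                    structural = data.frame(from = character(0),
                                            to = character(0)))
  th4 <- c(0.8, 0.6, 0.7, 0.5, 0.4, 0.6, 0.5, 1.0)
  dat <- simulate_from_spec(sp4, th4, n = 900, seed = 38)
  fit <- fit_ml(sp4, dat)

  # frozen arithmetic oracle on synthetic chi-squares
  fake <- fit
  fake$chi2_ml <- 50; fake$df <- 25; fake$n <- 916
  base <- list(chi2_ml = 1000, df = 45, chi2_sb = 1000, scaling_c = 1)
  sb <- list(chi2_sb = 50, scaling_c = 1, df = 25, p_value = 0.5)
  idx <- fit_indices(fake, baseline = base, sb = sb)
  expect_equal(idx$ml$rmsea, sqrt(25 / (25 * 915)), tolerance = 1e-12)
  expect_equal(idx$ml$cfi, 1 - 25 / 955, tolerance = 1e-12)
  expect_equal(idx$ml$tli,
               ((1000 / 45) - 2) / ((1000 / 45) - 1), tolerance = 1e-12)

  # perfect fit: saturated-like triad gives RMSEA 0, CFI 1, SRMR ~ 0
  triad <- fit_ml(triad_spec(), dat[, 1:3])
  base_t <- baseline_fit(triad)
  idx_t <- fit_indices(triad, baseline = base_t, sb = NULL)
  expect_equal(idx_t$ml$rmsea, 0)
  expect_equal(idx_t$ml$cfi, 1)
  expect_lt(idx_t$srmr, 1e-6)

  # real over-identified fit: indices in range, CD in [0, 1]
  idx4 <- fit_indices(fit)
  expect_gte(idx4$sb$rmsea, 0)
  expect_lte(idx4$sb$cfi, 1)
  expect_true(idx4$cd >= 0 && idx4$cd <= 1)
})

test_that("standardization rescales by implied sds and is scale invariant", {
  # single path x -> y with var(x) = 4, b = 0.25, residual var 0.75:
  # implied var(y) = 1, standardized coefficient 0.5
  sp <- build_spec(measurement = list(),
                   structural = data.frame(from = "x", to = "y"))
  fit <- structure(list(spec = sp, theta = c(0.25, 4, 0.75)),
                   class = "sem_fit")
  std <- standardize(fit)
  expect_equal(unname(std$estimates["beta:x->y"]), 0.5, tolerance = 1e-12)

  # rescaling an indicator leaves the standardized solution unchanged
  set.seed(39)
  cfg <- default_config()
  dat <- prepare_model_data(generate_cohort(cfg, seed = 50, n = 916))
  spec <- default_sem_spec()
  f1 <- fit_ml(spec, dat)
  dat2 <- dat
  dat2$parcel_2 <- dat2$parcel_2 * 10
  f2 <- fit_ml(spec, dat2)
  s1 <- standardize(f1)$estimates
  s2 <- standardize(f2)$estimates
  keep <- grep("beta:|lambda:", names(s1))
  expect_equal(s1[keep], s2[keep], tolerance = 1e-4)
})

test_that("R-squared of endogenous variables comes from implied variances", {
  sp <- build_spec(measurement = list(),
                   structural = data.frame(from = "x", to = "y"))
  fit <- structure(list(spec = sp, theta = c(0.25, 4, 0.75)),
                   class = "sem_fit")
  r2 <- r_squared(fit)
  expect_equal(unname(r2["y"]), 0.25, tolerance = 1e-12)  # 1 - 0.75/1
})

test_that("Heywood cases are reported, and bounds can prevent them", {
  set.seed(40)
  # tiny sample with a near-degenerate indicator often drives a residual
  # variance negative; the flag must report it rather than crash
  sp <- triad_spec()
  found <- FALSE
  for (s in 1:20) {
    set.seed(s)
    n <- 30
    f <- rnorm(n)
    dat <- data.frame(y1 = f + rnorm(n, 0, 0.1),
                      y2 = f + rnorm(n, 0, 1.5),
                      y3 = f + rnorm(n, 0, 0.05))
    fit <- fit_ml(sp, dat)
    if (length(fit$heywood)) {
      found <- TRUE
      fitb <- fit_ml(sp, dat, constrain_variances = TRUE)
      expect_length(fitb$heywood, 0)
      break
    }
  }
  expect_true(found)
})
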