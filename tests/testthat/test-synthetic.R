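test_that("path calibration inverts the effect decomposition", {
  # single-mediator chain: with M -> Y fixed at 0.4 and targets direct 0.3
  # / indirect 0.2, the X -> M path must solve to 0.5
  topo <- data.frame(from = c("X", "M", "X"), to = c("M", "Y", "Y"),
                     fixed = c(NA, 0.4, NA))
  targets <- data.frame(source = c("X", "M"), direct = c(0.3, 0.4),
                        indirect = c(0.2, 0))
  cal <- calibrate_paths(targets, topo, outcome = "Y")
  expect_equal(cal$B["M", "X"], 0.5, tolerance = 1e-6)
  expect_lt(cal$residual, 1e-6)

  # round-trip on the packaged targets: forward decomposition reproduces
  # the published direct and indirect columns
  tg <- table4_targets()
  cal4 <- calibrate_paths(tg, default_topology())
  tot <- total_effects(cal4$B)
  for (k in seq_len(nrow(tg))) {
    src <- tg$source[k]
    expect_equal(cal4$B["dep", src], tg$direct[k], tolerance = 1e-9)
    expect_equal(tot["dep", src] - cal4$B["dep", src], tg$indirect[k],
                 tolerance = 1e-3)
  }

  # indirect target without any mediator path is infeasible
  topo0 <- data.frame(from = "X", to = "Y", fixed = NA)
  expect_error(calibrate_paths(data.frame(source = "X", direct = 0.3,
                                          indirect = 0.2),
                               topo0, outcome = "Y"), "infeasible")
})

test_that("default config validates and carries the published margins", {
  cfg <- default_config()
  expect_equal(unname(cfg$stressor_prevalences["untimed"]), 0.134)
  expect_equal(unname(cfg$stressor_prevalences["food_difficulty"]), 0.042)
  # implied total effect of fear of birth under the calibrated B
  tot <- total_effects(cfg$structural$B)
  expect_equal(tot["dep", "fear_birth"], 0.30, tolerance = 1e-3)
  expect_silent(validate_config(cfg))
  bad <- cfg
  bad$epds_thresholds <- c(1, 1, 2)
  expect_error(validate_config(bad), "increasing")
})

test_that("generation is deterministic given the seed", {
  cfg <- default_config()
  a <- generate_cohort(cfg, seed = 123, n = 200)
  b <- generate_cohort(cfg, seed = 123, n = 200)
  expect_identical(a, b)
  c <- generate_cohort(cfg, seed = 124, n = 200)
  expect_false(identical(a, c))
})

test_that("generated records respect the declared ranges", {
  coh <- generate_cohort(default_config(), seed = 7, n = 500)
  items <- as.matrix(coh[paste0("epds_", 1:10)])
  expect_true(all(items %in% 0:3))
  expect_true(all(coh$marital_agreement %in% 1:4))
  expect_true(all(coh$partner_support %in% 1:5))
  expect_true(all(coh$osss3_1 %in% 1:4))
  expect_true(all(coh$osss3_2 %in% 1:5 & coh$osss3_3 %in% 1:5))
  expect_true(all(rowSums(coh[paste0("osss3_", 1:3)]) %in% 3:14))
  expect_true(all(coh$gestational_weeks >= 13 & coh$gestational_weeks <= 42))
  expect_true(all(coh$muac_cm > 0))
  expect_true(all(coh$pregnancy_intention %in%
                    c("planned", "untimed", "unintended")))
  expect_true(all(coh$cluster_id %in% 1:6))
})

test_that("marginal prevalences converge to the configured values", {
  cfg <- default_config()
  coh <- generate_cohort(cfg, seed = 202, n = 50000)
  prev <- cfg$stressor_prevalences
  expect_lt(abs(mean(coh$food_access_difficulty) - prev[["food_difficulty"]]),
            0.005)
  expect_lt(abs(mean(coh$pregnancy_intention == "untimed") -
                  prev[["untimed"]]), 0.005)
  expect_lt(abs(mean(coh$pregnancy_intention == "unintended") -
                  prev[["unintended"]]), 0.005)
  expect_lt(abs(mean(coh$fear_of_birth) - prev[["fear_of_birth"]]), 0.005)
  expect_lt(abs(mean(coh$history_cmd) - prev[["history_cmd"]]), 0.005)
})

test_that("zero structural paths produce a null association pattern", {
  cfg <- default_config()
  zero <- table4_targets()
  zero$direct <- 0; zero$indirect <- 0; zero$total <- 0
  cfg$targets <- zero
  cfg$structural <- calibrate_paths(zero, default_topology())
  cfg$prop_coef_override <- NULL
  cfg$dep_resid_override <- NULL
  coh <- generate_cohort(cfg, seed = 203, n = 5000)
  tot <- rowSums(coh[paste0("epds_", 1:10)])
  expect_lt(abs(cor(tot, coh$fear_of_birth)), 0.05)
  expect_lt(abs(cor(tot, coh$food_access_difficulty)), 0.05)
  expect_lt(abs(cor(tot, coh$marital_agreement)), 0.05)
})

test_that("generated parcels form a clean single factor", {
  cfg <- default_config()
  ok <- 0
  for (s in 1:5) {
    coh <- generate_cohort(cfg, seed = 300 + s, n = 916)
    pc <- parcel_cohort(score_cohort(coh))
    fit <- fit_ml(triad_spec(),
                  setNames(pc[paste0("parcel_", 1:3)],
                           c("y1", "y2", "y3")))
    # a 3-indicator factor is just-identified: admissibility is the test
    if (fit$converged && !length(fit$heywood)) ok <- ok + 1
  }
  expect_gte(ok, 4)
})

test_that("PCI coping totals centre near the published median", {
  coh <- generate_cohort(default_config(), seed = 400, n = 5000)
  tot <- rowSums(coh[paste0("pci4_", 1:4)])
  expect_true(median(tot) %in% 7:9)
})

test_that("recovery harness reports all structural paths", {
  rep2 <- recovery_experiment(default_config(), reps = 2, n = 250,
                              seed = 500)
  expect_equal(nrow(rep2$paths), 14)
  expect_true(all(c("generating", "mean_estimate", "bias", "rmse",
                    "coverage") %in% names(rep2$paths)))
  expect_true(rep2$runtime_s > 0)
})
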