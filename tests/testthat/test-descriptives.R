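test_that("Pearson chi-square matches direct formula evaluation", {
  null_tab <- matrix(10, 2, 2)
  r0 <- pearson_chi_square(null_tab)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  r1 <- pearson_chi_square(matrix(c(20, 10, 10, 20), 2))
  expect_equal(r1$statistic, 100 / 15, tolerance = 1e-12)  # all E = 15
  expect_equal(r1$df, 1)

  # trimester-by-depression counts; oracle = literal sum((O-E)^2/E)
  O <- matrix(c(16, 47, 323, 530), 2)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  r2 <- pearson_chi_square(O)
  expect_equal(r2$statistic, sum((O - E)^2 / E), tolerance = 1e-12)
  expect_equal(r2$p_value,
               pchisq(sum((O - E)^2 / E), 1, lower.tail = FALSE))

  # independent route: stats::chisq.test without correction
  ct <- suppressWarnings(chisq.test(O, correct = FALSE))
  expect_equal(r2$statistic, unname(ct$statistic), tolerance = 1e-10)

  # invariance under row/column permutation
  perm <- matrix(c(47, 16, 530, 323), 2)
  expect_equal(pearson_chi_square(perm)$statistic, r2$statistic)
})

test_that("Fisher enumeration reproduces the hypergeometric closed form", {
  # diagonal 3+3 table: point probs (.05,.45,.45,.05) -> two-sided p = .10
  r <- fisher_exact(matrix(c(3, 0, 0, 3), 2))
  expect_equal(r$p_value, 0.10, tolerance = 1e-10)

  # zero row margin: single possible table
  expect_equal(fisher_exact(matrix(c(0, 3, 0, 5), 2))$p_value, 1)

  # food-access 2x2: strongly associated
  food <- matrix(c(13, 50, 25, 828), 2, byrow = TRUE)
  expect_lte(fisher_exact(food)$p_value, 0.001)

  # enumeration equals stats::fisher.test (probability-mass rule) across
  # random small tables, 2x2 and 2x3
  set.seed(11)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 4), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact(tab)$p_value,
                 fisher.test(tab)$p.value, tolerance = 1e-8)
  }
  for (i in 1:10) {
    tab <- matrix(rpois(6, 3), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact(tab)$p_value,
                 fisher.test(tab)$p.value, tolerance = 1e-8)
  }
  expect_error(fisher_exact(matrix(200, 3, 3), max_tables = 1000), "large")
})

test_that("expected-count rule picks the footnoted test", {
  food <- matrix(c(13, 50, 25, 828), 2, byrow = TRUE)
  expect_equal(choose_test(food), "fisher_exact")     # min E ~ 2.61
  trim <- matrix(c(16, 47, 323, 530), 2)
  expect_equal(choose_test(trim), "pearson_chi2")     # min E ~ 23.3
  expect_equal(choose_test(matrix(100, 2, 2)), "pearson_chi2")
  expect_equal(test_association(food)$method, "fisher_exact")
})

test_that("Clopper-Pearson prevalence reproduces printed intervals", {
  p <- prevalence(63, 916)
  expect_equal(p$percent, 6.9)
  expect_equal(p$percent_ci, c(5.3, 8.7))
  expect_equal(p$proportion, 63 / 916)

  # independent oracle: beta-quantile relation and stats::binom.test
  expect_equal(p$ci_low, qbeta(0.025, 63, 916 - 63 + 1), tolerance = 1e-12)
  expect_equal(p$ci_high, qbeta(0.975, 64, 916 - 63), tolerance = 1e-12)
  bt <- binom.test(63, 916)
  expect_equal(c(p$ci_low, p$ci_high), as.numeric(bt$conf.int),
               tolerance = 1e-9, ignore_attr = TRUE)

  expect_equal(prevalence(0, 50)$ci_low, 0)
  expect_equal(prevalence(50, 50)$ci_high, 1)
  p2 <- prevalence(5, 10)
  expect_equal(c(p2$ci_low, p2$ci_high),
               c(qbeta(.025, 5, 6), qbeta(.975, 6, 5)), tolerance = 1e-12)
  expect_error(prevalence(5, 4), "<=")
})

test_that("Clopper-Pearson coverage is at least nominal in simulation", {
  set.seed(20)
  p_true <- 0.07; n <- 916
  k <- rbinom(4000, n, p_true)
  lo <- ifelse(k == 0, 0, qbeta(0.025, k, n - k + 1))
  hi <- ifelse(k == n, 1, qbeta(0.975, k + 1, n - k))
  expect_gte(mean(lo <= p_true & p_true <= hi), 0.95)
})

test_that("numeric summaries use sample sd and type-7 quartiles", {
  s <- summarize_numeric(c(1, 2, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$median, 2)
  expect_equal(summarize_numeric(rep(4, 5))$sd, 0)
  s6 <- summarize_numeric(c(2, 7, 1, 9, 4, 6))
  expect_equal(c(s6$q1, s6$median, s6$q3), c(2.5, 5, 6.75))
  expect_error(summarize_numeric(numeric(0)), "values")
})

test_that("Fleiss sample size behaves per the continuity-corrected formula", {
  # direct re-evaluation of the formula as an independent arithmetic oracle
  oracle <- function(alpha, power, r, p2, rr) {
    p1 <- p2 * rr
    za <- qnorm(1 - alpha / 2); zb <- qnorm(power)
    pb <- (p1 + r * p2) / (1 + r); qb <- 1 - pb; d <- abs(p1 - p2)
    n1 <- (za * sqrt((r + 1) / r * pb * qb) +
             zb * sqrt(p1 * (1 - p1) + p2 * (1 - p2) / r))^2 / d^2
    n1c <- n1 / 4 * (1 + sqrt(1 + 2 * (r + 1) / (n1 * r * d)))^2
    ceiling(n1c) + ceiling(r * n1c)
  }
  got <- sample_size_two_proportions(0.05, 0.9, 2, 0.25, 1.5)
  expect_equal(got$n_total, oracle(0.05, 0.9, 2, 0.25, 1.5))
  expect_equal(got$p_exposed, 0.375)

  # monotonicity: more power, or smaller effect, needs more subjects
  lo_pow <- sample_size_two_proportions(0.05, 0.8, 2, 0.25, 1.5)$n_total
  expect_gt(got$n_total, lo_pow)
  small_eff <- sample_size_two_proportions(0.05, 0.9, 2, 0.25, 1.2)$n_total
  expect_gt(small_eff, got$n_total)

  # attrition inflation rounds up
  expect_equal(inflate_for_attrition(809, 0.2), 971L)
  expect_equal(got$n_total_inflated,
               as.integer(ceiling(got$n_total * 1.0)))

  expect_error(sample_size_two_proportions(0.05, 0.9, 2, 0.25, 1),
               "unbounded")
  # absolute-difference reading of the effect
  ad <- sample_size_two_proportions(0.05, 0.9, 2, 0.25, 0.125,
                                    effect_type = "absolute_difference")
  expect_equal(ad$n_total, got$n_total)
})

test_that("crosstab builder returns counts, percents and a test", {
  cfg <- default_config()
  coh <- score_cohort(generate_cohort(cfg, seed = 9, n = 400))
  coh$depressed <- coh$epds_total >= 12
  ct <- crosstab_depression(coh, "fear_of_birth")
  expect_equal(sum(ct$table), 400)
  expect_true(ct$test$method %in% c("pearson_chi2", "fisher_exact"))
  expect_true(ct$test$p_value >= 0 && ct$test$p_value <= 1)
  expect_equal(unname(colSums(ct$percent)), c(100, 100), tolerance = 0.2)
})
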