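test_that("EPDS scoring applies totals, categories and flags", {
  s0 <- score_epds(rep(0L, 10))
  expect_equal(s0$total, 0)
  expect_equal(s0$category, "none")
  expect_length(s0$flags, 0)

  s30 <- score_epds(rep(3L, 10))
  expect_equal(s30$total, 30)
  expect_equal(s30$category, "excluded_high")
  expect_true(all(c("self_harm_flag", "referral_flag", "exclusion_flag")
                  %in% s30$flags))

  # category boundaries: 11 none / 12 possible / 16 possible / 17 excluded
  mk <- function(total) {
    r <- rep(0L, 10)
    r[seq_len(total %/% 3)] <- 3L
    r[total %/% 3 + 1] <- total %% 3
    r[1:10]
  }
  expect_equal(score_epds(mk(11))$category, "none")
  expect_equal(score_epds(mk(12))$category, "possible_depression")
  expect_equal(score_epds(mk(16))$category, "possible_depression")
  expect_equal(score_epds(mk(17))$category, "excluded_high")

  # referral at >= 13, or any item-10 endorsement regardless of total
  expect_false("referral_flag" %in% score_epds(mk(12))$flags)
  expect_true("referral_flag" %in% score_epds(mk(13))$flags)
  low_self_harm <- c(rep(0L, 9), 1L)
  expect_true(all(c("self_harm_flag", "referral_flag") %in%
                    score_epds(low_self_harm)$flags))
})

test_that("EPDS scorer rejects malformed input", {
  expect_error(score_epds(rep(0L, 9)), "10")
  expect_error(score_epds(c(rep(0L, 9), 4L)), "range")
  expect_error(score_epds(c(rep(0L, 9), NA)), "missing")
  expect_error(score_epds(c(rep(0.5, 10))), "integer")
})

test_that("EPDS total is monotone in each item", {
  base <- c(1L, 0L, 2L, 1L, 0L, 1L, 2L, 0L, 1L, 0L)
  t0 <- score_epds(base)$total
  for (i in 1:10) {
    bumped <- base
    bumped[i] <- bumped[i] + 1L
    expect_gt(score_epds(bumped)$total, t0 - 1e-12)
  }
})

test_that("OSSS-3 scoring uses the poor/<9 rule on the 3..14 range", {
  expect_equal(score_osss3(c(1L, 1L, 1L))$total, 3)
  expect_equal(score_osss3(c(1L, 1L, 1L))$category, "poor")
  expect_equal(score_osss3(c(4L, 5L, 5L))$total, 14)
  # boundary forced by "less than nine"
  expect_equal(score_osss3(c(2L, 3L, 3L))$category, "poor")          # 8
  expect_equal(score_osss3(c(2L, 3L, 4L))$category, "moderate_to_strong") # 9
  expect_error(score_osss3(c(5L, 5L, 5L)), "range")  # item 1 max is 4
  expect_error(score_osss3(c(1L, 1L)), "3")
})

test_that("PCI-4 totals span 0..12 with no category", {
  expect_equal(score_pci4(rep(0L, 4))$total, 0)
  expect_equal(score_pci4(rep(3L, 4))$total, 12)
  expect_true(is.na(score_pci4(rep(1L, 4))$category))
  expect_error(score_pci4(rep(4L, 4)), "range")
})

test_that("MUAC rule set matches the printed cutoffs, gap unassigned", {
  expect_equal(classify_muac(20.0), "normal")
  expect_equal(classify_muac(24.1), "underweight")
  expect_equal(classify_muac(17.0), "out_of_range")
  expect_equal(classify_muac(22.2), "out_of_range")  # 22-22.5 gap
  expect_equal(classify_muac(22.0), "normal")
  expect_equal(classify_muac(22.5), "underweight")
  # the conventional rule swaps the labels
  expect_equal(classify_muac(20.0, "conventional"), "underweight")
  expect_equal(classify_muac(24.1, "conventional"), "normal")
  expect_error(classify_muac(-1), "positive")
})

test_that("Cronbach alpha matches direct formula evaluation", {
  # perfectly consistent: three duplicated columns
  x <- rnorm(10)
  expect_equal(cronbach_alpha(cbind(x, x, x)), 1.0)

  # 4-subject x 3-item toy matrix, frozen from direct population-variance
  # evaluation of k/(k-1) (1 - sum var_i / var_total)
  m <- matrix(c(1, 2, 3, 4, 2, 3, 4, 5, 1, 3, 2, 4), nrow = 4)
  expect_equal(cronbach_alpha(m), 0.9512195, tolerance = 1e-6)

  # invariant to adding a constant to all items
  expect_equal(cronbach_alpha(m + 7), cronbach_alpha(m))

  expect_warning(a <- cronbach_alpha(matrix(1, 5, 3)), "zero")
  expect_true(is.na(a))
  expect_error(cronbach_alpha(m[1:2, ]), "subjects")
})

test_that("eligibility partitions the cohort exactly", {
  totals <- c(rep(5, 880), rep(13, 20), rep(14, 16), rep(17, 20), rep(25, 4))
  rec <- cohort_with_totals(totals)  # 940 records, 24 with >= 17
  parts <- apply_eligibility(rec)
  expect_equal(nrow(parts$analysis), 916)
  expect_equal(nrow(parts$excluded), 24)
  expect_equal(nrow(parts$analysis) + nrow(parts$excluded), nrow(rec))
  # referral: >= 13 (includes the excluded records)
  expect_equal(nrow(parts$referral), 60)

  empty <- rec[0, ]
  pe <- apply_eligibility(empty)
  expect_equal(nrow(pe$analysis), 0)
  expect_equal(nrow(pe$excluded), 0)
  expect_equal(nrow(pe$referral), 0)

  low <- cohort_with_totals(rep(3, 10))
  pl <- apply_eligibility(low)
  expect_equal(nrow(pl$excluded), 0)
  expect_equal(nrow(pl$referral), 0)
})

test_that("scoring is row-wise: permutation of subjects permutes results", {
  cfg <- default_config()
  coh <- generate_cohort(cfg, seed = 42, n = 40)
  sc <- score_cohort(coh)
  perm <- sample(nrow(coh))
  sc_perm <- score_cohort(coh[perm, ])
  expect_equal(sc_perm$epds_total, sc$epds_total[perm])
  expect_equal(sc_perm$osss3_category, sc$osss3_category[perm])
})

test_that("cohort reader applies column maps and the EPDS direction key", {
  cfg <- default_config()
  coh <- generate_cohort(cfg, seed = 3, n = 15)
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  renamed <- coh
  names(renamed)[names(renamed) == "epds_1"] <- "edinburgh_q1"
  write.csv(renamed, f, row.names = FALSE)
  back <- read_cohort(f, column_map = c(edinburgh_q1 = "epds_1"))
  expect_equal(back$epds_1, coh$epds_1)

  # raw-coded file: reverse-keyed items are flipped on read
  raw <- coh
  key <- epds_direction_key()
  for (i in which(key < 0)) {
    raw[[paste0("epds_", i)]] <- 3L - raw[[paste0("epds_", i)]]
  }
  write.csv(raw, f, row.names = FALSE)
  decoded <- read_cohort(f, epds_raw = TRUE)
  for (i in 1:10) {
    expect_equal(decoded[[paste0("epds_", i)]], coh[[paste0("epds_", i)]])
  }
})
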