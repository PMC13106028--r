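test_that("spirometric eligibility applies strict thresholds", {
  p <- pheno_params()
  e <- assess_eligibility(list(age = 55, fev1_fvc = 0.69, pack_years = 15),
                          p, mode = "spirometric")
  expect_true(e$eligible)
  # ratio exactly at 0.7 fails the strict inequality
  e <- assess_eligibility(list(age = 55, fev1_fvc = 0.70, pack_years = 15),
                          p, mode = "spirometric")
  expect_false(e$eligible)
  e <- assess_eligibility(list(age = 55, fev1_fvc = 0.69, pack_years = 9),
                          p, mode = "spirometric")
  expect_false(e$eligible)
  # smoker flag substitutes for pack-years only when allowed
  rec <- list(age = 55, fev1_fvc = 0.6, smoker_flag = TRUE)
  expect_equal(assess_eligibility(rec, p, "spirometric")$status,
               "indeterminate")
  expect_true(assess_eligibility(rec, p, "spirometric",
                                 allow_smoker_flag = TRUE)$eligible)
})

test_that("ICD eligibility needs a J41-J44 code, smoking and age 40-85", {
  p <- pheno_params()
  base <- list(age = 60, icd_codes = "J44.9", smoker_flag = TRUE)
  expect_true(assess_eligibility(base, p, "icd")$eligible)
  expect_false(assess_eligibility(modifyList(base, list(icd_codes = "J45.0")),
                                  p, "icd")$eligible)
  expect_false(assess_eligibility(modifyList(base, list(age = 86)),
                                  p, "icd")$eligible)
  expect_true(assess_eligibility(modifyList(base, list(age = 40)),
                                 p, "icd")$eligible)
  expect_false(assess_eligibility(modifyList(base, list(smoker_flag = FALSE)),
                                  p, "icd")$eligible)
  expect_equal(assess_eligibility(list(age = 60, icd_codes = "J44.9"),
                                  p, "icd")$status, "indeterminate")
})

test_that("cleaning removes implausible records then one IQR pass", {
  mk <- function(w) data.frame(time_days = seq_along(w) * 30,
                               weight_kg = w)
  r <- clean_series(mk(c(80, 81, 19, 80)))
  expect_equal(r$report$low_weight, 1)
  expect_equal(r$series$weight_kg, c(80, 81, 80))

  # IQR fence with zero IQR: any deviation from the common value goes
  r <- clean_series(mk(c(80, 80, 80, 80, 160)))
  expect_equal(r$report$iqr_outlier, 1)
  expect_false(160 %in% r$series$weight_kg)

  # clean input is untouched
  r <- clean_series(mk(c(78, 80, 82, 81)))
  expect_equal(r$report$low_weight + r$report$low_bmi +
                 r$report$iqr_outlier, 0)
  expect_equal(nrow(r$series), 4)

  # low BMI rule, and full accounting of removals
  s <- data.frame(time_days = c(0, 30, 60), weight_kg = c(80, 25, 80),
                  bmi = c(26, 8, 26))
  r <- clean_series(s)
  expect_equal(r$report$low_bmi, 1)
  expect_equal(r$report$retained + r$report$low_bmi, 3)
})

test_that("cleaning soundness: no implausible record survives", {
  set.seed(42)
  for (i in 1:50) {
    s <- random_series()
    # splice in contaminants
    bad <- data.frame(participant_id = "px",
                      time_days = sample.int(2200, 3),
                      weight_kg = c(runif(1, 5, 19.9), 15, 500),
                      bmi = c(NA, 8, 150))
    r <- clean_series(rbind(s, bad))
    expect_true(all(r$series$weight_kg >= 20))
    expect_true(all(is.na(r$series$bmi) | r$series$bmi >= 10))
  }
})

test_that("window enumeration yields the 17-window ladder", {
  s <- data.frame(time_days = c(0, 2000), weight_kg = c(80, 80))
  w <- enumerate_windows(s)
  expect_equal(nrow(w), 17)
  expect_equal(w$start_before, seq(60, 12, by = -3))
  expect_equal(w$span_months, c(rep(12, 15), 9, 6))
  expect_equal(w$start_before[1], 60)
  expect_equal(w$end_before[1], 48)
  expect_equal(w$start_before[17], 12)
  expect_equal(w$end_before[17], 6)
})

test_that("window slope fit matches closed-form OLS on collinear points", {
  dpm <- 30.4375
  # three exactly collinear points losing 1/3 kg per month, at 58, 52 and
  # 48 months before the final record: inside the (60,48] window only
  t_final <- round(108 * dpm)
  t <- t_final - round(c(58, 52, 48) * dpm)
  mm <- t / dpm
  w <- 80 - (mm - mm[1]) / 3
  s <- data.frame(time_days = c(t, t_final), weight_kg = c(w, 70))
  win <- enumerate_windows(s)[1, ]
  f <- fit_window_slope(s, win)
  expect_false(f$skipped)
  expect_equal(f$n_points, 3)
  expect_equal(f$slope, -1 / 3, tolerance = 1e-9)
  expect_equal(f$ref_weight, mean(w))
  expect_equal(f$annualized_loss_fraction, (1 / 3 * 12) / mean(w),
               tolerance = 1e-9)
  expect_equal(f$slope_p, 0)  # perfectly collinear: variance fully explained

  # two points are never fitted
  s2 <- s[c(1, 2, 4), ]
  expect_true(fit_window_slope(s2, win)$skipped)

  # constant weights: zero slope, zero loss fraction
  s3 <- s
  s3$weight_kg <- 80
  f3 <- fit_window_slope(s3, win)
  expect_equal(f3$slope, 0)
  expect_equal(f3$annualized_loss_fraction, 0)
})

test_that("EHR classifier detects an unregained loss episode", {
  dpm <- 30.4375
  # 80 kg baseline, -10%/yr for 18 months ending 12 months before the
  # final record, then plateau at 68 kg
  t <- round(seq(0, 72, by = 1.5) * dpm)
  onset <- round(42 * dpm)  # months 42..60 of a 72-month history
  loss_end <- round(60 * dpm)
  w <- ifelse(t <= onset, 80,
              ifelse(t <= loss_end, 80 - 0.10 * 80 / 365.25 * (t - onset),
                     80 - 0.10 * 80 / 365.25 * (loss_end - onset)))
  s <- data.frame(time_days = t, weight_kg = w, bmi = w / 1.75^2)
  call <- classify_ehr(s)
  expect_equal(call$status, "case")
  expect_equal(call$basis, "slope_window")
  expect_gt(call$max_wl_window_weight, call$final_weight)
})

test_that("fully regained episodes and flat low-BMI endings classify correctly", {
  dpm <- 30.4375
  t <- round(seq(0, 72, by = 1.5) * dpm)
  # loss then full regain to baseline, final BMI 24 -> control
  onset <- round(18 * dpm); bottom <- round(36 * dpm); top <- round(54 * dpm)
  w <- approx(x = c(0, onset, bottom, top, max(t)),
              y = c(80, 80, 68, 80, 80), xout = t)$y
  s <- data.frame(time_days = t, weight_kg = w, bmi = w / 1.82^2)
  expect_equal(classify_ehr(s)$status, "control")

  # flat trajectory but final BMI 19.5 -> case via the low-BMI rule
  s2 <- data.frame(time_days = t, weight_kg = 60, bmi = 19.5)
  call <- classify_ehr(s2)
  expect_equal(call$status, "case")
  expect_equal(call$basis, "low_bmi")

  # empty cleaned series is indeterminate, not control
  expect_equal(classify_ehr(s2[0, ])$status, "indeterminate")
})

test_that("annualized-loss threshold is sharp at 5% per year", {
  # in-window loss of 5%/yr (+1e-9 construction margin over the exactly
  # representable boundary) is detected; 4.9%/yr is not
  hi <- classify_ehr(sharpness_series(0.05 + 1e-9))
  lo <- classify_ehr(sharpness_series(0.049))
  expect_equal(hi$status, "case")
  expect_equal(hi$basis, "slope_window")
  expect_equal(lo$status, "control")
})

test_that("visit classifier applies the consecutive-pair and regain rules", {
  mk <- function(w, bmi_last = 24) {
    n <- length(w)
    data.frame(time_days = seq(0, by = 400, length.out = n),
               weight_kg = w, bmi = c(rep(NA, n - 1), bmi_last))
  }
  expect_equal(classify_visits(mk(c(80, 75, 76)))$status, "case")   # 6.25% kept off
  expect_equal(classify_visits(mk(c(80, 75, 81)))$status, "control") # regained
  expect_equal(classify_visits(mk(c(80, 75, 80)))$status, "control") # tie = regained
  expect_equal(classify_visits(mk(c(80, 78, 77)))$status, "control") # <5% per pair
  expect_equal(classify_visits(mk(c(80, 81, 82), bmi_last = 19))$basis,
               "low_bmi")
  expect_equal(classify_visits(mk(80))$status, "indeterminate")
})

test_that("strictly increasing weights with final BMI >= 20 are controls", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(4:30, 1)
    t <- sort(sample.int(2100, n))
    w <- 70 + cumsum(runif(n, 0.01, 1))
    s <- data.frame(time_days = t, weight_kg = w, bmi = w / 1.7^2)
    expect_equal(classify_ehr(s)$status, "control")
    expect_equal(classify_visits(s)$status, "control")
  }
})

test_that("EHR classifier agrees with the brute-force oracle", {
  set.seed(2024)
  for (i in 1:200) {
    s <- random_series()
    expect_equal(classify_ehr(s)$status, brute_classify_ehr(s),
                 info = sprintf("series %d", i))
  }
})

test_that("classification is deterministic", {
  set.seed(5)
  s <- random_series()
  c1 <- classify_ehr(s)
  c2 <- classify_ehr(s)
  expect_identical(c1, c2)
})

test_that("phenotype_cohort cleans, classifies and reports per participant", {
  set.seed(9)
  w1 <- random_series(); w1$participant_id <- "a"
  w2 <- random_series(); w2$participant_id <- "b"
  w2 <- rbind(w2, data.frame(participant_id = "b", time_days = 10,
                             weight_kg = 12, bmi = 5))
  ph <- phenotype_cohort(rbind(w1, w2), mode = "ehr")
  expect_equal(nrow(ph$calls), 2)
  expect_equal(sum(ph$cleaning$low_weight), 1)
  expect_true(all(ph$calls$status %in% c("case", "control",
                                         "indeterminate")))
})
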