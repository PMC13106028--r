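test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(n_participants = 0), "positive")
  expect_error(sim_config(case_fraction_target = 1.2), "case_fraction")
  expect_error(sim_config(aaf_spectrum = c(0.6)), "aaf_spectrum")
  expect_error(sim_config(n_variants = 5,
                          planted_effects = data.frame(variant = 9,
                                                       beta = 1)),
               "invalid variant indices")
})

test_that("genotype simulation hits requested allele frequencies", {
  ids <- sprintf("P%04d", 1:10000)
  cfg <- sim_config(n_participants = 10000, n_cohorts = 1,
                    n_variants = 3, aaf_spectrum = c(0, 0.5, 0.005),
                    seed = 3)
  g <- simulate_genotypes(cfg, ids)
  # AAF 0 -> monomorphic reference, MAC 0
  expect_equal(g$variants$aaf[1], 0)
  expect_equal(g$variants$mac[1], 0)
  expect_true(all(g$dosage[, 1] == 0))
  # AAF 0.5 at n = 10000: realized frequency within 3 binomial SDs
  expect_true(g$variants$aaf[2] > 0.485 && g$variants$aaf[2] < 0.515)
  # rare variant requested -> rare variant delivered
  expect_lt(g$variants$aaf[3], 0.01)
  expect_gt(g$variants$mac[3], 0)
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(n_participants = 50, n_cohorts = 2, n_variants = 10,
                    seed = 77)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$cohorts[[1]]$genotypes$dosage,
                   s2$cohorts[[1]]$genotypes$dosage)
  expect_identical(s1$cohorts[[1]]$weights, s2$cohorts[[1]]$weights)
  expect_identical(s1$cohorts[[2]]$truth, s2$cohorts[[2]]$truth)
})

test_that("phenotype intercept calibration lands on the target fraction", {
  ids <- sprintf("P%04d", 1:5000)
  cfg <- sim_config(n_participants = 5000, n_cohorts = 1, n_variants = 4,
                    case_fraction_target = 0.5,
                    covariate_effects = list(age = 0, sex = 0,
                                             pc = rep(0, 5)),
                    seed = 12)
  g <- simulate_genotypes(cfg, ids)
  cov <- simulate_covariates(cfg, ids)
  tr <- simulate_phenotype(g, cov, cfg)
  expect_lt(abs(mean(tr$wl_true) - 0.5), 0.02)

  # a huge planted effect saturates: nearly all alt-homozygotes are cases
  cfg2 <- sim_config(n_participants = 5000, n_cohorts = 1, n_variants = 4,
                     aaf_spectrum = 0.4, case_fraction_target = 0.3,
                     planted_effects = data.frame(variant = 1, beta = 10),
                     seed = 13)
  g2 <- simulate_genotypes(cfg2, ids)
  tr2 <- simulate_phenotype(g2, simulate_covariates(cfg2, ids), cfg2)
  hom <- g2$dosage[, 1] == 2
  expect_gt(mean(tr2$wl_true[hom]), 0.95)
})

test_that("case trajectories follow the closed-form loss profile", {
  cfg <- sim_config(n_participants = 200, n_cohorts = 1,
                    visit_style = "ehr_style", n_variants = 4,
                    trajectory_noise_sd = 0, low_bmi_case_fraction = 0,
                    contamination_rates = c(low_weight = 0, low_bmi = 0,
                                            outlier = 0),
                    seed = 21)
  st <- simulate_study(cfg)
  tr <- st$cohorts[[1]]$truth
  w <- st$cohorts[[1]]$weights
  cases <- tr[tr$wl_true == 1, ]
  expect_gt(nrow(cases), 20)
  for (i in seq_len(nrow(cases))) {
    s <- w[w$participant_id == cases$participant_id[i], ]
    expected_final <- cases$baseline_kg[i] *
      (1 - cases$episode_rate[i] * cases$episode_duration_days[i] / 365.25)
    expect_equal(s$weight_kg[nrow(s)], expected_final, tolerance = 1e-8)
  }
  # noiseless controls without episodes drift linearly: |slope| < 2%/yr
  ctrl <- tr[tr$wl_true == 0 & is.na(tr$episode_rate), ]
  for (i in seq_len(min(nrow(ctrl), 30))) {
    s <- w[w$participant_id == ctrl$participant_id[i], ]
    slope_frac <- (s$weight_kg[nrow(s)] - s$weight_kg[1]) /
      s$weight_kg[1] / (diff(range(s$time_days)) / 365.25)
    expect_lt(abs(slope_frac), 0.02)
  }
})

test_that("regain_fraction 1 returns every control episode to baseline", {
  cfg <- sim_config(n_participants = 150, n_cohorts = 1,
                    visit_style = "ehr_style", n_variants = 4,
                    trajectory_noise_sd = 0, regain_fraction = 1,
                    contamination_rates = c(low_weight = 0, low_bmi = 0,
                                            outlier = 0),
                    seed = 22)
  st <- simulate_study(cfg)
  tr <- st$cohorts[[1]]$truth
  w <- st$cohorts[[1]]$weights
  ctrl <- tr[tr$wl_true == 0, ]
  expect_true(all(!is.na(ctrl$episode_rate)))  # every control has an episode
  for (i in seq_len(nrow(ctrl))) {
    s <- w[w$participant_id == ctrl$participant_id[i], ]
    expect_gte(s$weight_kg[nrow(s)] + 1e-9, ctrl$baseline_kg[i])
  }
})

test_that("contamination honours rates and tags every inserted record", {
  cfg <- sim_config(n_participants = 400, n_cohorts = 1,
                    visit_style = "ehr_style", n_variants = 4, seed = 23)
  st <- simulate_study(cfg)
  w0 <- st$cohorts[[1]]$weights
  tr <- st$cohorts[[1]]$truth

  # rates 0: identity
  cfg0 <- cfg
  cfg0$contamination_rates[] <- 0
  clean <- w0[w0$contaminant_tag == "", , drop = FALSE]
  expect_identical(contaminate(clean, tr, cfg0), clean)

  # rate 1 for low weight: every participant gains a sub-20 kg record
  cfg1 <- cfg
  cfg1$contamination_rates <- c(low_weight = 1, low_bmi = 0, outlier = 0)
  wc <- contaminate(clean, tr, cfg1)
  low <- tapply(wc$weight_kg < 20, wc$participant_id, any)
  expect_true(all(low))

  # rates 0.05: per-rule counts inside the binomial 99% interval
  cfg2 <- cfg
  cfg2$contamination_rates <- c(low_weight = 0.05, low_bmi = 0.05,
                                outlier = 0.05)
  wc2 <- contaminate(clean, tr, cfg2)
  n <- length(unique(clean$participant_id))
  ci <- qbinom(c(0.005, 0.995), n, 0.05)
  for (tag in c("low_weight", "low_bmi", "outlier")) {
    cnt <- sum(wc2$contaminant_tag == tag)
    expect_gte(cnt, ci[1])
    expect_lte(cnt, ci[2])
  }
})

test_that("cohort files round-trip losslessly", {
  cfg <- sim_config(n_participants = 40, n_cohorts = 1, n_variants = 12,
                    aaf_spectrum = c(0.3, 0.005), seed = 31)
  st <- simulate_study(cfg)
  co <- st$cohorts[[1]]
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, st$masks, dir)

  w <- read_weights(paths["weights"])
  expect_equal(w$weight_kg, co$weights$weight_kg, tolerance = 1e-12)
  expect_equal(nrow(read.delim(paths["truth"])), nrow(co$truth))

  blk <- read_vcf(paths["vcf"])
  expect_equal(blk$variants$id, co$genotypes$variants$id)
  expect_equal(unname(blk$dosage), unname(co$genotypes$dosage))

  masks <- read_group_file(paths["groups"], blk)
  expect_setequal(masks$gene, st$masks$gene)
  expect_equal(nrow(masks), nrow(st$masks))
})
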