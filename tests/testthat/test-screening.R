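# Screening pathways: schedules, episode detection, misclassification,
# biopsy counting, and the pathway-equivalence identity.

test_that("screen ages form the protocol's arithmetic sequence", {
  expect_equal(screen_ages(screening_protocol(55, 64, 3)), c(55, 58, 61, 64))
  expect_equal(screen_ages(screening_protocol(55, 55, 3)), 55)
  expect_equal(screen_ages(screening_protocol(55, 64, 20)), 55)
  expect_error(screening_protocol(65, 60), "start_age")
  expect_error(screening_protocol(attendance = 1.2), "probability")
})

test_that("misclassification only downgrades", {
  u <- c(0.05, 0.2, 0.9)
  expect_equal(misclassify(rep("low", 3), 0.363, u), rep("low", 3))
  expect_equal(misclassify(rep("high", 3), 0.087, u),
               c("low", "high", "high"))
  expect_equal(misclassify(rep("high", 3), 0, u), rep("high", 3))
  expect_error(misclassify("high", 1.5, 0.5), "probability")
})

test_that("episode detection probabilities are the Bernoulli products", {
  n <- 1e5
  tests <- flat_tests(psa = 0.7)
  hi <- match("T2_GT7_M0", preclinical_states()$label)
  lo <- match("T2_LT7_M0", preclinical_states()$label)
  set.seed(1)
  u <- list(psa = runif(n), mri = runif(n), comp = runif(n), bx = runif(n))

  # with every sensitivity 1 and full compliance, detection is certain
  perfect <- flat_tests(psa = 1, trusgb_sens = 1, biopsy_compliance = 1,
                        mpmri_sens_low = 1, mpmri_sens_high = 1,
                        mrigb_sens_low = 1, mrigb_sens_high = 1)
  expect_true(all(screen_episode_detects(rep(hi, 100), "regular", perfect,
                                         lapply(u, head, 100))))
  expect_true(all(screen_episode_detects(rep(lo, 100), "mri", perfect,
                                         lapply(u, head, 100))))

  # mpMRI triage with zero low-grade sensitivity filters all low grade
  filt <- flat_tests(psa = 1, mpmri_sens_low = 0)
  expect_false(any(screen_episode_detects(rep(lo, n), "mri", filt, u)))

  # per-attended-screen detection probability at base-case values
  p_reg <- 0.7 * 0.9 * 0.9
  p_mri <- 0.7 * 0.94 * 0.9 * 0.91
  f_reg <- mean(screen_episode_detects(rep(hi, n), "regular", tests, u))
  f_mri <- mean(screen_episode_detects(rep(hi, n), "mri", tests, u))
  expect_lt(abs(f_reg - p_reg), 4 * sqrt(p_reg * (1 - p_reg) / n))
  expect_lt(abs(f_mri - p_mri), 4 * sqrt(p_mri * (1 - p_mri) / n))
})

test_that("per-screen recorded-significant rates at defaults are 0.516 vs 0.703", {
  # P(recorded significant | attended, high-grade state, PSA positive)
  n <- 1e5
  tests <- flat_tests(psa = 1)
  hi <- match("T1_EQ7_M0", preclinical_states()$label)
  set.seed(2)
  u <- list(psa = runif(n), mri = runif(n), comp = runif(n), bx = runif(n))
  u_mis <- runif(n)
  det_reg <- screen_episode_detects(rep(hi, n), "regular", tests, u)
  det_mri <- screen_episode_detects(rep(hi, n), "mri", tests, u)
  rec_reg <- det_reg & misclassify(rep("high", n), 0.363, u_mis) == "high"
  rec_mri <- det_mri & misclassify(rep("high", n), 0.087, u_mis) == "high"
  p_reg <- 0.9 * 0.9 * (1 - 0.363) # 0.516
  p_mri <- 0.94 * 0.9 * 0.91 * (1 - 0.087) # 0.703
  expect_lt(abs(mean(rec_reg) - p_reg), 4 * sqrt(p_reg * (1 - p_reg) / n))
  expect_lt(abs(mean(rec_mri) - p_mri), 4 * sqrt(p_mri * (1 - p_mri) / n))
})

test_that("expected biopsies divide detections by the pathway PPV", {
  tests <- flat_tests()
  expect_equal(expected_biopsies(0, 0, tests, "regular")$total, 0)
  expect_equal(expected_biopsies(58, 0, tests, "mri")$screen_biopsies, 100)
  expect_equal(expected_biopsies(22.7, 0, tests, "regular")$screen_biopsies,
               100)
  b <- expected_biopsies(10, 35.8, tests, "regular")
  expect_equal(b$clinical_biopsies, 100)
  expect_equal(b$total, b$screen_biopsies + b$clinical_biopsies)
  zero <- flat_tests(ppv_mri = 0)
  expect_error(expected_biopsies(1, 0, zero, "mri"), "PPV")
})

test_that("screening overlay detects at the first eligible screen and computes lead time", {
  # onset at 56 into a high-grade state, certain tests, screens 55/58/61/64
  nh <- list(onset = list(family = "fixed", age = 56, prob = 1),
             entry_state_distribution = list(T1_EQ7_M0 = 1),
             progression_rates = list(),
             clinical_dx_rates = local({
               st <- preclinical_states()
               r <- as.list(stats::setNames(rep(0, 18), st$label))
               r[["T1_EQ7_M0"]] <- 1e-9 # essentially never diagnosed
               r
             }))
  cohort <- build_cohort(50, life_table(0:90, c(rep(0, 90), 1)), 1)
  h <- simulate_disease_history(nh, cohort, 1)
  protocol <- screening_protocol(55, 64, 3, attendance = 1)
  tests <- flat_tests(psa = 1, trusgb_sens = 1, biopsy_compliance = 1)
  draws <- make_draws(1, 50, 4)
  out <- simulate_screening(h, protocol, tests, draws, "regular")
  expect_true(all(out$mode == "screen"))
  expect_true(all(out$detection_age == 58))
  expect_equal(out$lead_time, h$clinical_dx_age - 58)

  # no onset: no detection in any mode
  nh0 <- nh; nh0$onset$prob <- 0
  h0 <- simulate_disease_history(nh0, cohort, 1)
  out0 <- simulate_screening(h0, protocol, tests, draws, "regular")
  expect_true(all(!out0$detected & out0$mode == "none"))
})

test_that("no screen event occurs at or after min(clinical dx, death)", {
  run <- default_run(n = 2e4, seed = 5)
  h <- run$records$history
  lim <- pmin(ifelse(is.na(h$clinical_dx_age), Inf, h$clinical_dx_age),
              h$other_cause_death_age)
  for (arm in c("regular", "mri")) {
    out <- run$records[[arm]]$outcome
    for (k in seq_along(out$screen_ages)) {
      expect_true(all(out$screen_ages[k] < lim[out$attended[, k]]))
    }
    scr <- out$screen_detected
    expect_true(all(out$detection_age[scr] < lim[scr]))
  }
})

test_that("pathway-equivalence parameters make the two pathways identical man-by-man", {
  cfg <- equivalence_config()
  res <- run_paired_simulation(2e4, cfg, 9)
  oreg <- res$records$regular$outcome
  omri <- res$records$mri$outcome
  for (f in c("detected", "mode", "detection_age", "state_at_detection",
              "true_grade", "recorded_grade", "lead_time")) {
    expect_identical(oreg[[f]], omri[[f]])
  }
  # and the aggregated arms agree exactly
  expect_equal(res$arms$regular, res$arms$mri)
})
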