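# Outcome aggregation: overdiagnosis classification, utility-loss
# accounting, percent-change conventions, paired-run contracts and the
# qualitative pathway comparison at the default parameterization.

test_that("overdiagnosis is screen detection without lifetime clinical diagnosis", {
  mk_hist <- function(dx, death) {
    structure(list(n = 1, onset_age = 50,
                   clinical_dx_age = dx, state_at_dx = 5L,
                   other_cause_death_age = death),
              class = "life_history_set")
  }
  mk_out <- function(mode) list(mode = mode)
  expect_true(classify_overdiagnosed(mk_hist(70, 65), mk_out("screen")))
  expect_false(classify_overdiagnosed(mk_hist(63, 80), mk_out("screen")))
  expect_true(classify_overdiagnosed(mk_hist(NA, 65), mk_out("screen")))
  expect_false(classify_overdiagnosed(mk_hist(70, 65), mk_out("clinical")))
  expect_false(classify_overdiagnosed(mk_hist(70, 65), mk_out("none")))
})

test_that("utility loss sums (1 - utility) x duration truncated at death", {
  ut <- default_config()$utilities
  # one mpMRI episode: 0.04 x 1/52
  ev <- data.frame(id = 1L, label = "mpmri", age = 60)
  expect_equal(compute_utility_loss(ev, ut, death_age = 80),
               0.04 * 1 / 52)
  # MRIGB carries half the TRUSGB disutility at the TRUSGB duration
  ev2 <- data.frame(id = c(1L, 2L), label = c("trusgb", "mrigb"),
                    age = c(60, 60))
  loss <- compute_utility_loss(ev2, ut, death_age = c(80, 80))
  expect_equal(loss[2], 0.5 * loss[1])
  expect_equal(loss[1], 0.10 * 3 / 52)
  # empty event list: zero
  expect_equal(compute_utility_loss(ev[0, ], ut, death_age = c(80, 80)),
               c(0, 0))
  # truncation at death
  ev3 <- data.frame(id = 1L, label = "treatment_palliative", age = 79.5)
  expect_equal(compute_utility_loss(ev3, ut, death_age = 80), 0.4 * 0.5)
  # unmatched label is a configuration error
  expect_error(compute_utility_loss(data.frame(id = 1L, label = "spa_day",
                                               age = 60), ut, 80),
               "no utility entry")
})

test_that("percent change divides by the larger value and keeps the sign", {
  expect_equal(percent_change(396, 278), -(118 / 396) * 100)
  expect_equal(round(percent_change(396, 278)), -30)
  expect_equal(round(percent_change(36.0, 51.3), 1), 29.8)
  expect_equal(percent_change(5, 5), 0)
  expect_equal(percent_change(0, 0), 0)
})

test_that("paired runs are deterministic and collapse correctly at zero attendance", {
  cfg <- default_config()
  r1 <- run_paired_simulation(5000, cfg, 3)
  r2 <- run_paired_simulation(5000, cfg, 3)
  expect_identical(r1$arms, r2$arms)
  expect_identical(r1$comparison$table, r2$comparison$table)

  cfg0 <- default_config()
  cfg0$screening$attendance <- 0
  r0 <- run_paired_simulation(5000, cfg0, 3)
  for (arm in c("regular", "mri")) {
    a <- r0$arms[[arm]]
    expect_equal(a$screen_detected, 0)
    expect_equal(a$overdiagnosed, 0)
    expect_equal(a$pca_deaths, r0$arms$noscreen$pca_deaths)
    expect_equal(a$life_years, r0$arms$noscreen$life_years)
    expect_equal(a$men_biopsied, r0$arms$noscreen$men_biopsied)
  }
})

test_that("QALY accounting identity holds exactly per arm", {
  run <- default_run(n = 2e4, seed = 5)
  for (arm in c("regular", "mri")) {
    a <- run$arms[[arm]]; ns <- run$arms$noscreen
    lyg <- a$life_years - ns$life_years
    d_ul <- a$utility_loss - ns$utility_loss
    qal <- run$comparison[[arm]]$qaly_gained
    expect_equal(qal, lyg - d_ul)
    expect_equal(a$qalys, a$life_years - a$utility_loss)
  }
})

test_that("per-arm invariants hold: overdiagnosed within screen detections, grades partition detections", {
  run <- default_run(n = 2e4, seed = 5)
  for (arm in c("noscreen", "regular", "mri")) {
    a <- run$arms[[arm]]
    expect_lte(a$overdiagnosed, a$screen_detected + 1e-12)
    expect_equal(a$insignificant_detected + a$significant_detected,
                 a$screen_detected + a$clinically_detected)
    expect_true(all(unlist(a) >= 0))
  }
  expect_equal(run$arms$noscreen$screen_detected, 0)
})

test_that("the MRI pathway improves the harm-benefit profile at default parameters", {
  # qualitative pathway comparison on the synthetic parameterization
  run <- default_run(n = 1e5, seed = 42)
  reg <- run$arms$regular; mri <- run$arms$mri
  expect_lt(mri$men_biopsied, reg$men_biopsied)
  expect_lt(mri$insignificant_detected, reg$insignificant_detected)
  expect_gt(mri$significant_detected, reg$significant_detected)
  expect_lt(mri$overdiagnosed, reg$overdiagnosed)
  expect_lt(run$comparison$mri$harm_benefit,
            run$comparison$regular$harm_benefit)
  expect_true(run$comparison$pct_significant_missed > 0 &&
                run$comparison$pct_significant_missed < 100)
})

test_that("raising a high-grade sensitivity never reduces significant detections or deaths averted", {
  cfg <- default_config()
  base <- run_paired_simulation(3e4, cfg, 21)
  up <- cfg
  up$tests$mpmri_sens_high <- 0.97
  up$tests$mrigb_sens_high <- 0.94
  bumped <- run_paired_simulation(3e4, up, 21)
  expect_gte(bumped$arms$mri$significant_detected,
             base$arms$mri$significant_detected)
  expect_gte(bumped$comparison$mri$deaths_averted,
             base$comparison$mri$deaths_averted)
  # man-level coupling: every man screen-detected at baseline stays detected
  expect_true(all(!base$records$mri$outcome$screen_detected |
                    bumped$records$mri$outcome$screen_detected))
})
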