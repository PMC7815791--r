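# Tornado and threshold sensitivity analyses.

test_that("the multiplicative sensitivity transform reproduces the threshold arithmetic", {
  tests <- flat_tests()
  t14 <- transform_sensitivities(tests, 0.14)
  expect_equal(t14$mpmri_sens_high, 0.94 * 0.86) # 0.8084 -> 81%
  expect_equal(t14$mrigb_sens_high, 0.91 * 0.86) # 0.7826 -> 78%
  expect_equal(t14$mpmri_sens_low, 0.74 * 1.14)  # 0.8436 -> 84%
  expect_equal(t14$mrigb_sens_low, 0.44 * 1.14)  # 0.5016 -> 50%
  expect_equal(round(100 * c(t14$mpmri_sens_high, t14$mrigb_sens_high,
                             t14$mpmri_sens_low, t14$mrigb_sens_low)),
               c(81, 78, 84, 50))

  # identity at zero, clamping at one, domain errors
  expect_equal(transform_sensitivities(tests, 0), tests)
  big <- transform_sensitivities(tests, 0.9)
  expect_equal(big$mpmri_sens_low, 1)
  expect_true(all(unlist(big[grep("sens", names(big))]) <= 1))
  expect_error(transform_sensitivities(tests, -0.1), "delta")
  expect_error(transform_sensitivities(tests, 1), "delta")
})

test_that("tornado bars move the harm-benefit ratio in the expected directions", {
  cfg <- default_config()
  n <- 1e5; seed <- 11 # ratios per bound need ~10^5 men to resolve
  tab <- cached("tornado_1e5_11", tornado(cfg, seed, n))
  expect_setequal(tab$parameter, names(default_sensitivity_bounds()))
  # sorted by bar width, descending
  widths <- abs(tab$ratio_at_low - tab$ratio_at_high)
  expect_true(all(diff(widths) <= 1e-12))
  # better high-grade sensitivity improves (lowers) the ratio; better
  # low-grade sensitivity worsens it -- for all four parameters
  for (p in c("mpmri_sens_high", "mrigb_sens_high")) {
    r <- tab[tab$parameter == p, ]
    expect_lt(r$ratio_at_high, r$ratio_at_low)
  }
  for (p in c("mpmri_sens_low", "mrigb_sens_low")) {
    r <- tab[tab$parameter == p, ]
    expect_gt(r$ratio_at_high, r$ratio_at_low)
  }
  # the MRI pathway keeps a lower ratio than the regular pathway across
  # every bound
  reg_ratio <- default_run(n = 1e5, seed = 42)$comparison$regular$harm_benefit
  expect_true(all(c(tab$ratio_at_low, tab$ratio_at_high) < reg_ratio))
})

test_that("tornado with zero-width bounds reproduces the baseline exactly", {
  degen <- tornado(default_config(), 11, 2e4,
                   bounds = list(mpmri_sens_high = c(0.94, 0.94)))
  expect_equal(degen$ratio_at_low, degen$baseline_ratio)
  expect_equal(degen$ratio_at_high, degen$baseline_ratio)
})

test_that("the delta transform thins detections by grade under common random numbers", {
  # Raising low-grade and lowering high-grade sensitivities together must,
  # man-by-man, grow the set of low-grade screen detections and shrink both
  # the high-grade screen detections and the recorded-significant count.
  # (The aggregate overdiagnosis count mixes the two opposing grade
  # components and has no parameterization-free direction.)
  cfg <- default_config()
  deltas <- c(0, 0.1, 0.2)
  runs <- lapply(deltas, function(d) {
    c2 <- cfg
    c2$tests <- transform_sensitivities(c2$tests, d)
    run_paired_simulation(2e4, c2, 19)
  })
  low_scr <- vapply(runs, function(r) {
    o <- r$records$mri$outcome
    sum(o$screen_detected & o$true_grade == "low")
  }, numeric(1))
  high_scr <- vapply(runs, function(r) {
    o <- r$records$mri$outcome
    sum(o$screen_detected & o$true_grade == "high")
  }, numeric(1))
  sig <- vapply(runs, function(r) r$arms$mri$significant_detected, numeric(1))
  expect_true(all(diff(low_scr) >= 0))
  expect_true(all(diff(high_scr) <= 0))
  expect_true(all(diff(sig) <= 0))
})

test_that("threshold crossings agree with a bisection oracle on the same seeded metric", {
  cfg <- default_config()
  n <- 2e4; seed <- 19
  scan <- threshold_scan(cfg, seed, n, delta_grid = seq(0, 0.4, by = 0.1))
  expect_equal(scan$grid$delta, seq(0, 0.4, by = 0.1))
  expect_true(all(is.finite(scan$grid$metric_mri)))
  d0 <- scan$grid$metric_mri - scan$grid$metric_regular
  if (!is.na(scan$crossing_delta)) {
    # bisection refinement on the identical seeded metric function must
    # land within one grid spacing of the interpolated crossing
    f <- function(d) {
      c2 <- cfg
      c2$tests <- transform_sensitivities(c2$tests, d)
      res <- run_paired_simulation(n, c2, seed)
      res$comparison$mri$qaly_per_death_averted -
        res$comparison$regular$qaly_per_death_averted
    }
    i <- max(which(d0 > 0 & !is.na(d0)))
    lo <- scan$grid$delta[i]; hi <- scan$grid$delta[i + 1]
    for (rep in 1:4) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) lo <- mid else hi <- mid
    }
    expect_lt(abs((lo + hi) / 2 - scan$crossing_delta), 0.1)
  } else {
    # no sign change anywhere on the grid
    expect_true(all(d0 > 0) || all(d0 <= 0))
  }
})

test_that("a grid where the MRI metric always dominates has no crossing", {
  toy <- analytic_toy_model()$config
  # both pathways start with perfect tests in the toy model, so the metric
  # difference starts at zero and never crosses from strictly above
  scan <- threshold_scan(toy, 5, 5000, delta_grid = c(0, 0.05))
  expect_true(is.na(scan$crossing_delta))
})
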