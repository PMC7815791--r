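# Shared fixtures: cached simulation runs (the heavy paired runs are reused
# across test files) and small toy configurations built in code.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# Paired three-arm run at the default synthetic parameterization.
default_run <- function(n = 1e5, seed = 42) {
  cached(sprintf("default_%d_%d", n, seed),
         run_paired_simulation(n, default_config(), seed))
}

# Paired run on the analytic toy model.
toy_run <- function(n = 1e5, seed = 7) {
  cached(sprintf("toy_%d_%d", n, seed),
         run_paired_simulation(n, analytic_toy_model()$config, seed))
}

# A small two-state natural-history config: entry in T1_LT7_M0, one allowed
# progression (Gleason up) at rate mu, clinical diagnosis from the entry
# state at rate lambda_a and from the progressed state at rate lambda_b.
two_state_nh <- function(mu, lambda_a, lambda_b = lambda_a) {
  st <- preclinical_states()
  dx <- as.list(stats::setNames(rep(0, nrow(st)), st$label))
  dx[["T1_LT7_M0"]] <- lambda_a
  dx[["T1_EQ7_M0"]] <- lambda_b
  list(onset = list(family = "fixed", age = 50, prob = 1),
       entry_state_distribution = list(T1_LT7_M0 = 1),
       progression_rates =
         if (mu > 0) list("T1_LT7_M0 -> T1_EQ7_M0" = mu) else list(),
       clinical_dx_rates = dx)
}

# Test parameters with uniform PSA positivity, convenient for unit tests.
flat_tests <- function(psa = 1, ...) {
  st <- preclinical_states()
  test_params(psa_pos_prob = stats::setNames(rep(psa, nrow(st)), st$label),
              ...)
}

# A degenerate treatment block: everyone on active surveillance (M1
# palliative), exponential baseline, configurable cure curve.
as_only_treatment <- function(cure_cmax = 0, cure_lambda = 0,
                              baseline = list(low_M0 = 0.05, high_M0 = 0.1,
                                              low_M1 = 0.3, high_M1 = 0.4)) {
  rows <- list()
  for (band in 1:3) for (t in 1:3) for (grade in c("low", "high")) {
    for (m in 0:1) {
      rows[[length(rows) + 1L]] <- list(
        age_band = band, t_stage = t, grade = grade, metastasis = m,
        RP = 0, RT = 0, AS = if (m == 0) 1 else 0,
        palliative = if (m == 1) 1 else 0)
    }
  }
  list(age_breaks = c(65, 75), assignment = rows, hr_rp = 0.56, hr_rt = 0.56,
       baseline_survival = baseline,
       cure_cmax = cure_cmax, cure_lambda = cure_lambda, cure_m1 = FALSE)
}

# Parameter setting under which the two pathways must produce identical
# outcomes for every man (the pathway-equivalence identity). The
# MRI-specific utilities are neutralized too so the whole ArmResult, not
# just the detection outcomes, must coincide.
equivalence_config <- function() {
  cfg <- default_config()
  cfg$tests$mpmri_sens_low <- 1
  cfg$tests$mpmri_sens_high <- 1
  cfg$tests$mrigb_sens_low <- cfg$tests$trusgb_sens
  cfg$tests$mrigb_sens_high <- cfg$tests$trusgb_sens
  cfg$tests$misclass_mrigb <- cfg$tests$misclass_regular
  cfg$tests$ppv_mri <- cfg$tests$ppv_screen_regular
  cfg$utilities <- lapply(cfg$utilities, function(u) {
    if (u$label == "mpmri") u$utility <- 1
    if (u$label == "mrigb") u$utility <- 0.90 # TRUSGB utility
    u
  })
  cfg
}
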