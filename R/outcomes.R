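# Paired three-arm simulation (no screening, regular pathway, MRI pathway)
# under common random numbers, and aggregation of all per-1000-men
# outcomes: detections by recorded grade, overdiagnosis, prostate-cancer
# deaths, life-years, utility loss and QALYs.

#' Was a screen-detected cancer overdiagnosed?
#'
#' A screen-detected cancer is overdiagnosed when clinical diagnosis would
#' never have occurred during the man's lifetime without screening.
#'
#' @param history A `life_history_set`.
#' @param outcome A `screen_outcome_set` of the same cohort.
#' @return Logical vector (FALSE for clinically detected and undetected men).
#' @export
classify_overdiagnosed <- function(history, outcome) {
  dx <- history$clinical_dx_age
  outcome$mode == "screen" &
    (is.na(dx) | dx > history$other_cause_death_age)
}

#' Utility loss from a list of health-state events
#'
#' Each event contributes `(1 - utility) * duration`, with the duration
#' truncated at the man's death. Events are matched to the utility table by
#' label; an unmatched label is a configuration error.
#'
#' @param events A data.frame with columns `id` (man index), `label`, `age`
#'   (event start age in years).
#' @param utilities A utility table: data.frame with `label`, `utility`
#'   (in `[0,1]`), `duration` (years).
#' @param death_age Per-man death ages (indexed by `id`).
#' @return Per-man total years of utility lost (length = `length(death_age)`).
#' @export
compute_utility_loss <- function(events, utilities, death_age) {
  utilities <- build_utility_table(utilities)
  n <- length(death_age)
  loss <- rep(0, n)
  if (is.null(events) || nrow(events) == 0) return(loss)
  row <- match(events$label, utilities$label)
  if (anyNA(row)) {
    stop_bad("configuration error: no utility entry for health state '",
             events$label[is.na(row)][1], "'")
  }
  dur <- pmin(utilities$duration[row],
              pmax(death_age[events$id] - events$age, 0))
  ev_loss <- (1 - utilities$utility[row]) * dur
  agg <- tapply(ev_loss, events$id, sum)
  loss[as.integer(names(agg))] <- agg
  loss
}

# Build the per-arm health-state event list used for QALY accounting:
# attended PSA tests, mpMRI episodes, biopsy procedures (screen biopsies
# use the pathway's modality, clinical biopsies are TRUSGB in every arm),
# the assigned treatment at detection, and terminal illness preceding a
# prostate-cancer death.
arm_events <- function(history, outcome, mort, trt_params, draws) {
  ages <- outcome$screen_ages
  ev <- list()
  add <- function(mask_mat, label) {
    for (k in seq_along(ages)) {
      ids <- which(mask_mat[, k])
      if (length(ids)) {
        ev[[length(ev) + 1L]] <<- data.frame(id = ids, label = label,
                                             age = ages[k])
      }
    }
  }
  if (outcome$pathway != "none") {
    add(outcome$attended, "psa_test")
    if (outcome$pathway == "mri") {
      add(outcome$psa_pos, "mpmri")
      add(outcome$biopsied, "mrigb")
    } else {
      add(outcome$biopsied, "trusgb")
    }
  }
  clin <- which(outcome$clinical_biopsy)
  if (length(clin)) {
    ev[[length(ev) + 1L]] <- data.frame(id = clin, label = "trusgb",
                                        age = outcome$detection_age[clin])
  }
  det <- which(outcome$detected)
  if (length(det)) {
    trt <- assign_treatment(outcome$detection_age[det],
                            outcome$state_at_detection[det],
                            outcome$recorded_grade[det],
                            trt_params, draws$trt[det])
    ev[[length(ev) + 1L]] <- data.frame(
      id = det, label = paste0("treatment_", tolower(trt)),
      age = outcome$detection_age[det])
  }
  pca <- which(mort$cause == "prostate_cancer")
  if (length(pca)) {
    ev[[length(ev) + 1L]] <- data.frame(
      id = pca, label = "terminal_illness",
      age = pmax(mort$death_age[pca] - 0.5, 0))
  }
  if (!length(ev)) {
    return(data.frame(id = integer(), label = character(), age = numeric()))
  }
  do.call(rbind, ev)
}

#' Aggregate one arm's per-man records to per-1000-men outcomes
#'
#' @param history A `life_history_set`.
#' @param outcome The arm's `screen_outcome_set`.
#' @param mort The arm's mortality list (elements `death_age`, `cause`).
#' @param utility_loss Per-man utility loss in years.
#' @param tests A [test_params()] (for the PPV biopsy conversion).
#' @return A list of per-1000 quantities (`men_biopsied`,
#'   `insignificant_detected`, `significant_detected`, `screen_detected`,
#'   `clinically_detected`, `overdiagnosed`, `pca_deaths`, `life_years`,
#'   `utility_loss`, `qalys`).
#' @export
summarize_arm <- function(history, outcome, mort, utility_loss, tests) {
  n <- history$n
  per1000 <- function(x) 1000 * x / n
  scr <- sum(outcome$screen_detected)
  cli <- sum(outcome$clinical_detected)
  bx <- expected_biopsies(scr, cli, tests, outcome$pathway)
  det <- outcome$detected
  sig <- det & outcome$recorded_grade == "high"
  over <- classify_overdiagnosed(history, outcome)
  ul <- sum(utility_loss)
  ly <- sum(mort$death_age)
  list(men_biopsied = per1000(bx$total),
       insignificant_detected = per1000(sum(det & !sig)),
       significant_detected = per1000(sum(sig)),
       screen_detected = per1000(scr),
       clinically_detected = per1000(cli),
       overdiagnosed = per1000(sum(over)),
       pca_deaths = per1000(sum(mort$cause == "prostate_cancer")),
       life_years = per1000(ly),
       utility_loss = per1000(ul),
       qalys = per1000(ly - ul))
}

#' Signed percent change between the regular and MRI pathway
#'
#' Sign follows `mri - regular`; the magnitude divides the absolute
#' difference by the LARGER of the two values, the convention that
#' reproduces the published percent changes.
#'
#' @param regular_value,mri_value Non-negative values, at least one positive
#'   (both zero gives 0).
#' @return Signed percent.
#' @export
percent_change <- function(regular_value, mri_value) {
  if (regular_value == 0 && mri_value == 0) return(0)
  if (regular_value < 0 || mri_value < 0) {
    stop_bad("percent_change expects non-negative values")
  }
  sign(mri_value - regular_value) *
    abs(regular_value - mri_value) / max(regular_value, mri_value) * 100
}

#' Run the paired three-arm simulation
#'
#' Simulates one set of life histories and evaluates them under no
#' screening, the regular pathway and the MRI pathway with the same
#' attendance, PSA, compliance, biopsy, misclassification, treatment,
#' survival and cure uniforms (common random numbers), then aggregates all
#' outcomes per 1000 men. Deterministic given the seed.
#'
#' @param n Cohort size (>= 1).
#' @param config A run configuration ([default_config()] shape).
#' @param seed Master seed.
#' @return A list with `arms` (per-1000 ArmResults for `noscreen`,
#'   `regular`, `mri`), `comparison` (see [compare_pathways()]), `records`
#'   (per-man histories, outcomes and mortality for each arm), `n`, `seed`
#'   and `config_hash`.
#' @export
run_paired_simulation <- function(n, config, seed) {
  if (n < 1) stop_bad("run_paired_simulation: n must be >= 1")
  validate_run_config(config)
  lt <- config_life_table(config)
  protocol <- with(config$screening,
                   screening_protocol(start_age, stop_age, interval,
                                      attendance))
  tests <- build_test_params(config$tests)
  utilities <- build_utility_table(config$utilities)
  cohort <- build_cohort(n, lt, seed)
  history <- simulate_disease_history(config$natural_history, cohort, seed)
  draws <- make_draws(seed, n, length(screen_ages(protocol)))

  outcomes <- list(
    noscreen = simulate_screening(history, protocol, tests, draws, "none"),
    regular = simulate_screening(history, protocol, tests, draws, "regular"),
    mri = simulate_screening(history, protocol, tests, draws, "mri"))

  latent <- latent_clinical_course(history, tests, config$treatment, draws)
  arms <- list(); records <- list(history = history)
  for (arm in names(outcomes)) {
    mort <- arm_mortality(history, outcomes[[arm]], latent,
                          config$treatment, draws)
    events <- arm_events(history, outcomes[[arm]], mort, config$treatment,
                         draws)
    ul <- compute_utility_loss(events, utilities, mort$death_age)
    arms[[arm]] <- summarize_arm(history, outcomes[[arm]], mort, ul, tests)
    records[[arm]] <- list(outcome = outcomes[[arm]], mortality = mort,
                           utility_loss = ul)
  }
  comparison <- compare_pathways(arms$noscreen, arms$regular, arms$mri,
                                 records)
  list(arms = arms, comparison = comparison, records = records,
       n = n, seed = seed, config_hash = config_hash(config))
}

#' Compare the two screening pathways against the no-screening arm
#'
#' Computes deaths averted, life-years and QALYs gained, harm-benefit
#' ratios (overdiagnosed per death averted), per-death-averted ratios, the
#' man-matched percentage of significant cancers missed in the MRI pathway,
#' and a published-style comparison table with differences
#' (regular - MRI) and signed percent changes.
#'
#' @param noscreen,regular,mri Per-1000 ArmResults from [summarize_arm()].
#' @param records Optional per-man records (needed for the man-matched
#'   missed-significant percentage; NA otherwise).
#' @return A list with per-arm derived metrics and a `table` data.frame.
#' @export
compare_pathways <- function(noscreen, regular, mri, records = NULL) {
  derive <- function(arm) {
    da <- noscreen$pca_deaths - arm$pca_deaths
    lyg <- arm$life_years - noscreen$life_years
    qalyg <- arm$qalys - noscreen$qalys
    list(deaths_averted = da, ly_gained = lyg, qaly_gained = qalyg,
         harm_benefit = if (da > 0) arm$overdiagnosed / da else NA_real_,
         lyg_per_death_averted = if (da > 0) lyg / da else NA_real_,
         qaly_per_death_averted = if (da > 0) qalyg / da else NA_real_)
  }
  dreg <- derive(regular); dmri <- derive(mri)

  pct_missed <- NA_real_
  if (!is.null(records)) {
    oreg <- records$regular$outcome; omri <- records$mri$outcome
    sig_scr_reg <- oreg$screen_detected & oreg$recorded_grade == "high"
    if (any(sig_scr_reg)) {
      pct_missed <- 100 * sum(sig_scr_reg & !omri$screen_detected) /
        sum(sig_scr_reg)
    }
  }

  rows <- list(
    men_biopsied = c(regular$men_biopsied, mri$men_biopsied),
    insignificant_detected = c(regular$insignificant_detected,
                               mri$insignificant_detected),
    significant_detected = c(regular$significant_detected,
                             mri$significant_detected),
    overdiagnosed = c(regular$overdiagnosed, mri$overdiagnosed),
    deaths_averted = c(dreg$deaths_averted, dmri$deaths_averted),
    harm_benefit = c(dreg$harm_benefit, dmri$harm_benefit),
    ly_gained = c(dreg$ly_gained, dmri$ly_gained),
    lyg_per_death_averted = c(dreg$lyg_per_death_averted,
                              dmri$lyg_per_death_averted),
    qaly_gained = c(dreg$qaly_gained, dmri$qaly_gained),
    qaly_per_death_averted = c(dreg$qaly_per_death_averted,
                               dmri$qaly_per_death_averted))
  tab <- do.call(rbind, lapply(names(rows), function(nm) {
    v <- rows[[nm]]
    pc <- if (anyNA(v) || any(v < 0)) NA_real_ else percent_change(v[1], v[2])
    data.frame(metric = nm, regular = v[1], mri = v[2],
               difference = v[1] - v[2], percent_change = pc)
  }))
  list(regular = dreg, mri = dmri, pct_significant_missed = pct_missed,
       table = tab)
}
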