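# Treatment assignment and prostate-cancer mortality.
#
# Mortality benefit of screening is a lead-time dependent cure probability:
# a cured man never dies of prostate cancer; an uncured man keeps the date
# and cause of death he would have had without screening. Treatment
# (RP/RT hazard ratio 0.56 vs no treatment) acts on baseline survival after
# the counterfactual clinical diagnosis; palliative treatment (all M1) has
# no survival effect, and active surveillance is survival-neutral.

TREATMENTS <- c("RP", "RT", "AS", "palliative")

age_band_of <- function(age, breaks) {
  findInterval(age, breaks) + 1L # band 1 = below first break
}

age_band_labels <- function(breaks) {
  lo <- c(0, breaks)
  hi <- c(breaks, Inf)
  sprintf("[%g,%g)", lo, hi)
}

# Compile treatment config into a lookup of cumulative assignment
# probabilities keyed by "band|t|grade|m", plus survival/cure parameters.
compile_treatment_params <- function(tr) {
  breaks <- tr$age_breaks %||% c(65, 75)
  rows <- tr$assignment
  if (is.null(rows) || !length(rows)) {
    stop_bad("treatment.assignment must contain at least one row")
  }
  if (is.data.frame(rows)) rows <- split(rows, seq_len(nrow(rows)))
  keys <- character(length(rows))
  cum <- matrix(NA_real_, length(rows), length(TREATMENTS),
                dimnames = list(NULL, TREATMENTS))
  for (i in seq_along(rows)) {
    r <- as.list(rows[[i]])
    need <- c("age_band", "t_stage", "grade", "metastasis", TREATMENTS)
    if (!all(need %in% names(r))) {
      stop_bad("treatment.assignment row ", i, " must have fields: ",
               paste(need, collapse = ", "))
    }
    p <- unlist(r[TREATMENTS])
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop_bad("treatment.assignment row ", i,
               " probabilities must be >= 0 and sum to 1")
    }
    if (r$metastasis == 1 && p["palliative"] != 1) {
      stop_bad("treatment.assignment row ", i,
               ": metastasized (M1) rows must assign palliative with probability 1")
    }
    keys[i] <- paste(r$age_band, r$t_stage, r$grade, r$metastasis, sep = "|")
    cum[i, ] <- cumsum(p)
  }
  hr <- c(RP = tr$hr_rp %||% 0.56, RT = tr$hr_rt %||% 0.56,
          AS = 1, palliative = 1)
  if (any(hr <= 0) || any(hr > 1)) stop_bad("treatment hazard ratios must be in (0, 1]")
  bs <- tr$baseline_survival
  need <- c("low_M0", "high_M0", "low_M1", "high_M1")
  if (is.null(bs) || !all(need %in% names(bs))) {
    stop_bad("treatment.baseline_survival needs rates: ",
             paste(need, collapse = ", "))
  }
  bs <- unlist(bs)[need]
  if (any(bs <= 0)) stop_bad("baseline survival rates must be positive")
  cmax <- tr$cure_cmax %||% 0
  lam <- tr$cure_lambda %||% 0
  check_prob(cmax, "treatment.cure_cmax")
  if (lam < 0) stop_bad("treatment.cure_lambda must be >= 0")
  list(breaks = breaks, keys = keys, cum = cum, hr = hr,
       baseline = bs, cure_cmax = cmax, cure_lambda = lam,
       cure_m1 = isTRUE(tr$cure_m1))
}

#' Assign treatment at diagnosis
#'
#' Categorical draw from the assignment row indexed by (age band, T stage,
#' recorded grade, metastasis), with the fixed CDF ordering
#' RP < RT < AS < palliative. Vectorized.
#'
#' @param age Age at diagnosis (years).
#' @param state Preclinical state (label or index) at diagnosis.
#' @param recorded_grade Recorded grade at the diagnosing biopsy
#'   (`"low"`/`"high"`) -- treatment follows what the biopsy reported, which
#'   is how misclassification produces under- or overtreatment.
#' @param params The `treatment` block of the run configuration.
#' @param u Uniform draws.
#' @return Character vector of treatments.
#' @export
assign_treatment <- function(age, state, recorded_grade, params, u) {
  p <- compile_treatment_params(params)
  idx <- state_index(state)
  key <- paste(age_band_of(age, p$breaks), STATES$t_stage[idx],
               recorded_grade, STATES$metastasis[idx], sep = "|")
  row <- match(key, p$keys)
  if (anyNA(row)) {
    stop_bad("treatment.assignment: no row for index ",
             key[is.na(row)][1],
             " (age_band|t_stage|grade|metastasis)")
  }
  cum <- p$cum[row, , drop = FALSE]
  pick <- rowSums(cum < u) + 1L
  TREATMENTS[pmin(pick, length(TREATMENTS))]
}

#' Draw survival after clinical diagnosis
#'
#' Baseline survival is exponential with a per-(grade, metastasis) rate -- a
#' configurable parametric stand-in for a registry-era survival fit. RP and
#' RT multiply the hazard by the hazard ratio (default 0.56), i.e. divide
#' the survival-time draw by the hazard ratio; AS and palliative leave it
#' unchanged. Deterministic given `u`.
#'
#' @param state State (label or index) at clinical diagnosis; survival uses
#'   the TRUE grade and metastasis of this state.
#' @param age Age at diagnosis (unused by the exponential family; kept for
#'   interface stability).
#' @param treatment Assigned treatments (`"RP"`, `"RT"`, `"AS"`,
#'   `"palliative"`).
#' @param params The `treatment` block of the run configuration.
#' @param u Uniform draws.
#' @return Years from diagnosis to prostate-cancer death.
#' @export
pca_survival_after_clinical_dx <- function(state, age, treatment, params, u) {
  p <- compile_treatment_params(params)
  idx <- state_index(state)
  grade <- ifelse(is_significant(idx), "high", "low")
  key <- paste0(grade, "_M", STATES$metastasis[idx])
  rate <- p$baseline[key]
  hr <- p$hr[treatment]
  -log(u) / (rate * hr)
}

#' Lead-time dependent cure probability
#'
#' `c(L) = c_max * (1 - exp(-lambda * L))`: zero benefit at zero lead time,
#' monotone in lead time, saturating at `c_max`.
#'
#' @param lead_time Lead time in years (`Inf` allowed: the screen-detected
#'   cancer would never have surfaced clinically).
#' @param params The `treatment` block (uses `cure_cmax`, `cure_lambda`).
#' @return Cure probabilities.
#' @export
cure_probability <- function(lead_time, params) {
  p <- compile_treatment_params(params)
  if (any(lead_time < 0, na.rm = TRUE)) stop_bad("lead_time must be >= 0")
  if (p$cure_lambda == 0) return(rep(0, length(lead_time)))
  p$cure_cmax * (1 - exp(-p$cure_lambda * lead_time))
}

# Shared counterfactual clinical course: for every man whose disease would
# ever be clinically diagnosed, the recorded grade at the counterfactual
# clinical biopsy, the treatment then assigned, and the latent
# prostate-cancer death age. All draws are per-man and shared across arms,
# so "date and cause of death are not changed" holds exactly.
latent_clinical_course <- function(history, tests, trt_params, draws) {
  n <- history$n
  dx <- history$clinical_dx_age
  has <- !is.na(dx)
  latent_pca_death <- rep(Inf, n)
  treatment <- rep(NA_character_, n)
  recorded <- rep(NA_character_, n)
  if (any(has)) {
    st <- history$state_at_dx[has]
    grade <- ifelse(is_significant(st), "high", "low")
    rec <- ifelse(grade == "high" & draws$mis[has] >= tests$misclass_regular,
                  "high", "low")
    trt <- assign_treatment(dx[has], st, rec, trt_params, draws$trt[has])
    surv <- pca_survival_after_clinical_dx(st, dx[has], trt, trt_params,
                                           draws$surv[has])
    latent_pca_death[has] <- dx[has] + surv
    treatment[has] <- trt
    recorded[has] <- rec
  }
  list(latent_pca_death = latent_pca_death, treatment = treatment,
       recorded_grade = recorded)
}

# Per-arm mortality given the shared latent clinical course.
arm_mortality <- function(history, outcome, latent, trt_params, draws) {
  p <- compile_treatment_params(trt_params)
  n <- history$n
  pca_death <- latent$latent_pca_death
  cured <- rep(FALSE, n)
  scr <- outcome$screen_detected
  if (any(scr)) {
    m0 <- STATES$metastasis[outcome$state_at_detection[scr]] == 0
    elig <- if (p$cure_m1) rep(TRUE, sum(scr)) else m0
    cp <- rep(0, sum(scr))
    lt <- outcome$lead_time[scr]
    if (p$cure_lambda > 0) {
      cp[elig] <- p$cure_cmax * (1 - exp(-p$cure_lambda * lt[elig]))
    }
    cured[which(scr)] <- draws$cure[scr] < cp
  }
  pca_death[cured] <- Inf
  other <- history$other_cause_death_age
  death_age <- pmin(pca_death, other)
  cause <- ifelse(pca_death < other, "prostate_cancer", "other")
  list(pca_death_age = ifelse(is.finite(pca_death), pca_death, NA_real_),
       cured = cured, death_age = death_age, cause = cause)
}

#' Resolve mortality in the screened and unscreened counterfactual arms
#'
#' In the no-screening arm a clinical diagnosis before other-cause death
#' leads to a survival draw after treatment assignment. In the screened arm
#' a screen-detected non-metastatic cancer gets a Bernoulli cure draw at
#' the lead-time dependent cure probability; a cured man never dies of
#' prostate cancer, an uncured man keeps the no-screening death date and
#' cause (the same survival uniform is shared across arms).
#'
#' @param history A `life_history_set`.
#' @param outcome_screen Screened-arm `screen_outcome_set`.
#' @param outcome_noscreen No-screening counterfactual of the same cohort.
#' @param params A list with elements `tests` ([test_params()]) and
#'   `treatment` (treatment config block).
#' @param draws Common-random-number draws from [make_draws()].
#' @return A list with per-man vectors for each arm: `pca_death_age_screen`,
#'   `pca_death_age_noscreen`, `cured`, `death_age_screen`,
#'   `death_age_noscreen`, `cause_screen`, `cause_noscreen`.
#' @export
resolve_mortality <- function(history, outcome_screen, outcome_noscreen,
                              params, draws) {
  latent <- latent_clinical_course(history, params$tests, params$treatment,
                                   draws)
  ns <- arm_mortality(history, outcome_noscreen, latent, params$treatment,
                      draws)
  sc <- arm_mortality(history, outcome_screen, latent, params$treatment,
                      draws)
  list(pca_death_age_noscreen = ns$pca_death_age,
       pca_death_age_screen = sc$pca_death_age,
       cured = sc$cured,
       death_age_noscreen = ns$death_age, death_age_screen = sc$death_age,
       cause_noscreen = ns$cause, cause_screen = sc$cause,
       treatment_noscreen = latent$treatment)
}
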