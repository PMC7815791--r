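# Screening pathways: PSA episode, mpMRI triage (MRI pathway only), biopsy,
# grade misclassification and biopsy counting. Both pathways are evaluated
# on the same life histories under common random numbers.

#' Screening protocol
#'
#' @param start_age,stop_age First and last screening ages (defaults 55, 64).
#' @param interval Years between screens (default 3).
#' @param attendance Per-screen attendance probability (default 0.80).
#' @return An object of class `screening_protocol`.
#' @export
screening_protocol <- function(start_age = 55, stop_age = 64, interval = 3,
                               attendance = 0.80) {
  if (start_age > stop_age) stop_bad("screening: start_age must be <= stop_age")
  if (interval < 1) stop_bad("screening: interval must be >= 1")
  check_prob(attendance, "screening.attendance")
  structure(list(start_age = start_age, stop_age = stop_age,
                 interval = interval, attendance = attendance),
            class = "screening_protocol")
}

#' Screening ages implied by a protocol
#'
#' @param protocol A [screening_protocol()].
#' @return The arithmetic sequence of screen ages (e.g. 55, 58, 61, 64).
#' @export
screen_ages <- function(protocol) {
  seq(protocol$start_age, protocol$stop_age, by = protocol$interval)
}

#' Test characteristics of both diagnostic pathways
#'
#' Defaults carry the base-case values: TRUSGB sensitivity 0.90, biopsy
#' compliance 0.90, mpMRI sensitivity 0.94 (high grade) / 0.74 (low grade),
#' MRIGB sensitivity 0.91 / 0.44, grade misclassification 0.363 (TRUSGB)
#' vs 0.087 (MRIGB), and biopsy positive predictive values 0.227 (regular
#' screen), 0.358 (clinical) and 0.58 (MRI pathway). The PSA cut-off of
#' 3 ng/mL is represented only through the per-state positivity
#' probabilities `psa_pos_prob`.
#'
#' @param psa_pos_prob Named per-state probability that a PSA episode is
#'   positive (names are state labels; see [preclinical_states()]).
#' @param trusgb_sens,biopsy_compliance,mpmri_sens_low,mpmri_sens_high
#'   Probabilities.
#' @param mrigb_sens_low,mrigb_sens_high,misclass_regular,misclass_mrigb
#'   Probabilities.
#' @param ppv_screen_regular,ppv_clinical,ppv_mri Positive predictive values
#'   used to convert detected cancers into biopsy counts.
#' @return An object of class `test_params` (a validated list; `psa_pos_prob`
#'   is expanded to a length-18 vector in state order).
#' @export
test_params <- function(psa_pos_prob,
                        trusgb_sens = 0.90, biopsy_compliance = 0.90,
                        mpmri_sens_low = 0.74, mpmri_sens_high = 0.94,
                        mrigb_sens_low = 0.44, mrigb_sens_high = 0.91,
                        misclass_regular = 0.363, misclass_mrigb = 0.087,
                        ppv_screen_regular = 0.227, ppv_clinical = 0.358,
                        ppv_mri = 0.58) {
  scalars <- list(trusgb_sens = trusgb_sens,
                  biopsy_compliance = biopsy_compliance,
                  mpmri_sens_low = mpmri_sens_low,
                  mpmri_sens_high = mpmri_sens_high,
                  mrigb_sens_low = mrigb_sens_low,
                  mrigb_sens_high = mrigb_sens_high,
                  misclass_regular = misclass_regular,
                  misclass_mrigb = misclass_mrigb,
                  ppv_screen_regular = ppv_screen_regular,
                  ppv_clinical = ppv_clinical,
                  ppv_mri = ppv_mri)
  for (nm in names(scalars)) check_prob(scalars[[nm]], paste0("tests.", nm))
  pp <- unlist(psa_pos_prob)
  check_prob(pp, "tests.psa_pos_prob")
  full <- rep(NA_real_, nrow(STATES))
  full[state_index(names(pp))] <- pp
  if (anyNA(full)) {
    stop_bad("tests.psa_pos_prob missing states: ",
             paste(STATES$label[is.na(full)], collapse = ", "))
  }
  structure(c(list(psa_pos_prob = full), scalars), class = "test_params")
}

mpmri_sens <- function(tests, high) {
  ifelse(high, tests$mpmri_sens_high, tests$mpmri_sens_low)
}
mrigb_sens <- function(tests, high) {
  ifelse(high, tests$mrigb_sens_high, tests$mrigb_sens_low)
}

#' Does one attended screening episode detect the cancer?
#'
#' Regular pathway: positive PSA, then biopsy compliance, then TRUSGB
#' sensitivity. MRI pathway: positive PSA, then mpMRI triage at the
#' grade-specific sensitivity, then biopsy compliance, then MRIGB at the
#' grade-specific sensitivity. Vectorized; the same `u_psa` and `u_comp`
#' (and `u_bx`) draws should be supplied to both pathways when running
#' paired (common random numbers).
#'
#' @param state Preclinical state indices or labels (man attends and occupies
#'   a preclinical state).
#' @param pathway `"regular"` or `"mri"`.
#' @param tests A [test_params()].
#' @param u A list of uniform draws: `psa`, `comp`, `bx`, and (MRI pathway)
#'   `mri`, each the same length as `state`.
#' @return Logical vector: detected at this episode.
#' @export
screen_episode_detects <- function(state, pathway, tests, u) {
  idx <- state_index(state)
  high <- is_significant(idx)
  psa_pos <- u$psa < tests$psa_pos_prob[idx]
  if (pathway == "regular") {
    psa_pos & u$comp < tests$biopsy_compliance & u$bx < tests$trusgb_sens
  } else if (pathway == "mri") {
    psa_pos & u$mri < mpmri_sens(tests, high) &
      u$comp < tests$biopsy_compliance & u$bx < mrigb_sens(tests, high)
  } else {
    stop_bad("pathway must be 'regular' or 'mri'")
  }
}

#' Misclassify a biopsy grade
#'
#' Misclassification only downgrades: a truly significant (high-grade)
#' cancer is recorded as insignificant with probability `rate`; low-grade
#' cancers are always recorded low.
#'
#' @param true_grade `"low"` or `"high"` (vectorized).
#' @param rate Downgrade probability.
#' @param u Uniform draws.
#' @return Recorded grades, `"low"` or `"high"`.
#' @export
misclassify <- function(true_grade, rate, u) {
  check_prob(rate, "misclassification rate")
  ifelse(true_grade == "high" & u >= rate, "high", "low")
}

#' Convert detected cancers to expected biopsy counts via PPVs
#'
#' Number biopsied = screen detections divided by the screen PPV of the
#' pathway, plus clinical detections divided by the clinical PPV. Expected
#' counts stay fractional; rounding happens only at the reporting layer.
#'
#' @param screen_detections,clinical_detections Detected-cancer counts (>= 0).
#' @param tests A [test_params()].
#' @param pathway `"regular"`, `"mri"` or `"none"` (no screen biopsies).
#' @return A list with `screen_biopsies`, `clinical_biopsies`, `total`.
#' @export
expected_biopsies <- function(screen_detections, clinical_detections, tests,
                              pathway) {
  if (screen_detections < 0 || clinical_detections < 0) {
    stop_bad("detection counts must be >= 0")
  }
  ppv_screen <- switch(pathway,
                       regular = tests$ppv_screen_regular,
                       mri = tests$ppv_mri,
                       none = 1,
                       stop_bad("pathway must be 'regular', 'mri' or 'none'"))
  if (ppv_screen == 0 || tests$ppv_clinical == 0) {
    stop_bad("configuration error: PPV must be positive")
  }
  sb <- if (pathway == "none") 0 else screen_detections / ppv_screen
  cb <- clinical_detections / tests$ppv_clinical
  list(screen_biopsies = sb, clinical_biopsies = cb, total = sb + cb)
}

#' Overlay a screening pathway on simulated life histories
#'
#' Iterates over the protocol's screen ages; a man is eligible while he is
#' alive and not yet (clinically or screen-) diagnosed. Attendance is drawn
#' once per man per screen. The first successful episode sets
#' `mode = "screen"`; otherwise a clinical diagnosis before other-cause
#' death sets `mode = "clinical"` (the clinical biopsy uses TRUSGB grade
#' recording in both pathways). A negative episode leaves no memory.
#'
#' @param history A `life_history_set`.
#' @param protocol A [screening_protocol()].
#' @param tests A [test_params()].
#' @param draws Common-random-number draws from [make_draws()].
#' @param pathway `"regular"`, `"mri"`, or `"none"` (pure no-screening arm).
#' @return An object of class `screen_outcome_set`: vectors `detected`,
#'   `mode`, `detection_age`, `state_at_detection`, `true_grade`,
#'   `recorded_grade`, `lead_time` (Inf when clinical diagnosis would never
#'   occur), plus per-man event counts `n_psa_tests`, `n_mpmri`,
#'   `n_screen_biopsies`, `clinical_biopsy` and a matrix of attended screen
#'   flags used for utility accounting.
#' @export
simulate_screening <- function(history, protocol, tests, draws,
                               pathway = c("regular", "mri", "none")) {
  pathway <- match.arg(pathway)
  n <- history$n
  ages <- screen_ages(protocol)
  K <- length(ages)
  death <- history$other_cause_death_age
  dx <- history$clinical_dx_age
  dx_eff <- ifelse(is.na(dx), Inf, dx)

  detected <- rep(FALSE, n)
  detection_age <- rep(NA_real_, n)
  state_det <- rep(NA_integer_, n)
  n_psa <- n_mri <- n_sbx <- rep(0L, n)
  attended <- matrix(FALSE, n, K)
  psa_pos_mat <- matrix(FALSE, n, K)
  biopsied_mat <- matrix(FALSE, n, K)

  if (pathway != "none") {
    for (k in seq_len(K)) {
      s <- ages[k]
      eligible <- !detected & s < pmin(dx_eff, death)
      att <- eligible & draws$att[, k] < protocol$attendance
      if (!any(att)) next
      attended[, k] <- att
      n_psa <- n_psa + att
      st <- state_at(history, s)
      inpre <- att & !is.na(st)
      idx <- which(inpre)
      if (!length(idx)) next
      sti <- st[idx]
      high <- is_significant(sti)
      psa_pos <- draws$psa[idx, k] < tests$psa_pos_prob[sti]
      psa_pos_mat[idx, k] <- psa_pos
      if (pathway == "regular") {
        bx <- psa_pos & draws$comp[idx, k] < tests$biopsy_compliance
        det <- bx & draws$bx[idx, k] < tests$trusgb_sens
      } else {
        n_mri[idx] <- n_mri[idx] + psa_pos
        mri_pos <- psa_pos & draws$mri[idx, k] < mpmri_sens(tests, high)
        bx <- mri_pos & draws$comp[idx, k] < tests$biopsy_compliance
        det <- bx & draws$bx[idx, k] < mrigb_sens(tests, high)
      }
      biopsied_mat[idx, k] <- bx
      n_sbx[idx] <- n_sbx[idx] + bx
      new <- idx[det]
      detected[new] <- TRUE
      detection_age[new] <- s
      state_det[new] <- st[new]
    }
  }

  mode <- rep("none", n)
  mode[detected] <- "screen"
  clin <- !detected & dx_eff < death
  mode[clin] <- "clinical"
  detection_age[clin] <- dx[clin]
  state_det[clin] <- history$state_at_dx[clin]

  any_det <- detected | clin
  true_grade <- rep(NA_character_, n)
  true_grade[any_det] <- ifelse(is_significant(state_det[any_det]),
                                "high", "low")
  # one misclassification uniform per man, consumed by the recording biopsy;
  # the MRIGB rate applies only to screen detections on the MRI pathway
  rate <- ifelse(detected & pathway == "mri",
                 tests$misclass_mrigb, tests$misclass_regular)
  recorded_grade <- rep(NA_character_, n)
  recorded_grade[any_det] <- ifelse(
    true_grade[any_det] == "high" & draws$mis[any_det] >= rate[any_det],
    "high", "low")

  lead_time <- rep(NA_real_, n)
  lead_time[detected] <- dx_eff[detected] - detection_age[detected]
  lead_time[clin] <- 0

  structure(list(n = n, pathway = pathway, screen_ages = ages,
                 detected = any_det, mode = mode,
                 detection_age = detection_age,
                 state_at_detection = state_det,
                 true_grade = true_grade, recorded_grade = recorded_grade,
                 lead_time = lead_time,
                 screen_detected = detected, clinical_detected = clin,
                 n_psa_tests = as.integer(n_psa), n_mpmri = as.integer(n_mri),
                 n_screen_biopsies = as.integer(n_sbx),
                 clinical_biopsy = clin,
                 attended = attended, psa_pos = psa_pos_mat,
                 biopsied = biopsied_mat),
            class = "screen_outcome_set")
}
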