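# Natural history: onset, progression through the 18 preclinical states and
# clinical diagnosis, simulated as a semi-Markov process with exponential
# sojourn clocks. The counterfactual history is NOT truncated at other-cause
# death: the overdiagnosis definition needs to know whether clinical
# diagnosis would ever have happened during the man's lifetime.

GLEASON_LEVELS <- c("LT7", "EQ7", "GT7") # <7, =7, >7

#' The 18 preclinical detectable states
#'
#' Cross of T stage (T1, T2, T3), Gleason category (<7, =7, >7) and
#' metastatic status (M0, M1).
#'
#' @return A data.frame with columns `idx`, `label`, `t_stage` (1..3),
#'   `gleason` (1 = <7, 2 = 7, 3 = >7) and `metastasis` (0/1).
#' @export
preclinical_states <- function() {
  g <- expand.grid(gleason = 1:3, t_stage = 1:3, metastasis = 0:1)
  df <- data.frame(idx = seq_len(nrow(g)),
                   t_stage = g$t_stage, gleason = g$gleason,
                   metastasis = g$metastasis)
  df$label <- sprintf("T%d_%s_M%d", df$t_stage,
                      GLEASON_LEVELS[df$gleason], df$metastasis)
  df[, c("idx", "label", "t_stage", "gleason", "metastasis")]
}

STATES <- preclinical_states()

state_index <- function(state) {
  if (is.character(state)) {
    idx <- match(state, STATES$label)
    if (anyNA(idx)) {
      stop_bad("unknown preclinical state label: ",
               paste(state[is.na(idx)], collapse = ", "))
    }
    idx
  } else {
    state <- as.integer(state)
    if (any(!is.na(state) & (state < 1 | state > nrow(STATES)))) {
      stop_bad("state index out of range 1..", nrow(STATES))
    }
    state
  }
}

#' Is a preclinical state clinically significant?
#'
#' Clinically significant disease is Gleason score 7 or more; Gleason 6 and
#' below is insignificant.
#'
#' @param state State labels (e.g. `"T1_EQ7_M0"`) or indices into
#'   [preclinical_states()]; NA propagates.
#' @return Logical vector.
#' @export
is_significant <- function(state) {
  STATES$gleason[state_index(state)] >= 2
}

# ---- parameter validation / compilation -------------------------------

# Compile the config's natural_history block into fast internal form:
# an 18x18 progression-rate matrix, a length-18 clinical-diagnosis rate
# vector, a length-18 entry distribution and the onset model.
compile_nh_params <- function(nh) {
  ns <- nrow(STATES)
  onset <- nh$onset
  if (is.null(onset$family)) stop_bad("natural_history.onset.family missing")
  if (onset$family == "weibull") {
    if (is.null(onset$prob) || is.null(onset$shape) || is.null(onset$scale)) {
      stop_bad("natural_history.onset (weibull) needs prob, shape, scale")
    }
    check_prob(onset$prob, "natural_history.onset.prob")
    if (onset$prob > 0 && (onset$shape <= 0 || onset$scale <= 0)) {
      stop_bad("natural_history.onset: shape and scale must be positive")
    }
  } else if (onset$family == "fixed") {
    if (is.null(onset$age) || onset$age < 0) {
      stop_bad("natural_history.onset (fixed) needs a non-negative age")
    }
    onset$prob <- onset$prob %||% 1
    check_prob(onset$prob, "natural_history.onset.prob")
  } else {
    stop_bad("natural_history.onset.family must be 'weibull' or 'fixed'")
  }

  entry <- rep(0, ns)
  ed <- nh$entry_state_distribution
  if (is.null(ed) || is.null(names(ed)) || length(ed) < 1) {
    stop_bad("natural_history.entry_state_distribution must be a named list")
  }
  ed <- unlist(ed)
  idx <- state_index(names(ed))
  if (any(STATES$t_stage[idx] != 1 | STATES$metastasis[idx] != 0)) {
    stop_bad("entry_state_distribution: entry is only allowed into (T1, ., M0) states")
  }
  if (any(ed < 0) || abs(sum(ed) - 1) > 1e-9) {
    stop_bad("entry_state_distribution must be non-negative and sum to 1")
  }
  entry[idx] <- ed

  rate_mat <- matrix(0, ns, ns, dimnames = list(STATES$label, STATES$label))
  pr <- nh$progression_rates %||% list()
  if (length(pr)) {
    keys <- names(pr)
    parts <- strsplit(keys, "\\s*->\\s*")
    for (k in seq_along(pr)) {
      if (length(parts[[k]]) != 2) {
        stop_bad("progression_rates key must look like 'FROM -> TO': ", keys[k])
      }
      from <- state_index(parts[[k]][1])
      to <- state_index(parts[[k]][2])
      dt <- STATES$t_stage[to] - STATES$t_stage[from]
      dg <- STATES$gleason[to] - STATES$gleason[from]
      dm <- STATES$metastasis[to] - STATES$metastasis[from]
      if (dt < 0 || dg < 0 || dm < 0 || (dt + dg + dm) < 1) {
        stop_bad("progression_rates: transition must increase severity: ", keys[k])
      }
      rate <- as.numeric(pr[[k]])
      if (is.na(rate) || rate < 0) stop_bad("progression rate must be >= 0: ", keys[k])
      rate_mat[from, to] <- rate
    }
  }

  dx <- rep(0, ns)
  cd <- nh$clinical_dx_rates
  if (is.null(cd) || is.null(names(cd))) {
    stop_bad("natural_history.clinical_dx_rates must be a named list")
  }
  cd <- unlist(cd)
  if (any(cd < 0)) stop_bad("clinical_dx_rates must be >= 0")
  dx[state_index(names(cd))] <- cd

  list(onset = onset, entry = entry, rate_mat = rate_mat, dx_rates = dx)
}

# ---- simulation -------------------------------------------------------

#' Simulate counterfactual disease histories for a cohort
#'
#' Competing-risks semi-Markov simulation: in each occupied state an
#' exponential clock runs for every allowed progression and for clinical
#' diagnosis; the earliest clock fires. The trajectory is recorded in full
#' and is deliberately not stopped at the man's other-cause death age, so
#' the counterfactual clinical-diagnosis age may exceed it.
#'
#' @param params The `natural_history` block of the run configuration.
#' @param cohort A cohort data.frame from [build_cohort()].
#' @param seed Master seed (the natural-history stream is derived from it).
#' @return An object of class `life_history_set`: a list with `n`, `id`,
#'   `onset_age`, `path_state` / `path_age` (n x L matrices, NA-padded),
#'   `clinical_dx_age` (NA if diagnosis never occurs), `state_at_dx`, and
#'   `other_cause_death_age`.
#' @export
simulate_disease_history <- function(params, cohort, seed) {
  p <- compile_nh_params(params)
  n <- nrow(cohort)
  ns <- nrow(STATES)
  set.seed(seed_for(seed, "natural_history"))

  onset_age <- rep(NA_real_, n)
  if (p$onset$prob > 0) {
    has <- stats::runif(n) < p$onset$prob
    if (p$onset$family == "weibull") {
      onset_age[has] <- stats::qweibull(stats::runif(n)[has],
                                        shape = p$onset$shape,
                                        scale = p$onset$scale)
    } else {
      stats::runif(n) # keep stream alignment with the weibull branch
      onset_age[has] <- p$onset$age
    }
  } else {
    stats::runif(n); stats::runif(n)
  }

  max_steps <- ns # longest strictly-increasing chain is far shorter
  path_state <- matrix(NA_integer_, n, max_steps)
  path_age <- matrix(NA_real_, n, max_steps)
  clinical_dx_age <- rep(NA_real_, n)
  state_at_dx <- rep(NA_integer_, n)

  active <- which(!is.na(onset_age))
  if (length(active)) {
    u_entry <- stats::runif(n)
    cum_entry <- cumsum(p$entry)
    entry_state <- findInterval(u_entry[active], cum_entry, left.open = TRUE) + 1L
    cur_state <- entry_state
    cur_age <- onset_age[active]
    path_state[cbind(active, 1L)] <- cur_state
    path_age[cbind(active, 1L)] <- cur_age
    depth <- rep(1L, length(active))

    step <- 0L
    while (length(active) && step < max_steps) {
      step <- step + 1L
      rates <- p$rate_mat[cur_state, , drop = FALSE]
      dxr <- p$dx_rates[cur_state]
      tot <- rowSums(rates) + dxr
      # absorbed: nothing can fire -> no clinical diagnosis, trajectory ends
      stuck <- tot <= 0
      if (any(stuck)) {
        keep <- !stuck
        active <- active[keep]; cur_state <- cur_state[keep]
        cur_age <- cur_age[keep]; depth <- depth[keep]
        rates <- rates[keep, , drop = FALSE]; dxr <- dxr[keep]; tot <- tot[keep]
        if (!length(active)) break
      }
      dt <- stats::rexp(length(active), rate = tot)
      cur_age <- cur_age + dt
      target <- stats::runif(length(active)) * tot
      cum <- rates
      for (j in 2:ns) cum[, j] <- cum[, j - 1] + cum[, j]
      pick <- rowSums(cum < target) + 1L # ns+1 means clinical diagnosis
      is_dx <- pick > ns
      if (any(is_dx)) {
        ii <- active[is_dx]
        clinical_dx_age[ii] <- cur_age[is_dx]
        state_at_dx[ii] <- cur_state[is_dx]
      }
      move <- !is_dx
      if (any(move)) {
        new_state <- pick[move]
        ii <- active[move]
        d <- depth[move] + 1L
        path_state[cbind(ii, d)] <- new_state
        path_age[cbind(ii, d)] <- cur_age[move]
        active <- ii; cur_state <- new_state
        cur_age <- cur_age[move]; depth <- d
      } else {
        active <- integer(0)
      }
    }
  } else {
    stats::runif(n) # entry-state stream placeholder for alignment
  }

  structure(list(n = n, id = cohort$id, onset_age = onset_age,
                 path_state = path_state, path_age = path_age,
                 clinical_dx_age = clinical_dx_age, state_at_dx = state_at_dx,
                 other_cause_death_age = cohort$other_cause_death_age),
            class = "life_history_set")
}

#' State occupied at a given age
#'
#' Half-open convention: a state is occupied on `[entry_age, next_entry)`;
#' no state before onset or at/after clinical diagnosis.
#'
#' @param history A `life_history_set`.
#' @param age A single age in years (applied to every man).
#' @return Integer state indices (NA where no preclinical state is occupied).
#' @export
state_at <- function(history, age) {
  stopifnot(inherits(history, "life_history_set"), length(age) == 1)
  st <- rep(NA_integer_, history$n)
  for (k in seq_len(ncol(history$path_age))) {
    entered <- !is.na(history$path_age[, k]) & history$path_age[, k] <= age
    # entry ages increase along a row, so once nobody has entered at this
    # depth nobody can have entered deeper
    if (!any(entered)) break
    st[entered] <- history$path_state[entered, k]
  }
  dx <- history$clinical_dx_age
  st[!is.na(dx) & age >= dx] <- NA_integer_
  st
}
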