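# Cohort demography: other-cause mortality from an annual life table.
#
# The life table's qx is mortality from causes OTHER than prostate cancer;
# prostate-cancer death is modeled separately by the treatment/survival
# module, so using all-cause qx here would double-count.

#' Construct and validate a life table
#'
#' @param age Integer ages, contiguous from 0.
#' @param qx Annual probability of death from other causes at each age; the
#'   final entry must be 1 so every simulated man has a finite death age.
#' @return An object of class `life_table` with fields `age`, `qx`, `max_age`.
#' @export
life_table <- function(age, qx) {
  if (length(age) != length(qx) || length(age) < 1) {
    stop_bad("life table: age and qx must be non-empty and equally long")
  }
  age <- as.integer(age)
  if (age[1] != 0 || any(diff(age) != 1L)) {
    bad <- if (age[1] != 0) 1L else which(diff(age) != 1L)[1] + 1L
    stop_bad("life table: ages must be contiguous from 0 (row ", bad, ")")
  }
  if (anyNA(qx) || any(qx < 0) || any(qx > 1)) {
    bad <- which(is.na(qx) | qx < 0 | qx > 1)[1]
    stop_bad("life table: qx outside [0, 1] at row ", bad,
             " (age ", age[bad], ")")
  }
  last <- length(qx)
  if (qx[last] != 1) {
    stop_bad("life table: final qx must equal 1 at max_age (row ", last,
             ", age ", age[last], ", qx = ", qx[last], ")")
  }
  structure(list(age = age, qx = as.numeric(qx), max_age = age[last]),
            class = "life_table")
}

#' Read a life table from a CSV file
#'
#' Expects a header `age,qx` with contiguous integer ages from 0 and a final
#' qx of 1.
#'
#' @param path Path to the CSV file.
#' @return A validated [life_table()].
#' @export
load_life_table <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("age", "qx") %in% names(df))) {
    stop_bad("life table file ", path, " must have columns 'age' and 'qx'")
  }
  life_table(df$age, df$qx)
}

# P(death in year a) for a = 0..max_age, from the discrete survival curve.
death_year_probs <- function(table) {
  lx <- cumprod(c(1, 1 - table$qx)) # survival to the START of each age
  lx[seq_along(table$qx)] * table$qx
}

#' Sample an other-cause death age by inverse CDF
#'
#' Inverts the discrete annual survival curve and interpolates uniformly
#' within the death year: death in year `a` occurs at age `a + frac`,
#' `frac` in `[0, 1)`.
#'
#' @param table A [life_table()].
#' @param u Uniform(0,1) draws (vectorized).
#' @return Continuous death ages, one per element of `u`.
#' @export
sample_other_cause_death_age <- function(table, u) {
  stopifnot(inherits(table, "life_table"))
  if (any(u <= 0) || any(u >= 1)) stop_bad("u must lie strictly in (0, 1)")
  d <- death_year_probs(table)
  cum <- cumsum(d)
  cum[length(cum)] <- 1 # guard rounding; qx(max_age)=1 makes this exact
  idx <- findInterval(u, cum, left.open = TRUE) + 1L
  frac <- (u - c(0, cum)[idx]) / d[idx]
  table$age[idx] + frac
}

#' Analytic life expectancy at birth of a life table
#'
#' Uses the same uniform-within-year convention as the sampler, so Monte
#' Carlo means converge to this value.
#'
#' @param table A [life_table()].
#' @return Expected death age in years.
#' @export
life_expectancy <- function(table) {
  d <- death_year_probs(table)
  sum(d * (table$age + 0.5))
}

#' Build a cohort of simulated men
#'
#' @param n Cohort size (>= 1).
#' @param table A [life_table()] for other-cause mortality.
#' @param seed Master seed; the cohort stream is derived from it.
#' @return A data.frame with columns `id` and `other_cause_death_age`.
#' @export
build_cohort <- function(n, table, seed) {
  if (length(n) != 1 || is.na(n) || n < 1) {
    stop_bad("build_cohort: n must be at least 1")
  }
  n <- as.integer(n)
  set.seed(seed_for(seed, "other_cause_death"))
  u <- stats::runif(n)
  data.frame(id = seq_len(n),
             other_cause_death_age = sample_other_cause_death_age(table, u))
}
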