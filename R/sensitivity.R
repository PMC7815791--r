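# Sensitivity analyses over the MRI-pathway test characteristics: a one-way
# tornado on the harm-benefit ratio, and a simultaneous multiplicative
# threshold scan on QALYs gained per death averted.

#' Simultaneously transform the MRI test sensitivities
#'
#' Applies the relative (multiplicative) change used by the threshold
#' analysis: low-grade sensitivities are multiplied by `(1 + delta)` and
#' capped at 1, high-grade sensitivities by `(1 - delta)`. At delta = 0.14
#' this maps 0.94 to 0.8084, 0.91 to 0.7826, 0.74 to 0.8436 and 0.44 to
#' 0.5016. All other fields are unchanged.
#'
#' @param tests A [test_params()] (or the `tests` config list).
#' @param delta Relative change in `[0, 1)`.
#' @return The transformed object, same class as the input.
#' @export
transform_sensitivities <- function(tests, delta) {
  if (length(delta) != 1 || is.na(delta) || delta < 0 || delta >= 1) {
    stop_bad("delta must lie in [0, 1)")
  }
  tests$mpmri_sens_low <- min(1, tests$mpmri_sens_low * (1 + delta))
  tests$mrigb_sens_low <- min(1, tests$mrigb_sens_low * (1 + delta))
  tests$mpmri_sens_high <- tests$mpmri_sens_high * (1 - delta)
  tests$mrigb_sens_high <- tests$mrigb_sens_high * (1 - delta)
  tests
}

#' Default one-way bounds for the MRI test sensitivities
#'
#' The 95% confidence intervals / range of the four base-case MRI test
#' sensitivities: mpMRI high grade 0.70-0.97, mpMRI low grade 0.66-0.81,
#' MRIGB low grade 0.26-0.64, MRIGB high grade 0.87-0.94.
#'
#' @return A named list of `c(low, high)` bounds.
#' @export
default_sensitivity_bounds <- function() {
  list(mpmri_sens_high = c(0.70, 0.97),
       mpmri_sens_low = c(0.66, 0.81),
       mrigb_sens_low = c(0.26, 0.64),
       mrigb_sens_high = c(0.87, 0.94))
}

#' One-way (tornado) sensitivity analysis on the harm-benefit ratio
#'
#' Reruns the paired simulation with each MRI test sensitivity set to its
#' lower and upper bound in turn (all others at baseline), under the same
#' seed, and reports the MRI-pathway harm-benefit ratio (overdiagnosed per
#' death averted) at each bound, sorted by bar width.
#'
#' @param config A run configuration.
#' @param seed Master seed (shared by every rerun: common random numbers).
#' @param n Cohort size per rerun.
#' @param bounds Named list of `c(low, high)` bounds
#'   (default [default_sensitivity_bounds()]).
#' @return A data.frame with `parameter`, `low_bound`, `high_bound`,
#'   `ratio_at_low`, `ratio_at_high`, `baseline_ratio`, sorted by
#'   `abs(ratio_at_low - ratio_at_high)` descending.
#' @export
tornado <- function(config, seed, n, bounds = default_sensitivity_bounds()) {
  ratio_at <- function(cfg) {
    run_paired_simulation(n, cfg, seed)$comparison$mri$harm_benefit
  }
  baseline <- ratio_at(config)
  rows <- lapply(names(bounds), function(par) {
    b <- bounds[[par]]
    lo_cfg <- config; lo_cfg$tests[[par]] <- b[1]
    hi_cfg <- config; hi_cfg$tests[[par]] <- b[2]
    data.frame(parameter = par, low_bound = b[1], high_bound = b[2],
               ratio_at_low = ratio_at(lo_cfg),
               ratio_at_high = ratio_at(hi_cfg),
               baseline_ratio = baseline)
  })
  out <- do.call(rbind, rows)
  out[order(-abs(out$ratio_at_low - out$ratio_at_high)), , drop = FALSE]
}

#' Threshold scan on QALYs gained per death averted
#'
#' At each relative change `delta` the MRI sensitivities are transformed
#' with [transform_sensitivities()] and the paired simulation is rerun with
#' the SAME seed (common random numbers across grid points). The crossing
#' is the delta where the MRI-pathway metric first falls to the
#' regular-pathway metric, located by linear interpolation between grid
#' points (NA if no crossing occurs on the grid).
#'
#' @param config A run configuration.
#' @param seed Master seed.
#' @param n Cohort size per grid point.
#' @param delta_grid Ascending grid of relative changes in `[0, 1)`.
#' @return A list with `grid` (data.frame `delta`, `metric_regular`,
#'   `metric_mri`) and `crossing_delta`.
#' @export
threshold_scan <- function(config, seed, n,
                           delta_grid = seq(0, 0.25, by = 0.05)) {
  if (is.unsorted(delta_grid, strictly = TRUE) ||
      any(delta_grid < 0) || any(delta_grid >= 1)) {
    stop_bad("delta_grid must be strictly ascending within [0, 1)")
  }
  grid <- do.call(rbind, lapply(delta_grid, function(d) {
    cfg <- config
    cfg$tests <- transform_sensitivities(cfg$tests, d)
    res <- run_paired_simulation(n, cfg, seed)
    data.frame(delta = d,
               metric_regular = res$comparison$regular$qaly_per_death_averted,
               metric_mri = res$comparison$mri$qaly_per_death_averted)
  }))
  diff <- grid$metric_mri - grid$metric_regular
  crossing <- NA_real_
  for (i in seq_len(nrow(grid) - 1)) {
    if (!is.na(diff[i]) && !is.na(diff[i + 1]) &&
        diff[i] > 0 && diff[i + 1] <= 0) {
      crossing <- grid$delta[i] + (grid$delta[i + 1] - grid$delta[i]) *
        diff[i] / (diff[i] - diff[i + 1])
      break
    }
  }
  list(grid = grid, crossing_delta = crossing)
}
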