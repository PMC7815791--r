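# Derived-metric arithmetic of the published comparison table, computable
# from explicitly supplied per-pathway values without any simulation. This
# is the worked-example surface: differences, signed percent changes,
# harm-benefit ratios and per-death-averted ratios.

#' Published-style comparison table from supplied per-pathway values
#'
#' Takes the per-1000 per-pathway outcomes as printed (number biopsied,
#' insignificant and significant cancers detected, overdiagnosed cases,
#' deaths averted, life-years gained, QALYs gained) and computes every
#' derived row: differences (regular - MRI, reported as printed with the
#' absolute difference plus a signed percent change whose magnitude divides
#' by the larger of the two values), overdiagnosed cases per death averted,
#' LY gained per death averted and QALYs gained per death averted.
#'
#' @param regular,mri Named lists (or vectors) with elements `men_biopsied`,
#'   `insignificant_detected`, `significant_detected`, `overdiagnosed`,
#'   `deaths_averted`, `ly_gained`, `qaly_gained`.
#' @return A data.frame with columns `metric`, `regular`, `mri`,
#'   `difference` (regular - MRI), `abs_difference`, `percent_change`.
#' @export
table2_from_values <- function(regular, mri) {
  need <- c("men_biopsied", "insignificant_detected", "significant_detected",
            "overdiagnosed", "deaths_averted", "ly_gained", "qaly_gained")
  regular <- as.list(regular); mri <- as.list(mri)
  miss <- setdiff(need, intersect(names(regular), names(mri)))
  if (length(miss)) {
    stop_bad("table2_from_values: missing per-pathway values: ",
             paste(miss, collapse = ", "))
  }
  ratio <- function(x, da) if (da > 0) x / da else NA_real_
  regular$harm_benefit <- ratio(regular$overdiagnosed, regular$deaths_averted)
  mri$harm_benefit <- ratio(mri$overdiagnosed, mri$deaths_averted)
  regular$lyg_per_death_averted <- ratio(regular$ly_gained,
                                         regular$deaths_averted)
  mri$lyg_per_death_averted <- ratio(mri$ly_gained, mri$deaths_averted)
  regular$qaly_per_death_averted <- ratio(regular$qaly_gained,
                                          regular$deaths_averted)
  mri$qaly_per_death_averted <- ratio(mri$qaly_gained, mri$deaths_averted)

  metrics <- c(need, "harm_benefit", "lyg_per_death_averted",
               "qaly_per_death_averted")
  do.call(rbind, lapply(metrics, function(nm) {
    r <- regular[[nm]]; m <- mri[[nm]]
    pc <- if (is.na(r) || is.na(m)) NA_real_ else percent_change(r, m)
    data.frame(metric = nm, regular = r, mri = m,
               difference = r - m, abs_difference = abs(r - m),
               percent_change = pc)
  }))
}
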