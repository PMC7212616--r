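#' Production efficiency factor for a given year
#'
#' Environmental intensity of food production is assumed to improve linearly
#' in percentage points of the base-year intensity: the factor is
#' `1 - annual_gain * (year - base_year)` (an observed 20% decline over 16
#' years annualizes to 1.25%/yr on this arithmetic). The factor applies
#' uniformly to all indicators and food groups.
#'
#' @param year calendar year (>= `base_year`).
#' @param base_year year at which the factor is 1.
#' @param annual_gain fraction of base-year intensity gained per year.
#' @return multiplier in (0, 1].
#' @examples
#' efficiency_factor(2034, 2018)          # 0.80 after 16 years at 1.25%/yr
#' @export
efficiency_factor <- function(year, base_year, annual_gain = 0.0125) {
  if (any(year < base_year))
    abort_validation("year must not precede the efficiency base year")
  f <- 1 - annual_gain * (year - base_year)
  if (any(f <= 0))
    abort_validation("efficiency factor fell to zero or below over the horizon")
  f
}

#' Environmental impact of one year's consumption
#'
#' Five-indicator impact vector: sum over food groups of national kg times
#' the per-kg footprint, scaled by the production efficiency factor of the
#' year.
#'
#' @param kg_by_group named vector of national kg/year per food group.
#' @param footprints food-group x indicator matrix of per-kg footprints.
#' @param year calendar year.
#' @param base_year efficiency base year.
#' @param annual_gain efficiency gain per year.
#' @return named numeric impact vector (ghg kg CO2-eq, acidification kg
#'   SO2-eq, fresh_eutroph kg P-eq, salt_eutroph kg N-eq, land m2a).
#' @export
annual_impact <- function(kg_by_group, footprints, year, base_year,
                          annual_gain = 0.0125) {
  if (any(kg_by_group < 0)) abort_validation("consumption kg must be non-negative")
  missing <- setdiff(names(kg_by_group), rownames(footprints))
  if (length(missing))
    abort_validation(paste("no footprint for food group:",
                           paste(missing, collapse = ", ")))
  f <- efficiency_factor(year, base_year, annual_gain)
  as.numeric(kg_by_group %*% footprints[names(kg_by_group), , drop = FALSE]) *
    f -> v
  stats::setNames(v, colnames(footprints))
}

#' Monetize an environmental impact difference
#'
#' Dot product of an indicator delta with the unit costs. Sign convention:
#' pass the avoided burden (reference minus scenario) so that an avoided
#' burden is a positive benefit.
#'
#' @param impact_delta named impact vector (reference minus scenario).
#' @param unit_costs named EUR-per-unit vector over the same indicators.
#' @return EUR.
#' @export
monetize_impact <- function(impact_delta, unit_costs) {
  idx <- names(unit_costs)
  sum(impact_delta[idx] * unit_costs[idx])
}

#' Yearly environmental impacts of a consumption trajectory
#'
#' @param trajectory an `scba_trajectory`.
#' @param inputs an `scba_inputs` bundle (footprints).
#' @param config configuration (base year, efficiency gain).
#' @param annual_gain efficiency gain, defaulting to the configured one.
#' @param groups food groups to include (default all); relative scenario
#'   effects on a priced exposure are conventionally reported on its own
#'   groups (e.g. the meat impact under a meat tax).
#' @return year x indicator matrix of impacts.
#' @export
impact_trajectory <- function(trajectory, inputs, config = inputs$config,
                              annual_gain = config$environment$annual_gain,
                              groups = colnames(trajectory$national_kg)) {
  t(vapply(seq_along(trajectory$years), function(i)
    annual_impact(stats::setNames(trajectory$national_kg[i, groups], groups),
                  inputs$footprints,
                  trajectory$years[i], config$base_year, annual_gain),
    numeric(ncol(inputs$footprints)))) -> m
  rownames(m) <- trajectory$years
  m
}

#' Relative impact change of a scenario versus reference in a given year
#'
#' Efficiency gains affect both scenarios identically, so this ratio depends
#' only on consumption; with per-kg footprints it is identical across all
#' five indicators for a uniform consumption scaling.
#'
#' @param impact_scen,impact_ref year x indicator impact matrices.
#' @param year calendar year.
#' @return named vector of relative changes (scenario/reference - 1) per
#'   indicator; negative means reduced burden.
#' @export
relative_impact_change <- function(impact_scen, impact_ref, year) {
  i <- match(as.character(year), rownames(impact_ref))
  if (is.na(i)) abort_validation("year outside the impact horizon")
  impact_scen[i, ] / impact_ref[i, ] - 1
}
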