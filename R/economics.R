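#' Change in consumer surplus after a price change
#'
#' Rule-of-half approximations to the welfare change of consumers. Two forms
#' are implemented: `as_printed`, the triangle term
#' `0.5 * (p0 - p1) * (q0 - q1)`, and `full_roh`, the standard rule of half
#' `0.5 * (p0 - p1) * (q0 + q1)` (trapezoid under the demand curve). The
#' package default is `full_roh`, whose magnitudes match the scale of a
#' national 30-year welfare ledger; the triangle form is retained as an
#' option. A price rise gives a negative surplus change (consumer loss), a
#' subsidy a positive one.
#'
#' @param p0,p1 price before / after (EUR per kg).
#' @param q0,q1 quantity before / after (kg); non-negative.
#' @param form `"full_roh"` or `"as_printed"`.
#' @return EUR.
#' @examples
#' consumer_surplus(10, 11.5, 100, 92, form = "as_printed") # -6
#' consumer_surplus(10, 11.5, 100, 92)                      # -144
#' @export
consumer_surplus <- function(p0, p1, q0, q1,
                             form = c("full_roh", "as_printed")) {
  form <- match.arg(form)
  if (any(q0 < 0) || any(q1 < 0))
    abort_validation("quantities must be non-negative")
  switch(form,
    as_printed = 0.5 * (p0 - p1) * (q0 - q1),
    full_roh = 0.5 * (p0 - p1) * (q0 + q1))
}

#' Government policy revenue of a price intervention
#'
#' For a tax: tax receipts on the (reduced) consumption minus the VAT lost
#' on the forgone consumption. For a subsidy: VAT gained on the extra
#' consumption minus the subsidy outlay. Prices follow the CPI trend,
#' `price_t = price_0 * (1 + cpi)^t`.
#'
#' @param price_change signed price change fraction (tax > 0, subsidy < 0).
#' @param q0,q1 yearly reference / scenario quantities (kg; vectors over
#'   years).
#' @param price_per_kg base-year consumer price (EUR/kg).
#' @param cpi_rate consumer price index trend (fraction/year).
#' @param vat_rate food VAT rate (fraction).
#' @param year_offset years since the base year (vector matching q0).
#' @return EUR per year (vector).
#' @export
policy_revenue <- function(price_change, q0, q1, price_per_kg, cpi_rate,
                           vat_rate, year_offset = seq_along(q0)) {
  if (any(price_per_kg <= 0)) abort_validation("prices must be positive")
  price_t <- price_per_kg * (1 + cpi_rate)^year_offset
  if (price_change >= 0) {
    price_change * price_t * q1 - vat_rate * price_t * (q0 - q1)
  } else {
    vat_rate * price_t * (q1 - q0) - (-price_change) * price_t * q1
  }
}

#' Healthcare cost savings from averted disease cases
#'
#' Averted prevalent case-years valued at per-disease cost-of-illness rates.
#' A disease whose caseload rises under the scenario (compensatory disease
#' in longer-lived survivors) contributes negatively.
#'
#' @param delta an `scba_health_delta`.
#' @param cost_per_case named EUR per prevalent-case-year per disease.
#' @return data.frame (year, amount) in EUR, positive = saving.
#' @export
healthcare_savings <- function(delta, cost_per_case) {
  bd <- delta$by_disease
  unknown <- setdiff(unique(bd$disease), names(cost_per_case))
  if (length(unknown))
    abort_validation(paste("no healthcare cost for disease:",
                           paste(unknown, collapse = ", ")))
  amt <- tapply(bd$averted_cases * cost_per_case[bd$disease], bd$year, sum)
  data.frame(year = as.integer(names(amt)), amount = as.numeric(amt))
}

#' Monetized health outcome (QALY) stream
#'
#' @param delta an `scba_health_delta`.
#' @param qaly_value EUR per QALY.
#' @return data.frame (year, amount) in EUR.
#' @export
qaly_benefit <- function(delta, qaly_value) {
  data.frame(year = delta$qaly$year,
             amount = delta$qaly$qaly_gain * qaly_value)
}

#' Productivity effects of averted working-age disease
#'
#' Two components per averted working-age prevalent case-year: absenteeism
#' plus presenteeism costs, and the fiscal participation effect (income tax
#' and welfare payments). Under the human-capital method the participation
#' stream counts in full; the friction-cost method keeps only
#' `friction_fraction` of it. A configurable consumer share routes part of
#' the total to consumers, the rest to government.
#'
#' @param delta an `scba_health_delta` (its working-age columns are used).
#' @param economics the `economics` component of a configuration.
#' @param method `"human_capital"` or `"friction"`.
#' @return data.frame (year, stakeholder, amount) in EUR.
#' @export
productivity_effects <- function(delta, economics,
                                 method = c("human_capital", "friction")) {
  method <- match.arg(method)
  bd <- delta$by_disease
  unknown <- setdiff(unique(bd$disease),
                     names(economics$absenteeism_presenteeism_cost))
  if (length(unknown))
    abort_validation(paste("no productivity cost for disease:",
                           paste(unknown, collapse = ", ")))
  fr <- if (method == "friction") economics$friction_fraction else 1
  per_case <- economics$absenteeism_presenteeism_cost[bd$disease] +
    fr * economics$participation_fiscal_effect[bd$disease]
  amt <- tapply(bd$averted_cases_wa * per_case, bd$year, sum)
  share <- economics$productivity_consumer_share
  years <- as.integer(names(amt))
  rbind(
    data.frame(year = years, stakeholder = "consumers",
               amount = as.numeric(amt) * share),
    data.frame(year = years, stakeholder = "government",
               amount = as.numeric(amt) * (1 - share)))
}
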