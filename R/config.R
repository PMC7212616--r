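#' Default configuration for the food-pricing SCBA
#'
#' Returns the full set of tunable parameters used by the synthetic-data
#' generator and the analysis pipeline. Values that the underlying study
#' prints (elasticities, environmental unit costs, efficiency gains, QALY
#' values, discount rates, VAT, implementation cost) are defaults here;
#' values the study draws from unpublished sources (relative risks,
#' per-disease costs, food prices, CPI) are plausible placeholders and are
#' meant to be overridden for any real application.
#'
#' @param ... named overrides for top-level entries; nested lists are merged
#'   element-wise (e.g. `monetization = list(discount_rate = 0.04)` changes
#'   only the discount rate).
#'
#' @return A named list of class `scba_config` with components:
#' \describe{
#'   \item{horizon}{years simulated after the base year (default 30).}
#'   \item{base_year}{calendar base year for prices and discounting (2018).}
#'   \item{population}{target size, Gompertz-Makeham mortality parameters,
#'     sex ratio at birth.}
#'   \item{consumption}{population-mean intake targets (g/day), meat group
#'     split, gamma shape of within-cell intake, seeded cell-level noise.}
#'   \item{elasticity}{own-price elasticity point estimates and 95% CIs per
#'     food exposure, plus which setting (`point`, `high`, `low`) to use and
#'     the functional form (`iso_elastic` or `linear`).}
#'   \item{categories}{intake cut-points (g/day) defining risk-factor
#'     categories per exposure.}
#'   \item{rr}{relative-risk means and 95% CIs per (exposure, disease,
#'     category); category 1 of the meat exposure and the top category of
#'     the fruit/vegetable exposure are the references (RR = 1).}
#'   \item{environment}{annual production efficiency gain (fraction of the
#'     base-year intensity per year), variant gains, environmental unit
#'     costs in EUR per indicator unit, and high/low cost scalings.}
#'   \item{economics}{consumer prices per kg, CPI trend, food VAT rate,
#'     per-disease healthcare and productivity costs, participation fiscal
#'     effect, implementation cost, friction fraction, productivity
#'     consumer share, working-age band.}
#'   \item{monetization}{QALY values, discount rate, consumer-surplus form.}
#'   \item{mc}{Monte-Carlo iteration count for relative-risk uncertainty.}
#' }
#' @examples
#' cfg <- scba_config(monetization = list(discount_rate = 0.015))
#' cfg$monetization$discount_rate
#' @export
scba_config <- function(...) {
  diseases <- c("diabetes_type2", "stroke", "lung_cancer", "chd",
                "colorectal_cancer")
  cfg <- list(
    horizon = 30L,
    base_year = 2018L,
    population = list(
      total = 16979107,
      makeham = 2e-4,
      gompertz_a = c(female = 1.6e-5, male = 2.6e-5),
      gompertz_b = 0.1,
      sex_ratio_male = 0.512
    ),
    consumption = list(
      meat_target = 107,
      fv_target = 250,
      meat_split = c(red_meat = 0.42, processed_meat = 0.33, poultry = 0.25),
      gamma_shape = 4,
      cell_noise_sd = 0.05
    ),
    elasticity = list(
      meat = list(point = -0.60, ci = c(-0.66, -0.54)),
      fruit_vegetables = list(point = -0.53, ci = c(-0.59, -0.48)),
      setting = "point",
      form = "iso_elastic"
    ),
    categories = list(
      meat = c(50, 100),
      fruit_vegetables = c(150, 300)
    ),
    rr = default_rr_table(),
    environment = list(
      annual_gain = 0.0125,
      gain_high = 0.0175,
      gain_low = 0.0075,
      unit_costs = c(ghg = 0.057, acidification = 5.40,
                     fresh_eutroph = 3.11, salt_eutroph = 1.90,
                     land = 0.0261),
      unit_cost_scale_high = 1.5,
      unit_cost_scale_low = 0.5
    ),
    economics = list(
      price_per_kg = c(red_meat = 11.0, processed_meat = 10.0,
                       poultry = 7.5, fruit_vegetables = 2.7),
      cpi_rate = 0.012,
      vat_rate_food = 0.06,
      healthcare_cost_per_case = c(diabetes_type2 = 3000, stroke = 9000,
                                   lung_cancer = 20000, chd = 6000,
                                   colorectal_cancer = 15000),
      absenteeism_presenteeism_cost = c(diabetes_type2 = 2500, stroke = 7000,
                                        lung_cancer = 9000, chd = 5000,
                                        colorectal_cancer = 8000),
      participation_fiscal_effect = c(diabetes_type2 = 2000, stroke = 6000,
                                      lung_cancer = 8000, chd = 4000,
                                      colorectal_cancer = 7000),
      implementation_cost = 20e6,
      friction_fraction = 0.2,
      productivity_consumer_share = 0.15,
      working_age = c(15, 75)
    ),
    monetization = list(
      qaly_value = 50000,
      qaly_value_high = 100000,
      discount_rate = 0.03,
      cs_form = "full_roh"
    ),
    mc = list(n_iter = 100L),
    diseases = diseases
  )
  cfg <- merge_config(cfg, list(...))
  class(cfg) <- c("scba_config", "list")
  validate_config(cfg)
  cfg
}

# recursive element-wise merge; overrides win
merge_config <- function(base, overrides) {
  for (nm in names(overrides)) {
    if (is.list(base[[nm]]) && is.list(overrides[[nm]]) &&
        !is.data.frame(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], overrides[[nm]])
    } else {
      base[[nm]] <- overrides[[nm]]
    }
  }
  base
}

#' Default relative-risk table
#'
#' Synthetic placeholder relative risks per (exposure, disease, category).
#' The meat exposure covers red plus processed meat (poultry carries no
#' health association, i.e. RR = 1 by exclusion); its lowest intake category
#' is the reference. For fruit and vegetables low intake carries the excess
#' risk, so the top category is the reference. The magnitudes (1.0-1.4) echo
#' the gradients typical of meta-analyses of diet and chronic disease but are
#' configuration, not estimates.
#'
#' @return data.frame with columns exposure, disease, category, rr, ci_low,
#'   ci_high. Reference categories have rr = 1 and a degenerate CI.
#' @export
default_rr_table <- function() {
  mk <- function(exposure, disease, rr) {
    halfw <- ifelse(rr == 1, 0, 0.35 * (rr - 1) + 0.02)
    data.frame(exposure = exposure, disease = disease,
               category = seq_along(rr), rr = rr,
               ci_low = pmax(rr - halfw, 1e-6), ci_high = rr + halfw,
               stringsAsFactors = FALSE)
  }
  rbind(
    mk("meat", "diabetes_type2",    c(1, 1.15, 1.35)),
    mk("meat", "stroke",            c(1, 1.08, 1.18)),
    mk("meat", "lung_cancer",       c(1, 1.05, 1.12)),
    mk("meat", "chd",               c(1, 1.00, 1.00)),
    mk("meat", "colorectal_cancer", c(1, 1.12, 1.28)),
    mk("fruit_vegetables", "diabetes_type2",    c(1.00, 1.00, 1)),
    mk("fruit_vegetables", "stroke",            c(1.35, 1.15, 1)),
    mk("fruit_vegetables", "lung_cancer",       c(1.15, 1.07, 1)),
    mk("fruit_vegetables", "chd",               c(1.28, 1.12, 1)),
    mk("fruit_vegetables", "colorectal_cancer", c(1.10, 1.05, 1))
  )
}

abort_validation <- function(msg) {
  stop(errorCondition(msg,
                      class = c("foodscba_validation_error", "error")))
}

validate_config <- function(cfg) {
  ec <- cfg$economics
  if (cfg$horizon < 1) abort_validation("horizon must be >= 1 year")
  if (cfg$population$total <= 0) abort_validation("population total must be positive")
  if (cfg$consumption$meat_target < 0 || cfg$consumption$fv_target < 0)
    abort_validation("intake targets must be non-negative")
  if (cfg$consumption$gamma_shape <= 0)
    abort_validation("gamma shape must be positive")
  if (abs(sum(cfg$consumption$meat_split) - 1) > 1e-8)
    abort_validation("meat_split fractions must sum to 1")
  for (expo in c("meat", "fruit_vegetables")) {
    e <- cfg$elasticity[[expo]]
    if (!(e$ci[1] <= e$point && e$point <= e$ci[2]))
      abort_validation(sprintf("elasticity CI must bracket point for %s", expo))
    b <- cfg$categories[[expo]]
    if (is.unsorted(b, strictly = TRUE))
      abort_validation("category boundaries must be strictly increasing")
  }
  rr <- cfg$rr
  if (any(rr$rr <= 0)) abort_validation("relative risks must be positive")
  if (any(rr$ci_low > rr$rr | rr$rr > rr$ci_high))
    abort_validation("RR confidence intervals must bracket the mean")
  if (any(cfg$environment$unit_costs <= 0))
    abort_validation("environmental unit costs must be positive")
  if (cfg$environment$annual_gain < 0)
    abort_validation("efficiency gain must be non-negative")
  if (any(ec$price_per_kg <= 0)) abort_validation("prices must be positive")
  if (ec$vat_rate_food < 0 || ec$vat_rate_food > 1)
    abort_validation("VAT rate must lie in [0,1]")
  if (any(ec$healthcare_cost_per_case < 0) ||
      any(ec$absenteeism_presenteeism_cost < 0) ||
      any(ec$participation_fiscal_effect < 0) ||
      ec$implementation_cost < 0)
    abort_validation("monetary inputs must be non-negative")
  if (ec$friction_fraction < 0 || ec$friction_fraction > 1)
    abort_validation("friction fraction must lie in [0,1]")
  if (cfg$monetization$qaly_value <= 0)
    abort_validation("QALY value must be positive")
  if (cfg$monetization$discount_rate < 0)
    abort_validation("discount rate must be non-negative")
  invisible(cfg)
}

#' Read a configuration from a YAML file
#'
#' Entries found in the file override the defaults of [scba_config()];
#' anything not mentioned keeps its default. The `rr` entry, if present,
#' must be a list of records with fields exposure, disease, category, rr,
#' ci_low, ci_high.
#'
#' @param path path to a YAML file.
#' @return An `scba_config` object.
#' @export
read_scba_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$rr)) {
    raw$rr <- do.call(rbind, lapply(raw$rr, as.data.frame))
  }
  for (nm in c("unit_costs")) {
    if (!is.null(raw$environment[[nm]]))
      raw$environment[[nm]] <- unlist(raw$environment[[nm]])
  }
  for (nm in c("price_per_kg", "healthcare_cost_per_case",
               "absenteeism_presenteeism_cost", "participation_fiscal_effect",
               "working_age")) {
    if (!is.null(raw$economics[[nm]]))
      raw$economics[[nm]] <- unlist(raw$economics[[nm]])
  }
  if (!is.null(raw$consumption$meat_split))
    raw$consumption$meat_split <- unlist(raw$consumption$meat_split)
  do.call(scba_config, raw)
}

#' Write a configuration to YAML
#'
#' @param config an `scba_config` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scba_config <- function(config, path) {
  out <- unclass(config)
  out$rr <- split(config$rr, seq_len(nrow(config$rr)))
  out$rr <- lapply(out$rr, as.list)
  names(out$rr) <- NULL
  yaml::write_yaml(out, path)
  invisible(path)
}
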