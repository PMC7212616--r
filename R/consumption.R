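#' Price-intervention scenarios
#'
#' The three policy scenarios modelled against a no-policy reference: a 15%
#' or 30% consumer price increase on all meat (red, processed, poultry) and
#' a 10% price decrease on fruit and vegetables. Price pass-through is full
#' from the first policy year and constant thereafter.
#'
#' @param name one of `"reference"`, `"meat15"`, `"meat30"`, `"fv10"`.
#' @param start_year first policy year; defaults to base year + 1.
#' @param horizon_years projection length in years.
#' @return list of class `scba_scenario` with `name`, `price_change` (named
#'   signed fraction per food group) and horizon fields.
#' @export
scenario_spec <- function(name = c("reference", "meat15", "meat30", "fv10"),
                          start_year = NULL, horizon_years = 30L) {
  name <- match.arg(name)
  if (horizon_years < 1) abort_validation("horizon_years must be >= 1")
  meat_groups <- c("red_meat", "processed_meat", "poultry")
  price_change <- switch(name,
    reference = numeric(0),
    meat15 = stats::setNames(rep(0.15, 3), meat_groups),
    meat30 = stats::setNames(rep(0.30, 3), meat_groups),
    fv10 = c(fruit_vegetables = -0.10))
  structure(list(name = name, price_change = price_change,
                 start_year = start_year, horizon_years = horizon_years),
            class = "scba_scenario")
}

#' Apply an own-price elasticity to a quantity
#'
#' Projects the quantity demanded after a relative price change. Two
#' functional forms are supported: `iso_elastic` (constant elasticity),
#' `q1 = q0 * (1 + dp)^e`, and `linear`, `q1 = q0 * (1 + e * dp)`, truncated
#' at zero. The iso-elastic form is the package default.
#'
#' @param q0 baseline quantity (any non-negative unit; g/day or kg).
#' @param price_change signed relative price change (e.g. 0.15 for +15%);
#'   must exceed -1.
#' @param elasticity own-price elasticity (dimensionless, negative for
#'   normal goods).
#' @param form `"iso_elastic"` or `"linear"`.
#' @return the projected quantity, same shape as `q0`.
#' @examples
#' apply_elasticity(107, 0.15, -0.60)           # 98.39 g/day
#' apply_elasticity(107, 0.15, -0.60, "linear") # 97.37 g/day
#' @export
apply_elasticity <- function(q0, price_change, elasticity,
                             form = c("iso_elastic", "linear")) {
  form <- match.arg(form)
  if (any(q0 < 0)) abort_validation("baseline quantity must be non-negative")
  if (price_change <= -1)
    abort_validation("price_change must be greater than -1")
  q1 <- switch(form,
    iso_elastic = q0 * (1 + price_change)^elasticity,
    linear = q0 * (1 + elasticity * price_change))
  pmax(q1, 0)
}

# elasticity value for a food group under the configured setting
elasticity_for <- function(group, config) {
  expo <- if (group == "fruit_vegetables") "fruit_vegetables" else "meat"
  e <- config$elasticity[[expo]]
  switch(config$elasticity$setting,
    point = e$point,
    high = e$ci[1],   # larger magnitude (more negative)
    low = e$ci[2],
    abort_validation("elasticity setting must be point, high or low"))
}

#' Project consumption over the horizon under a scenario
#'
#' Builds the yearly consumption trajectory per (age, sex, food group). The
#' reference scenario carries each cell's baseline mean unchanged (no
#' autonomous trend); price interventions scale every cell of the priced
#' food groups by the elasticity response from the first policy year onward.
#' National annual kilograms are recomputed yearly against the pyramid.
#'
#' @param inputs an `scba_inputs` bundle.
#' @param scenario an `scba_scenario` or a scenario name.
#' @param config configuration; defaults to the bundle's.
#' @return list of class `scba_trajectory`: `cells` (year, age, sex,
#'   food_group, g_per_day), `national_kg` (year x food group matrix),
#'   `mean_intake` (year x food group population-weighted means), `years`,
#'   `scenario`.
#' @export
project_consumption <- function(inputs, scenario, config = inputs$config) {
  if (is.character(scenario))
    scenario <- scenario_spec(scenario, horizon_years = config$horizon)
  years <- config$base_year + seq_len(config$horizon)
  base <- inputs$consumption
  groups <- unique(base$food_group)
  for (g in names(scenario$price_change)) {
    if (!g %in% groups)
      abort_validation(sprintf("no consumption profile for priced group %s", g))
  }

  scale_g <- stats::setNames(rep(1, length(groups)), groups)
  for (g in names(scenario$price_change)) {
    scale_g[g] <- apply_elasticity(1, scenario$price_change[[g]],
                                   elasticity_for(g, config),
                                   config$elasticity$form)
  }

  scaled <- base
  scaled$g_per_day <- base$g_per_day * scale_g[base$food_group]

  cells <- do.call(rbind, lapply(years, function(y)
    data.frame(year = y, scaled[, c("age", "sex", "food_group", "g_per_day")])))
  rownames(cells) <- NULL

  kg_year <- national_annual_kg(scaled, inputs$pyramid)
  national_kg <- matrix(rep(kg_year, each = length(years)),
                        nrow = length(years),
                        dimnames = list(years, names(kg_year)))
  w <- inputs$pyramid$count / sum(inputs$pyramid$count)
  key <- paste(inputs$pyramid$age, inputs$pyramid$sex)
  mi <- vapply(colnames(national_kg), function(g) {
    sub <- scaled[scaled$food_group == g, ]
    sum(w[match(paste(sub$age, sub$sex), key)] * sub$g_per_day)
  }, numeric(1))
  mean_intake <- matrix(rep(mi, each = length(years)), nrow = length(years),
                        dimnames = dimnames(national_kg))

  structure(list(cells = cells, national_kg = national_kg,
                 mean_intake = mean_intake, years = years,
                 scenario = scenario$name, scale = scale_g),
            class = "scba_trajectory")
}

#' Population-mean intake of an exposure in a given year
#'
#' @param trajectory an `scba_trajectory`.
#' @param year calendar year.
#' @param groups food groups to sum (e.g. all meat groups).
#' @return g/day population mean.
#' @export
mean_intake <- function(trajectory, year,
                        groups = c("red_meat", "processed_meat", "poultry")) {
  yi <- match(year, trajectory$years)
  if (is.na(yi)) abort_validation("year outside the projection horizon")
  sum(trajectory$mean_intake[yi, groups])
}
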