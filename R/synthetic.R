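#' Generate the full synthetic input bundle
#'
#' Builds seeded synthetic stand-ins for the data sources a national
#' food-pricing SCBA needs: a stationary age-by-sex population pyramid with
#' annual newborn inflow, mean daily intake of four food groups per age and
#' sex (calibrated so the population-weighted means hit the configured
#' targets exactly), incidence / prevalence / excess-mortality / disability
#' tables for five chronic diseases, relative risks per intake category,
#' per-kg environmental footprints for five impact indicators, and consumer
#' prices with a CPI trend.
#'
#' The same seed and configuration always produce an identical bundle.
#'
#' @param seed integer seed for the cell-level intake noise.
#' @param config an [scba_config()] object.
#' @return A list of class `scba_inputs` with elements `pyramid`,
#'   `newborns`, `mortality`, `consumption`, `diseases`, `disability`,
#'   `rr`, `footprints`, `economics`, `config`, `seed`.
#' @examples
#' inp <- generate_inputs(seed = 1)
#' national_annual_kg(inp$consumption, inp$pyramid)
#' @export
generate_inputs <- function(seed = 1L, config = scba_config()) {
  validate_config(config)
  ages <- 0:100
  sexes <- c("female", "male")
  grid <- expand.grid(age = ages, sex = sexes, stringsAsFactors = FALSE)

  ## mortality: Gompertz-Makeham by sex
  pp <- config$population
  mu <- pp$makeham + pp$gompertz_a[grid$sex] * exp(pp$gompertz_b * grid$age)
  mortality <- data.frame(grid, rate = as.numeric(mu))

  ## stationary pyramid: counts(a+1) = counts(a) * exp(-mu(a)),
  ## age 100 is a closed bucket accumulating its survivors
  counts <- numeric(nrow(grid))
  for (s in sexes) {
    idx <- which(grid$sex == s)
    m <- mortality$rate[idx]
    births <- if (s == "male") pp$sex_ratio_male else 1 - pp$sex_ratio_male
    cs <- numeric(length(ages))
    cs[1] <- births
    for (a in seq_len(length(ages) - 1L)) cs[a + 1L] <- cs[a] * exp(-m[a])
    denom <- 1 - exp(-m[length(ages)])
    if (denom > 0) cs[length(ages)] <- cs[length(ages)] / denom
    counts[idx] <- cs
  }
  counts <- counts * (pp$total / sum(counts))
  pyramid <- data.frame(grid, count = counts)
  newborns <- sum(pyramid$count[pyramid$age == 0])

  ## intake profiles: smooth age shapes, male/female contrast, seeded
  ## multiplicative noise, then exact renormalization to the configured
  ## population-weighted targets
  set.seed(seed)
  cc <- config$consumption
  meat_shape <- age_profile_meat(grid$age) *
    ifelse(grid$sex == "male", 1.25, 1)
  fv_shape <- age_profile_fv(grid$age) *
    ifelse(grid$sex == "male", 0.95, 1.05)
  meat_shape <- meat_shape * exp(stats::rnorm(nrow(grid), 0, cc$cell_noise_sd))
  fv_shape <- fv_shape * exp(stats::rnorm(nrow(grid), 0, cc$cell_noise_sd))
  w <- pyramid$count / sum(pyramid$count)
  meat_mean <- meat_shape * (cc$meat_target / sum(w * meat_shape))
  fv_mean <- fv_shape * (cc$fv_target / sum(w * fv_shape))

  groups <- names(cc$meat_split)
  consumption <- do.call(rbind, c(
    lapply(groups, function(g)
      data.frame(grid, food_group = g,
                 g_per_day = meat_mean * cc$meat_split[[g]],
                 gamma_shape = cc$gamma_shape)),
    list(data.frame(grid, food_group = "fruit_vegetables",
                    g_per_day = fv_mean, gamma_shape = cc$gamma_shape))
  ))
  rownames(consumption) <- NULL

  diseases <- synthetic_disease_table(grid, config$diseases)
  disability <- c(diabetes_type2 = 0.07, stroke = 0.30, lung_cancer = 0.40,
                  chd = 0.15, colorectal_cancer = 0.25)[config$diseases]

  footprints <- default_footprints()

  structure(list(pyramid = pyramid, newborns = newborns,
                 mortality = mortality, consumption = consumption,
                 diseases = diseases, disability = disability,
                 rr = config$rr, footprints = footprints,
                 economics = config$economics,
                 config = config, seed = seed),
            class = "scba_inputs")
}

# meat intake rises through childhood, plateaus in adulthood, tapers in old age
age_profile_meat <- function(age) {
  ifelse(age < 20, 0.35 + 0.65 * age / 20,
         ifelse(age <= 70, 1, pmax(0.6, 1 - 0.006 * (age - 70))))
}

# fruit & vegetables: lower in childhood, mild rise with age
age_profile_fv <- function(age) {
  0.55 + 0.45 * pmin(age, 35) / 35 + 0.002 * pmax(age - 50, 0)
}

# synthetic epidemiology: exponential-in-age incidence with caps, steady-state
# style prevalence, per-disease excess mortality among prevalent cases
synthetic_disease_table <- function(grid, diseases) {
  pars <- list(
    diabetes_type2    = list(i0 = 2.5e-3, b = 0.055, cap = 0.020, dur = 20,
                             em = 0.008, male = 1.10),
    stroke            = list(i0 = 1.0e-3, b = 0.085, cap = 0.050, dur = 8,
                             em = 0.060, male = 1.20),
    lung_cancer       = list(i0 = 6.0e-4, b = 0.070, cap = 0.008, dur = 3,
                             em = 0.350, male = 1.40),
    chd               = list(i0 = 2.0e-3, b = 0.075, cap = 0.040, dur = 12,
                             em = 0.040, male = 1.30),
    colorectal_cancer = list(i0 = 8.0e-4, b = 0.070, cap = 0.010, dur = 6,
                             em = 0.120, male = 1.15)
  )
  do.call(rbind, lapply(diseases, function(d) {
    p <- pars[[d]]
    inc <- pmin(p$cap, p$i0 * exp(p$b * (grid$age - 50))) *
      ifelse(grid$sex == "male", p$male, 1)
    inc[grid$age < 20] <- inc[grid$age < 20] * 0.05
    prev <- pmin(0.5, inc * p$dur / (1 + inc * p$dur))
    data.frame(disease = d, grid, incidence = inc, prevalence = prev,
               excess_mortality = p$em)
  }))
}

#' Synthetic per-kg environmental footprints
#'
#' Five impact indicators per kg of food: greenhouse gases (kg CO2-eq),
#' acidification (kg SO2-eq), freshwater eutrophication (kg P-eq), saltwater
#' eutrophication (kg N-eq) and land use (m2a). Magnitudes are calibrated so
#' the consumption-weighted national totals are of the order reported for
#' Dutch meat and fruit/vegetable consumption; meat exceeds fruit and
#' vegetables in every indicator, the structural assumption all downstream
#' signs rely on.
#'
#' @return matrix, food groups in rows, indicators in columns.
#' @export
default_footprints <- function() {
  m <- rbind(
    red_meat         = c(48,   0.60,  0.0095,  0.105,  35),
    processed_meat   = c(40,   0.50,  0.0080,  0.088,  29),
    poultry          = c(16,   0.20,  0.0030,  0.032,  11),
    fruit_vegetables = c(2.1,  0.006, 0.0002,  0.0014, 0.26)
  )
  colnames(m) <- c("ghg", "acidification", "fresh_eutroph", "salt_eutroph",
                   "land")
  m
}

#' National annual consumption in kg per food group
#'
#' Converts mean daily intakes (g/day per age-sex cell) to national annual
#' kilograms against a population pyramid:
#' sum over cells of count x g/day x 365 / 1000.
#'
#' @param profile data.frame with columns age, sex, food_group, g_per_day.
#' @param pyramid data.frame with columns age, sex, count.
#' @return named numeric vector of kg/year per food group.
#' @export
national_annual_kg <- function(profile, pyramid) {
  key_p <- paste(profile$age, profile$sex)
  key_y <- paste(pyramid$age, pyramid$sex)
  if (!all(key_p %in% key_y))
    abort_validation("consumption profile and pyramid are on different age-sex grids")
  cnt <- pyramid$count[match(key_p, key_y)]
  kg <- tapply(cnt * profile$g_per_day * 365 / 1000, profile$food_group, sum)
  out <- as.numeric(kg)
  names(out) <- names(kg)
  out
}

#' Write an input bundle to plain-text files
#'
#' Writes population.csv, consumption.csv, diseases.csv, rr.csv,
#' footprints.csv and economics.json into `dir`.
#'
#' @param inputs an `scba_inputs` bundle.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_inputs <- function(inputs, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(inputs$pyramid, file.path(dir, "population.csv"),
                   row.names = FALSE)
  utils::write.csv(inputs$consumption, file.path(dir, "consumption.csv"),
                   row.names = FALSE)
  utils::write.csv(inputs$diseases, file.path(dir, "diseases.csv"),
                   row.names = FALSE)
  utils::write.csv(inputs$rr, file.path(dir, "rr.csv"), row.names = FALSE)
  fp <- data.frame(food_group = rownames(inputs$footprints),
                   inputs$footprints, row.names = NULL)
  utils::write.csv(fp, file.path(dir, "footprints.csv"), row.names = FALSE)
  econ <- c(inputs$economics,
            list(newborns = inputs$newborns,
                 disability = as.list(inputs$disability)))
  jsonlite::write_json(econ, file.path(dir, "economics.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read an input bundle written by [write_inputs()]
#'
#' @param dir directory containing the CSV/JSON files.
#' @param config the configuration the bundle was generated under.
#' @return An `scba_inputs` bundle.
#' @export
read_inputs <- function(dir, config = scba_config()) {
  pyramid <- utils::read.csv(file.path(dir, "population.csv"))
  consumption <- utils::read.csv(file.path(dir, "consumption.csv"))
  diseases <- utils::read.csv(file.path(dir, "diseases.csv"))
  rr <- utils::read.csv(file.path(dir, "rr.csv"))
  fp <- utils::read.csv(file.path(dir, "footprints.csv"))
  footprints <- as.matrix(fp[, -1])
  rownames(footprints) <- fp$food_group
  econ <- jsonlite::read_json(file.path(dir, "economics.json"),
                              simplifyVector = TRUE)
  disability <- unlist(econ$disability)
  newborns <- econ$newborns
  econ$disability <- NULL
  econ$newborns <- NULL
  pp <- config$population
  mu <- pp$makeham + pp$gompertz_a[pyramid$sex] * exp(pp$gompertz_b * pyramid$age)
  mortality <- data.frame(age = pyramid$age, sex = pyramid$sex,
                          rate = as.numeric(mu))
  structure(list(pyramid = pyramid, newborns = newborns,
                 mortality = mortality, consumption = consumption,
                 diseases = diseases, disability = disability,
                 rr = rr, footprints = footprints, economics = econ,
                 config = config, seed = NA_integer_),
            class = "scba_inputs")
}
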