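# Small hand-built input bundles for exercising the health engine on grids
# where every update can be followed by hand.

# disease parameter rows: list(name = list(inc =, prev =, em =, dw =, rr_meat =
# c(...), rr_fv = c(...))) with rr vectors over 3 categories
make_toy_inputs <- function(ages = 0:2,
                            meat_mean = 80, fv_mean = 250,
                            counts = 1000, newborns = 0,
                            mortality_rate = 0.01,
                            horizon = 5L,
                            gamma_shape = 4,
                            diseases = list(
                              d1 = list(inc = 0.02, prev = 0.05, em = 0.1,
                                        dw = 0.2,
                                        rr_meat = c(1, 1.3, 1.6),
                                        rr_fv = c(1, 1, 1)))) {
  grid <- expand.grid(age = ages, sex = c("female", "male"),
                      stringsAsFactors = FALSE)
  rr <- do.call(rbind, lapply(names(diseases), function(d) {
    p <- diseases[[d]]
    rbind(
      data.frame(exposure = "meat", disease = d, category = 1:3,
                 rr = p$rr_meat,
                 ci_low = pmax(p$rr_meat - 0.1 * (p$rr_meat != 1), 1e-6),
                 ci_high = p$rr_meat + 0.1 * (p$rr_meat != 1)),
      data.frame(exposure = "fruit_vegetables", disease = d, category = 1:3,
                 rr = p$rr_fv,
                 ci_low = pmax(p$rr_fv - 0.1 * (p$rr_fv != 1), 1e-6),
                 ci_high = p$rr_fv + 0.1 * (p$rr_fv != 1)))
  }))
  config <- scba_config(horizon = as.integer(horizon),
                        diseases = names(diseases), rr = rr,
                        consumption = list(gamma_shape = gamma_shape))
  cons <- do.call(rbind, list(
    data.frame(grid, food_group = "red_meat", g_per_day = meat_mean * 0.6,
               gamma_shape = gamma_shape),
    data.frame(grid, food_group = "processed_meat",
               g_per_day = meat_mean * 0.4, gamma_shape = gamma_shape),
    data.frame(grid, food_group = "poultry", g_per_day = 20,
               gamma_shape = gamma_shape),
    data.frame(grid, food_group = "fruit_vegetables", g_per_day = fv_mean,
               gamma_shape = gamma_shape)))
  dtab <- do.call(rbind, lapply(names(diseases), function(d) {
    p <- diseases[[d]]
    data.frame(disease = d, grid, incidence = p$inc, prevalence = p$prev,
               excess_mortality = p$em)
  }))
  disability <- vapply(diseases, `[[`, numeric(1), "dw")
  names(disability) <- names(diseases)
  structure(list(
    pyramid = data.frame(grid, count = counts),
    newborns = newborns,
    mortality = data.frame(grid, rate = mortality_rate),
    consumption = cons, diseases = dtab, disability = disability,
    rr = rr, footprints = default_footprints(),
    economics = config$economics, config = config, seed = NA_integer_),
    class = "scba_inputs")
}
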