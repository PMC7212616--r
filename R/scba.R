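#' Present value of a future amount
#'
#' @param amount EUR (vector).
#' @param year_offset years after the base year (vector, >= 0).
#' @param rate discount rate (fraction/year).
#' @return discounted EUR.
#' @examples
#' discount_value(100, 10, 0.03) # 74.41
#' @export
discount_value <- function(amount, year_offset, rate) {
  if (any(year_offset < 0)) abort_validation("year_offset must be non-negative")
  if (rate < 0) abort_validation("discount rate must be non-negative")
  amount / (1 + rate)^year_offset
}

# effect rows in ledger order; stakeholder attribution follows the
# consumer/government stratification of a national welfare table
ledger_effects <- function() {
  c(healthcare_costs = "government",
    health_qaly = "consumers",
    productivity = NA,            # split by configuration
    environment = "government",
    policy_revenue = "government",
    consumer_surplus = "consumers",
    policy_costs = "government")
}

# nominal yearly cashflows for one scenario given a health delta
build_cashflows <- function(delta, traj_scen, traj_ref, impact_scen,
                            impact_ref, scenario, config) {
  ec <- config$economics
  years <- traj_ref$years
  off <- years - config$base_year
  rows <- list()
  add <- function(effect, stakeholder, year, amount)
    rows[[length(rows) + 1L]] <<- data.frame(
      year = year, effect = effect, stakeholder = stakeholder,
      amount = amount)

  ## health-driven effects
  hs <- healthcare_savings(delta, ec$healthcare_cost_per_case)
  add("healthcare_costs", "government", hs$year, hs$amount)
  if (!identical(config$monetization$information_assumption, "perfect")) {
    qb <- qaly_benefit(delta, config$monetization$qaly_value)
    add("health_qaly", "consumers", qb$year, qb$amount)
  }
  method <- config$economics$productivity_method
  if (is.null(method)) method <- "human_capital"
  pr <- productivity_effects(delta, ec, method)
  add("productivity", pr$stakeholder, pr$year, pr$amount)

  ## environment: avoided burden is a benefit
  uc <- config$environment$unit_costs
  env <- vapply(seq_along(years), function(i)
    monetize_impact(impact_ref[i, ] - impact_scen[i, ], uc), numeric(1))
  add("environment", "government", years, env)

  ## market effects
  cs <- numeric(length(years))
  rev <- numeric(length(years))
  for (g in names(scenario$price_change)) {
    dp <- scenario$price_change[[g]]
    p0 <- ec$price_per_kg[[g]] * (1 + ec$cpi_rate)^off
    q0 <- traj_ref$national_kg[, g]
    q1 <- traj_scen$national_kg[, g]
    cs <- cs + consumer_surplus(p0, p0 * (1 + dp), q0, q1,
                                config$monetization$cs_form)
    rev <- rev + policy_revenue(dp, q0, q1, ec$price_per_kg[[g]],
                                ec$cpi_rate, ec$vat_rate_food, off)
  }
  add("consumer_surplus", "consumers", years, cs)
  add("policy_revenue", "government", years, rev)

  cost <- ifelse(years == years[1] & scenario$name != "reference",
                 -ec$implementation_cost, 0)
  add("policy_costs", "government", years, cost)

  do.call(rbind, rows)
}

#' Discount and aggregate cashflows into a welfare ledger
#'
#' Discounts each yearly cashflow to the base year and aggregates to one row
#' per (effect, stakeholder) in million EUR. Grand totals per stakeholder
#' and for society are attached as attributes; by construction the societal
#' total equals both the sum over effects and the sum over stakeholders.
#'
#' @param cashflows data.frame (year, effect, stakeholder, amount in EUR).
#' @param discount_rate fraction/year.
#' @param base_year discounting base year.
#' @return data.frame of class `scba_ledger` with columns effect,
#'   stakeholder, value_meur and attributes `total`, `by_stakeholder`,
#'   `discount_rate`, `base_year`.
#' @export
assemble_ledger <- function(cashflows, discount_rate, base_year) {
  pv <- discount_value(cashflows$amount, cashflows$year - base_year,
                       discount_rate)
  agg <- stats::aggregate(list(value_meur = pv / 1e6),
                          by = list(effect = cashflows$effect,
                                    stakeholder = cashflows$stakeholder),
                          FUN = sum)
  ord <- order(match(agg$effect, names(ledger_effects())), agg$stakeholder)
  agg <- agg[ord, , drop = FALSE]
  rownames(agg) <- NULL
  by_st <- tapply(agg$value_meur, agg$stakeholder, sum)
  structure(agg, class = c("scba_ledger", "data.frame"),
            total = sum(agg$value_meur),
            by_stakeholder = by_st,
            discount_rate = discount_rate, base_year = base_year)
}

# rebuild an scba_health_delta from one Monte-Carlo draw
delta_from_draw <- function(draws, k, years, diseases) {
  structure(list(
    by_disease = data.frame(
      year = rep(years, length(diseases)),
      disease = rep(diseases, each = length(years)),
      averted_cases = as.numeric(draws$averted[, , k]),
      averted_cases_wa = as.numeric(draws$averted_wa[, , k]),
      incident_diff = NA_real_),
    qaly = data.frame(year = years, qaly_gain = draws$qaly_gain[, k])),
    class = "scba_health_delta")
}

#' Run the full social cost-benefit analysis for one scenario
#'
#' End-to-end pipeline: generates the synthetic inputs for the seed, projects
#' consumption under the scenario and the reference, runs the multistate
#' health model (with Monte-Carlo uncertainty over relative risks when
#' `n_iter >= 2`), computes environmental impacts, monetizes all effects and
#' assembles the discounted 30-year welfare ledger stratified by consumers
#' and government. Monte-Carlo low/high bounds (2.5th/97.5th percentiles)
#' propagate only through the relative-risk-dependent rows (healthcare,
#' health outcomes, productivity) and through the grand totals.
#'
#' @param scenario `"reference"`, `"meat15"`, `"meat30"` or `"fv10"`.
#' @param config an [scba_config()] object.
#' @param seed integer seed controlling the synthetic inputs and the
#'   Monte-Carlo draws; identical seeds give identical results.
#' @param n_iter Monte-Carlo iterations (0 disables uncertainty bounds).
#' @param inputs optionally, a pre-generated `scba_inputs` bundle (the seed
#'   is then only used for the Monte-Carlo draws).
#' @return An object of class `scba`.
#' @examples
#' \donttest{
#' fit <- scba("meat15", seed = 1, n_iter = 10)
#' fit
#' summary(fit)
#' }
#' @export
scba <- function(scenario = c("meat15", "meat30", "fv10", "reference"),
                 config = scba_config(), seed = 1L,
                 n_iter = config$mc$n_iter, inputs = NULL) {
  scenario <- match.arg(scenario)
  if (is.null(inputs)) inputs <- generate_inputs(seed, config)
  spec <- scenario_spec(scenario, horizon_years = config$horizon)
  traj_ref <- project_consumption(inputs, "reference", config)
  traj_scen <- if (scenario == "reference") traj_ref
               else project_consumption(inputs, spec, config)

  mc <- NULL
  if (scenario != "reference" && n_iter >= 2) {
    mc <- monte_carlo_health(inputs, traj_scen, traj_ref, config,
                             n_iter = n_iter, seed = seed)
    delta <- mc$point
  } else {
    ref_state <- simulate_health(traj_ref, inputs, config)
    scen_state <- if (scenario == "reference") ref_state
                  else simulate_health(traj_scen, inputs, config)
    delta <- health_delta(scen_state, ref_state)
  }

  impact_ref <- impact_trajectory(traj_ref, inputs, config)
  impact_scen <- if (scenario == "reference") impact_ref
                 else impact_trajectory(traj_scen, inputs, config)

  cashflows <- build_cashflows(delta, traj_scen, traj_ref, impact_scen,
                               impact_ref, spec, config)
  ledger <- assemble_ledger(cashflows, config$monetization$discount_rate,
                            config$base_year)

  if (!is.null(mc)) {
    ledger <- add_mc_bounds(ledger, mc, traj_scen, traj_ref, impact_scen,
                            impact_ref, spec, config)
  }
  structure(list(scenario = scenario, seed = seed, n_iter = n_iter,
                 config = config, inputs = inputs,
                 trajectory = traj_scen, reference = traj_ref,
                 health = delta, mc = mc,
                 impact = list(scenario = impact_scen,
                               reference = impact_ref),
                 cashflows = cashflows, ledger = ledger),
            class = "scba")
}

# percentile bounds for RR-dependent ledger rows and grand totals
add_mc_bounds <- function(ledger, mc, traj_scen, traj_ref, impact_scen,
                          impact_ref, spec, config) {
  years <- traj_ref$years
  diseases <- dimnames(mc$draws$averted)[[2]]
  n_iter <- dim(mc$draws$averted)[3]
  per_iter <- vector("list", n_iter)
  for (k in seq_len(n_iter)) {
    dk <- delta_from_draw(mc$draws, k, years, diseases)
    cf <- build_cashflows(dk, traj_scen, traj_ref, impact_scen, impact_ref,
                          spec, config)
    lk <- assemble_ledger(cf, config$monetization$discount_rate,
                          config$base_year)
    per_iter[[k]] <- lk
  }
  key <- paste(ledger$effect, ledger$stakeholder)
  vals <- vapply(per_iter, function(lk)
    lk$value_meur[match(key, paste(lk$effect, lk$stakeholder))],
    numeric(nrow(ledger)))
  vals <- matrix(vals, nrow = nrow(ledger))
  rr_rows <- ledger$effect %in% c("healthcare_costs", "health_qaly",
                                  "productivity")
  qlo <- apply(vals, 1, stats::quantile, 0.025, names = FALSE)
  qhi <- apply(vals, 1, stats::quantile, 0.975, names = FALSE)
  ledger$lo_meur <- ifelse(rr_rows, qlo, ledger$value_meur)
  ledger$hi_meur <- ifelse(rr_rows, qhi, ledger$value_meur)
  totals <- colSums(vals)
  st_tot <- vapply(per_iter, function(lk) attr(lk, "by_stakeholder"),
                   numeric(2))
  attr(ledger, "total_ci") <- stats::quantile(totals, c(0.025, 0.975),
                                              names = FALSE)
  attr(ledger, "by_stakeholder_ci") <- apply(st_tot, 1, stats::quantile,
                                             c(0.025, 0.975), names = FALSE)
  ledger
}

#' One-way sensitivity analysis
#'
#' Re-runs the pipeline varying one axis at a time from the base
#' configuration: discount rate (1.5% / 4%), elasticity at the 95% CI bounds,
#' the HEC-LEG / LEC-HEG environmental settings (high unit costs with low
#' efficiency gain, and vice versa with a 1.75%/yr gain), the friction-cost
#' productivity method, the perfect-information assumption (QALY rows
#' dropped), and the high QALY value. A variant with the base setting
#' reproduces the base ledger exactly.
#'
#' @param scenario scenario name.
#' @param config base configuration.
#' @param variants list of `list(axis =, setting =)` specs; the default runs
#'   the full standard set.
#' @param seed,n_iter as in [scba()].
#' @return list of class `scba_sensitivity`: `runs` (named list of `scba`
#'   objects) and `summary` (data.frame axis, setting, total_meur,
#'   consumers_meur, government_meur).
#' @export
run_sensitivity <- function(scenario, config = scba_config(),
                            variants = default_variants(), seed = 1L,
                            n_iter = config$mc$n_iter) {
  runs <- list()
  rows <- list()
  for (v in variants) {
    cfg <- variant_config(config, v$axis, v$setting)
    fit <- scba(scenario, cfg, seed = seed, n_iter = n_iter)
    nm <- paste(v$axis, v$setting, sep = ":")
    runs[[nm]] <- fit
    st <- attr(fit$ledger, "by_stakeholder")
    rows[[nm]] <- data.frame(axis = v$axis, setting = as.character(v$setting),
                             total_meur = attr(fit$ledger, "total"),
                             consumers_meur = st[["consumers"]],
                             government_meur = st[["government"]])
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  structure(list(runs = runs, summary = summary),
            class = "scba_sensitivity")
}

#' @rdname run_sensitivity
#' @export
default_variants <- function() {
  list(list(axis = "base", setting = "base"),
       list(axis = "discount_rate", setting = 0.015),
       list(axis = "discount_rate", setting = 0.04),
       list(axis = "elasticity_bound", setting = "high"),
       list(axis = "elasticity_bound", setting = "low"),
       list(axis = "environment_scenario", setting = "HEC-LEG"),
       list(axis = "environment_scenario", setting = "LEC-HEG"),
       list(axis = "productivity_method", setting = "friction"),
       list(axis = "information_assumption", setting = "perfect"),
       list(axis = "qaly_value", setting = 100000))
}

#' Apply a one-way sensitivity variant to a configuration
#'
#' @param config base configuration.
#' @param axis one of `"base"`, `"discount_rate"`, `"elasticity_bound"`,
#'   `"environment_scenario"`, `"productivity_method"`,
#'   `"information_assumption"`, `"qaly_value"`.
#' @param setting the axis setting (see [run_sensitivity()]).
#' @return the modified configuration.
#' @export
variant_config <- function(config, axis, setting) {
  switch(axis,
    base = config,
    discount_rate = merge_config(config,
      list(monetization = list(discount_rate = setting))),
    elasticity_bound = merge_config(config,
      list(elasticity = list(setting = setting))),
    environment_scenario = {
      env <- config$environment
      if (setting == "HEC-LEG") {
        env$unit_costs <- env$unit_costs * env$unit_cost_scale_high
        env$annual_gain <- env$gain_low
      } else if (setting == "LEC-HEG") {
        env$unit_costs <- env$unit_costs * env$unit_cost_scale_low
        env$annual_gain <- env$gain_high
      } else abort_validation("unknown environment scenario")
      config$environment <- env
      config
    },
    productivity_method = merge_config(config,
      list(economics = list(productivity_method = setting))),
    information_assumption = merge_config(config,
      list(monetization = list(information_assumption = setting))),
    qaly_value = merge_config(config,
      list(monetization = list(qaly_value = setting))),
    abort_validation(sprintf("unknown sensitivity axis: %s", axis)))
}

#' Write all pipeline outputs of a run to CSV
#'
#' Writes trajectory.csv, impact.csv, health_delta.csv, cashflows.csv,
#' ledger.csv, ledger_by_stakeholder.csv and a run manifest (manifest.json
#' with scenario, seed, iteration count and key configuration values).
#'
#' @param fit an `scba` object.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scba_outputs <- function(fit, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(fit$trajectory$cells, file.path(dir, "trajectory.csv"),
                   row.names = FALSE)
  imp <- do.call(rbind, lapply(c("scenario", "reference"), function(w) {
    m <- fit$impact[[w]]
    data.frame(year = as.integer(rep(rownames(m), ncol(m))),
               scenario = ifelse(w == "scenario", fit$scenario, "reference"),
               indicator = rep(colnames(m), each = nrow(m)),
               amount = as.numeric(m))
  }))
  utils::write.csv(imp, file.path(dir, "impact.csv"), row.names = FALSE)
  hd <- fit$health$by_disease
  if (!is.null(fit$mc)) {
    ci <- fit$mc$ci_cases
    hd$ci_low <- ci$lo[match(paste(hd$year, hd$disease),
                             paste(ci$year, ci$disease))]
    hd$ci_high <- ci$hi[match(paste(hd$year, hd$disease),
                              paste(ci$year, ci$disease))]
  }
  utils::write.csv(hd, file.path(dir, "health_delta.csv"), row.names = FALSE)
  utils::write.csv(fit$cashflows, file.path(dir, "cashflows.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(fit$ledger), file.path(dir, "ledger.csv"),
                   row.names = FALSE)
  st <- attr(fit$ledger, "by_stakeholder")
  utils::write.csv(data.frame(stakeholder = names(st),
                              total_meur = as.numeric(st)),
                   file.path(dir, "ledger_by_stakeholder.csv"),
                   row.names = FALSE)
  manifest <- list(scenario = fit$scenario, seed = fit$seed,
                   n_iter = fit$n_iter,
                   base_year = fit$config$base_year,
                   horizon = fit$config$horizon,
                   discount_rate = fit$config$monetization$discount_rate,
                   qaly_value = fit$config$monetization$qaly_value,
                   elasticity_form = fit$config$elasticity$form)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
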