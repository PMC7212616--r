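#' Category proportions of a within-cell intake distribution
#'
#' Intake within an age-sex cell is modelled as gamma distributed with the
#' cell mean and a common shape parameter (non-negative, right-skewed).
#' Returns the probability mass falling into each risk-factor category
#' defined by the intake cut-points. An infinite shape (or zero dispersion)
#' collapses to a point mass at the mean; a zero mean puts all mass in the
#' first category.
#'
#' @param mean cell mean intake (g/day); may be a vector of cells.
#' @param shape gamma shape parameter (> 0), or `Inf` for a point mass.
#' @param boundaries strictly increasing intake cut-points (g/day).
#' @return matrix with one row per element of `mean` and one column per
#'   category (`length(boundaries) + 1`); rows sum to 1.
#' @examples
#' categorize_intake(100, 4, c(50, 100))
#' @export
categorize_intake <- function(mean, shape, boundaries) {
  if (is.unsorted(boundaries, strictly = TRUE))
    abort_validation("category boundaries must be strictly increasing")
  if (any(mean < 0)) abort_validation("intake mean must be non-negative")
  ncat <- length(boundaries) + 1L
  out <- matrix(0, length(mean), ncat)
  if (is.infinite(shape)) {
    idx <- findInterval(mean, boundaries, left.open = TRUE) + 1L
    out[cbind(seq_along(mean), idx)] <- 1
  } else {
    if (shape <= 0) abort_validation("gamma shape must be positive")
    pos <- mean > 0
    if (any(pos)) {
      cum <- vapply(boundaries, function(b)
        stats::pgamma(b, shape = shape, rate = shape / mean[pos]),
        numeric(sum(pos)))
      cum <- matrix(cum, nrow = sum(pos))
      out[pos, ] <- cbind(cum, 1) - cbind(0, cum)
    }
    out[!pos, 1] <- 1
  }
  out
}

#' Net annual flows between adjacent intake categories
#'
#' Estimates the minimal net flows between adjacent categories that carry a
#' category distribution at time t into the distribution at t+1 (a
#' simplified net-flow view of risk-factor transition rates). Flow `c` is
#' the net mass moving from category `c` to `c+1` (negative values flow
#' backwards); flows conserve total mass by construction.
#'
#' @param dist_t,dist_t1 category proportion vectors summing to 1.
#' @return numeric vector of length `length(dist_t) - 1` of net flows.
#' @examples
#' estimate_transitions(c(0.5, 0.5, 0), c(0.3, 0.6, 0.1)) # 0.2, 0.1
#' @export
estimate_transitions <- function(dist_t, dist_t1) {
  if (length(dist_t) != length(dist_t1))
    abort_validation("distributions must have the same number of categories")
  if (abs(sum(dist_t) - 1) > 1e-8 || abs(sum(dist_t1) - 1) > 1e-8)
    abort_validation("category distributions must sum to 1")
  flows <- cumsum(dist_t - dist_t1)
  flows[-length(flows)]
}

#' Incidence scaled by a shift in the risk-factor distribution
#'
#' Potential-impact-style scaling: the baseline incidence (observed under
#' the reference category distribution `p_ref`) is multiplied by the ratio
#' of RR-weighted category prevalences under the scenario versus the
#' reference, `sum(p_scen * rr) / sum(p_ref * rr)`. Equal distributions
#' leave the incidence unchanged.
#'
#' @param baseline baseline incidence rate (person-year^-1).
#' @param p_ref,p_scen category proportion vectors summing to 1.
#' @param rr relative risks per category (> 0), reference category 1.
#' @return scaled incidence, same shape as `baseline`.
#' @export
scaled_incidence <- function(baseline, p_ref, p_scen, rr) {
  if (any(rr <= 0)) abort_validation("relative risks must be positive")
  if (abs(sum(p_ref) - 1) > 1e-8 || abs(sum(p_scen) - 1) > 1e-8)
    abort_validation("category proportions must sum to 1")
  baseline * sum(p_scen * rr) / sum(p_ref * rr)
}

# per-cell, per-disease incidence scaling factors for a trajectory against
# the reference exposure means; cells ordered as inputs$pyramid
incidence_factors <- function(inputs, trajectory, config, rr_table) {
  pyr <- inputs$pyramid
  key <- paste(pyr$age, pyr$sex)
  cell_exposure <- function(cons) {
    meat <- rep(0, nrow(pyr))
    for (g in c("red_meat", "processed_meat")) {
      sub <- cons[cons$food_group == g, ]
      meat <- meat + sub$g_per_day[match(key, paste(sub$age, sub$sex))]
    }
    sub <- cons[cons$food_group == "fruit_vegetables", ]
    fv <- sub$g_per_day[match(key, paste(sub$age, sub$sex))]
    list(meat = meat, fruit_vegetables = fv)
  }
  ref <- cell_exposure(inputs$consumption)
  y1 <- trajectory$cells[trajectory$cells$year == trajectory$years[1], ]
  scen <- cell_exposure(y1)

  shape <- config$consumption$gamma_shape
  factors <- matrix(1, nrow(pyr), length(config$diseases),
                    dimnames = list(NULL, config$diseases))
  for (expo in c("meat", "fruit_vegetables")) {
    b <- config$categories[[expo]]
    p_ref <- categorize_intake(ref[[expo]], shape, b)
    p_scen <- categorize_intake(scen[[expo]], shape, b)
    for (d in config$diseases) {
      rr <- rr_table$rr[rr_table$exposure == expo & rr_table$disease == d]
      if (length(rr) != length(b) + 1L)
        abort_validation(sprintf("RR table lacks categories for %s / %s",
                                 expo, d))
      factors[, d] <- factors[, d] *
        as.numeric(p_scen %*% rr) / as.numeric(p_ref %*% rr)
    }
  }
  factors
}

#' Simulate population health over the horizon
#'
#' A dynamic multistate model in 1-year cycles on the age-sex grid. Each
#' cycle, susceptibles acquire each disease with probability
#' `1 - exp(-incidence * factor)` where the factor scales baseline incidence
#' for the scenario's risk-factor category distribution; prevalent cases die
#' at background plus disease-specific excess mortality (independent
#' diseases, additive rates converted per disease); survivors age by one
#' year, the open age-100 bucket retains its survivors, and newborns enter
#' at age 0 disease-free. Per-cell utility is 1 minus the sum of prevalent
#' disability weights (floored at 0); yearly QALYs are population times
#' utility.
#'
#' @param trajectory an `scba_trajectory` for the scenario (the module
#'   assumes intervention means are constant from the first policy year, as
#'   produced by [project_consumption()]).
#' @param inputs an `scba_inputs` bundle (reference consumption,
#'   epidemiology, demography).
#' @param config configuration; defaults to the bundle's.
#' @param rr_table relative risks to use (defaults to the bundle's; the
#'   Monte-Carlo wrapper passes sampled tables).
#' @return list of class `scba_health`: `years`, `population`, `qalys`,
#'   `deaths`, `newborns`, and year-by-disease matrices `cases` (prevalent),
#'   `cases_wa` (prevalent, working ages), `incident`, `incident_wa`.
#' @export
simulate_health <- function(trajectory, inputs, config = inputs$config,
                            rr_table = inputs$rr) {
  pyr <- inputs$pyramid
  ages <- sort(unique(pyr$age))
  sexes <- unique(pyr$sex)
  n_a <- length(ages)
  diseases <- config$diseases
  n_d <- length(diseases)
  H <- config$horizon
  years <- config$base_year + seq_len(H)

  key <- paste(pyr$age, pyr$sex)
  mu <- inputs$mortality$rate[match(key, paste(inputs$mortality$age,
                                               inputs$mortality$sex))]
  N <- pyr$count
  P <- matrix(0, nrow(pyr), n_d, dimnames = list(NULL, diseases))
  inc <- matrix(0, nrow(pyr), n_d, dimnames = list(NULL, diseases))
  em <- numeric(n_d)
  dw <- as.numeric(inputs$disability[diseases])
  for (j in seq_len(n_d)) {
    sub <- inputs$diseases[inputs$diseases$disease == diseases[j], ]
    m <- match(key, paste(sub$age, sub$sex))
    P[, j] <- sub$prevalence[m]
    inc[, j] <- sub$incidence[m]
    em[j] <- sub$excess_mortality[1]
  }
  if (any(inc < 0) || any(em < 0) || any(mu < 0))
    abort_validation("rates must be non-negative")

  f <- incidence_factors(inputs, trajectory, config, rr_table)
  wa <- pyr$age >= config$economics$working_age[1] &
    pyr$age <= config$economics$working_age[2]
  nb_sex <- stats::setNames(
    inputs$newborns * c(1 - config$population$sex_ratio_male,
                        config$population$sex_ratio_male),
    c("female", "male"))

  dims <- list(years, diseases)
  out <- list(years = years,
              population = numeric(H), qalys = numeric(H),
              deaths = numeric(H), newborns = inputs$newborns,
              cases = matrix(0, H, n_d, dimnames = dims),
              cases_wa = matrix(0, H, n_d, dimnames = dims),
              incident = matrix(0, H, n_d, dimnames = dims),
              incident_wa = matrix(0, H, n_d, dimnames = dims))
  s_d <- exp(-em)

  for (t in seq_len(H)) {
    util <- pmax(0, 1 - as.numeric(P %*% dw))
    out$population[t] <- sum(N)
    out$qalys[t] <- sum(N * util)
    NP <- N * P
    out$cases[t, ] <- colSums(NP)
    out$cases_wa[t, ] <- colSums(NP[wa, , drop = FALSE])

    ## disease acquisition
    q_inc <- 1 - exp(-inc * f)
    new_cases <- (1 - P) * q_inc
    out$incident[t, ] <- colSums(N * new_cases)
    out$incident_wa[t, ] <- colSums((N * new_cases)[wa, , drop = FALSE])
    P1 <- P + new_cases

    ## mortality: background for all, excess among prevalent cases
    smult <- 1 - sweep(P1, 2, 1 - s_d, `*`)   # survival factor per disease
    S <- exp(-mu) * exp(rowSums(log(smult)))
    P2 <- sweep(P1, 2, s_d, `*`) / smult
    N1 <- N * S
    out$deaths[t] <- sum(N) - sum(N1)

    ## ageing and newborn inflow
    N_next <- N
    P_next <- P
    for (s in sexes) {
      i <- which(pyr$sex == s)          # ordered by age within sex
      top <- i[n_a]; pen <- i[n_a - 1L]
      denom <- N1[pen] + N1[top]
      P_next[i[-1L], ] <- P2[i[-n_a], , drop = FALSE]
      if (denom > 0)
        P_next[top, ] <- (N1[pen] * P2[pen, ] + N1[top] * P2[top, ]) / denom
      N_next[i[-1L]] <- N1[i[-n_a]]
      N_next[top] <- N1[pen] + N1[top]
      N_next[i[1L]] <- nb_sex[[s]]
      P_next[i[1L], ] <- 0
    }
    N <- N_next
    P <- P_next
  }
  structure(out, class = "scba_health")
}

#' Difference between a scenario and the reference health state
#'
#' @param scenario_state,reference_state `scba_health` objects on the same
#'   grid and horizon.
#' @return list of class `scba_health_delta`: `by_disease` data.frame
#'   (year, disease, averted_cases, averted_cases_wa, incident_diff) where
#'   averted counts are reference minus scenario prevalent cases, and
#'   `qaly` data.frame (year, qaly_gain) as scenario minus reference.
#' @export
health_delta <- function(scenario_state, reference_state) {
  if (!identical(scenario_state$years, reference_state$years) ||
      !identical(dimnames(scenario_state$cases),
                 dimnames(reference_state$cases)))
    abort_validation("health states are on different grids")
  cases_diff <- reference_state$cases - scenario_state$cases
  wa_diff <- reference_state$cases_wa - scenario_state$cases_wa
  inc_diff <- scenario_state$incident - reference_state$incident
  by_disease <- data.frame(
    year = rep(scenario_state$years, ncol(cases_diff)),
    disease = rep(colnames(cases_diff), each = length(scenario_state$years)),
    averted_cases = as.numeric(cases_diff),
    averted_cases_wa = as.numeric(wa_diff),
    incident_diff = as.numeric(inc_diff))
  qaly <- data.frame(year = scenario_state$years,
                     qaly_gain = scenario_state$qalys - reference_state$qalys)
  structure(list(by_disease = by_disease, qaly = qaly),
            class = "scba_health_delta")
}

# one normal draw of the RR table: sd = CI width / 3.92, truncated > 0
sample_rr_table <- function(rr_table) {
  sd <- (rr_table$ci_high - rr_table$ci_low) / 3.92
  rr_table$rr <- pmax(stats::rnorm(nrow(rr_table), rr_table$rr, sd), 1e-6)
  rr_table
}

#' Monte-Carlo uncertainty over relative risks
#'
#' Re-runs the scenario simulation `n_iter` times with every relative risk
#' drawn from a normal distribution centred on its mean with standard
#' deviation (CI width)/3.92, truncated at a small positive value, and
#' reports 2.5th/97.5th percentile bounds for yearly averted cases and QALY
#' gains. The reference simulation does not depend on the relative risks
#' (its scaling factor is identically 1), so it is run once.
#'
#' @param inputs an `scba_inputs` bundle.
#' @param trajectory_scen,trajectory_ref scenario and reference
#'   trajectories from [project_consumption()].
#' @param config configuration.
#' @param n_iter number of iterations (>= 2).
#' @param seed RNG seed; identical seeds give identical results.
#' @return list of class `scba_health_mc`: `point` (`scba_health_delta` at
#'   the RR means), `ci_cases` / `ci_cases_wa` (data.frames year, disease,
#'   lo, hi), `ci_qaly` (year, lo, hi), and `draws` with per-iteration
#'   `averted` / `averted_wa` (year x disease x iter arrays) and `qaly_gain`
#'   (year x iter) used downstream for ledger bounds.
#' @export
monte_carlo_health <- function(inputs, trajectory_scen, trajectory_ref,
                               config = inputs$config, n_iter = 100L,
                               seed = 1L) {
  if (n_iter < 2) abort_validation("n_iter must be at least 2")
  ref_state <- simulate_health(trajectory_ref, inputs, config)
  point <- health_delta(simulate_health(trajectory_scen, inputs, config),
                        ref_state)
  H <- length(ref_state$years)
  diseases <- colnames(ref_state$cases)
  averted <- array(0, c(H, length(diseases), n_iter),
                   dimnames = list(ref_state$years, diseases, NULL))
  averted_wa <- averted
  qaly_gain <- matrix(0, H, n_iter, dimnames = list(ref_state$years, NULL))
  set.seed(seed)
  for (k in seq_len(n_iter)) {
    rr_k <- sample_rr_table(inputs$rr)
    st <- simulate_health(trajectory_scen, inputs, config, rr_table = rr_k)
    averted[, , k] <- ref_state$cases - st$cases
    averted_wa[, , k] <- ref_state$cases_wa - st$cases_wa
    qaly_gain[, k] <- st$qalys - ref_state$qalys
  }
  qt <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE)
  ci_arr <- function(a) {
    lo <- apply(a, c(1, 2), function(x) qt(x)[1])
    hi <- apply(a, c(1, 2), function(x) qt(x)[2])
    data.frame(year = rep(ref_state$years, length(diseases)),
               disease = rep(diseases, each = H),
               lo = as.numeric(lo), hi = as.numeric(hi))
  }
  ci_q <- t(apply(qaly_gain, 1, qt))
  structure(list(point = point,
                 ci_cases = ci_arr(averted),
                 ci_cases_wa = ci_arr(averted_wa),
                 ci_qaly = data.frame(year = ref_state$years,
                                      lo = ci_q[, 1], hi = ci_q[, 2]),
                 draws = list(averted = averted, averted_wa = averted_wa,
                              qaly_gain = qaly_gain),
                 n_iter = n_iter, seed = seed),
            class = "scba_health_mc")
}
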