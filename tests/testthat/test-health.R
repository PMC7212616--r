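test_that("categorize_intake integrates the gamma density over categories", {
  b <- c(50, 100)
  p <- categorize_intake(100, 4, b)
  expect_equal(rowSums(p), 1)
  # independent quadrature oracle on the gamma density
  oracle <- c(
    stats::integrate(stats::dgamma, 0, 50, shape = 4, rate = 4 / 100)$value,
    stats::integrate(stats::dgamma, 50, 100, shape = 4, rate = 4 / 100)$value,
    stats::integrate(stats::dgamma, 100, Inf, shape = 4, rate = 4 / 100)$value)
  expect_equal(as.numeric(p), oracle, tolerance = 1e-6)

  # point mass at the mean when dispersion vanishes
  expect_equal(as.numeric(categorize_intake(75, Inf, b)), c(0, 1, 0))
  # all mass below the first boundary
  expect_equal(as.numeric(categorize_intake(0, 4, b)), c(1, 0, 0))
  expect_error(categorize_intake(10, 4, c(100, 50)),
               class = "foodscba_validation_error")
})

test_that("estimate_transitions yields mass-conserving adjacent net flows", {
  expect_equal(estimate_transitions(c(0.5, 0.5, 0), c(0.5, 0.5, 0)), c(0, 0))
  expect_equal(estimate_transitions(c(0.5, 0.5, 0), c(0.3, 0.6, 0.1)),
               c(0.2, 0.1))
  set.seed(42)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    p0 <- as.numeric(stats::rmultinom(1, 100, rep(1, k))) / 100
    p1 <- as.numeric(stats::rmultinom(1, 100, rep(1, k))) / 100
    f <- estimate_transitions(p0, p1)
    # inflow minus outflow reproduces each cell's change
    net <- c(f, 0) - c(0, f)
    expect_equal(p0 - p1, net, tolerance = 1e-12)
  }
  expect_error(estimate_transitions(c(0.5, 0.4), c(0.5, 0.5)),
               class = "foodscba_validation_error")
})

test_that("scaled_incidence applies the RR-weighted prevalence ratio", {
  expect_equal(scaled_incidence(0.01, c(0.5, 0.5), c(1, 0), c(1, 1)), 0.01)
  expect_equal(scaled_incidence(0.3, c(0.5, 0.5), c(1, 0), c(1, 2)),
               0.3 / 1.5)
  p <- c(0.2, 0.5, 0.3)
  expect_equal(scaled_incidence(0.07, p, p, c(1, 1.3, 1.9)), 0.07)
  expect_error(scaled_incidence(0.01, c(0.5, 0.5), c(1, 0), c(1, -2)),
               class = "foodscba_validation_error")
})

test_that("a disease-free population accrues QALYs equal to person-years", {
  inp <- make_toy_inputs(diseases = list(
    d1 = list(inc = 0, prev = 0, em = 0.1, dw = 0.2,
              rr_meat = c(1, 1.3, 1.6), rr_fv = c(1, 1, 1))))
  st <- simulate_health(project_consumption(inp, "reference"), inp)
  expect_equal(st$qalys, st$population)
  expect_true(all(st$cases == 0))
})

test_that("population is conserved each cycle and bounds are respected", {
  inp <- make_toy_inputs(ages = 0:10, newborns = 120, mortality_rate = 0.02,
                         horizon = 8L)
  st <- simulate_health(project_consumption(inp, "reference"), inp)
  for (t in seq_len(7))
    expect_equal(st$population[t + 1],
                 st$population[t] - st$deaths[t] + inp$newborns)
  expect_true(all(st$qalys <= st$population + 1e-9))
  expect_true(all(st$cases >= 0))
  # prevalent cases can never exceed the living population
  expect_true(all(st$cases <= st$population))
})

test_that("zero mortality and zero newborns leave the population constant", {
  inp <- make_toy_inputs(ages = 0:5, newborns = 0, mortality_rate = 0,
                         horizon = 6L,
                         diseases = list(
                           d1 = list(inc = 0.02, prev = 0.05, em = 0,
                                     dw = 0.2, rr_meat = c(1, 1.3, 1.6),
                                     rr_fv = c(1, 1, 1))))
  st <- simulate_health(project_consumption(inp, "reference"), inp)
  expect_equal(st$population, rep(st$population[1], 6))
})

test_that("the cohort dynamics match a hand-rolled iteration", {
  # one disease, ages 0-2, one-sex-equivalent (both sexes identical),
  # no newborns; follow the documented update rules step by step
  inc <- 0.02; prev0 <- 0.05; em <- 0.1; mu <- 0.01; n0 <- 1000
  inp <- make_toy_inputs(ages = 0:2, newborns = 0, mortality_rate = mu,
                         horizon = 4L, counts = n0,
                         diseases = list(
                           d1 = list(inc = inc, prev = prev0, em = em,
                                     dw = 0.2, rr_meat = c(1, 1.3, 1.6),
                                     rr_fv = c(1, 1, 1))))
  st <- simulate_health(project_consumption(inp, "reference"), inp)

  # oracle: explicit small-vector iteration over one sex (x2 at the end)
  N <- rep(n0, 3); P <- rep(prev0, 3)
  pop <- cases <- qaly <- numeric(4)
  for (t in 1:4) {
    pop[t] <- 2 * sum(N); cases[t] <- 2 * sum(N * P)
    qaly[t] <- 2 * sum(N * (1 - 0.2 * P))
    q <- 1 - exp(-inc)                       # reference: scaling factor 1
    P1 <- P + (1 - P) * q
    sm <- 1 - P1 * (1 - exp(-em))
    S <- exp(-mu) * sm
    P2 <- P1 * exp(-em) / sm
    N1 <- N * S
    N <- c(0, N1[1], N1[2] + N1[3])
    P <- c(0, P2[1],
           if (N[3] > 0) (N1[2] * P2[2] + N1[3] * P2[3]) / N[3] else 0)
  }
  expect_equal(st$population, pop)
  expect_equal(as.numeric(st$cases), cases)
  expect_equal(st$qalys, qaly)
})

test_that("simulation is deterministic and all-RR-1 gives a zero delta", {
  inp <- make_toy_inputs(ages = 0:10, horizon = 6L, meat_mean = 105,
                         diseases = list(
                           d1 = list(inc = 0.02, prev = 0.05, em = 0.1,
                                     dw = 0.2, rr_meat = c(1, 1, 1),
                                     rr_fv = c(1, 1, 1))))
  ref <- project_consumption(inp, "reference")
  tax <- project_consumption(inp, "meat15")
  st1 <- simulate_health(tax, inp)
  st2 <- simulate_health(tax, inp)
  expect_identical(st1, st2)
  d <- health_delta(st1, simulate_health(ref, inp))
  expect_true(all(abs(d$by_disease$averted_cases) < 1e-9))
  expect_true(all(abs(d$qaly$qaly_gain) < 1e-9))
})

test_that("a tax averts cases of an RR>1 disease in every later year", {
  inp <- make_toy_inputs(ages = 30:60, meat_mean = 95, horizon = 10L,
                         diseases = list(
                           d1 = list(inc = 0.03, prev = 0.08, em = 0.15,
                                     dw = 0.2, rr_meat = c(1, 1.6, 2.6),
                                     rr_fv = c(1, 1, 1))))
  d <- health_delta(
    simulate_health(project_consumption(inp, "meat15"), inp),
    simulate_health(project_consumption(inp, "reference"), inp))
  averted <- d$by_disease$averted_cases
  expect_true(all(averted[-1] > 0))
  expect_true(all(d$qaly$qaly_gain[-1] > 0))
})

test_that("an unrelated disease gains cases when survivors live longer", {
  # strong aversion of a lethal disease frees survivors who then acquire the
  # RR=1 disease: its absolute caseload must rise under the tax
  inp <- make_toy_inputs(ages = 40:70, meat_mean = 95, horizon = 15L,
                         mortality_rate = 0.01,
                         diseases = list(
                           lethal = list(inc = 0.05, prev = 0.10, em = 0.5,
                                         dw = 0.3, rr_meat = c(1, 2, 4),
                                         rr_fv = c(1, 1, 1)),
                           compens = list(inc = 0.03, prev = 0.05, em = 0.02,
                                          dw = 0.1, rr_meat = c(1, 1, 1),
                                          rr_fv = c(1, 1, 1))))
  d <- health_delta(
    simulate_health(project_consumption(inp, "meat15"), inp),
    simulate_health(project_consumption(inp, "reference"), inp))
  bd <- d$by_disease
  last <- max(bd$year)
  expect_gt(bd$averted_cases[bd$disease == "lethal" & bd$year == last], 0)
  # negative averted = more cases in the scenario
  expect_lt(bd$averted_cases[bd$disease == "compens" & bd$year == last], 0)
  expect_gt(bd$incident_diff[bd$disease == "compens" & bd$year == last], 0)
})

test_that("Monte-Carlo runs are seed-reproducible with sane intervals", {
  inp <- make_toy_inputs(ages = 30:50, meat_mean = 95, horizon = 5L)
  ref <- project_consumption(inp, "reference")
  tax <- project_consumption(inp, "meat15")
  mc1 <- monte_carlo_health(inp, tax, ref, n_iter = 20, seed = 5)
  mc2 <- monte_carlo_health(inp, tax, ref, n_iter = 20, seed = 5)
  expect_identical(mc1, mc2)
  expect_true(all(mc1$ci_cases$lo <= mc1$ci_cases$hi))
  expect_error(monte_carlo_health(inp, tax, ref, n_iter = 1),
               class = "foodscba_validation_error")

  # zero-width CIs degenerate to the point run
  inp0 <- inp
  inp0$rr$ci_low <- inp0$rr$ci_high <- inp0$rr$rr
  mc0 <- monte_carlo_health(inp0, tax, ref, n_iter = 5, seed = 1)
  last <- max(mc0$point$qaly$year)
  expect_equal(mc0$ci_qaly$lo, mc0$point$qaly$qaly_gain, tolerance = 1e-9)
  expect_equal(mc0$ci_qaly$hi, mc0$point$qaly$qaly_gain, tolerance = 1e-9)
})

test_that("the 95% interval almost always covers the point estimate", {
  inp <- make_toy_inputs(ages = 30:50, meat_mean = 95, horizon = 5L)
  ref <- project_consumption(inp, "reference")
  tax <- project_consumption(inp, "meat15")
  covered <- vapply(1:12, function(s) {
    mc <- monte_carlo_health(inp, tax, ref, n_iter = 30, seed = s)
    last <- max(mc$point$qaly$year)
    pt <- mc$point$by_disease$averted_cases[mc$point$by_disease$year == last]
    ci <- mc$ci_cases[mc$ci_cases$year == last, ]
    ci$lo <= pt && pt <= ci$hi
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})
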