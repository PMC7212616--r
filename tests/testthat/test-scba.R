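test_that("discounting matches the closed form and is additive", {
  expect_equal(discount_value(100, 0, 0.03), 100)
  expect_equal(discount_value(100, 10, 0.03), 74.41, tolerance = 1e-4)
  expect_equal(discount_value(123, 17, 0), 123)
  a <- discount_value(40, 7, 0.03) + discount_value(60, 7, 0.03)
  expect_equal(discount_value(100, 7, 0.03), a)
  expect_error(discount_value(1, -1, 0.03),
               class = "foodscba_validation_error")
})

test_that("the reference-vs-reference ledger is identically zero", {
  fit <- scba("reference", seed = 1, n_iter = 0)
  expect_true(all(abs(fit$ledger$value_meur) < 1e-9))
  expect_equal(attr(fit$ledger, "total"), 0)
})

test_that("ledger accounting identities hold to machine precision", {
  fit <- scba("meat15", seed = 1, n_iter = 5)
  led <- fit$ledger
  expect_equal(sum(led$value_meur), attr(led, "total"))
  expect_equal(sum(attr(led, "by_stakeholder")), attr(led, "total"))
  sums <- tapply(led$value_meur, led$stakeholder, sum)
  expect_equal(unname(sums[names(attr(led, "by_stakeholder"))]),
               unname(attr(led, "by_stakeholder")))
  # Monte-Carlo bounds only on RR-dependent rows
  rr_rows <- led$effect %in% c("healthcare_costs", "health_qaly",
                               "productivity")
  expect_true(all(led$lo_meur[!rr_rows] == led$value_meur[!rr_rows]))
  expect_true(all(led$lo_meur <= led$hi_meur))
})

test_that("tax scenarios split stakeholders as payers and gainers", {
  fit <- scba("meat15", seed = 1, n_iter = 0)
  st <- attr(fit$ledger, "by_stakeholder")
  expect_lt(st[["consumers"]], 0)
  expect_gt(st[["government"]], 0)
  sub <- scba("fv10", seed = 1, n_iter = 0)
  st2 <- attr(sub$ledger, "by_stakeholder")
  expect_gt(st2[["consumers"]], 0)
  expect_lt(st2[["government"]], 0)
  # net welfare gain for society under the default synthetic calibration
  expect_gt(attr(fit$ledger, "total"), 0)
  expect_gt(attr(sub$ledger, "total"), 0)
})

test_that("a meat tax averts most diabetes cases in the final year", {
  fit <- scba("meat15", seed = 1, n_iter = 0)
  bd <- fit$health$by_disease
  last <- bd[bd$year == max(bd$year), ]
  expect_equal(last$disease[which.max(last$averted_cases)], "diabetes_type2")
  # compensatory CHD increase, as the engine must permit
  expect_lt(last$averted_cases[last$disease == "chd"], 0)
})

test_that("runs are reproducible for a fixed seed", {
  f1 <- scba("meat15", seed = 3, n_iter = 4)
  f2 <- scba("meat15", seed = 3, n_iter = 4)
  expect_identical(as.data.frame(f1$ledger), as.data.frame(f2$ledger))
  expect_identical(attr(f1$ledger, "total_ci"), attr(f2$ledger, "total_ci"))
})

test_that("one-way sensitivity at the base setting is a bit-exact no-op", {
  base <- scba("meat15", seed = 2, n_iter = 3)
  sens <- run_sensitivity("meat15",
                          variants = list(list(axis = "base",
                                               setting = "base")),
                          seed = 2, n_iter = 3)
  expect_identical(as.data.frame(sens$runs[[1]]$ledger),
                   as.data.frame(base$ledger))
})

test_that("sensitivity axes move the ledger in the documented directions", {
  cfg <- scba_config()
  base <- scba("meat15", cfg, seed = 1, n_iter = 0)
  env_row <- function(f)
    f$ledger$value_meur[f$ledger$effect == "environment"]

  hi <- scba("meat15", variant_config(cfg, "elasticity_bound", "high"),
             seed = 1, n_iter = 0)
  lo <- scba("meat15", variant_config(cfg, "elasticity_bound", "low"),
             seed = 1, n_iter = 0)
  expect_gt(env_row(hi), env_row(base))
  expect_lt(env_row(lo), env_row(base))

  perfect <- scba("meat15",
                  variant_config(cfg, "information_assumption", "perfect"),
                  seed = 1, n_iter = 0)
  expect_false("health_qaly" %in% perfect$ledger$effect)
  expect_lt(attr(perfect$ledger, "total"), attr(base$ledger, "total"))

  friction <- scba("meat15",
                   variant_config(cfg, "productivity_method", "friction"),
                   seed = 1, n_iter = 0)
  prod <- function(f)
    sum(f$ledger$value_meur[f$ledger$effect == "productivity"])
  expect_lt(prod(friction), prod(base))

  # a lower discount rate never shrinks the PV magnitude of a
  # single-signed stream
  low_r <- scba("meat15", variant_config(cfg, "discount_rate", 0.015),
                seed = 1, n_iter = 0)
  m <- match(paste(base$ledger$effect, base$ledger$stakeholder),
             paste(low_r$ledger$effect, low_r$ledger$stakeholder))
  expect_true(all(abs(low_r$ledger$value_meur[m]) >=
                    abs(base$ledger$value_meur) - 1e-9))

  hecleg <- scba("meat15",
                 variant_config(cfg, "environment_scenario", "HEC-LEG"),
                 seed = 1, n_iter = 0)
  lecheg <- scba("meat15",
                 variant_config(cfg, "environment_scenario", "LEC-HEG"),
                 seed = 1, n_iter = 0)
  expect_gt(env_row(hecleg), env_row(base))
  expect_lt(env_row(lecheg), env_row(base))
  expect_error(variant_config(cfg, "nonsense", 1),
               class = "foodscba_validation_error")
})

test_that("pipeline outputs are written and the manifest is faithful", {
  fit <- scba("meat15", seed = 1, n_iter = 3)
  dir <- withr::local_tempdir()
  write_scba_outputs(fit, dir)
  expect_true(all(file.exists(file.path(dir,
    c("trajectory.csv", "impact.csv", "health_delta.csv", "cashflows.csv",
      "ledger.csv", "ledger_by_stakeholder.csv", "manifest.json")))))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$scenario, "meat15")
  expect_equal(man$seed, 1)
  led <- utils::read.csv(file.path(dir, "ledger.csv"))
  expect_equal(sum(led$value_meur), attr(fit$ledger, "total"),
               tolerance = 1e-9)
})

test_that("print, summary and plot methods run quietly", {
  fit <- scba("meat15", seed = 1, n_iter = 3)
  expect_output(print(fit), "meat15")
  expect_output(print(summary(fit)), "Averted prevalent cases")
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(fit))
})
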