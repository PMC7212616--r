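#' @export
print.scba <- function(x, ...) {
  cat(sprintf("Social cost-benefit analysis: scenario '%s'\n", x$scenario))
  cat(sprintf("  horizon %d years (%d-%d), base year %d, discount %.1f%%\n",
              x$config$horizon, x$reference$years[1],
              max(x$reference$years), x$config$base_year,
              100 * x$config$monetization$discount_rate))
  if (!is.null(x$mc))
    cat(sprintf("  Monte-Carlo iterations over relative risks: %d\n",
                x$mc$n_iter))
  cat("\n")
  print(x$ledger)
  invisible(x)
}

#' @export
print.scba_ledger <- function(x, ...) {
  df <- as.data.frame(x)
  df$value_meur <- round(df$value_meur)
  if (!is.null(df$lo_meur)) {
    df$range <- ifelse(df$lo_meur == df$hi_meur, "",
                       sprintf("[%d, %d]", round(df$lo_meur),
                               round(df$hi_meur)))
    df$lo_meur <- df$hi_meur <- NULL
  }
  cat(sprintf("Discounted welfare ledger (million EUR, base year %d)\n",
              attr(x, "base_year")))
  print(df, row.names = FALSE)
  st <- attr(x, "by_stakeholder")
  cat(sprintf("\nTotals: societal %d", round(attr(x, "total"))))
  ci <- attr(x, "total_ci")
  if (!is.null(ci)) cat(sprintf(" [%d, %d]", round(ci[1]), round(ci[2])))
  cat(sprintf(" | consumers %d | government %d\n",
              round(st[["consumers"]]), round(st[["government"]])))
  invisible(x)
}

#' Summary of an SCBA run
#'
#' Reports the endpoint consumption means, the 2048-style relative
#' environmental change, the final-year health deltas with Monte-Carlo
#' bounds, and the discounted ledger with stakeholder totals.
#'
#' @param object an `scba` object.
#' @param ... unused.
#' @export
summary.scba <- function(object, ...) {
  yrs <- object$reference$years
  last <- max(yrs)
  meat_groups <- c("red_meat", "processed_meat", "poultry")
  endpoint <- c(
    meat_ref = mean_intake(object$reference, last, meat_groups),
    meat_scen = mean_intake(object$trajectory, last, meat_groups),
    fv_ref = mean_intake(object$reference, last, "fruit_vegetables"),
    fv_scen = mean_intake(object$trajectory, last, "fruit_vegetables"))
  priced <- names(scenario_spec(object$scenario)$price_change)
  env_change <- if (length(priced)) {
    imp_s <- impact_trajectory(object$trajectory, object$inputs,
                               object$config, groups = priced)
    imp_r <- impact_trajectory(object$reference, object$inputs,
                               object$config, groups = priced)
    relative_impact_change(imp_s, imp_r, last)
  } else {
    relative_impact_change(object$impact$scenario,
                           object$impact$reference, last)
  }
  bd <- object$health$by_disease
  final <- bd[bd$year == last, c("disease", "averted_cases")]
  if (!is.null(object$mc)) {
    ci <- object$mc$ci_cases
    ci <- ci[ci$year == last, ]
    final$ci_low <- ci$lo[match(final$disease, ci$disease)]
    final$ci_high <- ci$hi[match(final$disease, ci$disease)]
  }
  qg <- object$health$qaly
  out <- list(scenario = object$scenario, endpoint_year = last,
              endpoint_intake = endpoint, env_change = env_change,
              final_averted = final,
              qaly_final = qg$qaly_gain[qg$year == last],
              ledger = object$ledger)
  class(out) <- "summary.scba"
  out
}

#' @export
print.summary.scba <- function(x, ...) {
  cat(sprintf("SCBA scenario '%s', endpoint year %d\n\n", x$scenario,
              x$endpoint_year))
  e <- x$endpoint_intake
  cat(sprintf("Mean intake (g/day): meat %.1f -> %.1f; F&V %.1f -> %.1f\n",
              e[["meat_ref"]], e[["meat_scen"]], e[["fv_ref"]],
              e[["fv_scen"]]))
  cat(sprintf("Environmental change vs reference (all indicators): %+.2f%%\n",
              100 * mean(x$env_change)))
  cat(sprintf("QALYs gained in %d: %.0f\n", x$endpoint_year, x$qaly_final))
  cat(sprintf("Averted prevalent cases in %d:\n", x$endpoint_year))
  fa <- x$final_averted
  fa$averted_cases <- round(fa$averted_cases)
  if (!is.null(fa$ci_low)) {
    fa$ci_low <- round(fa$ci_low); fa$ci_high <- round(fa$ci_high)
  }
  print(fa, row.names = FALSE)
  cat("\n")
  print(x$ledger)
  invisible(x)
}

#' Plot an SCBA run
#'
#' Three base-graphics panels: the population-mean intake trajectory of the
#' priced exposure versus reference, averted prevalent cases per disease
#' over time, and the discounted ledger as a horizontal bar chart.
#'
#' @param x an `scba` object.
#' @param which subset of panels (1:3).
#' @param ... passed to [graphics::barplot()] for panel 3.
#' @export
plot.scba <- function(x, which = 1:3, ...) {
  old <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(old))
  graphics::par(mfrow = c(1, length(which)), mar = c(4, 8, 3, 1))
  yrs <- x$reference$years
  groups <- if (x$scenario == "fv10") "fruit_vegetables"
            else c("red_meat", "processed_meat", "poultry")
  if (1 %in% which) {
    ref <- vapply(yrs, mean_intake, numeric(1), trajectory = x$reference,
                  groups = groups)
    scen <- vapply(yrs, mean_intake, numeric(1), trajectory = x$trajectory,
                   groups = groups)
    graphics::par(mar = c(4, 4, 3, 1))
    graphics::plot(yrs, ref, type = "l", lty = 2, ylim = range(ref, scen),
                   xlab = "year", ylab = "mean intake (g/day)",
                   main = "Consumption")
    graphics::lines(yrs, scen, col = 2)
    graphics::legend("right", c("reference", x$scenario), lty = c(2, 1),
                     col = c(1, 2), bty = "n")
  }
  if (2 %in% which) {
    bd <- x$health$by_disease
    dz <- unique(bd$disease)
    m <- sapply(dz, function(d) bd$averted_cases[bd$disease == d])
    graphics::par(mar = c(4, 4, 3, 1))
    graphics::matplot(yrs, m, type = "l", lty = 1, col = seq_along(dz),
                      xlab = "year", ylab = "averted prevalent cases",
                      main = "Health")
    graphics::abline(h = 0, col = "grey")
    graphics::legend("topleft", dz, lty = 1, col = seq_along(dz), bty = "n",
                     cex = 0.7)
  }
  if (3 %in% which) {
    led <- as.data.frame(x$ledger)
    lab <- paste(led$effect, substr(led$stakeholder, 1, 3), sep = ".")
    graphics::par(mar = c(4, 9, 3, 1))
    graphics::barplot(led$value_meur, names.arg = lab, horiz = TRUE,
                      las = 1, xlab = "million EUR (discounted)",
                      main = "Ledger", ...)
  }
  invisible(x)
}

#' @export
print.scba_sensitivity <- function(x, ...) {
  cat("One-way sensitivity analysis\n")
  s <- x$summary
  s$total_meur <- round(s$total_meur)
  s$consumers_meur <- round(s$consumers_meur)
  s$government_meur <- round(s$government_meur)
  print(s, row.names = FALSE)
  invisible(x)
}
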