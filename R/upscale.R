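# Ecosystem-scale CH4 projection: per-lake production from occurrence
# probability, habitat fraction, and incubation rates; profile scaling;
# CO2-equivalent conversion; ensemble Monte Carlo uncertainty.

#' Parameters of the lake-scale CH4 projection
#'
#' @param habitat_fraction maximum fraction of lake area coverable by
#'   emergent macrophytes (littoral habitat regression for Boreal lakes in
#'   the 0.1-1000 km^2 size range)
#' @param rate_mean mean CH4 production rate over a 150-day growing season
#'   (mg m^-2), default the macrophyte-amended sediment mean
#' @param rate_se standard error of the rate, used for Monte Carlo draws
#'   (Normal truncated at 0)
#' @param surficial_fraction fraction of whole-profile production captured
#'   by the incubated 5 cm surficial sediment; totals are divided by this
#' @param gwp_co2eq kg CO2 with the same warming effect as 1 kg CH4
#' @param colonization_mode how to count colonized lakes: `"expected"` (sum
#'   of occurrence probabilities) or `"threshold"` (count of lakes with
#'   probability above `threshold`)
#' @param threshold occurrence probability cutoff for `"threshold"` mode
#' @return an object of class `upscale_params`
#' @export
upscale_params <- function(habitat_fraction = 0.28, rate_mean = 7220,
                           rate_se = 900, surficial_fraction = 0.70,
                           gwp_co2eq = 25,
                           colonization_mode = c("expected", "threshold"),
                           threshold = 0.5) {
  colonization_mode <- match.arg(colonization_mode)
  if (habitat_fraction <= 0 || habitat_fraction > 1 ||
      surficial_fraction <= 0 || surficial_fraction > 1)
    stop("fractions must lie in (0, 1]")
  if (gwp_co2eq <= 0) stop("gwp_co2eq must be positive")
  if (rate_mean < 0 || rate_se < 0) stop("rate parameters must be nonnegative")
  structure(list(habitat_fraction = habitat_fraction, rate_mean = rate_mean,
                 rate_se = rate_se, surficial_fraction = surficial_fraction,
                 gwp_co2eq = gwp_co2eq, colonization_mode = colonization_mode,
                 threshold = threshold),
            class = "upscale_params")
}

#' Seasonal CH4 production of one or more lakes
#'
#' Coverage is the occurrence probability times the maximum emergent-
#' macrophyte habitat (`habitat_fraction` of lake area); production is the
#' per-area rate applied to that coverage, scaled to the whole sediment
#' profile by dividing by `surficial_fraction`.
#'
#' @param area_km2 lake surface area(s), km^2
#' @param p_occ occurrence probability in \[0, 1\] (vectorized)
#' @param params an [upscale_params()]
#' @param rate override the rate (mg m^-2); defaults to `params$rate_mean`
#' @return CH4 production in kg per growing season (vector)
#' @export
lake_production <- function(area_km2, p_occ, params = upscale_params(),
                            rate = params$rate_mean) {
  if (any(p_occ < 0 | p_occ > 1)) stop("p_occ must lie in [0, 1]")
  if (any(area_km2 < 0)) stop("areas must be nonnegative")
  coverage_m2 <- p_occ * params$habitat_fraction * area_km2 * 1e6
  rate * coverage_m2 * 1e-6 / params$surficial_fraction  # mg -> kg
}

#' Convert CH4 mass to CO2 equivalents
#'
#' @param ch4_kg CH4 mass (kg)
#' @param gwp global warming potential (kg CO2 per kg CH4)
#' @return CO2-equivalent mass (kg)
#' @export
to_co2eq <- function(ch4_kg, gwp = 25) {
  if (gwp <= 0) stop("gwp must be positive")
  ch4_kg * gwp
}

.colonized_count <- function(p, params) {
  switch(params$colonization_mode,
         expected = sum(p),
         threshold = sum(p > params$threshold))
}

#' Ensemble change in lake CH4 production, current vs future
#'
#' Monte Carlo propagation of rate uncertainty and climate-ensemble spread:
#' each draw samples a production rate from Normal(`rate_mean`, `rate_se`)
#' truncated at zero and one future scenario column uniformly, computes
#' current and future totals with [lake_production()], and records the
#' percent change. Because the same rate multiplies every lake, the percent
#' change of each draw depends only on the occurrence probabilities (the
#' rate cancels). A deterministic per-scenario table at the mean rate is
#' also returned, with its minimum percent change across the ensemble.
#'
#' @param lakes data.frame from [gen_lakes()] (columns `lake_id`,
#'   `area_km2`, `p_current` and scenario columns; scenario column names are
#'   taken from the `scenario_cols` attribute or every column starting with
#'   `p_` other than `p_current`)
#' @param params an [upscale_params()]
#' @param n_mc Monte Carlo draws
#' @param seed integer seed
#' @return an object of class `upscale_result`: `draws` (per draw: rate,
#'   scenario, current/future kg CH4, pct change), `summary` (median and
#'   2.5/97.5 per cent quantiles of totals, CO2 equivalents and pct change),
#'   `by_scenario` (deterministic totals and pct change per scenario at the
#'   mean rate, plus colonized-lake counts), `min_pct_change`,
#'   `colonized_current`, `pct_change_defined`
#' @export
ensemble_change <- function(lakes, params = upscale_params(), n_mc = 1000,
                            seed = 1L) {
  need <- c("area_km2", "p_current")
  if (!all(need %in% names(lakes))) stop("lakes table needs area_km2, p_current")
  scen <- attr(lakes, "scenario_cols")
  if (is.null(scen))
    scen <- setdiff(grep("^p_", names(lakes), value = TRUE), "p_current")
  if (length(scen) < 1) stop("need at least one future scenario column")

  area <- lakes$area_km2
  # totals are linear in rate: precompute unit totals (kg per (mg m^-2))
  unit_cur <- sum(lake_production(area, lakes$p_current, params, rate = 1))
  unit_fut <- vapply(scen, function(s)
    sum(lake_production(area, lakes[[s]], params, rate = 1)), numeric(1))

  if (!is.null(seed)) set.seed(seed)
  rate <- stats::rnorm(n_mc, params$rate_mean, params$rate_se)
  while (any(rate < 0))  # truncate at zero by redrawing
    rate[rate < 0] <- stats::rnorm(sum(rate < 0), params$rate_mean,
                                   params$rate_se)
  which_scen <- sample.int(length(scen), n_mc, replace = TRUE)

  cur_kg <- rate * unit_cur
  fut_kg <- rate * unit_fut[which_scen]
  pct_defined <- unit_cur > 0
  pct <- if (pct_defined) 100 * (fut_kg - cur_kg) / cur_kg else
    rep(NA_real_, n_mc)

  q <- function(x) stats::quantile(x, c(0.5, 0.025, 0.975), names = FALSE,
                                   na.rm = TRUE)
  summ <- data.frame(
    quantity = c("current_kg_ch4", "future_kg_ch4", "current_kg_co2eq",
                 "future_kg_co2eq", "pct_change"),
    rbind(q(cur_kg), q(fut_kg),
          q(to_co2eq(cur_kg, params$gwp_co2eq)),
          q(to_co2eq(fut_kg, params$gwp_co2eq)), q(pct)),
    stringsAsFactors = FALSE)
  names(summ)[2:4] <- c("median", "q025", "q975")

  by_scen <- data.frame(
    scenario = scen,
    future_kg_ch4 = params$rate_mean * unit_fut,
    future_kg_co2eq = to_co2eq(params$rate_mean * unit_fut, params$gwp_co2eq),
    pct_change = if (pct_defined)
      100 * (unit_fut - unit_cur) / unit_cur else NA_real_,
    colonized_future = vapply(scen, function(s)
      .colonized_count(lakes[[s]], params), numeric(1)),
    stringsAsFactors = FALSE)
  rownames(by_scen) <- NULL

  structure(list(draws = data.frame(rate = rate, scenario = scen[which_scen],
                                    current_kg = cur_kg, future_kg = fut_kg,
                                    pct_change = pct,
                                    stringsAsFactors = FALSE),
                 summary = summ,
                 by_scenario = by_scen,
                 min_pct_change = if (pct_defined) min(by_scen$pct_change)
                   else NA_real_,
                 current_kg_ch4 = params$rate_mean * unit_cur,
                 colonized_current = .colonized_count(lakes$p_current, params),
                 pct_change_defined = pct_defined,
                 params = params, n_mc = n_mc),
            class = "upscale_result")
}

#' @export
print.upscale_result <- function(x, ...) {
  cat(sprintf("upscale_result: %d lakes scenarios x %d draws\n",
              nrow(x$by_scenario), x$n_mc))
  cat(sprintf("  current total: %.3g kg CH4 (%.3g kg CO2-eq) at the mean rate\n",
              x$current_kg_ch4, to_co2eq(x$current_kg_ch4, x$params$gwp_co2eq)))
  if (x$pct_change_defined) {
    cat(sprintf("  pct change: median %.1f%% [%.1f, %.1f], ensemble minimum %.1f%%\n",
                x$summary$median[x$summary$quantity == "pct_change"],
                x$summary$q025[x$summary$quantity == "pct_change"],
                x$summary$q975[x$summary$quantity == "pct_change"],
                x$min_pct_change))
  } else cat("  pct change undefined: current total is zero\n")
  cat(sprintf("  colonized lakes (%s mode): %.1f current\n",
              x$params$colonization_mode, x$colonized_current))
  invisible(x)
}
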