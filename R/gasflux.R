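# Headspace gas-flux accounting: convert periodic headspace concentration
# measurements into cumulative CH4/CO2 production per jar, correcting for
# repeated N2 injection and sample withdrawal.

.R_GAS <- 8.314462618      # J mol^-1 K^-1
.MOLAR_MASS <- c(CH4 = 16.04, CO2 = 44.01)  # g mol^-1

#' Incubation jar geometry and sampling protocol
#'
#' Describes a sediment incubation jar: headspace volume, sediment surface
#' area, incubation temperature/pressure, and the per-sampling-event gas
#' handling (N2 injected to homogenize, sample volume withdrawn).
#'
#' The default headspace volume corresponds to a 250 mL jar filled with
#' sediment to 4.5 cm depth over a 28.3 cm^2 surface
#' (250 - 4.5 * 28.3 = 122.65 mL).
#'
#' @param headspace_volume_mL headspace gas volume between sampling events (mL)
#' @param sediment_area_cm2 sediment surface area (cm^2)
#' @param temperature_C incubation temperature (deg C)
#' @param pressure_kPa headspace pressure (kPa)
#' @param inject_mL volume of N2 homogenized into the headspace before each
#'   sample is drawn (mL)
#' @param withdraw_mL gas sample volume withdrawn at each event (mL)
#' @return an object of class `jar_spec` (a named list)
#' @export
jar_spec <- function(headspace_volume_mL = 122.65, sediment_area_cm2 = 28.3,
                     temperature_C = 20.5, pressure_kPa = 101.325,
                     inject_mL = 10, withdraw_mL = 10) {
  stopifnot(headspace_volume_mL > 0, sediment_area_cm2 > 0,
            pressure_kPa > 0, inject_mL >= 0, withdraw_mL >= 0)
  if (withdraw_mL > headspace_volume_mL + inject_mL)
    stop("withdraw_mL cannot exceed headspace + injected volume")
  structure(list(headspace_volume_mL = headspace_volume_mL,
                 sediment_area_cm2 = sediment_area_cm2,
                 temperature_C = temperature_C,
                 pressure_kPa = pressure_kPa,
                 inject_mL = inject_mL,
                 withdraw_mL = withdraw_mL),
            class = "jar_spec")
}

#' Convert a mixing ratio to gas mass
#'
#' Ideal-gas conversion of a headspace mixing ratio (ppm by volume) in a known
#' volume to mass of gas, at the incubation temperature and pressure.
#'
#' @param ppm mixing ratio in parts per million by volume
#' @param volume_mL gas volume (mL)
#' @param temperature_C temperature (deg C)
#' @param pressure_kPa pressure (kPa)
#' @param gas `"CH4"` or `"CO2"`
#' @return mass in mg (vectorized over `ppm` and `volume_mL`)
#' @export
ppm_to_mass <- function(ppm, volume_mL, temperature_C = 20.5,
                        pressure_kPa = 101.325, gas = c("CH4", "CO2")) {
  gas <- match.arg(gas)
  if (any(ppm < 0) || any(volume_mL < 0))
    stop("ppm and volume must be nonnegative")
  n_total <- (pressure_kPa * 1000) * (volume_mL * 1e-6) /
    (.R_GAS * (temperature_C + 273.15))            # mol of gas in the volume
  n_total * ppm * 1e-6 * .MOLAR_MASS[[gas]] * 1000 # mg
}

#' Convert gas mass to a mixing ratio
#'
#' Inverse of [ppm_to_mass()]: the ppm-by-volume mixing ratio that `mass_mg`
#' of gas produces when homogenized into `volume_mL`.
#'
#' @param mass_mg gas mass (mg)
#' @inheritParams ppm_to_mass
#' @return mixing ratio in ppm by volume
#' @export
mass_to_ppm <- function(mass_mg, volume_mL, temperature_C = 20.5,
                        pressure_kPa = 101.325, gas = c("CH4", "CO2")) {
  gas <- match.arg(gas)
  if (any(mass_mg < 0) || any(volume_mL <= 0))
    stop("mass must be nonnegative and volume positive")
  n_total <- (pressure_kPa * 1000) * (volume_mL * 1e-6) /
    (.R_GAS * (temperature_C + 273.15))
  (mass_mg / 1000 / .MOLAR_MASS[[gas]]) / n_total * 1e6
}

#' Event-by-event production ledger for one jar and gas
#'
#' Reconstructs cumulative gas production from an ordered series of headspace
#' concentration measurements, accounting for the gas removed at each
#' sampling event. With `measure_state = "mixed"` (default) each recorded
#' concentration is interpreted as the post-injection mixed state: the
#' headspace mass m is diluted into `V + inject_mL` before measurement, and
#' the withdrawal then removes `m * withdraw / (V + inject)`. With
#' `"pre"` the concentration is read in the undiluted volume `V` and the
#' injection happens after the reading but before withdrawal.
#'
#' Total production is the mass remaining after the final withdrawal plus
#' all removed portions added back.
#'
#' @param days strictly increasing sampling days
#' @param ppm concentration at each event (ppm by volume, mixing state per
#'   `measure_state`)
#' @param jar a [jar_spec()]
#' @param gas `"CH4"` or `"CO2"`
#' @param measure_state `"mixed"` or `"pre"`
#' @return a list with elements `mass_at_event` (mg in headspace when
#'   measured), `removed` (mg withdrawn per event), `final_mass` (mg left
#'   after the last withdrawal), `total_mg`, `rate_mg_m2` (total per m^2 of
#'   sediment), `implied_production` (mg produced between consecutive
#'   events), and `negative_flag` (TRUE if any implied production is
#'   negative, i.e. a concentration drop inconsistent with the removals).
#' @export
production_ledger <- function(days, ppm, jar = jar_spec(),
                              gas = c("CH4", "CO2"),
                              measure_state = c("mixed", "pre")) {
  gas <- match.arg(gas)
  measure_state <- match.arg(measure_state)
  stopifnot(length(days) == length(ppm), length(days) >= 1)
  if (any(diff(days) <= 0)) stop("sampling days must be strictly increasing")
  if (any(ppm < 0)) stop("concentrations must be nonnegative")

  V <- jar$headspace_volume_mL
  Vmix <- V + jar$inject_mL
  Vmeasure <- if (measure_state == "mixed") Vmix else V

  mass_at_event <- ppm_to_mass(ppm, Vmeasure, jar$temperature_C,
                               jar$pressure_kPa, gas)
  removed <- mass_at_event * jar$withdraw_mL / Vmix
  after <- mass_at_event - removed
  # production implied between events; first interval starts from a flushed
  # (zero CH4/CO2) headspace
  implied <- mass_at_event - c(0, after[-length(after)])
  k <- length(days)
  total <- after[k] + sum(removed)
  area_m2 <- jar$sediment_area_cm2 * 1e-4
  list(mass_at_event = mass_at_event,
       removed = removed,
       final_mass = after[k],
       total_mg = total,
       rate_mg_m2 = total / area_m2,
       implied_production = implied,
       negative_flag = any(implied < -1e-9 * max(mass_at_event, 1e-12)))
}

#' Cumulative production for a table of headspace series
#'
#' Applies [production_ledger()] to every (jar, gas) series in a long-format
#' headspace table and returns per-jar production estimates.
#'
#' @param headspace data.frame with columns `jar_id`, `treatment`, `om_pct`,
#'   `spike`, `day`, `gas`, `ppm` (the format written by [gen_incubation()])
#' @param jar a [jar_spec()] shared by all jars
#' @param measure_state see [production_ledger()]
#' @param strict drop jars whose series imply negative production between
#'   events (default keeps them, flagged)
#' @return data.frame with one row per jar x gas: `jar_id`, `treatment`,
#'   `om_pct`, `spike`, `gas`, `total_mg`, `rate_mg_m2`, `flagged`
#' @export
cumulative_production <- function(headspace, jar = jar_spec(),
                                  measure_state = c("mixed", "pre"),
                                  strict = FALSE) {
  measure_state <- match.arg(measure_state)
  need <- c("jar_id", "treatment", "om_pct", "spike", "day", "gas", "ppm")
  if (!all(need %in% names(headspace)))
    stop("headspace table must have columns: ", paste(need, collapse = ", "))
  if (nrow(headspace) == 0) stop("empty headspace table")

  keys <- unique(headspace[, c("jar_id", "gas")])
  out <- lapply(seq_len(nrow(keys)), function(r) {
    sel <- headspace$jar_id == keys$jar_id[r] & headspace$gas == keys$gas[r]
    s <- headspace[sel, ]
    s <- s[order(s$day), ]
    led <- production_ledger(s$day, s$ppm, jar, gas = keys$gas[r],
                             measure_state = measure_state)
    data.frame(jar_id = keys$jar_id[r],
               treatment = s$treatment[1], om_pct = s$om_pct[1],
               spike = s$spike[1], gas = keys$gas[r],
               total_mg = led$total_mg, rate_mg_m2 = led$rate_mg_m2,
               flagged = led$negative_flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (any(out$flagged))
    message(sum(out$flagged),
            " jar series imply negative production between events")
  if (strict) out <- out[!out$flagged, ]
  rownames(out) <- NULL
  out
}

#' Treatment-group summaries of production estimates
#'
#' @param estimates output of [cumulative_production()]
#' @return data.frame with one row per (treatment, om_pct, spike, gas):
#'   `n`, `mean_rate_mg_m2`, `se_rate_mg_m2`
#' @export
summarize_treatments <- function(estimates) {
  need <- c("treatment", "om_pct", "spike", "gas", "rate_mg_m2")
  if (!all(need %in% names(estimates)))
    stop("estimates must come from cumulative_production()")
  agg <- stats::aggregate(rate_mg_m2 ~ treatment + om_pct + spike + gas,
                          data = estimates,
                          FUN = function(x) c(n = length(x), mean = mean(x),
                                              se = stats::sd(x) / sqrt(length(x))))
  out <- cbind(agg[, c("treatment", "om_pct", "spike", "gas")],
               as.data.frame(agg$rate_mg_m2))
  names(out)[5:7] <- c("n", "mean_rate_mg_m2", "se_rate_mg_m2")
  out$n <- as.integer(out$n)
  # sd of a single observation is NA; report SE 0 only for n >= 2 identical
  out[order(out$gas, out$om_pct, out$spike, out$treatment), , drop = FALSE]
}
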