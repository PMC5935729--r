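# Seeded generators for every pipeline input: jar incubation headspace
# series, fluorescence EEM cubes, qPCR plates, and lake scenario tables.
# Defaults reproduce the structure of the incubation experiment: natural
# sediment amended with coniferous (CON), deciduous (DEC) or Typha latifolia
# (TYP) litter at 10/20/40 % organic matter, plus un-amended controls (CTR)
# and a methanogen-spiked arm at 20 % OM.

#' Configuration for the synthetic-data generators
#'
#' Bundles the knobs shared by [gen_incubation()], [gen_eems()],
#' [gen_qpcr()] and [gen_lakes()]. Defaults encode the study conditions the
#' pipeline is designed for: four replicate jars per amendment x OM cell,
#' a 150-day incubation, treatment-mean CH4 production spanning 2.63 to
#' 7.22e3 mg m^-2, mcrA copy deficits of 1.72e2 (CON) and 1.33e4 (DEC)
#' relative to TYP, and 5 GCM x 3 RCP climate scenarios.
#'
#' @param seed integer seed consumed by the generators
#' @param n_replicates replicate jars per treatment cell (>= 2)
#' @param treatments amendment labels; `CTR` is the un-amended control
#' @param om_levels organic-matter fractions by dry weight
#' @param production_means named vector, mean cumulative CH4 production over
#'   150 d per treatment (mg m^-2)
#' @param co2_mean mean cumulative CO2 production (mg m^-2), shared across
#'   treatments (CO2 production does not differ among amendments)
#' @param spike_multipliers named vector, multiplicative effect of the
#'   methanogen-rich spike on CH4 production per treatment
#' @param production_cv between-jar coefficient of variation of total
#'   production (lognormal, mean-preserving); 0 gives exact treatment means
#' @param sampling_days strictly increasing sampling days; the final day
#'   must be 150 (the growing-season endpoint)
#' @param curve_k,curve_t0 logistic shape of the cumulative production curve
#'   (rate per day, midpoint day); defaults put >99 per cent of the
#'   asymptote before day 150
#' @param eem_noise relative (multiplicative) sd of EEM intensity noise
#' @param ct_sd qPCR replicate Ct standard deviation for unknowns
#' @param std_ct_sd replicate Ct standard deviation for the dilution standards
#' @param qpcr_slope,qpcr_intercept standard-curve parameters (Ct per log10
#'   copies; Ct at 1 copy); the defaults give amplification efficiency
#'   ~0.972
#' @param copy_deficits named vector, fold-fewer mcrA copies than TYP per
#'   treatment (TYP itself is 1)
#' @param typ_copies true mcrA copies per reaction in the TYP treatment
#' @param n_lakes number of lakes in the scenario table
#' @param area_range_km2 lower/upper truncation of lake surface area (km^2)
#' @param gcms,rcps climate-model and emission-scenario labels whose
#'   combinations form the future occurrence columns
#' @param occurrence_ratio named by RCP: target ratio of area-weighted future
#'   to current occurrence probability per scenario
#' @return an object of class `synth_config` (a named list)
#' @export
synth_config <- function(seed = 1L,
                         n_replicates = 4L,
                         treatments = c("CTR", "CON", "DEC", "TYP"),
                         om_levels = c(0.10, 0.20, 0.40),
                         production_means = c(CTR = 5.16, CON = 17.2,
                                              DEC = 2.63, TYP = 7220),
                         co2_mean = 2e4,
                         spike_multipliers = c(CTR = 4, CON = 1,
                                               DEC = 1, TYP = 2),
                         production_cv = 0.25,
                         sampling_days = c(7, 14, 21, 35, 50, 70, 90,
                                           110, 130, 150),
                         curve_k = 0.08, curve_t0 = 60,
                         eem_noise = 0.01,
                         ct_sd = 0.2, std_ct_sd = 0,
                         qpcr_slope = -3.391, qpcr_intercept = 38,
                         copy_deficits = c(CTR = 1e3, CON = 172,
                                           DEC = 1.33e4, TYP = 1),
                         typ_copies = 5e5,
                         n_lakes = 500L,
                         area_range_km2 = c(0.1, 1000),
                         gcms = c("canESM2", "hadGEM2-ES", "CESM1-CAM5",
                                  "MIROC-ESM-CHEM", "composite-AR5"),
                         rcps = c("2.6", "4.5", "8.5"),
                         occurrence_ratio = c("2.6" = 1.73, "4.5" = 2.0,
                                              "8.5" = 2.5)) {
  if (n_replicates < 2) stop("n_replicates must be >= 2")
  if (any(production_means < 0)) stop("production_means must be >= 0")
  if (any(diff(sampling_days) <= 0))
    stop("sampling_days must be strictly increasing")
  if (utils::tail(sampling_days, 1) != 150)
    stop("final sampling day must be 150")
  if (any(area_range_km2 <= 0) || diff(area_range_km2) <= 0)
    stop("area_range_km2 must be positive and ordered")
  if (!all(treatments %in% names(production_means)))
    stop("production_means must name every treatment")
  if (qpcr_slope >= 0) stop("qpcr_slope must be negative")
  structure(as.list(environment()), class = "synth_config")
}

# normalized logistic reaching exactly 1 at day 150
.cum_fraction <- function(t, k, t0, t_end = 150) {
  L <- stats::plogis(k * (c(t, 0, t_end) - t0))
  n <- length(t)
  (L[seq_len(n)] - L[n + 1]) / (L[n + 2] - L[n + 1])
}

#' Simulate headspace series for the jar incubation experiment
#'
#' Forward-simulates every jar through the sampling-event model: cumulative
#' true production follows a logistic curve reaching the jar's total at day
#' 150; at each sampling day the produced mass accumulated since the last
#' event is added to the headspace, the headspace is homogenized with
#' `inject_mL` of N2, the mixed concentration is recorded, and `withdraw_mL`
#' is removed. Jars comprise every treatment x OM x replicate cell plus a
#' spiked arm at 20 % OM. True cumulative production is stored alongside so
#' recovery tests never re-derive it.
#'
#' @param config a [synth_config()]
#' @param jar a [jar_spec()]
#' @return list with `headspace` (long data.frame: `jar_id`, `treatment`,
#'   `om_pct`, `spike`, `day`, `gas`, `ppm`) and `truth` (one row per jar x
#'   gas with `true_total_mg_m2`)
#' @export
gen_incubation <- function(config = synth_config(), jar = jar_spec()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  cells <- expand.grid(rep = seq_len(config$n_replicates),
                       om_pct = config$om_levels * 100,
                       treatment = config$treatments,
                       spike = FALSE,
                       stringsAsFactors = FALSE)
  spiked <- expand.grid(rep = seq_len(config$n_replicates),
                        om_pct = 20, treatment = config$treatments,
                        spike = TRUE, stringsAsFactors = FALSE)
  cells <- rbind(cells, spiked)
  cells$jar_id <- sprintf("J%03d", seq_len(nrow(cells)))

  area_m2 <- jar$sediment_area_cm2 * 1e-4
  days <- config$sampling_days
  frac <- .cum_fraction(days, config$curve_k, config$curve_t0)
  sdlog <- sqrt(log(1 + config$production_cv^2))

  rows <- vector("list", nrow(cells))
  truth <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    tr <- cells$treatment[i]
    mult <- if (cells$spike[i]) config$spike_multipliers[[tr]] else 1
    per_gas <- c(CH4 = config$production_means[[tr]] * mult,
                 CO2 = config$co2_mean)
    jitter <- if (config$production_cv > 0)
      stats::rlnorm(2, -sdlog^2 / 2, sdlog) else c(1, 1)
    totals <- per_gas * jitter  # mg m^-2 at day 150, the stored truth
    gas_rows <- lapply(names(totals), function(g) {
      cum_mg <- totals[[g]] * frac * area_m2   # mg produced by each day
      m <- 0; ppm <- numeric(length(days))
      Vmix <- jar$headspace_volume_mL + jar$inject_mL
      for (k in seq_along(days)) {
        m <- m + cum_mg[k] - if (k > 1) cum_mg[k - 1] else 0
        ppm[k] <- mass_to_ppm(m, Vmix, jar$temperature_C, jar$pressure_kPa, g)
        m <- m - m * jar$withdraw_mL / Vmix
      }
      data.frame(jar_id = cells$jar_id[i], treatment = tr,
                 om_pct = cells$om_pct[i], spike = cells$spike[i],
                 day = days, gas = g, ppm = ppm, stringsAsFactors = FALSE)
    })
    rows[[i]] <- do.call(rbind, gas_rows)
    truth[[i]] <- data.frame(jar_id = cells$jar_id[i], treatment = tr,
                             om_pct = cells$om_pct[i], spike = cells$spike[i],
                             gas = names(totals),
                             true_total_mg_m2 = unname(totals),
                             stringsAsFactors = FALSE)
  }
  list(headspace = do.call(rbind, c(rows, make.row.names = FALSE)),
       truth = do.call(rbind, c(truth, make.row.names = FALSE)))
}

#' Reference fluorophore spectra
#'
#' The five Gaussian reference components used to build and label synthetic
#' EEMs: two humic-like components (C1 310/414 nm, C2 345/462 nm), the
#' tryptophan (C3 280/354 nm) and tyrosine (C4 270/306 nm) protein-like
#' components, and the phenol-leachate-associated component C5 (275/318 nm).
#'
#' @param ex_sigma,em_sigma Gaussian widths (nm) of the excitation and
#'   emission profiles
#' @return data.frame with columns `label`, `ex_peak`, `em_peak`,
#'   `ex_sigma`, `em_sigma`, `kind`
#' @export
reference_spectra <- function(ex_sigma = 15, em_sigma = 25) {
  stopifnot(ex_sigma > 0, em_sigma > 0)
  data.frame(label = paste0("C", 1:5),
             ex_peak = c(310, 345, 280, 270, 275),
             em_peak = c(414, 462, 354, 306, 318),
             ex_sigma = ex_sigma, em_sigma = em_sigma,
             kind = c("humic", "humic", "tryptophan", "tyrosine", "phenol"),
             stringsAsFactors = FALSE)
}

.gauss_profile <- function(grid, peak, sigma) exp(-(grid - peak)^2 / (2 * sigma^2))

#' Simulate a fluorescence EEM cube
#'
#' Builds each sample EEM as a nonnegative trilinear mixture of Gaussian
#' fluorophores at the reference peak positions, with per-treatment score
#' means (C5 zero in CTR, lowest among amended in TYP, highest in DEC),
#' multiplicative intensity noise, porewater DOC sidecars, and optional
#' inner-filter attenuation from a CDOM-like absorbance spectrum. True
#' component scores are stored for recovery tests.
#'
#' @param config a [synth_config()] (`eem_noise` and `seed` are used)
#' @param ref a [reference_spectra()] table; peaks must lie on the grids
#' @param n_per_treatment samples per treatment (total must be >= 6 for
#'   split-half validation)
#' @param apply_ife attenuate intensities by `10^-(A(ex)+A(em))/2` from the
#'   generated absorbance, to exercise [inner_filter_correct()]
#' @return an [eem_cube()] with `true_scores` attached
#' @export
gen_eems <- function(config = synth_config(), ref = reference_spectra(),
                     n_per_treatment = 8, apply_ife = FALSE) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 1L)
  ex <- seq(250, 450, by = 5)
  em <- seq(300, 600, by = 2)
  if (!all(ref$ex_peak %in% ex) || !all(ref$em_peak %in% em))
    stop("reference peaks must lie on the 250-450/5 nm and 300-600/2 nm grids")
  trs <- config$treatments
  n <- length(trs) * n_per_treatment
  if (n < 6) stop("need at least 6 samples for split-half validation")

  nf <- nrow(ref)
  Bex <- vapply(seq_len(nf),
                function(f) .gauss_profile(ex, ref$ex_peak[f], ref$ex_sigma[f]),
                numeric(length(ex)))
  Bem <- vapply(seq_len(nf),
                function(f) .gauss_profile(em, ref$em_peak[f], ref$em_sigma[f]),
                numeric(length(em)))

  # score means (arbitrary fluorescence units) per treatment x component;
  # C5 pattern: absent in CTR, lowest of the amended in TYP, highest in DEC
  # tyrosine-like C4 is weighted toward fresh/unprocessed DOM (CTR, TYP) so
  # its sample-score pattern is not collinear with tryptophan-like C3;
  # score diversity across samples is what makes the trilinear model unique
  mean_tbl <- rbind(CTR = c(2.0, 1.5, 0.5, 1.5, 0.0),
                    CON = c(4.0, 3.0, 1.0, 0.6, 1.2),
                    DEC = c(4.0, 3.0, 1.0, 0.4, 2.5),
                    TYP = c(3.0, 2.0, 2.0, 1.2, 0.4))
  doc_mean <- c(CTR = 5, CON = 15, DEC = 20, TYP = 12)

  treatment <- rep(trs, each = n_per_treatment)
  scores <- matrix(0, n, nf, dimnames = list(NULL, ref$label))
  for (i in seq_len(n)) {
    mu <- mean_tbl[treatment[i], ]
    scores[i, ] <- mu * stats::rlnorm(nf, -0.4^2 / 2, 0.4)
  }
  doc <- doc_mean[treatment] * stats::rlnorm(n, -0.2^2 / 2, 0.2)

  X <- array(0, dim = c(n, length(ex), length(em)))
  for (i in seq_len(n)) {
    M <- matrix(0, length(ex), length(em))
    for (f in seq_len(nf)) M <- M + scores[i, f] * outer(Bex[, f], Bem[, f])
    X[i, , ] <- M
  }
  if (config$eem_noise > 0)
    X <- X * (1 + array(stats::rnorm(length(X), 0, config$eem_noise), dim = dim(X)))
  X <- pmax(X, 0)

  abs_wl <- seq(250, 600, by = 2)
  absorbance <- t(vapply(seq_len(n), function(i) {
    0.008 * doc[i] * exp(-0.015 * (abs_wl - 254))
  }, numeric(length(abs_wl))))

  if (apply_ife) {
    for (i in seq_len(n)) {
      a_ex <- stats::approx(abs_wl, absorbance[i, ], ex)$y
      a_em <- stats::approx(abs_wl, absorbance[i, ], em)$y
      X[i, , ] <- X[i, , ] * 10^(-outer(a_ex, a_em, `+`) / 2)
    }
  }

  ids <- sprintf("S%03d", seq_len(n))
  cube <- eem_cube(X, ex, em, sample_ids = ids,
                   meta = data.frame(sample = ids, treatment = treatment,
                                     doc_mg_L = unname(doc),
                                     stringsAsFactors = FALSE),
                   absorbance = absorbance, abs_wl = abs_wl)
  cube$true_scores <- scores
  cube$ife_applied <- apply_ife
  cube
}

#' Simulate a qPCR plate
#'
#' Generates a 10-fold serial-dilution standard set with known copies and
#' unknowns (one pooled sample per treatment x OM level) whose Ct values
#' follow the log-linear standard-curve model
#' `Ct = intercept + slope * log10(copies) + N(0, ct_sd)`, run in triplicate.
#' True copy numbers per treatment are the TYP value divided by the
#' configured fold-deficits and are constant across OM levels, so the
#' treatment fold structure is exact in truth.
#'
#' @param config a [synth_config()]
#' @param n_standards dilution points, 10-fold steps from `top_copies` down
#' @param top_copies copies per reaction of the most concentrated standard
#' @return data.frame with columns `well_type` (`standard`/`unknown`),
#'   `sample`, `treatment`, `om_pct`, `true_copies`, `rep`, `ct`; the slope
#'   and intercept used are attached as attributes
#' @export
gen_qpcr <- function(config = synth_config(), n_standards = 7,
                     top_copies = 1e7) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 2L)
  slope <- config$qpcr_slope
  intercept <- config$qpcr_intercept
  ct_of <- function(copies, sd) {
    mu <- intercept + slope * log10(copies)
    mu + if (sd > 0) stats::rnorm(length(copies), 0, sd) else 0
  }
  std_copies <- top_copies / 10^(seq_len(n_standards) - 1)
  std <- do.call(rbind, lapply(seq_along(std_copies), function(d) {
    data.frame(well_type = "standard",
               sample = sprintf("STD%d", d), treatment = NA_character_,
               om_pct = NA_real_, true_copies = std_copies[d],
               rep = 1:3, ct = ct_of(rep(std_copies[d], 3), config$std_ct_sd),
               stringsAsFactors = FALSE)
  }))
  trs <- config$treatments
  copies_tr <- config$typ_copies / config$copy_deficits[trs]
  unk <- do.call(rbind, lapply(trs, function(tr) {
    do.call(rbind, lapply(config$om_levels * 100, function(om) {
      data.frame(well_type = "unknown",
                 sample = sprintf("%s_%g", tr, om), treatment = tr,
                 om_pct = om, true_copies = copies_tr[[tr]],
                 rep = 1:3, ct = ct_of(rep(copies_tr[[tr]], 3), config$ct_sd),
                 stringsAsFactors = FALSE)
    }))
  }))
  out <- rbind(std, unk)
  rownames(out) <- NULL
  attr(out, "slope") <- slope
  attr(out, "intercept") <- intercept
  out
}

#' Simulate a Boreal-Shield lake scenario table
#'
#' Draws `n_lakes` surface areas from a truncated log-normal
#' (log10(area) ~ N(-0.5, 0.8), truncated to `area_range_km2`) so most mass
#' sits at small lakes, beta-distributed current occurrence probabilities,
#' and one future occurrence column per GCM x RCP combination. Future
#' probabilities are lake-level perturbations of the current ones rescaled so
#' the area-weighted future/current ratio of each scenario equals the
#' configured `occurrence_ratio` for its RCP (clamped to [0, 1]).
#'
#' @param config a [synth_config()]
#' @return data.frame with columns `lake_id`, `area_km2`, `p_current`, and
#'   one `p_<GCM>_<RCP>` column per scenario; scenario column names are
#'   attached as attribute `scenario_cols`
#' @export
gen_lakes <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 3L)
  n <- config$n_lakes
  lo <- log10(config$area_range_km2[1]); hi <- log10(config$area_range_km2[2])
  draw_area <- function(m) {
    x <- stats::rnorm(m, -0.5, 0.8)
    x[x >= lo & x <= hi]
  }
  areas <- draw_area(2 * n)
  while (length(areas) < n) areas <- c(areas, draw_area(n))
  areas <- 10^areas[seq_len(n)]

  p_cur <- stats::rbeta(n, 0.8, 8)
  out <- data.frame(lake_id = sprintf("L%04d", seq_len(n)),
                    area_km2 = areas, p_current = p_cur,
                    stringsAsFactors = FALSE)
  scen_cols <- character(0)
  aw_cur <- sum(p_cur * areas)
  for (g in config$gcms) for (r in config$rcps) {
    target <- config$occurrence_ratio[[r]]
    p <- pmin(1, p_cur * target * stats::rlnorm(n, -0.1^2 / 2, 0.1))
    for (it in 1:50) {  # rescale so the area-weighted ratio hits the target
      s <- target * aw_cur / sum(p * areas)
      if (abs(s - 1) < 1e-12) break
      p <- pmin(1, p * s)
    }
    col <- paste0("p_", gsub("[^A-Za-z0-9.]", ".", g), "_", r)
    out[[col]] <- p
    scen_cols <- c(scen_cols, col)
  }
  attr(out, "scenario_cols") <- scen_cols
  out
}
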