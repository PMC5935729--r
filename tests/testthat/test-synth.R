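# Generators: determinism, stored truths, and structural contracts.

test_that("generators are bit-identical under the same seed", {
  cfg <- synth_config(seed = 42, n_lakes = 50L)
  expect_identical(gen_incubation(cfg), gen_incubation(cfg))
  expect_identical(gen_eems(cfg, n_per_treatment = 2),
                   gen_eems(cfg, n_per_treatment = 2))
  expect_identical(gen_qpcr(cfg), gen_qpcr(cfg))
  expect_identical(gen_lakes(cfg), gen_lakes(cfg))
})

test_that("zero production mean gives all-zero concentrations", {
  cfg <- synth_config(seed = 1, production_means = c(CTR = 0, CON = 0,
                                                     DEC = 0, TYP = 0),
                      co2_mean = 0, production_cv = 0)
  inc <- gen_incubation(cfg)
  expect_true(all(inc$headspace$ppm == 0))
})

test_that("stored production truth equals the configured mean exactly at zero variance", {
  cfg <- synth_config(seed = 7, production_means = c(CTR = 2.63, CON = 2.63,
                                                     DEC = 2.63, TYP = 2.63),
                      spike_multipliers = c(CTR = 1, CON = 1, DEC = 1, TYP = 1),
                      production_cv = 0)
  inc <- gen_incubation(cfg)
  ch4 <- inc$truth[inc$truth$gas == "CH4", ]
  expect_true(all(ch4$true_total_mg_m2 == 2.63))
})

test_that("incubation design has 8 cells of n jars at 20% OM including the spike arm", {
  cfg <- synth_config(seed = 3)
  inc <- gen_incubation(cfg)
  at20 <- unique(inc$truth[inc$truth$om_pct == 20,
                           c("jar_id", "treatment", "spike")])
  cells <- table(at20$treatment, at20$spike)
  expect_equal(dim(cells), c(4, 2))
  expect_true(all(cells == cfg$n_replicates))
})

test_that("config invariants are enforced", {
  expect_error(synth_config(sampling_days = c(10, 5, 150)), "increasing")
  expect_error(synth_config(sampling_days = c(10, 50, 120)), "150")
  expect_error(synth_config(n_replicates = 1), "n_replicates")
  expect_error(synth_config(area_range_km2 = c(10, 1)), "ordered")
  expect_error(synth_config(qpcr_slope = 3.39), "negative")
})

test_that("EEM grids are 41 excitation x 151 emission points", {
  cube <- gen_eems(synth_config(seed = 1), n_per_treatment = 2)
  expect_equal(dim(cube$intensity)[2:3], c(41L, 151L))
  expect_equal(cube$ex, seq(250, 450, by = 5))
  expect_equal(cube$em, seq(300, 600, by = 2))
})

test_that("a noiseless single-component EEM is an exact rank-1 outer product", {
  cube <- make_gauss_cube(n = 1, noise = 0, ex_peaks = 330, em_peaks = 420)
  sl <- cube$intensity[1, , ]
  expect_equal(sl, cube$true_scores[1, 1] * outer(cube$true_ex[, 1],
                                                  cube$true_em[, 1]),
               tolerance = 1e-12)
  expect_equal(qr(sl)$rank, 1L)
})

test_that("CTR samples carry exactly zero phenol-component score and intensities are nonnegative", {
  cube <- gen_eems(synth_config(seed = 5), n_per_treatment = 3)
  ctr <- cube$meta$treatment == "CTR"
  expect_true(all(cube$true_scores[ctr, "C5"] == 0))
  expect_true(any(cube$true_scores[!ctr, "C5"] > 0))
  expect_true(all(cube$intensity >= 0))
})

test_that("off-grid reference peaks are rejected", {
  ref <- reference_spectra()
  ref$em_peak[1] <- 413  # not on the 2 nm grid
  expect_error(gen_eems(synth_config(seed = 1), ref = ref), "grid")
})

test_that("qPCR plate: zero Ct noise gives identical triplicates and exact dilution spacing", {
  cfg <- synth_config(seed = 2, ct_sd = 0, std_ct_sd = 0,
                      qpcr_slope = -3.3219)
  pl <- gen_qpcr(cfg)
  reps <- tapply(pl$ct, pl$sample, function(x) diff(range(x)))
  expect_true(all(reps == 0))
  std <- unique(pl[pl$well_type == "standard", c("true_copies", "ct")])
  std <- std[order(-std$true_copies), ]
  expect_equal(diff(std$ct), rep(3.3219, nrow(std) - 1), tolerance = 1e-12)
})

test_that("default true copy numbers encode the CON and DEC fold-deficits", {
  pl <- gen_qpcr(synth_config(seed = 2))
  cp <- tapply(pl$true_copies[pl$well_type == "unknown"],
               pl$treatment[pl$well_type == "unknown"], unique)
  expect_equal(cp[["TYP"]] / cp[["CON"]], 172)
  expect_equal(cp[["TYP"]] / cp[["DEC"]], 1.33e4)
})

test_that("lake table respects area bounds, probability ranges, and 15 scenario columns", {
  lakes <- gen_lakes(synth_config(seed = 4, n_lakes = 200L))
  expect_equal(nrow(lakes), 200L)
  expect_true(all(lakes$area_km2 >= 0.1 & lakes$area_km2 <= 1000))
  scen <- attr(lakes, "scenario_cols")
  expect_length(scen, 15L)
  probs <- as.matrix(lakes[, c("p_current", scen)])
  expect_true(all(probs >= 0 & probs <= 1))
  # future occurrence exceeds current on average, per scenario
  aw <- colSums(probs * lakes$area_km2)
  expect_true(all(aw[scen] > aw["p_current"]))
})
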