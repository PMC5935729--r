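# Inner-filter correction, component matching, phenol index, and the EEM
# CSV interchange. PARAFAC fitting behaviour is in test-parafac.R.

test_that("zero absorbance leaves the cube unchanged", {
  cube <- make_gauss_cube(n = 3)
  cube$absorbance <- matrix(0, 3, 176)
  cube$abs_wl <- seq(250, 600, by = 2)
  cor <- inner_filter_correct(cube)
  expect_equal(cor$intensity, cube$intensity)
  expect_length(cor$ife_flagged, 0)
})

test_that("flat absorbance 0.3 multiplies intensities by 10^0.3", {
  cube <- make_gauss_cube(n = 2)
  cube$absorbance <- matrix(0.3, 2, 176)
  cube$abs_wl <- seq(250, 600, by = 2)
  cor <- inner_filter_correct(cube)
  expect_equal(cor$intensity, cube$intensity * 10^0.3, tolerance = 1e-12)
})

test_that("correction inverts the generator's attenuation", {
  cfg <- synth_config(seed = 8, eem_noise = 0)
  plain <- gen_eems(cfg, n_per_treatment = 2, apply_ife = FALSE)
  atten <- gen_eems(cfg, n_per_treatment = 2, apply_ife = TRUE)
  cor <- inner_filter_correct(atten)
  expect_lt(max(abs(cor$intensity - plain$intensity)), 1e-8)
})

test_that("samples with absorbance beyond the correction's validity are flagged", {
  cube <- make_gauss_cube(n = 2)
  cube$absorbance <- rbind(rep(0.2, 176), rep(2.0, 176))
  cube$abs_wl <- seq(250, 600, by = 2)
  expect_equal(inner_filter_correct(cube)$ife_flagged, "S02")
})

test_that("missing absorbance is rejected", {
  cube <- make_gauss_cube(n = 2)
  expect_error(inner_filter_correct(cube), "no absorbance")
  cube$absorbance <- rbind(rep(0.2, 176), rep(NA_real_, 176))
  cube$abs_wl <- seq(250, 600, by = 2)
  expect_error(inner_filter_correct(cube), "missing absorbance")
})

test_that("matching reference profiles to themselves gives the identity with printed peaks", {
  ref <- reference_spectra()
  ex <- seq(250, 450, by = 5)
  em <- seq(300, 600, by = 2)
  model <- structure(list(
    scores = matrix(1, 2, 5),
    ex_loadings = vapply(1:5, function(f)
      exp(-(ex - ref$ex_peak[f])^2 / (2 * ref$ex_sigma[f]^2)), numeric(41)),
    em_loadings = vapply(1:5, function(f)
      exp(-(em - ref$em_peak[f])^2 / (2 * ref$em_sigma[f]^2)), numeric(151)),
    ncomp = 5, ex = ex, em = em), class = "parafac_model")
  m <- match_components(model, ref)
  expect_equal(m$label, paste0("C", 1:5))
  expect_equal(m$congruence, rep(1, 5), tolerance = 1e-12)
  expect_equal(m$ex_peak_fit[m$label == "C5"], 275)
  expect_equal(m$em_peak_fit[m$label == "C5"], 318)
})

test_that("a single component against a single reference is always assigned", {
  cube <- make_gauss_cube(n = 4, ex_peaks = 330, em_peaks = 420)
  fit <- fit_parafac(cube, 1, nstart = 2, seed = 1)
  ref1 <- reference_spectra()[3, ]
  m <- match_components(fit, ref1)
  expect_equal(nrow(m), 1L)
  expect_equal(m$label, "C3")
})

test_that("phenol index: proportionality, zero-score and DOC-scaling contracts", {
  ref <- reference_spectra()
  c5_scores <- c(0, 0, 1, 2, 3, 4, 0.5, 1.5, 2.5, 3.5)
  cube <- make_gauss_cube(n = 10, ex_peaks = ref$ex_peak,
                          em_peaks = ref$em_peak,
                          scores = cbind(2, 1, 0.5, 0.5, c5_scores),
                          doc = c(10, 20, rep(10, 8)))
  fit <- fit_parafac(cube, 5, nstart = 6, seed = 2)
  pi1 <- phenol_index(fit, cube, ref)
  # zero true C5 -> zero index (fitted score collapses to ~0)
  expect_lt(pi1$phenol_index[1], 1e-6 * max(pi1$phenol_index))
  # index is proportion * DOC
  expect_equal(pi1$phenol_index, pi1$proportion * pi1$doc_mg_L)
  # halving DOC halves the index at fixed scores
  cube2 <- cube
  cube2$meta$doc_mg_L <- cube$meta$doc_mg_L / 2
  pi2 <- phenol_index(fit, cube2, ref)
  expect_equal(pi2$phenol_index, pi1$phenol_index / 2)
})

test_that("a sample with all fluorescence in the phenol component has index equal to DOC", {
  ref <- reference_spectra()
  ex <- seq(250, 450, by = 5)
  em <- seq(300, 600, by = 2)
  model <- structure(list(
    # rows: pure-phenol, dark, phenol-free, even split across all five
    scores = rbind(c(0, 0, 0, 0, 7), c(0, 0, 0, 0, 0),
                   c(1, 1, 1, 1, 0), c(2, 2, 2, 2, 2)),
    ex_loadings = vapply(1:5, function(f)
      exp(-(ex - ref$ex_peak[f])^2 / (2 * ref$ex_sigma[f]^2)), numeric(41)),
    em_loadings = vapply(1:5, function(f)
      exp(-(em - ref$em_peak[f])^2 / (2 * ref$em_sigma[f]^2)), numeric(151)),
    ncomp = 5, ex = ex, em = em), class = "parafac_model")
  cube <- eem_cube(array(1, c(4, 41, 151)), ex, em,
                   sample_ids = sprintf("S%d", 1:4),
                   meta = data.frame(sample = sprintf("S%d", 1:4),
                                     doc_mg_L = c(10, 5, 3, 2)))
  pix <- phenol_index(model, cube, ref)
  expect_equal(pix$phenol_index, c(10, 0, 0, 2 / 10 * 2))
})

test_that("EEM cubes survive the CSV round trip", {
  cube <- gen_eems(synth_config(seed = 9), n_per_treatment = 2)
  dir <- withr::local_tempdir()
  write_eem_csv(cube, dir)
  back <- read_eem_csv(dir)
  expect_equal(back$intensity, cube$intensity, tolerance = 1e-12)
  expect_equal(back$ex, cube$ex)
  expect_equal(back$em, cube$em)
  expect_equal(back$meta$doc_mg_L, cube$meta$doc_mg_L, tolerance = 1e-12)
  expect_equal(back$absorbance, cube$absorbance, tolerance = 1e-12,
               ignore_attr = TRUE)
})
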