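# Shared fixtures: small, fast EEM cubes with known trilinear structure on
# coarse grids, used by the unit tests (the full-size generator cubes are
# reserved for the acceptance checks).

make_gauss_cube <- function(n = 12, noise = 0, seed = 1,
                            ex = seq(250, 450, by = 10),
                            em = seq(300, 600, by = 5),
                            ex_peaks = c(280, 330, 400),
                            em_peaks = c(330, 420, 520),
                            ex_sigma = 15, em_sigma = 25,
                            doc = NULL, scores = NULL) {
  set.seed(seed)
  nf <- length(ex_peaks)
  Bex <- vapply(ex_peaks, function(p) exp(-(ex - p)^2 / (2 * ex_sigma^2)),
                numeric(length(ex)))
  Bem <- vapply(em_peaks, function(p) exp(-(em - p)^2 / (2 * em_sigma^2)),
                numeric(length(em)))
  if (is.null(scores)) scores <- matrix(stats::rlnorm(n * nf, 0, 0.5), n)
  X <- array(0, c(n, length(ex), length(em)))
  for (i in seq_len(n)) {
    M <- matrix(0, length(ex), length(em))
    for (f in seq_len(nf)) M <- M + scores[i, f] * outer(Bex[, f], Bem[, f])
    X[i, , ] <- M
  }
  if (noise > 0)
    X <- pmax(X * (1 + array(stats::rnorm(length(X), 0, noise), dim(X))), 0)
  if (is.null(doc)) doc <- rep(10, n)
  ids <- sprintf("S%02d", seq_len(n))
  cube <- eem_cube(X, ex, em, sample_ids = ids,
                   meta = data.frame(sample = ids, doc_mg_L = doc))
  cube$true_scores <- scores
  cube$true_ex <- Bex
  cube$true_em <- Bem
  cube
}

# forward-simulate a production trajectory through the sampling-event model,
# independently of the generator: returns the recorded mixed-state ppm
simulate_jar_ppm <- function(cum_mg, jar, gas = "CH4") {
  Vmix <- jar$headspace_volume_mL + jar$inject_mL
  m <- 0
  ppm <- numeric(length(cum_mg))
  prev <- 0
  for (k in seq_along(cum_mg)) {
    m <- m + cum_mg[k] - prev
    prev <- cum_mg[k]
    ppm[k] <- mass_to_ppm(m, Vmix, jar$temperature_C, jar$pressure_kPa, gas)
    m <- m - m * jar$withdraw_mL / Vmix
  }
  ppm
}
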