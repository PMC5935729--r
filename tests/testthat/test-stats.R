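# ANOVA layer and the log-log phenol-CH4 model.

make_production <- function(means, n = 4, sd = 0, om = 20, seed = 1) {
  set.seed(seed)
  cells <- strsplit(names(means), "\\+")
  do.call(rbind, lapply(seq_along(means), function(i) {
    data.frame(jar_id = sprintf("%s_%d", names(means)[i], seq_len(n)),
               treatment = cells[[i]][1],
               om_pct = om,
               spike = length(cells[[i]]) > 1,
               gas = "CH4",
               rate_mg_m2 = means[i] * exp(stats::rnorm(n, 0, sd)))
  }))
}

full_design <- function(sd = 0.3, seed = 2) {
  means <- c(CTR = 5.2, CON = 17, DEC = 2.6, TYP = 7200,
             "CTR+s" = 21, "CON+s" = 17, "DEC+s" = 2.6, "TYP+s" = 14000)
  make_production(means, n = 4, sd = sd, seed = seed)
}

test_that("the 8-cell x n=4 design yields df (7, 24)", {
  res <- anova_amendment_spike(full_design(), om_level = 20)
  expect_equal(res$df_between, 7L)
  expect_equal(res$df_within, 24L)
  expect_gt(res$F, 1)
  expect_lt(res$p, 0.001)
})

test_that("identical observations across all groups give an undefined F and one group", {
  d <- make_production(c(A = 3, B = 3, "A+s" = 3), sd = 0)
  res <- anova_amendment_spike(d, om_level = 20, log_scale = FALSE)
  expect_true(is.na(res$F))
  expect_true(all(res$groups$label == 1L))
})

test_that("clearly separated groups receive distinct labels", {
  d <- make_production(c(LO = 1, HI = 1000), n = 4, sd = 0.05, seed = 3)
  res <- anova_amendment_spike(d, om_level = 20)
  lab <- res$groups$label[match(c("HI", "LO"), res$groups$group)]
  expect_equal(lab, c(1L, 2L))  # numbered in decreasing mean order
})

test_that("cells with n < 2 are rejected", {
  d <- full_design()
  d <- d[!(d$treatment == "TYP" & !d$spike & seq_len(nrow(d)) %% 4 != 1), ]
  d2 <- rbind(full_design(), data.frame(jar_id = "X", treatment = "NEW",
                                        om_pct = 20, spike = FALSE,
                                        gas = "CH4", rate_mg_m2 = 5))
  expect_error(anova_amendment_spike(d2, om_level = 20), "n >= 2")
})

test_that("raw-scale F is invariant to adding a constant and location labels persist", {
  d <- full_design(sd = 0.2, seed = 5)
  r1 <- anova_amendment_spike(d, om_level = 20, log_scale = FALSE)
  d2 <- d
  d2$rate_mg_m2 <- d$rate_mg_m2 + 1e4
  r2 <- anova_amendment_spike(d2, om_level = 20, log_scale = FALSE)
  expect_equal(r2$F, r1$F, tolerance = 1e-10)
  expect_equal(r2$groups$label[order(r2$groups$group)],
               r1$groups$label[order(r1$groups$group)])
})

test_that("an exact power law is fitted with zero residual", {
  x <- c(0.5, 1, 2, 4, 8, 16)
  y <- 100 * x^-2
  fit <- loglog_fit(x, y)
  expect_equal(fit$coefficients$estimate[2], -2, tolerance = 1e-10)
  expect_equal(fit$coefficients$estimate[1], log(100), tolerance = 1e-10)
  expect_lt(fit$sigma, 1e-10)
})

test_that("degenerate inputs to the log-log fit are rejected", {
  expect_error(loglog_fit(2, 5), "at least 3")
  expect_error(loglog_fit(c(1, 2, 0), c(1, 2, 3)), "strictly positive")
  expect_error(loglog_fit(c(1, 2, 3), c(1, 0, 3)), "strictly positive")
})

test_that("multiplying production by c shifts the intercept by log c, slope unchanged", {
  set.seed(8)
  x <- exp(stats::rnorm(30))
  y <- 50 * x^-1.3 * exp(stats::rnorm(30, 0, 0.3))
  f1 <- loglog_fit(x, y)
  f2 <- loglog_fit(x, 10 * y)
  expect_equal(f2$coefficients$estimate[2], f1$coefficients$estimate[2],
               tolerance = 1e-10)
  expect_equal(f2$coefficients$estimate[1] - f1$coefficients$estimate[1],
               log(10), tolerance = 1e-10)
})

test_that("slope CI coverage is ~95% on noisy power-law data", {
  set.seed(17)
  true_slope <- -1.5
  cover <- logical(1000)
  for (r in seq_len(1000)) {
    x <- exp(stats::rnorm(36, 0, 0.8))
    y <- 20 * x^true_slope * exp(stats::rnorm(36, 0, 0.5))
    ci <- loglog_fit(x, y)$coefficients[2, c("lower", "upper")]
    cover[r] <- ci$lower <= true_slope && true_slope <= ci$upper
  }
  expect_gte(mean(cover), 0.92)
  expect_lte(mean(cover), 0.98)
})

test_that("the confidence band straddles the fitted line across the phenol range", {
  set.seed(9)
  x <- exp(stats::rnorm(40))
  y <- 30 * x^-1 * exp(stats::rnorm(40, 0, 0.4))
  fit <- loglog_fit(x, y)
  expect_true(all(fit$band$lower <= fit$band$fit))
  expect_true(all(fit$band$fit <= fit$band$upper))
  expect_equal(range(fit$band$phenol), range(x), tolerance = 1e-10)
})
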