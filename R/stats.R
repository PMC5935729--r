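# Statistical layer: the amendment x spike one-way ANOVA with transitive
# group labelling, and the log-log phenol-CH4 regression with confidence
# band.

#' One-way ANOVA of production across amendment x spike cells
#'
#' Treats each amendment x spike combination at one OM level as a group
#' (4 amendments x 2 spike states = 8 cells in the full design) and runs a
#' one-way ANOVA. Production spans orders of magnitude, so the default
#' analyses log-transformed rates; `log_scale = FALSE` analyses the raw
#' scale. Group separation labels are obtained by re-levelling the baseline
#' group: every pair is compared with the pooled-variance t statistic on the
#' residual degrees of freedom (exactly the intercept-adjusted coefficient
#' test under each re-levelling), non-significant pairs (p >= alpha) are
#' merged transitively into clusters, and clusters are numbered in
#' decreasing order of group mean.
#'
#' @param production data.frame from [cumulative_production()] (or any table
#'   with `treatment`, `spike`, `om_pct`, `gas`, `rate_mg_m2`)
#' @param om_level OM percentage to analyse (spiked jars at the same OM are
#'   included)
#' @param gas which gas to analyse
#' @param log_scale analyse `log(rate)` (default) or raw rates
#' @param alpha significance level for group separation
#' @return an object of class `anova_result`: `F`, `df_between`,
#'   `df_within`, `p`, and `groups` (per cell: mean, n, cluster label)
#' @export
anova_amendment_spike <- function(production, om_level = 20, gas = "CH4",
                                  log_scale = TRUE, alpha = 0.05) {
  d <- production[production$om_pct == om_level & production$gas == gas, ]
  if (nrow(d) == 0) stop("no rows at om_level ", om_level, " for ", gas)
  d$group <- paste0(d$treatment, ifelse(d$spike, "+spike", ""))
  n_per <- table(d$group)
  if (any(n_per < 2)) stop("every cell needs n >= 2; offending: ",
                           paste(names(n_per)[n_per < 2], collapse = ", "))
  y <- if (log_scale) {
    if (any(d$rate_mg_m2 <= 0))
      stop("log-scale ANOVA needs strictly positive rates; use log_scale = FALSE")
    log(d$rate_mg_m2)
  } else d$rate_mg_m2
  g <- factor(d$group)
  k <- nlevels(g); N <- length(y)

  means <- tapply(y, g, mean)
  ns <- tapply(y, g, length)
  ss_within <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  ss_between <- sum(ns * (means - mean(y))^2)
  df_b <- k - 1; df_w <- N - k
  if (ss_within < 1e-12 * max(ss_between, 1) && ss_between < 1e-12) {
    # all observations identical: F undefined, a single homogeneous group
    groups <- data.frame(group = names(means), n = as.integer(ns),
                         mean = as.numeric(means), label = 1L,
                         stringsAsFactors = FALSE)
    return(structure(list(F = NA_real_, df_between = df_b, df_within = df_w,
                          p = NA_real_, groups = groups,
                          log_scale = log_scale),
                     class = "anova_result"))
  }
  Fstat <- (ss_between / df_b) / (ss_within / df_w)
  p <- stats::pf(Fstat, df_b, df_w, lower.tail = FALSE)

  # pairwise separation via pooled-variance t tests (baseline re-levelling)
  s2 <- ss_within / df_w
  adj <- matrix(FALSE, k, k)
  for (a in seq_len(k - 1)) for (b in (a + 1):k) {
    tstat <- (means[a] - means[b]) / sqrt(s2 * (1 / ns[a] + 1 / ns[b]))
    p_ab <- 2 * stats::pt(abs(tstat), df_w, lower.tail = FALSE)
    adj[a, b] <- adj[b, a] <- p_ab >= alpha  # connect if NOT separated
  }
  diag(adj) <- TRUE
  # transitive closure -> connected components
  lab <- seq_len(k)
  repeat {
    changed <- FALSE
    for (a in seq_len(k)) for (b in seq_len(k)) {
      if (adj[a, b] && lab[b] != lab[a]) {
        lab[lab == lab[b]] <- lab[a]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  # number clusters by decreasing cluster mean
  cl_means <- tapply(means, lab, mean)
  renum <- stats::setNames(rank(-cl_means, ties.method = "first"),
                           names(cl_means))
  groups <- data.frame(group = names(means), n = as.integer(ns),
                       mean = as.numeric(means),
                       label = as.integer(renum[as.character(lab)]),
                       stringsAsFactors = FALSE)
  groups <- groups[order(groups$label, -groups$mean), ]
  rownames(groups) <- NULL
  structure(list(F = Fstat, df_between = df_b, df_within = df_w, p = p,
                 groups = groups, log_scale = log_scale),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("anova_result: F(%d, %d) = %s, p = %s [%s scale]\n",
              x$df_between, x$df_within,
              if (is.na(x$F)) "NA" else sprintf("%.2f", x$F),
              if (is.na(x$p)) "NA" else format.pval(x$p, digits = 3),
              if (x$log_scale) "log" else "raw"))
  print(x$groups)
  invisible(x)
}

#' Log-log regression of CH4 production on the phenol index
#'
#' Least squares of `log(production)` on `log(phenol index)`; the slope is
#' the elasticity of CH4 production with respect to relative phenol
#' concentration (negative when phenols suppress methanogenesis). Zeros are
#' not log-transformable: samples with nonpositive production or index must
#' be excluded beforehand (un-amended controls have no phenol signal and are
#' not part of this fit).
#'
#' Natural logarithms are used internally; the slope is invariant to the
#' log base, and `base` only rescales the reported intercept.
#'
#' @param phenol phenol index per sample (strictly positive)
#' @param production CH4 production per sample (strictly positive)
#' @param conf confidence level for coefficient intervals and the mean
#'   prediction band
#' @param base log base for the reported intercept
#' @param n_band points in the fitted band across the observed phenol range
#' @return an object of class `loglog_fit`: `coefficients` (estimate and CI
#'   for intercept and slope), `band` (phenol grid, fitted production,
#'   lower/upper), `sigma`, `r_squared`, `model`
#' @export
loglog_fit <- function(phenol, production, conf = 0.95, base = exp(1),
                       n_band = 100) {
  stopifnot(length(phenol) == length(production))
  if (length(phenol) < 3)
    stop("need at least 3 observations for a log-log fit with a CI")
  if (any(phenol <= 0) || any(production <= 0))
    stop("log-log fit requires strictly positive phenol and production; ",
         "exclude zero (e.g. un-amended control) samples first")
  lx <- log(phenol); ly <- log(production)
  fit <- stats::lm(ly ~ lx)
  smry <- suppressWarnings(summary(fit))  # exact power laws fit perfectly
  ci <- suppressWarnings(stats::confint(fit, level = conf))
  co <- stats::coef(fit)
  coefficients <- data.frame(
    term = c("intercept", "slope"),
    estimate = c(unname(co[1]) / log(base), unname(co[2])),
    lower = c(ci[1, 1] / log(base), ci[2, 1]),
    upper = c(ci[1, 2] / log(base), ci[2, 2]),
    stringsAsFactors = FALSE)
  grid <- exp(seq(min(lx), max(lx), length.out = n_band))
  pred <- stats::predict(fit, newdata = data.frame(lx = log(grid)),
                         interval = "confidence", level = conf)
  band <- data.frame(phenol = grid,
                     fit = exp(pred[, "fit"]),
                     lower = exp(pred[, "lwr"]),
                     upper = exp(pred[, "upr"]))
  structure(list(coefficients = coefficients, band = band,
                 sigma = smry$sigma,
                 r_squared = smry$r.squared,
                 n = length(phenol), conf = conf, model = fit),
            class = "loglog_fit")
}

#' @export
print.loglog_fit <- function(x, ...) {
  cat(sprintf("loglog_fit: n = %d, R^2 = %.3f\n", x$n, x$r_squared))
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}
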