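# qPCR absolute quantification: standard-curve fitting, copies per gram dry
# sediment, and treatment fold-differences.

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of mean Ct on log10 copies over a serial-dilution
#' standard set. Requires at least three dilution points spanning at least
#' two orders of magnitude. Amplification efficiency is
#' `10^(-1/slope) - 1` (1 = perfect doubling each cycle).
#'
#' @param copies known copies per reaction, one value per well
#' @param ct measured Ct, same length (replicates share a `copies` value and
#'   are averaged per dilution point before the fit)
#' @return an object of class `standard_curve`: `slope`, `intercept`,
#'   `r_squared`, `efficiency`, `ct_range`, `log10_range`, `model`
#' @export
fit_standard_curve <- function(copies, ct) {
  stopifnot(length(copies) == length(ct), all(copies > 0))
  pts <- stats::aggregate(ct ~ copies, data = data.frame(copies, ct), mean)
  if (nrow(pts) < 3)
    stop("need at least 3 distinct dilution points, have ", nrow(pts))
  lr <- log10(range(pts$copies))
  if (diff(lr) < 2)
    stop("dilution series must span at least 2 orders of magnitude")
  fit <- stats::lm(ct ~ log10(copies), data = pts)
  smry <- suppressWarnings(summary(fit))  # noiseless assays fit perfectly
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0)
    stop("positive standard-curve slope: Ct must decrease with copies")
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = smry$r.squared,
                 efficiency = 10^(-1 / slope) - 1,
                 ct_range = range(pts$ct),
                 log10_range = lr,
                 model = fit),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("standard_curve: Ct = %.3f %+.4f * log10(copies)\n",
              x$intercept, x$slope))
  cat(sprintf("  R^2 = %.4f, efficiency = %.1f%%, range 10^%.1f-10^%.1f copies\n",
              x$r_squared, 100 * x$efficiency, x$log10_range[1], x$log10_range[2]))
  invisible(x)
}

#' Default normalization constants for copies per gram dry weight
#'
#' @param elution_uL DNA elution volume (microlitre)
#' @param template_uL template volume per reaction (microlitre)
#' @param dry_mass_g extracted sediment dry mass (g)
#' @param yield extraction yield fraction in (0, 1]
#' @return named list of normalization factors
#' @export
qpcr_norm <- function(elution_uL = 100, template_uL = 2, dry_mass_g = 0.25,
                      yield = 1) {
  vals <- c(elution_uL, template_uL, dry_mass_g, yield)
  if (any(vals <= 0)) stop("normalization factors must be positive")
  list(elution_uL = elution_uL, template_uL = template_uL,
       dry_mass_g = dry_mass_g, yield = yield)
}

#' Quantify unknowns against a standard curve
#'
#' Averages replicate Ct per sample, inverts the standard curve to copies
#' per reaction, and normalizes to copies per gram dry sediment:
#' `copies_rxn * (elution/template) / (dry_mass * yield)`. Mean Ct outside
#' the standard-curve range is extrapolated with a warning.
#'
#' @param curve a [fit_standard_curve()] object
#' @param unknowns data.frame with columns `sample` and `ct` (replicate
#'   rows); extra columns (`treatment`, `om_pct`, ...) are carried through
#' @param norm a [qpcr_norm()] list
#' @return data.frame with one row per sample: carried metadata, `mean_ct`,
#'   `n_reps`, `copies_rxn`, `copies_gdw`
#' @export
quantify_copies <- function(curve, unknowns, norm = qpcr_norm()) {
  stopifnot(inherits(curve, "standard_curve"))
  if (!all(c("sample", "ct") %in% names(unknowns)))
    stop("unknowns must have columns sample and ct")
  meta_cols <- setdiff(names(unknowns), c("ct", "rep", "well_type",
                                          "true_copies"))
  sp <- split(unknowns, unknowns$sample)
  out <- do.call(rbind, lapply(sp, function(d) {
    row <- d[1, meta_cols, drop = FALSE]
    row$mean_ct <- mean(d$ct)
    row$n_reps <- nrow(d)
    row
  }))
  out <- out[order(match(out$sample, unique(unknowns$sample))), ]
  outside <- out$mean_ct < min(curve$ct_range) | out$mean_ct > max(curve$ct_range)
  if (any(outside))
    warning(sum(outside), " sample(s) outside the standard-curve Ct range; ",
            "copies are extrapolated")
  out$copies_rxn <- 10^((out$mean_ct - curve$intercept) / curve$slope)
  out$copies_gdw <- out$copies_rxn * (norm$elution_uL / norm$template_uL) /
    (norm$dry_mass_g * norm$yield)
  rownames(out) <- NULL
  out
}

#' Treatment fold-differences in gene abundance
#'
#' For each treatment, the fold-difference in copies per gram dry weight
#' relative to a reference treatment, computed per OM level and combined as
#' a geometric mean (abundances span orders of magnitude, so averaging is
#' done on the log scale); the standard error across OM levels is computed
#' on log10 folds and back-transformed.
#'
#' @param quant output of [quantify_copies()] with `treatment` and `om_pct`
#'   columns
#' @param reference reference treatment label
#' @return data.frame per treatment: `n_levels`, `fold_vs_ref` (geometric
#'   mean of treatment/reference), `deficit` (reference/treatment, the
#'   fold-fewer copies than the reference), `log10_fold_se`
#' @export
fold_table <- function(quant, reference = "TYP") {
  need <- c("treatment", "om_pct", "copies_gdw")
  if (!all(need %in% names(quant)))
    stop("quant must have columns: ", paste(need, collapse = ", "))
  if (!reference %in% quant$treatment)
    stop("reference treatment ", reference, " not present")
  ref <- quant[quant$treatment == reference, c("om_pct", "copies_gdw")]
  names(ref)[2] <- "ref_copies"
  merged <- merge(quant, ref, by = "om_pct")
  merged$log10_fold <- log10(merged$copies_gdw / merged$ref_copies)
  sp <- split(merged, merged$treatment)
  out <- do.call(rbind, lapply(sp, function(d) {
    lf <- d$log10_fold
    data.frame(treatment = d$treatment[1],
               n_levels = length(lf),
               fold_vs_ref = 10^mean(lf),
               deficit = 10^(-mean(lf)),
               log10_fold_se = if (length(lf) > 1)
                 stats::sd(lf) / sqrt(length(lf)) else 0,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
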