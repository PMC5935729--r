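# Fluorescence EEM processing: container, inner-filter correction, CSV
# interchange, and the relative phenol index. The PARAFAC fitting machinery
# lives in parafac.R.

#' EEM cube container
#'
#' Holds a sample x excitation x emission fluorescence intensity array with
#' per-sample absorbance spectra and porewater DOC concentrations.
#'
#' @param intensity numeric array, `n_samples x n_ex x n_em`
#' @param ex excitation wavelength grid (nm), strictly increasing
#' @param em emission wavelength grid (nm), strictly increasing
#' @param sample_ids character sample identifiers
#' @param meta data.frame of per-sample metadata; must contain `sample` and,
#'   for [phenol_index()], `doc_mg_L`
#' @param absorbance optional matrix `n_samples x length(abs_wl)` of
#'   dimensionless absorbance (1 cm pathlength)
#' @param abs_wl wavelength grid of `absorbance` (nm); must cover the
#'   excitation and emission grids for inner-filter correction
#' @return an object of class `eem_cube`
#' @export
eem_cube <- function(intensity, ex, em, sample_ids = NULL, meta = NULL,
                     absorbance = NULL, abs_wl = NULL) {
  stopifnot(is.array(intensity), length(dim(intensity)) == 3)
  d <- dim(intensity)
  if (d[2] != length(ex) || d[3] != length(em))
    stop("intensity dimensions must match ex/em grids")
  if (any(diff(ex) <= 0) || any(diff(em) <= 0))
    stop("wavelength grids must be strictly increasing")
  if (any(!is.finite(intensity) & !is.na(intensity)))
    stop("intensities must be finite or NA")
  if (is.null(sample_ids)) sample_ids <- sprintf("S%03d", seq_len(d[1]))
  stopifnot(length(sample_ids) == d[1])
  if (!is.null(absorbance)) {
    absorbance <- as.matrix(absorbance)
    if (nrow(absorbance) != d[1] || ncol(absorbance) != length(abs_wl))
      stop("absorbance must be n_samples x length(abs_wl)")
  }
  if (!is.null(meta) && !is.null(meta$doc_mg_L) && any(meta$doc_mg_L < 0))
    stop("DOC must be nonnegative")
  structure(list(intensity = intensity, ex = ex, em = em,
                 sample_ids = sample_ids, meta = meta,
                 absorbance = absorbance, abs_wl = abs_wl),
            class = "eem_cube")
}

#' @export
print.eem_cube <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("eem_cube: %d samples, %d excitation x %d emission (%g-%g / %g-%g nm)\n",
              d[1], d[2], d[3], min(x$ex), max(x$ex), min(x$em), max(x$em)))
  cat(sprintf("  absorbance: %s; DOC: %s\n",
              if (is.null(x$absorbance)) "none" else "present",
              if (is.null(x$meta$doc_mg_L)) "none" else "present"))
  invisible(x)
}

#' Inner-filter correction of an EEM cube
#'
#' Multiplies each intensity by `10^((A(ex) + A(em)) / 2)`, the standard
#' absorbance-based correction for primary and secondary inner-filter
#' attenuation in a 1 cm cuvette. Absorbance is linearly interpolated onto
#' the excitation and emission grids. Samples whose maximum absorbance
#' exceeds 1.5 are beyond the approximation's validity and are flagged in
#' the returned cube's `ife_flagged` field (not dropped).
#'
#' @param cube an [eem_cube()] with absorbance spectra
#' @return the corrected cube; `ife_flagged` holds the flagged sample ids
#' @export
inner_filter_correct <- function(cube) {
  stopifnot(inherits(cube, "eem_cube"))
  if (is.null(cube$absorbance))
    stop("cube has no absorbance spectra; cannot correct inner-filter effects")
  if (min(cube$abs_wl) > min(cube$ex) || max(cube$abs_wl) < max(cube$em))
    stop("absorbance grid must cover the excitation and emission ranges")
  n <- dim(cube$intensity)[1]
  flagged <- character(0)
  for (i in seq_len(n)) {
    a <- cube$absorbance[i, ]
    if (anyNA(a)) stop("sample ", cube$sample_ids[i], " has missing absorbance")
    a_ex <- stats::approx(cube$abs_wl, a, cube$ex)$y
    a_em <- stats::approx(cube$abs_wl, a, cube$em)$y
    cube$intensity[i, , ] <- cube$intensity[i, , ] *
      10^(outer(a_ex, a_em, `+`) / 2)
    if (max(a) > 1.5) flagged <- c(flagged, cube$sample_ids[i])
  }
  cube$ife_flagged <- flagged
  cube
}

#' Tucker congruence coefficient
#'
#' Cosine similarity between two loading vectors, the standard measure for
#' matching fluorescence components across fits.
#'
#' @param x,y numeric vectors of equal length
#' @return congruence in \[-1, 1\]
#' @export
tucker_congruence <- function(x, y) {
  stopifnot(length(x) == length(y))
  sum(x * y) / sqrt(sum(x^2) * sum(y^2))
}

# congruence on concatenated excitation+emission loadings, all pairs
.congruence_matrix <- function(ex1, em1, ex2, em2) {
  f1 <- ncol(ex1); f2 <- ncol(ex2)
  outer(seq_len(f1), seq_len(f2),
        Vectorize(function(a, b)
          tucker_congruence(c(ex1[, a], em1[, a]), c(ex2[, b], em2[, b]))))
}

# greedy bijective matching by decreasing congruence; ties by row then column
.greedy_match <- function(cong) {
  n <- min(nrow(cong), ncol(cong))
  rows <- integer(n); cols <- integer(n); vals <- numeric(n)
  cc <- cong
  for (k in seq_len(n)) {
    idx <- which(cc == max(cc, na.rm = TRUE), arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE][1, ]
    rows[k] <- idx[1]; cols[k] <- idx[2]; vals[k] <- cc[idx[1], idx[2]]
    cc[idx[1], ] <- -Inf; cc[, idx[2]] <- -Inf
  }
  o <- order(rows)
  data.frame(component = rows[o], ref = cols[o], congruence = vals[o])
}

#' Match fitted components to reference spectra
#'
#' Assigns each fitted component the reference label that maximizes Tucker
#' congruence of the concatenated excitation+emission loadings against
#' Gaussian reference profiles, as a bijection (greedy, highest congruence
#' first, ties broken by component index). Also reports each component's
#' fitted peak wavelengths (grid argmax of the loadings).
#'
#' @param model a [fit_parafac()] model
#' @param ref a [reference_spectra()] table
#' @return data.frame with one row per fitted component: `component`,
#'   `label`, `kind`, `congruence`, `ex_peak_fit`, `em_peak_fit`
#' @export
match_components <- function(model, ref = reference_spectra()) {
  stopifnot(inherits(model, "parafac_model"))
  rex <- vapply(seq_len(nrow(ref)),
                function(f) .gauss_profile(model$ex, ref$ex_peak[f], ref$ex_sigma[f]),
                numeric(length(model$ex)))
  rem <- vapply(seq_len(nrow(ref)),
                function(f) .gauss_profile(model$em, ref$em_peak[f], ref$em_sigma[f]),
                numeric(length(model$em)))
  cong <- .congruence_matrix(model$ex_loadings, model$em_loadings, rex, rem)
  m <- .greedy_match(cong)
  data.frame(component = m$component,
             label = ref$label[m$ref],
             kind = ref$kind[m$ref],
             congruence = m$congruence,
             ex_peak_fit = model$ex[apply(model$ex_loadings[, m$component,
                                                            drop = FALSE], 2, which.max)],
             em_peak_fit = model$em[apply(model$em_loadings[, m$component,
                                                            drop = FALSE], 2, which.max)],
             stringsAsFactors = FALSE)
}

#' Relative phenol index per sample
#'
#' The relative phenol-leachate concentration of each sample: the proportion
#' of total fitted fluorescence carried by the phenol-associated component
#' multiplied by the porewater DOC concentration.
#'
#' @param model a [fit_parafac()] model fitted to `cube`
#' @param cube the [eem_cube()] the model was fitted to (supplies DOC)
#' @param ref reference spectra used to identify the phenol component
#' @param phenol_label reference label of the phenol-leachate component
#' @return data.frame with `sample`, `proportion` (phenol share of total
#'   score, 0 when all scores are 0), `doc_mg_L`, `phenol_index`
#' @export
phenol_index <- function(model, cube, ref = reference_spectra(),
                         phenol_label = "C5") {
  stopifnot(inherits(model, "parafac_model"), inherits(cube, "eem_cube"))
  if (is.null(cube$meta$doc_mg_L))
    stop("cube metadata must contain doc_mg_L")
  if (nrow(model$scores) != length(cube$sample_ids))
    stop("model and cube sample counts differ")
  matched <- match_components(model, ref)
  comp <- matched$component[matched$label == phenol_label]
  if (length(comp) != 1)
    stop("no component matched to label ", phenol_label)
  tot <- rowSums(model$scores)
  prop <- ifelse(tot > 0, model$scores[, comp] / tot, 0)
  data.frame(sample = cube$sample_ids,
             proportion = prop,
             doc_mg_L = cube$meta$doc_mg_L,
             phenol_index = prop * cube$meta$doc_mg_L,
             stringsAsFactors = FALSE)
}

#' Write / read an EEM cube as per-sample CSV files
#'
#' The interchange format: one CSV per sample with emission wavelengths as
#' rows and excitation wavelengths as columns, plus `manifest.csv` listing
#' each sample's file, DOC and absorbance file, and `absorbance_<id>.csv`
#' sidecars (wavelength, absorbance).
#'
#' @param cube an [eem_cube()]
#' @param dir output / input directory
#' @return `write_eem_csv` returns `dir` invisibly; `read_eem_csv` returns
#'   an [eem_cube()]
#' @export
write_eem_csv <- function(cube, dir) {
  stopifnot(inherits(cube, "eem_cube"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  doc <- if (!is.null(cube$meta$doc_mg_L)) cube$meta$doc_mg_L else
    rep(NA_real_, length(cube$sample_ids))
  manifest <- data.frame(sample = cube$sample_ids,
                         eem_file = paste0("eem_", cube$sample_ids, ".csv"),
                         doc_mg_L = doc,
                         abs_file = if (is.null(cube$absorbance)) NA_character_ else
                           paste0("absorbance_", cube$sample_ids, ".csv"),
                         stringsAsFactors = FALSE)
  for (i in seq_along(cube$sample_ids)) {
    m <- t(cube$intensity[i, , ])  # emission rows, excitation cols
    df <- data.frame(em_nm = cube$em, m)
    names(df)[-1] <- paste0("ex_", cube$ex)
    utils::write.csv(df, file.path(dir, manifest$eem_file[i]), row.names = FALSE)
    if (!is.null(cube$absorbance))
      utils::write.csv(data.frame(wl_nm = cube$abs_wl,
                                  absorbance = cube$absorbance[i, ]),
                       file.path(dir, manifest$abs_file[i]), row.names = FALSE)
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_eem_csv
#' @export
read_eem_csv <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  first <- utils::read.csv(file.path(dir, manifest$eem_file[1]),
                           check.names = FALSE)
  em <- first[[1]]
  ex <- as.numeric(sub("^ex_", "", names(first)[-1]))
  n <- nrow(manifest)
  X <- array(NA_real_, dim = c(n, length(ex), length(em)))
  absorbance <- NULL; abs_wl <- NULL
  for (i in seq_len(n)) {
    d <- utils::read.csv(file.path(dir, manifest$eem_file[i]), check.names = FALSE)
    X[i, , ] <- t(as.matrix(d[, -1]))
    if (!is.na(manifest$abs_file[i])) {
      a <- utils::read.csv(file.path(dir, manifest$abs_file[i]))
      if (is.null(absorbance)) {
        abs_wl <- a[[1]]
        absorbance <- matrix(NA_real_, n, length(abs_wl))
      }
      absorbance[i, ] <- a[[2]]
    }
  }
  eem_cube(X, ex, em, sample_ids = manifest$sample,
           meta = data.frame(sample = manifest$sample,
                             doc_mg_L = manifest$doc_mg_L,
                             stringsAsFactors = FALSE),
           absorbance = absorbance, abs_wl = abs_wl)
}
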