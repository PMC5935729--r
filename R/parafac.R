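# Nonnegative PARAFAC (trilinear CP decomposition) by hierarchical
# alternating least squares, with multi-start initialization, missing-value
# imputation (for scatter-excised cubes), and split-half validation.

# column-wise Khatri-Rao product; rows of Q cycle fastest
.khatri_rao <- function(P, Q) {
  P[rep(seq_len(nrow(P)), each = nrow(Q)), , drop = FALSE] *
    Q[rep.int(seq_len(nrow(Q)), nrow(P)), , drop = FALSE]
}

# one HALS pass over the columns of factor `Fac` given the mode's MTTKRP
# `P = X_(mode) %*% KR` and Gram matrix `G`; each column update solves the
# nonnegative least-squares subproblem exactly, so the objective cannot rise
.hals_update <- function(Fac, P, G) {
  for (f in seq_len(ncol(Fac))) {
    gff <- G[f, f]
    if (gff < 1e-14) next
    Fac[, f] <- pmax(0, Fac[, f] + (P[, f] - Fac %*% G[, f]) / gff)
  }
  Fac
}

# random localized spectral bumps: a better-conditioned initialization for
# fluorescence loadings than dense uniform noise, which tends to collapse
# heavily overlapping components into one
.bump_init <- function(grid, ncomp) {
  vapply(seq_len(ncomp), function(f) {
    peak <- stats::runif(1, min(grid), max(grid))
    width <- stats::runif(1, 10, 40)
    exp(-(grid - peak)^2 / (2 * width^2))
  }, numeric(length(grid)))
}

#' Fit a nonnegative PARAFAC model to an EEM cube
#'
#' Decomposes the sample x excitation x emission array into `ncomp`
#' trilinear components `X[i,j,k] ~ sum_f A[i,f] B[j,f] C[k,f]` with all
#' factors nonnegative, by hierarchical alternating least squares (each
#' factor column update solves its nonnegative subproblem exactly, so the
#' residual sum of squares is non-increasing across iterations). The first
#' start initializes the spectral loadings from the singular vectors of the
#' mode unfoldings; the remaining `nstart - 1` starts use random localized
#' Gaussian bumps, which separate strongly overlapping fluorophores far more
#' reliably than dense random noise. The best start by explained variance is
#' kept; results are deterministic given `seed`. Missing intensities (NA,
#' e.g. from scatter excision) are handled by expectation-style imputation
#' from the current model at every iteration.
#'
#' After fitting, excitation and emission loading columns are rescaled to
#' unit maximum and the magnitude is pushed into the sample scores;
#' components are ordered by decreasing total score. The reconstruction is
#' invariant under this renormalization.
#'
#' @param cube an [eem_cube()] (or a bare 3-d array)
#' @param ncomp number of components, >= 1; needs at least `2 * ncomp`
#'   samples
#' @param nstart random initializations
#' @param tol convergence tolerance on the change in fit
#'   (1 - SSE/SS_total) between iterations
#' @param maxit maximum ALS iterations per start
#' @param seed integer seed for the initializations
#' @return an object of class `parafac_model`: `scores` (n x F),
#'   `ex_loadings` (J x F, unit-max columns), `em_loadings` (K x F),
#'   `expvar` (explained variance fraction), `fit_history` of the best
#'   start, `converged`, `iterations`, and the grids `ex`, `em`
#' @export
fit_parafac <- function(cube, ncomp, nstart = 10, tol = 1e-9, maxit = 5000,
                        seed = 1L) {
  X <- if (inherits(cube, "eem_cube")) cube$intensity else cube
  stopifnot(is.array(X), length(dim(X)) == 3, ncomp >= 1)
  d <- dim(X); I <- d[1]; J <- d[2]; K <- d[3]
  if (I < 2 * ncomp)
    stop("need at least 2 * ncomp samples (", 2 * ncomp, "), have ", I)

  has_na <- anyNA(X)
  na_idx <- if (has_na) which(is.na(X)) else integer(0)
  if (has_na) X[na_idx] <- mean(X, na.rm = TRUE)

  # unfoldings (recomputed per imputation pass when NAs are present)
  unfold <- function(X) list(
    X1 = matrix(X, I, J * K),                      # cols (j,k), j fastest
    X2 = matrix(aperm(X, c(2, 1, 3)), J, I * K),   # cols (i,k), i fastest
    X3 = matrix(aperm(X, c(3, 1, 2)), K, I * J))   # cols (i,j), i fastest
  U <- unfold(X)
  ssx <- sum(X^2)

  ex_grid <- if (inherits(cube, "eem_cube")) cube$ex else seq_len(J)
  em_grid <- if (inherits(cube, "eem_cube")) cube$em else seq_len(K)

  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  for (s in seq_len(nstart)) {
    if (s == 1) {
      B <- abs(svd(U$X2, nu = ncomp)$u[, seq_len(ncomp), drop = FALSE])
      C <- abs(svd(U$X3, nu = ncomp)$u[, seq_len(ncomp), drop = FALSE])
    } else {
      B <- .bump_init(ex_grid, ncomp)
      C <- .bump_init(em_grid, ncomp)
    }
    # scores from the exact least-squares solve given the initial loadings
    G0 <- crossprod(B) * crossprod(C)
    A <- pmax(U$X1 %*% .khatri_rao(C, B) %*% solve(G0 + 1e-12 * diag(ncomp)), 0)
    fit_hist <- numeric(0)
    fit_old <- -Inf
    converged <- FALSE
    for (it in seq_len(maxit)) {
      A <- .hals_update(A, U$X1 %*% .khatri_rao(C, B),
                        crossprod(B) * crossprod(C))
      B <- .hals_update(B, U$X2 %*% .khatri_rao(C, A),
                        crossprod(A) * crossprod(C))
      P3 <- U$X3 %*% .khatri_rao(B, A)
      C <- .hals_update(C, P3, crossprod(A) * crossprod(B))
      ss_model <- sum(crossprod(A) * crossprod(B) * crossprod(C))
      sse <- ssx - 2 * sum(C * P3) + ss_model
      fit <- 1 - sse / ssx
      fit_hist <- c(fit_hist, fit)
      if (has_na) {
        Xhat_na <- .cp_reconstruct_at(A, B, C, na_idx, c(I, J, K))
        X[na_idx] <- Xhat_na
        U <- unfold(X)
        ssx <- sum(X^2)
      }
      if (is.finite(fit_old) && abs(fit - fit_old) < tol) {
        converged <- TRUE
        break
      }
      fit_old <- fit
    }
    if (is.null(best) || fit > best$fit) {
      best <- list(A = A, B = B, C = C, fit = fit, fit_hist = fit_hist,
                   converged = converged, iterations = length(fit_hist))
    }
    if (has_na) { X[na_idx] <- mean(X[-na_idx]); U <- unfold(X); ssx <- sum(X^2) }
  }

  A <- best$A; B <- best$B; C <- best$C
  bmax <- pmax(apply(B, 2, max), 1e-300)
  cmax <- pmax(apply(C, 2, max), 1e-300)
  B <- sweep(B, 2, bmax, "/")
  C <- sweep(C, 2, cmax, "/")
  A <- sweep(A, 2, bmax * cmax, "*")
  ord <- order(colSums(A), decreasing = TRUE)
  structure(list(scores = A[, ord, drop = FALSE],
                 ex_loadings = B[, ord, drop = FALSE],
                 em_loadings = C[, ord, drop = FALSE],
                 ncomp = ncomp,
                 expvar = best$fit,
                 fit_history = best$fit_hist,
                 converged = best$converged,
                 iterations = best$iterations,
                 nstart = nstart,
                 ex = if (inherits(cube, "eem_cube")) cube$ex else seq_len(J),
                 em = if (inherits(cube, "eem_cube")) cube$em else seq_len(K)),
            class = "parafac_model")
}

# model values at a subset of linear array indices
.cp_reconstruct_at <- function(A, B, C, idx, d) {
  i <- (idx - 1) %% d[1] + 1
  j <- ((idx - 1) %/% d[1]) %% d[2] + 1
  k <- (idx - 1) %/% (d[1] * d[2]) + 1
  rowSums(A[i, , drop = FALSE] * B[j, , drop = FALSE] * C[k, , drop = FALSE])
}

#' @export
print.parafac_model <- function(x, ...) {
  cat(sprintf("parafac_model: %d components, %.4f%% variance explained\n",
              x$ncomp, 100 * x$expvar))
  cat(sprintf("  %s after %d iterations (best of %d starts)\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$nstart))
  pk_ex <- x$ex[apply(x$ex_loadings, 2, which.max)]
  pk_em <- x$em[apply(x$em_loadings, 2, which.max)]
  cat("  peaks (ex/em nm): ",
      paste(sprintf("%g/%g", pk_ex, pk_em), collapse = ", "), "\n")
  invisible(x)
}

#' Reconstruct the fitted EEM cube from a PARAFAC model
#'
#' @param model a [fit_parafac()] model
#' @return array n x J x K of fitted intensities
#' @export
parafac_fitted <- function(model) {
  stopifnot(inherits(model, "parafac_model"))
  I <- nrow(model$scores); J <- nrow(model$ex_loadings)
  K <- nrow(model$em_loadings)
  X1 <- model$scores %*% t(.khatri_rao(model$em_loadings, model$ex_loadings))
  array(X1, dim = c(I, J, K))
}

#' Split-half validation of a PARAFAC model
#'
#' Splits the samples into random halves, fits each half independently, and
#' matches components across halves by Tucker congruence of the concatenated
#' excitation+emission loadings. A component structure is validated when the
#' minimum matched congruence across all splits reaches the threshold.
#'
#' @param cube an [eem_cube()]
#' @param ncomp components to fit
#' @param n_splits random half-half splits
#' @param threshold minimum Tucker congruence to pass
#' @param nstart,tol,maxit passed to [fit_parafac()]
#' @param seed seed for the splits and fits
#' @return list with `splits` (per split: matched congruence per component),
#'   `min_congruence`, and `pass`
#' @export
split_half_validate <- function(cube, ncomp, n_splits = 2, threshold = 0.95,
                                nstart = 10, tol = 1e-9, maxit = 5000,
                                seed = 1L) {
  stopifnot(inherits(cube, "eem_cube"))
  n <- dim(cube$intensity)[1]
  if (n < 4 * ncomp)
    warning("fewer than 2*ncomp samples per half; split fits may be unstable")
  set.seed(seed)
  take <- function(idx) {
    eem_cube(cube$intensity[idx, , , drop = FALSE], cube$ex, cube$em,
             sample_ids = cube$sample_ids[idx])
  }
  splits <- vector("list", n_splits)
  for (s in seq_len(n_splits)) {
    perm <- sample.int(n)
    h1 <- sort(perm[seq_len(n %/% 2)])
    h2 <- sort(perm[(n %/% 2 + 1):n])
    f1 <- fit_parafac(take(h1), ncomp, nstart = nstart, tol = tol,
                      maxit = maxit, seed = seed + 100 * s)
    f2 <- fit_parafac(take(h2), ncomp, nstart = nstart, tol = tol,
                      maxit = maxit, seed = seed + 100 * s + 1)
    cong <- .congruence_matrix(f1$ex_loadings, f1$em_loadings,
                               f2$ex_loadings, f2$em_loadings)
    splits[[s]] <- .greedy_match(cong)
  }
  min_cong <- min(vapply(splits, function(m) min(m$congruence), numeric(1)))
  list(splits = splits, min_congruence = min_cong,
       pass = min_cong >= threshold)
}

#' Excise first-order Rayleigh scatter from an EEM cube
#'
#' Masks (sets to NA) intensities within `width` nm of the first-order
#' Rayleigh line (emission = excitation). [fit_parafac()] treats the masked
#' region as missing data.
#'
#' @param cube an [eem_cube()]
#' @param width half-width of the excised band (nm)
#' @return the cube with the scatter band set to NA
#' @export
excise_scatter <- function(cube, width = 10) {
  stopifnot(inherits(cube, "eem_cube"), width >= 0)
  band <- abs(outer(cube$ex, cube$em, function(x, m) m - x)) <= width
  for (i in seq_len(dim(cube$intensity)[1])) {
    sl <- cube$intensity[i, , ]
    sl[band] <- NA_real_
    cube$intensity[i, , ] <- sl
  }
  cube
}
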