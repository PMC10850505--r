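#' Back-calculate a SAXS profile from a bead model (Debye formula)
#'
#' Evaluates the Debye double sum over all bead pairs with constant per-bead
#' form factors,
#' \deqn{I(q) = \sum_i \sum_j f_i f_j \frac{\sin(q d_{ij})}{q d_{ij}},}
#' so that \eqn{I(0) = (\sum_i f_i)^2}. No hydration shell or excluded-volume
#' term is applied: the reduced bead representation is used consistently on
#' both the "experimental" (synthetic) and calculated sides of the pipeline.
#'
#' @param model a [conformer_model()].
#' @param q_grid increasing non-negative q grid (1/A), or a
#'   [scattering_curve()] whose grid is reused.
#' @return A [scattering_curve()] without sigma.
#' @export
compute_profile <- function(model, q_grid) {
  stopifnot(inherits(model, "conformer_model"))
  if (inherits(q_grid, "scattering_curve")) q_grid <- q_grid$q
  q_grid <- as.numeric(q_grid)
  if (any(!is.finite(q_grid)) || any(q_grid < 0) || any(diff(q_grid) <= 0))
    stop("q_grid must be finite, non-negative and strictly increasing")
  I <- debye_profile_cpp(model$points, model$weights, q_grid)
  scattering_curve(q_grid, I)
}

#' Average scattering curves over an ensemble
#'
#' Pointwise (weighted) mean of member curves; with the default uniform
#' weights this is \eqn{I(q) = \frac{1}{N}\sum_{n=1}^N I_n(q)}.
#'
#' @param curves list of [scattering_curve()] on one common q grid.
#' @param weights optional non-negative weights summing to 1 (default uniform).
#' @return A [scattering_curve()] without sigma.
#' @export
ensemble_profile <- function(curves, weights = NULL) {
  if (length(curves) < 1L) stop("empty curve list")
  q <- curves[[1]]$q
  for (cu in curves) {
    if (!inherits(cu, "scattering_curve")) stop("curves must be scattering_curve objects")
    if (!same_grid(cu, curves[[1]])) stop("curves are not on a common q grid")
  }
  if (is.null(weights)) weights <- rep(1 / length(curves), length(curves))
  weights <- as.numeric(weights)
  if (length(weights) != length(curves)) stop("weights length must match curves")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  Im <- vapply(curves, function(cu) cu$I, numeric(length(q)))
  scattering_curve(q, as.vector(Im %*% weights))
}

#' Optimal intensity scale factor between calculated and experimental curves
#'
#' Closed-form least-squares minimizer over the scale \eqn{\mu} of the
#' uncertainty-weighted discrepancy:
#' \deqn{\mu = \frac{\sum_k I_{calc,k} I_{exp,k}/\sigma_k^2}
#'                  {\sum_k I_{calc,k}^2/\sigma_k^2}.}
#'
#' @param calc calculated [scattering_curve()].
#' @param exp experimental [scattering_curve()] with sigma, same grid.
#' @return The scalar scale factor.
#' @export
optimal_scale <- function(calc, exp) {
  stopifnot(inherits(calc, "scattering_curve"), inherits(exp, "scattering_curve"))
  if (is.null(exp$sigma)) stop("experimental curve must carry sigma")
  if (!same_grid(calc, exp)) stop("q grids differ")
  w <- 1 / exp$sigma^2
  denom <- sum(calc$I^2 * w)
  if (denom <= 0) stop("calculated curve is identically zero; scale undefined")
  sum(calc$I * exp$I * w) / denom
}

#' Chi-square goodness of fit between calculated and experimental curves
#'
#' \deqn{\chi^2 = \frac{1}{K-1}\sum_{i=1}^{K}
#'   \left[\frac{\mu I(q_i) - I_{exp}(q_i)}{\sigma(q_i)}\right]^2}
#' with K experimental points. When `mu` is omitted it is set to the analytic
#' optimum from [optimal_scale()]. Residuals are stored in the
#' \eqn{(\mu I_{calc} - I_{exp})/\sigma} sign convention (the numerator of the
#' statistic); the display convention \eqn{(I_{exp} - I_{calc})/\sigma} is
#' provided by [residual_plot_data()].
#'
#' @param calc calculated [scattering_curve()].
#' @param exp experimental [scattering_curve()] with sigma, same grid.
#' @param mu optional fixed scale factor.
#' @return An object of class `fit_result`: list with `mu`, `chi2`, `K`,
#'   `residuals`.
#' @export
saxs_chi2 <- function(calc, exp, mu = NULL) {
  stopifnot(inherits(calc, "scattering_curve"), inherits(exp, "scattering_curve"))
  if (is.null(exp$sigma)) stop("experimental curve must carry sigma")
  if (!same_grid(calc, exp)) stop("q grids differ")
  K <- length(exp$q)
  if (K < 2L) stop("need at least 2 experimental points")
  if (is.null(mu)) mu <- optimal_scale(calc, exp)
  res <- (mu * calc$I - exp$I) / exp$sigma
  structure(list(mu = mu, chi2 = sum(res^2) / (K - 1), K = K, residuals = res),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result: chi2 = %.4f, mu = %.4g, K = %d>\n", x$chi2, x$mu, x$K))
  invisible(x)
}

#' Radius of gyration from bead coordinates
#'
#' Weight-weighted RMS distance from the weighted centroid.
#'
#' @param model a [conformer_model()].
#' @return Rg in Angstrom.
#' @export
rg_from_coords <- function(model) {
  stopifnot(inherits(model, "conformer_model"))
  w <- model$weights
  W <- sum(w)
  if (W <= 0) stop("all-zero weights; Rg undefined")
  ctr <- colSums(model$points * w) / W
  d2 <- rowSums(sweep(model$points, 2, ctr)^2)
  sqrt(sum(w * d2) / W)
}

#' Guinier fit of the low-q region
#'
#' Linear fit of log(I) against q^2 on the largest low-q window satisfying
#' q*Rg <= `qrg_max`, iterated to self-consistency (the window is recomputed
#' from the fitted Rg and the fit repeated). Returns
#' \eqn{R_g = \sqrt{-3\,\mathrm{slope}}} and \eqn{I_0 = e^{\mathrm{intercept}}}.
#'
#' @param curve a [scattering_curve()] with positive low-q intensities.
#' @param qrg_max Guinier-validity bound on q*Rg (default 1.3, the community
#'   standard for globular scatterers).
#' @param n_iter number of window-update iterations (default 2).
#' @param min_points minimum points in the fit window.
#' @return An object of class `guinier_fit`: list with `rg`, `i0`, `q_range`,
#'   `n_points`, `nonglobular` (flag set when the slope is non-negative).
#' @export
guinier_fit <- function(curve, qrg_max = 1.3, n_iter = 2, min_points = 5) {
  stopifnot(inherits(curve, "scattering_curve"))
  pos <- curve$I > 0
  if (sum(pos[seq_len(min(length(pos), min_points))]) < min_points)
    stop("no valid low-q window: need >= ", min_points, " leading points with I > 0")
  fit_window <- function(idx) {
    stats::lm.fit(cbind(1, curve$q[idx]^2), log(curve$I[idx]))$coefficients
  }
  idx <- which(pos)[seq_len(min_points)]
  cf <- fit_window(idx)
  for (it in seq_len(n_iter)) {
    if (cf[2] >= 0) break
    rg <- sqrt(-3 * cf[2])
    idx <- which(pos & curve$q * rg <= qrg_max)
    if (length(idx) < min_points) idx <- which(pos)[seq_len(min_points)]
    cf <- fit_window(idx)
  }
  nonglobular <- cf[2] >= 0
  rg <- if (nonglobular) NA_real_ else sqrt(-3 * cf[2])
  structure(list(rg = unname(rg), i0 = unname(exp(cf[1])),
                 q_range = range(curve$q[idx]), n_points = length(idx),
                 nonglobular = nonglobular),
            class = "guinier_fit")
}

#' Pair-distance distribution function of one or more bead models
#'
#' Weight-product histogram of all inter-bead distances (ordered pairs, i != j)
#' pooled over the supplied models, normalized to unit trapezoid integral.
#' `dmax` is the maximum pairwise distance over all models and the density is
#' zero beyond it.
#'
#' @param models list of [conformer_model()] (a single model may be passed
#'   directly).
#' @param n_bins number of histogram bins over \[0, dmax\] (default 100).
#' @return An object of class `pddf`: list with `r` (bin centers), `p`
#'   (densities), `dmax`.
#' @export
pddf_model <- function(models, n_bins = 100) {
  if (inherits(models, "conformer_model")) models <- list(models)
  if (length(models) < 1L) stop("empty model list")
  dists <- list(); wprod <- list()
  for (m in models) {
    stopifnot(inherits(m, "conformer_model"))
    n <- n_points(m)
    if (n < 2L) next
    d <- as.vector(stats::dist(m$points))
    ij <- utils::combn(n, 2)
    dists[[length(dists) + 1L]] <- d
    wprod[[length(wprod) + 1L]] <- m$weights[ij[1, ]] * m$weights[ij[2, ]]
  }
  if (length(dists) == 0L) stop("no pairs: all models have fewer than 2 points")
  d <- unlist(dists); w <- unlist(wprod)
  dmax <- max(d)
  breaks <- seq(0, dmax, length.out = n_bins + 1L)
  bin <- pmin(findInterval(d, breaks, rightmost.closed = TRUE), n_bins)
  p <- as.numeric(tapply(w, factor(bin, levels = seq_len(n_bins)), sum))
  p[is.na(p)] <- 0
  r <- (breaks[-1] + breaks[-length(breaks)]) / 2
  # normalize to unit trapezoid integral over the bin-center grid
  integ <- sum(diff(r) * (p[-1] + p[-length(p)]) / 2)
  structure(list(r = r, p = p / integ, dmax = dmax), class = "pddf")
}

#' Kratky transform of a scattering curve
#'
#' Replaces the ordinate by q^2 I(q) (sigma propagated as q^2 sigma).
#' Compact globular scatterers show a peaked transform; expanded or
#' disordered chains plateau or rise at high q.
#'
#' @param curve a [scattering_curve()].
#' @return A [scattering_curve()] holding q^2 I(q).
#' @export
kratky_transform <- function(curve) {
  stopifnot(inherits(curve, "scattering_curve"))
  scattering_curve(curve$q, curve$q^2 * curve$I,
                   if (is.null(curve$sigma)) NULL else curve$q^2 * curve$sigma)
}

# ---- NSD superposition -------------------------------------------------

rotation_from_angles <- function(ang) {
  ca <- cos(ang); sa <- sin(ang)
  Rz1 <- matrix(c(ca[1], -sa[1], 0, sa[1], ca[1], 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Ry  <- matrix(c(ca[2], 0, sa[2], 0, 1, 0, -sa[2], 0, ca[2]), 3, 3, byrow = TRUE)
  Rz2 <- matrix(c(ca[3], -sa[3], 0, sa[3], ca[3], 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Rz1 %*% Ry %*% Rz2
}

mean_nn_dist <- function(pts) {
  dm <- as.matrix(stats::dist(pts))
  diag(dm) <- Inf
  mean(apply(dm, 1, min))
}

nsd_of_points <- function(A, B, dA2, dB2) {
  # normalized spatial discrepancy between two placed point sets
  cross <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  cross[cross < 0] <- 0
  sqrt(0.5 * (mean(apply(cross, 1, min)) / dB2 + mean(apply(cross, 2, min)) / dA2))
}

nsd_best_oriented <- function(A, B, dA2, dB2) {
  # principal-axes alignments (4 proper flips) x both enantiomers,
  # then local refinement over rotation angles + translation
  cA <- colMeans(A); cB <- colMeans(B)
  A0 <- sweep(A, 2, cA); B0 <- sweep(B, 2, cB)
  VA <- eigen(crossprod(A0) / nrow(A0), symmetric = TRUE)$vectors
  VB <- eigen(crossprod(B0) / nrow(B0), symmetric = TRUE)$vectors
  if (det(VA) < 0) VA[, 3] <- -VA[, 3]
  if (det(VB) < 0) VB[, 3] <- -VB[, 3]
  flips <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  best <- list(nsd = Inf, R = diag(3), t = c(0, 0, 0))
  for (mirror in c(1, -1)) {
    Bm <- B0
    Bm[, 1] <- mirror * Bm[, 1]
    for (f in flips) {
      R <- VA %*% diag(f) %*% t(VB)
      v <- nsd_of_points(A0, Bm %*% t(R), dA2, dB2)
      if (v < best$nsd) best <- list(nsd = v, R = R, mirror = mirror)
    }
  }
  # local refinement: Euler angles applied after the best coarse rotation,
  # plus a translation
  Bm <- B0
  Bm[, 1] <- best$mirror * Bm[, 1]
  obj <- function(par) {
    R <- rotation_from_angles(par[1:3]) %*% best$R
    nsd_of_points(A0, sweep(Bm %*% t(R), 2, par[4:6], "+"), dA2, dB2)
  }
  opt <- stats::optim(c(0, 0, 0, 0, 0, 0), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  list(nsd = min(opt$value, best$nsd),
       rotation = rotation_from_angles(opt$par[1:3]) %*% best$R,
       translation = opt$par[4:6], mirror = best$mirror,
       center_a = cA, center_b = cB)
}

#' Superpose two bead models and compute their normalized spatial discrepancy
#'
#' Rigid-body superposition minimizing the normalized spatial discrepancy
#' (NSD),
#' \deqn{NSD(A,B) = \sqrt{\tfrac12\left[\frac{1}{N_A d_B^2}\sum_i
#'   \min_j d^2(a_i, b_j) + \frac{1}{N_B d_A^2}\sum_j \min_i d^2(b_j, a_i)
#'   \right]}}
#' with \eqn{d_A, d_B} the mean nearest-neighbour distances within each model.
#' The search covers the principal-axes alignments, their four proper flips and
#' both enantiomers, followed by local Nelder-Mead refinement over rotation and
#' translation. The value is symmetrized over argument order, so
#' `align_and_nsd(a, b)` and `align_and_nsd(b, a)` agree exactly.
#'
#' @param a,b [conformer_model()] objects with at least 2 non-collinear points.
#' @return List with `nsd` and `transform` (rotation, translation, mirror flag,
#'   the centroids removed before rotation, and which argument order won the
#'   symmetrized search).
#' @export
align_and_nsd <- function(a, b) {
  stopifnot(inherits(a, "conformer_model"), inherits(b, "conformer_model"))
  A <- a$points; B <- b$points
  if (nrow(A) < 2L || nrow(B) < 2L) stop("models must have >= 2 points")
  if (nrow(A) > 2L && qr(sweep(A, 2, colMeans(A)))$rank < 2) stop("model 'a' is degenerate")
  if (nrow(B) > 2L && qr(sweep(B, 2, colMeans(B)))$rank < 2) stop("model 'b' is degenerate")
  dA2 <- mean_nn_dist(A)^2
  dB2 <- mean_nn_dist(B)^2
  ab <- nsd_best_oriented(A, B, dA2, dB2)
  ba <- nsd_best_oriented(B, A, dB2, dA2)
  if (ab$nsd <= ba$nsd) {
    list(nsd = ab$nsd, transform = c(ab[c("rotation", "translation", "mirror",
                                          "center_a", "center_b")],
                                     order = "a_fixed"))
  } else {
    list(nsd = ba$nsd, transform = c(ba[c("rotation", "translation", "mirror",
                                          "center_a", "center_b")],
                                     order = "b_fixed"))
  }
}
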