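#' ITC titration protocol
#'
#' Injection schedule and concentrations for an isothermal titration
#' calorimetry experiment in which the titrant (syringe) is injected into the
#' cell species. The default schedule is a single 1 ul priming injection
#' followed by 18 injections of 2 ul.
#'
#' @param cell_volume_ul active cell volume V0 in microlitre.
#' @param cell_conc molar concentration of the species in the cell.
#' @param syringe_conc molar concentration of the injectant.
#' @param injections_ul vector of injection volumes in microlitre.
#' @return An object of class `itc_protocol`.
#' @export
itc_protocol <- function(cell_volume_ul = 200, cell_conc, syringe_conc,
                         injections_ul = c(1, rep(2, 18))) {
  stopifnot(cell_volume_ul > 0, cell_conc > 0, syringe_conc > 0,
            all(injections_ul > 0))
  structure(list(cell_volume_ul = cell_volume_ul, cell_conc = cell_conc,
                 syringe_conc = syringe_conc,
                 injections_ul = as.numeric(injections_ul)),
            class = "itc_protocol")
}

# Forward heat model shared by the simulators and the fitter.
# `bound_conc` maps (P_total, R_total) -> concentration of bound titrant;
# dilution uses the discrete displacement model: each injection of dv
# dilutes the current cell contents by (1 - dv/V0) and the measured heat is
# the heat-content increment corrected for the displaced volume,
#   dQ_i = Q_i - Q_{i-1} + (dv_i/V0) (Q_i + Q_{i-1}) / 2.
itc_forward_heats <- function(protocol, dh, bound_conc) {
  V0 <- protocol$cell_volume_ul
  dh_ucal <- dh * 1e9            # kcal/mol -> ucal/mol
  V0_l <- V0 * 1e-6              # ul -> litre
  R <- protocol$cell_conc
  P <- 0
  Qprev <- 0
  heats <- numeric(length(protocol$injections_ul))
  for (i in seq_along(protocol$injections_ul)) {
    dv <- protocol$injections_ul[i]
    f <- 1 - dv / V0
    R <- R * f
    P <- P * f + protocol$syringe_conc * dv / V0
    B <- bound_conc(P, R)
    Q <- B * V0_l * dh_ucal
    heats[i] <- Q - Qprev + (dv / V0) * (Q + Qprev) / 2
    Qprev <- Q
  }
  heats
}

single_site_bound <- function(n, kd) {
  function(P, R) {
    b <- P + n * R + kd
    (b - sqrt(b^2 - 4 * P * n * R)) / 2
  }
}

#' Simulate a single-site ITC titration
#'
#' Exact forward model of the single-binding-site isotherm: the bound-titrant
#' concentration after each injection is the physical root of the binding
#' quadratic, the heat content is \eqn{Q_i = [B]_i V_0 \Delta H}, and the
#' measured injection heat is the increment corrected for the displaced
#' volume. Dilution of both species by the injected volume is tracked.
#' Gaussian noise of standard deviation `noise_sd` is added when non-zero.
#'
#' @param n stoichiometry (sites per cell-species molecule).
#' @param kd dissociation constant in molar.
#' @param dh binding enthalpy in kcal per mole of titrant.
#' @param protocol an [itc_protocol()].
#' @param noise_sd Gaussian noise SD on the injection heats (ucal).
#' @param seed seed used when `noise_sd > 0`.
#' @return An object of class `titration_experiment`: the protocol plus
#'   `heats_ucal` and a `c_value` field (cell concentration / Kd); c-values
#'   far outside \[1, 1000\] are flagged with a warning attribute
#'   `identifiability`.
#' @export
simulate_titration <- function(n, kd, dh, protocol, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(protocol, "itc_protocol"), n > 0, kd > 0)
  heats <- itc_forward_heats(protocol, dh, single_site_bound(n, kd))
  if (noise_sd > 0)
    heats <- withr::with_seed(as.integer(seed),
                              heats + stats::rnorm(length(heats), 0, noise_sd))
  cval <- protocol$cell_conc / kd
  out <- structure(c(unclass(protocol),
                     list(heats_ucal = heats, c_value = cval)),
                   class = "titration_experiment")
  if (cval < 1e-4 || cval > 1e7)
    attr(out, "identifiability") <- sprintf(
      "c-value %.3g outside [1e-4, 1e7]; fit may be ill-conditioned", cval)
  out
}

#' Simulate a titration into a species carrying two independent identical sites
#'
#' Independent forward route for the two-site mechanism: the free-titrant
#' concentration L solves the conservation equation
#' \eqn{P_t = L + 2 R_t L/(K_d + L)} (per-site dissociation constant
#' \eqn{K_d}), and the bound concentration is \eqn{P_t - L}. Because the two
#' sites are identical and independent, the resulting isotherm coincides with
#' a single-site system of stoichiometry 2 - which is exactly what a
#' single-site fit of such data reports.
#'
#' @param kd per-site dissociation constant (molar).
#' @param dh binding enthalpy in kcal per mole of titrant.
#' @param protocol an [itc_protocol()] (cell species = the two-site molecule).
#' @param noise_sd,seed as in [simulate_titration()].
#' @return A `titration_experiment`.
#' @export
simulate_two_site_titration <- function(kd, dh, protocol, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(protocol, "itc_protocol"), kd > 0)
  two_site_bound <- function(P, R) {
    # L^2 + L (kd + 2R - P) - kd P = 0, positive root
    b <- kd + 2 * R - P
    L <- (-b + sqrt(b^2 + 4 * kd * P)) / 2
    P - L
  }
  heats <- itc_forward_heats(protocol, dh, two_site_bound)
  if (noise_sd > 0)
    heats <- withr::with_seed(as.integer(seed),
                              heats + stats::rnorm(length(heats), 0, noise_sd))
  structure(c(unclass(protocol),
              list(heats_ucal = heats, c_value = protocol$cell_conc / kd)),
            class = "titration_experiment")
}

#' Fit the single-binding-site model to an ITC titration
#'
#' Least-squares fit of (N, Kd, dH) to blank-subtracted injection heats using
#' the same exact forward model as [simulate_titration()] (Levenberg-
#' Marquardt on \eqn{(N, \log_{10} K_d, \Delta H)}, multi-start over a Kd
#' grid). The first injection - conventionally discarded because of syringe
#' diffusion during equilibration - is down-weighted.
#'
#' @param expt a `titration_experiment`.
#' @param blank optional blank (titrant into buffer) `titration_experiment`
#'   with the same injection schedule; its heats are subtracted.
#' @param first_injection_weight weight on the first injection residual
#'   (default 0.01).
#' @return An object of class `binding_fit`: list with `n`, `kd` (molar),
#'   `dh` (kcal/mol), `rss` (weighted residual sum of squares, ucal^2),
#'   `fitted_heats`, `heats` (the data after blank subtraction).
#' @export
fit_single_site <- function(expt, blank = NULL, first_injection_weight = 0.01) {
  stopifnot(inherits(expt, "titration_experiment"))
  heats <- expt$heats_ucal
  if (!is.null(blank)) {
    stopifnot(inherits(blank, "titration_experiment"))
    if (length(blank$heats_ucal) != length(heats) ||
        any(blank$injections_ul != expt$injections_ul))
      stop("blank protocol does not match the experiment")
    heats <- heats - blank$heats_ucal
  }
  if (length(heats) < 5L) stop("need at least 5 injections for a stable fit")
  protocol <- itc_protocol(expt$cell_volume_ul, expt$cell_conc,
                           expt$syringe_conc, expt$injections_ul)
  w <- rep(1, length(heats)); w[1] <- first_injection_weight
  scale <- max(abs(heats), 1e-12)
  if (max(abs(diff(heats / scale))) < 1e-3)
    stop("heats carry no curvature (saturated or empty titration); ",
         "Kd is not identifiable")
  resid_fun <- function(par) {
    n <- par[1]; kd <- 10^par[2]; dh <- par[3]
    model <- itc_forward_heats(protocol, dh, single_site_bound(n, kd))
    sqrt(w) * (model - heats) / scale
  }
  dh0 <- sum(heats) / (sum(protocol$injections_ul) * 1e-6 *
                         protocol$syringe_conc) / 1e9  # rough kcal/mol
  if (!is.finite(dh0) || dh0 == 0) dh0 <- -1
  best <- NULL; best_rss <- Inf
  for (log_kd0 in seq(-9, -3, by = 1)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = c(1, log_kd0, dh0), fn = resid_fun,
                         lower = c(1e-3, -15, -Inf), upper = c(1e3, 0, Inf),
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best_rss) { best <- fit; best_rss <- rss }
  }
  if (is.null(best)) stop("single-site fit failed to converge from any start")
  par <- best$par
  fitted <- itc_forward_heats(protocol, par[3], single_site_bound(par[1], 10^par[2]))
  structure(list(n = par[1], kd = 10^par[2], dh = par[3],
                 rss = sum((sqrt(w) * (fitted - heats))^2),
                 fitted_heats = fitted, heats = heats),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("<binding_fit: N = %.3f, Kd = %.4g M (%.3f uM), dH = %.3f kcal/mol>\n",
              x$n, x$kd, x$kd * 1e6, x$dh))
  invisible(x)
}

#' Fold change between two dissociation constants
#'
#' `kd_a / kd_b`: how many times weaker binding `a` is than binding `b`.
#'
#' @param kd_a,kd_b dissociation constants (same units, both positive).
#' @return The ratio.
#' @export
fold_change <- function(kd_a, kd_b) {
  stopifnot(kd_a > 0, kd_b > 0)
  kd_a / kd_b
}

#' Combined amide chemical shift perturbations between two states
#'
#' For every residue present in both peak lists computes the combined CSP
#' with the standard amide weighting,
#' \deqn{CSP = \sqrt{\Delta\delta_H^2 + (\Delta\delta_N / w_N)^2},}
#' default \eqn{w_N = 5}. Residues present in only one list are reported
#' separately: peaks present free but lost on binding are candidate
#' exchange-broadened (intermediate-exchange) residues.
#'
#' @param free,bound [peak_list()] objects for the two states.
#' @param n_weight nitrogen down-weighting factor (default 5).
#' @return List with `records` (data.frame residue, delta_h, delta_n, csp),
#'   `missing_in_bound` and `missing_in_free` (residue numbers).
#' @export
csp_compute <- function(free, bound, n_weight = 5) {
  stopifnot(inherits(free, "peak_list"), inherits(bound, "peak_list"),
            n_weight > 0)
  shared <- intersect(free$residue, bound$residue)
  if (length(shared) == 0L) stop("no residues shared between the two peak lists")
  i <- match(shared, free$residue); j <- match(shared, bound$residue)
  dh <- bound$dH_ppm[j] - free$dH_ppm[i]
  dn <- bound$dN_ppm[j] - free$dN_ppm[i]
  records <- data.frame(residue = shared, delta_h = dh, delta_n = dn,
                        csp = sqrt(dh^2 + (dn / n_weight)^2))
  records <- records[order(records$residue), , drop = FALSE]
  rownames(records) <- NULL
  list(records = records,
       missing_in_bound = sort(setdiff(free$residue, bound$residue)),
       missing_in_free = sort(setdiff(bound$residue, free$residue)))
}

#' Select residues with apparent chemical shift perturbations
#'
#' Default rule: CSP strictly greater than mean + `k_sd` standard deviations
#' (computed over the observed residues). An absolute ppm cutoff can be used
#' instead.
#'
#' @param records the `records` data.frame from [csp_compute()] (or the full
#'   csp_compute result).
#' @param k_sd SD multiplier for the mean + k*SD rule (default 1).
#' @param cutoff absolute CSP cutoff in ppm; when given it replaces the
#'   mean + k*SD rule.
#' @return Integer vector of selected residue numbers.
#' @export
csp_select_perturbed <- function(records, k_sd = 1, cutoff = NULL) {
  if (is.list(records) && !is.data.frame(records) && "records" %in% names(records))
    records <- records$records
  stopifnot(is.data.frame(records), nrow(records) > 0)
  thr <- if (!is.null(cutoff)) cutoff
  else mean(records$csp) + k_sd * stats::sd(records$csp)
  sort(records$residue[records$csp > thr])
}

#' Backbone amide assignment completeness
#'
#' Percentage of observable amides assigned: prolines lack a backbone amide
#' proton and are excluded from the denominator,
#' \eqn{100 \cdot assigned / (total - prolines)}, reported to one decimal.
#'
#' @param assigned number of assigned HN resonances.
#' @param total total residue count of the construct.
#' @param prolines number of prolines.
#' @return Percentage rounded to 1 decimal.
#' @export
assignment_completeness <- function(assigned, total, prolines = 0) {
  assigned <- as.integer(assigned); total <- as.integer(total)
  prolines <- as.integer(prolines)
  if (prolines < 0 || prolines >= total) stop("prolines must be in [0, total)")
  if (assigned < 0 || assigned > total - prolines)
    stop("assigned exceeds observable residues (total - prolines)")
  round(100 * assigned / (total - prolines), 1)
}
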