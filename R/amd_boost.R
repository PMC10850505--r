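#' Accelerated-MD dual-boost parameters
#'
#' Thresholds and strength factors of the dual-boost accelerated-MD bias:
#' `e_p`/`alpha_p` act on the total potential, `e_d`/`alpha_d` on the
#' dihedral (torsion) potential. All values in kcal/mol.
#'
#' @param e_p total-potential threshold.
#' @param alpha_p total-potential boost strength factor (> 0; larger alpha
#'   means a gentler boost).
#' @param e_d dihedral threshold.
#' @param alpha_d dihedral boost strength factor (> 0).
#' @return An object of class `amd_parameters`.
#' @export
amd_parameters <- function(e_p, alpha_p, e_d, alpha_d) {
  stopifnot(is.finite(e_p), is.finite(alpha_p), is.finite(e_d), is.finite(alpha_d))
  if (alpha_p <= 0 || alpha_d <= 0) stop("alpha_p and alpha_d must be > 0")
  structure(list(e_p = e_p, alpha_p = alpha_p, e_d = e_d, alpha_d = alpha_d),
            class = "amd_parameters")
}

#' @export
print.amd_parameters <- function(x, ...) {
  cat(sprintf("<amd_parameters: E_p = %.6g, alpha_p = %.6g, E_d = %.6g, alpha_d = %.6g kcal/mol>\n",
              x$e_p, x$alpha_p, x$e_d, x$alpha_d))
  invisible(x)
}

#' Dual-boost bias potential
#'
#' Evaluates the accelerated-MD boost
#' \deqn{\Delta V = \frac{(E_p - V)^2}{\alpha_p + E_p - V}
#'              + \frac{(E_d - V_d)^2}{\alpha_d + E_d - V_d}}
#' with each term applied only when its energy lies below its threshold
#' (per-term gating, the dual-boost convention: the total-potential term is
#' active iff \eqn{V < E_p} and the dihedral term iff \eqn{V_d < E_d}).
#' The boost is non-negative, vanishes continuously at the thresholds, and
#' the biased potential \eqn{V + \Delta V} remains strictly increasing in V
#' below threshold (slope \eqn{(\alpha/(\alpha + E - V))^2 \in (0, 1]}), so
#' the energy landscape is flattened without reordering minima.
#'
#' @param v total potential V (kcal/mol); vectorized.
#' @param v_d dihedral potential V_d (kcal/mol); recycled against `v`.
#' @param params an [amd_parameters()].
#' @return List with `delta_v` (the boost) and `v_biased` (`v + delta_v`).
#' @export
boost_potential <- function(v, v_d, params) {
  stopifnot(inherits(params, "amd_parameters"))
  n <- max(length(v), length(v_d))
  v <- rep_len(as.numeric(v), n); v_d <- rep_len(as.numeric(v_d), n)
  term <- function(x, e, alpha) {
    out <- numeric(length(x))
    below <- x < e
    if (any(below)) {
      gap <- e - x[below]
      denom <- alpha + gap
      if (any(denom <= 0)) stop("boost denominator alpha + E - V <= 0")
      out[below] <- gap^2 / denom
    }
    out
  }
  dv <- term(v, params$e_p, params$alpha_p) + term(v_d, params$e_d, params$alpha_d)
  list(delta_v = dv, v_biased = v + dv)
}

#' Energy trace from a conventional-MD run
#'
#' Total and dihedral potential-energy series (kcal/mol) together with the
#' system size, as needed by the dual-boost parameter recipe.
#'
#' @param v_total series of total potential energies.
#' @param v_dihedral series of dihedral (torsion) energies, same length.
#' @param n_atoms total atom count of the simulated system.
#' @param n_residues solute residue count.
#' @return An object of class `energy_trace`.
#' @export
energy_trace <- function(v_total, v_dihedral, n_atoms, n_residues) {
  v_total <- as.numeric(v_total); v_dihedral <- as.numeric(v_dihedral)
  if (length(v_total) < 1L || length(v_total) != length(v_dihedral))
    stop("energy series must be non-empty and equal length")
  if (n_atoms < 1 || n_residues < 1) stop("atom and residue counts must be positive")
  structure(list(v_total = v_total, v_dihedral = v_dihedral,
                 n_atoms = as.integer(n_atoms), n_residues = as.integer(n_residues)),
            class = "energy_trace")
}

#' Estimate dual-boost parameters from a cMD energy trace
#'
#' Standard dual-boost recipe (all kcal/mol):
#' \deqn{E_p = \langle V \rangle + 0.16\,n_{atoms}, \quad
#'       \alpha_p = 0.16\,n_{atoms},}
#' \deqn{E_d = \langle V_d \rangle + 4\,n_{res}, \quad
#'       \alpha_d = \tfrac{4}{5}\,n_{res}.}
#' For a 175-residue construct this gives \eqn{\alpha_d = 140} kcal/mol.
#'
#' @param trace an [energy_trace()].
#' @return An [amd_parameters()].
#' @export
estimate_amd_parameters <- function(trace) {
  stopifnot(inherits(trace, "energy_trace"))
  amd_parameters(
    e_p = mean(trace$v_total) + 0.16 * trace$n_atoms,
    alpha_p = 0.16 * trace$n_atoms,
    e_d = mean(trace$v_dihedral) + 4 * trace$n_residues,
    alpha_d = 4 * trace$n_residues / 5
  )
}

#' Check landscape flattening of the boost on an energy grid
#'
#' Numerically verifies that below threshold the biased potential has slope
#' \eqn{dV_{bias}/dV = (\alpha/(\alpha + E - V))^2 \in (0, 1]}: strictly
#' increasing (minima ordering preserved) but compressed (barriers lowered).
#'
#' @param params an [amd_parameters()].
#' @param v_grid increasing grid of total potential energies; the dihedral
#'   energy is held at its threshold so only the total-potential term acts.
#' @return List with `v` (interior grid points), `slope` (numerical
#'   derivative of the biased potential), `monotone` and `compressed` flags.
#' @export
flattening_check <- function(params, v_grid) {
  stopifnot(inherits(params, "amd_parameters"))
  v_grid <- sort(as.numeric(v_grid))
  vb <- boost_potential(v_grid, params$e_d, params)$v_biased
  slope <- diff(vb) / diff(v_grid)
  list(v = (v_grid[-1] + v_grid[-length(v_grid)]) / 2, slope = slope,
       monotone = all(slope > 0), compressed = all(slope <= 1 + 1e-9))
}
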