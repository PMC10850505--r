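#' Configuration of the SAXS-oriented ensemble refinement loop
#'
#' @param n_es ensemble size selected each cycle.
#' @param n_cycles number of selection/resampling cycles.
#' @param burst_sweeps Metropolis sweeps per sampler burst (the stand-in for
#'   one short independent simulation).
#' @param snapshots_per_burst conformers harvested per burst.
#' @param pool_mode `"accumulate"` (selection sees every structure generated
#'   so far; guarantees a monotone non-increasing best chi-square) or
#'   `"replace"` (selection sees only the latest bursts).
#' @param q_grid q grid used for profile caching (default the experimental
#'   curve's grid).
#' @param seed root seed; per-cycle, per-member burst seeds and per-cycle GA
#'   seeds are derived from it deterministically.
#' @param ga a [ga_config()] template for cycles where exhaustive selection is
#'   too expensive (its seed field is re-derived per cycle from `seed`).
#' @param exhaustive_cap subset-count threshold below which selection is exact.
#' @return An object of class `refinement_config`.
#' @export
refinement_config <- function(n_es, n_cycles, burst_sweeps = 30,
                              snapshots_per_burst = 5,
                              pool_mode = c("accumulate", "replace"),
                              q_grid = NULL, seed = 1L,
                              ga = NULL, exhaustive_cap = 1e4) {
  pool_mode <- match.arg(pool_mode)
  stopifnot(n_es >= 1, n_cycles >= 1, burst_sweeps >= 1, snapshots_per_burst >= 1)
  if (is.null(ga)) ga <- ga_config(seed = 1L)
  structure(list(n_es = as.integer(n_es), n_cycles = as.integer(n_cycles),
                 burst_sweeps = as.integer(burst_sweeps),
                 snapshots_per_burst = as.integer(snapshots_per_burst),
                 pool_mode = pool_mode, q_grid = q_grid,
                 seed = as.integer(seed), ga = ga,
                 exhaustive_cap = exhaustive_cap),
            class = "refinement_config")
}

# counter-based derived seeds: independent streams per (cycle, member),
# kept below 2^31 - 1
derive_seed <- function(root, cycle, member = 0L) {
  as.integer((as.double(root) * 48271 + cycle * 7919 + member * 104729) %% 2147483647)
}

#' Run the SAXS-oriented ensemble refinement loop
#'
#' Iterates the sampling/selection scheme: a preliminary burst from the
#' initial structure seeds the conformer pool; each cycle then (i) selects the
#' `n_es`-member ensemble minimizing chi-square against the experimental
#' curve (exhaustive when cheap, genetic algorithm otherwise, with the
#' previous best ensemble injected into the GA population so the accumulate
#' mode is monotone), and (ii) restarts one independent short burst from each
#' selected conformer, adding the snapshots to the pool. Chi-square and the
#' selected-ensemble radii of gyration are recorded per cycle. The whole run
#' is reproducible from `cfg$seed`.
#'
#' @param initial starting [conformer_model()].
#' @param exp experimental [scattering_curve()] with sigma.
#' @param sampler a sampler honouring the [toy_sampler()] contract
#'   (`initialize` and `burst` functions).
#' @param cfg a [refinement_config()].
#' @param verbose print per-cycle chi-square.
#' @return An object of class `refinement_state`: list with `pool`, `best`
#'   (final `ensemble_selection`), `chi2_by_cycle`, `mu_by_cycle`,
#'   `rg_samples_by_cycle` (list of per-cycle selected-member Rg vectors),
#'   `indices_by_cycle`, and `cfg`.
#' @export
run_refinement <- function(initial, exp, sampler, cfg, verbose = FALSE) {
  stopifnot(inherits(initial, "conformer_model"),
            inherits(exp, "scattering_curve"),
            inherits(cfg, "refinement_config"))
  if (is.null(exp$sigma)) stop("experimental curve must carry sigma")
  q_grid <- if (is.null(cfg$q_grid)) exp$q else cfg$q_grid
  start <- sampler$initialize(initial, derive_seed(cfg$seed, 0L))
  if (n_points(start) != n_points(initial))
    stop("sampler contract violation: initialize changed the point count")
  # the preliminary burst must seed a pool at least n_es deep; it is run
  # proportionally longer than the per-cycle bursts
  prelim_snaps <- max(cfg$snapshots_per_burst, 2L * cfg$n_es)
  prelim_sweeps <- cfg$burst_sweeps *
    ceiling(prelim_snaps / cfg$snapshots_per_burst)
  prelim <- sampler$burst(start, prelim_sweeps, prelim_snaps,
                          derive_seed(cfg$seed, 0L, 1L))
  if (any(vapply(prelim, n_points, integer(1)) != n_points(initial)))
    stop("sampler contract violation: burst changed the point count")
  pool <- pool_profiles(conformer_pool(prelim), q_grid)

  chi2s <- numeric(cfg$n_cycles)
  mus <- numeric(cfg$n_cycles)
  rg_samples <- vector("list", cfg$n_cycles)
  idx_by_cycle <- vector("list", cfg$n_cycles)
  prev_best <- NULL
  for (cyc in seq_len(cfg$n_cycles)) {
    if (pool_size(pool) < cfg$n_es)
      stop("pool smaller than n_es at cycle ", cyc,
           " (pool_mode = ", cfg$pool_mode, ")")
    ga <- cfg$ga
    ga$seed <- derive_seed(cfg$seed, cyc, 999999L)
    seed_chrom <- if (!is.null(prev_best) && cfg$pool_mode == "accumulate")
      list(prev_best$indices) else NULL
    best <- select_ensemble(pool, exp, cfg$n_es, ga,
                            seed_chromosomes = seed_chrom,
                            exhaustive_cap = cfg$exhaustive_cap)
    chi2s[cyc] <- best$fit$chi2
    mus[cyc] <- best$fit$mu
    rg_samples[[cyc]] <- pool$rg[best$indices]
    idx_by_cycle[[cyc]] <- best$indices
    if (verbose)
      message(sprintf("cycle %d: chi2 = %.4f (pool %d)", cyc, best$fit$chi2,
                      pool_size(pool)))
    if (cyc < cfg$n_cycles) {
      new_members <- list()
      for (m in seq_along(best$indices)) {
        snaps <- sampler$burst(pool$members[[best$indices[m]]],
                               cfg$burst_sweeps, cfg$snapshots_per_burst,
                               derive_seed(cfg$seed, cyc, m))
        if (any(vapply(snaps, n_points, integer(1)) != n_points(initial)))
          stop("sampler contract violation: burst changed the point count")
        new_members <- c(new_members, snaps)
      }
      if (cfg$pool_mode == "accumulate") {
        pool$members <- c(pool$members, new_members)
        pool <- pool_profiles(pool, q_grid)
        # indices of prev best remain valid: members only appended
        prev_best <- best
      } else {
        # replace mode: selection history cannot be carried over
        pool <- pool_profiles(conformer_pool(new_members), q_grid)
        prev_best <- NULL
      }
    }
  }
  structure(list(pool = pool, best = best, chi2_by_cycle = chi2s,
                 mu_by_cycle = mus, rg_samples_by_cycle = rg_samples,
                 indices_by_cycle = idx_by_cycle, cfg = cfg),
            class = "refinement_state")
}

#' @export
print.refinement_state <- function(x, ...) {
  cat(sprintf("<refinement_state: %d cycles, final chi2 = %.4f, pool %d>\n",
              length(x$chi2_by_cycle), x$best$fit$chi2, pool_size(x$pool)))
  invisible(x)
}

#' Radius-of-gyration distribution over the last refinement cycles
#'
#' Pools the Rg values of the selected-ensemble members from the last
#' `last_k` cycles and histograms them with a fixed bin width, density
#' normalized.
#'
#' @param state a `refinement_state`.
#' @param last_k number of trailing cycles to pool (default 10).
#' @param bin_width histogram bin width in Angstrom (default 0.5).
#' @return An object of class `rg_histogram`: list with `centers`, `density`,
#'   `counts`, `bin_width`, and the pooled `values`.
#' @export
rg_distribution <- function(state, last_k = 10, bin_width = 0.5) {
  stopifnot(inherits(state, "refinement_state"))
  nc <- length(state$rg_samples_by_cycle)
  if (last_k > nc) stop("only ", nc, " cycles available; last_k = ", last_k)
  vals <- unlist(state$rg_samples_by_cycle[(nc - last_k + 1L):nc])
  lo <- floor(min(vals) / bin_width) * bin_width
  hi <- ceiling(max(vals) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  h <- graphics::hist(vals, breaks = breaks, plot = FALSE)
  structure(list(centers = h$mids, density = h$density, counts = h$counts,
                 bin_width = bin_width, values = vals),
            class = "rg_histogram")
}

#' Locate peaks of a (smoothed) Rg histogram
#'
#' Smooths the density with a centered moving average and reports local
#' maxima, sorted by decreasing height. A smoothing window of 1 bin disables
#' smoothing; wider windows merge sub-bin-scale doublets.
#'
#' @param hist an `rg_histogram` (or any list with `centers` and `density`).
#' @param smooth_window odd moving-average window in bins (default 3).
#' @return data.frame with columns `rg` (peak location) and `height`, ordered
#'   by decreasing height.
#' @export
find_rg_peaks <- function(hist, smooth_window = 3) {
  d <- hist$density
  n <- length(d)
  if (n == 0L) stop("empty histogram")
  w <- max(1L, as.integer(smooth_window))
  if (w %% 2L == 0L) w <- w + 1L
  if (w > 1L && n > w) {
    half <- (w - 1L) %/% 2L
    pad <- c(rep(0, half), d, rep(0, half))
    d <- vapply(seq_len(n), function(i) mean(pad[i:(i + w - 1L)]), numeric(1))
  }
  is_peak <- vapply(seq_len(n), function(i) {
    left <- if (i == 1L) 0 else d[i - 1L]
    right <- if (i == n) 0 else d[i + 1L]
    d[i] > 0 && d[i] >= left && d[i] >= right && (d[i] > left || d[i] > right)
  }, logical(1))
  out <- data.frame(rg = hist$centers[is_peak], height = d[is_peak])
  out[order(-out$height), , drop = FALSE]
}

#' Residual table of an ensemble fit, in the display sign convention
#'
#' Per-point residuals \eqn{(I_{exp} - \mu I_{calc})/\sigma_{exp}} (the
#' experiment-minus-model convention used for residual plots; the chi-square
#' statistic is sign-agnostic). Also reports the lag-1 autocorrelation of the
#' residuals as a flatness summary: values near 0 indicate white, structure-
#' free residuals.
#'
#' @param best an `ensemble_selection` (with its fitted curve), or a
#'   [scattering_curve()] of the calculated model.
#' @param exp experimental [scattering_curve()] with sigma.
#' @return List with `table` (data.frame q, residual) and `lag1_autocor`.
#' @export
residual_plot_data <- function(best, exp) {
  calc <- if (inherits(best, "ensemble_selection")) best$curve else best
  stopifnot(inherits(calc, "scattering_curve"), inherits(exp, "scattering_curve"))
  fit <- saxs_chi2(calc, exp)
  res <- -fit$residuals  # (I_exp - mu I_calc)/sigma
  n <- length(res)
  lag1 <- if (n >= 3 && stats::sd(res) > 0)
    stats::cor(res[-n], res[-1]) else NA_real_
  list(table = data.frame(q = exp$q, residual = res), lag1_autocor = lag1,
       chi2 = fit$chi2, mu = fit$mu)
}
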