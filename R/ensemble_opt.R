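#' Conformer pool with cached profiles
#'
#' A list of candidate conformers together with their back-calculated
#' scattering profiles on a common q grid. Profiles are cached as a K x M
#' matrix (K grid points, M members) so that ensemble averaging during
#' selection is a cheap column mean.
#'
#' @param members list of [conformer_model()].
#' @return An object of class `conformer_pool` with elements `members`,
#'   `profiles` (NULL until [pool_profiles()] is called), `q` (grid of the
#'   cached profiles) and `rg` (per-member radii of gyration, cached lazily).
#' @export
conformer_pool <- function(members) {
  if (inherits(members, "conformer_model")) members <- list(members)
  if (length(members) < 1L) stop("empty pool")
  for (m in members) stopifnot(inherits(m, "conformer_model"))
  structure(list(members = members, profiles = NULL, q = NULL, rg = NULL),
            class = "conformer_pool")
}

#' @export
print.conformer_pool <- function(x, ...) {
  cat(sprintf("<conformer_pool: %d members%s>\n", length(x$members),
              if (is.null(x$profiles)) "" else sprintf(", profiles cached on %d q points",
                                                       length(x$q))))
  invisible(x)
}

pool_size <- function(pool) length(pool$members)

#' Cache member scattering profiles on a q grid
#'
#' Computes (or reuses) the Debye profile of every member on `q_grid`.
#' Idempotent: members whose profile is already cached on the same grid are
#' not recomputed, so growing pools only pay for new members.
#'
#' @param pool a [conformer_pool()].
#' @param q_grid q grid (1/A) or a [scattering_curve()] whose grid is used.
#' @return The pool with `profiles` (K x M matrix), `q` and `rg` populated.
#' @export
pool_profiles <- function(pool, q_grid) {
  stopifnot(inherits(pool, "conformer_pool"))
  if (inherits(q_grid, "scattering_curve")) q_grid <- q_grid$q
  q_grid <- as.numeric(q_grid)
  M <- pool_size(pool)
  reuse <- !is.null(pool$profiles) && length(pool$q) == length(q_grid) &&
    all(pool$q == q_grid)
  old <- if (reuse) ncol(pool$profiles) else 0L
  if (old < M) {
    new_prof <- vapply(pool$members[(old + 1L):M],
                       function(m) compute_profile(m, q_grid)$I,
                       numeric(length(q_grid)))
    new_rg <- vapply(pool$members[(old + 1L):M], rg_from_coords, numeric(1))
    pool$profiles <- cbind(if (old > 0L) pool$profiles, new_prof)
    pool$rg <- c(if (old > 0L) pool$rg, new_rg)
  } else if (!reuse) {
    pool$profiles <- vapply(pool$members, function(m) compute_profile(m, q_grid)$I,
                            numeric(length(q_grid)))
    pool$rg <- vapply(pool$members, rg_from_coords, numeric(1))
  }
  pool$q <- q_grid
  pool
}

# chi2 of the uniform average of cached profiles `idx` against (Iexp, w=1/sigma^2)
chi2_of_subset <- function(profiles, idx, Iexp, w) {
  Ic <- if (length(idx) == 1L) profiles[, idx] else rowMeans(profiles[, idx, drop = FALSE])
  denom <- sum(Ic^2 * w)
  mu <- sum(Ic * Iexp * w) / denom
  res <- (mu * Ic - Iexp)
  c(chi2 = sum(res^2 * w) / (length(Iexp) - 1), mu = mu)
}

make_selection <- function(pool, exp, idx) {
  idx <- sort(as.integer(idx))
  curves <- lapply(idx, function(i) scattering_curve(pool$q, pool$profiles[, i]))
  avg <- ensemble_profile(curves)
  fit <- saxs_chi2(avg, exp)
  structure(list(indices = idx, N = length(idx), weights = rep(1 / length(idx), length(idx)),
                 fit = fit, curve = avg),
            class = "ensemble_selection")
}

#' @export
print.ensemble_selection <- function(x, ...) {
  cat(sprintf("<ensemble_selection: N = %d, chi2 = %.4f, mu = %.4g>\n  indices: %s\n",
              x$N, x$fit$chi2, x$fit$mu, paste(x$indices, collapse = " ")))
  invisible(x)
}

#' Exhaustive best-fitting ensemble search
#'
#' Enumerates every distinct-index subset of size `n_es`, scores the uniform
#' average of the cached member profiles against the experimental curve
#' (scale factor optimized analytically per subset) and returns the global
#' chi-square minimum. Ties are broken by the lexicographically smallest
#' sorted index list, making the result fully deterministic.
#'
#' @param pool a [conformer_pool()]; profiles are cached on `exp`'s grid if
#'   not already.
#' @param exp experimental [scattering_curve()] with sigma.
#' @param n_es ensemble size.
#' @param max_subsets guard on the number of subsets enumerated (default 2e6).
#' @return An `ensemble_selection`: sorted `indices`, size `N`, uniform
#'   `weights`, `fit` ([saxs_chi2()] result) and the averaged `curve`.
#' @export
select_ensemble_exhaustive <- function(pool, exp, n_es, max_subsets = 2e6) {
  stopifnot(inherits(pool, "conformer_pool"), inherits(exp, "scattering_curve"))
  if (is.null(exp$sigma)) stop("experimental curve must carry sigma")
  M <- pool_size(pool)
  n_es <- as.integer(n_es)
  if (n_es < 1L || n_es > M) stop("n_es must be in [1, pool size]")
  if (choose(M, n_es) > max_subsets)
    stop("choose(", M, ", ", n_es, ") exceeds the exhaustive cap; ",
         "use select_ensemble_ga()")
  pool <- pool_profiles(pool, exp)
  w <- 1 / exp$sigma^2
  subsets <- utils::combn(M, n_es)
  chi2s <- apply(subsets, 2, function(idx)
    chi2_of_subset(pool$profiles, idx, exp$I, w)[["chi2"]])
  # combn emits subsets in lexicographic order, so which.min's first-match
  # rule is exactly the documented tie-break
  make_selection(pool, exp, subsets[, which.min(chi2s)])
}

#' Genetic-algorithm configuration for ensemble selection
#'
#' @param population population size.
#' @param generations number of generations.
#' @param crossover per-pair crossover probability (uniform subset crossover
#'   with repair to distinct indices).
#' @param mutation per-gene mutation probability (replace with a random unused
#'   index).
#' @param elite number of elite chromosomes carried over unchanged.
#' @param seed mandatory integer random seed.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(population = 100, generations = 200, crossover = 0.5,
                      mutation = 0.1, elite = 10, seed) {
  if (missing(seed)) stop("ga_config requires an explicit seed")
  stopifnot(population > 0, generations > 0, elite >= 1, elite <= population,
            crossover >= 0, crossover <= 1, mutation >= 0, mutation <= 1)
  structure(list(population = as.integer(population),
                 generations = as.integer(generations),
                 crossover = crossover, mutation = mutation,
                 elite = as.integer(elite), seed = as.integer(seed)),
            class = "ga_config")
}

#' Genetic-algorithm best-fitting ensemble search
#'
#' Selects the `n_es`-member subset of the pool whose uniform profile average
#' best fits the experimental curve, using a seeded genetic algorithm:
#' chromosomes are distinct-index subsets, fitness is the negative chi-square
#' (scale factor optimized analytically inside the evaluation), parents are
#' chosen by binary tournament, crossover samples the child from the union of
#' its parents (repairing to distinctness), mutation replaces genes with
#' random unused indices, and elitism preserves the best chromosomes so the
#' best fitness per generation is non-decreasing.
#'
#' @param pool a [conformer_pool()].
#' @param exp experimental [scattering_curve()] with sigma.
#' @param n_es ensemble size.
#' @param cfg a [ga_config()].
#' @param seed_chromosomes optional list of index vectors injected into the
#'   initial population (used by the refinement loop to carry the previous
#'   best ensemble across cycles).
#' @return An `ensemble_selection` (see [select_ensemble_exhaustive()]).
#' @export
select_ensemble_ga <- function(pool, exp, n_es, cfg, seed_chromosomes = NULL) {
  stopifnot(inherits(pool, "conformer_pool"), inherits(exp, "scattering_curve"),
            inherits(cfg, "ga_config"))
  if (is.null(exp$sigma)) stop("experimental curve must carry sigma")
  M <- pool_size(pool)
  n_es <- as.integer(n_es)
  if (n_es > M) stop("n_es (", n_es, ") exceeds pool size (", M, ")")
  pool <- pool_profiles(pool, exp)
  w <- 1 / exp$sigma^2
  Iexp <- exp$I
  profiles <- pool$profiles

  eval_chi2 <- function(idx) chi2_of_subset(profiles, idx, Iexp, w)[["chi2"]]

  best_idx <- withr::with_seed(cfg$seed, {
    popn <- cfg$population
    population <- lapply(seq_len(popn), function(i) sort(sample.int(M, n_es)))
    if (!is.null(seed_chromosomes)) {
      seed_chromosomes <- lapply(seed_chromosomes, function(s) sort(as.integer(s)))
      stopifnot(all(vapply(seed_chromosomes, length, integer(1)) == n_es))
      population[seq_along(seed_chromosomes)] <- seed_chromosomes
    }
    fitness <- -vapply(population, eval_chi2, numeric(1))
    for (gen in seq_len(cfg$generations)) {
      ord <- order(fitness, decreasing = TRUE)
      elite_set <- population[ord[seq_len(cfg$elite)]]
      elite_fit <- fitness[ord[seq_len(cfg$elite)]]
      n_child <- popn - cfg$elite
      children <- vector("list", n_child)
      for (k in seq_len(n_child)) {
        # binary tournament selection for each parent
        pick <- function() {
          ij <- sample.int(popn, 2L)
          if (fitness[ij[1]] >= fitness[ij[2]]) population[[ij[1]]] else population[[ij[2]]]
        }
        p1 <- pick(); p2 <- pick()
        child <- if (stats::runif(1) < cfg$crossover) {
          un <- union(p1, p2)
          sort(un[sample.int(length(un), n_es)])
        } else p1
        # per-gene mutation: replace with a random unused index
        mut <- which(stats::runif(n_es) < cfg$mutation)
        if (length(mut) > 0L) {
          for (g in mut) {
            unused <- setdiff(seq_len(M), child)
            if (length(unused) > 0L)
              child[g] <- unused[sample.int(length(unused), 1L)]
          }
          child <- sort(child)
        }
        children[[k]] <- child
      }
      population <- c(elite_set, children)
      fitness <- c(elite_fit, -vapply(children, eval_chi2, numeric(1)))
    }
    # deterministic tie-break: lowest chi2, then lexicographically smallest
    best_fit <- max(fitness)
    cand <- population[fitness >= best_fit - 0]
    key <- vapply(cand, function(x) paste(sprintf("%09d", x), collapse = ","), character(1))
    cand[[order(key)[1]]]
  })
  make_selection(pool, exp, best_idx)
}

#' Best-fitting ensemble with automatic algorithm choice
#'
#' Uses exhaustive enumeration when the subset count is small enough
#' (guaranteeing the global optimum), otherwise the genetic algorithm.
#'
#' @inheritParams select_ensemble_ga
#' @param exhaustive_cap subset-count threshold for the exhaustive route
#'   (default 1e4).
#' @return An `ensemble_selection`.
#' @export
select_ensemble <- function(pool, exp, n_es, cfg, seed_chromosomes = NULL,
                            exhaustive_cap = 1e4) {
  if (choose(pool_size(pool), n_es) <= exhaustive_cap) {
    select_ensemble_exhaustive(pool, exp, n_es)
  } else {
    select_ensemble_ga(pool, exp, n_es, cfg, seed_chromosomes = seed_chromosomes)
  }
}
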