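q_small <- seq(0.01, 0.3, length.out = 80)

# sampler stub that only ever returns copies of one ground-truth conformer
copy_sampler <- function(truth) {
  list(initialize = function(model, seed) model,
       burst = function(start, n_sweeps, n_snapshots, seed) {
         lapply(seq_len(n_snapshots), function(i) {
           m <- truth; m$id <- paste0("copy_", i); m
         })
       })
}

test_that("refinement reaches chi2 ~ 0 when the sampler emits the exact truth", {
  spec <- small_spec("bound")
  truth <- make_pool(spec, 1, seed = 31)$members[[1]]
  tprof <- compute_profile(truth, q_small)
  exp_ <- scattering_curve(q_small, tprof$I, sigma = 0.02 * tprof$I)
  init <- make_two_domain_conformer(spec, linker_state_extended(spec))
  st <- run_refinement(init, exp_, copy_sampler(truth),
                       refinement_config(n_es = 2, n_cycles = 3, seed = 5))
  expect_true(all(st$chi2_by_cycle < 1e-9))
})

test_that("accumulate-mode chi2 is non-increasing and runs are seed-reproducible", {
  spec <- small_spec("bound")
  truth <- make_pool(spec, 2, seed = 41)$members
  exp_ <- simulate_saxs_experiment(truth, q_grid = q_small,
                                   noise = noise_model(seed = 42))
  init <- make_two_domain_conformer(small_spec("apo"), linker_state_extended(spec))
  samp <- toy_sampler(small_spec("apo"))
  for (seed in c(1, 2)) {
    cfg <- refinement_config(n_es = 3, n_cycles = 6, burst_sweeps = 10,
                             snapshots_per_burst = 3, seed = seed)
    st <- run_refinement(init, exp_, samp, cfg)
    expect_true(all(diff(st$chi2_by_cycle) <= 1e-12))
  }
  cfg <- refinement_config(n_es = 3, n_cycles = 4, burst_sweeps = 10,
                           snapshots_per_burst = 3, seed = 9)
  a <- run_refinement(init, exp_, samp, cfg)
  b <- run_refinement(init, exp_, samp, cfg)
  expect_identical(a$chi2_by_cycle, b$chi2_by_cycle)
  expect_identical(a$indices_by_cycle, b$indices_by_cycle)
})

test_that("replace mode forgets history and may lose monotonicity guarantees", {
  spec <- small_spec("bound")
  truth <- make_pool(spec, 2, seed = 51)$members
  exp_ <- simulate_saxs_experiment(truth, q_grid = q_small,
                                   noise = noise_model(seed = 52))
  init <- make_two_domain_conformer(small_spec("apo"), linker_state_extended(spec))
  st <- run_refinement(init, exp_, toy_sampler(small_spec("apo")),
                       refinement_config(n_es = 3, n_cycles = 4, burst_sweeps = 8,
                                         snapshots_per_burst = 3,
                                         pool_mode = "replace", seed = 3))
  # pool holds only the latest bursts: n_es bursts x snapshots each
  expect_equal(length(st$pool$members), 3 * 3)
})

test_that("rg_distribution pools trailing cycles into a unit-mass histogram", {
  spec <- small_spec("bound")
  truth <- make_pool(spec, 1, seed = 61)$members[[1]]
  tprof <- compute_profile(truth, q_small)
  exp_ <- scattering_curve(q_small, tprof$I, sigma = 0.02 * tprof$I)
  init <- make_two_domain_conformer(spec, linker_state_extended(spec))
  st <- run_refinement(init, exp_, copy_sampler(truth),
                       refinement_config(n_es = 2, n_cycles = 4, seed = 5))
  expect_error(rg_distribution(st, last_k = 10), "cycles")
  h <- rg_distribution(st, last_k = 3)
  expect_equal(sum(h$density * h$bin_width), 1, tolerance = 1e-9)
  # all selected conformers identical: mass concentrates in one bin
  expect_equal(sum(h$counts > 0), 1L)
})

test_that("peak finding resolves doublets only without smoothing", {
  uni <- list(centers = seq(20, 24, 0.5), density = c(0, 0.1, 0.4, 1.0, 0.4, 0.1, 0, 0, 0))
  expect_equal(find_rg_peaks(uni, smooth_window = 1)$rg[1], 21.5)
  bi <- list(centers = seq(24, 29, 0.5),
             density = c(0, 0.2, 1.0, 0.3, 0.9, 0.2, 0, 0, 0, 0, 0))
  sharp <- find_rg_peaks(bi, smooth_window = 1)
  expect_equal(sort(sharp$rg[1:2]), c(25.0, 26.0))
  smoothed <- find_rg_peaks(bi, smooth_window = 3)
  expect_equal(nrow(smoothed), 1L)  # 0.8-A-scale doublet merges under smoothing
})

test_that("residuals use the experiment-minus-model convention and are white for true fits", {
  q <- seq(0.01, 0.2, length.out = 50)
  I <- 100 * exp(-q^2 * 15^2 / 3)
  calc <- scattering_curve(q, I)
  perfect <- residual_plot_data(calc, scattering_curve(q, I, sigma = 0.02 * I))
  expect_true(all(abs(perfect$table$residual) < 1e-9))
  # single raised point: its residual is positive in this convention
  sigma <- 0.02 * I
  bump <- I; bump[25] <- bump[25] + 5 * sigma[25]
  r <- residual_plot_data(calc, scattering_curve(q, bump, sigma = sigma))
  expect_gt(r$table$residual[25], 3)
  # correctly specified noise gives near-zero lag-1 autocorrelation
  qq <- seq(0.01, 0.3, length.out = 200)
  II <- 100 * exp(-qq^2 * 15^2 / 3)
  ss <- 0.02 * II
  for (s in 1:3) {
    set.seed(s)
    noisy <- scattering_curve(qq, II + rnorm(200, 0, ss), sigma = ss)
    rr <- residual_plot_data(scattering_curve(qq, II), noisy)
    expect_lt(abs(rr$lag1_autocor), 0.2)
  }
})
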