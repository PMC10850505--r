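test_that("conformer construction is deterministic with extension maximal at zero bend", {
  spec <- two_domain_spec(mode = "apo")
  ext <- make_two_domain_conformer(spec, linker_state_extended(spec))
  ext2 <- make_two_domain_conformer(spec, linker_state_extended(spec))
  expect_identical(ext$points, ext2$points)
  expect_equal(nrow(ext$points), 175)
  expect_equal(ext$labels$resno, 56:230)
  centroid_dist <- function(m) {
    c1 <- colMeans(m$points[1:spec$n1, ])
    c2 <- colMeans(m$points[(spec$n1 + spec$n_link + 1):175, ])
    sqrt(sum((c1 - c2)^2))
  }
  d_ext <- centroid_dist(ext)
  set.seed(61)
  for (i in 1:20) {
    st <- linker_state_extended(spec)
    st$theta <- runif(12, 0.05, 1.2)
    st$phi <- runif(12, -pi, pi)
    m <- tryCatch(make_two_domain_conformer(spec, st), error = function(e) NULL)
    if (!is.null(m)) expect_lt(centroid_dist(m), d_ext)
  }
})

test_that("pools are seed-reproducible and bound pools are more compact than apo", {
  spec_a <- two_domain_spec(mode = "apo")
  spec_b <- two_domain_spec(mode = "bound")
  p1 <- make_pool(spec_a, 4, seed = 7)
  p2 <- make_pool(spec_a, 4, seed = 7)
  expect_identical(lapply(p1$members, `[[`, "points"),
                   lapply(p2$members, `[[`, "points"))
  ra <- vapply(make_pool(spec_a, 500, seed = 71)$members, rg_from_coords, numeric(1))
  rb <- vapply(make_pool(spec_b, 500, seed = 72)$members, rg_from_coords, numeric(1))
  expect_lt(mean(rb), mean(ra))
  # separation of the means: > 3 standard errors of the difference
  se_diff <- sqrt(var(ra) / 500 + var(rb) / 500)
  expect_gt((mean(ra) - mean(rb)) / se_diff, 3)
  # apo ensembles are also more heterogeneous
  expect_gt(sd(ra), sd(rb))
})

test_that("synthetic SAXS curves carry the generating sigma and calibrate to chi2 ~ 1", {
  spec <- small_spec("bound")
  truth <- make_pool(spec, 3, seed = 81)$members
  tprof <- ensemble_profile(lapply(truth, compute_profile, q_grid = default_q_grid()))
  # vanishing noise: the simulated intensities converge to the truth profile,
  # so the fit scored at a fixed (finite) error model goes to chi2 = 0
  tiny <- simulate_saxs_experiment(truth, noise = noise_model(relative_sd = 1e-9, seed = 1))
  expect_equal(tiny$I, tprof$I, tolerance = 1e-7)
  fixed_sigma <- scattering_curve(tiny$q, tiny$I, sigma = 0.02 * abs(tprof$I))
  expect_lt(saxs_chi2(tprof, fixed_sigma)$chi2, 1e-9)
  one <- simulate_saxs_experiment(truth, noise = noise_model(seed = 5))
  expect_equal(one$sigma, pmax(0.02 * abs(tprof$I), 0))
  chis <- vapply(1:100, function(s)
    saxs_chi2(tprof, simulate_saxs_experiment(truth, noise = noise_model(seed = s)))$chi2,
    numeric(1))
  expect_gt(mean(chis), 0.85)
  expect_lt(mean(chis), 1.15)
})

test_that("toy sampler honours its contract and cools monotonically at zero temperature", {
  spec <- small_spec("apo")
  init <- make_two_domain_conformer(spec, linker_state_extended(spec))
  samp <- toy_sampler(spec)
  s1 <- samp$burst(init, 10, 4, seed = 3)
  s2 <- samp$burst(init, 10, 4, seed = 3)
  expect_identical(lapply(s1, `[[`, "points"), lapply(s2, `[[`, "points"))
  expect_true(all(vapply(s1, function(m) nrow(m$points), integer(1)) ==
                    nrow(init$points)))
  # zero temperature: snapshot energies never increase
  cold <- toy_sampler(spec, temperature = 0)
  bent <- make_two_domain_conformer(spec, {
    st <- linker_state_extended(spec); st$theta <- rep(0.35, spec$n_link + 1); st
  })
  snaps <- cold$burst(bent, 20, 10, seed = 4)
  e <- vapply(snaps, function(m) cold$energy(m)[["total"]], numeric(1))
  expect_true(all(diff(e) <= 1e-9))
})

test_that("the dual-boost bias broadens the sampled Rg distribution", {
  spec <- small_spec("apo")
  init <- make_two_domain_conformer(spec, linker_state_extended(spec))
  # stiff linker: the unboosted walk stays near the extended minimum
  plain <- toy_sampler(spec, k_bend = 2)
  e_ref <- plain$energy(init)[["total"]]
  boosted <- toy_sampler(spec, k_bend = 2,
                         boost = amd_parameters(e_p = e_ref + 40, alpha_p = 8,
                                                e_d = 30, alpha_d = 3))
  sd_plain <- numeric(5); sd_boost <- numeric(5)
  for (s in 1:5) {
    rg_p <- vapply(plain$burst(init, 40, 40, seed = s),
                   rg_from_coords, numeric(1))
    rg_b <- vapply(boosted$burst(init, 40, 40, seed = 100 + s),
                   rg_from_coords, numeric(1))
    sd_plain[s] <- sd(rg_p); sd_boost[s] <- sd(rg_b)
  }
  expect_gt(mean(sd_boost), mean(sd_plain))
  # pooled variance comparison across the seeded runs
  expect_lt(t.test(sd_boost, sd_plain, alternative = "greater")$p.value, 0.05)
})

test_that("peak-list pairs report vanished residues and null planted effects", {
  pair <- make_peak_list_pair(40, seed = 2)
  out <- csp_compute(pair$free, pair$bound)
  expect_lt(max(out$records$csp), 0.02)  # baseline jitter only
  pair_v <- make_peak_list_pair(40, vanish = c(10, 11), seed = 2)
  expect_equal(csp_compute(pair_v$free, pair_v$bound)$missing_in_bound, c(10L, 11L))
  expect_error(make_peak_list_pair(40, planted = data.frame(residue = 5, dH = 1, dN = 1),
                                   vanish = 5), "overlap")
})
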