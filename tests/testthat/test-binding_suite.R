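methods_protocol <- function(cell_conc = 20e-6, syringe_conc = 300e-6) {
  itc_protocol(cell_volume_ul = 200, cell_conc = cell_conc,
               syringe_conc = syringe_conc)
}

test_that("stoichiometric and null limits of the titration forward model", {
  prot <- methods_protocol()
  # kd -> 0: every pre-saturation injection delivers dH x moles injected
  tight <- simulate_titration(n = 1, kd = 1e-15, dh = -10, protocol = prot)
  per_mol <- -10 * 1e9  # ucal per mol injectant
  inj2_expected <- per_mol * prot$syringe_conc * 2e-6
  expect_equal(tight$heats_ucal[2], inj2_expected, tolerance = 0.01)
  expect_lt(abs(tight$heats_ucal[19]), abs(inj2_expected) * 0.01)
  # dH = 0 gives zero heat everywhere
  expect_equal(simulate_titration(1, 1e-6, 0, prot)$heats_ucal, rep(0, 19))
})

test_that("noise-free round trip recovers (n, kd, dh) across a c-value sweep", {
  for (cval in c(5, 50, 500)) {
    kd <- 20e-6 / cval
    expt <- simulate_titration(n = 1, kd = kd, dh = -12,
                               protocol = methods_protocol())
    fit <- fit_single_site(expt)
    expect_equal(fit$kd, kd, tolerance = 1e-6)
    expect_equal(fit$n, 1, tolerance = 1e-6)
    expect_equal(fit$dh, -12, tolerance = 1e-6)
  }
})

test_that("blank subtraction and first-injection handling are benign on clean data", {
  prot <- methods_protocol()
  expt <- simulate_titration(1, 1.11e-6, -10, prot)
  blank <- expt
  blank$heats_ucal <- rep(0.5, 19)  # constant dilution heat
  expt_b <- expt
  expt_b$heats_ucal <- expt$heats_ucal + 0.5
  fit <- fit_single_site(expt_b, blank = blank)
  expect_equal(fit$kd, 1.11e-6, tolerance = 1e-6)
  # discarding the first injection entirely moves Kd by < 1%
  fit_w0 <- fit_single_site(expt, first_injection_weight = 0)
  fit_def <- fit_single_site(expt)
  expect_lt(abs(fit_w0$kd - fit_def$kd) / fit_def$kd, 0.01)
})

test_that("Kd estimates under 2%-of-max noise at c = 50 achieve the information bound", {
  # The 19-injection schedule carries limited information about Kd: the
  # Cramer-Rao bound for this protocol/noise is about 12% relative SE, so the
  # calibration check is that the fitted-Kd spread matches the bound (an
  # efficient, unbiased estimator), with near-nominal 2-sigma coverage.
  prot <- methods_protocol()
  kd <- 20e-6 / 50
  clean <- simulate_titration(1, kd, -10, prot)
  noise_sd <- 0.02 * max(abs(clean$heats_ucal))
  jac <- vapply(1:3, function(k) {
    d <- 1e-5; par <- c(1, log(kd), -10); par[k] <- par[k] + d
    (simulate_titration(par[1], exp(par[2]), par[3], prot)$heats_ucal -
       clean$heats_ucal) / d
  }, numeric(19))
  crlb_se <- sqrt(diag(solve(crossprod(jac) / noise_sd^2)))[2]  # se of log Kd
  n_rep <- 200
  log_err <- vapply(seq_len(n_rep), function(s) {
    expt <- simulate_titration(1, kd, -10, prot, noise_sd = noise_sd, seed = s)
    fit <- tryCatch(fit_single_site(expt), error = function(e) NULL)
    if (is.null(fit)) NA_real_ else log(fit$kd / kd)
  }, numeric(1))
  expect_true(all(is.finite(log_err)))
  expect_lt(abs(mean(log_err)), 0.5 * crlb_se)          # unbiased
  expect_gt(sd(log_err), 0.7 * crlb_se)                 # efficient, not
  expect_lt(sd(log_err), 1.3 * crlb_se)                 #   over-dispersed
  expect_gte(mean(abs(log_err) < 2.2 * crlb_se), 0.95)  # ~2-sigma coverage
})

test_that("two identical independent sites fit as a single site with N = 2", {
  prot <- itc_protocol(cell_volume_ul = 200, cell_conc = 10e-6,
                       syringe_conc = 400e-6)
  expt <- simulate_two_site_titration(kd = 1e-6, dh = -10, protocol = prot)
  fit <- fit_single_site(expt)
  expect_equal(fit$n, 2, tolerance = 1e-6)
  expect_equal(fit$kd, 1e-6, tolerance = 1e-6)
  expect_equal(fit$dh, -10, tolerance = 1e-6)
})

test_that("fold change is a plain Kd ratio with reciprocal symmetry", {
  expect_equal(fold_change(2e-6, 2e-6), 1)
  expect_equal(fold_change(137 * 3e-8, 3e-8), 137)
  expect_equal(fold_change(5e-6, 2e-7) * fold_change(2e-7, 5e-6), 1)
})

test_that("CSP combines amide shifts with nitrogen down-weighting", {
  free <- peak_list(1:3, "X", c(8.0, 8.1, 8.2), c(120, 121, 122))
  bound <- peak_list(1:3, "X", c(8.0, 8.2, 8.2), c(120, 121.5, 122))
  out <- csp_compute(free, bound, n_weight = 5)
  expect_equal(out$records$csp[1], 0)
  expect_equal(out$records$csp[2], sqrt(0.1^2 + (0.5 / 5)^2), tolerance = 1e-9)
  # order invariance
  sh <- sample(3)
  out2 <- csp_compute(peak_list(sh, "X", c(8.0, 8.1, 8.2)[sh], c(120, 121, 122)[sh]),
                      bound, n_weight = 5)
  expect_equal(out2$records$csp, out$records$csp)
  # unit-scale property: scaling both dimensions scales the CSP
  f2 <- peak_list(1:3, "X", 2 * free$dH_ppm, 2 * free$dN_ppm)
  b2 <- peak_list(1:3, "X", 2 * bound$dH_ppm, 2 * bound$dN_ppm)
  expect_equal(csp_compute(f2, b2)$records$csp, 2 * out$records$csp)
})

test_that("perturbed-residue selection uses the mean + k SD rule", {
  recs <- data.frame(residue = 1:10, delta_h = 0, delta_n = 0,
                     csp = c(rep(0.01, 9), 0.1))
  expect_equal(csp_select_perturbed(recs), 10L)
  same <- data.frame(residue = 1:5, delta_h = 0, delta_n = 0, csp = rep(0.02, 5))
  expect_length(csp_select_perturbed(same), 0)  # SD = 0, strict inequality
  expect_equal(csp_select_perturbed(recs, cutoff = 0.005), 1:10)
})

test_that("planted perturbations are recovered from synthetic peak-list pairs", {
  set.seed(99)
  planted_res <- c(17, 24, 25, 27, 29, 30, 32, 36, 39, 44, 45, 47, 50, 55)
  planted <- data.frame(residue = planted_res,
                        dH = runif(14, 0.08, 0.2) * sample(c(-1, 1), 14, TRUE),
                        dN = runif(14, 0.5, 1.2) * sample(c(-1, 1), 14, TRUE))
  pair <- make_peak_list_pair(89, planted = planted, vanish = c(61, 70),
                              prolines = c(3, 12, 40, 66, 80), seed = 8)
  expect_false(any(c(3, 12, 40, 66, 80) %in% pair$free$residue))
  out <- csp_compute(pair$free, pair$bound)
  expect_equal(out$missing_in_bound, c(61L, 70L))
  expect_equal(csp_select_perturbed(out), sort(planted_res))
})

test_that("assignment completeness excludes prolines from the denominator", {
  expect_equal(assignment_completeness(79, 89, 5), 94.0)
  expect_equal(assignment_completeness(62, 75, 5), 88.6)
  expect_equal(assignment_completeness(0, 50, 0), 0)
  expect_error(assignment_completeness(85, 89, 5), "exceeds")
  expect_error(assignment_completeness(10, 10, 10), "prolines")
})
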