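test_that("Debye profile reproduces closed-form two-point values", {
  one <- conformer_model(matrix(0, 1, 3))
  expect_equal(compute_profile(one, c(0.01, 0.1, 0.3))$I, rep(1, 3))
  two <- conformer_model(matrix(c(0, 0, 0, 10, 0, 0), ncol = 3, byrow = TRUE))
  q <- c(1e-9, pi / 10)
  I <- compute_profile(two, q)$I
  expect_equal(I[1], 4, tolerance = 1e-9)   # (sum f)^2 at q -> 0
  expect_equal(I[2], 2, tolerance = 1e-12)  # 2 (1 + sin(qd)/(qd)) at qd = pi
})

test_that("Debye I(0) equals (sum f)^2 and bounds I(q) for random models", {
  set.seed(4)
  for (i in 1:10) {
    n <- sample(3:30, 1)
    m <- conformer_model(matrix(rnorm(n * 3, sd = 15), ncol = 3),
                         weights = runif(n, 0.2, 2))
    prof <- compute_profile(m, c(1e-9, seq(0.02, 0.4, by = 0.02)))
    expect_equal(prof$I[1], sum(m$weights)^2, tolerance = 1e-9)
    expect_true(all(prof$I <= prof$I[1] + 1e-9))
  }
})

test_that("ensemble averaging is a pointwise weighted mean", {
  q <- seq(0.01, 0.1, by = 0.01)
  c0 <- scattering_curve(q, rep(0, 10))
  c4 <- scattering_curve(q, rep(4, 10))
  expect_equal(ensemble_profile(list(c4, c4))$I, c4$I)
  expect_equal(ensemble_profile(list(c0, c4))$I, rep(2, 10))
  expect_equal(ensemble_profile(list(c0, c4), weights = c(0.25, 0.75))$I, rep(3, 10))
  expect_error(ensemble_profile(list(c0, scattering_curve(q + 1, rep(1, 10)))),
               "grid")
})

test_that("optimal scale matches the worked example and a dense grid search", {
  q <- c(0.01, 0.02)
  calc <- scattering_curve(q, c(1, 2))
  exp_ <- scattering_curve(q, c(2, 2), c(1, 1))
  expect_equal(optimal_scale(calc, exp_), 1.2, tolerance = 1e-12)
  expect_equal(optimal_scale(calc, scattering_curve(q, 3 * calc$I, c(1, 1))), 3)
  set.seed(11)
  for (i in 1:8) {
    K <- sample(10:60, 1)
    qq <- sort(runif(K, 0.01, 0.3))
    cc <- scattering_curve(qq, runif(K, 0.5, 5))
    ee <- scattering_curve(qq, runif(K, 0.5, 5), runif(K, 0.1, 1))
    mu <- optimal_scale(cc, ee)
    expect_equal(mu, grid_search_mu(cc, ee), tolerance = 1e-6)
  }
})

test_that("chi-square matches its definition and is scale invariant under free mu", {
  q <- c(0.01, 0.02)
  calc <- scattering_curve(q, c(1, 2))
  exp_ <- scattering_curve(q, c(2, 2), c(1, 1))
  fit <- saxs_chi2(calc, exp_)
  expect_equal(fit$mu, 1.2)
  expect_equal(fit$residuals, c(-0.8, 0.4))
  expect_equal(fit$chi2, 0.8)
  expect_equal(fit$chi2, mean(fit$residuals^2) * fit$K / (fit$K - 1))
  expect_equal(saxs_chi2(exp_, exp_, mu = 1)$chi2, 0)
  set.seed(12)
  for (cscale in c(0.01, 3, 250)) {
    qq <- seq(0.01, 0.3, length.out = 40)
    cc <- scattering_curve(qq, runif(40, 1, 5))
    ee <- scattering_curve(qq, runif(40, 1, 5), runif(40, 0.1, 0.5))
    scaled <- scattering_curve(qq, cscale * cc$I)
    expect_equal(saxs_chi2(scaled, ee)$chi2, saxs_chi2(cc, ee)$chi2,
                 tolerance = 1e-9)
  }
})

test_that("Guinier fit recovers exact synthetic parameters and scales correctly", {
  g <- guinier_fit(guinier_curve(rg = 20))
  expect_equal(g$rg, 20, tolerance = 1e-6)
  expect_equal(g$i0, 100, tolerance = 1e-6)
  g5 <- guinier_fit(guinier_curve(rg = 20, i0 = 500))
  expect_equal(g5$rg, 20, tolerance = 1e-6)
  expect_equal(g5$i0, 500, tolerance = 1e-6)
})

test_that("Guinier Rg agrees with the coordinate Rg at low q", {
  two <- conformer_model(matrix(c(-5, 0, 0, 5, 0, 0), ncol = 3, byrow = TRUE))
  rg_c <- rg_from_coords(two)  # 5 A by symmetry
  expect_equal(rg_c, 5)
  q <- seq(0.005, 1 / rg_c, length.out = 40)  # restrict to q Rg <= 1
  prof <- compute_profile(two, q)
  g <- guinier_fit(prof, qrg_max = 1.0)
  expect_equal(g$rg, rg_c, tolerance = 0.02)
})

test_that("coordinate Rg matches the pair-sum identity and the solid-sphere law", {
  set.seed(21)
  for (i in 1:5) {
    n <- sample(4:40, 1)
    m <- conformer_model(matrix(rnorm(n * 3, sd = 10), ncol = 3),
                         weights = runif(n, 0.5, 2))
    W <- sum(m$weights)
    d2 <- as.matrix(dist(m$points))^2
    rg_pair <- sqrt(sum(outer(m$weights, m$weights) * d2) / (2 * W^2))
    expect_equal(rg_from_coords(m), rg_pair, tolerance = 1e-9)
  }
  # Monte Carlo points in a ball of radius 30: Rg -> sqrt(3/5) * 30
  set.seed(22)
  pts <- matrix(runif(3 * 20000, -30, 30), ncol = 3)
  pts <- pts[rowSums(pts^2) <= 900, ][1:5000, ]
  expect_equal(rg_from_coords(conformer_model(pts)), sqrt(3 / 5) * 30,
               tolerance = 0.01)
})

test_that("PDDF is unit-normalized with mass at the pair distances", {
  two <- conformer_model(matrix(c(0, 0, 0, 10, 0, 0), ncol = 3, byrow = TRUE))
  p <- pddf_model(two, n_bins = 50)
  expect_equal(p$dmax, 10)
  integ <- sum(diff(p$r) * (p$p[-1] + p$p[-length(p$p)]) / 2)
  expect_equal(integ, 1, tolerance = 1e-9)
  expect_equal(p$r[which.max(p$p)], max(p$r))  # all mass in the r = 10 bin
  expect_error(pddf_model(conformer_model(matrix(0, 1, 3))), "pairs")
})

test_that("PDDF second moment reproduces Rg through the pair-sum identity", {
  set.seed(31)
  for (i in 1:4) {
    n <- sample(20:60, 1)
    m <- conformer_model(matrix(rnorm(n * 3, sd = 12), ncol = 3))
    p <- pddf_model(m, n_bins = 2000)  # fine bins: discretization ~ dmax/2000
    f <- p$r^2 * p$p
    second <- sum(diff(p$r) * (f[-1] + f[-length(f)]) / 2)
    rg2_est <- ((n - 1) / n) * second / 2
    expect_equal(sqrt(rg2_est), rg_from_coords(m), tolerance = 0.01)
  }
})

test_that("Kratky transform distinguishes globule from coil", {
  q <- seq(0.01, 0.6, length.out = 300)
  kg <- kratky_transform(scattering_curve(q, 100 * exp(-q^2 * 20^2 / 3)))
  imax <- which.max(kg$I)
  expect_gt(imax, 1); expect_lt(imax, length(q))  # interior maximum
  expect_equal(kratky_transform(scattering_curve(q, rep(3, 300)))$I, 3 * q^2)
  # Debye coil function plateaus at 2 I0 / Rg^2
  rg <- 20; i0 <- 50
  x <- q^2 * rg^2
  coil <- scattering_curve(q, i0 * 2 * (exp(-x) + x - 1) / x^2)
  kc <- kratky_transform(coil)
  tail_pts <- kc$I[q * rg >= 7.1]
  expect_true(all(abs(tail_pts / (2 * i0 / rg^2) - 1) < 0.02))
  # sigma propagates as q^2 sigma
  ks <- kratky_transform(scattering_curve(q, rep(1, 300), rep(0.1, 300)))
  expect_equal(ks$sigma, 0.1 * q^2)
})

test_that("NSD is zero under rigid motion and symmetric in its arguments", {
  set.seed(41)
  a <- conformer_model(matrix(rnorm(30, sd = 10), ncol = 3))
  ang <- pi / 2
  R <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  b <- conformer_model(sweep(a$points %*% t(R), 2, c(50, -20, 5), "+"))
  expect_equal(align_and_nsd(a, a)$nsd, 0, tolerance = 1e-6)
  expect_lt(align_and_nsd(a, b)$nsd, 1e-6)
  set.seed(42)
  c_ <- conformer_model(matrix(rnorm(24, sd = 8), ncol = 3))
  expect_equal(align_and_nsd(a, c_)$nsd, align_and_nsd(c_, a)$nsd,
               tolerance = 1e-9)
  expect_gt(align_and_nsd(a, c_)$nsd, 0)
})

test_that("NSD agrees with a brute-force rotation-grid search on toy models", {
  a <- conformer_model(matrix(c(0, 0, 0, 6, 0, 0, 0, 5, 0, 1, 1, 4),
                              ncol = 3, byrow = TRUE))
  b <- conformer_model(matrix(c(0.3, 0, 0, 6.2, 0.4, 0, 0, 4.6, 0.5, 0.8, 1.4, 3.6),
                              ncol = 3, byrow = TRUE))
  ours <- align_and_nsd(a, b)$nsd
  oracle <- nsd_oracle(a, b)
  expect_equal(ours, oracle, tolerance = 1e-3)
  expect_lte(ours, oracle + 1e-3)  # never worse than the grid
})
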