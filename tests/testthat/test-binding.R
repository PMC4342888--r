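test_that("the quadratic equilibrium matches a brute-force grid search", {
  b <- equilibrium_bound(2, 2, 2)
  b_oracle <- bound_grid_oracle(2, 2, 2)
  expect_equal(b, b_oracle, tolerance = 1e-5)
  # tight-binding limit: probe well below protein and K_d -> all bound
  # (bound fraction P/(P+Kd) = 0.99999)
  expect_equal(equilibrium_bound(100, 0.01, 0.001), 0.01, tolerance = 1e-4)
  # mass balance holds exactly
  for (kd in c(0.5, 2, 10)) {
    for (L in c(1, 4, 16)) {
      bb <- equilibrium_bound(2, L, kd)
      expect_lt(abs((2 - bb) * (L - bb) - kd * bb), 1e-10)
    }
  }
})

test_that("competition equilibrium satisfies mass balance to 1e-8", {
  for (ct in c(0, 0.5, 2, 8, 32)) {
    eq <- equilibrium_competition(2, 2, ct, 2, 1)
    expect_lt(eq$residual, 1e-8)
    expect_equal(eq$free_probe + eq$bound_probe, 2, tolerance = 1e-8)
  }
  # zero competitor reduces to the plain 1:1 curve
  eq0 <- equilibrium_competition(2, 2, 0, 2, 1)
  expect_equal(eq0$bound_probe, equilibrium_bound(2, 2, 2),
               tolerance = 1e-9)
})

test_that("titration generator is exact without noise and seeded with it", {
  tc <- simulate_titration(2, 2, probe_concs = seq(2, 16, 2))
  expect_equal(tc$points$fluorescence / tc$truth$scale,
               equilibrium_bound(2, seq(2, 16, 2), 2), tolerance = 1e-12)
  n1 <- simulate_titration(2, 2, noise_cv = 0.05, seed = 4)
  n2 <- simulate_titration(2, 2, noise_cv = 0.05, seed = 4)
  expect_identical(n1$points, n2$points)
  # competitor at 0 equals the no-competitor signal at the same probe conc
  cc <- simulate_titration(2, 2, competitor_kd = 1,
                           competitor_concs = c(0, 2, 4), probe_conc = 6)
  expect_equal(cc$points$fluorescence[1],
               1000 * equilibrium_bound(2, 6, 2), tolerance = 1e-9)
})

test_that("saturation fits recover the probe K_d to high accuracy", {
  for (kd in c(0.5, 1, 2, 5, 10)) {
    tc <- simulate_titration(2, kd, probe_concs = seq(2, 16, 2))
    ft <- fit_saturation(tc)
    expect_lt(abs(ft$k_probe - kd) / kd, 1e-3)
    expect_gt(ft$fit_r2, 0.999)
    expect_true(ft$converged)
  }
  # flat curve: no binding
  flat <- simulate_titration(2, 2)
  flat$points$fluorescence <- rep(100, nrow(flat$points))
  expect_error(fit_saturation(flat), "no-binding")
})

test_that("probe fits for 1-5 uM parameters come back in 1-5 uM", {
  # the working range reported for the odorant-binding-protein probes
  for (s in 1:3) {
    kd_true <- c(1.2, 2.8, 4.6)[s]
    tc <- simulate_titration(2, kd_true, probe_concs = seq(2, 16, 2),
                             noise_cv = 0.02, seed = 500 + s)
    ft <- fit_saturation(tc)
    expect_gt(ft$k_probe, 1)
    expect_lt(ft$k_probe, 5)
  }
})

test_that("Scatchard and direct nonlinear fits agree on noiseless data", {
  skip_if_not_installed("minpack.lm")
  tc <- simulate_titration(2, 3, probe_concs = seq(2, 16, 2))
  ft <- fit_saturation(tc)
  nls_fit <- minpack.lm::nlsLM(
    fluorescence ~ fsat / 2 * (((2 + conc + kd) -
      sqrt((2 + conc + kd)^2 - 8 * conc)) / 2),
    data = tc$points, start = list(fsat = max(tc$points$fluorescence) * 1.4,
                                   kd = 1))
  expect_lt(abs(ft$k_probe - coef(nls_fit)["kd"]) / coef(nls_fit)["kd"],
            0.02)
})

test_that("IC50 extraction: exact points, interpolation, censoring", {
  mk <- function(conc, f) structure(
    list(mode = "competition", protein_conc = 2, probe_conc = 2,
         points = data.frame(conc = conc, fluorescence = f), truth = NULL),
    class = "titration_curve")
  # exact half at a measured point
  out <- find_ic50(mk(c(0, 4, 8), c(100, 50, 20)))
  expect_equal(out$ic50, 4)
  expect_false(out$censored)
  # log-linear interpolation between bracketing points, verified against a
  # dense re-simulation of the generating equilibrium
  dense <- simulate_titration(2, 2, competitor_kd = 1,
                              competitor_concs = c(0, seq(0.25, 24, 0.05)),
                              probe_conc = 2)
  coarse <- simulate_titration(2, 2, competitor_kd = 1,
                               competitor_concs = c(0, 2, 8, 16),
                               probe_conc = 2)
  ic_dense <- find_ic50(dense)$ic50
  ic_coarse <- find_ic50(coarse)$ic50
  expect_lt(abs(ic_coarse - ic_dense) / ic_dense, 0.05)
  # never halves: censored lower bound at the top tested concentration
  out2 <- find_ic50(mk(c(0, 2, 8), c(100, 80, 60)))
  expect_true(out2$censored)
  expect_equal(out2$ic50, 8)
  expect_error(find_ic50(mk(c(0, 2, 8), c(0, -1, -2))), "F0")
})

test_that("kd_from_ic50 follows the printed equation and its limits", {
  expect_equal(kd_from_ic50(4, 2, 2), 2)
  # no-probe-competition limit: K_d -> IC50
  expect_equal(kd_from_ic50(4, 1e-12, 2), 4, tolerance = 1e-9)
  # monotonicity: increasing in ic50 and k_probe, decreasing in probe conc
  expect_gt(kd_from_ic50(5, 2, 2), kd_from_ic50(4, 2, 2))
  expect_gt(kd_from_ic50(4, 2, 3), kd_from_ic50(4, 2, 2))
  expect_lt(kd_from_ic50(4, 3, 2), kd_from_ic50(4, 2, 2))
})

test_that("the full competitor pipeline recovers a planted K_d", {
  errs <- vapply(1:8, function(s) {
    tc <- simulate_titration(2, 2, competitor_kd = 1,
                             competitor_concs = c(0, seq(1, 16)),
                             probe_conc = 2, noise_cv = 0.02,
                             seed = 700 + s)
    fc <- fit_competitor(tc, k_probe = 2)
    abs(fc$k_d - 1)
  }, 0)
  expect_lt(median(errs), 0.15)
  # censoring soundness: un-censored IC50s lie inside the tested range
  tc2 <- simulate_titration(2, 2, competitor_kd = 50,
                            competitor_concs = c(0, 1, 2, 4),
                            probe_conc = 2)
  fc2 <- fit_competitor(tc2, k_probe = 2)
  expect_true(fc2$censored)
})

test_that("micelle artifacts perturb only the high-concentration tail", {
  clean <- simulate_titration(2, 2, competitor_kd = 1,
                              competitor_concs = c(0, 0.5, 1, 2, 4, 8, 16),
                              probe_conc = 2)
  mic <- simulate_titration(2, 2, competitor_kd = 1,
                            competitor_concs = c(0, 0.5, 1, 2, 4, 8, 16),
                            probe_conc = 2,
                            micelle_onset = 6, micelle_slope = 50)
  expect_equal(clean$points$fluorescence[1:5], mic$points$fluorescence[1:5])
  expect_true(all(mic$points$fluorescence[6:7] >
                    clean$points$fluorescence[6:7]))
})
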