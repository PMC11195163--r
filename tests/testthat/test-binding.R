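test_that("observed anisotropy matches direct evaluation", {
  iso <- observed_anisotropy(2, 2, 2, 2)
  expect_equal(iso$G, 1)
  expect_equal(iso$r_obs, 0)
  expect_equal(observed_anisotropy(3, 1, 2, 2)$r_obs, 0.4)
  expect_equal(observed_anisotropy(3, 1, 2, 2)$G, 1)
  # fully polarised limit
  expect_equal(observed_anisotropy(5, 0, 2, 2)$r_obs, 1)
  expect_error(observed_anisotropy(-1, 1, 1, 1), "positive")
})

test_that("quadratic isotherm matches hand evaluation and limits", {
  expect_equal(fraction_bound(0.67, 1.0, 0.2), 0.5694, tolerance = 1e-3)
  expect_equal(fraction_bound(0.67, 0, 0.2), 0)
  expect_equal(fraction_bound(1e-9, 1.0, 0.2), 1, tolerance = 1e-6)
  # monotonicity
  kds <- c(0.1, 0.5, 1, 5, 20)
  expect_true(all(diff(vapply(kds, fraction_bound, numeric(1),
                              l_total = 1, m_total = 0.2)) < 0))
  L <- seq(0, 10, by = 0.5)
  fb <- fraction_bound(0.67, L, 0.2)
  expect_true(all(diff(fb) > 0))
  expect_true(all(fb >= 0 & fb <= 1))
  # degenerate macromolecule concentration falls back to the hyperbola
  h <- fraction_bound(2, 4, 0)
  expect_equal(as.numeric(h), 4 / 6)
  expect_identical(attr(h, "limit"), "hyperbolic")
})

test_that("quadratic isotherm agrees with a numeric mass-action root", {
  grid <- expand.grid(kd = c(0.05, 0.67, 5, 120),
                      L = seq(0.04, 40, length.out = 25))
  for (i in seq_len(nrow(grid))) {
    expect_equal(fraction_bound(grid$kd[i], grid$L[i], 0.2),
                 mass_action_root(grid$kd[i], grid$L[i], 0.2),
                 tolerance = 1e-10)
  }
})

test_that("anisotropy observable model matches hand evaluation", {
  expect_equal(anisotropy_model(0, 0.05, 0.15, 0.8), 0.05)
  expect_equal(anisotropy_model(1, 0.05, 0.15, 0.8), 0.15)
  expect_equal(anisotropy_model(1, 0.05, 0.15, 3), 0.15)
  fb <- fraction_bound(0.67, 1.0, 0.2)
  expect_equal(anisotropy_model(fb, 0.05, 0.15, 0.8), 0.1014, tolerance = 1e-3)
  # Q = 1 reduces exactly to linear mixing
  f <- seq(0, 1, by = 0.05)
  expect_equal(anisotropy_model(f, 0.03, 0.2, 1), 0.03 + f * (0.2 - 0.03))
  expect_error(anisotropy_model(1.2, 0.05, 0.15, 1), "0, 1")
})

test_that("anisotropy fit recovers noiseless truth exactly", {
  grid <- c(0, exp(seq(log(0.05), log(20), length.out = 13)))
  ser <- generate_anisotropy_titration(binding_params(0.67, 0.05, 0.15, 0.8),
                                       0.2, grid, noise_sd = 0)
  fit <- fit_anisotropy_titration(ser)
  expect_true(fit$converged)
  expect_equal(fit$params$kd, 0.67, tolerance = 1e-6)
  expect_equal(fit$params$r_f, 0.05, tolerance = 1e-8)
  expect_equal(fit$params$r_b, 0.15, tolerance = 1e-8)
  expect_equal(fit$params$q, 0.8, tolerance = 1e-6)
  expect_lt(sqrt(sum(fit$residuals^2)), 1e-10)
})

test_that("anisotropy fit honours fixed parameters and preconditions", {
  grid <- c(0, exp(seq(log(0.05), log(20), length.out = 13)))
  ser <- generate_anisotropy_titration(binding_params(0.67, 0.05, 0.15, 0.8),
                                       0.2, grid, noise_sd = 0.002, seed = 4)
  fit <- fit_anisotropy_titration(ser, fix = list(q = 0.8))
  expect_true(fit$converged)
  expect_lt(abs(fit$params$kd / 0.67 - 1), 0.1)
  expect_equal(fit$params$q, 0.8)
  expect_false("q" %in% names(fit$params_vec))
  short <- titration_series(c(0, 1, 2), c(0.05, 0.1, 0.14), 0.2, "anisotropy")
  expect_error(fit_anisotropy_titration(short), "6")
  flat <- titration_series(grid, rep(0.07, length(grid)), 0.2, "anisotropy")
  expect_false(fit_anisotropy_titration(flat)$converged)
  expect_error(fit_anisotropy_titration(ser, fix = list(zz = 1)), "unknown")
})

test_that("CSP titration fit recovers truth and scales linearly", {
  gpaper <- c(50, 100, 150, 250, 375, 500, 750, 1000, 1500, 2000, 2500)
  clean <- generate_csp_titration(100, 0.2, 500, gpaper, noise_sd = 0)
  fit <- fit_csp_titration(clean)
  expect_true(fit$converged)
  expect_equal(fit$kd, 100, tolerance = 1e-6)
  expect_equal(fit$dmax, 0.2, tolerance = 1e-8)
  doubled <- clean
  doubled$observable <- 2 * clean$observable
  fit2 <- fit_csp_titration(doubled)
  expect_equal(fit2$dmax, 2 * fit$dmax, tolerance = 1e-6)
  expect_equal(fit2$kd, fit$kd, tolerance = 1e-6)
  expect_error(fit_csp_titration(titration_series(c(1, 2, 3, 4), c(0, .1, .2, .3),
                                                  1, "csp")), "5")
})

test_that("CSP K_D recovery in the stoichiometric regime is within 15 percent", {
  gpaper <- c(50, 100, 150, 250, 375, 500, 750, 1000, 1500, 2000, 2500)
  errs <- vapply(1:7, function(s) {
    ser <- generate_csp_titration(100, 0.2, 500, gpaper, noise_sd = 0.004,
                                  seed = s)
    abs(fit_csp_titration(ser)$kd / 100 - 1)
  }, numeric(1))
  # M/K_D = 5 makes single titrations noisy; the median seed is the check
  expect_lt(median(errs), 0.15)
})

test_that("profile-likelihood intervals cover the K_D truth with Q floating", {
  grid <- c(0, exp(seq(log(0.05), log(20), length.out = 13)))
  covered <- vapply(1:50, function(s) {
    ser <- generate_anisotropy_titration(binding_params(0.67, 0.05, 0.15, 0.8),
                                         0.2, grid, noise_sd = 0.002, seed = s)
    ci <- kd_profile_interval(ser)
    ci$lower <= 0.67 && 0.67 <= ci$upper
  }, logical(1))
  expect_gte(sum(covered), 45)
})

test_that("relative affinity reproduces the experimental fold difference", {
  expect_equal(relative_affinity(0.67, 1.9), 2.8358, tolerance = 1e-4)
  expect_equal(round(relative_affinity(0.67, 1.9), 1), 2.8)
  expect_equal(relative_affinity(2, 2), 1)
  expect_error(relative_affinity(0, 1), "positive")
})
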