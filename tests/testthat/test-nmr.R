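test_that("exponential decay fit recovers noiseless parameters exactly", {
  delays <- seq(0.02, 1, length.out = 10)
  ser <- generate_decay_series(0.2, 100, delays, noise_sd = 0)
  fit <- fit_exponential_decay(ser)
  expect_true(fit$converged)
  expect_equal(fit$T, 0.2, tolerance = 1e-8)
  expect_equal(fit$I0, 100, tolerance = 1e-8)
})

test_that("decay fit tolerates noise and flags degenerate data", {
  delays <- seq(0.02, 1, length.out = 10)
  noisy <- generate_decay_series(0.2, 100, delays, noise_sd = 1, seed = 7)
  fit <- fit_exponential_decay(noisy)
  expect_true(fit$converged)
  expect_lt(abs(fit$T / 0.2 - 1), 0.05)
  expect_gt(fit$se_T, 0)
  flat <- relaxation_series(delays, rep(5, 10))
  expect_false(fit_exponential_decay(flat)$converged)
  rising <- relaxation_series(delays, seq(1, 10))
  expect_false(fit_exponential_decay(rising)$converged)
  expect_error(relaxation_series(c(-0.1, 0.2, 0.4), c(3, 2, 1)), "non-negative")
  expect_error(relaxation_series(c(0.1, 0.1, 0.1), c(3, 2, 1)), "distinct")
})

test_that("duplicate delays are averaged before fitting", {
  delays <- c(0.05, 0.05, 0.2, 0.4, 0.8)
  ints <- c(90, 92, 60, 35, 15)
  fit <- fit_exponential_decay(relaxation_series(delays, ints))
  expect_equal(fit$n_averaged, 1L)
  merged <- fit_exponential_decay(
    relaxation_series(c(0.05, 0.2, 0.4, 0.8), c(91, 60, 35, 15)))
  expect_equal(fit$T, merged$T, tolerance = 1e-10)
})

test_that("decay-time recovery is unbiased at 1 percent noise", {
  delays <- seq(0.02, 1, length.out = 12)
  t_hat <- vapply(1:100, function(s) {
    fit_exponential_decay(generate_decay_series(0.2, 100, delays,
                                                noise_sd = 1, seed = s))$T
  }, numeric(1))
  expect_lt(abs(mean(t_hat) / 0.2 - 1), 0.01)
})

test_that("combined CSP matches hand evaluation and its bounds", {
  expect_equal(csp(0, 0), 0)
  expect_equal(csp(0.05, 0.5), sqrt(0.05^2 + (0.10137 * 0.5)^2), tolerance = 1e-12)
  expect_equal(csp(0.05, 0.5), 0.0712, tolerance = 1e-3)
  expect_equal(csp(0.1, 0), 0.1)
  expect_equal(csp(0.02, 0.3, nucleus_x = "carbon13"),
               sqrt(0.02^2 + (0.2516 * 0.3)^2))
  # symmetric under sign flips; never below either scaled component
  set.seed(23)
  for (i in 1:20) {
    dh <- rnorm(1, 0, 0.1); dx <- rnorm(1, 0, 1)
    v <- csp(dh, dx)
    expect_equal(v, csp(-dh, dx))
    expect_equal(v, csp(dh, -dx))
    expect_gte(v, max(abs(dh), 0.10137 * abs(dx)) / sqrt(2))
  }
  expect_error(csp(0.1, 0.2, gamma_ratio = 1.5), "ratio")
})

test_that("secondary shifts subtract the coil reference", {
  coil <- data.frame(residue = 1:4, ca = c(56, 58, 45, 57),
                     cb = c(30, 32, NA, 33))
  obs <- coil
  expect_equal(secondary_shifts(obs, coil)$ss, rep(0, 4))
  obs2 <- coil
  obs2$ca[2] <- coil$ca[2] + 2
  obs2$cb[2] <- coil$cb[2] - 0.5
  out <- secondary_shifts(obs2, coil)
  expect_equal(out$ss[2], 2.5)
  # glycine row (no Cbeta) falls back to the Calpha deviation, flagged
  obs2$ca[3] <- coil$ca[3] + 1.2
  out <- secondary_shifts(obs2, coil)
  expect_equal(out$ss[3], 1.2)
  expect_equal(out$flag[3], "ca_only")
  expect_error(secondary_shifts(obs2[1:3, ], coil), "aligned")
})

test_that("secondary shifts are linear in the observed shifts and smoothable", {
  coil <- data.frame(residue = 1:6, ca = rep(56, 6), cb = rep(30, 6))
  o1 <- coil; o1$ca <- coil$ca + c(1, 0, 2, 0, 1, 0)
  o2 <- coil; o2$cb <- coil$cb + c(0, 1, 0, 2, 0, 1)
  both <- coil
  both$ca <- o1$ca; both$cb <- o2$cb
  expect_equal(secondary_shifts(both, coil)$ss,
               secondary_shifts(o1, coil)$ss + secondary_shifts(o2, coil)$ss)
  sm <- secondary_shifts(o1, coil, smoothing_window = 3)$ss
  raw <- secondary_shifts(o1, coil)$ss
  expect_equal(sm[2], mean(raw[1:3]))
  expect_equal(sm[1], mean(raw[1:2]))     # truncated edge window
  expect_error(secondary_shifts(o1, coil, smoothing_window = 2), "odd")
})

test_that("hetNOE is a plain peak-height ratio", {
  expect_equal(het_noe(1, 1), 1)
  expect_equal(het_noe(0, 2), 0)
  expect_equal(het_noe(0.75, 1.0), 0.75)
  expect_error(het_noe(0.5, 0), "nonzero")
})
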