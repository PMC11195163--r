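test_that("generators are pure functions of their seed", {
  e1 <- sample_frc_ensemble(15, n_frames = 50, seed = 41)
  e2 <- sample_frc_ensemble(15, n_frames = 50, seed = 41)
  expect_identical(e1$xyz, e2$xyz)
  expect_false(identical(e1$xyz, sample_frc_ensemble(15, n_frames = 50, seed = 42)$xyz))
  tr <- binding_truth(0.01, 0.02)
  t1 <- simulate_binding_trajectory(tr, 500, seed = 41)
  t2 <- simulate_binding_trajectory(tr, 500, seed = 41)
  expect_identical(t1$distance, t2$distance)
  grid <- c(0, 0.5, 1, 2, 4, 8)
  s1 <- generate_anisotropy_titration(binding_params(0.67), 0.2, grid, seed = 41)
  s2 <- generate_anisotropy_titration(binding_params(0.67), 0.2, grid, seed = 41)
  expect_identical(s1$observable, s2$observable)
  d1 <- generate_decay_series(0.2, 100, c(0, 0.1, 0.2), noise_sd = 1, seed = 41)
  d2 <- generate_decay_series(0.2, 100, c(0, 0.1, 0.2), noise_sd = 1, seed = 41)
  expect_identical(d1$intensity, d2$intensity)
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(sample_frc_ensemble(5, n_frames = 3, seed = 1))
  invisible(generate_decay_series(0.2, 1, c(0, 1, 2), noise_sd = 1, seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("FRC sampler satisfies its geometric constraints exactly", {
  model <- null_chain_model(l = 3.8, alpha = 0.8)
  e <- sample_frc_ensemble(12, model, n_frames = 30, seed = 43)
  for (f in c(1, 17, 30)) {
    xyz <- frame_coords(e, f)
    bonds <- diff(xyz)
    lens <- sqrt(rowSums(bonds^2))
    expect_equal(lens, rep(3.8, 11), tolerance = 1e-10)
    units <- bonds / lens
    cosines <- rowSums(units[-1, ] * units[-nrow(units), ])
    expect_equal(cosines, rep(0.8, 10), tolerance = 1e-10)
  }
  # two-residue chains are a single exact bond
  e2 <- sample_frc_ensemble(2, model, n_frames = 10, seed = 44)
  d <- sqrt(colSums((e2$xyz[2, , ] - e2$xyz[1, , ])^2))
  expect_equal(d, rep(3.8, 10), tolerance = 1e-10)
})

test_that("FRC sampler converges to the closed-form mean squared distance", {
  e <- sample_frc_ensemble(68, n_frames = 20000, seed = 45)
  samples <- colSums((e$xyz[11, , ] - e$xyz[1, , ])^2)
  sem <- sd(samples) / sqrt(length(samples))
  expect_lt(abs(mean(samples) - 784.0193), 3 * sem)
})

test_that("binding truth wires the stationary fraction to mass action", {
  tr <- binding_truth(0.02, 0.02)
  expect_equal(tr$f_star, 0.5)
  expect_equal(tr$kd_uM, simulation_box(40)$c_box_uM * 0.5)
  tr2 <- binding_truth_at_fraction(0.8, p_off = 0.02)
  expect_equal(tr2$p_on / (tr2$p_on + tr2$p_off), 0.8)
  expect_error(binding_truth(0, 0.5), "0, 1")
  expect_error(binding_truth(0.5, 1), "0, 1")
  expect_error(binding_truth_at_fraction(1), "0, 1")
})

test_that("two-state chain matches its switching probabilities", {
  tr <- binding_truth(0.02, 0.02)
  traj <- simulate_binding_trajectory(tr, 1e5, seed = 47)
  states <- attr(traj, "states")
  expect_lt(abs(mean(states) - 0.5), 0.02)
  # empirical transition rates inside binomial 99 percent intervals
  from_b <- which(states[-length(states)])
  off_hat <- sum(!states[from_b + 1])
  ci_off <- qbinom(c(0.005, 0.995), length(from_b), tr$p_off)
  expect_gte(off_hat, ci_off[1])
  expect_lte(off_hat, ci_off[2])
  from_u <- which(!states[-length(states)])
  on_hat <- sum(states[from_u + 1])
  ci_on <- qbinom(c(0.005, 0.995), length(from_u), tr$p_on)
  expect_gte(on_hat, ci_on[1])
  expect_lte(on_hat, ci_on[2])
})

test_that("distance emission respects the state-conditional distributions", {
  tr <- binding_truth(0.05, 0.05, mu_b = 30, sigma_b = 6)
  traj <- simulate_binding_trajectory(tr, 20000, seed = 49)
  states <- attr(traj, "states")
  rmax <- tr$box$edge_ang * sqrt(3) / 2
  expect_true(all(traj$distance > 0))
  expect_true(all(traj$distance[!states] <= rmax))
  expect_equal(mean(traj$distance[states]), 30, tolerance = 0.02)
  # r^2-weighted unbound density has mean 3/4 of its upper edge
  expect_equal(mean(traj$distance[!states]), 0.75 * rmax, tolerance = 0.02)
})

test_that("titration and decay generators reduce to their forward models", {
  grid <- c(0, 0.5, 1, 2, 4, 8, 16)
  p <- binding_params(0.67, 0.05, 0.15, 0.8)
  clean <- generate_anisotropy_titration(p, 0.2, grid, noise_sd = 0)
  expect_equal(clean$observable,
               anisotropy_model(fraction_bound(0.67, grid, 0.2), 0.05, 0.15, 0.8))
  expect_equal(clean$observable[1], 0.05)   # zero-ligand point is r_F
  ccsp <- generate_csp_titration(100, 0.2, 500, c(50, 500, 5000, 5e4, 5e5),
                                 noise_sd = 0)
  expect_equal(ccsp$observable[1], 0.2 * fraction_bound(100, 50, 500))
  expect_gt(ccsp$observable[5], 0.199)      # saturates at dmax
  dec <- generate_decay_series(0.2, 100, c(0, 0.1, 0.4), noise_sd = 0)
  expect_equal(dec$intensity, 100 * exp(-c(0, 0.1, 0.4) / 0.2))
  expect_equal(dec$intensity[1], 100)
  expect_error(generate_decay_series(-1, 100, c(0, 1, 2)), "positive")
  expect_error(generate_anisotropy_titration(p, 0.2, c(-1, 0, 1)), "non-negative")
})

test_that("titration refit study recovers the experimental constants", {
  st <- titration_refit_study(seed = 7)
  expect_lt(abs(st$kd_fit[["tar"]] / 0.67 - 1), 0.1)
  expect_lt(abs(st$kd_fit[["ru30"]] / 1.9 - 1), 0.1)
  expect_lt(abs(st$fold_ratio / (1.9 / 0.67) - 1), 0.15)
})
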