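test_that("simulation box concentration follows Avogadro arithmetic", {
  box <- simulation_box(40)
  expect_equal(box$c_box_uM, 25.946, tolerance = 1e-4)
  expect_equal(box$edge_ang, 400)
  # doubling the volume halves the single-pair concentration
  box2 <- simulation_box(40 * 2^(1 / 3))
  expect_equal(box2$c_box_uM, box$c_box_uM / 2, tolerance = 1e-10)
  expect_error(simulation_box(-1), "positive")
})

test_that("coarse-graining keeps one C1' bead per nucleotide per model", {
  tf <- tempfile(fileext = ".pdb")
  write_toy_rna_pdb(tf, n_nt = 4, n_models = 3)
  expect_warning(cg <- coarse_grain_rna_structure(tf), "HOH")
  expect_equal(n_beads(cg), 4)
  expect_equal(n_frames(cg), 3)
  # beads carry the C1' coordinates with nucleotide numbering preserved
  expect_equal(frame_coords(cg, 2)[, 1], c(2, 4, 6, 8))
  expect_equal(frame_coords(cg, 3)[, 3], rep(2, 4))
  expect_equal(cg$labels$name, c("G1", "A2", "C3", "U4"))
  tf2 <- tempfile(fileext = ".pdb")
  write_toy_rna_pdb(tf2, n_nt = 3, n_models = 1, with_water = FALSE,
                    drop_c1_in = 2)
  expect_error(coarse_grain_rna_structure(tf2), "missing atom C1'.*A:2")
})

test_that("COM distances honour the minimum-image convention", {
  box <- simulation_box(40)
  pair <- conformational_ensemble(rbind(c(0, 0, 0), c(30, 0, 0)))
  expect_equal(com_distance_trajectory(pair, 1, 2, box)$distance, 30)
  wrapped <- conformational_ensemble(rbind(c(5, 0, 0), c(395, 0, 0)))
  expect_equal(com_distance_trajectory(wrapped, 1, 2, box)$distance, 10)
  # rigid translation of both groups leaves distances unchanged
  shifted <- conformational_ensemble(rbind(c(5, 0, 0), c(395, 0, 0)) +
                                       matrix(c(123, -7, 50), 2, 3, byrow = TRUE))
  expect_equal(com_distance_trajectory(shifted, 1, 2, box)$distance, 10,
               tolerance = 1e-10)
  expect_error(com_distance_trajectory(pair, 1, 1, box), "disjoint")
})

test_that("two-Gaussian fit recovers a known mixture", {
  set.seed(31)
  x <- c(rnorm(25000, 30, 5), rnorm(25000, 150, 40))
  fit <- fit_two_gaussian_rdf(x)
  expect_true(fit$converged)
  expect_true(fit$bound_present && fit$unbound_present)
  expect_lt(abs(fit$mu1 / 30 - 1), 0.02)
  expect_lt(abs(fit$mu2 / 150 - 1), 0.02)
  # mirrored input gives the mirrored parameters
  fitm <- fit_two_gaussian_rdf(400 - x)
  expect_equal(fitm$mu1, 400 - fit$mu2, tolerance = 1)
  expect_equal(fitm$mu2, 400 - fit$mu1, tolerance = 1)
})

test_that("unimodal distance distributions are flagged unbound-only", {
  set.seed(33)
  u <- 346 * runif(40000)^(1 / 3)   # r^2-weighted unbound emission only
  fit <- fit_two_gaussian_rdf(u)
  expect_true(fit$converged)
  expect_false(fit$bound_present)
  expect_true(fit$unbound_present)
  expect_error(bound_threshold(fit), "undefined")
})

test_that("bound threshold is the component-density intersection", {
  mk_fit <- function(a1, m1, s1, a2, m2, s2) {
    structure(list(a1 = a1, mu1 = m1, sigma1 = s1, a2 = a2, mu2 = m2,
                   sigma2 = s2, converged = TRUE, separated = TRUE,
                   bound_present = TRUE, unbound_present = TRUE,
                   message = "ok"), class = "two_gaussian_fit")
  }
  # symmetric mixture: exact midpoint
  expect_equal(bound_threshold(mk_fit(0.5, 30, 10, 0.5, 150, 10)), 90,
               tolerance = 1e-6)
  # skewed amplitudes: compare to a dense-grid sign-change oracle
  f <- mk_fit(0.6, 30, 8, 0.3, 150, 35)
  grid <- seq(30, 150, by = 1e-4)
  dens_diff <- 0.6 * dnorm(grid, 30, 8) - 0.3 * dnorm(grid, 150, 35)
  oracle <- grid[which(diff(sign(dens_diff)) != 0)[1]]
  expect_equal(bound_threshold(f), oracle, tolerance = 1e-3)
})

test_that("bound-frame classification matches a brute-force oracle", {
  trace <- c(40, 40, 40, 60, 60, 40, 40, 40, 40, 40, 40, 60, 40, 40, 60,
             60, 60, 60, 60, 60)
  ann <- classify_bound_frames(trace, threshold = 50, min_run = 5)
  expect_equal(sum(ann$bound), 6)           # runs of 3 and 6: only the 6 kept
  expect_equal(which(ann$bound), 6:11)
  none <- classify_bound_frames(rep(60, 10), 50, 5)
  expect_equal(sum(none$bound), 0)
  # min_run = 1 degenerates to plain thresholding
  plain <- classify_bound_frames(trace, 50, 1)
  expect_equal(plain$bound, trace < 50)
  # property check against the oracle on random traces
  set.seed(37)
  for (i in 1:20) {
    n <- sample(200:5000, 1)
    below <- runif(n) < runif(1, 0.2, 0.8)
    mr <- sample(1:8, 1)
    ann <- classify_bound_frames(ifelse(below, 10, 90), 50, mr)
    expect_identical(ann$bound, runlength_oracle(below, mr))
  }
})

test_that("apparent K_D follows single-pair mass action in the box", {
  box <- simulation_box(40)
  ann <- classify_bound_frames(c(rep(10, 50), rep(90, 50)), 50, 5)
  expect_equal(ann$fraction_bound, 0.5)
  kd <- apparent_kd(ann, box)
  expect_equal(kd$kd_uM, box$c_box_uM * 0.5, tolerance = 1e-12)
  expect_equal(kd$kd_uM, 12.97, tolerance = 1e-3)
  # correction factor is explicit and multiplicative
  expect_equal(apparent_kd(ann, box, correction = 0.8)$kd_uM, kd$kd_uM * 0.8)
  allb <- classify_bound_frames(rep(10, 20), 50, 5)
  expect_error(apparent_kd(allb, box), "unbound")
  allu <- classify_bound_frames(rep(90, 20), 50, 5)
  expect_error(apparent_kd(allu, box), "bound")
})

test_that("relative K_D normalises to the reference affinity", {
  expect_equal(relative_kd(1, 3.5), 3.5)
  expect_equal(relative_kd(2, 2), 1)
  expect_error(relative_kd(1, 0), "positive")
})

test_that("contact frequencies enumerate bound frames", {
  # two molecules of one bead each over four frames
  coords <- list(rbind(c(0, 0, 0), c(5, 0, 0)),
                 rbind(c(0, 0, 0), c(40, 0, 0)),
                 rbind(c(0, 0, 0), c(5, 0, 0)),
                 rbind(c(0, 0, 0), c(400, 0, 0)))
  e <- conformational_ensemble(coords)
  ann <- classify_bound_frames(c(10, 10, 10, 90), 50, 1)
  cm <- contact_frequency(e, 1, 2, ann, cutoff = 15)
  expect_equal(cm$frequency[1, 1], 2 / 3)   # within 15 A in 2 of 3 bound frames
  expect_equal(cm$n_bound_frames, 3)
  # permanently-in-contact and never-in-contact pairs
  always <- contact_frequency(e, 1, 2,
                              classify_bound_frames(c(10, 90, 10, 90), 50, 1),
                              cutoff = 15)
  expect_equal(always$frequency[1, 1], 1)
  never <- contact_frequency(e, 1, 2,
                             classify_bound_frames(c(90, 10, 90, 90), 50, 1),
                             cutoff = 15)
  expect_equal(never$frequency[1, 1], 0)
  # frequencies never decrease when the cutoff grows
  wide <- contact_frequency(e, 1, 2, ann, cutoff = 45)
  expect_true(all(wide$frequency >= cm$frequency))
  nob <- classify_bound_frames(rep(90, 4), 50, 1)
  expect_error(contact_frequency(e, 1, 2, nob), "no bound frames")
})

test_that("the full pipeline recovers the generator's mass-action truth", {
  truth <- binding_truth_at_fraction(0.5)
  traj <- simulate_binding_trajectory(truth, 1e5, seed = 3)
  fit <- fit_two_gaussian_rdf(traj)
  thr <- bound_threshold(fit)
  ann <- classify_bound_frames(traj, thr, min_run = 5)
  kd <- apparent_kd(ann, truth$box)
  expect_lt(abs(ann$fraction_bound - truth$f_star), 0.03)
  expect_lt(abs(kd$kd_uM / truth$kd_uM - 1), 0.15)
})
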