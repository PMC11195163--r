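# Run code under a temporary RNG state derived from an integer seed,
# restoring the caller's stream afterwards so generators are pure functions
# of their arguments.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    stop("seed must be a single integer")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Sample a freely-rotating-chain ensemble
#'
#' Builds chains with a fixed bond length `l` and a fixed cosine `alpha` of
#' the bond-angle supplement, with uniformly distributed dihedrals: the
#' generative counterpart of the closed-form mean squared distance, so that
#' sampled mean squared separations converge to it. Bond length and bond
#' angle hold exactly on every frame by construction. Deterministic given
#' the seed.
#'
#' @param n_residues Number of beads (>= 2).
#' @param model A [null_chain_model()].
#' @param n_frames Number of independent chains to draw.
#' @param seed Integer seed.
#' @return A [conformational_ensemble()].
#' @export
sample_frc_ensemble <- function(n_residues, model = null_chain_model(),
                                n_frames = 1000, seed = 1) {
  stopifnot(inherits(model, "null_chain_model"))
  if (n_residues < 2) stop("n_residues must be >= 2")
  if (n_frames < 1) stop("n_frames must be >= 1")
  l <- model$l
  a <- model$alpha
  with_seed(seed, {
    nb <- as.integer(n_residues)
    nf <- as.integer(n_frames)
    # unit bond vectors, one matrix (n_frames x 3) per bond index
    u <- matrix(stats::rnorm(nf * 3), nf, 3)
    u <- u / sqrt(rowSums(u^2))
    coords <- array(0, dim = c(nb, 3, nf))
    coords[2, , ] <- t(u) * l
    if (nb > 2) {
      sin_t <- sqrt(1 - a^2)
      for (k in 3:nb) {
        # orthonormal frame (v, w) perpendicular to the previous bond u
        helper <- matrix(0, nf, 3)
        hm <- max.col(-abs(u))            # least-aligned axis per row
        helper[cbind(seq_len(nf), hm)] <- 1
        v <- cbind(u[, 2] * helper[, 3] - u[, 3] * helper[, 2],
                   u[, 3] * helper[, 1] - u[, 1] * helper[, 3],
                   u[, 1] * helper[, 2] - u[, 2] * helper[, 1])
        v <- v / sqrt(rowSums(v^2))
        w <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                   u[, 3] * v[, 1] - u[, 1] * v[, 3],
                   u[, 1] * v[, 2] - u[, 2] * v[, 1])
        phi <- stats::runif(nf, 0, 2 * pi)
        u <- a * u + sin_t * (cos(phi) * v + sin(phi) * w)
        u <- u / sqrt(rowSums(u^2))       # guard against drift
        coords[k, , ] <- coords[k - 1, , ] + t(u) * l
      }
    }
    conformational_ensemble(coords)
  })
}

#' Two-state binding truth record
#'
#' Parameters of the synthetic bound/unbound distance process: per-frame
#' Markov switching probabilities, the bound-state distance distribution,
#' and the box. The stationary bound fraction is
#' `f* = p_on / (p_on + p_off)` and the implied mass-action dissociation
#' constant is `K_D = c_box (1 - f*)^2 / f*`.
#'
#' Defaults emulate the coarse-grained runs the pipeline was built for: a
#' 40 nm periodic box, a bound well at 30 +/- 6 A (centre-of-mass contact
#' distance of a ~70-residue chain with a ~30-mer RNA), and dwell times of
#' tens to hundreds of frames so that a 1e5-frame trajectory holds a few
#' hundred association/dissociation events.
#'
#' @param p_on Unbound-to-bound switching probability per frame, in (0, 1).
#' @param p_off Bound-to-unbound switching probability per frame, in (0, 1).
#' @param mu_b,sigma_b Bound-state distance distribution (A).
#' @param box A [simulation_box()].
#' @return Object of class `binding_truth` with derived `f_star` and
#'   `kd_uM`.
#' @export
binding_truth <- function(p_on, p_off, mu_b = 30, sigma_b = 6,
                          box = simulation_box(40)) {
  if (p_on <= 0 || p_on >= 1 || p_off <= 0 || p_off >= 1) {
    stop("switching probabilities must lie in (0, 1)")
  }
  if (mu_b <= 0 || sigma_b <= 0) stop("bound-state distribution must be positive")
  f <- p_on / (p_on + p_off)
  structure(list(p_on = p_on, p_off = p_off, mu_b = mu_b, sigma_b = sigma_b,
                 box = box, f_star = f,
                 kd_uM = box$c_box_uM * (1 - f)^2 / f),
            class = "binding_truth")
}

#' Convenience: binding truth at a target stationary bound fraction
#'
#' Chooses `p_on` for a given `p_off` so that the stationary bound fraction
#' equals `f_star`.
#'
#' @param f_star Target stationary bound fraction in (0, 1).
#' @param p_off Bound-to-unbound switching probability (default 0.02,
#'   i.e. a mean bound dwell of 50 frames).
#' @inheritParams binding_truth
#' @return A [binding_truth()].
#' @export
binding_truth_at_fraction <- function(f_star, p_off = 0.02, mu_b = 30,
                                      sigma_b = 6, box = simulation_box(40)) {
  if (f_star <= 0 || f_star >= 1) stop("f_star must lie in (0, 1)")
  binding_truth(p_on = p_off * f_star / (1 - f_star), p_off = p_off,
                mu_b = mu_b, sigma_b = sigma_b, box = box)
}

#' Simulate a two-state centre-of-mass distance trajectory
#'
#' A bound/unbound Markov chain with the truth's switching probabilities.
#' Bound frames emit distances from a positive-truncated normal
#' `N(mu_b, sigma_b)`; unbound frames emit distances with density
#' proportional to r^2 on (0, half-edge * sqrt(3)) — a tractable stand-in
#' for the separation of two uniformly placed molecules in a periodic box
#' that affects only the unbound mode's shape, not the bound/unbound
#' fractions. The initial state is drawn from the stationary distribution.
#'
#' @param truth A [binding_truth()].
#' @param n_frames Number of frames (>= 50).
#' @param seed Integer seed.
#' @return A `com_trajectory` (see [com_distance_trajectory()]) carrying
#'   the truth and the latent state sequence as attributes `truth` and
#'   `states`.
#' @export
simulate_binding_trajectory <- function(truth, n_frames, seed = 1) {
  stopifnot(inherits(truth, "binding_truth"))
  if (n_frames < 50) stop("n_frames must be >= 50")
  with_seed(seed, {
    n <- as.integer(n_frames)
    stay_b <- 1 - truth$p_off
    stay_u <- 1 - truth$p_on
    u01 <- stats::runif(n)
    states <- logical(n)                  # TRUE = bound
    states[1] <- u01[1] < truth$f_star
    for (i in 2:n) {
      states[i] <- if (states[i - 1]) u01[i] < stay_b else u01[i] >= stay_u
    }
    nb <- sum(states)
    d <- numeric(n)
    if (nb > 0) {
      db <- stats::rnorm(nb, truth$mu_b, truth$sigma_b)
      while (any(db <= 0)) {
        db[db <= 0] <- stats::rnorm(sum(db <= 0), truth$mu_b, truth$sigma_b)
      }
      d[states] <- db
    }
    if (nb < n) {
      rmax <- truth$box$edge_ang * sqrt(3) / 2
      d[!states] <- rmax * stats::runif(n - nb)^(1 / 3)
    }
    structure(data.frame(frame = seq_len(n), distance = d),
              box = truth$box, truth = truth, states = states,
              class = c("com_trajectory", "data.frame"))
  })
}

#' Generate a synthetic anisotropy titration
#'
#' Forward model of the 1:1 quadratic isotherm pushed through the
#' anisotropy observable, plus i.i.d. Gaussian noise.
#'
#' @param params A [binding_params()] (K_D, r_F, r_B, Q).
#' @param m_total Total fluorescent macromolecule concentration, uM.
#' @param ligand_grid Strictly increasing ligand totals, uM.
#' @param noise_sd Gaussian noise SD in anisotropy units.
#' @param seed Integer seed.
#' @return A [titration_series()] of kind `"anisotropy"` with the truth
#'   stored in attribute `truth`.
#' @export
generate_anisotropy_titration <- function(params, m_total, ligand_grid,
                                          noise_sd = 0.002, seed = 1) {
  stopifnot(inherits(params, "binding_params"))
  if (any(ligand_grid < 0)) stop("concentrations must be non-negative")
  fb <- fraction_bound(params$kd, ligand_grid, m_total)
  mu <- anisotropy_model(fb, params$r_f, params$r_b, params$q)
  obs <- with_seed(seed, mu + stats::rnorm(length(mu), 0, noise_sd))
  out <- titration_series(ligand_grid, obs, m_total, kind = "anisotropy")
  attr(out, "truth") <- params
  out
}

#' Generate a synthetic CSP titration
#'
#' `csp(L) = dmax * F_B(K_D, L, M) + noise`.
#'
#' @param kd True dissociation constant, uM.
#' @param dmax Saturating combined shift change, ppm.
#' @inheritParams generate_anisotropy_titration
#' @return A [titration_series()] of kind `"csp"`.
#' @export
generate_csp_titration <- function(kd, dmax, m_total, ligand_grid,
                                   noise_sd = 0.002, seed = 1) {
  if (any(ligand_grid < 0)) stop("concentrations must be non-negative")
  mu <- dmax * fraction_bound(kd, ligand_grid, m_total)
  obs <- with_seed(seed, mu + stats::rnorm(length(mu), 0, noise_sd))
  out <- titration_series(ligand_grid, obs, m_total, kind = "csp")
  attr(out, "truth") <- list(kd = kd, dmax = dmax)
  out
}

#' Synthetic titration refit study
#'
#' The desk-scale counterpart of the study's affinity comparison: for each
#' true dissociation constant, generate `replicates` technical-replicate
#' anisotropy titrations, average them point-wise, and refit the 1:1 model
#' conditioning on the known intensity factor Q (for generated data Q is
#' known, and conditioning on it removes the shallow K_D-Q valley that
#' otherwise dominates single-titration uncertainty; see
#' [kd_profile_interval()] for interval estimates with Q floating).
#'
#' Defaults reproduce the study conditions: 200 nM labelled RNA, a dense
#' 28-point ligand grid spanning 0.03-40 uM (the grid density is a design
#' choice: it keeps the ratio of the two fitted constants conditioned to a
#' few percent), anisotropy noise 0.002, three technical replicates, and
#' the two experimentally fitted dissociation constants (0.67 uM for the
#' structured stem-loop, 1.9 uM for the unstructured 30-mer).
#'
#' @param kd_truth Named vector of true dissociation constants (uM).
#' @param seed Integer seed; replicate sub-seeds are derived from it.
#' @param replicates Technical replicates averaged per titration.
#' @param m_total Labelled macromolecule concentration, uM.
#' @param ligand_grid Ligand totals, uM.
#' @param noise_sd Anisotropy noise SD.
#' @param r_f,r_b,q Observable parameters of the generator.
#' @return List with `kd_fit` (named vector), `kd_truth`, and
#'   `fold_ratio` = max/min of the fitted constants (length-2 input only).
#' @export
titration_refit_study <- function(kd_truth = c(tar = 0.67, ru30 = 1.9),
                                  seed = 1, replicates = 3, m_total = 0.2,
                                  ligand_grid = c(0, exp(seq(log(0.03), log(40),
                                                             length.out = 27))),
                                  noise_sd = 0.002,
                                  r_f = 0.05, r_b = 0.15, q = 0.8) {
  kd_fit <- vapply(seq_along(kd_truth), function(i) {
    reps <- lapply(seq_len(replicates), function(r) {
      generate_anisotropy_titration(
        binding_params(kd_truth[[i]], r_f, r_b, q), m_total, ligand_grid,
        noise_sd = noise_sd,
        seed = (as.integer(seed) * 1009L + i * 101L + r) %% 2147483647L)
    })
    avg <- reps[[1]]
    avg$observable <- rowMeans(vapply(reps, function(x) x$observable,
                                      numeric(length(ligand_grid))))
    fit <- fit_anisotropy_titration(avg, fix = list(q = q))
    if (!fit$converged) stop("titration refit failed: ", fit$message)
    fit$params$kd
  }, numeric(1))
  names(kd_fit) <- names(kd_truth)
  out <- list(kd_fit = kd_fit, kd_truth = kd_truth)
  if (length(kd_fit) == 2) {
    out$fold_ratio <- relative_affinity(min(kd_fit), max(kd_fit))
  }
  out
}

#' Generate a synthetic single-exponential decay series
#'
#' @param T Decay time constant, s (> 0).
#' @param I0 Intensity at zero delay.
#' @param delays Non-negative delays, s.
#' @param noise_sd Gaussian noise SD in intensity units.
#' @param seed Integer seed.
#' @return A [relaxation_series()].
#' @export
generate_decay_series <- function(T, I0, delays, noise_sd = 0, seed = 1) {
  if (T <= 0) stop("T must be positive")
  if (any(delays < 0)) stop("delays must be non-negative")
  mu <- I0 * exp(-delays / T)
  obs <- with_seed(seed, mu + stats::rnorm(length(mu), 0, noise_sd))
  relaxation_series(delays, obs)
}
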