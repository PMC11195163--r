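#' Scattering profile container
#'
#' @param q Momentum transfer grid in inverse angstroms; strictly increasing
#'   and positive.
#' @param intensity Positive intensities (arbitrary units).
#' @return A data frame of class `scattering_profile` with columns `q`, `I`.
#' @export
scattering_profile <- function(q, intensity) {
  if (any(q <= 0) || any(diff(q) <= 0)) stop("q must be positive and strictly increasing")
  if (any(intensity <= 0)) stop("intensities must be positive")
  structure(data.frame(q = q, I = intensity),
            class = c("scattering_profile", "data.frame"))
}

#' Debye forward scattering of an ensemble
#'
#' Ensemble-averaged Debye sum with unit form factors,
#' `I(q) = < sum_ij sin(q r_ij) / (q r_ij) >_frames`, so that I(q -> 0)
#' approaches N^2 for N beads. This is a plumbing-level forward model that
#' lets Guinier/Kratky analyses be exercised on simulated ensembles; it does
#' not attempt solvent-layer or atomic form-factor corrections.
#'
#' @param ensemble A [conformational_ensemble()].
#' @param q Positive q grid (1/angstrom).
#' @return A [scattering_profile()].
#' @export
debye_scattering <- function(ensemble, q) {
  stopifnot(inherits(ensemble, "conformational_ensemble"))
  if (any(q <= 0)) stop("q must be positive")
  nb <- n_beads(ensemble)
  nf <- n_frames(ensemble)
  acc <- numeric(length(q))
  for (i in seq_len(nf)) {
    xyz <- ensemble$xyz[, , i, drop = FALSE]
    dim(xyz) <- dim(xyz)[1:2]
    r <- as.numeric(stats::dist(xyz))      # unique pairs
    qr <- outer(r, q)                      # pairs x q
    acc <- acc + nb + 2 * colSums(sin(qr) / qr)
  }
  scattering_profile(q, acc / nf)
}

#' Analytical Debye-function profile of a Gaussian chain
#'
#' `I(q) = I0 * 2 (exp(-x) + x - 1) / x^2` with `x = (q Rg)^2`: the
#' closed-form scattering of an ideal chain, used as an independent oracle
#' for Guinier and Kratky analyses.
#'
#' @param q Positive q grid (1/angstrom).
#' @param rg Radius of gyration in angstroms.
#' @param i0 Forward scattering intensity.
#' @return A [scattering_profile()].
#' @export
debye_function_profile <- function(q, rg, i0 = 1) {
  x <- (q * rg)^2
  scattering_profile(q, i0 * 2 * (exp(-x) + x - 1) / x^2)
}

#' Guinier fit of a scattering profile
#'
#' Linear fit of ln I against q^2 over a low-q window, iteratively shrunk
#' from the high-q end until the self-consistency condition
#' `q_max * Rg <= qrg_limit` holds; then `Rg = sqrt(-3 slope)` and
#' `I0 = exp(intercept)`. A non-negative slope or a window with fewer than
#' `min_points` points yields a failure result (`converged = FALSE`) rather
#' than an error.
#'
#' @param profile A [scattering_profile()].
#' @param qrg_limit Upper bound on q*Rg for the fitted window; 1.1 by
#'   default (the classical 1.3 is also reasonable for disordered chains).
#' @param min_points Minimum points in the fitted window (default 4).
#' @return Object of class `guinier_fit`: `rg`, `i0`, `q_range`,
#'   `n_points`, `converged`, `message`.
#' @export
guinier_fit <- function(profile, qrg_limit = 1.1, min_points = 4) {
  q <- profile$q
  I <- profile$I
  failure <- function(msg) {
    structure(list(rg = NA_real_, i0 = NA_real_, q_range = c(NA_real_, NA_real_),
                   n_points = 0L, converged = FALSE, message = msg),
              class = "guinier_fit")
  }
  hi <- length(q)
  for (iter in seq_len(length(q) + 1L)) {
    if (hi < min_points) return(failure("too few points inside the Guinier window"))
    idx <- seq_len(hi)
    fit <- stats::lm(log(I[idx]) ~ I(q[idx]^2))
    slope <- stats::coef(fit)[[2]]
    if (!is.finite(slope) || slope >= 0) {
      return(failure("non-negative Guinier slope (unphysical profile)"))
    }
    rg <- sqrt(-3 * slope)
    if (q[hi] * rg <= qrg_limit) {
      return(structure(list(
        rg = rg, i0 = exp(stats::coef(fit)[[1]]),
        q_range = c(q[1], q[hi]), n_points = hi,
        converged = TRUE, message = "ok"
      ), class = "guinier_fit"))
    }
    # shrink window to the largest q satisfying q*Rg <= limit (at least drop one)
    ok <- which(q * rg <= qrg_limit)
    hi <- min(hi - 1L, if (length(ok)) max(ok) else 0L)
  }
  failure("Guinier range iteration did not converge")
}

#' @export
print.guinier_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("<guinier_fit: Rg = %.2f A, I0 = %.4g, %d pts, qmax*Rg = %.2f>\n",
                x$rg, x$i0, x$n_points, x$q_range[2] * x$rg))
  } else {
    cat(sprintf("<guinier_fit: FAILED (%s)>\n", x$message))
  }
  invisible(x)
}

#' Dimensionless Kratky transform
#'
#' Returns `(q Rg, (q Rg)^2 I(q) / I0)` on the native q grid. For an ideal
#' chain the ordinate plateaus at 2 at large q*Rg; compact globule-like
#' profiles instead peak (near qRg = sqrt(3)) and decay.
#'
#' @param profile A [scattering_profile()].
#' @param guinier A converged [guinier_fit()] supplying Rg and I0.
#' @return Data frame with columns `qrg` and `kratky`.
#' @export
dimensionless_kratky <- function(profile, guinier) {
  if (!inherits(guinier, "guinier_fit") || !isTRUE(guinier$converged)) {
    stop("dimensionless_kratky needs a converged guinier_fit")
  }
  if (!is.finite(guinier$i0) || guinier$i0 <= 0) stop("I0 must be positive")
  qrg <- profile$q * guinier$rg
  data.frame(qrg = qrg, kratky = qrg^2 * profile$I / guinier$i0)
}
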