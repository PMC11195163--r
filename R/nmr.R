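#' Relaxation decay series
#'
#' Delays (s) with measured intensities. Duplicate delays are allowed (they
#' are averaged before fitting, their spread contributing to the reported
#' uncertainty).
#'
#' @param delays Non-negative delays in seconds, at least 3 distinct.
#' @param intensities Finite intensities, same length.
#' @return Object of class `relaxation_series` (a data frame).
#' @export
relaxation_series <- function(delays, intensities) {
  if (any(delays < 0)) stop("delays must be non-negative")
  if (length(unique(delays)) < 3) stop("need at least 3 distinct delays")
  if (length(delays) != length(intensities) || !all(is.finite(intensities))) {
    stop("intensities must be finite and match delays in length")
  }
  structure(data.frame(delay = delays, intensity = intensities),
            class = c("relaxation_series", "data.frame"))
}

#' Fit a single-exponential relaxation decay
#'
#' Least-squares fit of `I = I0 exp(-t / T)` (the T1/T2 decay model) with
#' parameter uncertainties from the fit covariance. Duplicate delays are
#' averaged first. Non-decaying or flat data yield a failure result
#' (`converged = FALSE`) rather than an error.
#'
#' @param series A [relaxation_series()] (or anything coercible: a data
#'   frame with `delay` and `intensity` columns).
#' @return List of class `decay_fit`: `T`, `I0`, `se_T`, `se_I0`,
#'   `converged`, `message`, `n_averaged` (duplicates merged per delay).
#' @export
fit_exponential_decay <- function(series) {
  d <- as.data.frame(series)
  if (any(d$delay < 0)) stop("delays must be non-negative")
  agg <- stats::aggregate(intensity ~ delay, data = d, FUN = mean)
  agg <- agg[order(agg$delay), ]
  t <- agg$delay
  y <- agg$intensity
  failure <- function(msg) {
    structure(list(T = NA_real_, I0 = NA_real_, se_T = NA_real_,
                   se_I0 = NA_real_, converged = FALSE, message = msg,
                   n_averaged = nrow(d) - nrow(agg)),
              class = "decay_fit")
  }
  if (length(t) < 3) return(failure("need >= 3 distinct delays"))
  if (stats::sd(y) == 0) return(failure("constant intensities"))
  if (any(y <= 0) || stats::cor(t, y) >= 0) {
    # log-linear init impossible or data not decaying; try anyway via nls
    if (stats::cor(t, y) >= 0) return(failure("intensities do not decay"))
  }
  # log-linear initialisation
  pos <- y > 0
  ini <- stats::lm(log(y[pos]) ~ t[pos])
  T0 <- -1 / stats::coef(ini)[[2]]
  if (!is.finite(T0) || T0 <= 0) T0 <- diff(range(t)) / 2
  I00 <- exp(stats::coef(ini)[[1]])
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ I0 * exp(-t / Tc), start = list(I0 = I00, Tc = T0),
                      lower = c(0, 1e-12)),
    error = function(e) NULL
  )
  if (is.null(fit)) return(failure("nonlinear fit did not converge"))
  co <- summary(fit)$coefficients
  structure(list(T = co["Tc", "Estimate"], I0 = co["I0", "Estimate"],
                 se_T = co["Tc", "Std. Error"], se_I0 = co["I0", "Std. Error"],
                 converged = TRUE, message = "ok",
                 n_averaged = nrow(d) - nrow(agg)),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("<decay_fit: T = %.4g +/- %.2g s, I0 = %.4g +/- %.2g>\n",
                x$T, x$se_T, x$I0, x$se_I0))
  } else cat(sprintf("<decay_fit: FAILED (%s)>\n", x$message))
  invisible(x)
}

# gamma_X / gamma_H ratios used to weight heteronuclear shifts in combined CSPs
CSP_GAMMA_RATIO <- c(nitrogen15 = 0.10137, carbon13 = 0.2516)

#' Combined chemical shift perturbation
#'
#' `delta = sqrt(dH^2 + (gamma_X/gamma_H * dX)^2)`, the standard combined
#' 1H/X chemical-shift change upon titration. Vectorised.
#'
#' @param delta_h 1H shift change(s), ppm.
#' @param delta_x Heteronucleus shift change(s), ppm.
#' @param nucleus_x `"nitrogen15"` (ratio 0.10137) or `"carbon13"` (0.2516).
#' @param gamma_ratio Optional explicit gamma_X/gamma_H in (0, 1).
#' @return Combined CSP(s) in ppm.
#' @export
csp <- function(delta_h, delta_x, nucleus_x = c("nitrogen15", "carbon13"),
                gamma_ratio = NULL) {
  if (is.null(gamma_ratio)) {
    nucleus_x <- match.arg(nucleus_x)
    gamma_ratio <- CSP_GAMMA_RATIO[[nucleus_x]]
  }
  if (gamma_ratio <= 0 || gamma_ratio >= 1) stop("gamma ratio must lie in (0, 1)")
  sqrt(delta_h^2 + (gamma_ratio * delta_x)^2)
}

#' Secondary chemical shifts
#'
#' Per-residue secondary-structure statistic from Calpha/Cbeta shifts
#' referenced against a random-coil table:
#' `(Ca_obs - Ca_coil) - (Cb_obs - Cb_coil)`. Positive values indicate
#' helical propensity, negative extended/strand character. Residues without
#' a Cbeta shift (glycines) use the Calpha deviation alone and are flagged.
#' An optional centred mean-smoothing window (truncated at the chain ends)
#' may be applied.
#'
#' @param observed Data frame with columns `residue`, `ca`, `cb` (ppm;
#'   `cb` may contain NA).
#' @param coil Coil-reference data frame with the same columns, aligned by
#'   `residue`.
#' @param smoothing_window Odd window for mean smoothing; 1 = none.
#' @return Data frame with `residue`, `d_ca`, `d_cb`, `ss`, `flag`.
#' @export
secondary_shifts <- function(observed, coil, smoothing_window = 1) {
  if (nrow(observed) != nrow(coil) || !all(observed$residue == coil$residue)) {
    stop("observed and coil tables must be aligned on the same residues")
  }
  if (smoothing_window %% 2 == 0 || smoothing_window < 1) {
    stop("smoothing_window must be odd and >= 1")
  }
  d_ca <- observed$ca - coil$ca
  d_cb <- observed$cb - coil$cb
  ss <- ifelse(is.na(d_cb), d_ca, d_ca - d_cb)
  flag <- ifelse(is.na(d_cb), "ca_only", "")
  if (smoothing_window > 1) {
    half <- (smoothing_window - 1) %/% 2
    n <- length(ss)
    ss <- vapply(seq_len(n), function(i) {
      w <- ss[max(1, i - half):min(n, i + half)]
      mean(w, na.rm = TRUE)
    }, numeric(1))
  }
  data.frame(residue = observed$residue, d_ca = d_ca, d_cb = d_cb,
             ss = ss, flag = flag)
}

#' Heteronuclear NOE ratio
#'
#' Ratio of peak heights with and without proton saturation.
#'
#' @param sat_height Saturated peak height(s).
#' @param ref_height Reference peak height(s); must be nonzero.
#' @return `sat_height / ref_height`.
#' @export
het_noe <- function(sat_height, ref_height) {
  if (any(ref_height == 0)) stop("reference height must be nonzero")
  sat_height / ref_height
}
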