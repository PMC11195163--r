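#' Observed anisotropy from polarised intensities
#'
#' `G = I_hv / I_hh` (instrument correction factor) and
#' `r_obs = (I_vv - G I_vh) / (I_vv + 2 G I_vh)`.
#'
#' @param ivv,ivh,ihv,ihh Polarised fluorescence intensities; the subscripts
#'   give excitation/emission polariser orientations. `ivv`, `ihv`, `ihh`
#'   must be positive; `ivh` may be zero (the fully polarised limit, r = 1).
#' @return List with `G` and `r_obs`.
#' @export
observed_anisotropy <- function(ivv, ivh, ihv, ihh) {
  if (any(c(ivv, ihv, ihh) <= 0) || any(ivh < 0)) {
    stop("intensities must be positive (ivh may be zero)")
  }
  G <- ihv / ihh
  list(G = G, r_obs = (ivv - G * ivh) / (ivv + 2 * G * ivh))
}

#' 1:1 binding model parameters
#'
#' @param kd Dissociation constant, uM (> 0).
#' @param r_f Anisotropy of the free fluorescent species.
#' @param r_b Anisotropy of the bound species.
#' @param q Intensity-change factor between free and bound states (> 0);
#'   1 means fluorescence intensity is unchanged on binding.
#' @return Object of class `binding_params`.
#' @export
binding_params <- function(kd, r_f = 0.05, r_b = 0.15, q = 1) {
  if (kd <= 0) stop("kd must be positive")
  if (q <= 0) stop("q must be positive")
  structure(list(kd = kd, r_f = r_f, r_b = r_b, q = q),
            class = "binding_params")
}

#' Fraction of the fluorescent macromolecule bound (1:1 quadratic isotherm)
#'
#' Exact solution of 1:1 mass action at total concentrations:
#' `F_B = (b - sqrt(b^2 - 4 L M)) / (2 M)` with `b = K_D + L + M`, where `L`
#' is total ligand (the titrated, unlabelled species) and `M` total
#' macromolecule (the fluorescent species the observable reports on).
#' When `M = 0` the hyperbolic limit `L / (K_D + L)` is used and flagged via
#' the `"limit"` attribute. Vectorised over `l_total`.
#'
#' @param kd Dissociation constant (same units as the concentrations, uM
#'   throughout this package).
#' @param l_total Total ligand concentration(s), >= 0.
#' @param m_total Total macromolecule concentration, >= 0.
#' @return Fraction(s) bound in \[0, 1\].
#' @export
fraction_bound <- function(kd, l_total, m_total) {
  if (kd <= 0) stop("kd must be positive")
  if (any(l_total < 0) || m_total < 0) stop("concentrations must be non-negative")
  if (m_total == 0) {
    out <- l_total / (kd + l_total)
    attr(out, "limit") <- "hyperbolic"
    return(out)
  }
  b <- kd + l_total + m_total
  fb <- (b - sqrt(b^2 - 4 * l_total * m_total)) / (2 * m_total)
  pmin(pmax(fb, 0), 1)
}

#' Anisotropy observable for a given bound fraction
#'
#' `r_obs = (Q F_B r_B + r_F (1 - F_B)) / (1 - F_B (1 - Q))`: fractional
#' mixing of free and bound anisotropies with an intensity-weighting factor
#' Q correcting for fluorescence-intensity differences between states. With
#' Q = 1 this reduces exactly to linear mixing.
#'
#' @param f_b Bound fraction(s) in \[0, 1\].
#' @param r_f,r_b Free and bound anisotropies.
#' @param q Intensity-change factor (> 0).
#' @return Observed anisotropy value(s).
#' @export
anisotropy_model <- function(f_b, r_f, r_b, q = 1) {
  if (any(f_b < 0 | f_b > 1)) stop("f_b must lie in [0, 1]")
  denom <- 1 - f_b * (1 - q)
  if (any(denom <= 0)) stop("model denominator must be positive")
  (q * f_b * r_b + r_f * (1 - f_b)) / denom
}

#' Titration series container
#'
#' @param ligand_total Strictly increasing, non-negative totals of the
#'   titrated ligand (uM).
#' @param observable Anisotropy or CSP values, same length.
#' @param m_total Total concentration of the observed macromolecule (uM).
#' @param kind `"anisotropy"` or `"csp"`.
#' @return Data frame of class `titration_series` with attributes
#'   `m_total` and `kind`.
#' @export
titration_series <- function(ligand_total, observable, m_total,
                             kind = c("anisotropy", "csp")) {
  kind <- match.arg(kind)
  if (any(ligand_total < 0) || any(diff(ligand_total) <= 0)) {
    stop("ligand totals must be non-negative and strictly increasing")
  }
  if (!all(is.finite(observable)) || length(observable) != length(ligand_total)) {
    stop("observable must be finite and match ligand grid")
  }
  if (m_total <= 0) stop("m_total must be positive")
  structure(data.frame(ligand_total = ligand_total, observable = observable),
            m_total = m_total, kind = kind,
            class = c("titration_series", "data.frame"))
}

#' Fit a fluorescence-anisotropy titration to the 1:1 model
#'
#' Nonlinear least squares of the composed model
#' `anisotropy_model(fraction_bound(K_D, L, M), r_F, r_B, Q)` over the four
#' parameters, honouring any fixed subset. Initialisation: r_F from the
#' first point, r_B from the last, Q = 1, K_D at the ligand concentration
#' where the observable crosses half range; K_D and Q are bounded positive.
#'
#' @param series A [titration_series()] of kind `"anisotropy"` with at
#'   least 6 points.
#' @param fix Named list of parameters to hold fixed, e.g.
#'   `list(q = 1)`; names among kd, r_f, r_b, q.
#' @return List of class `binding_fit`: `params` (a [binding_params()]),
#'   `se` (named standard errors, NA for fixed), `residuals`, `converged`,
#'   `message`.
#' @export
fit_anisotropy_titration <- function(series, fix = list()) {
  stopifnot(inherits(series, "titration_series"))
  if (attr(series, "kind") != "anisotropy") stop("series must be an anisotropy titration")
  L <- series$ligand_total
  y <- series$observable
  if (length(L) < 6) stop("need at least 6 titration points")
  if (stats::sd(y) == 0) {
    return(structure(list(params = NULL, se = NULL, residuals = NULL,
                          converged = FALSE, message = "flat observable"),
                     class = "binding_fit"))
  }
  M <- attr(series, "m_total")
  start <- list(kd = kd_init(L, y), r_f = y[1], r_b = y[length(y)], q = 1)
  lower <- c(kd = 1e-9, r_f = -0.5, r_b = -0.5, q = 1e-6)
  bad <- setdiff(names(fix), names(start))
  if (length(bad)) stop("unknown fixed parameter(s): ", paste(bad, collapse = ", "))
  free <- setdiff(names(start), names(fix))
  model_fun <- function(p) {
    pp <- c(as.list(p), fix)
    anisotropy_model(fraction_bound(pp$kd, L, M), pp$r_f, pp$r_b, pp$q)
  }
  # multi-start over K_D (and Q when free) to escape the shallow K_D-Q valley
  extra <- list()
  for (kd_try in start$kd * c(0.2, 1, 5)) {
    for (q_try in if ("q" %in% free) c(0.5, 1, 2) else 1) {
      st <- utils::modifyList(start, list(kd = kd_try, q = q_try))
      extra[[length(extra) + 1L]] <- st[free]
    }
  }
  fit_nls_generic(model_fun, y, start[free], lower[free], fix,
                  extra_starts = extra)
}

#' Fit a CSP titration to the 1:1 model
#'
#' Least squares of `csp(L) = dmax * F_B(K_D, L, M)` for the apparent
#' dissociation constant and the saturating shift change.
#'
#' @param series A [titration_series()] of kind `"csp"` with >= 5 points.
#' @return List of class `binding_fit` with elements `kd`, `dmax`, `se`,
#'   `residuals`, `converged`, `message`.
#' @export
fit_csp_titration <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  if (attr(series, "kind") != "csp") stop("series must be a csp titration")
  L <- series$ligand_total
  y <- series$observable
  if (length(L) < 5) stop("need at least 5 titration points")
  M <- attr(series, "m_total")
  start <- list(kd = kd_init(L, y), dmax = max(y))
  model_fun <- function(p) p$dmax * fraction_bound(p$kd, L, M)
  extra <- lapply(c(0.05, 0.2, 1, 5) * max(M, start$kd),
                  function(k) list(kd = k, dmax = max(y) * 1.5))
  out <- fit_nls_generic(model_fun, y, start,
                         lower = c(kd = 1e-9, dmax = 1e-12), fix = list(),
                         extra_starts = extra)
  if (out$converged) {
    out$kd <- out$params_vec[["kd"]]
    out$dmax <- out$params_vec[["dmax"]]
  }
  out
}

# ligand concentration at which the observable crosses half range
kd_init <- function(L, y) {
  target <- (y[1] + y[length(y)]) / 2
  i <- which.min(abs(y - target))
  max(L[i], min(L[L > 0]))
}

# shared bounded Levenberg-Marquardt driver over a named-parameter model;
# multi-start over a list of initialisations, keeping the least-SSR fit
fit_nls_generic <- function(model_fun, y, start, lower, fix, extra_starts = list()) {
  pn <- names(start)
  run_one <- function(st) {
    tryCatch(
      minpack.lm::nls.lm(
        par = unlist(st)[pn],
        lower = unname(lower[pn]),
        fn = function(par) {
          y - model_fun(stats::setNames(as.list(par), pn))
        },
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
  }
  fits <- lapply(c(list(start), extra_starts), run_one)
  fits <- Filter(function(f) !is.null(f) && !f$info %in% c(0, 5, 9), fits)
  failure <- function(msg) {
    structure(list(params = NULL, se = NULL, residuals = NULL,
                   converged = FALSE, message = msg),
              class = "binding_fit")
  }
  if (length(fits) == 0) return(failure("optimizer did not converge"))
  ssr <- vapply(fits, function(f) sum(f$fvec^2), numeric(1))
  fit <- fits[[which.min(ssr)]]
  est <- stats::setNames(fit$par, pn)
  se <- tryCatch(
    stats::setNames(summary(fit)$coefficients[, "Std. Error"], pn),
    error = function(e) stats::setNames(rep(NA_real_, length(pn)), pn)
  )
  all_par <- c(as.list(est), fix)
  params <- if (all(c("kd", "r_f", "r_b", "q") %in% names(all_par))) {
    binding_params(all_par$kd, all_par$r_f, all_par$r_b, all_par$q)
  } else NULL
  structure(list(params = params, params_vec = est, se = se,
                 residuals = fit$fvec, fixed = fix,
                 converged = TRUE, message = "ok"),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("<binding_fit: FAILED (%s)>\n", x$message))
    return(invisible(x))
  }
  est <- x$params_vec
  cat("<binding_fit>\n")
  for (nm in names(est)) {
    cat(sprintf("  %-5s %10.4g +/- %.3g\n", nm, est[[nm]], x$se[[nm]]))
  }
  invisible(x)
}

#' Profile-likelihood confidence interval for a fitted K_D
#'
#' The K_D-Q covariance of the 1:1 anisotropy model makes linearised
#' (Wald) standard errors optimistic, so interval estimates for K_D are
#' computed by profiling: for each candidate K_D the remaining parameters
#' are re-optimised, and the interval collects all K_D whose profiled sum
#' of squares stays below the F-test threshold
#' `SSR_min (1 + F(level; 1, n - p) / (n - p))`.
#'
#' @param series The fitted [titration_series()].
#' @param fix Named list of parameters held fixed during fitting (as passed
#'   to [fit_anisotropy_titration()]).
#' @param level Confidence level (default 0.95).
#' @return List with `kd`, `lower`, `upper` (bounds may be 0/Inf when the
#'   profile never crosses the threshold within the search range).
#' @export
kd_profile_interval <- function(series, fix = list(), level = 0.95) {
  fit <- fit_anisotropy_titration(series, fix = fix)
  if (!fit$converged) stop("base fit failed: ", fit$message)
  kd_hat <- fit$params$kd
  n <- nrow(series)
  p <- length(fit$params_vec)
  ssr0 <- sum(fit$residuals^2)
  crit <- ssr0 * (1 + stats::qf(level, 1, n - p) / (n - p))
  pssr <- function(kd) {
    f <- fit_anisotropy_titration(series, fix = c(list(kd = kd), fix))
    if (!f$converged) return(Inf)
    sum(f$residuals^2)
  }
  find_edge <- function(direction) {
    kd <- kd_hat
    v <- pssr(kd)
    if (v > crit) return(kd)  # profile already above threshold at the optimum
    for (i in 1:60) {
      kd_next <- kd * if (direction < 0) 0.7 else 1.4
      v_next <- pssr(kd_next)
      if (v_next > crit) {
        lk <- sort(log(c(kd, kd_next)))
        root <- tryCatch(
          stats::uniroot(function(l) pssr(exp(l)) - crit, lk,
                         f.lower = if (direction < 0) v_next - crit else v - crit,
                         f.upper = if (direction < 0) v - crit else v_next - crit,
                         tol = 1e-4)$root,
          error = function(e) log(kd_next)
        )
        return(exp(root))
      }
      kd <- kd_next
      v <- v_next
    }
    if (direction < 0) 0 else Inf
  }
  list(kd = kd_hat, lower = find_edge(-1), upper = find_edge(1))
}

#' Fold difference between two dissociation constants
#'
#' `kd_b / kd_a`: the fold by which partner a binds more tightly than
#' partner b. The study's experimental pair (0.67 uM for the structured RNA,
#' 1.9 uM for the unstructured one) gives ~2.8.
#'
#' @param kd_a,kd_b Dissociation constants (> 0), same units.
#' @return Fold difference.
#' @export
relative_affinity <- function(kd_a, kd_b) {
  if (kd_a <= 0 || kd_b <= 0) stop("dissociation constants must be positive")
  kd_b / kd_a
}
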