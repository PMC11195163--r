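#' Cubic periodic simulation box
#'
#' Stores the edge length and the concentration represented by a single
#' molecular pair in the box, `c_box = 1e6 / (V_nm3 * 1e-24 * N_A)` uM
#' (25.95 uM for the 40 nm box used in the coarse-grained binding runs).
#'
#' @param edge_nm Cubic box edge in nm (> 0).
#' @return Object of class `simulation_box`: `edge_nm`, `edge_ang`,
#'   `volume_nm3`, `c_box_uM`.
#' @export
simulation_box <- function(edge_nm) {
  if (edge_nm <= 0) stop("edge must be positive")
  v <- edge_nm^3
  structure(list(
    edge_nm = edge_nm,
    edge_ang = edge_nm * 10,
    volume_nm3 = v,
    c_box_uM = 1e6 / (v * 1e-24 * 6.02214076e23)
  ), class = "simulation_box")
}

NUCLEOTIDE_RESIDUES <- c("A", "C", "G", "U", "RA", "RC", "RG", "RU",
                         "ADE", "CYT", "GUA", "URA", "URI")

#' Coarse-grain an RNA structure to one bead per nucleotide
#'
#' Reduces a (multi-model) atomic structure to one bead per nucleotide by
#' keeping a single named atom (C1' by default), the same reduction used to
#' build rigid coarse-grained RNA inputs from deposited NMR conformers. Each
#' model becomes one frame; nucleotide numbering is preserved in the bead
#' labels. Non-nucleotide residues are skipped with a warning; a nucleotide
#' missing the named atom is an error naming it.
#'
#' @param pdb Path to a PDB file or a `bio3d` pdb object
#'   (read with `multi = TRUE` for multi-model files).
#' @param atom_name Atom kept per nucleotide; default `"C1'"`.
#' @return A [conformational_ensemble()] with one bead per nucleotide and
#'   one frame per model.
#' @export
coarse_grain_rna_structure <- function(pdb, atom_name = "C1'") {
  if (is.character(pdb)) {
    pdb <- bio3d::read.pdb(pdb, multi = TRUE, verbose = FALSE)
  }
  atoms <- pdb$atom
  resid <- toupper(trimws(atoms$resid))
  is_nt <- resid %in% NUCLEOTIDE_RESIDUES
  if (any(!is_nt)) {
    skipped <- unique(resid[!is_nt])
    warning("skipping non-nucleotide residue(s): ", paste(skipped, collapse = ", "))
  }
  atoms_nt <- atoms[is_nt, , drop = FALSE]
  keys <- unique(paste(atoms_nt$chain, atoms_nt$resno, sep = ":"))
  # accept both C1' and older C1* naming
  name_ok <- trimws(atoms_nt$elety) %in%
    c(atom_name, gsub("'", "*", atom_name, fixed = TRUE))
  sel_rows <- which(is_nt)[name_ok]
  sel_keys <- paste(atoms_nt$chain[name_ok], atoms_nt$resno[name_ok], sep = ":")
  missing <- setdiff(keys, sel_keys)
  if (length(missing) > 0) {
    stop(sprintf("nucleotide(s) missing atom %s: %s", atom_name,
                 paste(missing, collapse = ", ")))
  }
  ord <- match(keys, sel_keys)
  rows <- sel_rows[ord]
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  nb <- length(rows)
  coords <- array(NA_real_, dim = c(nb, 3, nf))
  for (f in seq_len(nf)) {
    m <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    coords[, , f] <- m[rows, , drop = FALSE]
  }
  labels <- data.frame(
    index = seq_len(nb),
    name = paste0(atoms_nt$resid[name_ok][ord], atoms_nt$resno[name_ok][ord])
  )
  conformational_ensemble(coords, labels = labels)
}

#' Centre-of-mass separation trajectory of a molecular pair
#'
#' Per-frame distance between the centroids of two bead groups under the
#' minimum-image convention for a cubic periodic box. Groups must partition
#' the beads disjointly; masses default to 1.
#'
#' @param ensemble A two-molecule [conformational_ensemble()].
#' @param group_a,group_b Disjoint bead index sets.
#' @param box A [simulation_box()].
#' @return Object of class `com_trajectory`: data frame with `frame` and
#'   `distance` (angstrom), with the box stored as an attribute.
#' @export
com_distance_trajectory <- function(ensemble, group_a, group_b, box) {
  stopifnot(inherits(ensemble, "conformational_ensemble"),
            inherits(box, "simulation_box"))
  if (length(intersect(group_a, group_b)) > 0) stop("groups must be disjoint")
  nb <- n_beads(ensemble)
  if (!all(c(group_a, group_b) %in% seq_len(nb))) stop("group indices out of range")
  m <- ensemble$masses
  edge <- box$edge_ang
  coma <- apply(ensemble$xyz[group_a, , , drop = FALSE], c(2, 3),
                stats::weighted.mean, w = m[group_a])
  comb <- apply(ensemble$xyz[group_b, , , drop = FALSE], c(2, 3),
                stats::weighted.mean, w = m[group_b])
  delta <- coma - comb                       # 3 x n_frames
  delta <- delta - edge * round(delta / edge)
  d <- sqrt(colSums(delta^2))
  structure(data.frame(frame = seq_along(d), distance = d),
            box = box, class = c("com_trajectory", "data.frame"))
}

#' Two-Gaussian fit of a centre-of-mass distance distribution
#'
#' Fits the histogram density of the pooled inter-molecular distances with
#' `A1 N(mu1, s1) + A2 N(mu2, s2)`; the smaller-mean component is the bound
#' state. The distribution is treated as a plain distance histogram (no
#' radial shell normalisation), so the component means live in distance
#' space. Initialisation is by a 2-means split of the distances with a
#' dense quantile-grid fallback. A failed fit or a vanishing larger-mean
#' component yields `unbound_present = FALSE` (such replicates are meant to
#' be omitted from K_D aggregation, not to raise).
#'
#' @param distances A `com_trajectory` or numeric vector of distances (A).
#' @param n_bins Histogram bin count; default Freedman-Diaconis.
#' @param min_weight Minimum mixture weight for the unbound component to
#'   count as present (default 0.01).
#' @return Object of class `two_gaussian_fit`: `a1`, `mu1`, `sigma1`,
#'   `a2`, `mu2`, `sigma2` (means ordered mu1 < mu2), `converged`,
#'   `unbound_present`, `message`, plus the binned `histogram`.
#' @export
fit_two_gaussian_rdf <- function(distances, n_bins = NULL, min_weight = 0.01) {
  x <- if (inherits(distances, "com_trajectory")) distances$distance else as.numeric(distances)
  if (length(x) < 100) stop("need at least 100 distances to fit a mixture")
  if (is.null(n_bins)) {
    bw <- 2 * stats::IQR(x) / length(x)^(1 / 3)   # Freedman-Diaconis
    n_bins <- max(20L, ceiling(diff(range(x)) / bw))
  }
  if (n_bins < 20) stop("n_bins must be >= 20")
  h <- graphics::hist(x, breaks = seq(min(x), max(x), length.out = n_bins + 1),
                      plot = FALSE)
  mids <- h$mids
  dens <- h$density
  failure <- function(msg) {
    structure(list(a1 = NA, mu1 = NA, sigma1 = NA, a2 = NA, mu2 = NA,
                   sigma2 = NA, converged = FALSE, separated = FALSE,
                   bound_present = FALSE, unbound_present = FALSE,
                   message = msg, histogram = data.frame(mid = mids, density = dens)),
              class = "two_gaussian_fit")
  }
  km <- tryCatch(stats::kmeans(x, centers = stats::quantile(x, c(0.1, 0.9))),
                 error = function(e) NULL)
  if (is.null(km)) return(failure("initialisation failed"))
  ord <- order(km$centers)
  grp <- match(km$cluster, ord)
  start <- list(
    a1 = mean(grp == 1), m1 = km$centers[ord[1]], s1 = max(stats::sd(x[grp == 1]), 1e-3),
    a2 = mean(grp == 2), m2 = km$centers[ord[2]], s2 = max(stats::sd(x[grp == 2]), 1e-3)
  )
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = unlist(start),
      lower = c(0, min(x), 1e-6, 0, min(x), 1e-6),
      fn = function(p) {
        dens - (p[1] * stats::dnorm(mids, p[2], p[3]) +
                  p[4] * stats::dnorm(mids, p[5], p[6]))
      },
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) NULL
  )
  if (is.null(fit) || fit$info %in% c(0, 5, 9)) {
    return(failure("two-Gaussian fit did not converge"))
  }
  p <- unname(fit$par)
  comp <- if (p[2] <= p[5]) list(c(p[1], p[2], p[3]), c(p[4], p[5], p[6]))
          else list(c(p[4], p[5], p[6]), c(p[1], p[2], p[3]))
  c1 <- comp[[1]]
  c2 <- comp[[2]]
  # components count as resolved modes only when their means are separated
  # relative to the larger width; otherwise the distribution is unimodal
  separated <- (c2[2] - c1[2]) > 2 * max(c1[3], c2[3])
  structure(list(
    a1 = c1[1], mu1 = c1[2], sigma1 = c1[3],
    a2 = c2[1], mu2 = c2[2], sigma2 = c2[3],
    converged = TRUE,
    separated = separated,
    bound_present = separated && c1[1] >= min_weight,
    unbound_present = if (separated) c2[1] >= min_weight else TRUE,
    message = if (separated) "ok" else "unimodal distribution; treated as unbound-only",
    histogram = data.frame(mid = mids, density = dens)
  ), class = "two_gaussian_fit")
}

#' @export
print.two_gaussian_fit <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("<two_gaussian_fit: FAILED (%s)>\n", x$message))
  } else {
    cat(sprintf(
      "<two_gaussian_fit: bound %.3f*N(%.1f, %.1f), unbound %.3f*N(%.1f, %.1f)%s>\n",
      x$a1, x$mu1, x$sigma1, x$a2, x$mu2, x$sigma2,
      if (x$unbound_present) "" else " [unbound component absent]"))
  }
  invisible(x)
}

#' Bound/unbound threshold from a two-Gaussian fit
#'
#' The distance at which the two weighted component densities intersect,
#' found numerically inside (mu1, mu2). For equal amplitudes and widths this
#' is the midpoint of the means. The reference value from the original
#' flexible-RNA runs, 53.5 A, may be supplied directly to
#' [classify_bound_frames()] instead.
#'
#' @param fit A converged [fit_two_gaussian_rdf()] with both components.
#' @return Threshold distance in angstroms.
#' @export
bound_threshold <- function(fit) {
  stopifnot(inherits(fit, "two_gaussian_fit"))
  if (!fit$converged || !fit$unbound_present || !fit$bound_present) {
    stop("threshold undefined: need a converged fit with both components present")
  }
  f <- function(xx) {
    fit$a1 * stats::dnorm(xx, fit$mu1, fit$sigma1) -
      fit$a2 * stats::dnorm(xx, fit$mu2, fit$sigma2)
  }
  lo <- fit$mu1
  hi <- fit$mu2
  if (f(lo) <= 0 || f(hi) >= 0) {
    # scan for a sign change on a dense grid before giving up
    grid <- seq(lo, hi, length.out = 2000)
    v <- f(grid)
    sc <- which(v[-1] * v[-length(v)] < 0)
    if (length(sc) == 0) stop("threshold undefined: no intersection inside (mu1, mu2)")
    lo <- grid[sc[1]]
    hi <- grid[sc[1] + 1]
  }
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Label bound frames by threshold and minimum lifetime
#'
#' Frames below the threshold are grouped into maximal consecutive runs;
#' only runs of at least `min_run` frames are labelled bound, so that
#' fleeting sub-threshold encounters do not count as complexes.
#'
#' @param distances A `com_trajectory` or numeric distance vector.
#' @param threshold Distance threshold in angstroms (> 0).
#' @param min_run Minimum bound-run length in frames (default 5).
#' @return Object of class `bound_annotation`: logical `bound` per frame,
#'   `threshold`, `min_run`, `fraction_bound`.
#' @export
classify_bound_frames <- function(distances, threshold, min_run = 5) {
  x <- if (inherits(distances, "com_trajectory")) distances$distance else as.numeric(distances)
  if (threshold <= 0) stop("threshold must be positive")
  if (min_run < 1) stop("min_run must be >= 1")
  below <- x < threshold
  r <- rle(below)
  keep <- r$values & r$lengths >= min_run
  bound <- rep(keep, r$lengths)
  structure(list(bound = bound, threshold = threshold, min_run = min_run,
                 fraction_bound = mean(bound)),
            class = "bound_annotation")
}

#' Apparent dissociation constant from a bound-frame annotation
#'
#' Single-pair mass action in the simulation box:
#' `K_D = c_box (1 - f)^2 / f` with `f` the bound-frame fraction, optionally
#' scaled by a finite-size (virial-style) correction factor, which defaults
#' to 1 and is surfaced rather than silently applied.
#'
#' @param annotation A [classify_bound_frames()] result.
#' @param box A [simulation_box()].
#' @param correction Multiplicative finite-size correction factor.
#' @return List: `kd_uM`, `fraction_bound`, `c_box_uM`, `correction`.
#' @export
apparent_kd <- function(annotation, box, correction = 1) {
  stopifnot(inherits(annotation, "bound_annotation"),
            inherits(box, "simulation_box"))
  f <- annotation$fraction_bound
  if (f == 0) stop("no bound frames: K_D unbounded")
  if (f == 1) stop("no unbound frames: K_D degenerate at 0")
  list(kd_uM = correction * box$c_box_uM * (1 - f)^2 / f,
       fraction_bound = f, c_box_uM = box$c_box_uM, correction = correction)
}

#' Relative dissociation constant
#'
#' `reference_kd / kd`: the fold by which this partner binds more tightly
#' than the reference (the flexible-homopolymer complex in the study).
#'
#' @param kd,reference_kd Dissociation constants (> 0).
#' @return Fold difference.
#' @export
relative_kd <- function(kd, reference_kd) {
  if (kd <= 0 || reference_kd <= 0) stop("dissociation constants must be positive")
  reference_kd / kd
}

#' Inter-molecular contact frequencies over bound frames
#'
#' Fraction of bound-state frames in which each (group A bead, group B bead)
#' pair lies within `cutoff` angstroms, plus per-bead marginal profiles
#' reported both as the maximum and the mean over partners.
#'
#' @param ensemble A two-molecule [conformational_ensemble()].
#' @param group_a,group_b Disjoint bead index sets (e.g. protein residues
#'   and RNA beads).
#' @param annotation A [classify_bound_frames()] result aligned with the
#'   trajectory.
#' @param cutoff Contact cutoff in angstroms (default 15).
#' @return Object of class `contact_map`: `frequency` matrix
#'   (len A x len B), `marginal_a`/`marginal_b` data frames with `max` and
#'   `mean` columns, `cutoff`, `n_bound_frames`.
#' @export
contact_frequency <- function(ensemble, group_a, group_b, annotation,
                              cutoff = 15) {
  stopifnot(inherits(ensemble, "conformational_ensemble"),
            inherits(annotation, "bound_annotation"))
  if (length(annotation$bound) != n_frames(ensemble)) {
    stop("annotation and trajectory lengths differ")
  }
  frames <- which(annotation$bound)
  if (length(frames) == 0) stop("contact map undefined: no bound frames")
  na <- length(group_a)
  nbb <- length(group_b)
  acc <- matrix(0, na, nbb)
  for (f in frames) {
    xa <- ensemble$xyz[group_a, , f, drop = FALSE]
    dim(xa) <- c(na, 3)
    xb <- ensemble$xyz[group_b, , f, drop = FALSE]
    dim(xb) <- c(nbb, 3)
    d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
    acc <- acc + (d2 < cutoff^2)
  }
  freq <- acc / length(frames)
  structure(list(
    frequency = freq,
    marginal_a = data.frame(index = group_a,
                            max = apply(freq, 1, max),
                            mean = rowMeans(freq)),
    marginal_b = data.frame(index = group_b,
                            max = apply(freq, 2, max),
                            mean = colMeans(freq)),
    cutoff = cutoff,
    n_bound_frames = length(frames)
  ), class = "contact_map")
}
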