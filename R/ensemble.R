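#' Conformational ensemble container
#'
#' Ordered frames of labelled 3D bead coordinates (in angstroms) for one
#' molecule or a molecular pair. Internally stored as an array with
#' dimensions `n_beads x 3 x n_frames`. All frames must share the bead count
#' and all coordinates must be finite.
#'
#' @param coords A `n_beads x 3 x n_frames` numeric array, a single
#'   `n_beads x 3` matrix (one frame), or a list of such matrices.
#' @param labels Optional data frame with columns `index` and `name`
#'   (1-based residue index and bead name). Defaults to sequential beads.
#' @param masses Optional per-bead masses; default 1 (bead-level CG).
#' @return An object of class `conformational_ensemble` with elements
#'   `xyz`, `labels`, `masses`.
#' @export
conformational_ensemble <- function(coords, labels = NULL, masses = NULL) {
  if (is.list(coords) && !is.array(coords)) {
    nb <- nrow(coords[[1]])
    if (!all(vapply(coords, nrow, 1L) == nb)) {
      stop("all frames must have the same bead count")
    }
    coords <- array(unlist(lapply(coords, t)), dim = c(3, nb, length(coords)))
    coords <- aperm(coords, c(2, 1, 3))
  }
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1))
  if (!is.array(coords) || length(dim(coords)) != 3 || dim(coords)[2] != 3) {
    stop("coords must be an n_beads x 3 x n_frames array")
  }
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  nb <- dim(coords)[1]
  if (is.null(labels)) {
    labels <- data.frame(index = seq_len(nb), name = paste0("B", seq_len(nb)))
  }
  if (nrow(labels) != nb) stop("labels must have one row per bead")
  if (is.null(masses)) masses <- rep(1, nb)
  if (length(masses) != nb || any(masses <= 0)) {
    stop("masses must be positive, one per bead")
  }
  structure(list(xyz = coords, labels = labels, masses = masses),
            class = "conformational_ensemble")
}

#' @rdname conformational_ensemble
#' @param x A `conformational_ensemble`.
#' @export
n_frames <- function(x) dim(x$xyz)[3]

#' @rdname conformational_ensemble
#' @export
n_beads <- function(x) dim(x$xyz)[1]

#' @rdname conformational_ensemble
#' @param i Frame index.
#' @export
frame_coords <- function(x, i) x$xyz[, , i, drop = TRUE]

#' @export
print.conformational_ensemble <- function(x, ...) {
  cat(sprintf("<conformational_ensemble: %d beads x %d frames>\n",
              n_beads(x), n_frames(x)))
  invisible(x)
}

#' Per-frame radius of gyration
#'
#' Mass-weighted RMS distance of beads from their centroid, per frame,
#' `Rg = sqrt(sum(m_i |x_i - xbar|^2) / sum(m_i))`, with an ensemble summary.
#'
#' @param ensemble A [conformational_ensemble()].
#' @return List with `rg` (per-frame, in angstroms), `mean` and `sd`.
#' @export
radius_of_gyration <- function(ensemble) {
  stopifnot(inherits(ensemble, "conformational_ensemble"))
  if (n_frames(ensemble) < 1) stop("ensemble has no frames")
  m <- ensemble$masses
  w <- m / sum(m)
  rg <- vapply(seq_len(n_frames(ensemble)), function(i) {
    xyz <- ensemble$xyz[, , i, drop = FALSE]
    dim(xyz) <- dim(xyz)[1:2]
    ctr <- colSums(xyz * w)
    d2 <- (xyz[, 1] - ctr[1])^2 + (xyz[, 2] - ctr[2])^2 + (xyz[, 3] - ctr[3])^2
    sqrt(sum(w * d2))
  }, numeric(1))
  list(rg = rg, mean = mean(rg), sd = stats::sd(rg))
}

#' Ensemble-mean inter-bead distance map
#'
#' Entry (i, j) is the mean over frames of the Euclidean distance between
#' beads i and j. Symmetric with a zero diagonal.
#'
#' @param ensemble A [conformational_ensemble()].
#' @return An `n x n` matrix of class `distance_map` (angstroms).
#' @export
mean_distance_map <- function(ensemble) {
  stopifnot(inherits(ensemble, "conformational_ensemble"))
  nb <- n_beads(ensemble)
  nf <- n_frames(ensemble)
  acc <- matrix(0, nb, nb)
  for (i in seq_len(nf)) {
    xyz <- ensemble$xyz[, , i, drop = FALSE]
    dim(xyz) <- dim(xyz)[1:2]
    acc <- acc + as.matrix(stats::dist(xyz))
  }
  acc <- acc / nf
  dimnames(acc) <- NULL
  structure(acc, class = c("distance_map", "matrix"))
}

#' Normalise a distance map by a random-coil expectation
#'
#' Divides each entry by the null expectation at the same sequence
#' separation `|i - j|`, the "relative distance" convention for comparing a
#' simulated ensemble against an ideal-coil reference. Ratios < 1 indicate
#' compaction relative to the coil, > 1 expansion. The diagonal is defined
#' as 1.
#'
#' @param map A `distance_map` (or plain square matrix).
#' @param null Either a numeric vector of expected distances indexed by
#'   separation 0..(n-1) (entry 1 corresponds to separation 0), or an
#'   [afrc_reference()] object.
#' @return Matrix of ratios, same dimensions as `map`.
#' @export
normalized_distance_map <- function(map, null) {
  n <- nrow(map)
  if (ncol(map) != n) stop("map must be square")
  if (inherits(null, "afrc_reference")) {
    if (length(null$mean_distance) < n) stop("null covers fewer separations than map")
    null <- null$mean_distance[seq_len(n)]
  }
  if (length(null) < n) stop("null must give expected distances for separations 0..(n-1)")
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  denom <- matrix(null[sep + 1L], n, n)
  off <- sep > 0
  if (any(denom[off] <= 0)) stop("null distance must be positive off-diagonal")
  out <- matrix(1, n, n)
  out[off] <- map[off] / denom[off]
  out
}
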