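#' Read a plain-text XYZ trajectory
#'
#' Parses the XMOL-style format: repeated blocks of a bead count line, a
#' comment line, and `count` lines of `name x y z`. Every frame must carry
#' the same bead count.
#'
#' @param path File path.
#' @return A [conformational_ensemble()].
#' @export
read_xyz_trajectory <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  pos <- 1L
  frames <- list()
  names_first <- NULL
  while (pos <= length(lines)) {
    nb <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(nb) || nb < 1) stop(sprintf("malformed frame header at line %d", pos))
    if (pos + 1L + nb > length(lines)) stop("truncated final frame")
    block <- lines[(pos + 2L):(pos + 1L + nb)]
    toks <- strsplit(trimws(block), "\\s+")
    if (any(vapply(toks, length, 1L) < 4)) stop("malformed coordinate line")
    nm <- vapply(toks, `[[`, "", 1)
    xyz <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
    if (is.null(names_first)) names_first <- nm
    if (length(nm) != length(names_first)) stop("frames differ in bead count")
    frames[[length(frames) + 1L]] <- xyz
    pos <- pos + 2L + nb
  }
  conformational_ensemble(frames,
                          labels = data.frame(index = seq_along(names_first),
                                              name = names_first))
}

#' Write an ensemble as a plain-text XYZ trajectory
#'
#' @param ensemble A [conformational_ensemble()].
#' @param path Output path.
#' @param comment Per-file comment placed on each frame's second line.
#' @export
write_xyz_trajectory <- function(ensemble, path, comment = "idrna frame") {
  stopifnot(inherits(ensemble, "conformational_ensemble"))
  nb <- n_beads(ensemble)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(ensemble))) {
    xyz <- ensemble$xyz[, , f, drop = FALSE]
    dim(xyz) <- c(nb, 3)
    writeLines(as.character(nb), con)
    writeLines(sprintf("%s %d", comment, f), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", ensemble$labels$name,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(path)
}

#' Read a (multi-model) PDB file as an ensemble
#'
#' Each MODEL/ENDMDL block becomes one frame. Optionally restricts to one
#' atom name per residue (e.g. `"CA"` for a Calpha trace).
#'
#' @param path PDB file path.
#' @param atom Optional atom name filter (e.g. `"CA"`); NULL keeps all.
#' @return A [conformational_ensemble()].
#' @export
read_ensemble_pdb <- function(path, atom = NULL) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  rows <- seq_len(nrow(pdb$atom))
  if (!is.null(atom)) {
    rows <- which(trimws(pdb$atom$elety) == atom)
    if (length(rows) == 0) stop(sprintf("no atoms named %s in %s", atom, path))
  }
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  coords <- array(NA_real_, dim = c(length(rows), 3, nf))
  for (f in seq_len(nf)) {
    m <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    coords[, , f] <- m[rows, , drop = FALSE]
  }
  conformational_ensemble(
    coords,
    labels = data.frame(index = seq_along(rows),
                        name = paste0(trimws(pdb$atom$resid[rows]),
                                      pdb$atom$resno[rows]))
  )
}

#' Write a distance map (or any matrix) as TSV
#'
#' @param map Matrix.
#' @param path Output path.
#' @export
write_distance_map <- function(map, path) {
  utils::write.table(unclass(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a contact map in long format
#'
#' Columns `index_a`, `index_b`, `frequency`.
#'
#' @param cmap A `contact_map` from [contact_frequency()].
#' @param path Output path.
#' @export
write_contact_map <- function(cmap, path) {
  stopifnot(inherits(cmap, "contact_map"))
  long <- expand.grid(index_a = cmap$marginal_a$index,
                      index_b = cmap$marginal_b$index)
  long$frequency <- as.vector(cmap$frequency)
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
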