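# Shared fixture builders; everything is generated in code at test time.

# One fixed-column PDB ATOM record.
pdb_atom_line <- function(i, name, res, resno, x, y, z) {
  sprintf("ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
          i, name, res, resno, x, y, z)
}

# Multi-model PDB of a toy RNA: per model, `n_nt` nucleotides each carrying
# P and C1' atoms on a line along x, plus an optional water row.
write_toy_rna_pdb <- function(path, n_nt = 3, n_models = 2, with_water = TRUE,
                              drop_c1_in = integer(0)) {
  res_names <- rep(c("G", "A", "C", "U"), length.out = n_nt)
  lines <- character(0)
  for (m in seq_len(n_models)) {
    lines <- c(lines, sprintf("MODEL     %4d", m))
    i <- 0L
    for (nt in seq_len(n_nt)) {
      i <- i + 1L
      lines <- c(lines, pdb_atom_line(i, "P", res_names[nt], nt,
                                      2 * nt - 1, 0, m - 1))
      if (!nt %in% drop_c1_in) {
        i <- i + 1L
        lines <- c(lines, pdb_atom_line(i, "C1'", res_names[nt], nt,
                                        2 * nt, 0, m - 1))
      }
    }
    if (with_water) {
      lines <- c(lines, pdb_atom_line(i + 1L, "O", "HOH", 99, 9, 9, 9))
    }
    lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}

# Discrete Gaussian chain: N beads, i.i.d. Gaussian bond vectors with
# per-residue segment scale b (so <r^2(k)> = b^2 k).
gaussian_chain_ensemble <- function(n_beads, b, n_frames, seed) {
  set.seed(seed)
  frames <- lapply(seq_len(n_frames), function(i) {
    steps <- matrix(stats::rnorm(3 * (n_beads - 1), 0, b / sqrt(3)),
                    n_beads - 1, 3)
    apply(steps, 2, function(col) cumsum(c(0, col)))
  })
  conformational_ensemble(frames)
}

# Brute-force run-length oracle for bound-frame classification.
runlength_oracle <- function(below, min_run) {
  n <- length(below)
  bound <- logical(n)
  i <- 1L
  while (i <= n) {
    if (below[i]) {
      j <- i
      while (j < n && below[j + 1L]) j <- j + 1L
      if (j - i + 1L >= min_run) bound[i:j] <- TRUE
      i <- j + 1L
    } else i <- i + 1L
  }
  bound
}

# Numeric mass-action root: solve (L - C)(M - C) = kd * C for the complex
# concentration C in [0, min(L, M)], return bound fraction C / M.
mass_action_root <- function(kd, L, M) {
  if (L == 0) return(0)
  f <- function(C) (L - C) * (M - C) - kd * C
  stats::uniroot(f, c(0, min(L, M)), tol = 1e-14)$root / M
}
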