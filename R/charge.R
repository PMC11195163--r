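#' Per-position formal charges of a sequence
#'
#' The charge rule is the one used throughout the coacervation stoichiometry
#' analysis at pH 7.5: Arg and Lys carry +1, Asp and Glu carry -1, His, Cys,
#' Tyr and the chain termini are neutral (the simulated construct carries
#' uncharged acetyl/amide caps), and every ribonucleotide carries -1 through
#' its backbone phosphate. Only pH 7.5 semantics are defined for this rule;
#' pH is validated but does not titrate side chains.
#'
#' @param seq A [protein_sequence()] or [rna_sequence()].
#' @param ph Solution pH, in \[0, 14\]. Only 7.5-style semantics are defined.
#' @return Integer vector of per-position charges.
#' @export
residue_charges <- function(seq, ph = 7.5) {
  if (!is.numeric(ph) || ph < 0 || ph > 14) stop("pH must lie in [0, 14]")
  chars <- strsplit(unclass(seq), "")[[1]]
  if (inherits(seq, "protein_sequence")) {
    q <- integer(length(chars))
    q[chars %in% c("R", "K")] <- 1L
    q[chars %in% c("D", "E")] <- -1L
    q
  } else if (inherits(seq, "rna_sequence")) {
    rep(-1L, length(chars))
  } else {
    stop("seq must be a protein_sequence or rna_sequence")
  }
}

#' Net formal charge of a sequence
#'
#' Additive over concatenation: the charge of a joined sequence equals the
#' sum of the parts. For the study pair this yields +12 for the 68-residue
#' SERF protein and -29 for the 29-nucleotide TAR fragment.
#'
#' @inheritParams residue_charges
#' @return Integer net charge in elementary charges.
#' @examples
#' net_charge(serf_sequence())  # +12
#' net_charge(tar_sequence())   # -29
#' @export
net_charge <- function(seq, ph = 7.5) {
  as.integer(sum(residue_charges(seq, ph)))
}

#' Net charge per residue (NCPR) profile
#'
#' Sliding-window mean of per-residue formal charges. Edge positions use the
#' truncated window so the profile covers every residue and its length equals
#' the sequence length.
#'
#' @param seq A [protein_sequence()].
#' @param window Odd window width, at most the sequence length. Default 5.
#' @param ph Solution pH (see [residue_charges()]).
#' @return A data frame of class `charge_profile` with columns `position` and
#'   `ncpr`; values lie in \[-1, 1\].
#' @export
ncpr_profile <- function(seq, window = 5, ph = 7.5) {
  if (!inherits(seq, "protein_sequence")) {
    stop("ncpr_profile expects a protein_sequence")
  }
  n <- length(seq)
  if (window %% 2 == 0 || window < 1 || window > n) {
    stop("window must be odd, >= 1 and <= sequence length")
  }
  q <- residue_charges(seq, ph)
  half <- (window - 1) %/% 2
  ncpr <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    mean(q[lo:hi])
  }, numeric(1))
  structure(
    data.frame(position = seq_len(n), ncpr = ncpr),
    window = window,
    class = c("charge_profile", "data.frame")
  )
}

#' Charge-matched protein:RNA molar ratio
#'
#' The molar ratio of (polycationic) protein to (polyanionic) RNA at which
#' total formal charges balance, `|q_rna| / q_protein`. For SERF (+12) and
#' TAR (-29) this is 29/12 = 2.42, close to the 2.5:1 ratio at which
#' turbidity of the mixture peaks.
#'
#' @param protein A [protein_sequence()] with positive net charge.
#' @param rna An [rna_sequence()] with negative net charge.
#' @param ph Solution pH.
#' @return The charge-matching protein:RNA molar ratio (a number).
#' @export
charge_match_ratio <- function(protein, rna, ph = 7.5) {
  qp <- net_charge(protein, ph)
  qr <- net_charge(rna, ph)
  if (qp <= 0 || qr >= 0) {
    stop(sprintf(
      "stoichiometry undefined: need protein charge > 0 and RNA charge < 0 (got %+d, %+d)",
      qp, qr
    ))
  }
  abs(qr) / qp
}

#' Write an NCPR profile as two-column TSV
#'
#' @param profile A `charge_profile` from [ncpr_profile()].
#' @param path Output file path.
#' @export
write_charge_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
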