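#' Protein sequence object
#'
#' A validated one-letter amino-acid sequence. Characters must come from the
#' 20-letter alphabet; the offending position is reported otherwise.
#'
#' @param residues One-letter amino-acid string.
#' @param name Free-text identifier.
#' @return An object of class `protein_sequence`.
#' @examples
#' protein_sequence("MKRDE", name = "toy")
#' @export
protein_sequence <- function(residues, name = "") {
  residues <- toupper(as.character(residues))
  stopifnot(length(residues) == 1)
  if (nchar(residues) == 0) stop("protein sequence must be nonempty")
  check_alphabet(residues, AA_ALPHABET, "amino-acid")
  structure(residues, name = name, class = "protein_sequence")
}

#' RNA sequence object
#'
#' @param nucleotides String over the alphabet A/C/G/U (T is rejected).
#' @param name Free-text identifier.
#' @return An object of class `rna_sequence`.
#' @export
rna_sequence <- function(nucleotides, name = "") {
  nucleotides <- toupper(as.character(nucleotides))
  stopifnot(length(nucleotides) == 1)
  if (nchar(nucleotides) == 0) stop("RNA sequence must be nonempty")
  check_alphabet(nucleotides, RNA_ALPHABET, "ribonucleotide")
  structure(nucleotides, name = name, class = "rna_sequence")
}

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
RNA_ALPHABET <- c("A", "C", "G", "U")

check_alphabet <- function(x, alphabet, what) {
  chars <- strsplit(x, "")[[1]]
  bad <- which(!chars %in% alphabet)
  if (length(bad) > 0) {
    stop(sprintf(
      "invalid %s character '%s' at position %d", what, chars[bad[1]], bad[1]
    ))
  }
  invisible(TRUE)
}

#' @export
length.protein_sequence <- function(x) nchar(unclass(x))

#' @export
length.rna_sequence <- function(x) nchar(unclass(x))

#' @export
print.protein_sequence <- function(x, ...) {
  cat(sprintf("<protein_sequence '%s', %d aa>\n%s\n",
              attr(x, "name"), length(x), unclass(x)))
  invisible(x)
}

#' @export
print.rna_sequence <- function(x, ...) {
  cat(sprintf("<rna_sequence '%s', %d nt>\n%s\n",
              attr(x, "name"), length(x), unclass(x)))
  invisible(x)
}

#' Bundled study sequences
#'
#' The 68-residue *S. cerevisiae* SERF protein (as simulated, with uncharged
#' terminal caps) and the 29-nucleotide apical fragment of the HIV-1 TAR RNA.
#' These are the two molecules whose binding and phase behaviour the package
#' analyses; they double as convenient defaults for examples and workflows.
#'
#' @return A `protein_sequence` or `rna_sequence`.
#' @export
serf_sequence <- function() {
  protein_sequence(
    paste0("MARGNQRDLARQKNLKKQKDMAKNQKKSGDPKKRMESDAE",
           "ILRQKQAAADARREAEKLEKLKAEKTRR"),
    name = "SERF (S. cerevisiae)"
  )
}

#' @rdname serf_sequence
#' @export
tar_sequence <- function() {
  rna_sequence("GGCAGAUCUGAGCCUGGGAGCUCUCUGCC", name = "HIV-1 TAR (apical)")
}

#' Read a sequence from a FASTA file
#'
#' Thin wrapper around [seqinr::read.fasta()] that returns validated sequence
#' objects. Multi-record files return a list.
#'
#' @param path FASTA file path.
#' @param type `"protein"` or `"rna"`.
#' @return A sequence object, or a list of them for multi-record files.
#' @export
read_sequence_fasta <- function(path, type = c("protein", "rna")) {
  type <- match.arg(type)
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  out <- lapply(seq_along(recs), function(i) {
    s <- toupper(as.character(recs[[i]]))
    nm <- attr(recs[[i]], "name")
    if (type == "protein") protein_sequence(s, name = nm)
    else rna_sequence(gsub("T", "U", s), name = nm)
  })
  if (length(out) == 1) out[[1]] else out
}
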