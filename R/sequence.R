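# Peptide sequence type and static amino-acid tables.

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
         Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
         L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
         S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

AA1_FROM_3 <- stats::setNames(names(AA3), AA3)

# Residue types carrying a chi1 (all but Gly/Ala) and a chi2 angle.
HAS_CHI1 <- setdiff(AA1, c("G", "A"))
HAS_CHI2 <- c("R", "N", "D", "Q", "E", "H", "I", "K", "L", "M",
              "F", "P", "W", "Y")

# Hydrophobic / acidic / basic classes used for contact CV pair sets.
ACIDIC_AA <- c("D", "E")
BASIC_AA <- c("R", "K")

# Heavy-atom masses (u) and van der Waals radii (nm) keyed by element.
ELEMENT_MASS <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06, H = 1.008)
ELEMENT_RADIUS <- c(C = 0.170, N = 0.155, O = 0.152, S = 0.180, H = 0.120)

# Study sequences: the C-terminal 27-mer of the UVR8 photoreceptor
# (author numbering 397-423) and its P411A point mutant.
UVR8_C27_WT <- "GKSWVSPAERYAVVPDETGLTDGSSKG"
UVR8_C27_P411A <- "GKSWVSPAERYAVVADETGLTDGSSKG"
UVR8_C27_OFFSET <- 397L

#' Construct a peptide sequence
#'
#' @param residues one-letter amino-acid string or character vector.
#' @param numbering_offset author number of the first residue
#'   (e.g. 397 for the UVR8 C-terminal peptide).
#' @return an object of class `PeptideSequence`.
#' @export
peptide_sequence <- function(residues, numbering_offset = 1L) {
  if (length(residues) == 1L && nchar(residues[1L]) > 1L) {
    residues <- strsplit(residues, "")[[1L]]
  }
  residues <- toupper(residues)
  bad <- setdiff(unique(residues), AA1)
  if (length(bad) > 0L) {
    stop("non-standard amino acid code(s): ", paste(bad, collapse = ", "))
  }
  if (length(residues) < 7L) {
    stop("sequence must have at least 7 residues")
  }
  structure(list(residues = residues,
                 numbering_offset = as.integer(numbering_offset)),
            class = "PeptideSequence")
}

#' @export
length.PeptideSequence <- function(x) length(x$residues)

#' @export
print.PeptideSequence <- function(x, ...) {
  cat(sprintf("PeptideSequence: %s (%d residues, numbering %d-%d)\n",
              paste(x$residues, collapse = ""), length(x$residues),
              x$numbering_offset,
              x$numbering_offset + length(x$residues) - 1L))
  invisible(x)
}

# Author numbering of each residue.
residue_numbers <- function(seq) {
  seq$numbering_offset + seq_along(seq$residues) - 1L
}

# Map author residue numbers to 1-based indices.
residue_index <- function(seq, author_numbers) {
  idx <- author_numbers - seq$numbering_offset + 1L
  if (any(idx < 1L | idx > length(seq$residues))) {
    stop("residue number outside sequence range")
  }
  idx
}
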