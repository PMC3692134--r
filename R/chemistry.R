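# Residue and atom dictionaries shared by parsing, typing, geometry and fixtures.
# All atom sets are heavy atoms only; hydrogens never survive parsing.

# Standard amino-acid heavy atoms (backbone N,CA,C,O plus side chain; no OXT).
.AA_ATOMS <- list(
  ALA = c("N", "CA", "C", "O", "CB"),
  ARG = c("N", "CA", "C", "O", "CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  ASN = c("N", "CA", "C", "O", "CB", "CG", "OD1", "ND2"),
  ASP = c("N", "CA", "C", "O", "CB", "CG", "OD1", "OD2"),
  CYS = c("N", "CA", "C", "O", "CB", "SG"),
  GLN = c("N", "CA", "C", "O", "CB", "CG", "CD", "OE1", "NE2"),
  GLU = c("N", "CA", "C", "O", "CB", "CG", "CD", "OE1", "OE2"),
  GLY = c("N", "CA", "C", "O"),
  HIS = c("N", "CA", "C", "O", "CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  ILE = c("N", "CA", "C", "O", "CB", "CG1", "CG2", "CD1"),
  LEU = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2"),
  LYS = c("N", "CA", "C", "O", "CB", "CG", "CD", "CE", "NZ"),
  MET = c("N", "CA", "C", "O", "CB", "CG", "SD", "CE"),
  PHE = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PRO = c("N", "CA", "C", "O", "CB", "CG", "CD"),
  SER = c("N", "CA", "C", "O", "CB", "OG"),
  THR = c("N", "CA", "C", "O", "CB", "OG1", "CG2"),
  TRP = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "NE1", "CE2",
          "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  VAL = c("N", "CA", "C", "O", "CB", "CG1", "CG2")
)

.AA_NAMES <- names(.AA_ATOMS)

# Deoxyribose + phosphate heavy atoms, 5'-to-3' bonded order.
.BACKBONE_ATOMS <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'",
                     "C3'", "O3'", "C2'", "C1'")

# Base-moiety heavy atoms per base type (10/11/8/9 for A/G/C/T).
.BASE_ATOMS <- list(
  A = c("N9", "C8", "N7", "C5", "C6", "N6", "N1", "C2", "N3", "C4"),
  G = c("N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2", "N2", "N3", "C4"),
  C = c("N1", "C2", "O2", "N3", "C4", "N4", "C5", "C6"),
  T = c("N1", "C2", "O2", "N3", "C4", "O4", "C5", "C7", "C6")
)

.PURINES <- c("A", "G")
.PYRIMIDINES <- c("C", "T")

# Frame definitions used for rigid-body base replacement: the glycosidic
# nitrogen anchors the template, all ring atoms define the base plane, and the
# interior bisector of the flanking ring angle at the anchor fixes the in-plane
# orientation.
.FRAME_ANCHOR <- c(A = "N9", G = "N9", C = "N1", T = "N1")
.FRAME_PLANE <- list(
  A = c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"),
  G = c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"),
  C = c("N1", "C2", "N3", "C4", "C5", "C6"),
  T = c("N1", "C2", "N3", "C4", "C5", "C6")
)
.FRAME_BISECTOR <- list(
  A = c("C4", "N9", "C8"),
  G = c("C4", "N9", "C8"),
  C = c("C2", "N1", "C6"),
  T = c("C2", "N1", "C6")
)

# Watson-Crick hydrogen-bond pivot used for pairing detection: purine N1
# faces pyrimidine N3.
.WC_ATOM <- c(A = "N1", G = "N1", C = "N3", T = "N3")

.COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Complement a base or base sequence
#'
#' Watson-Crick complement (`A<->T`, `C<->G`). Vectorized over single-letter
#' bases; a multi-character string is complemented letter by letter (use
#' [reverse_complement()] for the reverse-complement of a site).
#'
#' @param base Character vector of bases or a single sequence string.
#' @return Character vector of the same shape.
#' @export
#' @examples
#' complement_base(c("A", "C"))
complement_base <- function(base) {
  out <- chartr("ACGTacgt", "TGCAtgca", base)
  bad <- grepl("[^ACGT]", toupper(out))
  if (any(bad)) stop("invalid base letter(s): ", paste(unique(base[bad]), collapse = ", "))
  out
}

#' Reverse complement of a DNA sequence
#'
#' @param seq Character vector of A/C/G/T strings.
#' @return Reverse-complemented strings.
#' @export
#' @examples
#' reverse_complement("AACG")  # "CGTT"
reverse_complement <- function(seq) {
  vapply(seq, function(s) {
    paste(rev(strsplit(complement_base(s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Normalize residue names to the internal one-letter base code, or NA if the
# residue is not a recognized standard deoxyribonucleotide. Accepts both
# remediated (DA) and legacy (A) PDB dialects.
.base_code <- function(resid) {
  up <- toupper(resid)
  code <- ifelse(up %in% c("DA", "DT", "DC", "DG"), substr(up, 2, 2),
          ifelse(up %in% c("A", "T", "C", "G"), up, NA_character_))
  code
}

.is_purine <- function(base) base %in% .PURINES

# Normalize heavy-atom names across PDB dialects: primes written as '*',
# old-style phosphate oxygens O1P/O2P, and the thymine methyl C5M.
.normalize_atom_name <- function(name) {
  nm <- gsub("\\*", "'", toupper(trimws(name)))
  nm[nm == "O1P"] <- "OP1"
  nm[nm == "O2P"] <- "OP2"
  nm[nm == "C5M"] <- "C7"
  nm
}

# Map selenomethionine onto methionine (residue and selenium atom).
.normalize_protein_residue <- function(resid, elety) {
  resid <- toupper(trimws(resid))
  sel <- resid == "MSE"
  if (any(sel)) {
    resid[sel] <- "MET"
    elety[sel & elety == "SE"] <- "SD"
  }
  list(resid = resid, elety = elety)
}
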