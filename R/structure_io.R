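# PDB-format reading/writing and the complex container.
#
# The container is deliberately plain: a data frame of heavy atoms plus the
# protein/DNA chain partition. Waters, ions and other ligands are retained in
# the atom table but belong to neither chain set and are ignored by scoring.

.ATOM_COLS <- c("record", "elety", "alt", "resid", "chain", "resno", "ins",
                "x", "y", "z", "element")

.new_complex <- function(atoms) {
  rownames(atoms) <- NULL
  chains <- unique(atoms$chain)
  protein <- character(0)
  dna <- character(0)
  for (ch in chains) {
    res <- unique(atoms$resid[atoms$chain == ch])
    is_aa <- any(res %in% .AA_NAMES)
    is_nt <- any(!is.na(.base_code(res)))
    if (is_aa && is_nt)
      stop("chain '", ch, "' mixes amino acids and nucleotides")
    if (is_aa) protein <- c(protein, ch)
    if (is_nt) dna <- c(dna, ch)
  }
  structure(list(atoms = atoms,
                 protein_chains = sort(protein),
                 dna_chains = sort(dna)),
            class = "complex_structure")
}

# Guess the element from a PDB atom name (used when columns 77-78 are blank).
.element_from_name <- function(name) {
  nm <- gsub("[^A-Za-z]", "", name)
  one <- toupper(substr(nm, 1, 1))
  # two-letter elements that occur in protein/DNA context
  two <- toupper(substr(nm, 1, 2))
  ifelse(two %in% c("SE", "FE", "MG", "ZN", "MN", "CL", "BR", "NA", "CA") &
           nchar(name) > 3, two, one)
}

#' Parse a PDB-format protein-DNA complex
#'
#' Reads ATOM/HETATM records from PDB-format text. Hydrogens (and deuteriums)
#' are dropped, as are alternate locations other than blank or 'A'.
#' Insertion-coded residues are retained and identified by the composite
#' (residue number, insertion code). Chains containing at least one standard
#' amino acid become protein chains; chains containing at least one
#' deoxyribonucleotide (DA/DT/DC/DG or legacy A/T/C/G names) become DNA
#' chains. Selenomethionine (MSE) is treated as MET. Atoms on chains in
#' neither class (waters, ligands) are kept but never scored.
#'
#' @param text PDB-format text: a single string or a character vector of lines.
#' @return A `complex_structure`: list with `atoms` (data frame with columns
#'   `record`, `elety`, `alt`, `resid`, `chain`, `resno`, `ins`, `x`, `y`,
#'   `z`, `element`), `protein_chains`, `dna_chains`.
#' @seealso [read_complex()] to read from a file, [write_complex()] for the
#'   inverse, [detect_dsdna()] for duplex detection.
#' @export
parse_complex <- function(text) {
  if (length(text) == 1 && grepl("\n", text, fixed = TRUE))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  sel <- grepl("^(ATOM  |HETATM)", text)
  if (!any(sel))
    stop("parse error: no ATOM/HETATM records in input")
  lines <- text[sel]
  lineno <- which(sel)

  field <- function(from, to) trimws(substr(lines, from, to))
  xs <- suppressWarnings(as.numeric(substr(lines, 31, 38)))
  ys <- suppressWarnings(as.numeric(substr(lines, 39, 46)))
  zs <- suppressWarnings(as.numeric(substr(lines, 47, 54)))
  bad <- which(!is.finite(xs) | !is.finite(ys) | !is.finite(zs))
  if (length(bad))
    stop("parse error at line ", lineno[bad[1]], ": unreadable coordinates in '",
         trimws(lines[bad[1]]), "'")

  atoms <- data.frame(
    record = trimws(substr(lines, 1, 6)),
    elety = .normalize_atom_name(field(13, 16)),
    alt = trimws(substr(lines, 17, 17)),
    resid = field(18, 20),
    chain = substr(lines, 22, 22),
    resno = suppressWarnings(as.integer(field(23, 26))),
    ins = trimws(substr(lines, 27, 27)),
    x = xs, y = ys, z = zs,
    element = toupper(field(77, 78)),
    stringsAsFactors = FALSE
  )
  badno <- which(is.na(atoms$resno))
  if (length(badno))
    stop("parse error at line ", lineno[badno[1]], ": unreadable residue number")

  noel <- atoms$element == ""
  atoms$element[noel] <- .element_from_name(atoms$elety[noel])

  atoms <- atoms[atoms$alt %in% c("", "A"), , drop = FALSE]
  atoms <- atoms[!(atoms$element %in% c("H", "D")), , drop = FALSE]
  if (nrow(atoms) == 0)
    stop("parse error: no heavy atoms left after filtering")

  fix <- .normalize_protein_residue(atoms$resid, atoms$elety)
  atoms$resid <- fix$resid
  atoms$elety <- fix$elety

  cx <- .new_complex(atoms)
  if (length(cx$protein_chains) == 0 && length(cx$dna_chains) == 0)
    stop("no protein or DNA chains")
  cx
}

#' Read a protein-DNA complex from a PDB file
#'
#' @param file Path to a PDB-format file.
#' @return A `complex_structure`; see [parse_complex()].
#' @export
read_complex <- function(file) {
  parse_complex(readLines(file, warn = FALSE))
}

#' Write a complex as PDB-format text
#'
#' The inverse of [parse_complex()]: writing and re-parsing reproduces atom
#' names, residue numbering and coordinates (PDB fixed-width, 3 decimals).
#'
#' @param cx A `complex_structure`.
#' @param file Optional path; when given the text is also written there.
#' @return Character vector of PDB lines, invisibly when `file` is given.
#' @export
write_complex <- function(cx, file = NULL) {
  stopifnot(inherits(cx, "complex_structure"))
  atoms <- cx$atoms
  if (is.null(atoms) || nrow(atoms) == 0)
    stop("cannot write an empty structure")
  if (any(abs(atoms$x) >= 10000 | abs(atoms$y) >= 10000 | abs(atoms$z) >= 10000) ||
      any(atoms$x <= -1000 | atoms$y <= -1000 | atoms$z <= -1000))
    stop("coordinates overflow the fixed-width PDB coordinate columns")

  fmt_name <- function(nm) {
    # names shorter than 4 characters start in column 14
    padded <- ifelse(nchar(nm) < 4, paste0(" ", nm), nm)
    formatC(padded, width = -4)
  }
  lines <- character(0)
  serial <- 0L
  for (ch in unique(atoms$chain)) {
    sub <- atoms[atoms$chain == ch, , drop = FALSE]
    rec <- sprintf("%-6s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   sub$record, serial + seq_len(nrow(sub)), fmt_name(sub$elety),
                   "", sub$resid, sub$chain, sub$resno, sub$ins,
                   sub$x, sub$y, sub$z, 1, 0, sub$element)
    serial <- serial + nrow(sub)
    lines <- c(lines, rec, "TER")
  }
  lines <- c(lines, "END")
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' @export
print.complex_structure <- function(x, ...) {
  cat("Protein-DNA complex structure\n")
  cat("  atoms:         ", nrow(x$atoms), " (heavy)\n", sep = "")
  cat("  protein chains:", if (length(x$protein_chains))
    paste(x$protein_chains, collapse = ", ") else "none", "\n")
  cat("  DNA chains:    ", if (length(x$dna_chains))
    paste(x$dna_chains, collapse = ", ") else "none", "\n")
  other <- setdiff(unique(x$atoms$chain), c(x$protein_chains, x$dna_chains))
  if (length(other))
    cat("  other chains:  ", paste(other, collapse = ", "), "(excluded from scoring)\n")
  invisible(x)
}

# Composite atom identity used for equivalence between structures.
.atom_key <- function(atoms) {
  paste(atoms$chain, atoms$resno, atoms$ins, atoms$elety, sep = "|")
}

# Residue-level composite identity.
.res_key <- function(atoms) {
  paste(atoms$chain, atoms$resno, atoms$ins, sep = "|")
}

# Coordinate matrix of an atom table.
.xyz <- function(atoms) {
  cbind(atoms$x, atoms$y, atoms$z)
}

# Atoms belonging to protein / DNA chains.
.protein_atoms <- function(cx) {
  cx$atoms[cx$atoms$chain %in% cx$protein_chains &
             cx$atoms$resid %in% .AA_NAMES, , drop = FALSE]
}

.dna_atoms <- function(cx) {
  cx$atoms[cx$atoms$chain %in% cx$dna_chains &
             !is.na(.base_code(cx$atoms$resid)), , drop = FALSE]
}
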