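# All-atom distance-dependent knowledge-based potential.
#
# Pair score: S(i,j,r) = -ln( P(i,j,r) / P_ref(r) ), where P(i,j,r) is the
# pseudocounted distance distribution of atom-type pair (i,j) and P_ref(r)
# the type-pooled distance distribution. Pooled long-distance bins carry
# large mass, so |S| shrinks with distance: the reference acts as the weight
# that damps long-range contributions. Binding free energy of a complex is
# the sum of S over all typed protein-DNA heavy-atom pairs within the
# cutoff, in units of kT (dimensionless here).

#' Atom-type catalogue
#'
#' Residue-specific heavy-atom types: each (residue, atom name) combination
#' is its own type, e.g. the alpha-carbon of cysteine is distinct from the
#' alpha-carbon of alanine. The standard dictionaries enumerate exactly 167
#' protein types (20 amino acids, no OXT) and 82 DNA types (4 nucleotides:
#' 11 sugar-phosphate atoms each plus 10/11/8/9 base atoms for A/G/C/T).
#'
#' @return An `atom_type_catalog`: list with named index vectors
#'   `protein_types` (`"RES|ATOM"`) and `dna_types` (`"DN|ATOM"`).
#' @export
atom_type_catalog <- function() {
  pkeys <- unlist(lapply(.AA_NAMES, function(r) paste(r, .AA_ATOMS[[r]], sep = "|")))
  dnts <- paste0("D", c("A", "C", "G", "T"))
  dkeys <- unlist(lapply(dnts, function(nt) {
    base <- substr(nt, 2, 2)
    paste(nt, c(.BACKBONE_ATOMS, .BASE_ATOMS[[base]]), sep = "|")
  }))
  structure(list(protein_types = stats::setNames(seq_along(pkeys), pkeys),
                 dna_types = stats::setNames(seq_along(dkeys), dkeys)),
            class = "atom_type_catalog")
}

#' @export
print.atom_type_catalog <- function(x, ...) {
  cat("Atom-type catalogue:", length(x$protein_types), "protein types,",
      length(x$dna_types), "DNA types (residue-specific heavy atoms)\n")
  invisible(x)
}

#' Look up the type index of an atom
#'
#' @param residue_name Residue name (3-letter amino acid, DA/DT/DC/DG or
#'   legacy A/T/C/G nucleotide; MSE is typed as MET).
#' @param atom_name PDB heavy-atom name (legacy dialects O1P/C5M/star-primes
#'   accepted).
#' @param catalog An `atom_type_catalog`.
#' @return Integer type index, or `NA` for untyped atoms (waters, ligands,
#'   OXT, terminal-variant atoms).
#' @export
atom_type <- function(residue_name, atom_name, catalog = atom_type_catalog()) {
  atom <- .normalize_atom_name(atom_name)
  fix <- .normalize_protein_residue(residue_name, atom)
  res <- fix$resid; atom <- fix$elety
  base <- .base_code(res)
  key <- ifelse(is.na(base), paste(res, atom, sep = "|"),
                paste0("D", base, "|", atom))
  idx <- ifelse(is.na(base),
                unname(catalog$protein_types[key]),
                unname(catalog$dna_types[key]))
  unname(idx)
}

# Typed protein/DNA atom tables of a complex: rows with a type index.
.typed_protein <- function(cx, catalog) {
  at <- .protein_atoms(cx)
  if (nrow(at) == 0) return(cbind(at, type = integer(0)))
  at$type <- unname(catalog$protein_types[paste(at$resid, at$elety, sep = "|")])
  at[!is.na(at$type), , drop = FALSE]
}

.typed_dna <- function(cx, catalog) {
  at <- .dna_atoms(cx)
  if (nrow(at) == 0) return(cbind(at, type = integer(0)))
  key <- paste0("D", .base_code(at$resid), "|", at$elety)
  at$type <- unname(catalog$dna_types[key])
  at[!is.na(at$type), , drop = FALSE]
}

# Derive P, P_ref and S from a raw count array. Bins with zero pooled mass
# are uninformative and score 0.
.derive_scores <- function(counts, pseudocount) {
  dm <- dim(counts)
  nb <- dm[3]
  m <- matrix(counts, ncol = nb)            # (i,j) x bin
  p <- (m + pseudocount) / (rowSums(m) + nb * pseudocount)
  pooled <- colSums(m)
  p_ref <- pooled / sum(m)
  s <- -log(sweep(p, 2, p_ref, "/"))
  s[, p_ref == 0] <- 0
  list(scores = array(s, dm, dimnames = dimnames(counts)), p_ref = p_ref)
}

.new_potential <- function(counts, bin_width, cutoff, pseudocount, n_complexes) {
  der <- .derive_scores(counts, pseudocount)
  structure(list(counts = counts, bin_width = bin_width, cutoff = cutoff,
                 bin_edges = seq(0, cutoff, by = bin_width),
                 pseudocount = pseudocount, scores = der$scores,
                 p_ref = der$p_ref, n_complexes = n_complexes,
                 catalog = atom_type_catalog()),
            class = "pdna_potential")
}

#' Build a potential from an explicit count table
#'
#' Mainly for controlled experiments: supply `N_obs(i, j, bin)` directly
#' instead of accumulating it from structures.
#'
#' @param counts Numeric array `[167, 82, n_bins]` of non-negative pair
#'   counts (protein type x DNA type x distance bin).
#' @param bin_width,cutoff Distance binning in Angstrom; `n_bins` must equal
#'   `cutoff / bin_width`.
#' @param pseudocount Per-(type pair, bin) pseudocount (default 0).
#' @return A `pdna_potential`.
#' @export
potential_from_counts <- function(counts, bin_width = 0.5, cutoff = 15,
                                  pseudocount = 0) {
  cat_ <- atom_type_catalog()
  nb <- as.integer(round(cutoff / bin_width))
  if (bin_width <= 0 || cutoff <= bin_width)
    stop("need bin_width > 0 and cutoff > bin_width")
  stopifnot(all(dim(counts) == c(length(cat_$protein_types),
                                 length(cat_$dna_types), nb)),
            all(counts >= 0))
  dimnames(counts) <- list(names(cat_$protein_types), names(cat_$dna_types), NULL)
  .new_potential(counts, bin_width, cutoff, pseudocount, n_complexes = NA_integer_)
}

#' Train the knowledge-based potential from a complex collection
#'
#' Accumulates `N_obs(i, j, r)`: every (protein heavy atom, DNA heavy atom)
#' pair within `cutoff` contributes one count to the distance bin of its
#' type pair. Scores are `S = -ln(P(i,j,r)/P_ref(r))` with per-pair
#' pseudocounted normalization and the type-pooled reference distribution.
#'
#' @param complexes List of `complex_structure`s (each needs at least one
#'   in-range protein-DNA atom pair somewhere in the collection).
#' @param bin_width Distance bin width in Angstrom (default 0.5).
#' @param cutoff Maximum scored distance in Angstrom (default 15).
#' @param pseudocount Per-(type pair, bin) pseudocount (default 0.5), keeps
#'   scores finite for unseen bins.
#' @return A `pdna_potential`: counts, bin edges, derived scores, reference
#'   distribution.
#' @export
train_potential <- function(complexes, bin_width = 0.5, cutoff = 15,
                            pseudocount = 0.5) {
  if (inherits(complexes, "complex_structure")) complexes <- list(complexes)
  if (bin_width <= 0 || cutoff <= bin_width)
    stop("need bin_width > 0 and cutoff > bin_width")
  cat_ <- atom_type_catalog()
  ni <- length(cat_$protein_types); nj <- length(cat_$dna_types)
  nb <- as.integer(round(cutoff / bin_width))
  counts <- array(0L, c(ni, nj, nb),
                  dimnames = list(names(cat_$protein_types),
                                  names(cat_$dna_types), NULL))
  for (cx in complexes) {
    pa <- .typed_protein(cx, cat_)
    da <- .typed_dna(cx, cat_)
    if (nrow(pa) == 0 || nrow(da) == 0) next
    d2 <- .dist2(.xyz(pa), .xyz(da))
    hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
    if (nrow(hit) == 0) next
    bins <- pmin(nb, floor(sqrt(pmax(d2[hit], 0)) / bin_width) + 1L)
    lin <- (bins - 1L) * ni * nj + (da$type[hit[, 2]] - 1L) * ni + pa$type[hit[, 1]]
    tab <- tabulate(lin, nbins = ni * nj * nb)
    counts <- counts + array(tab, c(ni, nj, nb))
  }
  if (sum(counts) == 0)
    stop("no protein-DNA atom pairs within the cutoff in the training set")
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(names(cat_$protein_types), names(cat_$dna_types), NULL)
  .new_potential(counts, bin_width, cutoff, pseudocount, length(complexes))
}

#' @export
print.pdna_potential <- function(x, ...) {
  cat("Protein-DNA knowledge-based potential\n")
  cat("  bins:       ", length(x$p_ref), " x ", x$bin_width, " A (cutoff ",
      x$cutoff, " A)\n", sep = "")
  cat("  pair counts:", sum(x$counts), "\n")
  cat("  pseudocount:", x$pseudocount, "\n")
  if (!is.na(x$n_complexes)) cat("  trained on: ", x$n_complexes, "complexes\n")
  invisible(x)
}

#' Binding free energy of a complex
#'
#' `dG` is the sum of the statistical potential over all typed protein-DNA
#' heavy-atom pairs within the cutoff (dimensionless, kT = 1). Pairs beyond
#' the cutoff contribute zero.
#'
#' @param cx A `complex_structure` with protein and DNA chains.
#' @param potential A `pdna_potential`.
#' @return Numeric scalar dG.
#' @export
delta_g <- function(cx, potential) {
  stopifnot(inherits(cx, "complex_structure"), inherits(potential, "pdna_potential"))
  if (sum(potential$counts) == 0) stop("potential is untrained (no counts)")
  cat_ <- potential$catalog
  pa <- .typed_protein(cx, cat_)
  da <- .typed_dna(cx, cat_)
  if (nrow(pa) == 0 || nrow(da) == 0) return(0)
  nb <- length(potential$p_ref)
  d2 <- .dist2(.xyz(pa), .xyz(da))
  hit <- which(d2 <= potential$cutoff^2, arr.ind = TRUE)
  if (nrow(hit) == 0) return(0)
  bins <- pmin(nb, floor(sqrt(pmax(d2[hit], 0)) / potential$bin_width) + 1L)
  sum(potential$scores[cbind(pa$type[hit[, 1]], da$type[hit[, 2]], bins)])
}

#' Change in binding free energy
#'
#' @param mutant_dg dG of the mutated complex.
#' @param native_dg dG of the native complex.
#' @return `mutant_dg - native_dg` (negative favours the mutant).
#' @export
delta_delta_g <- function(mutant_dg, native_dg) {
  stopifnot(is.finite(mutant_dg), is.finite(native_dg))
  mutant_dg - native_dg
}

#' Write a potential to a self-describing text file
#'
#' Stores binning parameters and the non-zero count entries (by type key);
#' [read_potential()] reconstructs the potential bit-exactly.
#'
#' @param potential A `pdna_potential`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_potential <- function(potential, file) {
  stopifnot(inherits(potential, "pdna_potential"))
  nz <- which(potential$counts > 0, arr.ind = TRUE)
  hdr <- c("# bindspec protein-DNA potential v1",
           paste0("bin_width\t", format(potential$bin_width, digits = 17)),
           paste0("cutoff\t", format(potential$cutoff, digits = 17)),
           paste0("pseudocount\t", format(potential$pseudocount, digits = 17)),
           paste0("n_complexes\t", potential$n_complexes),
           "# protein_type\tdna_type\tbin\tcount")
  body <- sprintf("%s\t%s\t%d\t%d",
                  dimnames(potential$counts)[[1]][nz[, 1]],
                  dimnames(potential$counts)[[2]][nz[, 2]],
                  nz[, 3], potential$counts[nz])
  writeLines(c(hdr, body), file)
  invisible(file)
}

#' Read a potential written by [write_potential()]
#'
#' @param file Path to the text file.
#' @return A `pdna_potential`.
#' @export
read_potential <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[!grepl("^#", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  kv <- parts[lengths(parts) == 2]
  meta <- stats::setNames(vapply(kv, `[`, character(1), 2),
                          vapply(kv, `[`, character(1), 1))
  bw <- as.numeric(meta[["bin_width"]])
  cutoff <- as.numeric(meta[["cutoff"]])
  pc <- as.numeric(meta[["pseudocount"]])
  ncx <- suppressWarnings(as.integer(meta[["n_complexes"]]))
  cat_ <- atom_type_catalog()
  nb <- as.integer(round(cutoff / bw))
  counts <- array(0L, c(length(cat_$protein_types), length(cat_$dna_types), nb),
                  dimnames = list(names(cat_$protein_types),
                                  names(cat_$dna_types), NULL))
  rows <- parts[lengths(parts) == 4]
  if (length(rows)) {
    i <- cat_$protein_types[vapply(rows, `[`, character(1), 1)]
    j <- cat_$dna_types[vapply(rows, `[`, character(1), 2)]
    b <- as.integer(vapply(rows, `[`, character(1), 3))
    n <- as.integer(vapply(rows, `[`, character(1), 4))
    if (anyNA(i) || anyNA(j)) stop("unknown atom-type key in potential file")
    counts[cbind(i, j, b)] <- n
  }
  pot <- .new_potential(counts, bw, cutoff, pc, ncx)
  pot
}
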