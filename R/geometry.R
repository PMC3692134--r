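# Rigid-body base-pair replacement.
#
# A mutation swaps the base moiety of a nucleotide for a template of the new
# base type while leaving the sugar-phosphate backbone untouched. The
# template is carried in a canonical frame (glycosidic-nitrogen anchor at the
# origin, base-plane normal along +z, interior ring-angle bisector along +x)
# and placed through the inverse of the frame of the base being replaced:
# anchor onto anchor, normal onto normal, bisector onto bisector.

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("degenerate zero-length vector in frame construction")
  v / n
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Create a rigid transform
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation Length-3 vector (Angstrom).
#' @return A `rigid_transform` applying `x -> rotation %*% x + translation`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation is not orthonormal")
  if (det(rotation) < 0)
    stop("rotation has negative determinant (improper)")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#'
#' @param tr A `rigid_transform`.
#' @param coords Numeric matrix with 3 columns (or length-3 vector); row names
#'   are preserved.
#' @return Transformed coordinates, same shape.
#' @export
apply_transform <- function(tr, coords) {
  stopifnot(inherits(tr, "rigid_transform"))
  vec <- is.null(dim(coords))
  m <- if (vec) matrix(coords, 1, 3) else as.matrix(coords)
  out <- m %*% t(tr$rotation)
  out <- sweep(out, 2, tr$translation, "+")
  if (vec) return(drop(out))
  rownames(out) <- rownames(coords)
  out
}

#' Invert a rigid transform
#'
#' @param tr A `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
invert_transform <- function(tr) {
  stopifnot(inherits(tr, "rigid_transform"))
  rigid_transform(t(tr$rotation), -t(tr$rotation) %*% tr$translation)
}

#' Canonical frame of a base moiety
#'
#' Computes the rigid transform taking a base into its canonical frame: the
#' glycosidic-nitrogen anchor (N9 for purines, N1 for pyrimidines) at the
#' origin, the best-fit base-plane normal (principal axis of the ring-atom
#' covariance) along +z, and the interior bisector of the flanking ring angle
#' at the anchor (C4-N9-C8 for purines, C2-N1-C6 for pyrimidines), projected
#' into the plane, along +x. The normal's sign is fixed by the ring-chirality
#' cross product of the two bisector-arm vectors, so a base and any rigid
#' motion of it always frame consistently (no 180-degree flips).
#'
#' @param base_atoms Numeric matrix of base-moiety coordinates with atom-name
#'   row names (PDB heavy-atom names).
#' @param base_type One of "A", "C", "G", "T".
#' @return A `rigid_transform` mapping the base into the canonical frame.
#' @export
canonical_frame <- function(base_atoms, base_type) {
  base_type <- toupper(base_type)
  stopifnot(base_type %in% names(.BASE_ATOMS))
  coords <- as.matrix(base_atoms)
  rownames(coords) <- .normalize_atom_name(rownames(coords))
  anchor <- .FRAME_ANCHOR[[base_type]]
  plane <- .FRAME_PLANE[[base_type]]
  bis <- .FRAME_BISECTOR[[base_type]]
  need <- unique(c(anchor, plane, bis))
  missing <- setdiff(need, rownames(coords))
  if (length(missing))
    stop("missing frame atom(s) for base ", base_type, ": ",
         paste(missing, collapse = ", "))

  a <- coords[anchor, ]
  pm <- coords[plane, , drop = FALSE]
  cen <- colMeans(pm)
  cv <- crossprod(sweep(pm, 2, cen))
  eig <- eigen(cv, symmetric = TRUE)
  if (eig$values[2] < 1e-8 * max(eig$values[1], 1))
    stop("collinear plane atoms; base plane is undefined")
  n <- eig$vectors[, 3]
  u <- .unit(coords[bis[1], ] - a)
  v <- .unit(coords[bis[3], ] - a)
  chir <- .cross3(u, v)
  if (sum(n * chir) < 0) n <- -n
  b <- u + v
  if (sqrt(sum(b^2)) < 1e-8)
    stop("bisector atoms are collinear with the anchor")
  x <- b - sum(b * n) * n
  x <- .unit(x)
  y <- .cross3(n, x)
  r <- rbind(x, y, n)
  rownames(r) <- NULL
  rigid_transform(r, -r %*% a)
}

#' Build a base template by structural averaging
#'
#' Each instance is mapped into the canonical frame (see [canonical_frame()])
#' and the coordinates are averaged atom-wise; atoms absent from some
#' instances are averaged over the instances that carry them. The average is
#' re-framed so the canonical-frame invariants hold exactly.
#'
#' @param base_instances List of coordinate matrices with atom-name row names,
#'   all of the same base type.
#' @param base_type One of "A", "C", "G", "T".
#' @return A `base_template`: list with `base_type`, `atom_names`, `coords`,
#'   `anchor_atom`, `plane_atoms`, `bisector_atoms`.
#' @export
build_template <- function(base_instances, base_type) {
  base_type <- toupper(base_type)
  stopifnot(base_type %in% names(.BASE_ATOMS))
  if (length(base_instances) == 0)
    stop("at least one base instance is required")
  allowed <- .BASE_ATOMS[[base_type]]
  framed <- lapply(base_instances, function(inst) {
    m <- as.matrix(inst)
    rownames(m) <- .normalize_atom_name(rownames(m))
    m <- m[rownames(m) %in% allowed, , drop = FALSE]
    apply_transform(canonical_frame(m, base_type), m)
  })
  names_seen <- allowed[allowed %in% unique(unlist(lapply(framed, rownames)))]
  avg <- t(vapply(names_seen, function(nm) {
    have <- Filter(function(m) nm %in% rownames(m), framed)
    colMeans(do.call(rbind, lapply(have, function(m) m[nm, ])))
  }, numeric(3)))
  rownames(avg) <- names_seen
  avg <- apply_transform(canonical_frame(avg, base_type), avg)
  structure(list(base_type = base_type,
                 atom_names = names_seen,
                 coords = avg,
                 anchor_atom = .FRAME_ANCHOR[[base_type]],
                 plane_atoms = .FRAME_PLANE[[base_type]],
                 bisector_atoms = .FRAME_BISECTOR[[base_type]]),
            class = "base_template")
}

#' @export
print.base_template <- function(x, ...) {
  cat("Base template '", x$base_type, "': ", nrow(x$coords),
      " heavy atoms, anchor ", x$anchor_atom, "\n", sep = "")
  invisible(x)
}

.template_env <- new.env(parent = emptyenv())

#' Default base templates
#'
#' Templates for all four base types built from the package's idealized
#' planar base geometries (see [build_bdna()]). Use [build_template()] to
#' derive templates from your own structure collection instead; the averaging
#' procedure accepts any number of instances.
#'
#' @return Named list of four `base_template` objects (`A`, `C`, `G`, `T`).
#' @export
base_templates <- function() {
  if (is.null(.template_env$default)) {
    .template_env$default <- lapply(
      stats::setNames(nm = c("A", "C", "G", "T")),
      function(b) build_template(list(.ideal_base_coords(b)), b))
  }
  .template_env$default
}

# Base-moiety coordinate matrix of one residue, rownames = atom names.
.residue_base_coords <- function(cx, chain, resno, ins = "") {
  at <- cx$atoms[cx$atoms$chain == chain & cx$atoms$resno == resno &
                   cx$atoms$ins == ins, , drop = FALSE]
  if (nrow(at) == 0) stop("no residue ", resno, " on chain '", chain, "'")
  base <- .base_code(at$resid[1])
  if (is.na(base)) stop("residue ", at$resid[1], " ", resno, " on chain '",
                        chain, "' is not a standard nucleotide")
  sel <- at[at$elety %in% .BASE_ATOMS[[base]], , drop = FALSE]
  m <- .xyz(sel)
  rownames(m) <- sel$elety
  list(coords = m, base = base, atoms = at)
}

#' Mutate one base by rigid template replacement
#'
#' Replaces the base moiety of a nucleotide with the template of `new_type`:
#' (i) the template anchor is superimposed on the anchor of the old base,
#' (ii) the base-plane normals are aligned, (iii) the interior ring-angle
#' bisectors are aligned, (iv) the old base atoms are removed. Sugar and
#' phosphate atoms are untouched (bit-identical coordinates) and the residue
#' is renamed to the new base type, preserving the residue-name dialect of
#' the input (DA vs legacy A).
#'
#' @param cx A `complex_structure`.
#' @param chain,resno,ins Residue address of the nucleotide to mutate.
#' @param new_type Target base ("A", "C", "G" or "T").
#' @param templates Named list of `base_template`s; default [base_templates()].
#' @return The mutated `complex_structure`.
#' @export
mutate_base <- function(cx, chain, resno, new_type, templates = base_templates(),
                        ins = "") {
  stopifnot(inherits(cx, "complex_structure"))
  new_type <- toupper(new_type)
  if (!new_type %in% names(.BASE_ATOMS)) stop("invalid base type: ", new_type)
  tpl <- templates[[new_type]]
  if (is.null(tpl)) stop("templates do not contain base type ", new_type)

  res <- .residue_base_coords(cx, chain, resno, ins)
  fr <- canonical_frame(res$coords, res$base)
  placed <- apply_transform(invert_transform(fr), tpl$coords)

  old_name <- res$atoms$resid[1]
  new_name <- if (toupper(substr(old_name, 1, 1)) == "D" && nchar(old_name) == 2)
    paste0("D", new_type) else new_type

  atoms <- cx$atoms
  in_res <- atoms$chain == chain & atoms$resno == resno & atoms$ins == ins
  res_rows <- which(in_res)
  backbone <- atoms[in_res & atoms$elety %in% .BACKBONE_ATOMS, , drop = FALSE]
  backbone$resid <- new_name
  newbase <- data.frame(record = "ATOM", elety = rownames(placed), alt = "",
                        resid = new_name, chain = chain, resno = resno,
                        ins = ins, x = placed[, 1], y = placed[, 2],
                        z = placed[, 3],
                        element = substr(rownames(placed), 1, 1),
                        stringsAsFactors = FALSE)
  before <- if (min(res_rows) > 1) atoms[seq_len(min(res_rows) - 1), ] else atoms[0, ]
  after <- if (max(res_rows) < nrow(atoms)) atoms[seq(max(res_rows) + 1, nrow(atoms)), ]
           else atoms[0, ]
  .new_complex(rbind(before, backbone, newbase, after))
}

#' Mutate a Watson-Crick base pair
#'
#' Applies [mutate_base()] to both strands of a duplex pair, e.g. turning
#' `A<->T` into `C<->G`: strand A receives the first base of `new_pair`,
#' strand B the second. The backbone of both strands is unchanged.
#'
#' @param cx A `complex_structure`.
#' @param duplex A `dsdna_duplex` of `cx`.
#' @param pair_index 1-based pair position along strand A.
#' @param new_pair New pair as `"C<->G"`, `c("C", "G")`, or a single base for
#'   strand A (the complement is implied).
#' @param templates Named list of `base_template`s.
#' @return List with the mutated `complex` and the updated `duplex` (base
#'   letters refreshed; contact flags preserved).
#' @export
mutate_pair <- function(cx, duplex, pair_index, new_pair,
                        templates = base_templates()) {
  stopifnot(inherits(duplex, "dsdna_duplex"))
  if (length(new_pair) == 1 && grepl("<->", new_pair, fixed = TRUE))
    new_pair <- strsplit(new_pair, "<->", fixed = TRUE)[[1]]
  new_pair <- toupper(trimws(new_pair))
  if (length(new_pair) == 1) new_pair <- c(new_pair, .COMPLEMENT[[new_pair]])
  if (length(new_pair) != 2 || !all(new_pair %in% names(.BASE_ATOMS)))
    stop("invalid base pair specification")
  if (.COMPLEMENT[[new_pair[1]]] != new_pair[2])
    stop("requested pair ", new_pair[1], "<->", new_pair[2],
         " is not Watson-Crick complementary")
  if (pair_index < 1 || pair_index > nrow(duplex$pairs))
    stop("pair index ", pair_index, " out of range (1..", nrow(duplex$pairs), ")")

  ra <- duplex$strand_a[duplex$pairs[pair_index, 1], ]
  rb <- duplex$strand_b[duplex$pairs[pair_index, 2], ]
  cx <- mutate_base(cx, ra$chain, ra$resno, new_pair[1], templates, ins = ra$ins)
  cx <- mutate_base(cx, rb$chain, rb$resno, new_pair[2], templates, ins = rb$ins)
  duplex$strand_a$base[duplex$pairs[pair_index, 1]] <- new_pair[1]
  duplex$strand_b$base[duplex$pairs[pair_index, 2]] <- new_pair[2]
  list(complex = cx, duplex = duplex)
}

#' RMSD between two structures over equivalent atoms
#'
#' Root-mean-square deviation over atoms with identical (chain, residue
#' number, insertion code, atom name). No superposition is performed: mutant
#' structures share the native coordinate frame by construction.
#'
#' @param cx_a,cx_b `complex_structure`s sharing at least one equivalent atom.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(cx_a, cx_b) {
  stopifnot(inherits(cx_a, "complex_structure"), inherits(cx_b, "complex_structure"))
  ka <- .atom_key(cx_a$atoms)
  kb <- .atom_key(cx_b$atoms)
  idx <- match(ka, kb)
  keep <- which(!is.na(idx))
  if (length(keep) == 0) stop("structures share no equivalent atoms")
  d2 <- rowSums((.xyz(cx_a$atoms[keep, ]) - .xyz(cx_b$atoms[idx[keep], ]))^2)
  sqrt(mean(d2))
}
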