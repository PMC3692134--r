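# Synthetic protein-DNA fixtures.
#
# Everything here is generated analytically so that ground truth (chain
# pairing, contact distances, atom-pair distance distributions) is known by
# construction. Base moieties use idealized regular-ring geometry: planar
# bases, ring bond length 1.38 A, carbonyl 1.23 A, amino 1.34 A, methyl
# 1.50 A, glycosidic 1.47 A. Fixtures need internal consistency, not
# crystallographic accuracy; the helix is an idealized B-form ladder with
# uniform rise and twist and no propeller or roll.

.RING_BOND <- 1.38
.L_CARBONYL <- 1.23
.L_AMINO <- 1.34
.L_METHYL <- 1.50
.L_GLYCOSIDIC <- 1.47
.WC_HBOND <- 2.9

# Run expr under a temporary RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Exocyclic substituent along the exterior bisector at ring atom p with ring
# neighbours u and v.
.exo <- function(p, u, v, len) {
  p - len * .unit(.unit(u - p) + .unit(v - p))
}

# Idealized planar heavy-atom coordinates of one base moiety (z = 0),
# arbitrary in-plane frame; row names are PDB atom names.
.ideal_base_coords <- function(base) {
  base <- toupper(base)
  stopifnot(base %in% names(.BASE_ATOMS))
  hex_names <- c("N1", "C2", "N3", "C4", "C5", "C6")
  ang <- (seq_len(6) - 1) * pi / 3
  hex <- cbind(.RING_BOND * cos(ang), .RING_BOND * sin(ang), 0)
  rownames(hex) <- hex_names
  coords <- hex

  if (base %in% .PURINES) {
    c4 <- hex["C4", ]; c5 <- hex["C5", ]
    mid <- (c4 + c5) / 2
    apo5 <- .RING_BOND / (2 * tan(pi / 5))
    rad5 <- .RING_BOND / (2 * sin(pi / 5))
    cen5 <- mid + apo5 * .unit(mid)
    a4 <- atan2(c4[2] - cen5[2], c4[1] - cen5[1])
    a5 <- atan2(c5[2] - cen5[2], c5[1] - cen5[1])
    s <- sign(sin(a5 - a4))                  # direction from C4 towards C5
    pent_at <- function(k) {
      a <- a4 - s * k * 2 * pi / 5
      c(cen5[1] + rad5 * cos(a), cen5[2] + rad5 * sin(a), 0)
    }
    five <- rbind(N9 = pent_at(1), C8 = pent_at(2), N7 = pent_at(3))
    coords <- rbind(coords, five)
    if (base == "A") {
      coords <- rbind(coords,
                      N6 = .exo(hex["C6", ], hex["C5", ], hex["N1", ], .L_AMINO))
    } else {
      coords <- rbind(coords,
                      O6 = .exo(hex["C6", ], hex["C5", ], hex["N1", ], .L_CARBONYL),
                      N2 = .exo(hex["C2", ], hex["N1", ], hex["N3", ], .L_AMINO))
    }
  } else {
    coords <- rbind(coords,
                    O2 = .exo(hex["C2", ], hex["N1", ], hex["N3", ], .L_CARBONYL))
    if (base == "C") {
      coords <- rbind(coords,
                      N4 = .exo(hex["C4", ], hex["N3", ], hex["C5", ], .L_AMINO))
    } else {
      coords <- rbind(coords,
                      O4 = .exo(hex["C4", ], hex["N3", ], hex["C5", ], .L_CARBONYL),
                      C7 = .exo(hex["C5", ], hex["C4", ], hex["C6", ], .L_METHYL))
    }
  }
  coords[.BASE_ATOMS[[base]], , drop = FALSE]
}

# Schematic sugar-phosphate fragment in the canonical base frame (anchor at
# origin, base plane z = 0, glycosidic direction towards -x). Bond lengths
# are plausible (1.3-1.6 A); the sugar pucker is schematic.
.BACKBONE_LOCAL <- local({
  c1 <- c(-.L_GLYCOSIDIC, 0, 0)
  o4 <- c1 + c(-0.60, 1.15, 0.45)
  c2 <- c1 + c(-0.75, -1.05, 0.70)
  c3 <- c1 + c(-1.95, -0.60, 1.10)
  c4 <- c1 + c(-1.95, 0.85, 1.00)
  o3 <- c3 + c(-0.55, -1.20, 0.55)
  c5 <- c4 + c(-1.05, 1.05, 0.35)
  o5 <- c5 + c(-0.50, 1.20, 0.45)
  p <- o5 + c(-0.45, 1.25, 0.70)
  m <- rbind(P = p, OP1 = p + c(-1.25, 0.45, 0.70), OP2 = p + c(0.60, 0.75, -1.20),
             "O5'" = o5, "C5'" = c5, "C4'" = c4, "O4'" = o4,
             "C3'" = c3, "O3'" = o3, "C2'" = c2, "C1'" = c1)
  m[.BACKBONE_ATOMS, , drop = FALSE]
})

# Full heavy-atom nucleotide (backbone + base) in the canonical base frame.
.ideal_nucleotide <- function(base) {
  tpl <- base_templates()[[base]]
  rbind(.BACKBONE_LOCAL, tpl$coords)
}

.rot_z <- function(theta) {
  rbind(c(cos(theta), -sin(theta), 0), c(sin(theta), cos(theta), 0), c(0, 0, 1))
}
.FLIP_X <- diag(c(1, -1, -1))  # rotation by pi about x: antiparallel partner

# One Watson-Crick pair (both full nucleotides) in the pair frame: base
# planes at z ~ 0, hydrogen-bond axis along x, pair centered on the origin.
.ideal_pair <- function(base_a) {
  base_b <- .COMPLEMENT[[base_a]]
  place <- function(base, flip) {
    nt <- .ideal_nucleotide(base)
    if (flip) nt <- nt %*% t(.FLIP_X)
    anchor <- nt[.FRAME_ANCHOR[[base]], ]
    wc <- nt[.WC_ATOM[[base]], ]
    d <- wc - anchor
    theta <- atan2(d[2], d[1])
    # anchor -> WC direction along +x
    nt <- nt %*% t(.rot_z(-theta))
    sweep(nt, 2, nt[.WC_ATOM[[base]], ], "-")
  }
  a <- place(base_a, flip = FALSE)
  b <- place(base_b, flip = TRUE)
  b <- b %*% t(.rot_z(pi))                # anchor -> WC now along -x
  b <- sweep(b, 2, c(.WC_HBOND, 0, 0), "+")
  shift <- c(-.WC_HBOND / 2, 0, 0)
  list(a = sweep(a, 2, shift, "+"), b = sweep(b, 2, shift, "+"))
}

#' Build an idealized B-DNA duplex
#'
#' Generates a full heavy-atom antiparallel double helix for `sequence`
#' (strand A, 5' to 3'), with uniform helical rise and twist and idealized
#' planar base geometry. Watson-Crick pivot distances (purine N1 to
#' pyrimidine N3) are 2.9 A by construction. Chains are labelled `B` (given
#' strand) and `C` (complement, residues numbered 5' to 3' on its own
#' strand), so pair `i` of chain B partners residue `n - i + 1` of chain C.
#'
#' @param sequence DNA sequence over A/C/G/T, length >= 1.
#' @param rise Helical rise per base-pair step in Angstrom (default 3.38).
#' @param twist Helical twist per step in degrees (default 36).
#' @param jitter Standard deviation of optional isotropic Gaussian coordinate
#'   noise in Angstrom (default 0, exact geometry).
#' @param seed Integer seed used when `jitter > 0`.
#' @param chains Two chain identifiers (default `c("B", "C")`).
#' @return A `complex_structure` with two DNA chains and no protein.
#' @export
build_bdna <- function(sequence, rise = 3.38, twist = 36, jitter = 0,
                       seed = 1L, chains = c("B", "C")) {
  stopifnot(is.character(sequence), length(sequence) == 1, nchar(sequence) >= 1,
            rise > 0)
  bases <- strsplit(toupper(sequence), "")[[1]]
  if (any(!bases %in% names(.BASE_ATOMS)))
    stop("invalid base letter(s) in sequence: ",
         paste(unique(setdiff(bases, names(.BASE_ATOMS))), collapse = ", "))
  n <- length(bases)

  rows_a <- list(); rows_b <- list()
  for (p in seq_len(n)) {
    pair <- .ideal_pair(bases[p])
    rz <- .rot_z((p - 1) * twist * pi / 180)
    lift <- c(0, 0, (p - 1) * rise)
    a <- sweep(pair$a %*% t(rz), 2, lift, "+")
    b <- sweep(pair$b %*% t(rz), 2, lift, "+")
    mk <- function(m, chain, resno, base) {
      data.frame(record = "ATOM", elety = rownames(m), alt = "",
                 resid = paste0("D", base), chain = chain, resno = resno,
                 ins = "", x = m[, 1], y = m[, 2], z = m[, 3],
                 element = substr(rownames(m), 1, 1), stringsAsFactors = FALSE)
    }
    rows_a[[p]] <- mk(a, chains[1], p, bases[p])
    rows_b[[n - p + 1]] <- mk(b, chains[2], n - p + 1, .COMPLEMENT[[bases[p]]])
  }
  atoms <- rbind(do.call(rbind, rows_a), do.call(rbind, rows_b))
  if (jitter > 0) {
    noise <- .with_seed(seed, matrix(stats::rnorm(3 * nrow(atoms), 0, jitter),
                                     ncol = 3))
    atoms$x <- atoms$x + noise[, 1]
    atoms$y <- atoms$y + noise[, 2]
    atoms$z <- atoms$z + noise[, 3]
  }
  .new_complex(atoms)
}

#' Add single-residue protein probes at controlled distances
#'
#' Places one free-standing amino-acid residue (chain `P`) per requested
#' contact so that the named atom sits at exactly the requested distance from
#' the nearest base-moiety heavy atom of the indicated duplex pair; the
#' remaining residue atoms extend outward, away from the duplex, with
#' idealized spacing. Used to create known protein-DNA contacts and known
#' atom-pair distance distributions.
#'
#' @param cx A `complex_structure` from [build_bdna()] (or containing one
#'   detectable duplex).
#' @param contacts Data frame with columns `pair_index`, `distance` (Angstrom,
#'   > 1.5), `residue_name` (3-letter code), `atom_name`.
#' @param chain Probe chain identifier (default "P").
#' @return The `complex_structure` with probes appended.
#' @export
add_probe_protein <- function(cx, contacts, chain = "P") {
  stopifnot(inherits(cx, "complex_structure"))
  contacts <- as.data.frame(contacts)
  need <- c("pair_index", "distance", "residue_name", "atom_name")
  stopifnot(all(need %in% names(contacts)))
  if (any(contacts$distance <= 1.5))
    stop("probe distances must exceed 1.5 Angstrom")
  duplexes <- detect_dsdna(cx)
  if (length(duplexes) == 0) stop("no duplex found to place probes against")
  duplex <- duplexes[[1]]

  start_res <- {
    ex <- cx$atoms$resno[cx$atoms$chain == chain]
    if (length(ex)) max(ex) else 0L
  }
  probe_rows <- list()
  all_xyz <- .xyz(cx$atoms)

  for (k in seq_len(nrow(contacts))) {
    ct <- contacts[k, ]
    if (ct$pair_index < 1 || ct$pair_index > nrow(duplex$pairs))
      stop("pair_index ", ct$pair_index, " out of range")
    resname <- toupper(ct$residue_name)
    if (!resname %in% .AA_NAMES) stop("unknown residue name: ", resname)
    aname <- .normalize_atom_name(ct$atom_name)
    if (!aname %in% .AA_ATOMS[[resname]])
      stop("atom ", aname, " is not a heavy atom of ", resname)

    ra <- duplex$strand_a[duplex$pairs[ct$pair_index, 1], ]
    rb <- duplex$strand_b[duplex$pairs[ct$pair_index, 2], ]
    grab <- function(r) {
      at <- cx$atoms[cx$atoms$chain == r$chain & cx$atoms$resno == r$resno &
                       cx$atoms$ins == r$ins, , drop = FALSE]
      at[at$elety %in% .BASE_ATOMS[[r$base]], , drop = FALSE]
    }
    bm <- rbind(grab(ra), grab(rb))
    bxyz <- .xyz(bm)
    cen <- colMeans(bxyz)
    ord <- order(-sqrt(rowSums(sweep(bxyz, 2, cen)^2)))
    placed <- NULL
    for (cand in ord) {
      ref <- bxyz[cand, ]
      dir <- .unit(ref - cen)
      pos <- ref + ct$distance * dir
      dmin_base <- sqrt(min(.dist2(matrix(pos, 1), bxyz)))
      if (abs(dmin_base - ct$distance) > 1e-9) next
      if (min(.dist2(matrix(pos, 1), all_xyz)) < 1.5^2) next
      placed <- list(pos = pos, dir = dir)
      break
    }
    if (is.null(placed))
      stop("could not place probe ", k, " without steric overlap")

    perp <- .cross3(placed$dir, c(0, 0, 1))
    if (sqrt(sum(perp^2)) < 1e-6) perp <- .cross3(placed$dir, c(1, 0, 0))
    perp <- .unit(perp)
    anames <- .AA_ATOMS[[resname]]
    others <- setdiff(anames, aname)
    coords <- matrix(NA_real_, length(anames), 3,
                     dimnames = list(anames, NULL))
    coords[aname, ] <- placed$pos
    for (m in seq_along(others)) {
      coords[others[m], ] <- placed$pos + placed$dir * (1.2 * m) +
        perp * (0.8 * ((-1)^m))
    }
    if (min(.dist2(coords, all_xyz)) < 1.5^2)
      stop("could not place probe ", k, " without steric overlap")
    resno <- start_res + k
    probe_rows[[k]] <- data.frame(record = "ATOM", elety = anames, alt = "",
                                  resid = resname, chain = chain, resno = resno,
                                  ins = "", x = coords[, 1], y = coords[, 2],
                                  z = coords[, 3],
                                  element = substr(gsub("[0-9]", "", anames), 1, 1),
                                  stringsAsFactors = FALSE)
    all_xyz <- rbind(all_xyz, coords)
  }
  .new_complex(rbind(cx$atoms, do.call(rbind, probe_rows)))
}

#' Generate a synthetic training collection
#'
#' Random-sequence idealized duplexes decorated with single-residue probes at
#' seeded random distances; stands in for a pre-collected protein-DNA complex
#' set when training the knowledge-based potential. The planted contacts are
#' recorded in the `"planted"` attribute for ground-truth checks.
#'
#' @param n_complexes Number of complexes (>= 1).
#' @param seed Integer seed; output is fully reproducible.
#' @param site_length Duplex length per complex (default 8).
#' @param probes_per_complex Number of probe residues per complex (default 3).
#' @return List of `complex_structure`s with a `"planted"` attribute (data
#'   frame: complex, pair_index, distance, residue_name, atom_name).
#' @export
make_training_set <- function(n_complexes, seed = 1L, site_length = 8L,
                              probes_per_complex = 3L) {
  stopifnot(n_complexes >= 1)
  residues <- c("ARG", "LYS", "SER", "ASN", "GLU", "THR", "GLN", "ALA")
  .with_seed(seed, {
    planted <- list()
    out <- vector("list", n_complexes)
    for (i in seq_len(n_complexes)) {
      seqn <- paste(sample(c("A", "C", "G", "T"), site_length, replace = TRUE),
                    collapse = "")
      cx <- build_bdna(seqn)
      res <- sample(residues, probes_per_complex, replace = TRUE)
      ct <- data.frame(
        pair_index = sample(seq_len(site_length), probes_per_complex),
        distance = stats::runif(probes_per_complex, 2.8, 9),
        residue_name = res,
        atom_name = vapply(res, function(r) {
          side <- setdiff(.AA_ATOMS[[r]], c("N", "CA", "C", "O"))
          sample(if (length(side)) side else .AA_ATOMS[[r]], 1)
        }, character(1)),
        stringsAsFactors = FALSE)
      out[[i]] <- add_probe_protein(cx, ct)
      ct$complex <- i
      planted[[i]] <- ct
    }
    attr(out, "planted") <- do.call(rbind, planted)
    out
  })
}

#' Fixture with a planted high-specificity position
#'
#' Builds a small, fully synthetic study: a training collection in which
#' arginine probes are repeatedly observed close (3.2 A) to guanine pairs but
#' only at long range (7.5 A) near the other base types, plus serine probes
#' at a neutral 4.2 A from every base type; and a test complex whose duplex
#' carries a close arginine probe at one guanine position and neutral serine
#' probes at the three flanking positions. A potential trained on the
#' collection therefore rewards G specifically at the arginine-contacted
#' position, giving the full pipeline a known recoverable motif.
#'
#' @param seed Integer seed (controls the filler sequence context).
#' @return List with `training` (complex list), `complex`, `duplex`,
#'   `positions` (mutation range, pair indices), `rewarded_position` (pair
#'   index), `rewarded_base` ("G").
#' @export
make_planted_site_fixture <- function(seed = 1L) {
  .with_seed(seed, {
    rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                  collapse = "")
    training <- list()
    probe <- function(seqn, pair, dist, res, atom) {
      add_probe_protein(build_bdna(seqn),
                        data.frame(pair_index = pair, distance = dist,
                                   residue_name = res, atom_name = atom))
    }
    # arginine close to guanine: the planted short-range enrichment
    for (i in 1:6) {
      s <- rand_seq(7)
      seqn <- paste0(substr(s, 1, 3), "G", substr(s, 4, 7))
      training[[length(training) + 1]] <- probe(seqn, 4, 3.2, "ARG", "NH1")
    }
    # arginine seen near the other bases only at long range
    for (b in c("A", "C", "T")) for (i in 1:2) {
      s <- rand_seq(7)
      seqn <- paste0(substr(s, 1, 3), b, substr(s, 4, 7))
      training[[length(training) + 1]] <- probe(seqn, 4, 7.5, "ARG", "NH1")
    }
    # serine at the same neutral distance from every base type
    for (b in c("A", "C", "G", "T")) for (i in 1:2) {
      s <- rand_seq(7)
      seqn <- paste0(substr(s, 1, 3), b, substr(s, 4, 7))
      training[[length(training) + 1]] <- probe(seqn, 4, 4.2, "SER", "OG")
    }

    test_seq <- "TACGGCAT"   # positions 3..6 = CGGC; rewarded pair is 4 (G)
    cx <- build_bdna(test_seq)
    cx <- add_probe_protein(cx, data.frame(
      pair_index = c(4, 3, 5, 6),
      distance = c(3.2, 4.2, 4.2, 4.2),
      residue_name = c("ARG", "SER", "SER", "SER"),
      atom_name = c("NH1", "OG", "OG", "OG")))
    duplex <- flag_contacts(cx, detect_dsdna(cx)[[1]])
    list(training = training, complex = cx, duplex = duplex,
         positions = 3:6, rewarded_position = 4L, rewarded_base = "G")
  })
}
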