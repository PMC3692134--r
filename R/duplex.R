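# Double-stranded DNA detection and protein-contact annotation.

# Squared-distance matrix between two coordinate matrices (rows = points).
.dist2 <- function(a, b) {
  outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
}

# One row per standard nucleotide of a chain, ordered 5'->3' by residue
# number, with the Watson-Crick pivot atom coordinate attached.
.chain_bases <- function(cx, chain) {
  at <- cx$atoms[cx$atoms$chain == chain, , drop = FALSE]
  code <- .base_code(at$resid)
  unknown <- unique(at$resid[is.na(code) & at$record == "HETATM"])
  at <- at[!is.na(code), , drop = FALSE]
  keys <- unique(.res_key(at))
  rows <- lapply(keys, function(k) {
    sub <- at[.res_key(at) == k, , drop = FALSE]
    base <- .base_code(sub$resid[1])
    wc <- sub[sub$elety == .WC_ATOM[base], , drop = FALSE]
    if (nrow(wc) == 0) return(NULL)
    data.frame(chain = chain, resno = sub$resno[1], ins = sub$ins[1],
               base = base, wx = wc$x[1], wy = wc$y[1], wz = wc$z[1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  out <- out[order(out$resno, out$ins), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unknown_residues") <- unknown
  out
}

# Longest strictly decreasing subsequence (indices), O(n^2); duplexes are short.
.lds <- function(v) {
  n <- length(v)
  if (n == 0) return(integer(0))
  len <- rep(1L, n); prev <- rep(0L, n)
  for (i in seq_len(n)) for (j in seq_len(i - 1L)) {
    if (v[j] > v[i] && len[j] + 1L > len[i]) { len[i] <- len[j] + 1L; prev[i] <- j }
  }
  i <- which.max(len); out <- integer(0)
  while (i > 0L) { out <- c(i, out); i <- prev[i] }
  out
}

.new_duplex <- function(chain_a, chain_b, strand_a, strand_b, pairs) {
  structure(list(chain_a = chain_a, chain_b = chain_b,
                 strand_a = strand_a[, c("chain", "resno", "ins", "base")],
                 strand_b = strand_b[, c("chain", "resno", "ins", "base")],
                 pairs = pairs,
                 contact_flags = rep(NA, nrow(pairs)),
                 contacts = vector("list", nrow(pairs))),
            class = "dsdna_duplex")
}

#' Detect double-stranded DNA duplexes in a complex
#'
#' For every pair of distinct DNA chains, bases are paired when they are
#' Watson-Crick complementary and their hydrogen-bond pivot atoms (purine N1,
#' pyrimidine N3) lie within `hbond_cutoff`. A duplex is reported when at
#' least `min_run` consecutive pairs exist; the paired strands must run
#' antiparallel (partner indices strictly decreasing along strand A). A
#' self-complementary hairpin within one chain is never paired with itself.
#'
#' @param cx A `complex_structure` with at least one DNA chain.
#' @param hbond_cutoff Maximum N1-N3 distance in Angstrom (default 3.5).
#' @param min_run Minimum number of consecutive Watson-Crick pairs (default 3).
#' @return List of `dsdna_duplex` objects, ordered by chain identifiers;
#'   possibly empty.
#' @export
detect_dsdna <- function(cx, hbond_cutoff = 3.5, min_run = 3L) {
  stopifnot(inherits(cx, "complex_structure"))
  if (length(cx$dna_chains) == 0) stop("complex has no DNA chains")
  chains <- sort(cx$dna_chains)
  bases <- lapply(chains, function(ch) .chain_bases(cx, ch))
  names(bases) <- chains
  unknown <- unique(unlist(lapply(bases, attr, "unknown_residues")))
  if (length(unknown))
    warning("unrecognized nucleotide residue(s) excluded from duplex detection: ",
            paste(unknown, collapse = ", "))

  duplexes <- list()
  if (length(chains) < 2) return(duplexes)
  for (i in seq_len(length(chains) - 1)) for (j in seq(i + 1, length(chains))) {
    a <- bases[[i]]; b <- bases[[j]]
    if (is.null(a) || is.null(b)) next
    d2 <- .dist2(cbind(a$wx, a$wy, a$wz), cbind(b$wx, b$wy, b$wz))
    comp <- outer(a$base, b$base, function(x, y) .COMPLEMENT[x] == y)
    cand <- which(comp & d2 <= hbond_cutoff^2, arr.ind = TRUE)
    if (nrow(cand) == 0) next
    # greedy one-to-one assignment by increasing pivot distance
    ord <- order(d2[cand])
    used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
    ia <- integer(0); ib <- integer(0)
    for (k in ord) {
      ra <- cand[k, 1]; rb <- cand[k, 2]
      if (used_a[ra] || used_b[rb]) next
      used_a[ra] <- TRUE; used_b[rb] <- TRUE
      ia <- c(ia, ra); ib <- c(ib, rb)
    }
    o <- order(ia); ia <- ia[o]; ib <- ib[o]
    keep <- .lds(ib)          # enforce antiparallel geometry
    ia <- ia[keep]; ib <- ib[keep]
    if (length(ia) < min_run) next
    run <- 1L; best <- 1L
    if (length(ia) > 1) for (k in seq(2, length(ia))) {
      run <- if (ia[k] == ia[k - 1] + 1L && ib[k] == ib[k - 1] - 1L) run + 1L else 1L
      best <- max(best, run)
    }
    if (best < min_run) next
    duplexes[[length(duplexes) + 1L]] <-
      .new_duplex(chains[i], chains[j], a, b, cbind(ia = ia, ib = ib))
  }
  duplexes
}

#' Flag base pairs contacting the protein
#'
#' A pair is flagged when any heavy atom of the base moiety of either paired
#' base (sugar-phosphate backbone excluded) lies within `threshold` of any
#' protein heavy atom. The contacting protein residues are recorded per
#' flagged pair.
#'
#' @param cx The `complex_structure` the duplex came from.
#' @param duplex A `dsdna_duplex` from [detect_dsdna()].
#' @param threshold Contact distance in Angstrom; default 4.5.
#' @return The duplex with `contact_flags` and `contacts` filled in.
#' @export
flag_contacts <- function(cx, duplex, threshold = 4.5) {
  stopifnot(inherits(cx, "complex_structure"), inherits(duplex, "dsdna_duplex"))
  if (threshold <= 0) stop("contact threshold must be positive")
  prot <- .protein_atoms(cx)
  npair <- nrow(duplex$pairs)
  duplex$contact_flags <- rep(FALSE, npair)
  duplex$contacts <- replicate(npair, NULL, simplify = FALSE)
  if (nrow(prot) == 0) return(duplex)
  pxyz <- .xyz(prot)

  base_atoms_of <- function(strand, idx) {
    r <- strand[idx, ]
    at <- cx$atoms[cx$atoms$chain == r$chain & cx$atoms$resno == r$resno &
                     cx$atoms$ins == r$ins, , drop = FALSE]
    at[at$elety %in% .BASE_ATOMS[[r$base]], , drop = FALSE]
  }
  for (p in seq_len(npair)) {
    at <- rbind(base_atoms_of(duplex$strand_a, duplex$pairs[p, 1]),
                base_atoms_of(duplex$strand_b, duplex$pairs[p, 2]))
    if (nrow(at) == 0) next
    d2 <- .dist2(.xyz(at), pxyz)
    hit <- which(apply(d2, 2, min) <= threshold^2)
    if (length(hit)) {
      duplex$contact_flags[p] <- TRUE
      res <- unique(prot[hit, c("resid", "resno", "chain")])
      rownames(res) <- NULL
      duplex$contacts[[p]] <- res
    }
  }
  duplex
}

#' Base sequence of a duplex along strand A
#'
#' Bases of the paired positions, 5' to 3' along strand A. Pair positions are
#' 1-based in this order throughout the package.
#'
#' @param duplex A `dsdna_duplex`.
#' @return Single character string over A/C/G/T.
#' @export
duplex_sequence <- function(duplex) {
  paste(duplex$strand_a$base[duplex$pairs[, 1]], collapse = "")
}

#' Tabular report of a duplex
#'
#' @param duplex A `dsdna_duplex`, ideally after [flag_contacts()].
#' @return Data frame with pair index, both bases with residue numbers,
#'   contact flag and contacting protein residues.
#' @export
duplex_report <- function(duplex) {
  stopifnot(inherits(duplex, "dsdna_duplex"))
  a <- duplex$strand_a[duplex$pairs[, 1], ]
  b <- duplex$strand_b[duplex$pairs[, 2], ]
  contacts <- vapply(duplex$contacts, function(r) {
    if (is.null(r) || nrow(r) == 0) ""
    else paste(sprintf("%s%d:%s", r$resid, r$resno, r$chain), collapse = ",")
  }, character(1))
  data.frame(pair = seq_len(nrow(duplex$pairs)),
             base_a = a$base, resno_a = a$resno,
             base_b = b$base, resno_b = b$resno,
             contact = duplex$contact_flags,
             contacting_residues = contacts,
             stringsAsFactors = FALSE)
}

#' @export
print.dsdna_duplex <- function(x, ...) {
  cat("dsDNA duplex ", x$chain_a, " <-> ", x$chain_b, ", ",
      nrow(x$pairs), " base pairs\n", sep = "")
  cat("  strand A 5'->3': ", duplex_sequence(x), "\n", sep = "")
  if (!all(is.na(x$contact_flags))) {
    n <- sum(x$contact_flags, na.rm = TRUE)
    cat("  protein-contacting pairs: ", n, " (",
        paste(which(x$contact_flags), collapse = ", "), ")\n", sep = "")
  }
  invisible(x)
}
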