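# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

# 6-mer idealized duplex decorated with three single-residue probes.
fixture_complex <- function() {
  if (is.null(.fixture_cache$cx)) {
    .fixture_cache$cx <- add_probe_protein(build_bdna("ACGTAC"), data.frame(
      pair_index = c(2, 3, 5), distance = c(3.5, 4.0, 4.4),
      residue_name = c("ARG", "SER", "LYS"), atom_name = c("NH1", "OG", "NZ")))
  }
  .fixture_cache$cx
}

fixture_dna <- function() build_bdna("ACGTAC")

# Planted high-specificity fixture plus its trained potential.
planted_fixture <- function() {
  if (is.null(.fixture_cache$planted)) {
    fx <- make_planted_site_fixture(seed = 1)
    .fixture_cache$planted <- list(fx = fx, pot = train_potential(fx$training))
  }
  .fixture_cache$planted
}

# Compose a fixed-width PDB ATOM/HETATM line for hand-built inputs.
pdb_line <- function(record, serial, name, resid, chain, resno, x, y, z,
                     element = substr(name, 1, 1), alt = "") {
  padded <- if (nchar(name) < 4) paste0(" ", name) else name
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, padded, alt, resid, chain, resno, x, y, z, 1, 0, element)
}

# Brute-force binding-energy oracle: explicit per-atom summation, independent
# of the matrix path used by delta_g().
brute_force_dg <- function(cx, pot) {
  cat_ <- pot$catalog
  pa <- bindspec:::.typed_protein(cx, cat_)
  da <- bindspec:::.typed_dna(cx, cat_)
  if (nrow(pa) == 0 || nrow(da) == 0) return(0)
  nb <- length(pot$p_ref)
  total <- 0
  for (i in seq_len(nrow(pa))) {
    r <- sqrt((pa$x[i] - da$x)^2 + (pa$y[i] - da$y)^2 + (pa$z[i] - da$z)^2)
    keep <- which(r <= pot$cutoff)
    for (j in keep) {
      b <- min(nb, floor(r[j] / pot$bin_width) + 1L)
      total <- total + pot$scores[pa$type[i], da$type[j], b]
    }
  }
  total
}

# Exhaustive pairwise AUC oracle.
pairwise_auc <- function(scores, positive) {
  ps <- scores[positive]; ns <- scores[!positive]
  cmp <- outer(ps, ns, "-")
  (sum(cmp > 0) + 0.5 * sum(cmp == 0)) / (length(ps) * length(ns))
}

# Per-atom shape deviation after best-fit (Kabsch) superposition of a on b;
# removes frame-convention differences so only geometry is compared.
superposed_deviation <- function(a, b) {
  ca <- sweep(a, 2, colMeans(a)); cb <- sweep(b, 2, colMeans(b))
  s <- svd(crossprod(ca, cb))
  d <- sign(det(s$v %*% t(s$u)))
  r <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sqrt(rowSums((ca %*% t(r) - cb)^2))
}

# Random proper rigid transform for invariance properties.
random_rigid <- function() {
  m <- matrix(stats::rnorm(9), 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  rigid_transform(q, stats::rnorm(3, sd = 5))
}
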