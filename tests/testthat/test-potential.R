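# Atom typing and the distance-binned knowledge-based potential.

test_that("the atom-type catalogue is residue-specific and complete", {
  cat_ <- atom_type_catalog()
  expect_length(cat_$protein_types, 167)
  expect_length(cat_$dna_types, 82)
  expect_false(atom_type("CYS", "CA", cat_) == atom_type("ALA", "CA", cat_))
  gly <- grep("^GLY\\|", names(cat_$protein_types), value = TRUE)
  expect_setequal(gly, paste0("GLY|", c("N", "CA", "C", "O")))
  expect_true(is.na(atom_type("HOH", "O", cat_)))
  expect_true(is.na(atom_type("GLY", "OXT", cat_)))
  # legacy aliases type like their modern names
  expect_identical(atom_type("A", "O1P", cat_), atom_type("DA", "OP1", cat_))
  expect_identical(atom_type("MSE", "SE", cat_), atom_type("MET", "SD", cat_))
})

test_that("scores match hand arithmetic on a hand-built count table", {
  cat_ <- atom_type_catalog()
  nb <- 30L
  counts <- array(0, c(167, 82, nb))
  i1 <- atom_type("ALA", "CA", cat_); i2 <- atom_type("CYS", "CA", cat_)
  j1 <- atom_type("DA", "N9", cat_); j2 <- atom_type("DT", "O4", cat_)
  counts[i1, j1, 1] <- 4; counts[i1, j1, 2] <- 6
  counts[i2, j2, 1] <- 9; counts[i2, j2, 2] <- 1
  pot <- potential_from_counts(counts, pseudocount = 0)
  # P_ref = (13, 7)/20 over the two populated bins
  expect_equal(pot$scores[i1, j1, 1], -log(0.4 / (13 / 20)), tolerance = 1e-12)
  expect_equal(pot$scores[i1, j1, 2], -log(0.6 / (7 / 20)), tolerance = 1e-12)
  expect_equal(pot$scores[i2, j2, 1], -log(0.9 / (13 / 20)), tolerance = 1e-12)
  expect_equal(pot$scores[i2, j2, 2], -log(0.1 / (7 / 20)), tolerance = 1e-12)
  # one-bin concentration: P ~ 1 there
  expect_lt(pot$scores[i2, j2, 1], 0)
})

test_that("uniform counts give identically zero scores and doubling changes nothing", {
  nb <- 30L
  vb <- rep(seq_len(nb), each = 167 * 82)
  counts <- array(vb, c(167, 82, nb))
  pot <- potential_from_counts(counts, pseudocount = 0)
  expect_true(all(pot$scores == 0))

  set.seed(5)
  sparse <- array(0, c(167, 82, nb))
  idx <- cbind(sample(167, 50, TRUE), sample(82, 50, TRUE), sample(nb, 50, TRUE))
  sparse[idx] <- sample(1:9, 50, TRUE)
  p1 <- potential_from_counts(sparse, pseudocount = 0)
  p2 <- potential_from_counts(2 * sparse, pseudocount = 0)
  expect_equal(p1$scores, p2$scores, tolerance = 1e-12)
})

test_that("per-pair distributions normalize and the pooled reference sums to one", {
  nb <- 30L
  counts <- array(0, c(167, 82, nb))
  counts[1, 1, ] <- 1:nb          # dense row
  counts[5, 7, ] <- 2             # flat row
  counts[10, 3, 4] <- 7           # single-bin row
  pot <- potential_from_counts(counts, pseudocount = 0.5)
  expect_equal(sum(pot$p_ref), 1, tolerance = 1e-12)
  # reconstruct P from S and P_ref: all bins pooled-populated here
  for (ij in list(c(1, 1), c(5, 7), c(10, 3), c(2, 2))) {
    p <- exp(-pot$scores[ij[1], ij[2], ]) * pot$p_ref
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
})

test_that("training validates bins and requires in-range pairs", {
  expect_error(train_potential(list(), bin_width = 0), "bin_width")
  expect_error(train_potential(list(), bin_width = 2, cutoff = 1), "bin_width")
  far <- parse_complex(c(
    pdb_line("ATOM", 1, "N", "GLY", "A", 1, 100, 0, 0),
    pdb_line("ATOM", 2, "N9", "DA", "B", 1, 0, 0, 0)))
  expect_error(train_potential(list(far)), "no protein-DNA atom pairs")
})

test_that("dG is a one-term sum for a single atom pair and zero beyond cutoff", {
  pot <- planted_fixture()$pot
  cat_ <- pot$catalog
  pair <- parse_complex(c(
    pdb_line("ATOM", 1, "N", "GLY", "A", 1, 3.7, 0, 0),
    pdb_line("ATOM", 2, "N9", "DA", "B", 1, 0, 0, 0)))
  b <- floor(3.7 / pot$bin_width) + 1
  expect_equal(delta_g(pair, pot),
               pot$scores[atom_type("GLY", "N", cat_),
                          atom_type("DA", "N9", cat_), b],
               tolerance = 1e-12)
  far <- parse_complex(c(
    pdb_line("ATOM", 1, "N", "GLY", "A", 1, 50, 0, 0),
    pdb_line("ATOM", 2, "N9", "DA", "B", 1, 0, 0, 0)))
  expect_equal(delta_g(far, pot), 0)
  untrained <- potential_from_counts(array(0, c(167, 82, 30)))
  expect_error(delta_g(pair, untrained), "untrained")
})

test_that("dG equals the brute-force oracle and is rigid-motion invariant", {
  pot <- planted_fixture()$pot
  fixtures <- make_training_set(3, seed = 19, site_length = 6,
                                probes_per_complex = 2)
  set.seed(23)
  for (cx in fixtures) {
    dg <- delta_g(cx, pot)
    expect_equal(dg, brute_force_dg(cx, pot), tolerance = 1e-9)
    tr <- random_rigid()
    moved <- cx
    xyz <- apply_transform(tr, bindspec:::.xyz(cx$atoms))
    moved$atoms$x <- xyz[, 1]; moved$atoms$y <- xyz[, 2]; moved$atoms$z <- xyz[, 3]
    expect_equal(delta_g(moved, pot), dg, tolerance = 1e-9)
  }
})

test_that("ddG is a plain difference", {
  expect_equal(delta_delta_g(-12, -10), -2)
  expect_equal(delta_delta_g(3.25, 3.25), 0)
  expect_error(delta_delta_g(NaN, 0), "finite")
})

test_that("potential serialization round-trips bit-exactly", {
  pot <- train_potential(make_training_set(2, seed = 31, site_length = 5,
                                           probes_per_complex = 2))
  tf <- tempfile(fileext = ".tsv")
  write_potential(pot, tf)
  back <- read_potential(tf)
  expect_identical(back$counts, pot$counts)
  expect_identical(back$scores, pot$scores)
  expect_identical(back$bin_width, pot$bin_width)
  expect_identical(back$pseudocount, pot$pseudocount)
})

test_that("planted short-range enrichment drives the enriched score negative", {
  base <- make_training_set(6, seed = 11, site_length = 6,
                            probes_per_complex = 2)
  extra <- lapply(1:6, function(i) {
    s <- random_sites(1, 5, seed = 100 + i)
    seqn <- paste0(substr(s, 1, 2), "G", substr(s, 3, 5))
    add_probe_protein(build_bdna(seqn),
                      data.frame(pair_index = 3, distance = 3.0,
                                 residue_name = "ARG", atom_name = "NH1"))
  })
  pot <- train_potential(c(base, extra))
  i <- pot$catalog$protein_types[["ARG|NH1"]]
  b <- floor(3.0 / pot$bin_width) + 1
  js <- grep("^DG\\|", names(pot$catalog$dna_types))
  cnt <- pot$counts[i, js, b]
  expect_gt(max(cnt), 0)
  j_enriched <- js[which.max(cnt)]
  expect_lt(pot$scores[i, j_enriched, b], 0)
})
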