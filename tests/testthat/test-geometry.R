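# Canonical frames, template averaging, rigid-body mutation, RMSD.

test_that("canonical frame is identity on a canonical template and inverts known motions", {
  tpl <- base_templates()$A
  fr <- canonical_frame(tpl$coords, "A")
  expect_lt(max(abs(fr$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(fr$translation)), 1e-9)

  th <- pi / 2
  rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- tpl$coords %*% t(rz)
  fr2 <- canonical_frame(moved, "A")
  expect_lt(max(abs(fr2$rotation - t(rz))), 1e-6)
  expect_lt(max(abs(apply_transform(fr2, moved) - tpl$coords)), 1e-6)
})

test_that("frame recovery holds for random rigid motions of all base types", {
  set.seed(42)
  for (b in c("A", "C", "G", "T")) for (rep in 1:5) {
    tpl <- base_templates()[[b]]
    tr <- random_rigid()
    moved <- apply_transform(tr, tpl$coords)
    fr <- canonical_frame(moved, b)
    expect_lt(max(abs(apply_transform(fr, moved) - tpl$coords)), 1e-6)
    expect_equal(det(fr$rotation), 1, tolerance = 1e-9)
  }
})

test_that("frame construction reports missing or degenerate atoms", {
  tpl <- base_templates()$A
  expect_error(canonical_frame(tpl$coords[rownames(tpl$coords) != "N9", ], "A"),
               "N9")
  fake <- tpl$coords
  fake[, 2:3] <- 0
  fake[, 1] <- seq_len(nrow(fake))   # all atoms on a line
  expect_error(canonical_frame(fake, "A"), "collinear")
})

test_that("template averaging reproduces rigid-motion instances and denoises", {
  tpl <- base_templates()$G
  expect_error(build_template(list(), "G"), "at least one")
  one <- build_template(list(tpl$coords), "G")
  expect_lt(max(abs(one$coords - tpl$coords)), 1e-9)

  set.seed(7)
  two <- build_template(list(apply_transform(random_rigid(), tpl$coords),
                             apply_transform(random_rigid(), tpl$coords)), "G")
  expect_lt(max(abs(two$coords - tpl$coords)), 1e-6)

  set.seed(11)
  noisy <- lapply(1:100, function(i) {
    inst <- tpl$coords + matrix(rnorm(length(tpl$coords), 0, 0.05), ncol = 3)
    apply_transform(random_rigid(), inst)
  })
  avg <- build_template(noisy, "G")
  dev <- superposed_deviation(avg$coords, tpl$coords)
  expect_lt(max(dev), 0.02)
})

test_that("mutation preserves the backbone and places anchor and plane exactly", {
  cx <- fixture_dna()
  old <- cx$atoms[cx$atoms$chain == "B" & cx$atoms$resno == 1, ]
  mut <- mutate_base(cx, "B", 1, "C")
  new <- mut$atoms[mut$atoms$chain == "B" & mut$atoms$resno == 1, ]
  expect_identical(unique(new$resid), "DC")

  bb <- bindspec:::.BACKBONE_ATOMS
  expect_identical(old[old$elety %in% bb, c("x", "y", "z")] |> unname(),
                   new[new$elety %in% bb, c("x", "y", "z")] |> unname())
  # anchor on anchor: new N1 coincides with old N9
  oN9 <- unlist(old[old$elety == "N9", c("x", "y", "z")])
  nN1 <- unlist(new[new$elety == "N1", c("x", "y", "z")])
  expect_lt(sqrt(sum((oN9 - nN1)^2)), 1e-6)
  # plane normal on plane normal
  normal_of <- function(at, base) {
    m <- bindspec:::.xyz(at[at$elety %in% bindspec:::.FRAME_PLANE[[base]], ])
    ev <- eigen(crossprod(sweep(m, 2, colMeans(m))), symmetric = TRUE)$vectors[, 3]
    ev
  }
  na <- normal_of(old, "A"); nc <- normal_of(new, "C")
  ang <- acos(pmin(1, abs(sum(na * nc))))
  expect_lt(ang, 1e-6)
  # all other residues untouched
  rest_old <- cx$atoms[!(cx$atoms$chain == "B" & cx$atoms$resno == 1), ]
  rest_new <- mut$atoms[!(mut$atoms$chain == "B" & mut$atoms$resno == 1), ]
  expect_identical(rest_old$x, rest_new$x)
})

test_that("pair mutation renames both strands and composes back to native", {
  cx <- fixture_dna()
  d <- detect_dsdna(cx)[[1]]
  # templates built from the native bases themselves (pairs 1..4 = A,C,G,T)
  own <- lapply(stats::setNames(nm = c("A", "C", "G", "T")), function(b) {
    pos <- match(b, strsplit("ACGT", "")[[1]])
    inst <- bindspec:::.residue_base_coords(cx, "B", pos)$coords
    build_template(list(inst), b)
  })
  step <- mutate_pair(cx, d, 1, "C<->G", templates = own)
  expect_identical(duplex_sequence(step$duplex), "CCGTAC")
  resb <- step$complex$atoms[step$complex$atoms$chain == "B" &
                               step$complex$atoms$resno == 1, ]
  expect_identical(unique(resb$resid), "DC")
  back <- mutate_pair(step$complex, step$duplex, 1, "A<->T", templates = own)
  expect_lt(rmsd(back$complex, cx), 1e-6)
  native_xyz <- bindspec:::.xyz(cx$atoms[cx$atoms$chain == "B" & cx$atoms$resno == 1, ])
  back_xyz <- bindspec:::.xyz(back$complex$atoms[back$complex$atoms$chain == "B" &
                                                   back$complex$atoms$resno == 1, ])
  expect_lt(max(abs(native_xyz - back_xyz)), 1e-6)
})

test_that("pair mutation validates its arguments", {
  cx <- fixture_dna()
  d <- detect_dsdna(cx)[[1]]
  expect_error(mutate_pair(cx, d, 1, "A<->G"), "complementary")
  expect_error(mutate_pair(cx, d, 99, "A<->T"), "out of range")
  expect_error(mutate_base(cx, "B", 99, "C"), "no residue")
})

test_that("rmsd matches closed forms and requires shared atoms", {
  cx <- fixture_dna()
  expect_equal(rmsd(cx, cx), 0)
  shifted <- cx
  shifted$atoms$x <- shifted$atoms$x + 3
  shifted$atoms$y <- shifted$atoms$y + 4
  expect_equal(rmsd(cx, shifted), 5, tolerance = 1e-12)
  one <- cx
  one$atoms$x[1] <- one$atoms$x[1] + 2.5
  expect_equal(rmsd(cx, one), 2.5 / sqrt(nrow(cx$atoms)), tolerance = 1e-12)
  other <- cx
  other$atoms$chain <- ifelse(other$atoms$chain == "B", "X", "Y")
  expect_error(rmsd(cx, other), "no equivalent atoms")
})
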