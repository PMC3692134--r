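# Mutant enumeration, flexibility filtering, PFMs and the pipeline driver.

test_that("mutant enumeration matches the combinatorial closed form", {
  # sum over m of C(w, m) * 3^m, with/without the native sequence
  closed <- function(w, k, native) {
    sum(vapply(1:k, function(m) choose(w, m) * 3^m, numeric(1))) + native
  }
  for (w in c(2, 4, 6)) for (k in seq_len(min(w, 3))) {
    native <- paste(rep("A", w), collapse = "")
    expect_length(enumerate_mutants(native, max_mutations = k), closed(w, k, 0))
    expect_length(enumerate_mutants(native, max_mutations = k,
                                    include_native = TRUE), closed(w, k, 1))
  }
  expect_identical(enumerate_mutants("A", max_mutations = 1), c("C", "G", "T"))
})

test_that("enumeration is lexicographic, distinct and range-validated", {
  out <- enumerate_mutants("ACGT", max_mutations = 2, include_native = TRUE)
  expect_identical(out, sort(unique(out), method = "radix"))
  expect_true("ACGT" %in% out)
  sub <- enumerate_mutants("ACGTAC", positions = 2:3, max_mutations = 2)
  expect_length(sub, 3 + 3 + 9)
  # untouched positions never change
  expect_true(all(substr(sub, 1, 1) == "A" & substr(sub, 4, 6) == "TAC"))
  expect_error(enumerate_mutants("ACG", positions = 1:5, max_mutations = 1),
               "outside")
  expect_error(enumerate_mutants("ACG", max_mutations = 0), "max_mutations")
})

test_that("flexibility filter reproduces worked selections for both minimum signs", {
  # native dG -10; mutants dG' in {-12, -9, -7}: T = 2, the +3 change is out
  rec <- data.frame(sequence = c("NAT", "M1", "M2", "M3"),
                    n_mutations = c(0, 1, 1, 1), ddg = c(0, -2, 1, 3))
  out <- flexibility_filter(rec)
  expect_identical(out$selected, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(attr(out, "threshold"), 2)
  # all mutants worse: dG' in {-8, -5} vs native -10: T = 2, only -8 survives
  rec2 <- data.frame(sequence = c("NAT", "M1", "M2"),
                     n_mutations = c(0, 1, 1), ddg = c(0, 2, 5))
  out2 <- flexibility_filter(rec2)
  expect_identical(out2$selected, c(TRUE, TRUE, FALSE))
  # a single mutant sits exactly on the boundary and is always selected
  rec3 <- data.frame(sequence = c("NAT", "M1"), n_mutations = 0:1, ddg = c(0, 4))
  expect_true(all(flexibility_filter(rec3)$selected))
  expect_warning(flexibility_filter(data.frame(sequence = "NAT",
                                               n_mutations = 0, ddg = 0)),
                 "native")
})

test_that("filter selection is invariant to a constant energy shift", {
  set.seed(9)
  for (i in 1:20) {
    ddg <- round(rnorm(12, 0, 3), 3)
    rec <- data.frame(sequence = sprintf("M%02d", 1:13),
                      n_mutations = c(0, rep(1, 12)), ddg = c(0, ddg))
    base_sel <- flexibility_filter(rec)$selected
    # shifting every dG' and the native dG by c leaves all ddg unchanged
    shifted <- rec
    shifted$dg <- c(0, ddg) + rnorm(1) * 0 + 5.5
    expect_identical(flexibility_filter(shifted)$selected, base_sel)
  }
})

test_that("PFM construction counts frequencies and validates input", {
  p <- build_pfm("ACGT")
  expect_equal(unclass(p), diag(4)[, c(1, 2, 3, 4)],
               ignore_attr = TRUE)
  p2 <- build_pfm(c("AA", "AC"))
  expect_equal(unclass(p2)[, 1], c(A = 1, C = 0, G = 0, T = 0))
  expect_equal(unclass(p2)[, 2], c(A = 0.5, C = 0.5, G = 0, T = 0))
  expect_error(build_pfm(c("AA", "ACG")), "same length")
  # all 4^w sequences give the uniform matrix
  all3 <- enumerate_mutants("AAA", max_mutations = 3, include_native = TRUE)
  expect_length(all3, 64)
  expect_true(all(abs(unclass(build_pfm(all3)) - 0.25) < 1e-12))
  expect_true(all(abs(colSums(build_pfm(c("ACGT", "AATT", "CGCG"))) - 1) < 1e-12))
})

test_that("PFM scoring matches closed forms, truncates, and scans strands", {
  uni <- as_pfm(matrix(0.25, 4, 5))
  expect_equal(score_pfm(uni, "GATTA"), 5 * log2(0.26 / 0.25), tolerance = 1e-12)
  half <- as_pfm(matrix(c(0.5, 0.5, 0, 0), 4, 1))
  expect_equal(score_pfm(half, "A"), log2(0.51 / 0.25), tolerance = 1e-12)
  hot <- build_pfm("ACGT")
  scores <- vapply(enumerate_mutants("ACGT", max_mutations = 4,
                                     include_native = TRUE),
                   score_pfm, numeric(1), pfm = hot)
  expect_identical(names(which.max(scores)), "ACGT")
  # truncated overlap when the remaining substring is shorter than the PFM
  expect_equal(score_pfm(hot, "TTAC", k = 3),
               score_pfm(as_pfm(unclass(hot)[, 1:2]), "AC"), tolerance = 1e-12)
  expect_error(score_pfm(hot, "ACGT", k = 9), "out of range")
  # reverse-complement and scanning find the planted match
  expect_equal(score_pfm(hot, "ACGT", reverse_complement = TRUE),
               max(score_pfm(hot, "ACGT"), score_pfm(hot, "ACGT")), tolerance = 1e-12)
  expect_equal(score_pfm(hot, "GGACGTGG", scan = TRUE), score_pfm(hot, "ACGT"),
               tolerance = 1e-12)
  expect_equal(score_pfm(hot, reverse_complement("GGACGTGG"), scan = TRUE,
                         reverse_complement = TRUE),
               score_pfm(hot, "ACGT"), tolerance = 1e-12)
})

test_that("raising the frequency of a sequence's base never lowers its score", {
  set.seed(13)
  for (i in 1:20) {
    w <- sample(3:6, 1)
    m <- matrix(runif(4 * w, 0.05, 1), 4)
    p <- as_pfm(m)
    s <- paste(sample(c("A", "C", "G", "T"), w, TRUE), collapse = "")
    sc <- score_pfm(p, s)
    j <- sample(w, 1)
    base <- substr(s, j, j)
    bumped <- unclass(p)
    others <- setdiff(rownames(bumped), base)
    delta <- 0.5 * (1 - bumped[base, j])
    bumped[base, j] <- bumped[base, j] + delta
    bumped[others, j] <- bumped[others, j] * (1 - bumped[base, j]) /
      sum(bumped[others, j])
    expect_gte(score_pfm(as_pfm(bumped), s), sc - 1e-12)
  }
})

test_that("random sites are reproducible, uniform and correctly sized", {
  a <- random_sites(10000, 9, seed = 1)
  b <- random_sites(10000, 9, seed = 1)
  expect_identical(a, b)
  expect_length(a, 10000)
  expect_true(all(nchar(a) == 9))
  big <- random_sites(100000, 9, seed = 2)
  tab <- table(strsplit(paste(big, collapse = ""), "")[[1]])
  expect_true(all(abs(tab / sum(tab) - 0.25) < 0.005))
})

test_that("the pipeline scores every mutant consistently with a direct recomputation", {
  pl <- planted_fixture()
  cx <- pl$fx$complex
  fit <- predict_specificity(cx, pl$pot, positions = 3:6, max_mutations = 1)
  expect_equal(nrow(fit$records), 13)  # 4 positions x 3 + native
  expect_equal(sum(fit$records$n_mutations == 0), 1)
  nat <- fit$records[fit$records$n_mutations == 0, ]
  expect_equal(nat$ddg, 0)
  expect_equal(nat$rmsd, 0)

  d <- detect_dsdna(cx)[[1]]
  site <- strsplit(fit$native_sequence, "")[[1]]
  for (row in sample(which(fit$records$n_mutations == 1), 3)) {
    s <- strsplit(fit$records$sequence[row], "")[[1]]
    pos <- which(s != site)
    step <- mutate_pair(cx, d, (3:6)[pos], s[pos])
    expect_equal(fit$records$ddg[row],
                 delta_g(step$complex, pl$pot) - delta_g(cx, pl$pot),
                 tolerance = 1e-9)
    expect_equal(fit$records$rmsd[row], rmsd(step$complex, cx), tolerance = 1e-9)
  }
  # ddg-ascending puts the native at ddg = 0 between better and worse mutants
  expect_true(!is.unsorted(fit$records$ddg))
})

test_that("fit methods expose the PFM, rankings, predictions and simulations", {
  pl <- planted_fixture()
  fit <- predict_specificity(pl$fx$complex, pl$pot, positions = 3:6)
  expect_s3_class(fit, "specificity_fit")
  expect_identical(coef(fit), fit$pfm)
  expect_true(all(abs(colSums(coef(fit)) - 1) < 1e-12))

  by_pfm <- rank_records(fit, by = "pfm_score")
  expect_true(!is.unsorted(-by_pfm$pfm_score))
  # stable tie-break by sequence within equal keys
  ties <- split(by_pfm$sequence, by_pfm$pfm_score)
  expect_true(all(vapply(ties, function(s) !is.unsorted(s), logical(1))))

  preds <- predict(fit, c("CGGC", "ATAT"))
  expect_named(preds, c("CGGC", "ATAT"))
  expect_gt(preds["CGGC"], preds["ATAT"])

  sims <- simulate(fit, nsim = 50, seed = 4)
  expect_length(sims, 50)
  expect_true(all(nchar(sims) == ncol(coef(fit))))
  expect_identical(sims, simulate(fit, nsim = 50, seed = 4))

  tf <- tempfile(fileext = ".tsv")
  write_ranking(fit, tf)
  tab <- read.delim(tf)
  expect_identical(names(tab), c("sequence", "n_mutations", "dg", "ddg",
                                 "pfm_score", "rmsd", "selected"))
  expect_equal(nrow(tab), nrow(fit$records))
})
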