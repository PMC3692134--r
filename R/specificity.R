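# Mutant enumeration, energy-based selection, PFM construction and scoring,
# and the end-to-end pipeline driver.

.BASES <- c("A", "C", "G", "T")

#' Enumerate limited-mutation sequences
#'
#' All distinct sequences differing from `native` in at most `max_mutations`
#' positions within `positions`, each differing position taking any of the
#' three non-native bases. A site of width 6 yields 153 mutants for up to two
#' mutations; width 10 yields 435. Output is in deterministic lexicographic
#' order.
#'
#' @param native Native sequence (A/C/G/T string).
#' @param positions 1-based positions allowed to mutate (default: all).
#' @param max_mutations Maximum number of mutated positions `k`,
#'   `1 <= k <= length(positions)`.
#' @param include_native Include the unmutated sequence (default `FALSE`).
#' @return Character vector of sequences.
#' @export
#' @examples
#' length(enumerate_mutants("ACGTAC", max_mutations = 2))  # 153
enumerate_mutants <- function(native, positions = NULL, max_mutations = 1L,
                              include_native = FALSE) {
  native <- toupper(native)
  chars <- strsplit(native, "")[[1]]
  if (any(!chars %in% .BASES)) stop("native sequence must be over A/C/G/T")
  w <- length(chars)
  if (is.null(positions)) positions <- seq_len(w)
  positions <- as.integer(positions)
  if (any(positions < 1 | positions > w))
    stop("mutation positions outside the sequence (1..", w, ")")
  k <- as.integer(max_mutations)
  if (k < 1 || k > length(positions))
    stop("max_mutations must be between 1 and the number of positions")

  out <- if (include_native) native else character(0)
  for (m in seq_len(k)) {
    combos <- utils::combn(positions, m)
    for (ci in seq_len(ncol(combos))) {
      pos <- combos[, ci]
      alts <- lapply(pos, function(p) setdiff(.BASES, chars[p]))
      grid <- as.matrix(expand.grid(alts, stringsAsFactors = FALSE))
      block <- matrix(chars, nrow(grid), w, byrow = TRUE)
      block[, pos] <- grid
      out <- c(out, do.call(paste0, as.data.frame(block, stringsAsFactors = FALSE)))
    }
  }
  sort(unique(out), method = "radix")
}

#' Select mutants within the flexibility criterion
#'
#' The acceptable flexibility is `T = |min over mutants of (dG' - dG_native)|`;
#' a record is selected when its energy change does not exceed `T`. A negative
#' change is preferred, but a positive change within the acceptable range is
#' still favourable. The native record (zero mutations, ddG = 0) is always
#' selected.
#'
#' @param records Data frame with columns `n_mutations` and `ddg` (plus any
#'   others, preserved).
#' @return `records` with a logical `selected` column; the threshold is in
#'   attribute `"threshold"`.
#' @export
flexibility_filter <- function(records) {
  stopifnot(is.data.frame(records), all(c("n_mutations", "ddg") %in% names(records)))
  mut <- records$n_mutations > 0
  if (!any(mut)) {
    warning("no mutant records; only the native sequence is selected")
    records$selected <- records$n_mutations == 0
    attr(records, "threshold") <- 0
    return(records)
  }
  thr <- abs(min(records$ddg[mut]))
  records$selected <- records$ddg <= thr | records$n_mutations == 0
  attr(records, "threshold") <- thr
  records
}

#' Build a position frequency matrix
#'
#' Column-stochastic base frequencies of an equal-length sequence set; each
#' sequence counts once, no pseudocount (pseudocounts belong to scoring).
#'
#' @param sequences Character vector of equal-length A/C/G/T sequences.
#' @return A `pfm`: 4 x w numeric matrix (rows A, C, G, T; columns sum to 1)
#'   with the number of sequences in attribute `"support"`.
#' @export
build_pfm <- function(sequences) {
  if (length(sequences) < 1) stop("at least one sequence is required")
  sequences <- toupper(sequences)
  w <- unique(nchar(sequences))
  if (length(w) != 1) stop("sequences must all have the same length")
  m <- do.call(rbind, strsplit(sequences, ""))
  freq <- vapply(seq_len(w), function(j) {
    tab <- table(factor(m[, j], levels = .BASES))
    as.numeric(tab) / length(sequences)
  }, numeric(4))
  dimnames(freq) <- list(.BASES, seq_len(w))
  structure(freq, class = "pfm", support = length(sequences))
}

#' Coerce a 4 x w (or w x 4) matrix to a `pfm`
#'
#' Rows (or columns) must be in A, C, G, T order; columns are normalized to
#' frequencies.
#'
#' @param x Numeric matrix of frequencies or counts.
#' @param support Optional number of sequences behind the matrix.
#' @return A `pfm`.
#' @export
as_pfm <- function(x, support = NA_integer_) {
  m <- as.matrix(x)
  if (nrow(m) != 4 && ncol(m) == 4) m <- t(m)
  if (nrow(m) != 4) stop("a PFM needs 4 base rows (A, C, G, T)")
  if (any(m < 0)) stop("PFM entries must be non-negative")
  cs <- colSums(m)
  if (any(cs == 0)) stop("PFM has an empty column")
  m <- sweep(m, 2, cs, "/")
  dimnames(m) <- list(.BASES, seq_len(ncol(m)))
  structure(m, class = "pfm", support = support)
}

#' @export
print.pfm <- function(x, digits = 3, ...) {
  cat("Position frequency matrix, width ", ncol(x), sep = "")
  sup <- attr(x, "support")
  if (!is.null(sup) && !is.na(sup)) cat(" (", sup, " sequences)", sep = "")
  cat("\n")
  print(round(unclass(x), digits))
  invisible(x)
}

#' Reverse complement of a PFM
#'
#' Reverses the column order and swaps A with T and C with G.
#'
#' @param pfm A `pfm`.
#' @return The reverse-complement `pfm`.
#' @export
reverse_complement_pfm <- function(pfm) {
  m <- unclass(pfm)[c("T", "G", "C", "A"), rev(seq_len(ncol(pfm))), drop = FALSE]
  dimnames(m) <- list(.BASES, seq_len(ncol(m)))
  structure(m, class = "pfm", support = attr(pfm, "support"))
}

#' Score a sequence against a PFM
#'
#' Log-likelihood-ratio score: with position `k` of `S` aligned to the first
#' PFM column (no insertions or deletions),
#' `Score = sum_j log2((P[S_j, j] + eps) / background)` over the overlap; when
#' the substring from `k` is shorter than the PFM, the width is truncated
#' accordingly. Optionally the reverse complement is scored too and the
#' maximum returned, and scanning mode maximizes over all alignment offsets.
#' Within the pipeline `k = 1`: mutated sequences are already aligned to the
#' PFM.
#'
#' @param pfm A `pfm` of width `w`.
#' @param sequence Sequence to score (length >= 1).
#' @param k 1-based alignment offset into `sequence` (default 1).
#' @param reverse_complement Also score the reverse complement and return the
#'   maximum (default `FALSE`).
#' @param scan Maximize over all offsets `k` (default `FALSE`).
#' @param pseudocount Frequency pseudocount eps (default 0.01).
#' @param background Background frequency per base (default 0.25).
#' @return Numeric score (bits).
#' @export
score_pfm <- function(pfm, sequence, k = 1L, reverse_complement = FALSE,
                      scan = FALSE, pseudocount = 0.01, background = 0.25) {
  stopifnot(inherits(pfm, "pfm"))
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  one <- function(s, off) {
    chars <- strsplit(s, "")[[1]]
    wp <- min(ncol(pfm), length(chars) - off + 1L)
    j <- seq_len(wp)
    sum(log2((pfm[cbind(chars[off + j - 1L], j)] + pseudocount) / background))
  }
  strands <- sequence
  if (reverse_complement) strands <- c(sequence, reverse_complement(sequence))
  if (scan) {
    return(max(vapply(strands, function(s)
      max(vapply(seq_len(n), function(off) one(s, off), numeric(1))), numeric(1))))
  }
  k <- as.integer(k)
  if (k < 1 || k > n) stop("alignment offset k out of range (1..", n, ")")
  max(vapply(strands, one, numeric(1), off = k))
}

#' Random candidate binding sites
#'
#' i.i.d. uniform sequences over A/C/G/T, reproducible under `seed`; used as
#' negative samples when evaluating rankings.
#'
#' @param n Number of sequences (>= 1).
#' @param width Sequence length (>= 1).
#' @param seed Integer seed.
#' @return Character vector of `n` sequences.
#' @export
random_sites <- function(n, width, seed = 1L) {
  stopifnot(n >= 1, width >= 1)
  .with_seed(seed, {
    m <- matrix(sample(.BASES, n * width, replace = TRUE), n, width)
    do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
  })
}

# Resolve the duplex argument of predict_specificity.
.resolve_duplex <- function(cx, duplex) {
  if (inherits(duplex, "dsdna_duplex")) return(duplex)
  found <- detect_dsdna(cx)
  if (length(found) == 0) stop("no double-stranded DNA detected in the complex")
  labels <- vapply(found, function(d) paste0(d$chain_a, " <-> ", d$chain_b),
                   character(1))
  if (is.null(duplex)) {
    if (length(found) > 1)
      stop("multiple duplexes detected (", paste(labels, collapse = ", "),
           "); select one via the 'duplex' argument")
    return(found[[1]])
  }
  if (is.numeric(duplex)) {
    if (duplex < 1 || duplex > length(found)) stop("duplex index out of range")
    return(found[[duplex]])
  }
  want <- toupper(gsub("[^A-Za-z0-9]", "", duplex))
  hit <- which(vapply(found, function(d)
    toupper(paste0(d$chain_a, d$chain_b)) == want ||
      toupper(paste0(d$chain_b, d$chain_a)) == want, logical(1)))
  if (length(hit) != 1)
    stop("duplex '", duplex, "' not found; available: ",
         paste(labels, collapse = ", "))
  found[[hit]]
}

#' Predict binding specificity from a protein-DNA complex
#'
#' The end-to-end pipeline: enumerate all sequences with limited mutations
#' from the native site, synthesize each mutant structure by rigid-body base
#' replacement, score it with the knowledge-based potential (`dG'`, `ddG`,
#' RMSD versus native), keep the mutants within the flexibility criterion,
#' summarize them as a position frequency matrix, and score every sequence
#' against that PFM.
#'
#' @param cx A `complex_structure` with protein and DNA chains.
#' @param potential A trained `pdna_potential`.
#' @param duplex Which duplex to analyse: `NULL` (sole detected duplex), a
#'   `dsdna_duplex`, an index, or a chain label like `"B:C"`.
#' @param positions Pair positions (1-based along strand A) to mutate;
#'   default: the protein-contacting pairs (all pairs if none are flagged).
#' @param max_mutations Maximum mutations per sequence (default 2; two tends
#'   to give the most faithful PFMs, larger values help only for strongly
#'   degenerate sites).
#' @param templates Base templates for mutation (default [base_templates()]).
#' @param contact_threshold Contact distance for flagging, Angstrom.
#' @return A `specificity_fit`: ranked records (`sequence`, `n_mutations`,
#'   `dg`, `ddg`, `pfm_score`, `rmsd`, `selected`), the `pfm`, the native
#'   sequence/energy, the flexibility threshold, and the annotated duplex.
#' @seealso [rank_records()], [score_pfm()], [write_ranking()]
#' @export
predict_specificity <- function(cx, potential, duplex = NULL, positions = NULL,
                                max_mutations = 2L, templates = base_templates(),
                                contact_threshold = 4.5) {
  stopifnot(inherits(cx, "complex_structure"), inherits(potential, "pdna_potential"))
  dpx <- .resolve_duplex(cx, duplex)
  dpx <- flag_contacts(cx, dpx, threshold = contact_threshold)
  npair <- nrow(dpx$pairs)
  if (is.null(positions)) {
    positions <- which(dpx$contact_flags)
    if (length(positions) == 0) positions <- seq_len(npair)
  }
  positions <- sort(as.integer(positions))
  if (any(positions < 1 | positions > npair))
    stop("mutation positions outside the duplex (1..", npair, ")")

  site_chars <- strsplit(duplex_sequence(dpx), "")[[1]]
  native_site <- paste(site_chars[positions], collapse = "")
  seqs <- enumerate_mutants(native_site, seq_along(positions),
                            max_mutations = max_mutations,
                            include_native = TRUE)

  native_dg <- delta_g(cx, potential)
  rec <- lapply(seqs, function(s) {
    chars <- strsplit(s, "")[[1]]
    diffp <- which(chars != site_chars[positions])
    mcx <- cx
    mdx <- dpx
    for (d in diffp) {
      step <- mutate_pair(mcx, mdx, positions[d], chars[d], templates)
      mcx <- step$complex
      mdx <- step$duplex
    }
    dg <- if (length(diffp)) delta_g(mcx, potential) else native_dg
    data.frame(sequence = s, n_mutations = length(diffp), dg = dg,
               ddg = dg - native_dg,
               rmsd = if (length(diffp)) rmsd(mcx, cx) else 0,
               stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, rec)
  records <- flexibility_filter(records)
  thr <- attr(records, "threshold")
  pfm <- build_pfm(records$sequence[records$selected])
  records$pfm_score <- vapply(records$sequence, score_pfm, numeric(1), pfm = pfm)
  records <- records[order(records$ddg, records$sequence, method = "radix"), ]
  rownames(records) <- NULL
  records <- records[, c("sequence", "n_mutations", "dg", "ddg", "pfm_score",
                         "rmsd", "selected")]
  attr(records, "threshold") <- thr

  structure(list(records = records, pfm = pfm, native_sequence = native_site,
                 native_dg = native_dg, threshold = thr, positions = positions,
                 duplex = dpx, max_mutations = max_mutations,
                 call = match.call()),
            class = "specificity_fit")
}

#' Re-rank pipeline records by any column
#'
#' @param fit A `specificity_fit`.
#' @param by One of `"ddg"` (ascending), `"pfm_score"` (descending),
#'   `"n_mutations"` (ascending) or `"rmsd"` (ascending).
#' @return The records data frame, stably re-ordered (ties broken by sequence).
#' @export
rank_records <- function(fit, by = c("ddg", "pfm_score", "n_mutations", "rmsd")) {
  by <- match.arg(by)
  r <- fit$records
  key <- r[[by]]
  if (by == "pfm_score") key <- -key
  r <- r[order(key, r$sequence, method = "radix"), ]
  rownames(r) <- NULL
  r
}

#' Write the ranked mutant list as TSV
#'
#' @param fit A `specificity_fit`.
#' @param file Output path.
#' @param by Ranking column, see [rank_records()].
#' @return `file`, invisibly.
#' @export
write_ranking <- function(fit, file, by = "ddg") {
  utils::write.table(rank_records(fit, by), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @export
print.specificity_fit <- function(x, n = 8, ...) {
  cat("Structure-based binding-specificity prediction\n")
  cat("  native site:      ", x$native_sequence, " (pairs ",
      paste(range(x$positions), collapse = ".."), ")\n", sep = "")
  cat("  native dG:        ", format(x$native_dg, digits = 6), "\n", sep = "")
  cat("  mutants scored:   ", nrow(x$records) - 1L, " (<= ", x$max_mutations,
      " mutations)\n", sep = "")
  cat("  flexibility T:    ", format(x$threshold, digits = 6),
      "  (selected: ", sum(x$records$selected), ")\n", sep = "")
  cat("\nTop of the ranking (by ddG):\n")
  print(utils::head(x$records, n), digits = 4)
  invisible(x)
}

#' @export
summary.specificity_fit <- function(object, ...) {
  r <- object$records
  out <- list(native_sequence = object$native_sequence,
              native_dg = object$native_dg,
              threshold = object$threshold,
              n_records = nrow(r),
              n_selected = sum(r$selected),
              ddg_range = range(r$ddg),
              pfm = object$pfm,
              consensus = paste(rownames(object$pfm)[apply(object$pfm, 2,
                                                           which.max)],
                                collapse = ""))
  class(out) <- "summary.specificity_fit"
  out
}

#' @export
print.summary.specificity_fit <- function(x, ...) {
  cat("Binding-specificity fit summary\n")
  cat("  native site:", x$native_sequence, "  native dG:",
      format(x$native_dg, digits = 6), "\n")
  cat("  records:", x$n_records, " selected:", x$n_selected,
      " flexibility T:", format(x$threshold, digits = 6), "\n")
  cat("  ddG range: [", format(x$ddg_range[1], digits = 4), ", ",
      format(x$ddg_range[2], digits = 4), "]\n", sep = "")
  cat("  PFM consensus:", x$consensus, "\n\n")
  print(x$pfm)
  invisible(x)
}

#' @export
coef.specificity_fit <- function(object, ...) {
  object$pfm
}

#' Score new sequences with a fitted PFM
#'
#' @param object A `specificity_fit`.
#' @param newdata Character vector of sequences.
#' @param reverse_complement,scan Passed to [score_pfm()]; scanning with
#'   reverse-complement consideration is the default for external sequences.
#' @param ... Ignored.
#' @return Named numeric vector of PFM scores.
#' @export
predict.specificity_fit <- function(object, newdata,
                                    reverse_complement = TRUE, scan = TRUE, ...) {
  stats::setNames(vapply(newdata, score_pfm, numeric(1), pfm = object$pfm,
                         reverse_complement = reverse_complement, scan = scan),
                  newdata)
}

#' Sample sequences from the fitted PFM
#'
#' Draws independent positions from the column frequencies, a simple
#' generative read of the motif.
#'
#' @param object A `specificity_fit`.
#' @param nsim Number of sequences.
#' @param seed Integer seed.
#' @param ... Ignored.
#' @return Character vector of `nsim` sequences.
#' @export
simulate.specificity_fit <- function(object, nsim = 1, seed = 1L, ...) {
  p <- unclass(object$pfm)
  .with_seed(seed, {
    cols <- lapply(seq_len(ncol(p)), function(j)
      sample(rownames(p), nsim, replace = TRUE, prob = p[, j]))
    do.call(paste0, cols)
  })
}

#' Plot the fitted position frequency matrix
#'
#' Stacked per-position base frequencies (information-free logo substitute
#' using base graphics).
#'
#' @param x A `specificity_fit`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.specificity_fit <- function(x, ...) {
  graphics::barplot(unclass(x$pfm), legend.text = rownames(x$pfm),
                    xlab = "site position", ylab = "base frequency",
                    main = "Predicted position frequency matrix",
                    col = c("#33A02C", "#1F78B4", "#FF7F00", "#E31A1C"), ...)
  invisible(x)
}
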