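# Assessment metrics: Psi divergence between PFMs, PFM alignment, ROC/AUC,
# threshold sensitivity/specificity, and probe-intensity averaging for
# k-mer specificity references.

#' Psi divergence between two PFMs
#'
#' Width-averaged symmetric quadratic divergence between column-normalized
#' frequency matrices:
#' `Psi = (1/w) * sum_j sum_i (a_ij - b_ij)^2 / (a_ij + b_ij)`, with 0/0
#' terms counted as zero. Zero for identical PFMs; smaller values mean more
#' consistent motifs. Widths must match; use [align_pfms()] first otherwise.
#'
#' @param predicted,annotated `pfm` objects (or matrices coercible via
#'   [as_pfm()]) of equal width.
#' @return Non-negative numeric divergence.
#' @export
psi_test <- function(predicted, annotated) {
  a <- if (inherits(predicted, "pfm")) predicted else as_pfm(predicted)
  b <- if (inherits(annotated, "pfm")) annotated else as_pfm(annotated)
  if (ncol(a) != ncol(b))
    stop("PFM widths differ (", ncol(a), " vs ", ncol(b),
         "); align them first with align_pfms()")
  num <- (unclass(a) - unclass(b))^2
  den <- unclass(a) + unclass(b)
  terms <- ifelse(den == 0, 0, num / den)
  sum(terms) / ncol(a)
}

#' Align two PFMs by offset and strand
#'
#' Scans all ungapped offsets of the narrower PFM along the wider one, on
#' both strands (the reverse complement of a PFM reverses the columns and
#' swaps A with T and C with G), and minimizes the overlap-averaged Psi
#' divergence. Ties prefer larger overlap, then the forward strand, then the
#' smaller offset.
#'
#' @param predicted,annotated `pfm` objects; widths may differ.
#' @param min_overlap Smallest overlap width considered (default 1).
#' @return List with `offset` (column of the wider PFM aligned with column 1
#'   of the narrower), `strand` (`"forward"` or `"reverse"`, applied to the
#'   narrower), `psi`, and `overlap`.
#' @export
align_pfms <- function(predicted, annotated, min_overlap = 1L) {
  a <- if (inherits(predicted, "pfm")) predicted else as_pfm(predicted)
  b <- if (inherits(annotated, "pfm")) annotated else as_pfm(annotated)
  swap <- ncol(a) > ncol(b)
  shorter <- if (swap) b else a
  longer <- if (swap) a else b
  ws <- ncol(shorter); wl <- ncol(longer)

  best <- NULL
  for (strand in c("forward", "reverse")) {
    s <- if (strand == "forward") shorter else reverse_complement_pfm(shorter)
    for (o in seq(2L - ws, wl)) {
      js <- which(o + seq_len(ws) - 1L >= 1L & o + seq_len(ws) - 1L <= wl)
      if (length(js) < min_overlap) next
      sub_s <- unclass(s)[, js, drop = FALSE]
      sub_l <- unclass(longer)[, o + js - 1L, drop = FALSE]
      num <- (sub_s - sub_l)^2
      den <- sub_s + sub_l
      psi <- sum(ifelse(den == 0, 0, num / den)) / length(js)
      cand <- list(offset = o, strand = strand, psi = psi, overlap = length(js))
      if (is.null(best) || psi < best$psi - 1e-15 ||
          (abs(psi - best$psi) <= 1e-15 && cand$overlap > best$overlap))
        best <- cand
    }
  }
  if (is.null(best)) stop("no overlapping alignment of the two PFMs exists")
  best
}

.as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels != 0)
  tolower(as.character(labels)) %in% c("positive", "pos", "true", "1")
}

#' Area under the ROC curve of a labeled ranking
#'
#' Rank-sum (Mann-Whitney) AUC: the probability that a random positive
#' outscores a random negative, with tied scores contributing 1/2.
#'
#' @param scores Numeric scores (higher = predicted more likely positive).
#' @param labels Positive/negative labels: logical, 0/1, or
#'   `"positive"`/`"negative"` strings.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  pos <- .as_binary_labels(labels)
  stopifnot(length(scores) == length(pos))
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0 || nn == 0)
    stop("AUC needs at least one positive and one negative")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
}

#' Label the top-k reference-scored sequences as positives
#'
#' Exactly `k` sequences with the highest reference scores are labeled
#' positive; ties at the boundary are broken deterministically by sequence
#' (lexicographic).
#'
#' @param sequences Character vector.
#' @param ref_scores Reference scores (e.g. probe-averaged PBM intensities).
#' @param k Number of positives, `0 < k < length(sequences)`.
#' @return Data frame (`sequence`, `ref_score`, `label`) in the input order.
#' @export
top_k_positives <- function(sequences, ref_scores, k) {
  stopifnot(length(sequences) == length(ref_scores))
  k <- as.integer(k)
  if (k <= 0) stop("k must be positive")
  if (k >= length(sequences)) stop("k must be smaller than the number of sequences")
  ord <- order(-ref_scores, sequences, method = "radix")
  label <- rep("negative", length(sequences))
  label[ord[seq_len(k)]] <- "positive"
  data.frame(sequence = sequences, ref_score = ref_scores, label = label,
             stringsAsFactors = FALSE)
}

#' Sensitivity and specificity at a score threshold
#'
#' Scores at or above `threshold` are called positive.
#'
#' @param scores Numeric scores.
#' @param labels True labels (see [auc()]).
#' @param threshold Decision threshold.
#' @return Named vector: `sensitivity` (TPR) and `specificity` (TNR).
#' @export
sensitivity_specificity <- function(scores, labels, threshold) {
  pos <- .as_binary_labels(labels)
  called <- scores >= threshold
  c(sensitivity = sum(called & pos) / sum(pos),
    specificity = sum(!called & !pos) / sum(!pos))
}

#' Average probe intensities over probes containing a k-mer
#'
#' The relative specificity of a k-mer is summarized as the mean intensity
#' across all probes containing the k-mer or its reverse complement (both
#' orientations occur on double-stranded probes).
#'
#' @param kmers Character vector of target strings.
#' @param probes Character vector of probe sequences.
#' @param intensities Numeric intensities, one per probe.
#' @return Named numeric vector of mean intensities (`NA` when no probe
#'   contains the k-mer).
#' @export
average_probe_scores <- function(kmers, probes, intensities) {
  stopifnot(length(probes) == length(intensities))
  vapply(stats::setNames(nm = kmers), function(km) {
    hit <- grepl(km, probes, fixed = TRUE) |
      grepl(reverse_complement(km), probes, fixed = TRUE)
    if (!any(hit)) return(NA_real_)
    mean(intensities[hit])
  }, numeric(1))
}
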