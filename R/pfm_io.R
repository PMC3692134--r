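# Plain-text PFM formats: JASPAR-style 4-row and TRANSFAC-like matrices.

#' Write a PFM as text
#'
#' `"jaspar"` writes the familiar four base rows (`A [ ... ]`);
#' `"transfac"` writes a position-per-row matrix with a `PO` header and `XX`
#' terminator.
#'
#' @param pfm A `pfm`.
#' @param file Output path.
#' @param format `"jaspar"` (default) or `"transfac"`.
#' @param name Motif identifier written in the header.
#' @return `file`, invisibly.
#' @export
write_pfm <- function(pfm, file, format = c("jaspar", "transfac"),
                      name = "bindspec_pfm") {
  stopifnot(inherits(pfm, "pfm"))
  format <- match.arg(format)
  m <- unclass(pfm)
  if (format == "jaspar") {
    lines <- c(paste0(">", name),
               vapply(rownames(m), function(b)
                 sprintf("%s [ %s ]", b,
                         paste(format(m[b, ], digits = 10), collapse = " ")),
                 character(1)))
  } else {
    lines <- c(paste0("ID ", name), "PO A C G T",
               vapply(seq_len(ncol(m)), function(j)
                 sprintf("%02d %s", j,
                         paste(format(m[, j], digits = 10), collapse = " ")),
                 character(1)),
               "XX")
  }
  writeLines(lines, file)
  invisible(file)
}

#' Read a PFM from text
#'
#' Accepts JASPAR-style four-row matrices (`A [ ... ]`, brackets optional),
#' TRANSFAC-like position-per-row matrices (`PO`/`P0` header), or a bare
#' whitespace-separated numeric matrix (4 x w, or w x 4 transposed). Counts
#' are normalized to column frequencies.
#'
#' @param file Path to the matrix file.
#' @return A `pfm`.
#' @export
read_pfm <- function(file) {
  lines <- trimws(readLines(file, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (any(grepl("^[ACGT]\\s*\\[", lines)) ||
      any(grepl("^[ACGT]\\s+[0-9.]", lines))) {
    rows <- lapply(c("A", "C", "G", "T"), function(b) {
      ln <- lines[grepl(paste0("^", b, "\\b"), lines)][1]
      if (is.na(ln)) stop("JASPAR-style matrix is missing the ", b, " row")
      v <- suppressWarnings(as.numeric(
        strsplit(gsub("[][]", " ", sub("^[ACGT]", "", ln)), "\\s+")[[1]]))
      v[!is.na(v)]
    })
    if (length(unique(lengths(rows))) != 1)
      stop("JASPAR-style matrix rows have unequal widths")
    return(as_pfm(do.call(rbind, rows)))
  }
  if (any(grepl("^P[O0]\\b", lines))) {
    start <- which(grepl("^P[O0]\\b", lines))[1]
    body <- lines[seq(start + 1, length(lines))]
    body <- body[!grepl("^(XX|//)", body)]
    vals <- lapply(strsplit(body, "\\s+"), function(p) {
      v <- suppressWarnings(as.numeric(p))
      v <- v[!is.na(v)]
      if (length(v) > 4) v <- utils::tail(v, 4)  # drop the leading position index
      v
    })
    vals <- Filter(function(v) length(v) == 4, vals)
    if (length(vals) == 0) stop("no matrix rows found under the PO header")
    return(as_pfm(t(do.call(rbind, vals))))
  }
  m <- as.matrix(utils::read.table(text = lines))
  as_pfm(m)
}
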