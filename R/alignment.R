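#' Residue pairing by local alignment, and sequence motif search
#'
#' @description
#' C-alpha positions of two structures are paired through a Smith-Waterman
#' local alignment of their 1-letter residue sequences (the convention used to
#' build superposition pair lists for homologous photosensory modules). The
#' alignment is affine-gap (Gotoh): a gap of length k costs
#' `gap_open + (k - 1) * gap_extend`.
#'
#' @name pairing
#' @keywords internal
NULL

.default_subst <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      if (requireNamespace("Biostrings", quietly = TRUE)) {
        e <- new.env()
        utils::data("BLOSUM62", package = "Biostrings", envir = e)
        cache <<- e$BLOSUM62
      } else stop("no substitution table: install Biostrings or pass a matrix")
    }
    cache
  }
})

#' Alignment parameters
#'
#' @param substitution a square scoring matrix with residue letters as
#'   dimnames, or the name `"BLOSUM62"` (default, loaded from Biostrings).
#' @param gap_open gap opening penalty (>= 0), charged for the first gapped
#'   position.
#' @param gap_extend gap extension penalty (>= 0, <= `gap_open`), charged for
#'   each further gapped position.
#' @return An object of class `align_params`.
#' @export
align_params <- function(substitution = "BLOSUM62", gap_open = 10,
                         gap_extend = 1) {
  if (is.character(substitution)) {
    if (!identical(substitution, "BLOSUM62"))
      stop("unknown substitution table name: ", substitution)
    substitution <- .default_subst()
  }
  substitution <- as.matrix(substitution)
  if (is.null(rownames(substitution)) ||
      !identical(rownames(substitution), colnames(substitution)))
    stop("substitution matrix needs identical row and column letters")
  if (!(gap_open >= gap_extend && gap_extend >= 0))
    stop("need gap_open >= gap_extend >= 0")
  structure(list(substitution = substitution, gap_open = gap_open,
                 gap_extend = gap_extend), class = "align_params")
}

#' Read a substitution matrix in NCBI layout
#'
#' Plain-text matrix as distributed by NCBI: `#` comment lines, a header row
#' of residue letters, then one labelled row per letter.
#'
#' @param path file path.
#' @return Numeric matrix with letter dimnames.
#' @export
read_substitution_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- strsplit(trimws(lines[-1]), "\\s+")
  m <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(length(header))))
  rownames(m) <- vapply(rows, `[[`, "", 1L)
  colnames(m) <- header
  m[header, header, drop = FALSE]
}

encode_residues <- function(codes, letters) {
  idx <- match(codes, letters)
  unknown <- match("X", letters)
  if (anyNA(idx)) {
    if (is.na(unknown))
      stop("residue code(s) absent from substitution table and no X column: ",
           paste(unique(codes[is.na(idx)]), collapse = " "))
    idx[is.na(idx)] <- unknown
  }
  idx - 1L
}

as_codes <- function(x) {
  if (inherits(x, "calpha_trace")) x$codes
  else if (is.character(x) && length(x) == 1L) strsplit(x, "")[[1]]
  else as.character(x)
}

#' Pair residues of two C-alpha traces by Smith-Waterman local alignment
#'
#' @param trace_a,trace_b `calpha_trace` objects (or plain 1-letter sequences
#'   given as single strings, for sequence-only use). Unknown residues score
#'   through the table's `X` column.
#' @param params an [align_params()].
#' @return An object of class `residue_pairing`: `pairs` (two-column matrix of
#'   1-based positions into trace A and trace B, strictly increasing in both),
#'   `score`, and `coverage` (paired fraction of the shorter trace).
#' @export
smith_waterman_pair <- function(trace_a, trace_b, params = align_params()) {
  ca <- as_codes(trace_a); cb <- as_codes(trace_b)
  if (length(ca) == 0L || length(cb) == 0L)
    stop("empty trace passed to smith_waterman_pair")
  letters <- rownames(params$substitution)
  res <- .sw_align(encode_residues(ca, letters), encode_residues(cb, letters),
                   params$substitution, params$gap_open, params$gap_extend)
  pairs <- cbind(index_a = res$index_a, index_b = res$index_b)
  stopifnot(!is.unsorted(pairs[, 1], strictly = TRUE),
            !is.unsorted(pairs[, 2], strictly = TRUE))
  structure(list(pairs = pairs, score = res$score,
                 coverage = nrow(pairs) / min(length(ca), length(cb))),
            class = "residue_pairing")
}

#' @export
print.residue_pairing <- function(x, ...) {
  cat(sprintf("<residue_pairing> %d pairs, score %.1f, coverage %.2f\n",
              nrow(x$pairs), x$score, x$coverage))
  invisible(x)
}

#' Locate sequence motifs with X wildcards
#'
#' Finds every (possibly overlapping) occurrence of a motif such as `PASDIP`
#' or `PRXSF` (X matches any residue) in a 1-letter sequence, left to right.
#'
#' @param sequence 1-letter sequence (single string) or a `calpha_trace`.
#' @param pattern motif text; `X` is a wildcard.
#' @param resno optional residue numbers (taken from the trace when one is
#'   given); hit positions are reported in this numbering.
#' @param name optional motif name recorded in the result.
#' @return data.frame with columns `motif`, `start` (residue number of the
#'   first motif position) and `match` (the matched subsequence); zero rows
#'   when the motif is absent.
#' @export
find_motif <- function(sequence, pattern, resno = NULL, name = pattern) {
  if (inherits(sequence, "calpha_trace")) {
    if (is.null(resno)) resno <- sequence$resno
    sequence <- trace_sequence(sequence)
  }
  if (!nzchar(pattern)) stop("empty motif pattern")
  if (is.null(resno)) resno <- seq_len(nchar(sequence))
  rx <- paste0("(?=", gsub("X", ".", toupper(pattern), fixed = TRUE), ")")
  hits <- gregexpr(rx, toupper(sequence), perl = TRUE)[[1]]
  if (hits[1] == -1L)
    return(data.frame(motif = character(0), start = integer(0),
                      match = character(0)))
  starts <- as.integer(hits)
  data.frame(
    motif = name, start = resno[starts],
    match = substring(sequence, starts, starts + nchar(pattern) - 1L))
}
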