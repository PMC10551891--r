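# Global (Needleman-Wunsch) alignment with affine gaps. The dynamic program
# is implemented in C++ (src/nw.cpp) so whole tables of domain pairs align
# in one call. Gap cost convention used throughout the package: a gap of
# length L costs gap_open + (L - 1) * gap_extend (the first gapped residue
# is charged the opening penalty only); end gaps are penalized.

check_aa <- function(seqs) {
  bad <- grepl(sprintf("[^%s]", VALID_AA), seqs)
  if (any(bad))
    stop("sequence contains characters outside the 20 standard amino acids + X: ",
         paste(unique(seqs[bad]), collapse = ", "), call. = FALSE)
}

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

resolve_submat <- function(matrix) {
  submat <- if (is.character(matrix)) {
    if (identical(matrix, "BLOSUM62")) blosum62()
    else {
      e <- new.env()
      utils::data(list = matrix, package = "Biostrings", envir = e)
      get(matrix, envir = e)
    }
  } else matrix
  if (is.null(rownames(submat)) ||
      !identical(rownames(submat), colnames(submat)))
    stop("substitution matrix must have matching row/column names",
         call. = FALSE)
  submat
}

#' Global pairwise alignment of protein sequences
#'
#' Optimal Needleman-Wunsch global alignment under affine gap penalties
#' (Gotoh three-state dynamic program, end gaps penalized). Defaults mirror
#' the EMBOSS needle/needleall conventions: BLOSUM62, gap open 10, gap
#' extend 0.5; a gap of length L costs `gap_open + (L - 1) * gap_extend`.
#' Identity is the number of identical columns divided by the alignment
#' length (gapped columns count in the denominator, the EMBOSS convention).
#' `X` is accepted as an unknown residue and scores via the matrix's X
#' column (a mismatch-level penalty); any other non-standard letter is an
#' error.
#'
#' Vectorized: `seq_a` and `seq_b` are aligned element-wise (recycling the
#' shorter of the two).
#'
#' @param seq_a,seq_b non-empty amino-acid strings (character vectors of
#'   equal length, or either of length 1).
#' @param matrix substitution matrix: name of a matrix shipped with
#'   Biostrings (default `"BLOSUM62"`) or a numeric matrix with residue
#'   dimnames.
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @return For scalar input, a list with `aligned_a`, `aligned_b` (gapped
#'   strings of equal length), `score` and `identity`; for vector input, a
#'   `data.frame` with those columns, one row per pair.
#' @examples
#' global_align("ACDEFG", "ACDFG")  # one gap column, identity 5/6
#' @export
global_align <- function(seq_a, seq_b, matrix = "BLOSUM62", gap_open = 10,
                         gap_extend = 0.5) {
  scalar <- length(seq_a) == 1L && length(seq_b) == 1L
  res <- global_align_many(seq_a, seq_b, matrix, gap_open, gap_extend)
  if (scalar)
    list(aligned_a = res$aligned_a, aligned_b = res$aligned_b,
         score = res$score, identity = res$identity)
  else res
}

# Element-wise batch alignment; returns a data.frame.
global_align_many <- function(seq_a, seq_b, matrix = "BLOSUM62",
                              gap_open = 10, gap_extend = 0.5) {
  stopifnot(all(nzchar(seq_a)), all(nzchar(seq_b)),
            gap_open >= 0, gap_extend >= 0)
  check_aa(c(seq_a, seq_b))
  n <- max(length(seq_a), length(seq_b))
  seq_a <- rep_len(seq_a, n); seq_b <- rep_len(seq_b, n)
  submat <- resolve_submat(matrix)
  res <- .nw_align_batch(seq_a, seq_b, submat,
                         paste(rownames(submat), collapse = ""),
                         gap_open, gap_extend)
  data.frame(aligned_a = res$aligned_a, aligned_b = res$aligned_b,
             score = res$score, identity = res$identity,
             stringsAsFactors = FALSE)
}
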