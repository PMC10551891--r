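#' In-silico complete trypsin digestion
#'
#' Cleaves a protein sequence C-terminal to every lysine (K) or arginine (R)
#' that is not followed by proline (the Keil rule), with zero missed
#' cleavages. The peptides concatenate back to the input sequence.
#'
#' @param sequence single amino-acid string.
#' @return Character vector of peptides in N-to-C order.
#' @examples
#' tryptic_peptides("MKR")     # "MK"  "R"
#' tryptic_peptides("AAKPAA")  # "AAKPAA" (no cleavage before P)
#' @export
tryptic_peptides <- function(sequence) {
  stopifnot_character_seq(sequence)
  if (length(sequence) != 1L || !nzchar(sequence))
    stop("sequence must be a single non-empty string", call. = FALSE)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  cut <- which(chars == "K" | chars == "R")
  cut <- cut[cut < n]
  cut <- cut[chars[cut + 1L] != "P"]
  substring(sequence, c(1L, cut + 1L), c(cut, n))
}

#' Count and total length of theoretically observable tryptic peptides
#'
#' A tryptic peptide is "theoretically observable" when its length falls in
#' the detectability window of the instrument. The count is the denominator
#' of intensity-based absolute quantification (iBAQ); the summed length is
#' the corrected-length denominator of peptide-centric quantification.
#'
#' @param sequence single amino-acid string.
#' @param min_len,max_len observable window in residues (defaults 6 and 30,
#'   the usual iBAQ convention).
#' @return List with `observable_count` and `observable_length`.
#' @examples
#' observable_stats("MKR")             # 0 peptides in 6..30
#' observable_stats("MKR", 1, 30)      # 2 peptides, 3 residues
#' @export
observable_stats <- function(sequence, min_len = 6L, max_len = 30L) {
  stopifnot(min_len >= 1L, min_len <= max_len)
  lens <- nchar(tryptic_peptides(sequence))
  ok <- lens >= min_len & lens <= max_len
  list(observable_count = sum(ok), observable_length = sum(lens[ok]))
}
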