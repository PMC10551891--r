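#' Read a proteome from a FASTA file
#'
#' Each FASTA entry becomes one protein record. The header token before the
#' first whitespace is taken as the internal identifier; identifiers are
#' expected in the STRING-style `"taxid.locus"` namespace, and the numeric
#' prefix (if present) is parsed into the `taxid` column. Sequences are
#' uppercased.
#'
#' @param path path to a FASTA file.
#' @return A `data.frame` with columns `internal_id`, `sequence`, `taxid`
#'   (class `"proteome"`).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">9606.P1 desc", "MKR"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) stop("no records in ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(seqs))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L)
    stop("duplicate ids in ", path, ": ", paste(dup, collapse = ", "),
         call. = FALSE)
  as_proteome(data.frame(
    internal_id = ids,
    sequence = toupper(as.character(seqs)),
    stringsAsFactors = FALSE
  ))
}

as_proteome <- function(df) {
  stopifnot(all(c("internal_id", "sequence") %in% names(df)))
  if (any(!nzchar(df$sequence))) stop("empty sequence in proteome", call. = FALSE)
  df$taxid <- parse_taxid(df$internal_id)
  rownames(df) <- NULL
  class(df) <- c("proteome", "data.frame")
  df
}

parse_taxid <- function(ids) {
  pre <- sub("\\..*$", "", ids)
  out <- suppressWarnings(as.integer(pre))
  out[grepl("\\D", pre)] <- NA_integer_
  out
}

#' Write a proteome to a FASTA file
#'
#' Inverse of [read_fasta()]: identifiers become headers, sequences are
#' written unwrapped so the round trip is byte-preserving on ids and
#' sequences.
#'
#' @param proteome a proteome `data.frame` (`internal_id`, `sequence`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteome, path) {
  x <- Biostrings::AAStringSet(setNames(proteome$sequence, proteome$internal_id))
  Biostrings::writeXStringSet(x, path, width = 20000L)
  invisible(path)
}

#' Read an identifier alias table
#'
#' Tab-separated with columns `internal_id`, `alias`, `source` (the
#' namespace the alias comes from). An (alias, source) pair must map to at
#' most one internal id.
#'
#' @param path path to the TSV file.
#' @return A `data.frame` with columns `internal_id`, `alias`, `source`.
#' @export
read_alias_table <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                   stringsAsFactors = FALSE)
  need <- c("internal_id", "alias", "source")
  if (!all(need %in% names(df)))
    stop("alias table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  key <- paste(df$alias, df$source, sep = "\r")
  clash <- tapply(df$internal_id, key, function(v) length(unique(v)) > 1L)
  if (any(clash))
    stop("alias table maps one (alias, source) pair to several internal ids",
         call. = FALSE)
  df[, need]
}

#' Map external identifiers onto the internal namespace
#'
#' Lookup is exact-string and case-sensitive, tried across all namespaces in
#' the alias table. An id whose aliases point to more than one internal id
#' across namespaces is ambiguous and reported as unmapped. Every input id
#' lands in exactly one of `mapped` / `unmapped`.
#'
#' @param ids character vector of external identifiers.
#' @param aliases alias table as returned by [read_alias_table()].
#' @return A list with `mapped` (named character vector, external id ->
#'   internal id) and `unmapped` (character vector).
#' @examples
#' al <- data.frame(internal_id = "9606.P1", alias = "Q1", source = "uniprot")
#' map_identifiers(c("Q1", "ZZZ"), al)
#' @export
map_identifiers <- function(ids, aliases) {
  stopifnot_character_seq(ids, "ids")
  hits <- lapply(ids, function(id)
    unique(aliases$internal_id[aliases$alias == id]))
  ok <- vapply(hits, function(h) length(h) == 1L, logical(1))
  mapped <- setNames(vapply(hits[ok], identity, character(1)), ids[ok])
  list(mapped = mapped, unmapped = ids[!ok])
}

#' Map proteins between two proteomes by reciprocal best hit
#'
#' Every protein of `set_a` is globally aligned against every protein of
#' `set_b` (see [global_align()]). A pair (a, b) is reported when b is a's
#' unique best-scoring hit, a is b's unique best-scoring hit, and the
#' alignment identity is at least `min_identity`. Ties for best hit exclude
#' the protein (no one-to-one claim is made). The resulting mapping is
#' one-to-one and symmetric under swapping the two sets.
#'
#' @param set_a,set_b proteome `data.frame`s ([read_fasta()]).
#' @param min_identity minimum alignment identity required in the pair,
#'   as a fraction in (0, 1]. Default 0.9.
#' @param ... alignment parameters passed to [global_align()].
#' @return Named character vector: `internal_id` in `set_a` -> `internal_id`
#'   in `set_b`.
#' @export
reciprocal_best_hit <- function(set_a, set_b, min_identity = 0.9, ...) {
  stopifnot(min_identity > 0, min_identity <= 1)
  na <- nrow(set_a); nb <- nrow(set_b)
  if (na == 0L || nb == 0L) return(setNames(character(0), character(0)))
  al <- global_align_many(rep(set_a$sequence, times = nb),
                          rep(set_b$sequence, each = na), ...)
  score <- matrix(al$score, na, nb)
  ident <- matrix(al$identity, na, nb)
  best_b <- unique_argmax_rows(score)
  best_a <- unique_argmax_rows(t(score))
  keep <- which(!is.na(best_b))
  keep <- keep[!is.na(best_a[best_b[keep]]) & best_a[best_b[keep]] == keep]
  keep <- keep[ident[cbind(keep, best_b[keep])] >= min_identity]
  setNames(set_b$internal_id[best_b[keep]], set_a$internal_id[keep])
}

# Row-wise argmax, NA where the maximum is tied.
unique_argmax_rows <- function(m) {
  apply(m, 1L, function(r) {
    top <- which(r == max(r))
    if (length(top) == 1L) top else NA_integer_
  })
}
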