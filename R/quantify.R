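#' Read a MaxQuant-style protein-group table
#'
#' Understands the `proteinGroups.txt` dialect: tab-separated with a
#' `Majority protein IDs` column (semicolon-separated member ids) and an
#' `Intensity` column; all other columns are ignored.
#'
#' @param path path to the TSV file.
#' @return A `data.frame` with columns `group_id` (the first member id),
#'   `members` (semicolon-separated ids) and `intensity`.
#' @export
read_protein_groups <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                   check.names = FALSE, stringsAsFactors = FALSE)
  idcol <- intersect(c("Majority protein IDs", "majority_protein_ids"), names(df))
  qcol <- intersect(c("Intensity", "intensity"), names(df))
  if (length(idcol) == 0L || length(qcol) == 0L)
    stop("expected columns 'Majority protein IDs' and 'Intensity'",
         call. = FALSE)
  members <- df[[idcol[1]]]
  out <- data.frame(
    group_id = vapply(strsplit(members, ";", fixed = TRUE), `[`, character(1), 1L),
    members = members,
    intensity = as.numeric(df[[qcol[1]]]),
    stringsAsFactors = FALSE
  )
  if (any(is.na(out$intensity) | out$intensity < 0))
    stop("intensities must be non-negative numbers", call. = FALSE)
  out
}

#' Drop contaminant and reversed-decoy protein groups
#'
#' Removes every row whose group id, or any of whose member ids, starts with
#' `CON_` (contaminant) or `REV_` (reversed decoy sequence). Row order is
#' preserved; the filter is idempotent.
#'
#' @param groups protein-group table ([read_protein_groups()]).
#' @return The filtered table.
#' @export
filter_protein_groups <- function(groups) {
  bad <- vapply(strsplit(groups$members, ";", fixed = TRUE), function(m)
    any(grepl("^(CON_|REV_)", m)), logical(1))
  bad <- bad | grepl("^(CON_|REV_)", groups$group_id)
  if (any(bad)) msg("filter_protein_groups: dropped %d of %d rows (CON_/REV_)",
                    sum(bad), length(bad))
  groups[!bad, , drop = FALSE]
}

#' Read a peptide-level quantification table
#'
#' Tab-separated with columns `protein_id`, `peptide`, `quantity` (peak
#' intensity or spectral count) and optionally `fdr_score`.
#'
#' @param path path to the TSV file.
#' @return A `data.frame` of peptide measurements; `fdr_score` is `NA` when
#'   the column is absent.
#' @export
read_peptide_table <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                   stringsAsFactors = FALSE)
  need <- c("protein_id", "peptide", "quantity")
  if (!all(need %in% names(df)))
    stop("peptide table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (is.null(df$fdr_score)) df$fdr_score <- NA_real_
  if (any(df$quantity < 0)) stop("quantities must be non-negative", call. = FALSE)
  df[, c(need, "fdr_score")]
}

#' Filter peptides by false discovery rate
#'
#' Keeps peptides whose FDR score is at most `threshold` (default 0.01).
#' Peptides without a score are kept: they are assumed to come from sources
#' that were already FDR-filtered upstream.
#'
#' @param peps peptide table ([read_peptide_table()]).
#' @param threshold FDR threshold in (0, 1].
#' @return The filtered table.
#' @export
filter_peptides_fdr <- function(peps, threshold = 0.01) {
  stopifnot(threshold > 0, threshold <= 1)
  keep <- is.na(peps$fdr_score) | peps$fdr_score <= threshold
  if (any(!keep)) msg("filter_peptides_fdr: dropped %d of %d peptides (FDR > %g)",
                      sum(!keep), length(keep), threshold)
  peps[keep, , drop = FALSE]
}

#' Protein-centric (iBAQ-style) raw abundance
#'
#' For each protein group, the summed precursor intensity is divided by the
#' number of theoretically observable tryptic peptides of the protein the
#' group resolves to. Groups are resolved to their first member id found in
#' the proteome (the MaxQuant "majority leader" convention); groups that
#' resolve to no proteome protein, and proteins with zero observable
#' peptides, are dropped with a message. Several groups resolving to the
#' same protein have their intensities summed.
#'
#' @param groups filtered protein-group table.
#' @param proteome proteome `data.frame` ([read_fasta()]).
#' @param min_len,max_len observable peptide window ([observable_stats()]).
#' @return Named numeric vector of raw (unnormalized) abundances.
#' @export
protein_centric_abundance <- function(groups, proteome, min_len = 6L,
                                      max_len = 30L) {
  ids <- vapply(strsplit(groups$members, ";", fixed = TRUE), function(m) {
    hit <- m[m %in% proteome$internal_id]
    if (length(hit) == 0L) NA_character_ else hit[1L]
  }, character(1))
  if (anyNA(ids))
    msg("protein_centric_abundance: %d group(s) matched no proteome protein",
        sum(is.na(ids)))
  ok <- !is.na(ids)
  raw <- tapply(groups$intensity[ok], ids[ok], sum)
  seqs <- proteome$sequence[match(names(raw), proteome$internal_id)]
  counts <- vapply(seqs, function(s)
    observable_stats(s, min_len, max_len)$observable_count, numeric(1),
    USE.NAMES = FALSE)
  if (any(counts == 0L))
    msg("protein_centric_abundance: dropped %d protein(s) with no observable peptides",
        sum(counts == 0L))
  out <- as.numeric(raw[counts > 0]) / counts[counts > 0]
  setNames(out, names(raw)[counts > 0])
}

#' Peptide-centric raw abundance (length-normalized)
#'
#' For each protein, the sum over its peptides of quantity times peptide
#' length is divided by the total corrected length of its theoretically
#' observable tryptic peptides. Quantities may be peak intensities or
#' spectral counts. Peptides referencing proteins absent from the proteome,
#' and proteins whose observable length is zero, are dropped with a message.
#'
#' @param peps FDR-filtered peptide table.
#' @param proteome proteome `data.frame`.
#' @param min_len,max_len observable peptide window.
#' @return Named numeric vector of raw (unnormalized) abundances.
#' @export
peptide_centric_abundance <- function(peps, proteome, min_len = 6L,
                                      max_len = 30L) {
  known <- peps$protein_id %in% proteome$internal_id
  if (any(!known))
    msg("peptide_centric_abundance: dropped %d peptide(s) with unknown protein",
        sum(!known))
  peps <- peps[known, , drop = FALSE]
  num <- tapply(peps$quantity * nchar(peps$peptide), peps$protein_id, sum)
  seqs <- proteome$sequence[match(names(num), proteome$internal_id)]
  den <- vapply(seqs, function(s)
    observable_stats(s, min_len, max_len)$observable_length, numeric(1),
    USE.NAMES = FALSE)
  if (any(den == 0L))
    msg("peptide_centric_abundance: dropped %d protein(s) with zero observable length",
        sum(den == 0L))
  setNames(as.numeric(num[den > 0]) / den[den > 0], names(num)[den > 0])
}

#' Construct an abundance dataset
#'
#' An abundance dataset maps internal protein ids to abundances in parts per
#' million (ppm): each protein's share of all quantified protein molecules,
#' scaled so the dataset sums to 1e6.
#'
#' @param ppm named non-negative numeric vector summing to 1e6 (within 1e-6
#'   relative).
#' @param organism NCBI taxid (integer) or `NA`.
#' @param tissue tissue/ontology label, default `"WHOLE_ORGANISM"`.
#' @param method free-text quantification method.
#' @param score interaction z-score, or `NA` if not yet scored.
#' @param coverage fraction of the proteome quantified, or `NA`.
#' @return An object of class `"abundance_dataset"`.
#' @export
abundance_dataset <- function(ppm, organism = NA_integer_,
                              tissue = "WHOLE_ORGANISM", method = "",
                              score = NA_real_, coverage = NA_real_) {
  if (is.null(names(ppm)) || anyNA(names(ppm)))
    stop("ppm vector must be named by internal id", call. = FALSE)
  if (any(ppm < 0)) stop("ppm values must be non-negative", call. = FALSE)
  tot <- sum(ppm)
  if (abs(tot - 1e6) > 1e-6 * 1e6)
    stop("ppm must sum to 1e6 (got ", format(tot), ")", call. = FALSE)
  if (!is.na(coverage) && (coverage < 0 || coverage > 1))
    stop("coverage must be in [0, 1]", call. = FALSE)
  structure(list(ppm = ppm, organism = organism, tissue = tissue,
                 method = method, score = score, coverage = coverage),
            class = "abundance_dataset")
}

#' @export
print.abundance_dataset <- function(x, ...) {
  cat(sprintf("abundance_dataset: %d proteins, organism %s, tissue %s\n",
              length(x$ppm), x$organism, x$tissue))
  cat(sprintf("  method: %s | score: %s | coverage: %s\n", x$method,
              format(x$score), format(x$coverage)))
  invisible(x)
}

#' Normalize raw abundances to parts per million
#'
#' `ppm[id] = 1e6 * raw[id] / sum(raw)`. Zero raw values are kept as 0 ppm
#' (quantified as absent, which is distinct from not measured).
#'
#' @param raw named non-negative numeric vector with at least one positive
#'   value.
#' @param ... metadata passed to [abundance_dataset()].
#' @return An `abundance_dataset`.
#' @examples
#' to_ppm(c(A = 1, B = 3))$ppm  # 250000, 750000
#' @export
to_ppm <- function(raw, ...) {
  if (length(raw) == 0L || all(raw == 0))
    stop("no quantified proteins (all raw abundances zero)", call. = FALSE)
  if (any(raw < 0)) stop("raw abundances must be non-negative", call. = FALSE)
  abundance_dataset(1e6 * raw / sum(raw), ...)
}

#' Proteome coverage of a dataset
#'
#' Fraction of the proteome's proteins present in the dataset.
#'
#' @param ds an `abundance_dataset`.
#' @param proteome proteome `data.frame`.
#' @return Fraction in \[0, 1\].
#' @export
proteome_coverage <- function(ds, proteome) {
  if (nrow(proteome) == 0L) stop("empty proteome", call. = FALSE)
  length(intersect(names(ds$ppm), proteome$internal_id)) / nrow(proteome)
}

#' Write / read an abundance dataset
#'
#' The on-disk form is a two-column TSV `internal_id<TAB>ppm` plus a JSON
#' metadata sidecar `<path>.meta.json` carrying organism, tissue, method,
#' score and coverage.
#'
#' @param ds an `abundance_dataset`.
#' @param path TSV path.
#' @return `write_abundance` returns `path` invisibly; `read_abundance`
#'   returns the `abundance_dataset`.
#' @export
write_abundance <- function(ds, path) {
  write.table(data.frame(internal_id = names(ds$ppm), ppm = ds$ppm),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- ds[c("organism", "tissue", "method", "score", "coverage")]
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_abundance
#' @param path TSV path previously written by [write_abundance()].
#' @export
read_abundance <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  ppm <- setNames(df$ppm, df$internal_id)
  metapath <- paste0(path, ".meta.json")
  meta <- if (file.exists(metapath)) jsonlite::read_json(metapath) else list()
  abundance_dataset(
    ppm,
    organism = as.integer(meta$organism %||% NA_integer_),
    tissue = meta$tissue %||% "WHOLE_ORGANISM",
    method = meta$method %||% "",
    score = as.numeric(meta$score %||% NA_real_),
    coverage = as.numeric(meta$coverage %||% NA_real_)
  )
}
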