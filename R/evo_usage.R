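#' Read domain-annotation and ortholog-pair tables
#'
#' Domain annotations are TSV with columns `protein_id`, `domain`, `start`,
#' `end` (1-based inclusive residue coordinates). Ortholog pairs are TSV
#' with columns `id_a`, `id_b`, `one_to_one` (logical or 0/1); pairs flagged
#' as not one-to-one (complex orthology, i.e. paralogs on either side) are
#' excluded from all downstream analyses.
#'
#' @param path path to the TSV file.
#' @return A `data.frame`.
#' @export
read_domain_table <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("protein_id", "domain", "start", "end")
  if (!all(need %in% names(df)))
    stop("domain table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(df$start < 1L | df$end < df$start))
    stop("domain coordinates must satisfy 1 <= start <= end", call. = FALSE)
  df[, need]
}

#' @rdname read_domain_table
#' @export
read_ortholog_table <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("id_a", "id_b", "one_to_one")
  if (!all(need %in% names(df)))
    stop("ortholog table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df$one_to_one <- as.logical(df$one_to_one)
  df[, need]
}

domain_subseq <- function(proteome, protein_id, start, end) {
  seq <- proteome$sequence[match(protein_id, proteome$internal_id)]
  if (anyNA(seq)) stop("domain refers to protein absent from proteome",
                       call. = FALSE)
  if (any(end > nchar(seq)))
    stop("domain end exceeds protein length", call. = FALSE)
  substring(seq, start, end)
}

#' Align the shared domains of one ortholog pair
#'
#' For each domain type annotated on both proteins, every cross-product of
#' same-named domain instances is globally aligned ([global_align()]) and
#' only the highest-scoring instance pair is kept (ties: first by annotation
#' order); pairs below `min_identity` are dropped. Domains are extracted as
#' subsequences before alignment.
#'
#' @param id_a,id_b internal ids of a one-to-one ortholog pair (a = query
#'   species, b = reference species).
#' @param doms_a,doms_b domain tables ([read_domain_table()]).
#' @param proteome_a,proteome_b proteome `data.frame`s.
#' @param min_identity identity filter, default 0.40.
#' @param ... alignment parameters for [global_align()].
#' @return A `data.frame` with one row per retained domain pair: `id_a`,
#'   `id_b`, `domain`, `aligned_a`, `aligned_b`, `score`, `identity`.
#'   Zero rows when nothing matches.
#' @export
match_domains <- function(id_a, id_b, doms_a, doms_b, proteome_a, proteome_b,
                          min_identity = 0.40, ...) {
  da <- doms_a[doms_a$protein_id == id_a, , drop = FALSE]
  db <- doms_b[doms_b$protein_id == id_b, , drop = FALSE]
  shared <- intersect(da$domain, db$domain)
  out <- lapply(shared, function(dn) {
    ia <- which(da$domain == dn); ib <- which(db$domain == dn)
    cand <- expand.grid(i = ia, j = ib)
    alns <- lapply(seq_len(nrow(cand)), function(k) {
      sa <- domain_subseq(proteome_a, id_a, da$start[cand$i[k]], da$end[cand$i[k]])
      sb <- domain_subseq(proteome_b, id_b, db$start[cand$j[k]], db$end[cand$j[k]])
      global_align(sa, sb, ...)
    })
    best <- alns[[which.max(vapply(alns, `[[`, numeric(1), "score"))]]
    if (best$identity < min_identity) return(NULL)
    data.frame(id_a = id_a, id_b = id_b, domain = dn,
               aligned_a = best$aligned_a, aligned_b = best$aligned_b,
               score = best$score, identity = best$identity,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(id_a = character(0), id_b = character(0),
                      domain = character(0), aligned_a = character(0),
                      aligned_b = character(0), score = numeric(0),
                      identity = numeric(0), stringsAsFactors = FALSE)
  out
}

count_residues <- function(aligned, aa_set) {
  chars <- strsplit(gsub("-", "", aligned, fixed = TRUE), "", fixed = TRUE)
  vapply(chars, function(cs) sum(cs %in% aa_set), numeric(1))
}

#' Amino-acid usage ratios in aligned ortholog domains
#'
#' Counts the residues of `aa_set` (e.g. `c("C", "M")` for the
#' sulfur-containing amino acids) in the ungapped residues of each aligned
#' domain string and forms the ratio query/reference (`count_a / count_b`).
#' Pairs where either side has zero residues of interest are excluded: a
#' ratio is only meaningful when both proteins register the amino acid.
#' The reference protein's abundance is attached from `abundance`.
#'
#' @param aligned_pairs `data.frame` of aligned domain pairs
#'   ([match_domains()], possibly concatenated over many ortholog pairs).
#' @param aa_set character vector of residues of interest.
#' @param abundance an `abundance_dataset` for the reference species (its
#'   ids matched against `id_b`), or `NULL` to skip the join.
#' @param aggregate if `TRUE`, several qualifying domain pairs of one
#'   ortholog pair are aggregated to a single row by the mean of their
#'   ratios (counts are summed for reporting); default `FALSE`, one row per
#'   domain pair.
#' @return A `data.frame` with columns `id_a`, `id_b`, `domain`, `count_a`,
#'   `count_b`, `ratio`, `abundance_ppm` (NA when `abundance` is `NULL` or
#'   the protein is absent from it).
#' @export
usage_ratios <- function(aligned_pairs, aa_set = c("C", "M"),
                         abundance = NULL, aggregate = FALSE) {
  ca <- count_residues(aligned_pairs$aligned_a, aa_set)
  cb <- count_residues(aligned_pairs$aligned_b, aa_set)
  keep <- ca >= 1 & cb >= 1
  out <- data.frame(id_a = aligned_pairs$id_a[keep],
                    id_b = aligned_pairs$id_b[keep],
                    domain = aligned_pairs$domain[keep],
                    count_a = ca[keep], count_b = cb[keep],
                    ratio = ca[keep] / cb[keep],
                    stringsAsFactors = FALSE)
  if (aggregate && nrow(out) > 0L) {
    key <- paste(out$id_a, out$id_b, sep = "\r")
    out <- do.call(rbind, lapply(split(out, key), function(g) data.frame(
      id_a = g$id_a[1L], id_b = g$id_b[1L], domain = NA_character_,
      count_a = sum(g$count_a), count_b = sum(g$count_b),
      ratio = mean(g$ratio), stringsAsFactors = FALSE)))
    rownames(out) <- NULL
  }
  out$abundance_ppm <- if (is.null(abundance)) NA_real_
    else unname(abundance$ppm[match(out$id_b, names(abundance$ppm))])
  out
}

#' Spearman correlation between usage ratios and protein abundance
#'
#' Rank correlation (average ranks for ties) between the amino-acid usage
#' ratio and the reference protein abundance; the two-sided p-value uses the
#' t approximation. A negative rho with small p indicates depletion of the
#' residues of interest in abundant proteins of the query species.
#'
#' @param table `data.frame` from [usage_ratios()] with non-missing
#'   `abundance_ppm` (rows with missing abundance are dropped).
#' @return List with `rho`, `p_value`, `n`.
#' @export
abundance_usage_correlation <- function(table) {
  ok <- !is.na(table$abundance_ppm)
  x <- table$ratio[ok]; y <- table$abundance_ppm[ok]
  if (length(x) < 3L) stop("need at least three rows", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("degenerate ranks: ratios or abundances are constant", call. = FALSE)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Bin usage ratios by abundance for violin-style plots
#'
#' Rows are sorted by abundance and split into `n_bins` contiguous groups of
#' (near-)equal size (sizes differ by at most one). Each bin is summarized
#' by the median and 25th/75th percentiles of the ratio.
#'
#' @param table `data.frame` from [usage_ratios()].
#' @param n_bins number of bins (default 6).
#' @return A `data.frame` with one row per bin: `bin`, `n`,
#'   `abundance_median`, `ratio_median`, `ratio_p25`, `ratio_p75`.
#' @export
bin_for_plot <- function(table, n_bins = 6L) {
  table <- table[!is.na(table$abundance_ppm), , drop = FALSE]
  n <- nrow(table)
  stopifnot(n >= n_bins)
  ord <- order(table$abundance_ppm)
  sizes <- diff(floor(seq(0, n, length.out = n_bins + 1L)))
  bin <- rep(seq_len(n_bins), sizes)
  r <- table$ratio[ord]; ab <- table$abundance_ppm[ord]
  data.frame(
    bin = seq_len(n_bins),
    n = as.integer(sizes),
    abundance_median = as.numeric(tapply(ab, bin, median)),
    ratio_median = as.numeric(tapply(r, bin, median)),
    ratio_p25 = as.numeric(tapply(r, bin, quantile, probs = 0.25)),
    ratio_p75 = as.numeric(tapply(r, bin, quantile, probs = 0.75))
  )
}

#' Significance stars for correlation p-values
#'
#' `"***"` for p < 1e-5, `"**"` for p < 1e-3, `"*"` for p < 0.01, otherwise
#' the empty string.
#'
#' @param p numeric vector of p-values.
#' @return Character vector of star labels.
#' @export
significance_stars <- function(p) {
  ifelse(p < 1e-5, "***", ifelse(p < 1e-3, "**", ifelse(p < 0.01, "*", "")))
}

#' Assemble the species-by-species correlation heatmap table
#'
#' Collects per-(query, reference) Spearman results into matrices ready for
#' heatmap plotting, with significance stars assigned by
#' [significance_stars()].
#'
#' @param results `data.frame` with columns `query`, `reference`, `rho`,
#'   `p_value` (one row per species comparison).
#' @return List of three matrices (`rho`, `p_value`, `stars`), rows = query
#'   species, columns = reference species.
#' @export
species_heatmap_table <- function(results) {
  qs <- sort(unique(results$query)); rs <- sort(unique(results$reference))
  shape <- function(v, default) {
    m <- matrix(default, length(qs), length(rs), dimnames = list(qs, rs))
    m[cbind(match(results$query, qs), match(results$reference, rs))] <- v
    m
  }
  list(rho = shape(results$rho, NA_real_),
       p_value = shape(results$p_value, NA_real_),
       stars = shape(significance_stars(results$p_value), ""))
}

#' Full ortholog-domain usage pipeline for one species pair
#'
#' Runs [match_domains()] over all one-to-one ortholog pairs, computes
#' [usage_ratios()] against the reference-species abundances, and returns
#' the ratio table together with the abundance-usage Spearman correlation
#' and the binned plot summary.
#'
#' @param pairs ortholog table ([read_ortholog_table()]); rows with
#'   `one_to_one == FALSE` are skipped.
#' @param doms_a,doms_b domain tables.
#' @param proteome_a,proteome_b proteomes.
#' @param abundance reference-species `abundance_dataset`.
#' @param aa_set residues of interest (default sulfur: C and M).
#' @param min_identity alignment identity filter (default 0.40).
#' @param n_bins bins for the plot summary (default 6).
#' @param aggregate see [usage_ratios()].
#' @param ... alignment parameters.
#' @return List with `table` (the usage-ratio table), `correlation`
#'   (`rho`, `p_value`, `n`) and `bins`.
#' @export
domain_usage_analysis <- function(pairs, doms_a, doms_b, proteome_a,
                                  proteome_b, abundance,
                                  aa_set = c("C", "M"), min_identity = 0.40,
                                  n_bins = 6L, aggregate = FALSE, ...) {
  pairs <- pairs[pairs$one_to_one, , drop = FALSE]
  aligned <- lapply(seq_len(nrow(pairs)), function(i)
    match_domains(pairs$id_a[i], pairs$id_b[i], doms_a, doms_b,
                  proteome_a, proteome_b, min_identity, ...))
  aligned <- do.call(rbind, aligned)
  tab <- usage_ratios(aligned, aa_set, abundance, aggregate)
  list(table = tab,
       correlation = abundance_usage_correlation(tab),
       bins = bin_for_plot(tab, n_bins))
}
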