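#' Configuration for the synthetic-data generators
#'
#' Bundles the knobs of all `make_*()` generators. Every generator is a pure
#' function of its config (plus explicit extra arguments): the same config
#' always produces the same data. Each generator draws from its own RNG
#' stream derived from `seed`, so e.g. regenerating the network does not
#' shift the proteome.
#'
#' @param n_proteins number of proteins.
#' @param taxid synthetic organism taxid (ids are `"taxid.P0001"`, ...).
#' @param length_mean,length_sd protein length distribution (normal,
#'   truncated at 30 residues).
#' @param aa_frequencies named 20-vector of amino-acid frequencies summing
#'   to 1 (default uniform 0.05: the simplest null for composition tests).
#' @param abundance_mu,abundance_sigma mean and sd of log10 ppm before
#'   renormalization. The default sigma 1.3 spans roughly five orders of
#'   magnitude across a proteome, as real abundance distributions do.
#' @param network_density fraction of all protein pairs that become edges.
#' @param edge_consistency non-negative; edges are sampled with weight
#'   `exp(-edge_consistency * |log10 ratio|)`, so 0 gives uniform random
#'   edges (null) and larger values make interacting partners more similar
#'   in abundance.
#' @param depletion_beta planted sulfur-avoidance strength in the ortholog
#'   generator: the query-side retention of sulfur residues decays as
#'   `exp(-beta * rank(abundance)/n)`.
#' @param seed integer master seed.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_proteins = 200L, taxid = 9000L, length_mean = 300,
                       length_sd = 80,
                       aa_frequencies = setNames(rep(0.05, 20), AA20),
                       abundance_mu = 1.5, abundance_sigma = 1.3,
                       network_density = 0.01, edge_consistency = 0,
                       depletion_beta = 0, seed = 1L) {
  stopifnot(n_proteins >= 0, length(aa_frequencies) == 20L,
            abs(sum(aa_frequencies) - 1) < 1e-9,
            network_density >= 0, network_density <= 1,
            edge_consistency >= 0)
  if (is.null(names(aa_frequencies))) names(aa_frequencies) <- AA20
  structure(list(n_proteins = as.integer(n_proteins), taxid = as.integer(taxid),
                 length_mean = length_mean, length_sd = length_sd,
                 aa_frequencies = aa_frequencies, abundance_mu = abundance_mu,
                 abundance_sigma = abundance_sigma,
                 network_density = network_density,
                 edge_consistency = edge_consistency,
                 depletion_beta = depletion_beta, seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a random proteome
#'
#' Sequences are drawn i.i.d. from `cfg$aa_frequencies` with lengths from a
#' truncated normal (minimum 30 residues).
#'
#' @param cfg a [sim_config()].
#' @return A proteome `data.frame` as from [read_fasta()].
#' @export
make_proteome <- function(cfg) {
  if (cfg$n_proteins == 0L)
    return(as_proteome(data.frame(internal_id = character(0),
                                  sequence = character(0),
                                  stringsAsFactors = FALSE)))
  with_seed(child_seed(cfg$seed, 1L), {
    lens <- pmax(30L, as.integer(round(rnorm(cfg$n_proteins, cfg$length_mean,
                                             cfg$length_sd))))
    seqs <- vapply(lens, function(L)
      paste(sample(AA20, L, replace = TRUE, prob = cfg$aa_frequencies),
            collapse = ""), character(1))
    as_proteome(data.frame(
      internal_id = sprintf("%d.P%04d", cfg$taxid, seq_len(cfg$n_proteins)),
      sequence = seqs, stringsAsFactors = FALSE))
  })
}

#' Generate a synthetic abundance dataset
#'
#' log10 ppm values are drawn from a normal with the config's mu/sigma and
#' renormalized to 1e6.
#'
#' @param cfg a [sim_config()].
#' @param proteome proteome to quantify ([make_proteome()]).
#' @return An `abundance_dataset`.
#' @export
make_abundances <- function(cfg, proteome) {
  with_seed(child_seed(cfg$seed, 2L), {
    raw <- 10^rnorm(nrow(proteome), cfg$abundance_mu, cfg$abundance_sigma)
    names(raw) <- proteome$internal_id
    ds <- to_ppm(raw, organism = cfg$taxid, method = "synthetic")
    ds$coverage <- 1
    ds
  })
}

#' Generate a synthetic interaction network
#'
#' Edges are sampled without replacement from all unordered pairs of
#' quantified proteins, with weight `exp(-edge_consistency * |log10 ratio|)`.
#' With `edge_consistency = 0` edges are uniform random (a null network);
#' large values preferentially connect proteins of similar abundance, which
#' is the signal the interaction z-score detects.
#'
#' @param cfg a [sim_config()].
#' @param ds `abundance_dataset` whose proteins the edges connect.
#' @return An `interaction_network` with
#'   `round(network_density * n*(n-1)/2)` edges.
#' @export
make_network <- function(cfg, ds) {
  ids <- names(ds$ppm)[ds$ppm > 0]
  n <- length(ids)
  stopifnot(n >= 2L)
  n_pairs <- n * (n - 1) / 2
  n_edges <- max(1L, round(cfg$network_density * n_pairs))
  ii <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  jj <- sequence((n - 1L):1L) + ii
  lg <- log10(ds$ppm[ids])
  w <- exp(-cfg$edge_consistency * abs(lg[ii] - lg[jj]))
  pick <- with_seed(child_seed(cfg$seed, 3L),
                    sample.int(n_pairs, n_edges, prob = w))
  interaction_network(ids[ii[pick]], ids[jj[pick]])
}

#' Generate a synthetic peptide-level quantification table
#'
#' Emits each protein's theoretically observable tryptic peptides with
#' quantities proportional to the protein's ppm times multiplicative
#' lognormal noise (`10^N(0, noise_sd)` per peptide). With zero noise the
#' peptide-centric pipeline recovers the input ppm exactly. Optionally a
#' fraction of peptides is planted with an FDR score above 0.01 (the rest
#' get scores below it) to exercise the FDR filter; the number of planted
#' failures is recorded in the `"n_fdr_fail"` attribute.
#'
#' @param cfg a [sim_config()].
#' @param proteome the proteome.
#' @param ds the `abundance_dataset` the quantities derive from.
#' @param noise_sd sd of the per-peptide log10 multiplicative noise
#'   (default 0.2, a typical run-to-run spread).
#' @param min_len,max_len observable window.
#' @param with_fdr attach FDR scores (default `FALSE`: scores absent).
#' @param fdr_fail_rate fraction of peptides planted above the 0.01
#'   threshold when `with_fdr` is `TRUE`.
#' @return A peptide `data.frame` (see [read_peptide_table()]).
#' @export
make_peptide_table <- function(cfg, proteome, ds, noise_sd = 0.2,
                               min_len = 6L, max_len = 30L,
                               with_fdr = FALSE, fdr_fail_rate = 0.2) {
  peps <- lapply(seq_len(nrow(proteome)), function(i) {
    pp <- tryptic_peptides(proteome$sequence[i])
    pp <- pp[nchar(pp) >= min_len & nchar(pp) <= max_len]
    if (length(pp) == 0L) return(NULL)
    data.frame(protein_id = proteome$internal_id[i], peptide = pp,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, peps)
  if (is.null(out)) stop("no observable peptides in proteome", call. = FALSE)
  ppm <- ds$ppm[out$protein_id]
  with_seed(child_seed(cfg$seed, 4L), {
    out$quantity <- unname(ppm) * 10^rnorm(nrow(out), 0, noise_sd)
    if (with_fdr) {
      fail <- runif(nrow(out)) < fdr_fail_rate
      out$fdr_score <- ifelse(fail, runif(nrow(out), 0.0100001, 1),
                              runif(nrow(out), 0, 0.01))
      attr(out, "n_fdr_fail") <- sum(fail)
    } else out$fdr_score <- NA_real_
  })
  rownames(out) <- NULL
  out
}

#' Generate a synthetic MaxQuant-style protein-group table
#'
#' One group per quantified protein with intensity equal to ppm times the
#' protein's observable peptide count times lognormal noise (so the
#' iBAQ-style pipeline recovers the input ppm up to noise), plus planted
#' `CON_` contaminant and `REV_` decoy rows whose count is recorded in the
#' `"n_planted_bad"` attribute.
#'
#' @param cfg a [sim_config()].
#' @param proteome the proteome.
#' @param ds the `abundance_dataset`.
#' @param noise_sd sd of log10 multiplicative noise (default 0.2).
#' @param n_contaminants,n_decoys planted `CON_` / `REV_` rows.
#' @param min_len,max_len observable window.
#' @return A protein-group `data.frame` (see [read_protein_groups()]).
#' @export
make_protein_groups <- function(cfg, proteome, ds, noise_sd = 0.2,
                                n_contaminants = 0L, n_decoys = 0L,
                                min_len = 6L, max_len = 30L) {
  counts <- vapply(proteome$sequence, function(s)
    observable_stats(s, min_len, max_len)$observable_count, numeric(1),
    USE.NAMES = FALSE)
  keep <- counts > 0
  ids <- proteome$internal_id[keep]
  with_seed(child_seed(cfg$seed, 5L), {
    good <- data.frame(
      group_id = ids, members = ids,
      intensity = unname(ds$ppm[ids]) * counts[keep] *
        10^rnorm(sum(keep), 0, noise_sd),
      stringsAsFactors = FALSE)
    bad_ids <- c(sprintf("CON_%03d", seq_len(n_contaminants)),
                 sprintf("REV_%03d", seq_len(n_decoys)))
    bad <- data.frame(group_id = bad_ids, members = bad_ids,
                      intensity = 10^rnorm(length(bad_ids), 3, 1),
                      stringsAsFactors = FALSE)
    out <- rbind(good, bad)
    out <- out[sample.int(nrow(out)), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "n_planted_bad") <- length(bad_ids)
    out
  })
}

#' Generate a synthetic ortholog set with a planted sulfur-depletion signal
#'
#' Builds `n_pairs` one-to-one ortholog pairs between a query species (ids
#' `taxid+1`) and a reference species (ids `taxid+2`). Each pair shares one
#' domain: a master domain sequence is generated with at least three
#' sulfur residues (C/M); the reference copy keeps each sulfur residue with
#' probability `base_retention`, while the query copy keeps it with
#' probability `base_retention * exp(-depletion_beta * rank/n)`, where rank
#' is the abundance rank of the reference protein (ascending). Removed
#' sulfur residues and a fraction `sub_rate` of the other positions are
#' substituted by random non-sulfur residues. Thus the expected log usage
#' ratio (query/reference) falls linearly with abundance rank at slope
#' `-depletion_beta`, with binomial noise on both counts; `beta = 0` plants
#' no signal. Optionally `n_low_identity` query domains are replaced by
#' unrelated random sequences (planted failures of the 40% identity filter),
#' and `n_complex` extra pairs are emitted with `one_to_one = FALSE`.
#'
#' @param cfg a [sim_config()] (`depletion_beta`, `abundance_*`, `taxid`,
#'   `aa_frequencies`, `seed` are used).
#' @param n_pairs number of one-to-one pairs (default 500).
#' @param domain_len domain length in residues (default 80).
#' @param flank residues flanking the domain on each side (default 10).
#' @param sub_rate substitution rate at non-sulfur positions (default 0.05).
#' @param base_retention baseline sulfur retention on both sides
#'   (default 0.9; gives the reference-side counts binomial noise too).
#' @param n_low_identity planted below-identity-filter pairs (default 0).
#' @param n_complex planted non-one-to-one pairs (default 0).
#' @return List: `pairs`, `domains_a`, `domains_b`, `proteome_a`,
#'   `proteome_b`, `abundance` (reference species), `planted` (per-pair
#'   rank and retention actually used).
#' @export
make_ortholog_set <- function(cfg, n_pairs = 500L, domain_len = 80L,
                              flank = 10L, sub_rate = 0.05,
                              base_retention = 0.9, n_low_identity = 0L,
                              n_complex = 0L) {
  sulfur <- c("C", "M")
  non_sulfur <- setdiff(AA20, sulfur)
  f <- cfg$aa_frequencies
  p_s <- sum(f[sulfur])
  n_tot <- n_pairs + n_complex
  with_seed(child_seed(cfg$seed, 6L), {
    raw <- 10^rnorm(n_tot, cfg$abundance_mu, cfg$abundance_sigma)
    rk <- rank(raw, ties.method = "first") / n_tot

    make_domain_pair <- function(i) {
      k <- max(3L, stats::rbinom(1L, domain_len, p_s))
      pos <- sample.int(domain_len, k)
      master <- sample(non_sulfur, domain_len, replace = TRUE,
                       prob = f[non_sulfur])
      master[pos] <- sample(sulfur, k, replace = TRUE,
                            prob = f[sulfur] / p_s)
      mutate <- function(retention) {
        s <- master
        is_s <- s %in% sulfur
        drop <- is_s & runif(domain_len) > retention
        sub <- !is_s & runif(domain_len) < sub_rate
        repl <- drop | sub
        s[repl] <- sample(non_sulfur, sum(repl), replace = TRUE)
        paste(s, collapse = "")
      }
      ra <- base_retention * exp(-cfg$depletion_beta * rk[i])
      list(a = mutate(ra), b = mutate(base_retention), retention_a = ra)
    }
    doms <- lapply(seq_len(n_tot), make_domain_pair)
    if (n_low_identity > 0L) {
      idx <- seq_len(min(n_low_identity, n_pairs))
      for (i in idx)
        doms[[i]]$a <- paste(sample(AA20, domain_len, replace = TRUE),
                             collapse = "")
    }
    rand_flank <- function() paste(sample(non_sulfur, flank, replace = TRUE),
                                   collapse = "")
    build <- function(side) vapply(doms, function(d)
      paste0(rand_flank(), d[[side]], rand_flank()), character(1))
    tax_a <- cfg$taxid + 1L; tax_b <- cfg$taxid + 2L
    id_a <- sprintf("%d.O%04d", tax_a, seq_len(n_tot))
    id_b <- sprintf("%d.O%04d", tax_b, seq_len(n_tot))
    proteome_a <- as_proteome(data.frame(internal_id = id_a,
                                         sequence = build("a"),
                                         stringsAsFactors = FALSE))
    proteome_b <- as_proteome(data.frame(internal_id = id_b,
                                         sequence = build("b"),
                                         stringsAsFactors = FALSE))
    dom_tab <- function(ids) data.frame(
      protein_id = ids, domain = "DOM1", start = flank + 1L,
      end = flank + domain_len, stringsAsFactors = FALSE)
    ds <- to_ppm(setNames(raw, id_b), organism = tax_b, method = "synthetic")
    list(
      pairs = data.frame(id_a = id_a, id_b = id_b,
                         one_to_one = c(rep(TRUE, n_pairs),
                                        rep(FALSE, n_complex)),
                         stringsAsFactors = FALSE),
      domains_a = dom_tab(id_a), domains_b = dom_tab(id_b),
      proteome_a = proteome_a, proteome_b = proteome_b,
      abundance = ds,
      planted = data.frame(id_a = id_a, id_b = id_b, rank = rk,
                           retention_a = vapply(doms, `[[`, numeric(1),
                                                "retention_a"),
                           stringsAsFactors = FALSE))
  })
}

#' Write a full set of synthetic inputs to a directory
#'
#' Materializes one synthetic study as files: proteome FASTA, peptide TSV,
#' network TSV, abundance TSV, ortholog-pair TSV and domain TSVs, plus a
#' JSON sidecar recording the config (including the seed).
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
simulate_inputs <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prot <- make_proteome(cfg)
  ds <- make_abundances(cfg, prot)
  net <- make_network(cfg, ds)
  peps <- make_peptide_table(cfg, prot, ds)
  orth <- make_ortholog_set(cfg, n_pairs = min(200L, max(10L, cfg$n_proteins)))
  p <- function(f) file.path(dir, f)
  write_fasta(prot, p("proteome.fasta"))
  write_abundance(ds, p("abundance.tsv"))
  write_network(net, p("network.tsv"))
  write.table(peps, p("peptides.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_fasta(orth$proteome_a, p("ortholog_query.fasta"))
  write_fasta(orth$proteome_b, p("ortholog_reference.fasta"))
  write.table(orth$pairs, p("orthologs.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(orth$domains_a, p("domains_query.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(orth$domains_b, p("domains_reference.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_abundance(orth$abundance, p("ortholog_abundance.tsv"))
  jsonlite::write_json(unclass(cfg), p("sim_config.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(vapply(c("proteome.fasta", "abundance.tsv", "network.tsv",
                     "peptides.tsv", "ortholog_query.fasta",
                     "ortholog_reference.fasta", "orthologs.tsv",
                     "domains_query.tsv", "domains_reference.tsv",
                     "ortholog_abundance.tsv", "sim_config.json"), p,
                   character(1)))
}
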