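# Independent oracles and small fixture builders used across the suite.

# Trypsin digestion by lookahead/lookbehind regex: split after K/R not
# followed by P. Independent of the package's scan-based implementation.
regex_digest <- function(seq) {
  strsplit(seq, "(?<=[KR])(?!P)", perl = TRUE)[[1]]
}

random_sequence <- function(len, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Exhaustive brute-force global alignment score: recursively enumerates
# every gapped alignment under the package's affine convention
# (gap of length L costs gap_open + (L-1)*gap_extend, end gaps charged).
# Exponential; only for short sequences.
brute_force_score <- function(a, b, submat, gap_open = 10, gap_extend = 0.5) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  na <- length(ca); nb <- length(cb)
  rec <- function(i, j, state) {
    if (i > na && j > nb) return(0)
    best <- -Inf
    if (i <= na && j <= nb)
      best <- max(best, submat[ca[i], cb[j]] + rec(i + 1L, j + 1L, 0L))
    if (i <= na)
      best <- max(best, -(if (state == 1L) gap_extend else gap_open) +
                    rec(i + 1L, j, 1L))
    if (j <= nb)
      best <- max(best, -(if (state == 2L) gap_extend else gap_open) +
                    rec(i, j + 1L, 2L))
    best
  }
  rec(1L, 1L, 0L)
}

# Score an alignment (two gapped strings) under the same convention;
# validates that a reported alignment actually achieves its score.
score_alignment <- function(al_a, al_b, submat, gap_open = 10,
                            gap_extend = 0.5) {
  ca <- strsplit(al_a, "")[[1]]
  cb <- strsplit(al_b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  total <- 0
  prev <- 0L  # 1 = gap in b, 2 = gap in a
  for (k in seq_along(ca)) {
    if (ca[k] == "-") {
      total <- total - (if (prev == 2L) gap_extend else gap_open)
      prev <- 2L
    } else if (cb[k] == "-") {
      total <- total - (if (prev == 1L) gap_extend else gap_open)
      prev <- 1L
    } else {
      total <- total + submat[ca[k], cb[k]]
      prev <- 0L
    }
  }
  total
}

blosum62_test <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

as_proteome_df <- function(ids, seqs)
  ppmkit:::as_proteome(data.frame(internal_id = ids, sequence = seqs,
                                  stringsAsFactors = FALSE))

# A tiny abundance dataset from explicit ppm shares (renormalized).
toy_dataset <- function(ppm) to_ppm(ppm)

# Three synthetic datasets of graded quality over one proteome: a clean one
# (ppm close to truth), a medium one, and a noisy one. The network is built
# to be consistent with the true abundances.
make_trio <- function(seed, n = 120, density = 0.04) {
  cfg <- sim_config(n_proteins = n, network_density = density,
                    edge_consistency = 4, seed = seed)
  prot <- make_proteome(cfg)
  truth <- make_abundances(cfg, prot)
  net <- make_network(cfg, truth)
  noisy_copy <- function(ds, sd_log, sub_seed) {
    ppm <- ppmkit:::with_seed(sub_seed,
      ds$ppm * 10^rnorm(length(ds$ppm), 0, sd_log))
    to_ppm(ppm, organism = ds$organism)
  }
  list(datasets = list(clean = noisy_copy(truth, 0.1, seed * 13 + 1),
                       medium = noisy_copy(truth, 0.6, seed * 13 + 2),
                       noisy = noisy_copy(truth, 1.5, seed * 13 + 3)),
       net = net, truth = truth)
}

# Straight-line reimplementation of the interaction z-score, kept
# deliberately plain (no shared helpers with the package).
straightline_zscore <- function(ppm, edges_a, edges_b, n_shuffles, seed) {
  ppm <- ppm[ppm > 0]
  lg <- log10(ppm)
  ia <- match(edges_a, names(lg)); ib <- match(edges_b, names(lg))
  ok <- !is.na(ia) & !is.na(ib)
  ia <- ia[ok]; ib <- ib[ok]
  obs <- median(abs(lg[ia] - lg[ib]))
  set.seed(as.integer(seed))
  meds <- numeric(n_shuffles)
  for (s in seq_len(n_shuffles)) {
    p <- sample.int(length(lg))
    meds[s] <- median(abs(lg[p[ia]] - lg[p[ib]]))
  }
  (mean(meds) - obs) / sd(meds)
}
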