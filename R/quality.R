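#' Construct / read a protein-interaction network
#'
#' A network is an undirected set of internal-id pairs used as the reference
#' for quality scoring. Self-loops are rejected; duplicate pairs (in either
#' orientation) are collapsed. The TSV form is a headerless two-column edge
#' list.
#'
#' @param a,b character vectors of endpoint ids (recycled pairwise).
#' @return A `data.frame` with columns `a`, `b` (class
#'   `"interaction_network"`), edges stored with `a < b`.
#' @export
interaction_network <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (any(a == b)) stop("self-loops are not allowed", call. = FALSE)
  lo <- pmin(a, b); hi <- pmax(a, b)
  edges <- unique(data.frame(a = lo, b = hi, stringsAsFactors = FALSE))
  rownames(edges) <- NULL
  class(edges) <- c("interaction_network", "data.frame")
  edges
}

#' @rdname interaction_network
#' @param path two-column TSV edge list (no header).
#' @export
read_network <- function(path) {
  df <- read.delim(path, header = FALSE, sep = "\t", quote = "",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("network file must have two columns", call. = FALSE)
  interaction_network(as.character(df[[1]]), as.character(df[[2]]))
}

#' @rdname interaction_network
#' @param net an `interaction_network`.
#' @export
write_network <- function(net, path) {
  write.table(net, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Interaction z-score: network-based dataset quality
#'
#' Interacting protein pairs tend to be expressed at similar abundances, so
#' the median absolute log10 abundance ratio over a dataset's interacting
#' pairs measures its internal consistency. The observed median is compared
#' to a null distribution obtained by shuffling the abundance values across
#' the quantified protein labels (network fixed) `n_shuffles` times:
#' `z = (mean(null) - observed) / sd(null)`, so that better-than-random
#' consistency (small observed median) gives a large positive z. Zero-ppm
#' proteins are excluded (their log ratio is undefined); only edges with
#' both endpoints quantified above zero are used. Deterministic given
#' `seed`, and invariant to rescaling all ppm by a constant and to the
#' logarithm base.
#'
#' @param ds an `abundance_dataset`.
#' @param net an `interaction_network`.
#' @param n_shuffles number of label shuffles for the null (default 500).
#' @param seed integer seed for the shuffles (required: scoring must be
#'   reproducible).
#' @param log_base base of the logarithm (default 10; the z-score is
#'   invariant to this choice, which the test suite asserts).
#' @return A list of class `"consistency_score"`: `z`, `observed_median`,
#'   `null_medians`, `n_pairs_used`, `n_shuffles`, `seed`.
#' @export
interaction_zscore <- function(ds, net, n_shuffles = 500L, seed,
                               log_base = 10) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  ppm <- ds$ppm[ds$ppm > 0]
  if (length(ppm) < 2L)
    stop("need at least two proteins with positive ppm", call. = FALSE)
  lg <- log(ppm, base = log_base)
  ia <- match(net$a, names(lg))
  ib <- match(net$b, names(lg))
  use <- !is.na(ia) & !is.na(ib)
  if (!any(use)) stop("network does not overlap dataset", call. = FALSE)
  ia <- ia[use]; ib <- ib[use]
  observed <- median(abs(lg[ia] - lg[ib]))
  nulls <- with_seed(seed, vapply(seq_len(n_shuffles), function(s) {
    p <- sample.int(length(lg))
    median(abs(lg[p[ia]] - lg[p[ib]]))
  }, numeric(1)))
  s <- sd(nulls)
  if (s == 0) stop("degenerate null (all shuffled medians identical)",
                   call. = FALSE)
  structure(list(z = (mean(nulls) - observed) / s,
                 observed_median = observed, null_medians = nulls,
                 n_pairs_used = length(ia), n_shuffles = n_shuffles,
                 seed = seed),
            class = "consistency_score")
}

#' @export
print.consistency_score <- function(x, ...) {
  cat(sprintf("interaction z-score: %.3f (observed median |log10 ratio| %.4f over %d pairs, %d shuffles, seed %s)\n",
              x$z, x$observed_median, x$n_pairs_used, x$n_shuffles,
              format(x$seed)))
  invisible(x)
}

#' Tissue-specificity z-scores
#'
#' For each gene (row), abundances are log10-transformed after adding a
#' pseudocount and standardized across tissues:
#' `z = (x - mean(x)) / sd(x)` with the usual n-1 denominator. A gene that
#' is constant across tissues has undefined sd; its row is returned as all
#' zeros and flagged in the `"constant_genes"` attribute.
#'
#' @param mat numeric gene x tissue matrix of ppm values (rownames = genes).
#' @param pseudocount added before the log (default 1 ppm).
#' @return Matrix of z-scores, same dimensions and dimnames.
#' @export
tissue_specificity_zscore <- function(mat, pseudocount = 1) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) stop("need at least two tissues", call. = FALSE)
  x <- log10(mat + pseudocount)
  mu <- rowMeans(x)
  sdv <- apply(x, 1L, sd)
  flat <- sdv < .Machine$double.eps^0.5
  sdv[flat] <- 1  # sd floor: constant rows become all-zero z
  z <- (x - mu) / sdv
  z[flat, ] <- 0
  attr(z, "constant_genes") <- rownames(mat)[flat]
  z
}
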